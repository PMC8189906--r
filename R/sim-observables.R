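# Derived observables: coverage tracks, Hi-C interaction draws,
# gametologue CDS pairs and base-evidence chains, all with known truth.

#' Simulate female/male per-window coverage tracks
#'
#' Emulates mapping a female (XX) and a male (XY) short-read sample onto the
#' F1 assembly: per-window read counts are Poisson.  With both samples at
#' the same genome-wide (autosomal, two-copy) depth D, the female draws
#' rate D on autosomes, X and PAR and a configurable noise floor on Y
#' (mismapping surrogate, default 0); the male draws D on autosomes and
#' PAR and D/2 on each of X and Y (single copy).
#'
#' @param truth a [simulate_trio_genomes()] result, or directly a layout
#'   data.frame with columns `chrom`, `length`, `class` and optionally
#'   `par_bp` (for a class-Y scaffold, the length of a leading
#'   pseudoautosomal block drawing diploid coverage in both sexes)
#' @param female_depth,male_depth genome-wide mean depths (> 0)
#' @param window_bp window size in bp (> 0, at most the smallest chromosome)
#' @param seed integer seed (substream `"coverage"`)
#' @param noise_floor mean female depth on Y windows (mismapping surrogate)
#' @return data.table: chrom, start, end, class (per-window truth,
#'   `"PAR"` inside a leading pseudoautosomal block), female_depth,
#'   male_depth
#' @export
simulate_coverage_tracks <- function(truth, female_depth, male_depth,
                                     window_bp, seed, noise_floor = 0) {
  layout <- if (inherits(truth, "trio_truth")) truth$layout else
    as.data.frame(truth, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "length", "class") %in% names(layout)))
  if (window_bp <= 0) stop("window_bp must be > 0")
  if (female_depth <= 0 || male_depth <= 0) stop("depths must be > 0")
  if (window_bp > min(layout$length))
    stop("window_bp larger than the smallest chromosome (window error)")

  rate_f <- c(autosome = female_depth, X = female_depth, PAR = female_depth,
              Y = noise_floor)
  rate_m <- c(autosome = male_depth, X = male_depth / 2, PAR = male_depth,
              Y = male_depth / 2)

  with_substream(seed, "coverage", {
    rows <- lapply(seq_len(nrow(layout)), function(i) {
      L <- layout$length[i]
      starts <- seq(0L, L - 1L, by = window_bp)
      ends <- pmin(starts + window_bp, L)
      w <- ends - starts
      cls <- rep(layout$class[i], length(starts))
      par_bp <- if ("par_bp" %in% names(layout)) layout$par_bp[i] else 0
      if (isTRUE(par_bp > 0) && layout$class[i] == "Y")
        cls[starts < par_bp] <- "PAR"
      f <- rpois(length(starts), rate_f[cls] * w) / w
      m <- rpois(length(starts), rate_m[cls] * w) / w
      data.table::data.table(chrom = layout$chrom[i], start = starts,
                             end = ends, class = cls,
                             female_depth = f, male_depth = m)
    })
    data.table::rbindlist(rows)
  })
}

#' Simulate Hi-C interaction strengths for unplaced scaffolds
#'
#' For each scaffold, draws two vectors of interaction strengths: one
#' toward autosomes/X bins and one toward Y bins, both lognormal
#' (meanlog 0, sdlog 0.5, the rough shape of normalized contact counts);
#' for truly Y-linked scaffolds the Y-directed strengths are multiplied
#' by `bias` (>= 1).  Scaffolds with five or fewer values on
#' either side are flagged below the usability threshold.
#'
#' @param scaffold_spec data.frame with columns `scaffold` and `y_linked`
#'   (logical truth)
#' @param bias multiplier (>= 1) on Y-directed strengths of truly Y-linked
#'   scaffolds; 1 is the null
#' @param n_values number of interaction values per vector (>= 0); either a
#'   single count or one per scaffold
#' @param seed integer seed (substream `"hic"`)
#' @return data.table: scaffold, y_linked (truth), target
#'   (`"autosome_x"`/`"y"`), strength, usable (more than five values on
#'   both sides)
#' @export
simulate_hic_interactions <- function(scaffold_spec, bias, n_values, seed) {
  spec <- as.data.frame(scaffold_spec, stringsAsFactors = FALSE)
  stopifnot(all(c("scaffold", "y_linked") %in% names(spec)))
  if (any(n_values < 0)) stop("n_values must be >= 0")
  if (bias < 1) stop("bias must be >= 1")
  n_values <- rep_len(n_values, nrow(spec))
  with_substream(seed, "hic", {
    rows <- lapply(seq_len(nrow(spec)), function(i) {
      n <- n_values[i]
      if (n == 0L) return(NULL)
      s_aut <- stats::rlnorm(n, 0, 0.5)
      s_y <- stats::rlnorm(n, 0, 0.5) * if (spec$y_linked[i]) bias else 1
      usable <- n > 5L
      data.table::data.table(
        scaffold = spec$scaffold[i], y_linked = spec$y_linked[i],
        target = rep(c("autosome_x", "y"), each = n),
        strength = c(s_aut, s_y), usable = usable)
    })
    data.table::rbindlist(rows)
  })
}

# codons whose third position is fourfold degenerate and whose first and
# second positions are always non-synonymous under single changes
.SYN_CODON_PREFIX <- c("GG", "GC", "CC", "AC", "GT", "TC")

#' Simulate X-Y gametologue CDS pairs with planted synonymous divergence
#'
#' Builds in-frame CDS from codons whose third position is fourfold
#' degenerate, then substitutes third positions on the Y copy with
#' per-site probability p = 3/4 (1 - exp(-4/3 dS)), so the Nei-Gojobori
#' estimate of dS converges to the planted value as the CDS grows.  X
#' positions are assigned monotonically by stratum (row order of
#' `strata_spec` = position order along the X).
#'
#' @param strata_spec data.frame with columns `stratum`, `n_pairs`, `ds`
#'   (planted synonymous divergence, >= 0)
#' @param cds_length CDS length in bp (multiple of 3)
#' @param seed integer seed (substream `"gametologues"`)
#' @return data.table: gene, stratum (truth), ds_true, x_pos (bp), x_cds,
#'   y_cds
#' @export
simulate_gametologue_pairs <- function(strata_spec, cds_length, seed) {
  spec <- as.data.frame(strata_spec, stringsAsFactors = FALSE)
  stopifnot(all(c("stratum", "n_pairs", "ds") %in% names(spec)))
  if (cds_length %% 3 != 0) stop("cds_length must be a multiple of 3")
  if (any(spec$ds < 0)) stop("planted dS must be >= 0")
  if (any(spec$ds > 3))
    stop("planted dS ", max(spec$ds), " saturates the estimator for this ",
         "cds_length (parameter error)")
  n_codon <- cds_length %/% 3L
  with_substream(seed, "gametologues", {
    rows <- list()
    pos_cursor <- 0
    for (i in seq_len(nrow(spec))) {
      p_sub <- 0.75 * (1 - exp(-4 / 3 * spec$ds[i]))
      for (j in seq_len(spec$n_pairs[i])) {
        pre <- sample(.SYN_CODON_PREFIX, n_codon, replace = TRUE)
        third_x <- sample(DNA_BASES, n_codon, replace = TRUE)
        x_cds <- paste0(pre, third_x, collapse = "")
        hit <- runif(n_codon) < p_sub
        third_y <- third_x
        if (any(hit)) {
          third_y[hit] <- vapply(third_x[hit], function(b)
            sample(DNA_BASES[DNA_BASES != b], 1L), character(1))
        }
        y_cds <- paste0(pre, third_y, collapse = "")
        pos_cursor <- pos_cursor + 1e6 + floor(runif(1, 0, 5e5))
        rows[[length(rows) + 1L]] <- data.table::data.table(
          gene = sprintf("%s_g%d", spec$stratum[i], j),
          stratum = spec$stratum[i], ds_true = spec$ds[i],
          x_pos = pos_cursor, x_cds = x_cds, y_cds = y_cds)
      }
    }
    data.table::rbindlist(rows)
  })
}

#' Simulate base-evidence chains with planted error classes
#'
#' Each site carries a true class (`true_variant`, `sequencing_error` or
#' `polishing_error`) and its canonical chain of consensus bases: raw-read,
#' corrected-read, pre-polish assembly, post-polish assembly, short-read.
#' Every observed entry is the underlying base unless the consensus of
#' `depth` reads at per-base error `base_error` fails (majority miscall),
#' in which case a random other base is recorded.
#'
#' @param n_sites number of sites
#' @param class_probs named probabilities for the three classes (summing
#'   to 1)
#' @param depth consensus read depth
#' @param base_error per-base miscall probability
#' @param seed integer seed (substream `"chains"`)
#' @return data.table: site, truth_class, raw, corrected, pre, post, short
#' @export
simulate_evidence_chains <- function(n_sites,
                                     class_probs = c(true_variant = 0.6,
                                                     sequencing_error = 0.2,
                                                     polishing_error = 0.2),
                                     depth = 30, base_error = 1e-3,
                                     seed = 1L) {
  stopifnot(abs(sum(class_probs) - 1) < 1e-8)
  with_substream(seed, "chains", {
    cls <- sample(names(class_probs), n_sites, replace = TRUE,
                  prob = class_probs)
    truth_base <- sample(DNA_BASES, n_sites, replace = TRUE)
    wrong <- vapply(truth_base, function(b)
      sample(DNA_BASES[DNA_BASES != b], 1L), character(1))
    t <- truth_base; w <- wrong
    chain <- data.table::data.table(site = seq_len(n_sites), truth_class = cls,
                                    raw = t, corrected = t, pre = t,
                                    post = t, short = t)
    seq_i <- cls == "sequencing_error"
    chain[seq_i, c("raw", "pre", "post") :=
            list(w[seq_i], w[seq_i], w[seq_i])]
    pol_i <- cls == "polishing_error"
    chain[pol_i, post := w[pol_i]]
    # consensus miscall: majority of depth reads wrong
    p_flip <- stats::pbinom(floor(depth / 2), depth, 1 - base_error)
    for (col in c("raw", "corrected", "pre", "post", "short")) {
      flip <- runif(n_sites) < p_flip
      if (any(flip)) {
        cur <- chain[[col]][flip]
        chain[flip, (col) := vapply(cur, function(b)
          sample(DNA_BASES[DNA_BASES != b], 1L), character(1))]
      }
    }
    chain
  })
}
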