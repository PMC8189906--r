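# Per-site trio genotype tables rendered against each haplotype assembly.
#
# Site-level rendering assumes a colinear trio configuration (planted SNVs,
# ROH and DNMs but no indels/SVs), so that a position means the same site on
# both references and the lift-over between them is the identity.  The
# structural variant classes are exercised through the whole-genome
# alignment route instead.

# genotype caller: maximum binomial likelihood over alt-allele dosage
# {0, 1, 2} with per-read alt probabilities {e, 1/2, 1 - e}.  Returns a
# lookup table over all (depth, alt) pairs up to max_depth, mapping to the
# called dosage and a genotype-quality proxy (scaled log-likelihood ratio
# between the best and second-best dosage, capped at 99).
.gt_lookup <- function(max_depth, base_error) {
  e <- max(base_error, 1e-3)   # caller's error floor
  d <- rep(0:max_depth, times = 0:max_depth + 1L)
  a <- unlist(lapply(0:max_depth, function(k) 0:k))
  ll <- cbind(dbinom(a, d, e, log = TRUE),
              dbinom(a, d, 0.5, log = TRUE),
              dbinom(a, d, 1 - e, log = TRUE))
  best <- max.col(ll)
  ll_sorted <- t(apply(ll, 1, sort, decreasing = TRUE))
  gq <- pmin(99L, as.integer(round((ll_sorted[, 1] - ll_sorted[, 2]) *
                                     10 / log(10))))
  gt <- as.integer(best - 1L)
  gt[d == 0L] <- NA_integer_
  gq[d == 0L] <- 0L
  list(gt = gt, gq = gq,
       index = function(dd, aa) (dd * (dd + 1L)) %/% 2L + aa + 1L)
}

# render one individual's calls at n sites given true alt dosage
.render_individual <- function(dosage, depth_mean, base_error, lut) {
  n <- length(dosage)
  d <- rpois(n, depth_mean)
  maxd <- as.integer((sqrt(8 * length(lut$gt) + 1) - 3) / 2)
  d[d > maxd] <- maxd  # clamp the negligible tail beyond the lookup table
  p <- c(base_error, 0.5, 1 - base_error)[dosage + 1L]
  a <- rbinom(n, d, p)
  idx <- lut$index(d, a)
  list(dp = d, ad = a, gt = lut$gt[idx], gq = lut$gq[idx])
}

#' Render per-site trio genotype tables on both parental references
#'
#' For each reference (the child's maternal- and paternal-inherited
#' haplotype assemblies) every site carries the mother's, father's and
#' child's called genotype (alt-allele dosage 0, 1, 2 or `NA` for missing),
#' per-allele depths and a genotype-quality proxy.  A maternal DNM renders
#' on the paternal reference as parents 0/0 with a 0/1 child, and on the
#' maternal reference as parents 1/1 with a 0/1 child, because the maternal
#' assembly (built from the child's reads) carries the mutant base as its
#' reference allele.
#'
#' @param truth a [simulate_trio_genomes()] result with no planted
#'   indels/SVs (colinear references)
#' @param depth_mean mean depth per individual per site (> 0)
#' @param base_error per-base miscall probability, in `[0, 0.25)`
#' @param seed integer seed (substream `"site_calls"`)
#' @param pileup also emit per-site base-depth pileup tables (A/C/G/T
#'   counts); off by default because the genotype tables carry all the
#'   information the trio pipeline needs
#' @return list with elements `maternal` and `paternal`, each a data.table
#'   with columns chrom, pos (0-based), gt_m/gt_f/gt_c (dosages), dp_*,
#'   ad_* (alt-allele depth), gq_*; if `pileup = TRUE` also `pileup_maternal`
#'   and `pileup_paternal` with columns chrom, pos, A, C, G, T.
#' @export
simulate_site_calls <- function(truth, depth_mean, base_error, seed,
                                pileup = FALSE) {
  stopifnot(inherits(truth, "trio_truth"))
  if (depth_mean <= 0) stop("depth_mean must be > 0")
  if (base_error < 0 || base_error >= 0.25)
    stop("base_error must lie in [0, 0.25) (genotype model degenerate)")
  structural <- truth$variants$class %in%
    c("small_indel", "large_indel", "inversion", "translocation", "CNV",
      "inverted_translocation")
  if (any(structural))
    stop("simulate_site_calls requires a colinear trio ",
         "(no planted indels/SVs); got structural truth records")

  with_substream(seed, "site_calls", {
    maxd <- max(as.integer(stats::qpois(1 - 1e-12, depth_mean)), 10L)
    lut <- .gt_lookup(maxd, base_error)
    out <- list()
    for (ref in c("maternal", "paternal")) {
      tabs <- lapply(truth$layout$chrom, function(ch) {
        L <- truth$layout$length[truth$layout$chrom == ch]
        dos_m <- integer(L)   # alt dosage of mother relative to this ref
        dos_f <- integer(L)
        dos_c <- integer(L)
        v <- truth$variants[truth$variants$class == "SNV" &
                              truth$variants$ref_chrom == ch, ]
        if (nrow(v)) {
          i <- v$ref_start + 1L
          if (ref == "maternal") { dos_f[i] <- 2L } else { dos_m[i] <- 2L }
          dos_c[i] <- 1L
        }
        dn <- truth$dnms[truth$dnms$chrom == ch, ]
        if (nrow(dn)) {
          carrier_is_ref <- (dn$parent == "maternal") == (ref == "maternal")
          i <- dn$pos_mat + 1L
          # carrier reference holds the mutant base: parents are hom-alt
          ci <- i[carrier_is_ref]
          dos_m[ci] <- 2L; dos_f[ci] <- 2L; dos_c[ci] <- 1L
          # other reference holds the ancestral base: parents hom-ref
          oi <- i[!carrier_is_ref]
          dos_m[oi] <- 0L; dos_f[oi] <- 0L; dos_c[oi] <- 1L
        }
        m <- .render_individual(dos_m, depth_mean, base_error, lut)
        f <- .render_individual(dos_f, depth_mean, base_error, lut)
        cc <- .render_individual(dos_c, depth_mean, base_error, lut)
        data.table::setDT(list(chrom = rep(ch, L), pos = 0:(L - 1L),
                               gt_m = m$gt, gt_f = f$gt, gt_c = cc$gt,
                               dp_m = m$dp, dp_f = f$dp, dp_c = cc$dp,
                               ad_m = m$ad, ad_f = f$ad, ad_c = cc$ad,
                               gq_m = m$gq, gq_f = f$gq, gq_c = cc$gq))
      })
      out[[ref]] <- data.table::rbindlist(tabs)
      if (pileup) {
        tab <- out[[ref]]
        refseq <- truth$child[[if (ref == "maternal") "mat" else "pat"]]
        out[[paste0("pileup_", ref)]] <- .render_pileup(tab, refseq, truth)
      }
    }
    out
  })
}

# child-sample pileup: reference-allele and alt-allele depths mapped onto
# actual bases; remaining depth given the reference base
.render_pileup <- function(tab, refseq, truth) {
  base_cols <- c(A = 0L, C = 0L, G = 0L, T = 0L)
  chunks <- lapply(unique(tab$chrom), function(ch) {
    t2 <- tab[tab$chrom == ch, ]
    rb <- seq_chars(refseq[[ch]])[t2$pos + 1L]
    counts <- matrix(0L, nrow = nrow(t2), ncol = 4,
                     dimnames = list(NULL, names(base_cols)))
    ridx <- match(rb, names(base_cols))
    refdp <- t2$dp_c - t2$ad_c
    counts[cbind(seq_len(nrow(t2)), ridx)] <- refdp
    alt <- t2$ad_c > 0L
    if (any(alt)) {
      # alternative allele: a fixed different base per site (cycled)
      aidx <- (ridx[alt] %% 4L) + 1L
      counts[cbind(which(alt), aidx)] <- t2$ad_c[alt]
    }
    data.table::data.table(chrom = ch, pos = t2$pos,
                           A = counts[, "A"], C = counts[, "C"],
                           G = counts[, "G"], T = counts[, "T"])
  })
  data.table::rbindlist(chunks)
}
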