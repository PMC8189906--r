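# Sex-linked sequence identification: peak normalization of coverage,
# F/M ratio window classification, per-scaffold calls with PAR awareness,
# Hi-C interaction rescue of Y scaffolds, and longest-rule de-collapse.

#' Peak-normalize a per-window depth track
#'
#' Divides every window by the modal ("peak") per-window depth, estimated
#' as the midpoint of the highest bin of a histogram whose bin width is 5%
#' of the median depth.  After normalization the modal copy state sits at
#' 1, so the female-to-male ratio is comparable between samples sequenced
#' at different depths.
#'
#' @param depth numeric vector of per-window depths (at least one nonzero)
#' @return list: `normalized` (depth / peak), `peak`
#' @export
normalize_coverage <- function(depth) {
  if (all(depth == 0)) stop("all-zero track cannot be normalized")
  med <- median(depth[depth > 0])
  bw <- 0.05 * med
  if (bw <= 0) stop("degenerate track: zero median depth")
  nz <- depth[depth > 0]
  bins <- floor(nz / bw)
  tab <- table(bins)
  peak_bin <- as.numeric(names(tab)[which.max(tab)])
  peak <- (peak_bin + 0.5) * bw
  list(normalized = depth / peak, peak = peak)
}

#' Classify windows by normalized female/male coverage ratio
#'
#' The F/M ratio per window is normalized female depth over normalized
#' male depth; windows with ratio inside `x_range` (default 1.5-2.5) are
#' X-linked, inside `y_range` (default 0.0-0.3) Y-linked, anything else
#' unassigned.  Zero-male windows use a pseudocount of one read-equivalent
#' (1/peak on the normalized scale) in the denominator and the ratio is
#' capped at 10.
#'
#' @param female,male data.frames with columns `chrom`, `start`, `end`,
#'   `depth` (raw per-window depth), identical windows in both
#' @param x_range,y_range inclusive ratio ranges
#' @param cap ratio cap
#' @return data.table: chrom, start, end, female_norm, male_norm, ratio,
#'   window_class in `{"X", "Y", "unassigned"}`
#' @export
classify_windows <- function(female, male, x_range = c(1.5, 2.5),
                             y_range = c(0.0, 0.3), cap = 10) {
  female <- as.data.frame(female); male <- as.data.frame(male)
  if (nrow(female) != nrow(male) ||
      !all(female$chrom == male$chrom & female$start == male$start))
    stop("female and male tracks must share identical windows")
  nf <- normalize_coverage(female$depth)
  nm <- normalize_coverage(male$depth)
  pseudo <- 1 / nm$peak   # one read-equivalent on the normalized scale
  ratio <- ifelse(nm$normalized > 0,
                  nf$normalized / nm$normalized,
                  nf$normalized / (nm$normalized + pseudo))
  ratio <- pmin(ratio, cap)
  cls <- rep("unassigned", nrow(female))
  cls[ratio >= x_range[1] & ratio <= x_range[2]] <- "X"
  cls[ratio >= y_range[1] & ratio <= y_range[2]] <- "Y"
  data.table::data.table(chrom = female$chrom, start = female$start,
                         end = female$end, female_norm = nf$normalized,
                         male_norm = nm$normalized, ratio = ratio,
                         window_class = cls)
}

#' Call per-scaffold sex linkage with PAR awareness
#'
#' A scaffold is called X or Y when at least `majority` of its windows
#' share that class.  A terminal block of at least `par_min_run`
#' consecutive unassigned windows with ratio near 1 (within `par_band`)
#' on an otherwise-Y scaffold is annotated as a pseudoautosomal region
#' (PAR) and removed from the denominator rather than defeating the Y
#' call, mirroring a Y scaffold whose leading megabase shows equal female
#' and male coverage.
#'
#' @param windows output of [classify_windows()]
#' @param majority window-majority fraction required for a call
#' @param min_windows minimum windows per scaffold for any call
#' @param par_min_run minimum consecutive near-1 windows for a PAR block
#' @param par_band inclusive ratio band treated as "equal coverage"
#' @return data.table: chrom, n_windows, call in `{"X", "Y", "no_call"}`
#'   (autosomes fall to `no_call`: no sex class reaches the majority),
#'   par_annotated, par_start, par_end, reason
#' @export
call_scaffold_linkage <- function(windows, majority = 0.8,
                                  min_windows = 10L, par_min_run = 25L,
                                  par_band = c(0.75, 1.25)) {
  windows <- data.table::as.data.table(windows)
  out <- lapply(split(windows, windows$chrom), function(w) {
    w <- w[order(w$start), ]
    n <- nrow(w)
    if (n < min_windows)
      return(data.table::data.table(chrom = w$chrom[1], n_windows = n,
                                    call = "no_call", par_annotated = FALSE,
                                    par_start = NA_integer_,
                                    par_end = NA_integer_,
                                    reason = "fewer than min_windows windows"))
    class_call <- function(wc) {
      frac <- table(factor(wc, c("X", "Y", "unassigned"))) / length(wc)
      if (frac[["X"]] >= majority) "X"
      else if (frac[["Y"]] >= majority) "Y"
      else "no_call"
    }
    call <- class_call(w$window_class)
    par_idx <- integer(0)
    if (call != "Y") {
      # a terminal near-1 block may be a PAR masking an otherwise-Y
      # scaffold; trimming it must yield a Y call to count
      near1 <- w$window_class == "unassigned" &
        w$ratio >= par_band[1] & w$ratio <= par_band[2]
      lead <- if (all(near1)) n else which.min(near1) - 1L
      trail <- if (all(near1)) n else n - which.min(rev(near1)) + 1L
      cand_idx <- if (lead >= par_min_run && lead < n) seq_len(lead)
        else if (n - trail + 1L >= par_min_run && trail > 1L) trail:n
        else integer(0)
      if (length(cand_idx) &&
          class_call(w$window_class[-cand_idx]) == "Y") {
        call <- "Y"
        par_idx <- cand_idx
      }
    }
    par_ok <- length(par_idx) > 0L
    data.table::data.table(chrom = w$chrom[1], n_windows = n, call = call,
                           par_annotated = par_ok,
                           par_start = if (par_ok) min(w$start[par_idx])
                                       else NA_integer_,
                           par_end = if (par_ok) max(w$end[par_idx])
                                     else NA_integer_,
                           reason = if (call == "no_call")
                             "no class reaches the majority" else NA_character_)
  })
  data.table::rbindlist(out)
}

#' Rescue Y-linked scaffolds from Hi-C interaction strengths
#'
#' For each unplaced scaffold with more than `min_values` interaction
#' strengths to both the autosomes/X and the Y, compares the two strength
#' vectors by a two-sided Wilcoxon rank-sum test; p-values are
#' Benjamini-Hochberg corrected across tested scaffolds and a scaffold is
#' rescued as Y-linked iff its FDR-adjusted q is below `q_cut` and its
#' median Y strength exceeds its median autosome/X strength.
#'
#' @param interactions data.frame with columns `scaffold`, `target`
#'   (`"autosome_x"` or `"y"`), `strength`
#' @param q_cut FDR threshold (default 0.01)
#' @param min_values strict minimum count per side (default 5; a scaffold
#'   with exactly 5 values is excluded)
#' @return data.table: scaffold, n_aut, n_y, median_aut, median_y, p, q,
#'   tested, rescued
#' @export
hic_rescue <- function(interactions, q_cut = 0.01, min_values = 5L) {
  it <- data.table::as.data.table(interactions)
  stopifnot(all(c("scaffold", "target", "strength") %in% names(it)))
  per <- lapply(split(it, it$scaffold), function(d) {
    a <- d$strength[d$target == "autosome_x"]
    y <- d$strength[d$target == "y"]
    tested <- length(a) > min_values && length(y) > min_values
    p <- if (tested)
      suppressWarnings(wilcox.test(y, a, alternative = "two.sided")$p.value)
    else NA_real_
    data.table::data.table(scaffold = d$scaffold[1],
                           n_aut = length(a), n_y = length(y),
                           median_aut = if (length(a)) median(a) else NA_real_,
                           median_y = if (length(y)) median(y) else NA_real_,
                           p = p, tested = tested)
  })
  res <- data.table::rbindlist(per)
  res$q <- NA_real_
  res$q[res$tested] <- p.adjust(res$p[res$tested], method = "BH")
  res$rescued <- res$tested & !is.na(res$q) & res$q < q_cut &
    res$median_y > res$median_aut
  res
}

#' Reconstruct a collapsed region by the longest rule
#'
#' Iteratively selects the de-collapsed candidate contig with the longest
#' match to the backbone that does not overlap any previously selected
#' interval (ties broken by earlier backbone start), orders the selected
#' contigs by backbone position, fills unselected backbone stretches from
#' the backbone itself, and places a gap of exactly 1,000 `N` between
#' consecutive placed contigs.
#'
#' @param backbone backbone scaffold sequence (character string)
#' @param candidates data.frame with columns `id`, `seq` (contig
#'   sequence), `start`, `end` (mapped backbone interval, 0-based
#'   half-open), `match_len` (length of the backbone match)
#' @param gap_n number of N characters between adjacent placed contigs
#' @return list: `sequence` (reconstructed scaffold), `selected`
#'   (data.frame of placed candidates in backbone order)
#' @export
longest_rule_decollapse <- function(backbone, candidates, gap_n = 1000L) {
  cand <- as.data.frame(candidates, stringsAsFactors = FALSE)
  if (nrow(cand) == 0L)
    return(list(sequence = backbone,
                selected = cand[, intersect(c("id", "start", "end",
                                              "match_len"), names(cand))]))
  stopifnot(all(c("id", "seq", "start", "end", "match_len") %in% names(cand)))
  if (anyDuplicated(cand$id)) stop("duplicate candidate ids (input error)")
  if (any(cand$start < 0) || any(cand$end > nchar(backbone)) ||
      any(cand$start >= cand$end))
    stop("candidate interval outside backbone bounds")
  if (any(cand$match_len > cand$end - cand$start))
    stop("match length exceeds its backbone interval")
  selected <- integer(0)
  remaining <- seq_len(nrow(cand))
  while (length(remaining)) {
    ord <- remaining[order(-cand$match_len[remaining],
                           cand$start[remaining])]
    pick <- ord[1]
    selected <- c(selected, pick)
    ok <- vapply(remaining, function(i)
      cand$end[i] <= cand$start[pick] | cand$start[i] >= cand$end[pick],
      logical(1))
    remaining <- setdiff(remaining[ok], pick)
  }
  sel <- cand[selected[order(cand$start[selected])], , drop = FALSE]
  pieces <- character(0)
  cursor <- 0L
  for (i in seq_len(nrow(sel))) {
    if (sel$start[i] > cursor)
      pieces <- c(pieces, substr(backbone, cursor + 1L, sel$start[i]))
    if (i > 1L) pieces <- c(pieces, strrep("N", gap_n))
    pieces <- c(pieces, sel$seq[i])
    cursor <- sel$end[i]
  }
  if (cursor < nchar(backbone))
    pieces <- c(pieces, substr(backbone, cursor + 1L, nchar(backbone)))
  list(sequence = paste(pieces, collapse = ""),
       selected = sel[, c("id", "start", "end", "match_len")])
}
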