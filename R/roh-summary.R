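# Runs of homozygosity and the full-spectrum heterozygosity summary.

#' Detect runs of homozygosity from SNV positions
#'
#' Tiles each chromosome into `scan_window` windows, flags windows whose
#' SNV density falls below `density_cutoff` (default: 5% of the
#' genome-wide mean SNV density; zero-SNV windows always qualify), merges
#' adjacent flagged windows, and reports merged intervals of at least
#' `min_length` bp.
#'
#' @param snvs data.frame with columns `chrom` and `pos` (0-based),
#'   sorted per chromosome
#' @param chrom_lengths named numeric vector of chromosome lengths
#' @param scan_window scan window (bp, > 0)
#' @param density_cutoff SNVs per bp below which a window is homozygous;
#'   `NULL` uses 5% of the genome-wide mean density
#' @param min_length minimum reported interval (bp, default 1 Mb)
#' @return data.table: chrom, start, end, length; non-overlapping, sorted
#' @export
detect_roh <- function(snvs, chrom_lengths, scan_window = 1e5,
                       density_cutoff = NULL, min_length = 1e6) {
  if (scan_window <= 0) stop("scan_window must be > 0 (parameter error)")
  snvs <- as.data.frame(snvs)
  stopifnot(all(c("chrom", "pos") %in% names(snvs)),
            !is.null(names(chrom_lengths)))
  mean_density <- nrow(snvs) / sum(chrom_lengths)
  cutoff <- density_cutoff %||% (0.05 * mean_density)
  out <- lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    starts <- seq(0, L - 1, by = scan_window)
    ends <- pmin(starts + scan_window, L)
    pos <- snvs$pos[snvs$chrom == ch]
    counts <- if (length(pos))
      tabulate(floor(pos / scan_window) + 1L, nbins = length(starts))
    else integer(length(starts))
    flagged <- counts == 0L | counts / (ends - starts) < cutoff
    if (!any(flagged)) return(NULL)
    r <- rle(flagged)
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    keep <- which(r$values)
    iv <- data.table::data.table(chrom = ch,
                                 start = starts[run_start[keep]],
                                 end = ends[run_end[keep]])
    iv$length <- iv$end - iv$start
    iv[iv$length >= min_length, ]
  })
  res <- data.table::rbindlist(Filter(Negate(is.null), out))
  if (nrow(res) == 0L)
    return(data.table::data.table(chrom = character(), start = numeric(),
                                  end = numeric(), length = numeric()))
  data.table::setorder(res, chrom, start)
  res[]
}

#' Summarize the full spectrum of heterozygosity
#'
#' The SNV-only rate is the SNV count over the aligned length; the
#' overall rate counts every heterozygous base: one per SNV plus the full
#' length of each indel and SV (counted once regardless of which
#' haplotype carries the extra bases).  Optional per-window density
#' tracks use a 500-kb window for SNVs and a 1-Mb window for large
#' indels and CNVs (event counts).
#'
#' @param variants data.table of variant records (needs `class`,
#'   `ref_chrom`, `ref_start`, `length`)
#' @param aligned_length aligned bases used as the denominator (> 0); by
#'   convention the maternal-side aligned length
#' @param chrom_lengths optional named vector enabling density tracks and
#'   coordinate checks
#' @param snv_window,sv_window density window sizes (bp)
#' @param roh optional ROH table ([detect_roh()]) carried into the
#'   summary
#' @return object of class `het_summary`: list with `counts` (per
#'   class), `snv_rate_percent`, `overall_rate_percent`, `het_bases`,
#'   `aligned_length`, `densities` (list of data.tables or NULL), `roh`
#' @export
summarize_heterozygosity <- function(variants, aligned_length,
                                     chrom_lengths = NULL,
                                     snv_window = 5e5, sv_window = 1e6,
                                     roh = NULL) {
  if (aligned_length <= 0) stop("aligned length must be > 0")
  v <- data.table::as.data.table(variants)
  if (!is.null(chrom_lengths) && nrow(v)) {
    bad <- !(v$ref_chrom %in% names(chrom_lengths)) |
      v$ref_start >= unlist(chrom_lengths[v$ref_chrom])
    if (any(bad))
      stop("variant outside aligned coordinates (consistency error)")
  }
  classes <- c("SNV", "small_indel", "large_indel", "inversion",
               "translocation", "CNV", "inverted_translocation")
  counts <- vapply(classes, function(cl) sum(v$class == cl), integer(1))
  n_snv <- counts[["SNV"]]
  het_bases <- n_snv + sum(v$length[v$class != "SNV"])
  densities <- NULL
  if (!is.null(chrom_lengths)) {
    dens <- function(cls, win, what = "count") {
      rows <- lapply(names(chrom_lengths), function(ch) {
        L <- chrom_lengths[[ch]]
        starts <- seq(0, L - 1, by = win)
        sel <- v$class %in% cls & v$ref_chrom == ch
        cnt <- if (any(sel))
          tabulate(floor(v$ref_start[sel] / win) + 1L,
                   nbins = length(starts))
        else integer(length(starts))
        data.table::data.table(chrom = ch, start = starts,
                               end = pmin(starts + win, L), value = cnt)
      })
      data.table::rbindlist(rows)
    }
    snv_d <- dens("SNV", snv_window)
    snv_d$value <- 100 * snv_d$value / (snv_d$end - snv_d$start)  # percent
    densities <- list(snv = snv_d,
                      large_indel = dens("large_indel", sv_window),
                      cnv = dens("CNV", sv_window))
  }
  structure(list(counts = counts,
                 snv_rate_percent = 100 * n_snv / aligned_length,
                 overall_rate_percent = 100 * het_bases / aligned_length,
                 het_bases = het_bases, aligned_length = aligned_length,
                 densities = densities, roh = roh),
            class = "het_summary")
}

#' @export
print.het_summary <- function(x, ...) {
  cat("heterozygosity over", format(x$aligned_length, big.mark = ","),
      "aligned bp\n")
  cat(sprintf("  SNV-only rate: %.4f%%   overall rate: %.4f%%\n",
              x$snv_rate_percent, x$overall_rate_percent))
  nz <- x$counts[x$counts > 0]
  if (length(nz))
    cat("  ", paste(sprintf("%s: %d", names(nz), nz), collapse = ", "), "\n")
  if (!is.null(x$roh) && nrow(x$roh))
    cat("  ROH:", nrow(x$roh), "interval(s), longest",
        format(max(x$roh$length), big.mark = ","), "bp\n")
  invisible(x)
}
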