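#' Simulation configuration for a diploid trio truth set
#'
#' Bundles and validates every knob of the synthetic trio generator: the
#' genome layout (chromosome names, lengths and classes), per-bp rates for
#' heterozygous SNVs and indels, counts and length ranges for structural
#' variant classes, planted runs of homozygosity, the de novo mutation rate
#' with its paternal fraction, and the sequencing depth model.
#'
#' @param genome_layout data.frame with columns `chrom`, `length` (bp) and
#'   `class` (one of `"autosome"`, `"X"`, `"Y"`, `"PAR"`).
#' @param snv_rate heterozygous SNVs per bp between the two transmitted
#'   haplotypes (default 1.3e-3, the scale of a highly heterozygous diploid
#'   once indel and SV bases are excluded).
#' @param indel_rate heterozygous small indels (1-50 bp) per bp.
#' @param indel_len_max maximum small-indel length (bp); lengths are uniform
#'   on `[1, indel_len_max]`.
#' @param sv_spec data.frame with columns `class` (one of `"large_indel"`,
#'   `"inversion"`, `"translocation"`, `"CNV"`, `"inverted_translocation"`),
#'   `count`, `min_len`, `max_len`. May be empty (no SVs).
#' @param roh_spec data.frame with columns `chrom`, `start`, `length`:
#'   planted runs of homozygosity in which no heterozygous variant is placed.
#'   0-based start. May be empty.
#' @param dnm_rate de novo mutations per transmitted haploid site per
#'   generation; the total planted count is Poisson with mean
#'   `dnm_rate * (maternal + paternal haploid length)`.
#' @param paternal_fraction fraction of DNMs arising on the paternal
#'   haplotype (default 2/3, i.e. a 2:1 paternal:maternal ratio).
#' @param depth_mean mean sequencing depth per individual per site.
#' @param base_error per-base miscall probability, in `[0, 0.25)`.
#' @param seed master integer seed; all generators derive named substreams
#'   from it, so an identical (config, seed) pair reproduces every output.
#' @return object of class `sim_config`
#' @export
sim_config <- function(genome_layout,
                       snv_rate = 1.3e-3,
                       indel_rate = 1e-4,
                       indel_len_max = 50L,
                       sv_spec = NULL,
                       roh_spec = NULL,
                       dnm_rate = 0,
                       paternal_fraction = 2 / 3,
                       depth_mean = 30,
                       base_error = 1e-3,
                       seed = 1L) {
  layout <- as.data.frame(genome_layout, stringsAsFactors = FALSE)
  if (nrow(layout) == 0L)
    stop("genome_layout must contain at least one chromosome")
  stopifnot(all(c("chrom", "length", "class") %in% names(layout)))
  if (anyDuplicated(layout$chrom))
    stop("duplicate chromosome names in genome_layout")
  if (any(layout$length <= 0)) stop("chromosome lengths must be > 0")
  if (!all(layout$class %in% c("autosome", "X", "Y", "PAR")))
    stop("chromosome class must be autosome, X, Y or PAR")
  if (snv_rate < 0 || indel_rate < 0 || dnm_rate < 0)
    stop("rates must be >= 0")
  if (paternal_fraction < 0 || paternal_fraction > 1)
    stop("paternal_fraction must lie in [0, 1]")
  if (depth_mean <= 0) stop("depth_mean must be > 0")
  if (base_error < 0 || base_error >= 0.25)
    stop("base_error must lie in [0, 0.25)")
  if (!is.null(sv_spec) && nrow(as.data.frame(sv_spec)) > 0L) {
    sv_spec <- as.data.frame(sv_spec, stringsAsFactors = FALSE)
    stopifnot(all(c("class", "count", "min_len", "max_len") %in% names(sv_spec)))
    if (!all(sv_spec$class %in% c("large_indel", "inversion", "translocation",
                                  "CNV", "inverted_translocation")))
      stop("unknown SV class in sv_spec")
    if (any(sv_spec$min_len <= 0) || any(sv_spec$max_len < sv_spec$min_len))
      stop("sv_spec lengths must satisfy 0 < min_len <= max_len")
  } else sv_spec <- data.frame(class = character(), count = integer(),
                               min_len = integer(), max_len = integer())
  if (!is.null(roh_spec) && nrow(as.data.frame(roh_spec)) > 0L) {
    roh_spec <- as.data.frame(roh_spec, stringsAsFactors = FALSE)
    stopifnot(all(c("chrom", "start", "length") %in% names(roh_spec)))
    if (any(roh_spec$length <= 0)) stop("roh_spec lengths must be > 0")
    if (!all(roh_spec$chrom %in% layout$chrom))
      stop("roh_spec chromosome not in genome_layout")
  } else roh_spec <- data.frame(chrom = character(), start = integer(),
                                length = integer())
  structure(list(genome_layout = layout, snv_rate = snv_rate,
                 indel_rate = indel_rate, indel_len_max = as.integer(indel_len_max),
                 sv_spec = sv_spec, roh_spec = roh_spec, dnm_rate = dnm_rate,
                 paternal_fraction = paternal_fraction, depth_mean = depth_mean,
                 base_error = base_error, seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", nrow(x$genome_layout), "chromosome(s),",
      sum(x$genome_layout$length), "bp total\n")
  cat("  snv_rate", x$snv_rate, "| indel_rate", x$indel_rate,
      "| dnm_rate", x$dnm_rate, "(paternal fraction",
      round(x$paternal_fraction, 3), ")\n")
  cat("  depth_mean", x$depth_mean, "| base_error", x$base_error,
      "| seed", x$seed, "\n")
  if (nrow(x$sv_spec)) {
    cat("  SVs:", paste(sprintf("%s x%d", x$sv_spec$class, x$sv_spec$count),
                        collapse = ", "), "\n")
  }
  invisible(x)
}
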