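# Dual-reference trio de novo mutation calling.
#
# A DNM arising on one parental haplotype is carried by the child's
# assembly of that haplotype, so it shows the discovery pattern
# (0/0, 0/0, 0/1) on the OTHER parent's reference and the validation
# pattern (1/1, 1/1, 0/1) on the carrier reference.  Calling against both
# references and requiring both patterns removes read-level false
# positives, which show parents 0/0 on both references.

#' Site and genotype filters for DNM calling
#'
#' Default thresholds: genotype quality >= 20, offspring allelic balance
#' in [0.3, 0.7], no alternative-allele reads in the parents, and per-
#' individual depth between half and two times that individual's mean.
#'
#' @param gq_min minimum genotype quality
#' @param ab_range inclusive allelic-balance range for the heterozygous
#'   offspring
#' @param parental_alt_max maximum alternative-allele reads in a parent
#' @param depth_factor lower and upper multiples of the individual mean
#'   depth
#' @param enabled set `FALSE` to disable every filter (all sites pass)
#' @return object of class `dnm_filters`
#' @export
dnm_filters <- function(gq_min = 20, ab_range = c(0.3, 0.7),
                        parental_alt_max = 0, depth_factor = c(0.5, 2),
                        enabled = TRUE) {
  stopifnot(length(ab_range) == 2, ab_range[1] <= ab_range[2],
            length(depth_factor) == 2)
  structure(list(gq_min = gq_min, ab_range = ab_range,
                 parental_alt_max = parental_alt_max,
                 depth_factor = depth_factor, enabled = isTRUE(enabled)),
            class = "dnm_filters")
}

#' Call candidate de novo mutations on one reference
#'
#' A site is a candidate iff both parents are homozygous reference (0/0)
#' and the offspring is heterozygous (0/1) on this reference.  The
#' hypothesized parent of origin is the parent whose assembly is NOT the
#' reference: a maternal DNM is discovered on the paternal reference and
#' vice versa.  Sites with a missing genotype are skipped (uncallable).
#'
#' @param table per-site trio genotype table (see
#'   [simulate_site_calls()]): columns chrom, pos, gt_m, gt_f, gt_c
#'   (alt dosages), dp_*, ad_*, gq_*
#' @param reference which assembly the table was genotyped against,
#'   `"maternal"` or `"paternal"`
#' @return data.table of candidate rows with columns `origin` (hypothesized
#'   parent) and `reference` (discovery reference) appended
#' @export
call_candidates <- function(table, reference = c("maternal", "paternal")) {
  reference <- match.arg(reference)
  tab <- if (data.table::is.data.table(table)) table else
    data.table::as.data.table(table)
  cand <- tab[!is.na(tab$gt_m) & !is.na(tab$gt_f) & !is.na(tab$gt_c) &
                tab$gt_m == 0L & tab$gt_f == 0L & tab$gt_c == 1L, ]
  cand$origin <- if (reference == "paternal") "maternal" else "paternal"
  cand$reference <- reference
  cand
}

#' Cross-validate DNM candidates on the other reference
#'
#' A candidate discovered on one reference is validated iff on the other
#' reference both parents are homozygous for the alternative (1/1) and
#' the offspring is heterozygous (0/1).  Sites absent from the other
#' table are rejected as unmappable.  Validation is a pure restriction:
#' the validated set is always a subset of the candidates.
#'
#' @param candidates output of [call_candidates()]
#' @param other_table the trio genotype table on the other reference
#' @param liftover optional function mapping a data.frame with `chrom`,
#'   `pos` on the discovery reference to coordinates on the other
#'   reference; `NULL` means the references are colinear (identity)
#' @return the candidates with columns `validated` (logical) and
#'   `reject_reason`
#' @export
cross_validate_candidates <- function(candidates, other_table,
                                      liftover = NULL) {
  cand <- data.table::as.data.table(candidates)
  other <- if (data.table::is.data.table(other_table)) other_table else
    data.table::as.data.table(other_table)
  if (nrow(cand) == 0L) {
    cand$validated <- logical(0)
    cand$reject_reason <- character(0)
    return(cand)
  }
  key <- if (is.null(liftover)) cand[, c("chrom", "pos")] else
    liftover(cand[, c("chrom", "pos")])
  idx <- other[data.table::as.data.table(key), on = c("chrom", "pos"),
               which = TRUE]
  cand$validated <- FALSE
  cand$reject_reason <- NA_character_
  unmap <- is.na(idx)
  cand$reject_reason[unmap] <- "unmappable"
  ok <- which(!unmap)
  if (length(ok)) {
    o <- other[idx[ok], ]
    good <- !is.na(o$gt_m) & !is.na(o$gt_f) & !is.na(o$gt_c) &
      o$gt_m == 2L & o$gt_f == 2L & o$gt_c == 1L
    cand$validated[ok] <- good
    cand$reject_reason[ok][!good] <- "pattern mismatch on other reference"
  }
  cand
}

# vectorized filter evaluation; returns a data.table of logical flags
.filter_flags <- function(tab, means, filters, check_ab = TRUE) {
  n <- nrow(tab)
  if (!filters$enabled) {
    return(data.table::data.table(depth = rep(FALSE, n), gq = FALSE,
                                  parental_alt = FALSE, ab = FALSE))
  }
  lo <- filters$depth_factor[1]; hi <- filters$depth_factor[2]
  depth_bad <- tab$dp_m < lo * means[["m"]] | tab$dp_m > hi * means[["m"]] |
    tab$dp_f < lo * means[["f"]] | tab$dp_f > hi * means[["f"]] |
    tab$dp_c < lo * means[["c"]] | tab$dp_c > hi * means[["c"]]
  gq_bad <- tab$gq_m < filters$gq_min | tab$gq_f < filters$gq_min |
    tab$gq_c < filters$gq_min
  # "alternative reads in a parent": reads not matching that parent's
  # called homozygous allele (gt == 2 flips ad to dp - ad)
  hom_alt_m <- !is.na(tab$gt_m) & tab$gt_m == 2L
  hom_alt_f <- !is.na(tab$gt_f) & tab$gt_f == 2L
  alt_m <- tab$ad_m + hom_alt_m * (tab$dp_m - 2L * tab$ad_m)
  alt_f <- tab$ad_f + hom_alt_f * (tab$dp_f - 2L * tab$ad_f)
  par_bad <- alt_m > filters$parental_alt_max |
    alt_f > filters$parental_alt_max
  ab <- tab$ad_c / tab$dp_c   # dp 0 yields NaN, treated as missing
  ab_bad <- if (check_ab)
    !is.finite(ab) | ab < filters$ab_range[1] | ab > filters$ab_range[2]
  else rep(FALSE, n)
  data.table::data.table(depth = depth_bad, gq = gq_bad,
                         parental_alt = par_bad, ab = ab_bad)
}

#' Apply site and allelic-balance filters to trio sites
#'
#' @param table trio genotype rows (candidates or any sites)
#' @param means named list/vector of per-individual mean depths
#'   (`m`, `f`, `c`); computed from `table` when `NULL`
#' @param filters a [dnm_filters()]
#' @param check_ab also apply the offspring allelic-balance filter
#' @return the table with logical flag columns `fail_depth`, `fail_gq`,
#'   `fail_parental_alt`, `fail_ab` and the summary `pass`
#' @export
apply_site_filters <- function(table, means = NULL, filters = dnm_filters(),
                               check_ab = TRUE) {
  tab <- if (data.table::is.data.table(table)) table else
    data.table::as.data.table(table)
  tab <- data.table::copy(tab)
  means <- means %||% list(m = mean(tab$dp_m), f = mean(tab$dp_f),
                           c = mean(tab$dp_c))
  fl <- .filter_flags(tab, means, filters, check_ab)
  tab$fail_depth <- fl$depth
  tab$fail_gq <- fl$gq
  tab$fail_parental_alt <- fl$parental_alt
  tab$fail_ab <- fl$ab
  tab$pass <- !(fl$depth | fl$gq | fl$parental_alt | fl$ab)
  tab
}

#' Count callable sites on one reference
#'
#' A site is callable when both parents are homozygous reference and all
#' three individuals pass the depth, genotype-quality and parental
#' alternative-allele filters (the allelic-balance component of the
#' filters belongs to the alpha correction, not to callability).
#'
#' @inheritParams apply_site_filters
#' @return integer count of callable sites
#' @export
compute_callability <- function(table, means = NULL,
                                filters = dnm_filters()) {
  tab <- if (data.table::is.data.table(table)) table else
    data.table::as.data.table(table)
  if (nrow(tab) == 0L) {
    warning("empty table: callability 0")
    return(0L)
  }
  means <- means %||% list(m = mean(tab$dp_m), f = mean(tab$dp_f),
                           c = mean(tab$dp_c))
  hom <- !is.na(tab$gt_m) & !is.na(tab$gt_f) & tab$gt_m == 0L &
    tab$gt_f == 0L
  fl <- .filter_flags(tab, means, filters, check_ab = FALSE)
  sum(hom & !(fl$depth | fl$gq | fl$parental_alt))
}

#' Estimate the negative rate factor alpha by simulation
#'
#' Alpha is the fraction of true heterozygous offspring sites that the
#' site and allelic-balance filters would reject: it corrects callability
#' for DNMs the pipeline could never have reported.  Estimated by Monte
#' Carlo: offspring depth is drawn from the reference's depth model
#' (Poisson at the observed mean), alternative reads are Binomial(depth,
#' 1/2), the genotype and its quality are re-called, and the depth, GQ,
#' het-call and allelic-balance filters are applied.
#'
#' @param filters a [dnm_filters()]
#' @param depth_mean offspring mean depth on this reference (> 0)
#' @param base_error per-base miscall probability used by the genotype
#'   caller
#' @param n_sim number of simulated sites (>= 1000)
#' @param seed integer seed (substream `"alpha"`)
#' @param fixed_depth draw every site at exactly `depth_mean` reads
#'   instead of Poisson (useful to compare against closed-form binomial
#'   tails)
#' @return alpha in `[0, 1)`
#' @export
estimate_alpha <- function(filters = dnm_filters(), depth_mean = 30,
                           base_error = 1e-3, n_sim = 100000L, seed = 1L,
                           fixed_depth = FALSE) {
  if (depth_mean <= 0) stop("degenerate depth model (parameter error)")
  if (n_sim < 1000L) stop("n_sim must be >= 1000")
  if (!filters$enabled) return(0)
  with_substream(seed, "alpha", {
    d <- if (fixed_depth) rep(as.integer(depth_mean), n_sim)
         else rpois(n_sim, depth_mean)
    a <- rbinom(n_sim, d, 0.5)
    maxd <- max(as.integer(stats::qpois(1 - 1e-12, depth_mean)), 10L)
    d[d > maxd] <- maxd
    lut <- .gt_lookup(maxd, base_error)
    idx <- lut$index(d, a)
    gt <- lut$gt[idx]
    gq <- lut$gq[idx]
    lo <- filters$depth_factor[1]; hi <- filters$depth_factor[2]
    ab <- ifelse(d > 0, a / d, NA_real_)
    rejected <- d < lo * depth_mean | d > hi * depth_mean |
      is.na(gt) | gt != 1L | gq < filters$gq_min |
      is.na(ab) | ab < filters$ab_range[1] | ab > filters$ab_range[2]
    mean(rejected)
  })
}

#' Combine counts, callabilities and alphas into a mutation-rate estimate
#'
#' \deqn{\mu = \frac{M_{mat} + M_{pat}}
#'   {C_{mat}(1-\alpha_{mat}) + C_{pat}(1-\alpha_{pat})}}
#' with an exact (Garwood) Poisson 95% confidence interval on the summed
#' mutation count divided by the corrected denominator, and the
#' paternal:maternal ratio of validated parent-of-origin labels.
#'
#' @param m_maternal,m_paternal validated DNM counts by parent of origin
#' @param c_maternal,c_paternal callable site counts per reference
#' @param alpha_maternal,alpha_paternal negative rate factors in `[0, 1)`
#' @param conf confidence level for the Poisson interval
#' @return object of class `dnm_rate`: list with counts, callabilities,
#'   alphas, `mu`, `ci` (length 2), `ratio_paternal_maternal`
#' @export
estimate_rate <- function(m_maternal, m_paternal, c_maternal, c_paternal,
                          alpha_maternal = 0, alpha_paternal = 0,
                          conf = 0.95) {
  denom <- c_maternal * (1 - alpha_maternal) +
    c_paternal * (1 - alpha_paternal)
  if (denom <= 0) stop("zero denominator: alpha = 1 on both references")
  M <- m_maternal + m_paternal
  mu <- M / denom
  a <- (1 - conf) / 2
  ci <- c(if (M == 0) 0 else qgamma(a, M) / denom,
          qgamma(1 - a, M + 1) / denom)
  structure(list(m_maternal = m_maternal, m_paternal = m_paternal,
                 c_maternal = c_maternal, c_paternal = c_paternal,
                 alpha_maternal = alpha_maternal,
                 alpha_paternal = alpha_paternal,
                 mu = mu, ci = ci,
                 ratio_paternal_maternal =
                   if (m_maternal > 0) m_paternal / m_maternal else NA_real_),
            class = "dnm_rate")
}

#' @export
print.dnm_rate <- function(x, ...) {
  cat(sprintf("de novo mutation rate: %.3g per site per generation\n", x$mu))
  cat(sprintf("  95%% CI [%.3g, %.3g]; %d maternal + %d paternal DNMs\n",
              x$ci[1], x$ci[2], x$m_maternal, x$m_paternal))
  cat(sprintf("  callable: %.4g (maternal, alpha %.3f), %.4g (paternal, alpha %.3f)\n",
              x$c_maternal, x$alpha_maternal, x$c_paternal, x$alpha_paternal))
  invisible(x)
}

#' Run the full dual-reference DNM pipeline on a pair of trio tables
#'
#' Discovers candidates on each reference, cross-validates them on the
#' other, applies the site and allelic-balance filters on both
#' references, computes per-reference callability and alpha, and returns
#' the mutation-rate estimate.
#'
#' @param calls list with `maternal` and `paternal` trio genotype tables
#'   (as from [simulate_site_calls()])
#' @param filters a [dnm_filters()]
#' @param base_error caller error used for the alpha simulation
#' @param n_sim_alpha Monte Carlo size for alpha
#' @param seed integer seed for the alpha simulation
#' @param cross_validate require the validation pattern on the other
#'   reference (the dual-reference design); `FALSE` reduces to
#'   single-reference discovery
#' @return list: `rate` (a `dnm_rate`), `validated` (data.table of
#'   validated, filter-passing DNMs with parent of origin), `candidates`
#'   (per-reference candidate counts)
#' @export
run_dnm_pipeline <- function(calls, filters = dnm_filters(),
                             base_error = 1e-3, n_sim_alpha = 100000L,
                             seed = 1L, cross_validate = TRUE) {
  stopifnot(all(c("maternal", "paternal") %in% names(calls)))
  refs <- c("maternal", "paternal")
  for (r in refs) if (!data.table::is.data.table(calls[[r]]))
    calls[[r]] <- data.table::as.data.table(calls[[r]])
  means <- lapply(calls[refs], function(tb)
    list(m = mean(tb$dp_m), f = mean(tb$dp_f), c = mean(tb$dp_c)))
  validated <- list()
  n_cand <- c(maternal = 0L, paternal = 0L)
  for (ref in refs) {
    other <- setdiff(refs, ref)
    cand <- call_candidates(calls[[ref]], ref)
    n_cand[[ref]] <- nrow(cand)
    if (cross_validate && nrow(cand)) {
      cand <- cross_validate_candidates(cand, calls[[other]])
      cand <- cand[cand$validated, ]
    }
    if (nrow(cand)) {
      cand <- apply_site_filters(cand, means[[ref]], filters)
      cand <- cand[cand$pass, ]
    }
    if (cross_validate && nrow(cand)) {
      # filters must also pass on the carrier reference
      idx <- calls[[other]][cand[, c("chrom", "pos")],
                            on = c("chrom", "pos"), which = TRUE]
      oth <- apply_site_filters(calls[[other]][idx, ], means[[other]],
                                filters)
      cand <- cand[oth$pass, ]
    }
    validated[[ref]] <- cand
  }
  val <- data.table::rbindlist(validated, fill = TRUE)
  m_mat <- sum(val$origin == "maternal")
  m_pat <- sum(val$origin == "paternal")
  c_mat <- compute_callability(calls$maternal, means$maternal, filters)
  c_pat <- compute_callability(calls$paternal, means$paternal, filters)
  a_mat <- estimate_alpha(filters, means$maternal$c, base_error,
                          n_sim_alpha, seed)
  a_pat <- estimate_alpha(filters, means$paternal$c, base_error,
                          n_sim_alpha, seed + 1L)
  list(rate = estimate_rate(m_mat, m_pat, c_mat, c_pat, a_mat, a_pat),
       validated = val, candidates = n_cand)
}
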