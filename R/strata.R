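# Gametologue divergence: Nei-Gojobori (1986) dN/dS with Jukes-Cantor
# correction, dS-vs-position correlation, contiguous strata segmentation,
# and molecular-clock dating of recombination suppression.

.codon_env <- new.env(parent = emptyenv())

.genetic_code <- function() {
  if (is.null(.codon_env$code)) {
    gc <- Biostrings::GENETIC_CODE
    .codon_env$code <- stats::setNames(as.character(gc), names(gc))
  }
  .codon_env$code
}

# fraction of synonymous sites per codon: at each position, the share of
# the three possible single-base changes that preserve the amino acid
# (changes to stop codons count as non-synonymous)
.syn_sites <- function() {
  if (!is.null(.codon_env$syn)) return(.codon_env$syn)
  code <- .genetic_code()
  codons <- names(code)
  syn <- numeric(length(codons))
  names(syn) <- codons
  for (cd in codons) {
    if (code[[cd]] == "*") { syn[[cd]] <- NA_real_; next }
    s <- 0
    for (p in 1:3) {
      for (b in DNA_BASES) {
        if (b == substr(cd, p, p)) next
        mut <- cd
        substr(mut, p, p) <- b
        if (code[[mut]] != "*" && code[[mut]] == code[[cd]]) s <- s + 1 / 3
      }
    }
    syn[[cd]] <- s
  }
  .codon_env$syn <- syn
  syn
}

# synonymous / non-synonymous difference counts between two codons,
# averaged over all mutational pathways that avoid stop codons
.codon_diff <- function(c1, c2) {
  code <- .genetic_code()
  pos <- which(seq_chars(c1) != seq_chars(c2))
  nd <- length(pos)
  if (nd == 0L) return(c(sd = 0, nd = 0))
  perms <- switch(nd,
                  `1` = list(pos),
                  `2` = list(pos, rev(pos)),
                  `3` = {
                    p <- pos
                    list(p[c(1, 2, 3)], p[c(1, 3, 2)], p[c(2, 1, 3)],
                         p[c(2, 3, 1)], p[c(3, 1, 2)], p[c(3, 2, 1)])
                  })
  tally <- matrix(0, nrow = 0, ncol = 2)
  for (ord in perms) {
    cur <- c1
    sd <- 0; nn <- 0; blocked <- FALSE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (code[[nxt]] == "*") { blocked <- TRUE; break }
      if (code[[nxt]] == code[[cur]]) sd <- sd + 1 else nn <- nn + 1
      cur <- nxt
    }
    if (!blocked) tally <- rbind(tally, c(sd, nn))
  }
  if (nrow(tally) == 0L) {
    # all pathways pass through a stop; fall back to averaging over all
    for (ord in perms) {
      cur <- c1
      sd <- 0; nn <- 0
      for (p in ord) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        if (code[[nxt]] != "*" && code[[nxt]] == code[[cur]]) sd <- sd + 1
        else nn <- nn + 1
        cur <- nxt
      }
      tally <- rbind(tally, c(sd, nn))
    }
  }
  c(sd = mean(tally[, 1]), nd = mean(tally[, 2]))
}

#' Pairwise dN and dS by Nei-Gojobori (1986) with Jukes-Cantor correction
#'
#' Counts synonymous (S) and non-synonymous (N) sites per codon averaged
#' over both sequences, tallies synonymous and non-synonymous differences
#' averaged over mutational pathways, and corrects the proportions with
#' \eqn{d = -\frac{3}{4}\ln(1 - \frac{4}{3} p)}.
#'
#' @param x_cds,y_cds equal-length, in-frame, gap-free aligned CDS strings.
#'   A shared terminal stop codon is dropped; an internal stop is an error.
#' @return named list: dN, dS, S, N, Sd, Nd, pS, pN.  dS or dN is `NA`
#'   (saturation) when the corresponding p >= 3/4.
#' @examples
#' compute_dn_ds(strrep("GGT", 10), paste0(strrep("GGT", 9), "GGC"))$dS
#' @export
compute_dn_ds <- function(x_cds, y_cds) {
  x_cds <- toupper(x_cds); y_cds <- toupper(y_cds)
  if (nchar(x_cds) != nchar(y_cds))
    stop("CDS lengths differ; sequences must be aligned")
  if (nchar(x_cds) %% 3 != 0) stop("CDS length not a multiple of 3")
  if (grepl("-", x_cds, fixed = TRUE) || grepl("-", y_cds, fixed = TRUE))
    stop("gapped alignment not supported; supply gap-free CDS")
  n_codon <- nchar(x_cds) %/% 3L
  starts <- 3L * (seq_len(n_codon) - 1L) + 1L
  cx <- substring(x_cds, starts, starts + 2L)
  cy <- substring(y_cds, starts, starts + 2L)
  code <- .genetic_code()
  stop_x <- code[cx] == "*"
  stop_y <- code[cy] == "*"
  if (n_codon > 1L && stop_x[n_codon] && stop_y[n_codon]) {
    cx <- cx[-n_codon]; cy <- cy[-n_codon]
    stop_x <- stop_x[-n_codon]; stop_y <- stop_y[-n_codon]
  }
  if (any(stop_x) || any(stop_y))
    stop("internal stop codon in CDS (input error)")
  syn <- .syn_sites()
  S <- (sum(syn[cx]) + sum(syn[cy])) / 2
  N <- 3 * length(cx) - S
  diffs <- which(cx != cy)
  Sd <- 0; Nd <- 0
  for (i in diffs) {
    d <- .codon_diff(cx[i], cy[i])
    Sd <- Sd + d[["sd"]]
    Nd <- Nd + d[["nd"]]
  }
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  jc <- function(p) if (p >= 3 / 4) NA_real_ else -3 / 4 * log(1 - 4 / 3 * p)
  list(dN = jc(pN), dS = jc(pS), S = S, N = N, Sd = Sd, Nd = Nd,
       pS = pS, pN = pN)
}

#' Correlate gametologue dS with X-chromosome position
#'
#' Pearson product-moment correlation of pairwise dS against position on
#' the X (distance from the pseudoautosomal boundary), the classic
#' signature of evolutionary strata.  Pairs with missing or non-finite dS
#' (saturation, exclusion) are omitted.
#'
#' @param pairs data.frame with columns `ds` and `x_pos`
#' @return list: `r`, `p` (two-sided), `n`; `r` is `NA` with a `reason`
#'   when fewer than 3 usable pairs remain or either variable has zero
#'   variance
#' @export
correlate_ds_position <- function(pairs) {
  pairs <- as.data.frame(pairs)
  stopifnot(all(c("ds", "x_pos") %in% names(pairs)))
  ok <- is.finite(pairs$ds) & is.finite(pairs$x_pos)
  d <- pairs[ok, ]
  if (nrow(d) < 3L)
    return(list(r = NA_real_, p = NA_real_, n = nrow(d),
                reason = "fewer than 3 usable pairs"))
  if (var(d$ds) == 0 || var(d$x_pos) == 0)
    return(list(r = NA_real_, p = NA_real_, n = nrow(d),
                reason = "zero variance"))
  ct <- cor.test(d$ds, d$x_pos, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(d))
}

# optimal contiguous k-segmentation of y minimizing within-segment sums of
# squares (dynamic programming over prefix sums); returns segment ids
.segment_ls <- function(y, k) {
  n <- length(y)
  cs <- cumsum(y); cs2 <- cumsum(y^2)
  sse <- function(i, j) { # segment y[i..j], 1-based inclusive
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  cost <- matrix(Inf, nrow = k, ncol = n)
  back <- matrix(0L, nrow = k, ncol = n)
  for (j in 1:n) cost[1, j] <- sse(1, j)
  if (k > 1) for (m in 2:k) for (j in m:n) {
    for (i in m:j) {
      c0 <- cost[m - 1, i - 1] + sse(i, j)
      if (c0 < cost[m, j]) { cost[m, j] <- c0; back[m, j] <- i }
    }
  }
  seg <- integer(n)
  j <- n
  for (m in k:1) {
    i <- if (m == 1) 1L else back[m, j]
    seg[i:j] <- m
    j <- i - 1L
  }
  list(segments = seg, rss = cost[k, n])
}

#' Assign evolutionary strata from gametologue divergence
#'
#' Orders pairs by X position, excludes recently duplicated pairs (dS
#' below `duplicate_floor` and flagged as an intra-species duplication),
#' and segments the ordered dS values into `k` contiguous groups by
#' least-squares dynamic programming.  When `k` is `NULL` it is chosen by
#' a BIC-style penalty \eqn{n\log(RSS/n) + 4k\log n} (the heavy
#' multiplier guards against over-segmentation when within-stratum
#' residuals are small relative to between-stratum steps, the regime
#' gametologue dS values live in).  Labels S1..Sk are
#' ordered by decreasing mean dS (S1 oldest), so the label means are
#' monotone by construction.
#'
#' @param pairs data.frame with columns `ds`, `x_pos` and optionally
#'   `duplicate` (logical)
#' @param k number of strata, or `NULL` to choose by penalty
#' @param k_max largest k considered when `k` is `NULL`
#' @param duplicate_floor dS floor below which a flagged duplicate pair is
#'   excluded from all strata
#' @return data.frame: the input pairs (ordered by `x_pos`) with columns
#'   `stratum` (`"S1"`... or `"excluded"`) and `excluded_reason`
#' @export
assign_strata <- function(pairs, k = NULL, k_max = 8L,
                          duplicate_floor = 0.02) {
  pairs <- as.data.frame(pairs)
  stopifnot(all(c("ds", "x_pos") %in% names(pairs)))
  pairs <- pairs[order(pairs$x_pos), , drop = FALSE]
  dup <- if ("duplicate" %in% names(pairs)) pairs$duplicate else
    rep(FALSE, nrow(pairs))
  excl <- (dup & pairs$ds < duplicate_floor) | !is.finite(pairs$ds)
  use <- which(!excl)
  n <- length(use)
  if (!is.null(k) && k > n)
    stop("k exceeds the number of usable pairs (parameter error)")
  if (n == 0L) {
    pairs$stratum <- "excluded"
    pairs$excluded_reason <- ifelse(dup, "recent duplication", "missing dS")
    return(pairs)
  }
  y <- pairs$ds[use]
  if (is.null(k)) {
    kk <- seq_len(min(k_max, n))
    crit <- vapply(kk, function(m) {
      rss <- .segment_ls(y, m)$rss
      n * log(max(rss, 1e-12) / n) + 4 * m * log(n)
    }, numeric(1))
    k <- kk[which.min(crit)]
  }
  seg <- .segment_ls(y, k)$segments
  means <- tapply(y, seg, mean)
  lab_order <- order(means, decreasing = TRUE)  # S1 = highest mean dS
  lab <- paste0("S", match(seg, lab_order))
  pairs$stratum <- "excluded"
  pairs$stratum[use] <- lab
  pairs$excluded_reason <- NA_character_
  pairs$excluded_reason[excl & dup] <- "recent duplication"
  pairs$excluded_reason[excl & !dup] <- "missing dS"
  pairs
}

#' Date a divergence under a molecular clock
#'
#' For divergence `d` (substitutions per site between the two copies) and
#' a yearly substitution rate `r`, the time since the copies stopped
#' recombining is \eqn{T = d / (2 r)} (both lineages accumulate
#' substitutions).  Per-generation rates are converted with
#' \eqn{r = \mu / g}.
#'
#' @param d divergence (substitutions/site, >= 0)
#' @param rates list whose elements are either a single yearly rate
#'   (substitutions per position per year) or a named vector/list with
#'   `mu` (per generation) and `g` (generation time, years)
#' @return list: `estimates` (data.frame rate, from_generation, T_years)
#'   and `range` (min, max T across rates)
#' @examples
#' date_divergence(0.0605, list(1.11e-9, 1.20e-9))$range / 1e6  # Myr
#' @export
date_divergence <- function(d, rates) {
  if (d < 0) stop("divergence must be >= 0")
  if (!is.list(rates)) rates <- as.list(rates)
  rows <- lapply(rates, function(r) {
    if (is.list(r) || length(r) > 1) {
      r <- unlist(r)
      if (!all(c("mu", "g") %in% names(r)))
        stop("per-generation rates need named elements mu and g")
      if (r[["mu"]] <= 0 || r[["g"]] <= 0)
        stop("rates must be > 0 (parameter error)")
      yearly <- r[["mu"]] / r[["g"]]
      data.frame(rate = yearly, from_generation = TRUE,
                 T_years = d / (2 * yearly))
    } else {
      r <- as.numeric(r)
      if (r <= 0) stop("rates must be > 0 (parameter error)")
      data.frame(rate = r, from_generation = FALSE, T_years = d / (2 * r))
    }
  })
  est <- do.call(rbind, rows)
  list(estimates = est, range = range(est$T_years))
}
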