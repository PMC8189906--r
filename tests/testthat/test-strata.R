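# NG86 dN/dS, dS-position correlation, strata segmentation, clock dating

test_that("dN/dS matches hand-counted NG86 cases", {
  r0 <- compute_dn_ds("GGTGGT", "GGTGGT")
  expect_equal(r0$dN, 0)
  expect_equal(r0$dS, 0)

  r1 <- compute_dn_ds(strrep("GGT", 10), paste0(strrep("GGT", 9), "GGC"))
  expect_equal(r1$dS, -0.75 * log(1 - 4 / 30), tolerance = 1e-6)
  expect_equal(r1$dN, 0)
  expect_equal(r1$S, 10)        # one synonymous site per glycine codon
  expect_equal(r1$Sd, 1)

  # one non-synonymous change in 10 codons: GGT -> CGT (Gly -> Arg)
  r2 <- compute_dn_ds(strrep("GGT", 10), paste0("CGT", strrep("GGT", 9)))
  expect_equal(r2$dS, 0)
  expect_gt(r2$dN, 0)

  expect_error(compute_dn_ds("GGTTAAGGT", "GGTTAAGGT"), "stop")
  expect_error(compute_dn_ds("GGTT", "GGTT"), "multiple of 3")
  expect_error(compute_dn_ds("GGT", "GGTGGT"), "lengths differ")
})

test_that("dN/dS is symmetric and site counts are additive", {
  x1 <- random_cds(40, seed = 1); y1 <- random_cds(40, seed = 2)
  a <- compute_dn_ds(x1, y1)
  b <- compute_dn_ds(y1, x1)
  expect_equal(a$dS, b$dS)
  expect_equal(a$dN, b$dN)
  x2 <- random_cds(25, seed = 3); y2 <- random_cds(25, seed = 4)
  c1 <- compute_dn_ds(x2, y2)
  cc <- compute_dn_ds(paste0(x1, x2), paste0(y1, y2))
  expect_equal(cc$S, a$S + c1$S, tolerance = 1e-9)
  expect_equal(cc$Sd, a$Sd + c1$Sd, tolerance = 1e-9)
  expect_equal(cc$Nd, a$Nd + c1$Nd, tolerance = 1e-9)
})

test_that("planted dS is estimated consistently as the CDS grows", {
  est <- function(len, seed) {
    gp <- simulate_gametologue_pairs(
      data.frame(stratum = "S", n_pairs = 6, ds = 0.15), len, seed = seed)
    mean(vapply(seq_len(nrow(gp)), function(i)
      compute_dn_ds(gp$x_cds[i], gp$y_cds[i])$dS, numeric(1)))
  }
  short <- abs(est(999, 5) - 0.15)
  long <- abs(est(9999, 5) - 0.15)
  expect_lt(long, 0.02)
  expect_lt(long, short + 0.01)   # no worse at 10x the length
})

test_that("dS-position correlation matches direct arithmetic", {
  x <- c(1, 3, 4, 7, 9)
  y <- c(0.05, 0.11, 0.18, 0.34, 0.42)
  r_manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- correlate_ds_position(data.frame(ds = y, x_pos = x))
  expect_equal(r$r, r_manual, tolerance = 1e-12)
  expect_lt(r$p, 0.05)

  lin <- correlate_ds_position(data.frame(ds = 1:5 / 10, x_pos = 1:5))
  expect_equal(lin$r, 1)
  flat <- correlate_ds_position(data.frame(ds = rep(0.2, 5), x_pos = 1:5))
  expect_true(is.na(flat$r))
  expect_equal(flat$reason, "zero variance")
  few <- correlate_ds_position(data.frame(ds = c(0.1, 0.2),
                                          x_pos = c(1, 2)))
  expect_true(is.na(few$r))
})

test_that("strata segmentation recovers planted groups and excludes dups", {
  spec <- data.frame(stratum = c("young", "mid", "old"),
                     n_pairs = c(4, 4, 4), ds = c(0.03, 0.2, 0.5))
  gp <- simulate_gametologue_pairs(spec, 3999, seed = 8)
  gp$ds <- vapply(seq_len(nrow(gp)), function(i)
    compute_dn_ds(gp$x_cds[i], gp$y_cds[i])$dS, numeric(1))
  st <- assign_strata(gp[, c("ds", "x_pos")], k = 3)
  expect_equal(unname(table(st$stratum)[c("S1", "S2", "S3")]),
               c(4L, 4L, 4L), ignore_attr = TRUE)
  # contiguity along the X: labels change exactly twice
  expect_equal(sum(diff(match(st$stratum, unique(st$stratum))) != 0), 2L)
  # highest-dS group is S1 (oldest)
  expect_equal(unique(st$stratum[st$ds > 0.4]), "S1")
  # automatic k lands on 3 when steps dwarf the estimator noise
  set.seed(7)
  easy <- data.frame(ds = rep(c(0.05, 0.3, 0.6), each = 4) +
                       rnorm(12, 0, 0.005),
                     x_pos = sort(runif(12, 0, 1e7)))
  st_auto <- assign_strata(easy)
  expect_equal(length(unique(st_auto$stratum)), 3L)

  gp$duplicate <- c(TRUE, rep(FALSE, nrow(gp) - 1))
  gp$ds[1] <- 0.001     # recent duplication, near-zero divergence
  st2 <- assign_strata(gp[, c("ds", "x_pos", "duplicate")], k = 3)
  expect_equal(st2$stratum[st2$duplicate], "excluded")
  expect_equal(st2$excluded_reason[st2$duplicate], "recent duplication")

  one <- assign_strata(data.frame(ds = 0.1, x_pos = 1), k = 1)
  expect_equal(one$stratum, "S1")
  expect_error(assign_strata(data.frame(ds = 0.1, x_pos = 1), k = 5), "k")
})

test_that("stratum label means are monotone for random inputs", {
  set.seed(81)
  for (i in 1:20) {
    n <- sample(6:20, 1)
    d <- data.frame(ds = runif(n, 0, 0.6), x_pos = sort(runif(n, 0, 1e7)))
    k <- sample(1:4, 1)
    st <- assign_strata(d, k = min(k, n))
    m <- tapply(st$ds, st$stratum, mean)
    m <- m[order(names(m))]     # S1, S2, ...
    expect_true(all(diff(m) <= 1e-12))
  }
})

test_that("clock dating follows T = d / (2r) with unit conversions", {
  expect_equal(date_divergence(0, list(1e-9))$estimates$T_years, 0)
  r <- date_divergence(0.0605, list(1.11e-9, 1.20e-9))
  expect_equal(r$estimates$T_years[1], 0.0605 / (2 * 1.11e-9))
  expect_equal(r$range, sort(0.0605 / (2 * c(1.2e-9, 1.11e-9))))
  # per-generation rate: mu = 0.43e-8, g = 6 yr -> r ~ 7.17e-10 per year
  g <- date_divergence(0.0605, list(c(mu = 0.43e-8, g = 6)))
  expect_equal(g$estimates$rate, 0.43e-8 / 6)
  expect_equal(g$estimates$T_years, 0.0605 / (2 * 0.43e-8 / 6))
  expect_error(date_divergence(0.1, list(0)), "rates")
  expect_error(date_divergence(-1, list(1e-9)), "divergence")
  # linear in d, inverse in r, at random points
  set.seed(91)
  for (i in 1:20) {
    d <- runif(1, 0, 0.5); rr <- runif(1, 1e-10, 1e-8); kf <- runif(1, 1, 5)
    expect_equal(date_divergence(kf * d, list(rr))$estimates$T_years,
                 kf * date_divergence(d, list(rr))$estimates$T_years)
    expect_equal(date_divergence(d, list(kf * rr))$estimates$T_years,
                 date_divergence(d, list(rr))$estimates$T_years / kf)
  }
})
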