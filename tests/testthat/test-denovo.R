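# dual-reference DNM calling, filters, callability, alpha, rate formula

fake_table <- function(gt_m, gt_f, gt_c, dp = 30L, ad_c = 15L, gq = 60L,
                       pos = seq_along(gt_m) - 1L) {
  n <- length(gt_m)
  data.table::data.table(
    chrom = "c", pos = pos, gt_m = gt_m, gt_f = gt_f, gt_c = gt_c,
    dp_m = dp, dp_f = dp, dp_c = dp,
    ad_m = ifelse(!is.na(gt_m) & gt_m == 2L, dp, 0L),
    ad_f = ifelse(!is.na(gt_f) & gt_f == 2L, dp, 0L),
    ad_c = ad_c, gq_m = gq, gq_f = gq, gq_c = gq)
}

test_that("candidate calling keys on the 0/0, 0/0, 0/1 pattern", {
  tab <- fake_table(gt_m = c(0L, 1L, 0L, 0L, NA),
                    gt_f = c(0L, 0L, 0L, 0L, 0L),
                    gt_c = c(1L, 1L, 2L, 1L, 1L))
  cand <- call_candidates(tab, "paternal")
  expect_equal(cand$pos, c(0L, 3L))         # mother 0/1 and child 1/1 drop
  expect_true(all(cand$origin == "maternal"))
  cand2 <- call_candidates(tab, "maternal")
  expect_true(all(cand2$origin == "paternal"))
})

test_that("cross-validation demands 1/1, 1/1, 0/1 on the other reference", {
  cand <- call_candidates(fake_table(0L, 0L, 1L), "paternal")
  ok <- cross_validate_candidates(cand, fake_table(2L, 2L, 1L))
  expect_true(all(ok$validated))
  bad <- cross_validate_candidates(cand, fake_table(1L, 2L, 1L))
  expect_false(any(bad$validated))
  expect_equal(bad$reject_reason, "pattern mismatch on other reference")
  off <- cross_validate_candidates(cand, fake_table(2L, 2L, 1L, pos = 99L))
  expect_false(any(off$validated))
  expect_equal(off$reject_reason, "unmappable")
})

test_that("validation is a pure restriction of the candidate set", {
  set.seed(31)
  for (i in 1:20) {
    g <- function(n) sample(c(0L, 1L, 2L, NA), n, replace = TRUE)
    t1 <- fake_table(g(50), g(50), g(50))
    t2 <- fake_table(g(50), g(50), g(50))
    cand <- call_candidates(t1, "maternal")
    val <- cross_validate_candidates(cand, t2)
    expect_lte(sum(val$validated), nrow(cand))
    expect_true(all(val$pos %in% cand$pos))
  }
})

test_that("site filters flag depth, parental alt reads and allelic balance", {
  means <- list(m = 30, f = 30, c = 30)
  tab <- fake_table(0L, 0L, 1L)
  tab$dp_c <- 75L                           # 2.5x the mean
  r <- apply_site_filters(tab, means)
  expect_true(r$fail_depth)
  expect_false(r$pass)

  tab2 <- fake_table(0L, 0L, 1L)
  tab2$ad_f <- 2L                           # father carries alt reads
  r2 <- apply_site_filters(tab2, means)
  expect_true(r2$fail_parental_alt)

  tab3 <- fake_table(0L, 0L, 1L, ad_c = 15L)  # AB = 0.50
  r3 <- apply_site_filters(tab3, means)
  expect_true(r3$pass)
  tab4 <- fake_table(0L, 0L, 1L, ad_c = 5L)   # AB = 0.17
  expect_true(apply_site_filters(tab4, means)$fail_ab)
  # on the validation reference parents are 1/1: ref reads are the
  # "alternative" evidence there
  tab5 <- fake_table(2L, 2L, 1L)
  tab5$ad_m <- 28L                          # 2 reference reads
  expect_true(apply_site_filters(tab5, means)$fail_parental_alt)
})

test_that("callability is a brute-force recount of passing double-0/0 sites", {
  set.seed(41)
  n <- 400
  tab <- fake_table(sample(c(0L, 0L, 0L, 1L, 2L), n, TRUE),
                    sample(c(0L, 0L, 0L, 1L, 2L), n, TRUE),
                    sample(c(0L, 1L), n, TRUE),
                    dp = sample(c(5L, 30L, 40L, 70L), n, TRUE))
  means <- list(m = 30, f = 30, c = 30)
  f <- dnm_filters()
  got <- compute_callability(tab, means, f)
  manual <- 0L
  for (i in seq_len(n)) {
    row <- tab[i, ]
    hom <- !is.na(row$gt_m) && !is.na(row$gt_f) &&
      row$gt_m == 0L && row$gt_f == 0L
    dep <- all(c(row$dp_m, row$dp_f, row$dp_c) >= 15 &
                 c(row$dp_m, row$dp_f, row$dp_c) <= 60)
    alt <- row$ad_m <= 0 && row$ad_f <= 0
    if (hom && dep && alt) manual <- manual + 1L
  }
  expect_equal(got, manual)
  # filters disabled: every double-0/0 site counts
  off <- dnm_filters(enabled = FALSE)
  expect_equal(compute_callability(tab, means, off),
               sum(!is.na(tab$gt_m) & !is.na(tab$gt_f) &
                     tab$gt_m == 0L & tab$gt_f == 0L))
  expect_warning(compute_callability(tab[0, ], means, f), "empty")
})

test_that("alpha equals the exact binomial tail at fixed depth", {
  f <- dnm_filters(gq_min = 0, ab_range = c(0.3, 0.7),
                   parental_alt_max = Inf, depth_factor = c(0, Inf))
  a <- estimate_alpha(f, depth_mean = 30, base_error = 1e-3,
                      n_sim = 200000L, seed = 3, fixed_depth = TRUE)
  exact <- pbinom(8, 30, 0.5) + (1 - pbinom(21, 30, 0.5))
  expect_equal(a, exact, tolerance = 0.01)
  expect_equal(estimate_alpha(dnm_filters(enabled = FALSE)), 0)
  near1 <- estimate_alpha(dnm_filters(gq_min = 0, ab_range = c(0.49, 0.51),
                                      depth_factor = c(0, Inf),
                                      parental_alt_max = Inf),
                          depth_mean = 10, n_sim = 5000L, seed = 4)
  expect_gte(near1, 0.7)
  expect_error(estimate_alpha(depth_mean = 0), "degenerate")
  expect_error(estimate_alpha(n_sim = 10), "n_sim")
})

test_that("the rate formula, its CI and scaling behave exactly", {
  r <- estimate_rate(3, 6, 1.0465e9, 1.0465e9, 0, 0)
  expect_equal(r$mu, 9 / 2.093e9, tolerance = 1e-6)
  expect_equal(r$ratio_paternal_maternal, 2)
  # exact Garwood bounds on a count of 9
  expect_equal(r$ci[1], qgamma(0.025, 9) / 2.093e9, tolerance = 1e-6)
  expect_equal(r$ci[2], qgamma(0.975, 10) / 2.093e9, tolerance = 1e-6)

  r0 <- estimate_rate(0, 0, 1e9, 1e9)
  expect_equal(r0$mu, 0)
  expect_equal(r0$ci[1], 0)

  r1 <- estimate_rate(2, 4, 1e7, 1e7)
  r2 <- estimate_rate(2, 4, 2e7, 2e7)
  expect_equal(r1$mu, 2 * r2$mu)
  expect_error(estimate_rate(1, 1, 1e6, 1e6, 1, 1), "denominator")
})

test_that("cross-validation removes the false candidates discovery admits", {
  # no planted DNMs at an elevated base error: single-reference discovery
  # picks up read-level false candidates; the dual-reference validation
  # pattern (parents 1/1 on the carrier assembly) removes every one
  validated <- 0L
  candidates <- 0L
  for (rep in 1:3) {
    cfg <- sim_config(toy_layout(2e6), snv_rate = 1e-4, indel_rate = 0,
                      dnm_rate = 0, depth_mean = 30, base_error = 5e-3,
                      seed = 300 + rep)
    tr <- simulate_trio_genomes(cfg)
    sc <- simulate_site_calls(tr, 30, 5e-3, seed = 300 + rep)
    res <- run_dnm_pipeline(sc, seed = rep)
    validated <- validated + nrow(res$validated)
    candidates <- candidates + sum(res$candidates)
  }
  expect_equal(validated, 0L)
  expect_gte(candidates, 1L)
})

test_that("relabelling the references swaps origins and leaves mu fixed", {
  cfg <- sim_config(toy_layout(5e5), snv_rate = 1e-4, indel_rate = 0,
                    dnm_rate = 2e-5, paternal_fraction = 2 / 3,
                    seed = 19)
  tr <- simulate_trio_genomes(cfg)
  sc <- simulate_site_calls(tr, 30, 1e-3, seed = 19)
  a <- run_dnm_pipeline(sc, seed = 1)
  swapped <- list(maternal = sc$paternal, paternal = sc$maternal)
  b <- run_dnm_pipeline(swapped, seed = 1)
  expect_equal(a$rate$m_maternal, b$rate$m_paternal)
  expect_equal(a$rate$m_paternal, b$rate$m_maternal)
  expect_equal(a$rate$mu, b$rate$mu, tolerance = 0.02) # alpha draws differ
})
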