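# pileup pi, complex-site filter, SNP set algebra, evidence chains

test_that("pi matches the printed worked pileup and simple cases", {
  expect_equal(compute_pi(A = 20, T = 20, C = 14, G = 0), 1920 / 2862,
               tolerance = 1e-12)
  expect_equal(compute_pi(A = 30, T = 0, C = 0, G = 0), 0)
  expect_equal(compute_pi(A = 15, T = 15, C = 0, G = 0), 450 / 870,
               tolerance = 1e-12)
  expect_true(is.na(compute_pi(A = 1, T = 0, C = 0, G = 0)))
})

test_that("pi equals the sampling-without-replacement oracle for D <= 12", {
  combos <- expand.grid(A = 0:6, C = 0:6, G = 0:4, T = 0:4)
  combos <- combos[rowSums(combos) >= 2 & rowSums(combos) <= 12, ]
  got <- compute_pi(combos$A, combos$C, combos$G, combos$T)
  want <- mapply(brute_pi, combos$A, combos$C, combos$G, combos$T)
  expect_equal(got, unname(want), tolerance = 1e-12)
})

test_that("pi is label-permutation invariant and grows toward even splits", {
  expect_equal(compute_pi(A = 7, C = 3, G = 2, T = 0),
               compute_pi(A = 0, C = 2, G = 3, T = 7))
  # monoallelic perturbed toward an even two-allele split
  vals <- vapply(0:6, function(k) compute_pi(A = 12 - k, T = k, C = 0, G = 0),
                 numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("complex-site filter needs both high pi and a deep third allele", {
  expect_equal(classify_pileup_site(A = 20, T = 20, C = 14, G = 0),
               "complex")
  expect_equal(classify_pileup_site(A = 15, T = 15, C = 0, G = 0), "kept")
  expect_equal(classify_pileup_site(A = 5, T = 4, C = 0, G = 0),
               "low_depth")
  # third-highest ties broken by value: depths 10/10/10/0 -> third is 10
  expect_equal(classify_pileup_site(A = 10, T = 10, C = 10, G = 0),
               "complex")
})

test_that("confident SNP set algebra reproduces the two-step construction", {
  r <- build_snp_sets(setA = c("1", "2", "3"), setB = c("2", "3", "4"),
                      setC = c("3", "4", "5"))
  expect_setequal(r$set1, c("3", "4"))
  expect_setequal(r$set2, c("1", "2", "3", "4"))
  expect_setequal(r$set3, r$set2)

  pile <- data.frame(key = c("1", "2"), A = c(5, 20), C = c(4, 20),
                     G = c(0, 14), T = c(0, 0))
  r2 <- build_snp_sets(c("1", "2", "3"), c("2", "3"), c("3"),
                       pileups = pile)
  expect_false("1" %in% r2$set3)   # depth 9 -> excluded
  expect_false("2" %in% r2$set3)   # complex pileup -> excluded
  expect_true("3" %in% r2$set3)

  r3 <- build_snp_sets(c("a", "b"), character(0), character(0),
                       aligned = "a")
  expect_equal(r3$set1, character(0))
  expect_setequal(r3$set2, c("a", "b"))
  expect_equal(r3$set3, "a")
})

test_that("set identities hold over 1000 random triples", {
  set.seed(99)
  for (i in 1:1000) {
    u <- as.character(1:30)
    A <- sample(u, sample(0:20, 1))
    B <- sample(u, sample(0:20, 1))
    C <- sample(u, sample(0:20, 1))
    r <- build_snp_sets(A, B, C)
    expect_true(all(r$set1 %in% r$set2))
    expect_true(all(r$set3 %in% r$set2))
    expect_lte(length(r$set2), length(A) + length(r$set1))
    expect_setequal(r$set2, union(A, intersect(B, C)))
  }
})

test_that("evidence-chain decision table matches its fixed rules", {
  expect_equal(classify_evidence_chain("G", "A", "G", "G", "A"),
               "sequencing_error")
  expect_equal(classify_evidence_chain("A", "A", "A", "G", "A"),
               "polishing_error")
  expect_equal(classify_evidence_chain("A", "A", "A", "A", "A"),
               "true_variant")
  expect_equal(classify_evidence_chain("G", "A", "G", "G", "N"),
               "unresolved")
  expect_equal(classify_evidence_chain("G", "A", "A", "C", "T"),
               "unresolved")
})

test_that("chain classes are mutually exclusive and exhaustive", {
  alphabet <- c("A", "G", "N")
  grid <- expand.grid(raw = alphabet, corrected = alphabet, pre = alphabet,
                      post = alphabet, short = alphabet,
                      stringsAsFactors = FALSE)
  cls <- classify_evidence_chain(grid$raw, grid$corrected, grid$pre,
                                 grid$post, grid$short)
  expect_true(all(cls %in% c("sequencing_error", "polishing_error",
                             "true_variant", "unresolved")))
  expect_equal(length(cls), nrow(grid))   # one verdict per chain
  # every chain touching N is unresolved
  hasN <- apply(grid == "N", 1, any)
  expect_true(all(cls[hasN] == "unresolved"))
})

test_that("planted error classes are recovered at depth 30", {
  ch <- simulate_evidence_chains(20000, depth = 30, base_error = 1e-3,
                                 seed = 17)
  got <- classify_evidence_chain(ch$raw, ch$corrected, ch$pre, ch$post,
                                 ch$short)
  acc <- mean(got == ch$truth_class)
  expect_gte(acc, 0.95)
  rates <- estimate_error_rates(got, nrow(ch))
  truth_rate <- mean(ch$truth_class == "sequencing_error")
  expect_equal(unname(rates["sequencing_error_rate"]), truth_rate,
               tolerance = 0.05)
  expect_error(estimate_error_rates(got, 0), "assayed_bases")
  expect_equal(unname(estimate_error_rates(rep("true_variant", 5),
                                           1e6)["polishing_error_rate"]), 0)
})

test_that("planted polishing-error density is recovered within its CI", {
  dens <- 2e-4
  n <- 50000
  ch <- simulate_evidence_chains(
    n, class_probs = c(true_variant = 1 - dens, polishing_error = dens,
                       sequencing_error = 0),
    depth = 30, base_error = 1e-3, seed = 23)
  got <- classify_evidence_chain(ch$raw, ch$corrected, ch$pre, ch$post,
                                 ch$short)
  rate <- estimate_error_rates(got, n)[["polishing_error_rate"]]
  band <- qbinom(c(5e-4, 1 - 5e-4), n, dens) / n
  expect_true(rate >= band[1] && rate <= band[2])
})
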