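# heterozygosity spectrum: small variants, SV classes, ROH, summary

make_diploid <- function(seed = 3, len = 2e5, snv = 1e-3, indel = 1e-4) {
  cfg <- sim_config(toy_layout(len), snv_rate = snv, indel_rate = indel,
                    seed = seed)
  simulate_trio_genomes(cfg)
}

test_that("mismatch columns and short gaps become SNVs and small indels", {
  set.seed(10)
  s <- paste(sample(c("A", "C", "G", "T"), 4000, replace = TRUE),
             collapse = "")
  q <- s
  substr(q, 1001, 1001) <- if (substr(s, 1001, 1001) == "A") "C" else "A"
  substr(q, 2001, 2001) <- if (substr(s, 2001, 2001) == "G") "T" else "G"
  bl <- align_haplotypes(c(c = s), c(c = q))
  sm <- extract_small_variants(bl, c(c = s), c(c = q))
  expect_equal(sum(sm$class == "SNV"), 2L)
  expect_setequal(sm$ref_start[sm$class == "SNV"], c(1000L, 2000L))
  expect_equal(sm$ref_allele, substring(s, c(1001, 2001), c(1001, 2001)))

  # 3-bp deletion in the paternal haplotype
  q2 <- paste0(substr(s, 1, 1500), substr(s, 1504, 4000))
  bl2 <- align_haplotypes(c(c = s), c(c = q2))
  sm2 <- extract_small_variants(bl2, c(c = s), c(c = q2))
  ind <- sm2[sm2$class == "small_indel", ]
  expect_equal(nrow(ind), 1L)
  expect_equal(ind$length, 3L)
  expect_equal(nchar(ind$ref_allele), 3L)
})

test_that("a 60-bp gap is never a small indel and lands in the SV set", {
  set.seed(11)
  s <- paste(sample(c("A", "C", "G", "T"), 6000, replace = TRUE),
             collapse = "")
  q <- paste0(substr(s, 1, 3000), substr(s, 3061, 6000))
  bl <- align_haplotypes(c(c = s), c(c = q))
  sm <- extract_small_variants(bl, c(c = s), c(c = q))
  expect_equal(sum(sm$class == "small_indel"), 0L)
  sv <- classify_svs(bl)
  expect_equal(sv$class, "large_indel")
  expect_equal(sv$length, 60L)
})

test_that("round trip recovers planted SNVs and indels with exact alleles", {
  for (seed in c(3, 21)) {
    tr <- make_diploid(seed)
    bl <- align_haplotypes(tr$haplotypes$mat, tr$haplotypes$pat)
    sm <- extract_small_variants(bl, tr$haplotypes$mat, tr$haplotypes$pat)
    ts <- tr$variants[tr$variants$class == "SNV", ]
    cs <- sm[sm$class == "SNV", ]
    key_t <- paste(ts$ref_chrom, ts$ref_start, ts$ref_allele, ts$alt_allele)
    key_c <- paste(cs$ref_chrom, cs$ref_start, cs$ref_allele, cs$alt_allele)
    expect_setequal(key_t, key_c)
    ti <- tr$variants[tr$variants$class == "small_indel", ]
    keys_truth <- vapply(seq_len(nrow(ti)), function(i)
      norm_indel_key(ti[i, ], tr$haplotypes$mat[[ti$ref_chrom[i]]]),
      character(1))
    ci <- sm[sm$class == "small_indel", ]
    keys_call <- paste(ci$ref_chrom, ci$ref_start, ci$ref_allele,
                       ci$alt_allele)
    expect_setequal(keys_truth, keys_call)
  }
})

test_that("planted SV classes are recovered through the aligner", {
  sv <- data.frame(
    class = c("large_indel", "inversion", "translocation", "CNV",
              "inverted_translocation"),
    count = c(2, 1, 1, 1, 1),
    min_len = c(100, 2000, 1000, 1500, 1200),
    max_len = c(500, 2000, 1000, 1500, 1200))
  cfg <- sim_config(data.frame(chrom = c("a1", "a2"),
                               length = c(150000, 100000),
                               class = "autosome"),
                    snv_rate = 5e-4, indel_rate = 5e-5, sv_spec = sv,
                    seed = 11)
  tr <- simulate_trio_genomes(cfg)
  bl <- align_haplotypes(tr$haplotypes$mat, tr$haplotypes$pat)
  svs <- classify_svs(bl)
  truth <- tr$variants[!tr$variants$class %in% c("SNV", "small_indel"), ]
  for (cls in unique(truth$class)) {
    tt <- truth[truth$class == cls, ]
    cc <- svs[svs$class == cls, ]
    expect_equal(nrow(cc), nrow(tt), info = cls)
    # positions agree within anchor resolution
    expect_true(all(vapply(seq_len(nrow(tt)), function(i)
      any(cc$ref_chrom == tt$ref_chrom[i] &
            abs(cc$ref_start - tt$ref_start[i]) < 100), logical(1))),
      info = cls)
  }
  expect_equal(svs$copies[svs$class == "CNV"], 2L)
})

test_that("constructed multi-mapping query intervals classify as CNV", {
  # one query segment matching two disjoint reference loci
  blocks <- data.table::data.table(
    ref_chrom = c("r", "r", "r"),
    ref_start = c(0L, 10000L, 30000L),
    ref_end = c(8000L, 12000L, 40000L),
    qry_chrom = "q",
    qry_start = c(0L, 2000L, 22000L),
    qry_end = c(8000L, 4000L, 32000L),
    orientation = "forward", identity = 100, n_anchors = 10L)
  sv <- classify_svs(blocks)
  expect_true("CNV" %in% sv$class)
  cnv <- sv[sv$class == "CNV", ]
  expect_equal(cnv$qry_start, 2000L)
  expect_equal(cnv$qry_end, 4000L)
  expect_equal(cnv$copies, 2L)
})

test_that("unsorted block input is a contract error", {
  blocks <- data.table::data.table(
    ref_chrom = "r", ref_start = c(100L, 0L), ref_end = c(200L, 50L),
    qry_chrom = "q", qry_start = c(100L, 0L), qry_end = c(200L, 50L),
    orientation = "forward", identity = 100, n_anchors = 2L)
  expect_error(classify_svs(blocks), "sorted")
})

test_that("SV read validation follows the two evidence steps", {
  set.seed(12)
  mat <- c(m = paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE),
                     collapse = ""))
  pat <- c(p = paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE),
                     collapse = ""))
  sv <- list(ref_chrom = "m", ref_start = 2000L, ref_end = 3000L,
             qry_chrom = "p", qry_start = 2000L, qry_end = 3000L)
  # spanning read = the exact reference junction sequence
  good_read <- substr(mat[["m"]], 1701, 2300)
  status <- validate_sv_with_reads(sv, mat, pat, reads = good_read,
                                   min_similarity = 0)
  expect_equal(status, "read_supported")
  # junk read fails step 1; linked-read count saves it
  bad_read <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE),
                    collapse = "")
  expect_equal(validate_sv_with_reads(sv, mat, pat, reads = bad_read,
                                      linked_read_count = 12),
               "linked_read_supported")
  expect_equal(validate_sv_with_reads(sv, mat, pat, reads = bad_read),
               "rejected")
  expect_equal(validate_sv_with_reads(sv, mat, pat), "unresolved")
  near_end <- list(ref_chrom = "m", ref_start = 100L, ref_end = 300L,
                   qry_chrom = "p", qry_start = 100L, qry_end = 300L)
  expect_equal(validate_sv_with_reads(near_end, mat, pat,
                                      reads = good_read), "unresolved")
})

test_that("ROH detection respects the megabase floor", {
  roh <- data.frame(chrom = "a1", start = c(5e6, 15e6, 20e6),
                    length = c(0.4e6, 1.5e6, 8e6))
  cfg <- sim_config(toy_layout(30e6), snv_rate = 1e-3, indel_rate = 0,
                    roh_spec = roh, seed = 5)
  tr <- simulate_trio_genomes(cfg)
  snvs <- data.frame(chrom = tr$variants$ref_chrom,
                     pos = tr$variants$ref_start)
  rr <- detect_roh(snvs, c(a1 = 30e6))
  expect_equal(nrow(rr), 2L)     # the 0.4-Mb run never surfaces
  expect_true(all(rr$length >= 1e6))
  big <- rr[which.max(rr$length), ]
  ov <- min(big$end, 28e6) - max(big$start, 20e6)
  expect_gte(ov / 8e6, 0.95)     # planted 8-Mb run covered
  expect_error(detect_roh(snvs, c(a1 = 30e6), scan_window = 0), "scan_window")
})

test_that("a variant-free genome is wall-to-wall ROH", {
  rr <- detect_roh(data.frame(chrom = character(), pos = numeric()),
                   c(c1 = 3e6, c2 = 2e6))
  expect_equal(nrow(rr), 2L)
  expect_equal(rr$length, c(3e6, 2e6))
})

test_that("ROH intervals always respect the floor on random inputs", {
  for (seed in 1:5) {
    set.seed(seed)
    pos <- sort(sample(0:(5e6 - 1), rpois(1, 2000)))
    rr <- detect_roh(data.frame(chrom = "c", pos = pos), c(c = 5e6))
    expect_named(rr, c("chrom", "start", "end", "length"))
    if (nrow(rr)) expect_true(all(rr$length >= 1e6))
  }
})

test_that("heterozygosity summary arithmetic and monotonicity hold", {
  v_snv <- data.table::data.table(class = rep("SNV", 1300),
                                  ref_chrom = "c", ref_start = 1:1300,
                                  length = 1L)
  s1 <- summarize_heterozygosity(v_snv, 1e6)
  expect_equal(s1$snv_rate_percent, 0.13)
  expect_equal(s1$overall_rate_percent, 0.13)
  v_sv <- rbind(v_snv, data.table::data.table(
    class = c("large_indel", "CNV"), ref_chrom = "c",
    ref_start = c(5000L, 9000L), length = c(5300L, 7000L)))
  s2 <- summarize_heterozygosity(v_sv, 1e6)
  expect_equal(s2$overall_rate_percent, 1.36)
  expect_gte(s2$overall_rate_percent, s2$snv_rate_percent)
  expect_gte(s2$overall_rate_percent, s1$overall_rate_percent)
  s0 <- summarize_heterozygosity(v_snv[0, ], 1e6)
  expect_equal(s0$overall_rate_percent, 0)
  expect_error(summarize_heterozygosity(v_snv, 1e6,
                                        chrom_lengths = c(c = 100)),
               "consistency")
})
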