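# shared fixture builders and independent oracles

toy_layout <- function(length = 2e5, chrom = "a1", class = "autosome") {
  data.frame(chrom = chrom, length = length, class = class,
             stringsAsFactors = FALSE)
}

# left-normalized key for an indel truth record, comparable with calls
norm_indel_key <- function(truth_row, refseq) {
  n <- left_align_indel(refseq, truth_row$ref_start,
                        truth_row$ref_allele, truth_row$alt_allele)
  paste(truth_row$ref_chrom, n$pos, n$ref_allele, n$alt_allele)
}

# brute-force pi: 1 - sum(choose(d_b, 2)) / choose(D, 2)
brute_pi <- function(A, C, G, T) {
  D <- A + C + G + T
  if (D < 2) return(NA_real_)
  1 - sum(choose(c(A, C, G, T), 2)) / choose(D, 2)
}

# independent step-by-step verifier of the longest-non-overlapping rule:
# re-runs the selection with a plain loop and asserts each pick is the
# longest remaining candidate compatible with previous picks
verify_longest_rule <- function(cand, selected_ids) {
  remaining <- cand
  chosen <- list()
  picked <- character(0)
  repeat {
    compat <- vapply(seq_len(nrow(remaining)), function(i) {
      if (length(chosen) == 0L) return(TRUE)
      all(vapply(chosen, function(cv)
        remaining$end[i] <= cv[1] || remaining$start[i] >= cv[2],
        logical(1)))
    }, logical(1))
    if (!any(compat)) break
    pool <- remaining[compat, , drop = FALSE]
    best_len <- max(pool$match_len)
    pool <- pool[pool$match_len == best_len, , drop = FALSE]
    pick <- pool[which.min(pool$start), , drop = FALSE]
    picked <- c(picked, pick$id)
    chosen[[length(chosen) + 1L]] <- c(pick$start, pick$end)
    remaining <- remaining[remaining$id != pick$id, , drop = FALSE]
  }
  setequal(picked, selected_ids)
}

# random non-degenerate in-frame CDS from the generator's codon pool
random_cds <- function(n_codon, seed = 1) {
  set.seed(seed)
  pre <- sample(c("GG", "GC", "CC", "AC", "GT", "TC"), n_codon,
                replace = TRUE)
  paste0(pre, sample(c("A", "C", "G", "T"), n_codon, replace = TRUE),
         collapse = "")
}
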