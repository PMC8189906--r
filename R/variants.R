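# Small-variant extraction from gapless alignment blocks, SV
# classification at block junctions, and read-backed SV validation.

#' Left-align an indel against its reference context
#'
#' Normalizes an indel to its leftmost equivalent representation
#' (VCF-style), so that calls and truth records placed differently inside
#' a repeat compare equal.  Exactly one of `ref_allele`/`alt_allele` must
#' be empty.
#'
#' @param refseq reference chromosome sequence (string)
#' @param pos 0-based position where the indel starts
#' @param ref_allele deleted bases ("" for an insertion)
#' @param alt_allele inserted bases ("" for a deletion)
#' @return list(pos, ref_allele, alt_allele)
#' @export
left_align_indel <- function(refseq, pos, ref_allele, alt_allele) {
  del <- nchar(ref_allele) > 0L
  allele <- if (del) ref_allele else alt_allele
  L <- nchar(allele)
  if (L == 0L) return(list(pos = pos, ref_allele = ref_allele,
                           alt_allele = alt_allele))
  while (pos > 0L) {
    prev <- substr(refseq, pos, pos)  # base at 0-based pos-1
    if (prev != substr(allele, L, L)) break
    allele <- paste0(prev, substr(allele, 1L, L - 1L))
    pos <- pos - 1L
  }
  if (del) list(pos = pos, ref_allele = allele, alt_allele = "")
  else list(pos = pos, ref_allele = "", alt_allele = allele)
}

# decompose a global pairwise alignment of two junction segments into
# SNV and indel records (ref offsets are 0-based within the segment)
.decompose_alignment <- function(ref_seg, qry_seg) {
  if (nchar(ref_seg) == 0L && nchar(qry_seg) == 0L) return(list())
  if (nchar(ref_seg) == 0L)
    return(list(list(kind = "ins", off = 0L, ref = "", alt = qry_seg)))
  if (nchar(qry_seg) == 0L)
    return(list(list(kind = "del", off = 0L, ref = ref_seg, alt = "")))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(qry_seg), Biostrings::DNAString(ref_seg),
    type = "global", substitutionMatrix = mat,
    gapOpening = 6, gapExtension = 1)
  p <- seq_chars(as.character(Biostrings::alignedPattern(aln)))
  s <- seq_chars(as.character(Biostrings::alignedSubject(aln)))
  out <- list()
  roff <- 0L
  i <- 1L
  n <- length(p)
  while (i <= n) {
    if (s[i] != "-" && p[i] != "-") {
      if (s[i] != p[i])
        out[[length(out) + 1L]] <- list(kind = "snv", off = roff,
                                        ref = s[i], alt = p[i])
      roff <- roff + 1L
      i <- i + 1L
    } else if (p[i] == "-") {       # deletion in query
      j <- i
      while (j <= n && p[j] == "-") j <- j + 1L
      out[[length(out) + 1L]] <- list(
        kind = "del", off = roff,
        ref = paste(s[i:(j - 1L)], collapse = ""), alt = "")
      roff <- roff + (j - i)
      i <- j
    } else {                        # insertion in query
      j <- i
      while (j <= n && s[j] == "-") j <- j + 1L
      out[[length(out) + 1L]] <- list(
        kind = "ins", off = roff, ref = "",
        alt = paste(p[i:(j - 1L)], collapse = ""))
      i <- j
    }
  }
  out
}

#' Extract SNVs and small indels from alignment blocks
#'
#' Mismatch columns inside gapless blocks become SNVs.  Junctions between
#' consecutive collinear blocks whose length change is at most
#' `max_small` bp are re-aligned base-by-base (Needleman-Wunsch) and
#' decomposed into SNVs and indels; indels are left-aligned.  Junctions
#' implying a longer change are left to [classify_svs()].
#'
#' @param blocks output of [align_haplotypes()] or
#'   [read_alignment_blocks()], sorted by (ref_chrom, ref_start)
#' @param maternal,paternal the two haplotype genomes (named character
#'   vectors); maternal is the `ref` side of the blocks
#' @param max_small small-indel ceiling (bp, default 50)
#' @param refine_cap largest junction segment re-aligned base-by-base
#' @return data.table: class (`"SNV"`/`"small_indel"`), ref_chrom,
#'   ref_start, ref_end, qry_chrom, qry_start, qry_end, ref_allele,
#'   alt_allele, length
#' @export
extract_small_variants <- function(blocks, maternal, paternal,
                                   max_small = 50L, refine_cap = 5000L) {
  blocks <- data.table::as.data.table(blocks)
  recs <- list()
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    if (b$ref_end > nchar(maternal[[b$ref_chrom]]) ||
        b$qry_end > nchar(paternal[[b$qry_chrom]]))
      stop("block coordinates exceed sequence length (bounds error)")
    r <- substr(maternal[[b$ref_chrom]], b$ref_start + 1L, b$ref_end)
    q <- substr(paternal[[b$qry_chrom]], b$qry_start + 1L, b$qry_end)
    if (b$orientation == "reverse") q <- revcomp(q)
    rv <- utf8ToInt(r); qv <- utf8ToInt(q)
    mm <- which(rv != qv)
    for (m in mm) {
      qpos <- if (b$orientation == "forward") b$qry_start + m - 1L
              else b$qry_end - m
      recs[[length(recs) + 1L]] <- data.table::data.table(
        class = "SNV", ref_chrom = b$ref_chrom,
        ref_start = b$ref_start + m - 1L, ref_end = b$ref_start + m,
        qry_chrom = b$qry_chrom, qry_start = qpos, qry_end = qpos + 1L,
        ref_allele = intToUtf8(rv[m]), alt_allele = intToUtf8(qv[m]),
        length = 1L)
    }
  }
  # junction refinement between consecutive collinear forward blocks
  for (ch in unique(blocks$ref_chrom)) {
    bb <- blocks[blocks$ref_chrom == ch, ]
    bb <- bb[order(bb$ref_start), ]
    if (nrow(bb) < 2L) next
    for (i in seq_len(nrow(bb) - 1L)) {
      b1 <- bb[i, ]; b2 <- bb[i + 1L, ]
      if (b1$orientation != "forward" || b2$orientation != "forward") next
      if (b1$qry_chrom != b2$qry_chrom) next
      # adjacent blocks may overlap by a few bp when an anchor on the new
      # diagonal extends into the junction; trim the upstream block
      ov <- max(0L, b1$ref_end - b2$ref_start, b1$qry_end - b2$qry_start)
      if (ov > max_small) next
      ref_end1 <- b1$ref_end - ov
      qry_end1 <- b1$qry_end - ov
      dr <- b2$ref_start - ref_end1
      dq <- b2$qry_start - qry_end1
      if (dr < 0L || dq < 0L) next
      if (abs(dr - dq) > max_small || max(dr, dq) > refine_cap) next
      if (dr == 0L && dq == 0L) next
      ref_seg <- if (dr > 0L)
        substr(maternal[[ch]], ref_end1 + 1L, b2$ref_start) else ""
      qry_seg <- if (dq > 0L)
        substr(paternal[[b1$qry_chrom]], qry_end1 + 1L, b2$qry_start)
        else ""
      parts <- .decompose_alignment(ref_seg, qry_seg)
      for (pt in parts) {
        rpos <- ref_end1 + pt$off
        qpos <- qry_end1 + pt$off   # offset equal up to prior indels; fine
        if (pt$kind == "snv") {
          recs[[length(recs) + 1L]] <- data.table::data.table(
            class = "SNV", ref_chrom = ch, ref_start = rpos,
            ref_end = rpos + 1L, qry_chrom = b1$qry_chrom,
            qry_start = qpos, qry_end = qpos + 1L,
            ref_allele = pt$ref, alt_allele = pt$alt, length = 1L)
        } else {
          norm <- left_align_indel(maternal[[ch]], rpos, pt$ref, pt$alt)
          len <- max(nchar(pt$ref), nchar(pt$alt))
          recs[[length(recs) + 1L]] <- data.table::data.table(
            class = if (len <= max_small) "small_indel" else "large_indel",
            ref_chrom = ch, ref_start = norm$pos,
            ref_end = norm$pos + nchar(norm$ref_allele),
            qry_chrom = b1$qry_chrom, qry_start = qpos,
            qry_end = qpos + nchar(norm$alt_allele),
            ref_allele = norm$ref_allele, alt_allele = norm$alt_allele,
            length = len)
        }
      }
    }
  }
  if (length(recs) == 0L)
    return(data.table::data.table(class = character(),
                                  ref_chrom = character(),
                                  ref_start = integer(), ref_end = integer(),
                                  qry_chrom = character(),
                                  qry_start = integer(), qry_end = integer(),
                                  ref_allele = character(),
                                  alt_allele = character(),
                                  length = integer()))
  out <- data.table::rbindlist(recs)
  data.table::setorder(out, ref_chrom, ref_start)
  out[]
}

# weighted longest increasing subsequence over qry_start (weights = ref
# lengths); returns logical membership
.lis_blocks <- function(qry_start, weight) {
  n <- length(qry_start)
  if (n == 0L) return(logical(0))
  best <- weight
  prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (qry_start[j] < qry_start[i] && best[j] + weight[i] > best[i]) {
        best[i] <- best[j] + weight[i]
        prev[i] <- j
      }
    }
  }
  keep <- logical(n)
  i <- which.max(best)
  while (!is.na(i)) {
    keep[i] <- TRUE
    i <- prev[i]
  }
  keep
}
#' Classify structural variants from alignment blocks
#'
#' Works on blocks sorted per reference chromosome, with one
#' deterministic precedence: CNV > inverted_translocation > inversion >
#' translocation > large_indel.
#' \itemize{
#'   \item a reference (or query) interval covered by two or more blocks
#'     for more than `max_small` bp is a CNV; one record is emitted per
#'     contiguous multi-covered region, with the maximal coverage depth
#'     as the copy count.  Blocks mostly contained in such a region are
#'     copies, not relocations, and take no other class;
#'   \item a reverse-orientation block whose query interval sits between
#'     its syntenic neighbours is an inversion; a reverse block relocated
#'     elsewhere (or to another chromosome) is an inverted translocation;
#'   \item a forward block off the syntenic backbone (weighted longest
#'     increasing subsequence of query positions) or on another
#'     chromosome is a translocation;
#'   \item a junction between consecutive backbone blocks whose
#'     reference and query gaps differ by more than `max_small` bp is a
#'     large indel, unless the gap is explained by a relocated or copied
#'     block covering it.
#' }
#'
#' @param blocks sorted block table (contract error if unsorted)
#' @param max_small small/large indel boundary (bp, default 50)
#' @param neighbor_slack positional slack (bp) when testing whether a
#'   reverse block is in place
#' @return data.table: class, ref_chrom, ref_start, ref_end, qry_chrom,
#'   qry_start, qry_end, length, copies (CNV only, else NA)
#' @export
classify_svs <- function(blocks, max_small = 50L, neighbor_slack = 1000L) {
  blocks <- data.table::as.data.table(blocks)
  empty <- data.table::data.table(class = character(),
                                  ref_chrom = character(),
                                  ref_start = integer(), ref_end = integer(),
                                  qry_chrom = character(),
                                  qry_start = integer(), qry_end = integer(),
                                  length = integer(), copies = integer())
  if (nrow(blocks) == 0L) return(empty)
  ord <- order(blocks$ref_chrom, blocks$ref_start)
  if (!identical(ord, seq_len(nrow(blocks))))
    stop("blocks must be sorted by (ref_chrom, ref_start) (contract error)")
  n <- nrow(blocks)
  recs <- list()

  # --- CNV: sweep for intervals covered by >= 2 blocks -----------------
  multicover <- function(starts, ends) {
    ev <- data.frame(pos = c(starts, ends),
                     d = rep(c(1L, -1L), each = length(starts)))
    ev <- ev[order(ev$pos, -ev$d), ]
    depth <- cumsum(ev$d)
    out <- list()
    run_start <- NA_real_
    run_depth <- 0L
    for (i in seq_len(nrow(ev))) {
      if (depth[i] >= 2L) {
        if (is.na(run_start)) { run_start <- ev$pos[i]; run_depth <- depth[i] }
        else run_depth <- max(run_depth, depth[i])
      } else if (!is.na(run_start)) {
        out[[length(out) + 1L]] <- c(run_start, ev$pos[i], run_depth)
        run_start <- NA_real_
      }
    }
    out
  }
  cnv_regions_ref <- list()   # per record: chrom, start, end, depth
  cnv_regions_qry <- list()
  for (ch in unique(blocks$ref_chrom)) {
    idx <- which(blocks$ref_chrom == ch)
    for (reg in multicover(blocks$ref_start[idx], blocks$ref_end[idx])) {
      if (reg[2] - reg[1] > max_small)
        cnv_regions_ref[[length(cnv_regions_ref) + 1L]] <-
          list(chrom = ch, start = reg[1], end = reg[2], depth = reg[3])
    }
  }
  for (ch in unique(blocks$qry_chrom)) {
    idx <- which(blocks$qry_chrom == ch)
    for (reg in multicover(blocks$qry_start[idx], blocks$qry_end[idx])) {
      if (reg[2] - reg[1] > max_small)
        cnv_regions_qry[[length(cnv_regions_qry) + 1L]] <-
          list(chrom = ch, start = reg[1], end = reg[2], depth = reg[3])
    }
  }
  for (r in cnv_regions_ref) {
    cov <- which(blocks$ref_chrom == r$chrom &
                   blocks$ref_end > r$start & blocks$ref_start < r$end)
    recs[[length(recs) + 1L]] <- data.table::data.table(
      class = "CNV", ref_chrom = r$chrom,
      ref_start = as.integer(r$start), ref_end = as.integer(r$end),
      qry_chrom = blocks$qry_chrom[cov[1]],
      qry_start = min(blocks$qry_start[cov]),
      qry_end = max(blocks$qry_end[cov]),
      length = as.integer(r$end - r$start), copies = as.integer(r$depth))
  }
  for (r in cnv_regions_qry) {
    cov <- which(blocks$qry_chrom == r$chrom &
                   blocks$qry_end > r$start & blocks$qry_start < r$end)
    recs[[length(recs) + 1L]] <- data.table::data.table(
      class = "CNV", ref_chrom = blocks$ref_chrom[cov[1]],
      ref_start = min(blocks$ref_start[cov]),
      ref_end = max(blocks$ref_end[cov]),
      qry_chrom = r$chrom,
      qry_start = as.integer(r$start), qry_end = as.integer(r$end),
      length = as.integer(r$end - r$start), copies = as.integer(r$depth))
  }

  # blocks mostly contained in a multi-covered region are extra copies
  frac_in <- function(s, e, regions, chrom) {
    if (length(regions) == 0L) return(0)
    tot <- 0
    for (r in regions) {
      if (r$chrom != chrom) next
      tot <- tot + max(0, min(e, r$end) - max(s, r$start))
    }
    tot / (e - s)
  }
  cnv_block <- vapply(seq_len(n), function(i) {
    frac_in(blocks$ref_start[i], blocks$ref_end[i], cnv_regions_ref,
            blocks$ref_chrom[i]) >= 0.7 ||
      frac_in(blocks$qry_start[i], blocks$qry_end[i], cnv_regions_qry,
              blocks$qry_chrom[i]) >= 0.7
  }, logical(1))

  role <- ifelse(cnv_block, "CNV", "")
  for (ch in unique(blocks$ref_chrom)) {
    idx <- which(blocks$ref_chrom == ch & role != "CNV")
    if (length(idx) == 0L) next
    fwd <- idx[blocks$orientation[idx] == "forward"]
    if (length(fwd)) {
      ab <- tapply(blocks$ref_end[fwd] - blocks$ref_start[fwd],
                   blocks$qry_chrom[fwd], sum)
      dom <- names(ab)[which.max(ab)]
    } else dom <- NA_character_
    bb_cand <- fwd[blocks$qry_chrom[fwd] == dom]
    keep <- .lis_blocks(blocks$qry_start[bb_cand],
                        blocks$ref_end[bb_cand] - blocks$ref_start[bb_cand])
    backbone <- bb_cand[keep]
    role[backbone] <- "backbone"

    for (i in setdiff(idx, backbone)) {
      if (blocks$orientation[i] == "reverse") {
        prev_b <- backbone[blocks$ref_start[backbone] <= blocks$ref_start[i]]
        next_b <- backbone[blocks$ref_start[backbone] > blocks$ref_start[i]]
        lo <- if (length(prev_b)) blocks$qry_end[max(prev_b)] else -Inf
        hi <- if (length(next_b)) blocks$qry_start[min(next_b)] else Inf
        in_place <- !is.na(dom) && blocks$qry_chrom[i] == dom &&
          blocks$qry_start[i] >= lo - neighbor_slack &&
          blocks$qry_end[i] <= hi + neighbor_slack
        cls <- if (in_place) "inversion" else "inverted_translocation"
      } else cls <- "translocation"
      role[i] <- cls
      recs[[length(recs) + 1L]] <- data.table::data.table(
        class = cls, ref_chrom = blocks$ref_chrom[i],
        ref_start = blocks$ref_start[i], ref_end = blocks$ref_end[i],
        qry_chrom = blocks$qry_chrom[i], qry_start = blocks$qry_start[i],
        qry_end = blocks$qry_end[i],
        length = blocks$ref_end[i] - blocks$ref_start[i],
        copies = NA_integer_)
    }

    # large indels at backbone junctions not explained by other blocks
    if (length(backbone) >= 2L) {
      bs <- backbone[order(blocks$ref_start[backbone])]
      others <- setdiff(seq_len(n), backbone)
      covered <- function(s, e, side) {
        if (e <= s || length(others) == 0L) return(FALSE)
        ss <- if (side == "ref") blocks$ref_start[others] else
          blocks$qry_start[others]
        ee <- if (side == "ref") blocks$ref_end[others] else
          blocks$qry_end[others]
        chs <- if (side == "ref") blocks$ref_chrom[others] else
          blocks$qry_chrom[others]
        target_ch <- if (side == "ref") ch else dom
        ov <- pmin(ee, e) - pmax(ss, s)
        any(chs == target_ch & ov >= 0.5 * (e - s))
      }
      for (t in seq_len(length(bs) - 1L)) {
        b1 <- bs[t]; b2 <- bs[t + 1L]
        dr <- blocks$ref_start[b2] - blocks$ref_end[b1]
        dq <- blocks$qry_start[b2] - blocks$qry_end[b1]
        diff <- abs(dr - dq)
        if (diff <= max_small) next
        # a negative gap is a duplication already reported as CNV
        if (dr < -max_small || dq < -max_small) next
        if (covered(blocks$ref_end[b1], blocks$ref_start[b2], "ref")) next
        if (covered(blocks$qry_end[b1], blocks$qry_start[b2], "qry")) next
        recs[[length(recs) + 1L]] <- data.table::data.table(
          class = "large_indel", ref_chrom = ch,
          ref_start = blocks$ref_end[b1], ref_end = blocks$ref_start[b2],
          qry_chrom = blocks$qry_chrom[b1],
          qry_start = blocks$qry_end[b1], qry_end = blocks$qry_start[b2],
          length = diff, copies = NA_integer_)
      }
    }
  }
  if (length(recs) == 0L) return(empty)
  out <- data.table::rbindlist(recs)
  data.table::setorder(out, ref_chrom, ref_start)
  out[]
}


#' Validate a structural variant with local reads
#'
#' Step 1 clips `flank` bp on each side of the reference-side break
#' point, requires a local read alignment at identity above
#' `min_identity` over more than `min_aln_len` bp, and requires the two
#' haplotypes' junction regions to align at similarity above
#' `min_similarity`.  Step 2, taken when step 1 fails, requires the
#' linked-read count within the 5-kb flanking region to reach
#' `min_linked_reads`.  With no evidence at all the SV is unresolved.
#'
#' @param sv one SV record (list/one-row data.frame with ref_chrom,
#'   ref_start, ref_end, qry_chrom, qry_start, qry_end)
#' @param maternal,paternal haplotype genomes (named character vectors)
#' @param reads character vector of local long-read sequences (may be
#'   empty)
#' @param linked_read_count 10X linked-read count in the 5-kb flanking
#'   region (`NA` if not assayed)
#' @param flank break-point flank clipped for matching (bp)
#' @param min_identity,min_aln_len,min_similarity step-1 thresholds
#'   (fractions/bp)
#' @param min_linked_reads step-2 threshold
#' @return one of `"read_supported"`, `"linked_read_supported"`,
#'   `"rejected"`, `"unresolved"`
#' @export
validate_sv_with_reads <- function(sv, maternal, paternal,
                                   reads = character(0),
                                   linked_read_count = NA,
                                   flank = 300L, min_identity = 0.96,
                                   min_aln_len = 550L,
                                   min_similarity = 0.90,
                                   min_linked_reads = 5L) {
  sv <- as.list(sv)
  Lr <- nchar(maternal[[sv$ref_chrom]])
  Lq <- nchar(paternal[[sv$qry_chrom]])
  if (sv$ref_start < flank || sv$ref_start + flank > Lr ||
      sv$qry_start < flank || sv$qry_start + flank > Lq)
    return("unresolved")   # break point too close to a contig end
  ref_junction <- substr(maternal[[sv$ref_chrom]],
                         sv$ref_start - flank + 1L, sv$ref_start + flank)
  qry_junction <- substr(paternal[[sv$qry_chrom]],
                         sv$qry_start - flank + 1L, sv$qry_start + flank)
  if (length(reads) == 0L && is.na(linked_read_count)) return("unresolved")
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                     mismatch = -1)
  if (length(reads)) {
    sim <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(qry_junction),
      Biostrings::DNAString(ref_junction), type = "local",
      substitutionMatrix = submat, gapOpening = 4, gapExtension = 1)
    sim_ok <- Biostrings::pid(sim) / 100 > min_similarity
    for (rd in reads) {
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(rd), Biostrings::DNAString(ref_junction),
        type = "local", substitutionMatrix = submat,
        gapOpening = 4, gapExtension = 1)
      aln_len <- nchar(as.character(Biostrings::alignedSubject(aln)))
      if (Biostrings::pid(aln) / 100 > min_identity &&
          aln_len > min_aln_len && sim_ok)
        return("read_supported")
    }
  }
  if (!is.na(linked_read_count) && linked_read_count >= min_linked_reads)
    return("linked_read_supported")
  "rejected"
}
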