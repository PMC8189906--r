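# Built-in exact-anchor aligner for toy diploid genomes.
#
# Unique k-mers of the reference (maternal) genome are located in the
# query (paternal) genome on both strands; anchors sharing a diagonal are
# chained into gapless collinear blocks.  Because blocks never cross an
# indel (any length change shifts the diagonal), mismatch columns inside
# a block are SNVs and every indel or SV surfaces as a block junction or
# a relocated/reverse/multi-covering block.  Genomes beyond 50 Mb total
# are refused; externally computed alignment blocks (nucmer show-coords
# or PAF) are accepted instead via read_alignment_blocks().

.kmer_starts <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, 1:(n - k + 1L), k:n)
}

#' Align two haplotype genomes with exact unique anchors
#'
#' @param maternal,paternal named character vectors of chromosome
#'   sequences (A/C/G/T/N; anchors never contain N)
#' @param anchor_len anchor k-mer length (default 31)
#' @param join_gap maximal within-diagonal anchor gap (bp) bridged when
#'   chaining.  SNV clusters are bridged; anything longer splits blocks so
#'   that length-neutral events (inversions, substituted segments) surface
#'   as junctions rather than being absorbed.  Inversions shorter than
#'   `join_gap` are not separated from their flanks.
#' @param max_occ_qry maximal number of query occurrences of an anchor
#'   k-mer (> 1 admits duplicated segments so CNVs surface as ref
#'   intervals covered by two blocks)
#' @return data.table of alignment blocks: ref_chrom, ref_start, ref_end,
#'   qry_chrom, qry_start, qry_end (0-based half-open, start < end),
#'   orientation (`"forward"`/`"reverse"`), identity (percent),
#'   n_anchors; sorted by (ref_chrom, ref_start)
#' @export
align_haplotypes <- function(maternal, paternal, anchor_len = 31L,
                             join_gap = 200L, max_occ_qry = 4L) {
  if (is.null(names(maternal)) || is.null(names(paternal)))
    stop("sequences must be named character vectors")
  total <- sum(nchar(maternal)) + sum(nchar(paternal))
  if (total > 50e6)
    stop("built-in aligner is limited to 50 Mb total; supply external ",
         "alignment blocks via read_alignment_blocks()")
  for (s in c(maternal, paternal)) check_alphabet(s)
  k <- as.integer(anchor_len)

  # reference k-mers, kept only if unique across the whole reference
  ref_tab <- data.table::rbindlist(lapply(names(maternal), function(ch) {
    km <- .kmer_starts(maternal[[ch]], k)
    if (!length(km)) return(NULL)
    data.table::data.table(kmer = km, ref_chrom = ch,
                           ref_pos = 0:(length(km) - 1L))
  }))
  if (nrow(ref_tab) == 0L) return(.empty_blocks())
  ref_tab <- ref_tab[!grepl("N", ref_tab$kmer, fixed = TRUE), ]
  dup <- ref_tab$kmer %in% ref_tab$kmer[duplicated(ref_tab$kmer)]
  ref_tab <- ref_tab[!dup, ]

  # query occurrences on both strands (reverse strand scanned through the
  # reverse complement; rc_pos converts back to forward coordinates)
  qry_list <- lapply(names(paternal), function(ch) {
    sq <- paternal[[ch]]
    Lq <- nchar(sq)
    fw <- .kmer_starts(sq, k)
    rc <- .kmer_starts(revcomp(sq), k)
    rbind(
      if (length(fw)) data.table::data.table(
        kmer = fw, qry_chrom = ch, qry_pos = 0:(length(fw) - 1L),
        strand = "forward"),
      if (length(rc)) data.table::data.table(
        kmer = rc, qry_chrom = ch, qry_pos = Lq - k - (0:(length(rc) - 1L)),
        strand = "reverse"))
  })
  qry_tab <- data.table::rbindlist(qry_list)
  if (nrow(qry_tab) == 0L) return(.empty_blocks())
  qry_tab[, occ := .N, by = "kmer"]
  qry_tab <- qry_tab[qry_tab$occ <= max_occ_qry, ]
  qry_tab$occ <- NULL

  anchors <- merge(ref_tab, qry_tab, by = "kmer", allow.cartesian = TRUE)
  if (nrow(anchors) == 0L) return(.empty_blocks())

  # chain anchors sharing a diagonal; on the reverse strand the invariant
  # diagonal uses the position in the reverse-complemented query
  Lq_of <- stats::setNames(nchar(paternal), names(paternal))
  anchors$diag <- ifelse(anchors$strand == "forward",
                         anchors$qry_pos - anchors$ref_pos,
                         (Lq_of[anchors$qry_chrom] - k - anchors$qry_pos) -
                           anchors$ref_pos)
  data.table::setorder(anchors, ref_chrom, qry_chrom, strand, diag, ref_pos)
  grp <- paste(anchors$ref_chrom, anchors$qry_chrom, anchors$strand,
               anchors$diag)
  new_grp <- c(TRUE, grp[-1] != grp[-length(grp)])
  gap_break <- c(TRUE, diff(anchors$ref_pos) > join_gap)
  block_id <- cumsum(new_grp | gap_break)

  a <- anchors
  a$block_id <- block_id
  blocks <- a[, list(
    ref_chrom = ref_chrom[1],
    ref_start = min(ref_pos), ref_end = max(ref_pos) + k,
    qry_chrom = qry_chrom[1],
    qry_start = min(qry_pos), qry_end = max(qry_pos) + k,
    orientation = strand[1], n_anchors = .N), by = "block_id"]
  blocks$block_id <- NULL

  blocks$identity <- vapply(seq_len(nrow(blocks)), function(i) {
    b <- blocks[i, ]
    r <- substr(maternal[[b$ref_chrom]], b$ref_start + 1L, b$ref_end)
    q <- substr(paternal[[b$qry_chrom]], b$qry_start + 1L, b$qry_end)
    if (b$orientation == "reverse") q <- revcomp(q)
    mism <- sum(utf8ToInt(r) != utf8ToInt(q))
    100 * (1 - mism / nchar(r))
  }, numeric(1))
  data.table::setorder(blocks, ref_chrom, ref_start)
  data.table::setcolorder(blocks, c("ref_chrom", "ref_start", "ref_end",
                                    "qry_chrom", "qry_start", "qry_end",
                                    "orientation", "identity", "n_anchors"))
  blocks[]
}

.empty_blocks <- function() {
  data.table::data.table(ref_chrom = character(), ref_start = integer(),
                         ref_end = integer(), qry_chrom = character(),
                         qry_start = integer(), qry_end = integer(),
                         orientation = character(), identity = numeric(),
                         n_anchors = integer())
}

#' Read whole-genome alignment blocks from standard formats
#'
#' Accepts `nucmer show-coords -TH` tab output (columns S1 E1 S2 E2 LEN1
#' LEN2 %IDY REF QRY; 1-based inclusive; a reverse alignment has S2 > E2)
#' or PAF (0-based half-open; strand column).  Coordinates are
#' normalized to 0-based half-open with start < end on both sides and an
#' orientation flag.
#'
#' @param path file path
#' @param dialect `"coords"` or `"paf"`
#' @return data.table with the same columns as [align_haplotypes()]
#'   (n_anchors is `NA`); an empty file yields an empty table
#' @export
read_alignment_blocks <- function(path, dialect = c("coords", "paf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(.empty_blocks()[, -"n_anchors"])
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (dialect == "coords") {
      if (length(f) < 9L)
        stop("parse error at line ", i, ": expected >= 9 tab fields")
      v <- suppressWarnings(as.numeric(f[1:7]))
      if (any(is.na(v)))
        stop("parse error at line ", i, ": non-numeric coordinate")
      s1 <- v[1]; e1 <- v[2]; s2 <- v[3]; e2 <- v[4]; idy <- v[7]
      if (e1 < s1)
        stop("parse error at line ", i,
             ": reference end < start in coords dialect")
      if (s2 <= e2) {
        data.table::data.table(ref_chrom = f[8], ref_start = s1 - 1,
                               ref_end = e1, qry_chrom = f[9],
                               qry_start = s2 - 1, qry_end = e2,
                               orientation = "forward", identity = idy)
      } else {
        data.table::data.table(ref_chrom = f[8], ref_start = s1 - 1,
                               ref_end = e1, qry_chrom = f[9],
                               qry_start = e2 - 1, qry_end = s2,
                               orientation = "reverse", identity = idy)
      }
    } else {
      if (length(f) < 12L)
        stop("parse error at line ", i, ": expected >= 12 PAF fields")
      v <- suppressWarnings(as.numeric(f[c(3, 4, 8, 9, 10, 11)]))
      if (any(is.na(v)) || !(f[5] %in% c("+", "-")))
        stop("parse error at line ", i, ": malformed PAF row")
      data.table::data.table(ref_chrom = f[6], ref_start = v[3],
                             ref_end = v[4], qry_chrom = f[1],
                             qry_start = v[1], qry_end = v[2],
                             orientation = if (f[5] == "+") "forward"
                                           else "reverse",
                             identity = 100 * v[5] / max(v[6], 1))
    }
  })
  out <- data.table::rbindlist(rows)
  out$ref_start <- as.integer(out$ref_start)
  out$ref_end <- as.integer(out$ref_end)
  out$qry_start <- as.integer(out$qry_start)
  out$qry_end <- as.integer(out$qry_end)
  data.table::setorder(out, ref_chrom, ref_start)
  out[]
}
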