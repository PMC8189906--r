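# Pileup site QC: the per-site nucleotide-diversity statistic pi, the
# complex-site filter, confident-SNP set construction and the evidence-
# chain partition of assembly errors into sequencing vs polishing classes.

#' Per-site pileup nucleotide diversity
#'
#' \deqn{\pi = 2 (AT + AC + AG + TC + TG + CG) / (D (D - 1))}
#' where A, T, C, G are the per-base read depths at the site, the pairwise
#' terms are products of depths (AT = depth_A x depth_T, ...), and
#' D = A + T + C + G.  This is the probability that two reads drawn
#' without replacement from the pileup carry different bases; it is 0 for
#' a monoallelic pileup and approaches 1/2 for an even biallelic split.
#'
#' @param A,C,G,T per-base depths (vectors recycle)
#' @return pi in `[0, 1]`; `NA` where D < 2 (undefined)
#' @examples
#' compute_pi(A = 20, T = 20, C = 14, G = 0)  # 1920/2862
#' @export
compute_pi <- function(A, C, G, T) {
  D <- A + C + G + T
  num <- 2 * (A * T + A * C + A * G + T * C + T * G + C * G)
  out <- ifelse(D < 2, NA_real_, num / (D * (D - 1)))
  out
}

#' Classify a pileup site as kept, low-depth or complex
#'
#' A site is `low_depth` when total depth is below `min_depth`; `complex`
#' when pi exceeds `pi_cut` AND the third-highest base depth exceeds
#' `third_depth_cut` (three bases each carried by many reads, so no
#' typical haplotype base can be called); otherwise `kept`.  The
#' third-highest depth is the third entry of the depths sorted decreasing
#' by value (ties broken by value, not base label).
#'
#' @param A,C,G,T per-base depths (vectors recycle)
#' @param min_depth minimum usable depth (default 10)
#' @param pi_cut pi threshold for the complex condition (default 0.4)
#' @param third_depth_cut third-highest-depth threshold (default 5)
#' @return character vector in `{"kept", "low_depth", "complex"}`
#' @export
classify_pileup_site <- function(A, C, G, T, min_depth = 10,
                                 pi_cut = 0.4, third_depth_cut = 5) {
  n <- max(length(A), length(C), length(G), length(T))
  A <- rep_len(A, n); C <- rep_len(C, n)
  G <- rep_len(G, n); T <- rep_len(T, n)
  D <- A + C + G + T
  pi <- compute_pi(A, C, G, T)
  third <- apply(cbind(A, C, G, T), 1L,
                 function(x) sort(x, decreasing = TRUE)[3L])
  out <- rep("kept", n)
  out[!is.na(pi) & pi > pi_cut & third > third_depth_cut] <- "complex"
  out[D < min_depth] <- "low_depth"
  out
}

#' Build the confident SNP sets from three callers
#'
#' Reproduces the two-step set algebra: `Set1 = setB` \eqn{\cap} `setC`
#' (the two read-mapping callers agree), `Set2 = setA` \eqn{\cup} `Set1`
#' (union with the whole-genome-alignment set), and `Set3 = Set2` minus
#' sites failing the pileup filter ([classify_pileup_site()]) or absent
#' from both haplotype alignments.
#'
#' @param setA,setB,setC character vectors of site keys
#'   (`"chrom:pos:ref:alt"` or any consistent key)
#' @param pileups optional data.frame keyed by `key` with columns
#'   `A`, `C`, `G`, `T`; sites present here are screened with
#'   [classify_pileup_site()], sites absent are kept
#' @param aligned optional character vector of keys that align to both
#'   haplotype assemblies; when supplied, Set3 drops keys outside it
#' @param ... passed to [classify_pileup_site()]
#' @return list with `set1`, `set2`, `set3` (character vectors) and
#'   `filtered` (data.frame of Set2 keys with their filter verdict)
#' @export
build_snp_sets <- function(setA, setB, setC, pileups = NULL,
                           aligned = NULL, ...) {
  set1 <- intersect(setB, setC)
  set2 <- union(setA, set1)
  verdict <- rep("kept", length(set2))
  names(verdict) <- set2
  if (!is.null(pileups)) {
    pileups <- as.data.frame(pileups)
    stopifnot(all(c("key", "A", "C", "G", "T") %in% names(pileups)))
    if (anyDuplicated(pileups$key))
      stop("inconsistent duplicate pileup records for the same key")
    m <- match(set2, pileups$key)
    has <- !is.na(m)
    if (any(has)) {
      cl <- classify_pileup_site(pileups$A[m[has]], pileups$C[m[has]],
                                 pileups$G[m[has]], pileups$T[m[has]], ...)
      verdict[has] <- ifelse(cl == "kept", "kept", cl)
    }
  }
  if (!is.null(aligned)) verdict[!(set2 %in% aligned)] <- "unaligned"
  set3 <- set2[verdict == "kept"]
  list(set1 = set1, set2 = set2, set3 = set3,
       filtered = data.frame(key = set2, verdict = unname(verdict),
                             stringsAsFactors = FALSE))
}

#' Classify an evidence chain into an error type
#'
#' The chain records, for one haplotype at one site, the consensus base at
#' five stages: raw long reads, corrected long reads, pre-polish assembly,
#' post-polish assembly, and short reads.  The decision table (applied in
#' this order, so classes are mutually exclusive):
#' \itemize{
#'   \item any `N` at a decisive position: `unresolved`;
#'   \item `sequencing_error`: the final (post-polish) base matches the
#'     raw-read consensus but conflicts with both the corrected-read and
#'     the short-read consensus (a raw miscall survived assembly);
#'   \item `polishing_error`: the pre-polish base matched the short-read
#'     consensus and the post-polish base departed from it (polishing
#'     introduced the change);
#'   \item `true_variant`: final base, corrected reads and short reads
#'     agree;
#'   \item otherwise `unresolved`.
#' }
#'
#' @param raw,corrected,pre,post,short consensus bases (vectors recycle),
#'   each in `{A, C, G, T, N}`
#' @return character vector in `{"sequencing_error", "polishing_error",
#'   "true_variant", "unresolved"}`
#' @export
classify_evidence_chain <- function(raw, corrected, pre, post, short) {
  n <- max(length(raw), length(corrected), length(pre), length(post),
           length(short))
  raw <- rep_len(raw, n); corrected <- rep_len(corrected, n)
  pre <- rep_len(pre, n); post <- rep_len(post, n)
  short <- rep_len(short, n)
  bad <- raw == "N" | corrected == "N" | pre == "N" | post == "N" |
    short == "N"
  out <- rep("unresolved", n)
  is_seq <- post == raw & post != corrected & post != short
  is_pol <- !is_seq & pre == short & post != short
  is_true <- !is_seq & !is_pol & post == corrected & post == short
  out[is_seq] <- "sequencing_error"
  out[is_pol] <- "polishing_error"
  out[is_true] <- "true_variant"
  out[bad] <- "unresolved"
  out
}

#' Per-class error rates from classified sites
#'
#' @param classes character vector of [classify_evidence_chain()] outputs
#' @param assayed_bases denominator: number of assayed bases (> 0); by
#'   convention the number of sites with complete chains, configurable to
#'   the haplotype length
#' @return named numeric: sequencing_error_rate, polishing_error_rate
#' @export
estimate_error_rates <- function(classes, assayed_bases) {
  if (assayed_bases <= 0) stop("assayed_bases must be > 0")
  c(sequencing_error_rate = sum(classes == "sequencing_error") / assayed_bases,
    polishing_error_rate = sum(classes == "polishing_error") / assayed_bases)
}
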