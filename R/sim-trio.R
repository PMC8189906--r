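# Diploid trio truth-set generator.
#
# The maternal haplotype is drawn at random; the paternal haplotype is the
# maternal one with planted heterozygous variants (SNVs, indels, SVs); the
# child's maternal- and paternal-inherited haplotypes are the transmitted
# parental haplotypes plus planted de novo mutations.  Both parents are
# modelled homozygous for their transmitted allele at every site, which is
# what makes the dual-reference DNM genotype patterns exact: each haplotype
# assembly derives from the child's reads and therefore carries the child's
# DNMs as its reference base.

MARGIN_SV <- 150L     # bp kept clear around a structural event
MARGIN_SMALL <- 60L   # bp kept clear around a small indel
MARGIN_SNV <- 2L      # bp kept clear around an SNV
MARGIN_END <- 60L     # bp kept clear of sequence ends (anchor edge effects)
MAX_PLACEMENT_TRIES <- 100L

# occupancy masks: one raw vector per chromosome inside an environment,
# so that reservation updates are in place (reference semantics)
.mask_new <- function(chrom_lens) {
  e <- new.env(parent = emptyenv())
  for (ch in names(chrom_lens)) e[[ch]] <- raw(as.integer(chrom_lens[[ch]]))
  e
}

.mask_set <- function(mask, chrom, start, end) {
  s <- max(0L, as.integer(start))
  e <- min(length(mask[[chrom]]), as.integer(end))
  if (e > s) mask[[chrom]][(s + 1L):e] <- as.raw(1)
  invisible(mask)
}

.mask_free <- function(mask, chrom, start, end) {
  s <- max(0L, as.integer(start))
  e <- min(length(mask[[chrom]]), as.integer(end))
  if (e <= s) return(TRUE)
  !any(mask[[chrom]][(s + 1L):e] != as.raw(0))
}

.place_interval <- function(occ, roh, chrom_lens, len, margin, chroms = NULL) {
  chroms <- chroms %||% names(chrom_lens)
  w <- chrom_lens[chroms]
  w <- w[w > len + 2 * margin]
  if (length(w) == 0L) return(NULL)
  for (i in seq_len(MAX_PLACEMENT_TRIES)) {
    chrom <- if (length(w) == 1L) names(w) else
      sample(names(w), 1L, prob = as.numeric(w))
    start <- floor(runif(1, margin, w[[chrom]] - len - margin))
    end <- start + len
    if (.mask_free(occ, chrom, start - margin, end + margin) &&
        .mask_free(roh, chrom, start, end))
      return(list(chrom = chrom, start = as.integer(start),
                  end = as.integer(end)))
  }
  NULL
}

#' Simulate a diploid trio genome with planted truth
#'
#' Generates parental haplotype sequences, the child's transmitted
#' haplotypes, and machine-readable truth tables for every planted
#' heterozygous variant, de novo mutation and run of homozygosity.
#' Variant placement collisions are resolved by bounded resampling
#' (100 attempts) and then raise a placement error, so truth tables are
#' unambiguous by construction.  All coordinates are 0-based half-open;
#' `ref` denotes the maternal haplotype and `qry` the paternal one.
#'
#' @param config a [sim_config()]
#' @return object of class `trio_truth`: list with `haplotypes` (named
#'   character vectors `mat`, `pat` per chromosome), `child` (`mat`, `pat`
#'   carrying the DNMs), `variants`, `dnms`, `roh`, `layout`, `config`.
#' @examples
#' cfg <- sim_config(data.frame(chrom = "a1", length = 20000,
#'                              class = "autosome"),
#'                   snv_rate = 1e-3, indel_rate = 0, seed = 7)
#' tr <- simulate_trio_genomes(cfg)
#' nrow(tr$variants)
#' @export
simulate_trio_genomes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  layout <- config$genome_layout
  chrom_lens <- stats::setNames(as.numeric(layout$length), layout$chrom)

  with_substream(config$seed, "trio", {
    haps_mat <- vapply(layout$chrom, function(ch)
      random_dna(chrom_lens[[ch]]), character(1))
    names(haps_mat) <- layout$chrom

    occ <- .mask_new(chrom_lens)
    roh_mask <- .mask_new(chrom_lens)
    if (nrow(config$roh_spec)) {
      for (i in seq_len(nrow(config$roh_spec))) {
        r <- config$roh_spec[i, ]
        roh_mask <- .mask_set(roh_mask, r$chrom, r$start, r$start + r$length)
      }
    }

    events <- list()

    # --- structural variants --------------------------------------------
    sv <- config$sv_spec
    if (nrow(sv)) {
      for (i in seq_len(nrow(sv))) {
        for (j in seq_len(sv$count[i])) {
          len <- if (sv$min_len[i] == sv$max_len[i]) sv$min_len[i] else
            sample(sv$min_len[i]:sv$max_len[i], 1L)
          loc <- .place_interval(occ, roh_mask, chrom_lens, len, MARGIN_SV)
          if (is.null(loc))
            stop("could not place ", sv$class[i], " of length ", len,
                 " after ", MAX_PLACEMENT_TRIES, " attempts (placement error)")
          occ <- .mask_set(occ, loc$chrom, loc$start - MARGIN_SV,
                           loc$end + MARGIN_SV)
          cls <- sv$class[i]
          if (cls == "large_indel") {
            if (runif(1) < 0.5) {
              events[[length(events) + 1L]] <- list(
                chrom = loc$chrom, start = loc$start, end = loc$end,
                type = "del", class = "large_indel", len = len)
            } else {
              events[[length(events) + 1L]] <- list(
                chrom = loc$chrom, start = loc$start, end = loc$start,
                type = "ins", class = "large_indel", len = len,
                payload = random_dna(len))
            }
          } else if (cls == "inversion") {
            events[[length(events) + 1L]] <- list(
              chrom = loc$chrom, start = loc$start, end = loc$end,
              type = "inv", class = "inversion", len = len)
          } else if (cls == "CNV") {
            events[[length(events) + 1L]] <- list(
              chrom = loc$chrom, start = loc$start, end = loc$end,
              type = "dup", class = "CNV", len = len)
          } else { # translocation / inverted_translocation
            dest_chroms <- setdiff(layout$chrom, loc$chrom)
            if (length(dest_chroms) == 0L) dest_chroms <- loc$chrom
            dest <- .place_interval(occ, roh_mask, chrom_lens, 1L, MARGIN_SV,
                                    chroms = dest_chroms)
            if (is.null(dest))
              stop("could not place translocation destination (placement error)")
            occ <- .mask_set(occ, dest$chrom, dest$start - MARGIN_SV,
                             dest$start + MARGIN_SV)
            events[[length(events) + 1L]] <- list(
              chrom = loc$chrom, start = loc$start, end = loc$end,
              type = "cut", class = cls, len = len)
            events[[length(events) + 1L]] <- list(
              chrom = dest$chrom, start = dest$start, end = dest$start,
              type = "paste", class = cls, len = len,
              src_chrom = loc$chrom, src_start = loc$start,
              src_end = loc$end,
              inverted = (cls == "inverted_translocation"))
          }
        }
      }
    }

    # --- small indels ----------------------------------------------------
    if (config$indel_rate > 0) {
      n_indel <- rpois(1, config$indel_rate * sum(chrom_lens))
      for (j in seq_len(n_indel)) {
        len <- sample.int(config$indel_len_max, 1L)
        loc <- .place_interval(occ, roh_mask, chrom_lens, len, MARGIN_SMALL)
        if (is.null(loc))
          stop("could not place small indel (placement error)")
        occ <- .mask_set(occ, loc$chrom, loc$start - MARGIN_SMALL,
                         loc$end + MARGIN_SMALL)
        if (runif(1) < 0.5) {
          events[[length(events) + 1L]] <- list(
            chrom = loc$chrom, start = loc$start, end = loc$end,
            type = "del", class = "small_indel", len = len)
        } else {
          events[[length(events) + 1L]] <- list(
            chrom = loc$chrom, start = loc$start, end = loc$start,
            type = "ins", class = "small_indel", len = len,
            payload = random_dna(len))
        }
      }
    }

    # --- SNVs (batch placement, bounded resampling rounds) ---------------
    if (config$snv_rate > 0) {
      n_target <- rpois(1, config$snv_rate * sum(chrom_lens))
      placed <- 0L
      for (round in seq_len(MAX_PLACEMENT_TRIES)) {
        need <- n_target - placed
        if (need <= 0L) break
        chrom <- sample(layout$chrom, need, replace = TRUE,
                        prob = as.numeric(chrom_lens))
        pos <- floor(runif(need, MARGIN_END,
                           chrom_lens[chrom] - MARGIN_END - 1))
        for (ch in unique(chrom)) {
          sel <- which(chrom == ch)
          p <- as.integer(pos[sel])
          free <- occ[[ch]][p + 1L] == as.raw(0) &
            roh_mask[[ch]][p + 1L] == as.raw(0)
          p <- unique(p[free])
          if (length(p) == 0L) next
          # margin check + reserve
          for (pk in p) {
            if (!.mask_free(occ, ch, pk - MARGIN_SNV, pk + 1L + MARGIN_SNV))
              next
            occ <- .mask_set(occ, ch, pk - MARGIN_SNV, pk + 1L + MARGIN_SNV)
            ref <- substr(haps_mat[[ch]], pk + 1L, pk + 1L)
            alt <- sample(DNA_BASES[DNA_BASES != ref], 1L)
            events[[length(events) + 1L]] <- list(
              chrom = ch, start = pk, end = pk + 1L, type = "snv",
              class = "SNV", len = 1L, payload = alt, ref = ref)
            placed <- placed + 1L
          }
        }
      }
    }

    built <- .apply_events(haps_mat, events, layout$chrom)
    haps_pat <- built$pat
    variants <- built$variants

    # --- de novo mutations ----------------------------------------------
    dnms <- data.table::data.table(parent = character(), chrom = character(),
                                   pos_mat = integer(), pos_pat = integer(),
                                   ref = character(), alt = character())
    child_mat <- haps_mat
    child_pat <- haps_pat
    if (config$dnm_rate > 0) {
      total_len <- sum(nchar(haps_mat)) + sum(nchar(haps_pat))
      n_dnm <- rpois(1, config$dnm_rate * total_len)
      n_pat <- rbinom(1, n_dnm, config$paternal_fraction)
      parents <- c(rep("paternal", n_pat),
                   rep("maternal", max(0L, n_dnm - n_pat)))
      rows <- vector("list", length(parents))
      for (d in seq_along(parents)) {
        par <- parents[d]
        placed_at <- NULL
        for (try in seq_len(MAX_PLACEMENT_TRIES)) {
          chrom <- sample(layout$chrom, 1L, prob = as.numeric(chrom_lens))
          pos <- as.integer(floor(runif(1, 0, chrom_lens[[chrom]])))
          if (occ[[chrom]][pos + 1L] == as.raw(0)) {
            placed_at <- list(chrom = chrom, pos = pos)
            break
          }
        }
        if (is.null(placed_at)) stop("could not place DNM (placement error)")
        occ <- .mask_set(occ, placed_at$chrom, placed_at$pos,
                         placed_at$pos + 1L)
        pos_pat <- .lift_pos(built$offsets[[placed_at$chrom]], placed_at$pos)
        carrier <- if (par == "maternal") child_mat[[placed_at$chrom]]
                   else child_pat[[placed_at$chrom]]
        p1 <- if (par == "maternal") placed_at$pos else pos_pat
        ref <- substr(carrier, p1 + 1L, p1 + 1L)
        alt <- sample(DNA_BASES[DNA_BASES != ref], 1L)
        substr(carrier, p1 + 1L, p1 + 1L) <- alt
        if (par == "maternal") child_mat[[placed_at$chrom]] <- carrier
        else child_pat[[placed_at$chrom]] <- carrier
        rows[[d]] <- data.table::data.table(
          parent = par, chrom = placed_at$chrom,
          pos_mat = placed_at$pos, pos_pat = as.integer(pos_pat),
          ref = ref, alt = alt)
      }
      if (length(rows)) dnms <- data.table::rbindlist(rows)
    }

    roh <- data.table::as.data.table(config$roh_spec)
    if (nrow(roh)) roh[, end := start + length]

    structure(list(haplotypes = list(mat = haps_mat, pat = haps_pat),
                   child = list(mat = child_mat, pat = child_pat),
                   variants = variants, dnms = dnms, roh = roh,
                   layout = layout, config = config),
              class = "trio_truth")
  })
}

# lift a maternal coordinate to paternal coordinates through the per-
# chromosome offset map (matrix of [mat_breakpoint, cumulative_offset])
.lift_pos <- function(offmap, pos) {
  if (is.null(offmap) || nrow(offmap) == 0L) return(as.integer(pos))
  idx <- findInterval(pos, offmap[, 1])
  off <- if (idx == 0L) 0 else offmap[idx, 2]
  as.integer(pos + off)
}

# apply edit operations (maternal coords) to build the paternal haplotype,
# recording truth records with coordinates on both haplotypes
.apply_events <- function(haps_mat, events, chroms) {
  variants <- list()
  pat <- haps_mat
  offsets <- stats::setNames(vector("list", length(chroms)), chroms)

  for (i in seq_along(events)) {
    ev <- events[[i]]
    if (ev$type == "paste") {
      seg <- substr(haps_mat[[ev$src_chrom]], ev$src_start + 1L, ev$src_end)
      if (ev$inverted) seg <- revcomp(seg)
      events[[i]]$payload <- seg
    }
  }

  for (ch in chroms) {
    evs <- Filter(function(e) e$chrom == ch, events)
    if (length(evs) == 0L) {
      offsets[[ch]] <- matrix(numeric(0), ncol = 2)
      next
    }
    ord <- order(vapply(evs, `[[`, numeric(1), "start"))
    evs <- evs[ord]
    pieces <- character(2L * length(evs) + 1L)
    np <- 0L
    cursor <- 0L
    offset <- 0
    offmap <- matrix(numeric(0), ncol = 2)
    mat_seq <- haps_mat[[ch]]
    for (ev in evs) {
      np <- np + 1L
      pieces[np] <- substr(mat_seq, cursor + 1L, ev$start)
      ref_seg <- if (ev$end > ev$start)
        substr(mat_seq, ev$start + 1L, ev$end) else ""
      qry_seg <- switch(ev$type,
        snv = ev$payload,
        del = "",
        cut = "",
        ins = ev$payload,
        paste = ev$payload,
        inv = revcomp(ref_seg),
        dup = paste0(ref_seg, ref_seg))
      np <- np + 1L
      pieces[np] <- qry_seg
      qry_start <- ev$start + offset
      qry_end <- qry_start + nchar(qry_seg)
      rec <- switch(ev$type,
        snv = list(class = "SNV", ref_chrom = ch, ref_start = ev$start,
                   ref_end = ev$end, qry_chrom = ch,
                   qry_start = qry_start, qry_end = qry_end,
                   ref_allele = ev$ref, alt_allele = ev$payload, length = 1L),
        del = ,
        ins = list(class = ev$class, ref_chrom = ch, ref_start = ev$start,
                   ref_end = ev$end, qry_chrom = ch,
                   qry_start = qry_start, qry_end = qry_end,
                   ref_allele = ref_seg, alt_allele = qry_seg,
                   length = ev$len),
        inv = list(class = "inversion", ref_chrom = ch, ref_start = ev$start,
                   ref_end = ev$end, qry_chrom = ch,
                   qry_start = qry_start, qry_end = qry_end,
                   ref_allele = "", alt_allele = "", length = ev$len),
        dup = list(class = "CNV", ref_chrom = ch, ref_start = ev$start,
                   ref_end = ev$end, qry_chrom = ch,
                   qry_start = qry_start, qry_end = qry_end,
                   ref_allele = "", alt_allele = "", length = ev$len),
        paste = list(class = ev$class, ref_chrom = ev$src_chrom,
                     ref_start = ev$src_start, ref_end = ev$src_end,
                     qry_chrom = ch, qry_start = qry_start,
                     qry_end = qry_end, ref_allele = "", alt_allele = "",
                     length = ev$len),
        cut = NULL)
      if (!is.null(rec)) variants[[length(variants) + 1L]] <- rec
      delta <- nchar(qry_seg) - (ev$end - ev$start)
      if (delta != 0) {
        offset <- offset + delta
        offmap <- rbind(offmap, c(ev$end, offset))
      }
      cursor <- ev$end
    }
    np <- np + 1L
    pieces[np] <- substr(mat_seq, cursor + 1L, nchar(mat_seq))
    pat[[ch]] <- paste(pieces[seq_len(np)], collapse = "")
    offsets[[ch]] <- offmap
  }

  vt <- if (length(variants)) data.table::rbindlist(variants) else
    data.table::data.table(class = character(), ref_chrom = character(),
                           ref_start = integer(), ref_end = integer(),
                           qry_chrom = character(), qry_start = integer(),
                           qry_end = integer(), ref_allele = character(),
                           alt_allele = character(), length = integer())
  data.table::setorder(vt, ref_chrom, ref_start)
  list(pat = pat, variants = vt, offsets = offsets)
}

#' @export
print.trio_truth <- function(x, ...) {
  cat("trio_truth:", length(x$haplotypes$mat), "chromosome(s);",
      nrow(x$variants), "planted heterozygous variants;",
      nrow(x$dnms), "DNMs;", nrow(x$roh), "ROH\n")
  invisible(x)
}
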