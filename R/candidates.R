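# Stage 1: candidate junction reads from split alignments, plus the
# 5-base rescue of reads in which only one anchor aligned.

.empty_candidates <- function() {
  data.frame(chrom1 = character(0), start1 = integer(0), end1 = integer(0),
             chrom2 = character(0), start2 = integer(0), end2 = integer(0),
             read_id = character(0), score = integer(0),
             strand1 = character(0), strand2 = character(0),
             origin = character(0), read_start = integer(0),
             n_insert = integer(0), colinear = logical(0))
}

#' Derive candidate junction reads from split alignments
#'
#' A read whose two uniquely aligned, maximally extended halves together
#' explain the whole read but land on non-contiguous genomic loci defines
#' a candidate breakpoint pair:
#' * read fully explained, genomic gap > 0: junction/deletion-type
#'   candidate;
#' * genomic gap 0 with 1 or more unexplained central read bases:
#'   insertion-type candidate (the unexplained bases are the inserted
#'   sequence; geometry caps their number at the inter-anchor gap);
#' * contiguous alignments (gap 0, no leftover bases) yield nothing;
#' * reads with both an unexplained read gap and a genomic gap are dropped
#'   and counted.
#'
#' Halves on different chromosomes or strands, or in inverted genomic
#' order, are kept with a `colinear = FALSE` flag; classification decides
#' their fate ("other rearrangement").
#'
#' The candidate's two intervals are the extended half alignments in
#' genomic order, so `end1` is the left breakpoint and `start2` the right
#' breakpoint; `read_start` is the genomic start of the genomically-left
#' segment, used downstream for unique-start counting.
#'
#' @param halves half-alignment data.frame from [align_split_reads()].
#' @param verbose print the dropped-read count.
#' @return candidate data.frame (one row per candidate junction read).
#' @export
find_candidates <- function(halves, verbose = FALSE) {
  h <- halves[halves$paired & halves$unique, , drop = FALSE]
  if (!nrow(h)) return(.empty_candidates())
  hl <- h[h$half == "left", , drop = FALSE]
  hr <- h[h$half == "right", , drop = FALSE]
  hr <- hr[match(hl$read_id, hr$read_id), , drop = FALSE]

  residual <- hr$rstart - hl$rend
  same <- hl$chrom == hr$chrom & hl$strand == hr$strand
  plus <- hl$strand == "+"
  # genomic gap between the interior-facing ends, for same-chrom/strand pairs
  gap <- ifelse(plus, hr$gstart - hl$gend, hl$gstart - hr$gend)
  gap[!same] <- NA_integer_

  # insertion signature: unexplained central read bases over a zero genomic
  # gap. A slightly negative gap with leftover read bases means the left
  # half overextended into the insert (its first bases coincide with the
  # reference); trim the left half back by the overlap so the gap closes
  # and the full insert length (residual - gap) is restored.
  is_ins <- same & residual > 0L & !is.na(gap) & gap <= 0L
  fix <- which(is_ins & gap < 0L)
  for (i in fix) {
    k <- -gap[i]
    if (plus[i]) {       # genomically leftmost insert point on both strands
      hl$rend[i] <- hl$rend[i] - k
      hl$gend[i] <- hl$gend[i] - k
    } else {
      hr$rstart[i] <- hr$rstart[i] + k
      hr$gend[i] <- hr$gend[i] - k
    }
    residual[i] <- residual[i] + k
    gap[i] <- 0L
  }
  colinear <- same & !is.na(gap) & gap >= 0L
  is_junc <- colinear & residual == 0L & gap > 0L
  is_other <- !same & residual == 0L
  keep <- is_junc | is_ins | is_other
  dropped <- nrow(hl) - sum(keep) - sum(colinear & residual == 0L & gap == 0L)
  .msg(verbose, sprintf("%d candidate reads (%d dropped as unexplained)",
                        sum(keep), dropped))
  if (!any(keep)) return(.empty_candidates())

  hl <- hl[keep, , drop = FALSE]; hr <- hr[keep, , drop = FALSE]
  plus <- plus[keep]; same <- same[keep]
  residual <- residual[keep]

  # order the two segments genomically; on the minus strand the read-left
  # half sits genomically to the right
  seg1 <- hl; seg2 <- hr
  swap <- (same & !plus) |
    (!same & (hr$chrom < hl$chrom | (hr$chrom == hl$chrom & hr$gstart < hl$gstart)))
  seg1[swap, ] <- hr[swap, ]; seg2[swap, ] <- hl[swap, ]

  out <- data.frame(
    chrom1 = seg1$chrom, start1 = seg1$gstart, end1 = seg1$gend,
    chrom2 = seg2$chrom, start2 = seg2$gstart, end2 = seg2$gend,
    read_id = hl$read_id, score = hl$mismatches + hr$mismatches,
    strand1 = seg1$strand, strand2 = seg2$strand,
    origin = "gap-split", read_start = seg1$gstart,
    n_insert = ifelse(same, residual, 0L),
    colinear = same & ifelse(is.na(seg2$gstart - seg1$gend), FALSE,
                             seg2$gstart - seg1$gend >= 0L))
  sort_candidates(out)
}

#' Canonically sort candidates
#'
#' Sorting by (chrom1, left breakpoint, chrom2, right breakpoint, read id)
#' makes downstream grouping independent of input read order.
#'
#' @param candidates candidate data.frame.
#' @return the sorted data.frame.
#' @export
sort_candidates <- function(candidates) {
  o <- order(candidates$chrom1, candidates$end1, candidates$chrom2,
             candidates$start2, candidates$read_id)
  out <- candidates[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the rescue index
#'
#' For each candidate breakpoint, stores the first 5 reference bases on
#' the far side of the partner breakpoint: the sequence a half-aligned
#' read must continue with, beyond its extension, to confirm the
#' junction. Breakpoints within 5 bp of a chromosome end are skipped with
#' a notice.
#'
#' @param candidates candidate data.frame from [find_candidates()].
#' @param genome a [genome] object.
#' @param verbose print the skipped-entry count.
#' @return data.frame with `chrom`, `bp`, `side` ("left" = key is the left
#'   breakpoint), partner breakpoint (`pchrom`, `pbp`, `pstrand`) and the
#'   partner-side 5-mer `pseq` (plus-strand orientation).
#' @export
build_rescue_index <- function(candidates, genome, verbose = FALSE) {
  empty <- data.frame(chrom = character(0), bp = integer(0), side = character(0),
                      pchrom = character(0), pbp = integer(0),
                      pstrand = character(0), pseq = character(0))
  if (!nrow(candidates)) return(empty)
  cc <- unique(candidates[candidates$colinear,
                          c("chrom1", "end1", "chrom2", "start2",
                            "strand1", "strand2"), drop = FALSE])
  if (!nrow(cc)) return(empty)
  skipped <- 0L
  rows <- vector("list", 2L * nrow(cc))
  for (i in seq_len(nrow(cc))) {
    bp_l <- cc$end1[i]; bp_r <- cc$start2[i]; chrom <- cc$chrom1[i]
    # left-side key: partner 5-mer = first 5 bases of the right exon
    if (bp_r + 5L <= genome$lengths[[cc$chrom2[i]]]) {
      rows[[2L * i - 1L]] <- data.frame(chrom = chrom, bp = bp_l, side = "left",
        pchrom = cc$chrom2[i], pbp = bp_r, pstrand = cc$strand2[i],
        pseq = .gseq(genome, cc$chrom2[i], bp_r, bp_r + 5L))
    } else skipped <- skipped + 1L
    # right-side key: partner 5-mer = last 5 bases of the left exon
    if (bp_l - 5L >= 0L) {
      rows[[2L * i]] <- data.frame(chrom = cc$chrom2[i], bp = bp_r, side = "right",
        pchrom = chrom, pbp = bp_l, pstrand = cc$strand1[i],
        pseq = .gseq(genome, chrom, bp_l - 5L, bp_l))
    } else skipped <- skipped + 1L
  }
  .msg(verbose, sprintf("rescue index: %d entries (%d skipped near chromosome ends)",
                        sum(!vapply(rows, is.null, logical(1))), skipped))
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) empty else out
}

#' Rescue half-aligned reads against known candidate breakpoints
#'
#' A lone uniquely aligned half confirms a previously identified candidate
#' junction when (i) its extension ends exactly at one of the candidate's
#' breakpoints and (ii) the read's next 5 bases beyond the extension equal
#' the reference 5-mer on the far side of the partner breakpoint, with no
#' mismatch. As few as five bases of overlap with the other exon
#' therefore suffice. Halves with fewer than 5 read bases beyond the
#' breakpoint, and halves matching more than one distinct partner
#' breakpoint (ambiguous rescue), are not rescued and are counted.
#'
#' @param halves half-alignment data.frame (only lone halves, i.e.
#'   `paired == FALSE`, are considered).
#' @param index rescue index from [build_rescue_index()].
#' @param reads read data.frame with `read_id` and `seq`.
#' @param verbose print counts.
#' @return candidate data.frame with `origin = "rescued"`.
#' @export
rescue_half_aligned <- function(halves, index, reads, verbose = FALSE) {
  lone <- halves[!halves$paired & halves$unique, , drop = FALSE]
  if (!nrow(lone) || !nrow(index)) return(.empty_candidates())
  seqs <- stats::setNames(reads$seq, reads$read_id)
  n_short <- 0L; n_ambig <- 0L
  rows <- list()
  for (j in seq_len(nrow(lone))) {
    h <- lone[j, ]
    plus <- h$strand == "+"
    # interior-facing genomic coordinate and which junction side it can match
    if (h$half == "left") {
      bp <- if (plus) h$gend else h$gstart
      side <- if (plus) "left" else "right"
    } else {
      bp <- if (plus) h$gstart else h$gend
      side <- if (plus) "right" else "left"
    }
    cand <- index[index$side == side & index$chrom == h$chrom & index$bp == bp, ,
                  drop = FALSE]
    if (!nrow(cand)) next
    seq <- seqs[[h$read_id]]
    L <- nchar(seq)
    # the 5 read bases just beyond the extension, facing the read interior
    if (h$half == "left") {
      if (L - h$rend < 5L) { n_short <- n_short + 1L; next }
      over <- substr(seq, h$rend + 1L, h$rend + 5L)
    } else {
      if (h$rstart < 5L) { n_short <- n_short + 1L; next }
      over <- substr(seq, h$rstart - 4L, h$rstart)
    }
    over_plus <- if (plus) over else revcomp(over)
    hit <- cand[cand$pseq == over_plus & cand$pstrand == h$strand, , drop = FALSE]
    hit <- unique(hit[, c("pchrom", "pbp", "pstrand")])
    if (nrow(hit) == 0L) next
    if (nrow(hit) > 1L) { n_ambig <- n_ambig + 1L; next }
    left_is_half <- side == "left"
    bp_l <- if (left_is_half) bp else hit$pbp
    bp_r <- if (left_is_half) hit$pbp else bp
    rows[[length(rows) + 1L]] <- data.frame(
      chrom1 = if (left_is_half) h$chrom else hit$pchrom,
      start1 = if (left_is_half) h$gstart else bp_l - 5L,
      end1 = bp_l,
      chrom2 = if (left_is_half) hit$pchrom else h$chrom,
      start2 = bp_r,
      end2 = if (left_is_half) bp_r + 5L else h$gend,
      read_id = h$read_id, score = h$mismatches,
      strand1 = h$strand, strand2 = h$strand,
      origin = "rescued",
      read_start = h$gstart,
      n_insert = 0L, colinear = TRUE)
  }
  .msg(verbose, sprintf(
    "rescued %d lone halves (%d too short past breakpoint, %d ambiguous)",
    length(rows), n_short, n_ambig))
  if (!length(rows)) return(.empty_candidates())
  sort_candidates(do.call(rbind, rows))
}

# ---- BEDPE intermediate -----------------------------------------------------

.BEDPE_COLS <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
                 "read_id", "score", "strand1", "strand2",
                 "origin", "read_start", "n_insert")

#' Write candidate junction reads to a BEDPE file
#'
#' Standard 10-column BEDTools BEDPE (chrom1 start1 end1 chrom2 start2
#' end2 name score strand1 strand2) followed by three extra columns
#' (origin, read_start, n_insert). The two intervals are the read's two
#' extended half alignments in genomic order, so `end1`/`start2` are the
#' breakpoint pair. Gzip-transparent (use a `.gz` suffix).
#'
#' @param candidates candidate data.frame.
#' @param path output path.
#' @param chrmap optional chromosome renaming map.
#' @return `path`, invisibly.
#' @export
write_candidates_bedpe <- function(candidates, path, chrmap = NULL) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(.BEDPE_COLS, collapse = "\t")), con)
  if (nrow(candidates)) {
    tab <- candidates[, .BEDPE_COLS]
    tab$chrom1 <- .apply_chrmap(tab$chrom1, chrmap)
    tab$chrom2 <- .apply_chrmap(tab$chrom2, chrmap)
    utils::write.table(tab, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read candidate junction reads from a BEDPE file
#'
#' Inverse of [write_candidates_bedpe()]; `write -> read` is the identity
#' on the candidate table. Malformed lines raise a parse error naming the
#' line number.
#'
#' @param path BEDPE path (gzip-transparent).
#' @return candidate data.frame.
#' @export
read_candidates_bedpe <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines)) return(.empty_candidates())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != length(.BEDPE_COLS))
  if (length(bad))
    .stopf("malformed BEDPE line %d in '%s': %d fields (expected %d)",
           bad[1], path, nf[bad[1]], length(.BEDPE_COLS))
  m <- do.call(rbind, fields)
  num <- function(j) {
    v <- suppressWarnings(as.integer(m[, j]))
    if (anyNA(v))
      .stopf("malformed BEDPE line %d in '%s': non-numeric coordinate",
             which(is.na(v))[1], path)
    v
  }
  out <- data.frame(chrom1 = m[, 1], start1 = num(2), end1 = num(3),
                    chrom2 = m[, 4], start2 = num(5), end2 = num(6),
                    read_id = m[, 7], score = num(8),
                    strand1 = m[, 9], strand2 = m[, 10],
                    origin = m[, 11], read_start = num(12),
                    n_insert = num(13))
  out$colinear <- out$chrom1 == out$chrom2 & out$strand1 == out$strand2 &
    out$start2 - out$end1 >= 0L
  out
}
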