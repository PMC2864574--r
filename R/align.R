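#' Anchor configuration
#'
#' Parameters of the split-anchor alignment step: each read of length `L`
#' contributes two anchors of length `a` (its first and last `a` bases),
#' each aligned independently with at most `max_mismatches` substitutions
#' in the seed, then extended toward the read interior as long as read and
#' reference match exactly.
#'
#' @param read_length read length L (bp).
#' @param anchor_length anchor length a (bp, default 22).
#' @param max_mismatches maximum substitutions per anchor seed (default 2).
#' @return an object of class `anchor_config`.
#' @export
anchor_config <- function(read_length = 50L, anchor_length = 22L,
                          max_mismatches = 2L) {
  L <- as.integer(read_length); a <- as.integer(anchor_length)
  m <- as.integer(max_mismatches)
  if (a < 1L) .stopf("anchor_length must be >= 1")
  if (m < 0L) .stopf("max_mismatches must be >= 0")
  if (2L * a > L)
    .stopf("read_length (%d) must be at least twice anchor_length (%d)", L, a)
  structure(list(read_length = L, anchor_length = a, max_mismatches = m),
            class = "anchor_config")
}

#' @export
print.anchor_config <- function(x, ...) {
  cat(sprintf(
    "anchor config: L = %d bp, a = %d bp, gap = %d bp, <= %d seed mismatches\n",
    x$read_length, x$anchor_length, x$read_length - 2L * x$anchor_length,
    x$max_mismatches))
  invisible(x)
}

#' Split a read into two anchors
#'
#' @param sequence read sequence of length `L >= 2a`.
#' @param config an [anchor_config()].
#' @return list with `left` (first `a` bases), `right` (last `a` bases) and
#'   `gap` (`L - 2a`, the central stretch covered by neither anchor).
#' @export
split_read <- function(sequence, config) {
  L <- nchar(sequence); a <- config$anchor_length
  if (L < 2L * a) .stopf("read length %d is below 2 x anchor length %d", L, a)
  list(left = substr(sequence, 1L, a),
       right = substr(sequence, L - a + 1L, L),
       gap = L - 2L * a)
}

#' Number of read offsets at which a junction is directly detectable
#'
#' A junction breakpoint is directly detectable only when it falls in the
#' gap between the two anchor seeds (both gap edges included), which
#' happens for `L - 2a + 1` of the `L` possible breakpoint offsets. For
#' 50-bp reads and 22-bp anchors this is 7 of 50 (14%); for 75-bp reads it
#' rises to 32 of 75 (43%).
#'
#' @param read_length read length L (bp).
#' @param anchor_length anchor length a (bp).
#' @return integer count; 0 when `L < 2a`.
#' @export
detectable_offsets <- function(read_length, anchor_length) {
  L <- as.integer(read_length); a <- as.integer(anchor_length)
  if (L < 2L * a) return(0L)
  L - 2L * a + 1L
}

# ---- anchor alignment -------------------------------------------------------

# pigeonhole trusted bands covering [1, a] for max m mismatches: any hit with
# <= m substitutions has at least one of the m+1 bands substitution-free
.mismatch_bands <- function(a, m) {
  nb <- m + 1L
  cuts <- floor(a * (0:nb) / nb)
  lapply(seq_len(nb), function(i) c(cuts[i] + 1L, cuts[i + 1L]))
}

# all <= max_mismatch hits of a set of equal-length anchor sequences against
# the genome, both strands; returns data.frame(anchor, chrom, strand, start,
# mismatches) with `anchor` indexing `anchors` and `start` 0-based
.match_anchors <- function(anchors, genome, max_mismatches) {
  a <- unique(nchar(anchors))
  if (length(a) != 1L) .stopf("anchors must share one length")
  clean <- !grepl("[^ACGT]", anchors)
  hits <- list()

  collect <- function(idx, starts, chrom, strand) {
    if (!length(idx)) return()
    g <- substring(genome$seq[[chrom]], starts + 1L, starts + a)
    q <- anchors[idx]
    if (strand == "-") q <- revcomp(q)
    mm <- mapply(.nmismatch, q, g, USE.NAMES = FALSE)
    keep <- mm <= max_mismatches
    if (any(keep))
      hits[[length(hits) + 1L]] <<- data.frame(
        anchor = idx[keep], chrom = chrom, strand = strand,
        start = starts[keep], mismatches = mm[keep])
  }

  if (any(clean)) {
    uidx <- which(clean)
    for (strand in c("+", "-")) {
      qseq <- if (strand == "+") anchors[uidx] else revcomp(anchors[uidx])
      dss <- Biostrings::DNAStringSet(qseq)
      for (band in .mismatch_bands(a, max_mismatches)) {
        pd <- Biostrings::PDict(dss, tb.start = band[1], tb.end = band[2])
        for (chrom in names(genome$seq)) {
          mi <- Biostrings::matchPDict(pd, Biostrings::DNAString(genome$seq[[chrom]]),
                                       max.mismatch = max_mismatches)
          cnt <- S4Vectors::elementNROWS(mi)
          if (!sum(cnt)) next
          ir <- unlist(mi, use.names = FALSE)
          collect(rep(uidx, cnt), IRanges::start(ir) - 1L, chrom, strand)
        }
      }
    }
  }
  # anchors containing non-ACGT letters: scan each chromosome directly;
  # ambiguity letters never match the reference (fixed = TRUE)
  for (i in which(!clean)) {
    for (strand in c("+", "-")) {
      q <- if (strand == "+") anchors[i] else revcomp(anchors[i])
      for (chrom in names(genome$seq)) {
        mt <- Biostrings::matchPattern(q, Biostrings::DNAString(genome$seq[[chrom]]),
                                       max.mismatch = max_mismatches,
                                       fixed = TRUE)
        if (length(mt))
          collect(rep(i, length(mt)), Biostrings::start(mt) - 1L, chrom, strand)
      }
    }
  }
  if (!length(hits))
    return(data.frame(anchor = integer(0), chrom = character(0),
                      strand = character(0), start = integer(0),
                      mismatches = integer(0)))
  out <- do.call(rbind, hits)
  out <- unique(out)
  out[order(out$anchor, out$chrom, out$start, out$strand), , drop = FALSE]
}

#' Align one anchor to the genome
#'
#' Returns every location, on both strands, at which the anchor matches
#' the genome with at most `max_mismatches` substitutions, together with
#' the uniqueness verdict. An anchor is unique when exactly one location
#' achieves the minimum mismatch count observed for that anchor; extra
#' locations at strictly higher mismatch counts do not break uniqueness.
#' Non-ACGT letters in the anchor never match any reference base.
#'
#' @param anchor anchor sequence.
#' @param genome a [genome] object.
#' @param max_mismatches maximum substitutions.
#' @return list with `hits` (data.frame: `chrom`, `strand`, `start`
#'   (0-based), `mismatches`) and `unique` (logical).
#' @export
align_anchor <- function(anchor, genome, max_mismatches = 2L) {
  if (!nzchar(anchor)) .stopf("empty anchor")
  hits <- .match_anchors(anchor, genome, max_mismatches)
  hits$anchor <- NULL
  uni <- nrow(hits) > 0L && sum(hits$mismatches == min(hits$mismatches)) == 1L
  list(hits = hits, unique = uni)
}

# ---- extension --------------------------------------------------------------

# first index (1-based) at which two equal-length strings differ, or
# nchar+1 when identical
.first_mismatch <- function(x, y) {
  if (!nzchar(x)) return(1L)
  d <- which(charToRaw(x) != charToRaw(y))
  if (length(d)) d[1] else nchar(x) + 1L
}

#' Extend a half alignment maximally
#'
#' Grows the alignment toward the read interior one base at a time while
#' the read base equals the reference base, stopping at the first
#' mismatch, the chromosome end, or the read boundary. When the read's
#' other half was also retained (`lone = FALSE`), extension additionally
#' stops at the boundary of the other anchor's seed (the left half never
#' extends past read offset `L - a`, the right half never below `a`); a
#' lone half extends to the read end, which is what allows the 5-base
#' rescue to recognise breakpoints falling inside the failed anchor.
#' Extension never shrinks an interval.
#'
#' @param half a half-alignment row: list/one-row data.frame with fields
#'   `half` ("left"/"right"), `chrom`, `strand`, `gstart`, `gend` (genomic,
#'   0-based half-open), `rstart`, `rend` (read offsets, 0-based half-open).
#' @param read_seq the full read sequence.
#' @param genome a [genome] object.
#' @param config an [anchor_config()].
#' @param lone is this the read's only retained half?
#' @return the half alignment with grown `rstart`/`rend`/`gstart`/`gend`.
#' @export
extend_alignment <- function(half, read_seq, genome, config, lone = FALSE) {
  L <- nchar(read_seq); a <- config$anchor_length
  clen <- genome$lengths[[half$chrom]]
  plus <- half$strand == "+"
  if (half$half == "left") {
    lim_read <- (if (lone) L else L - a) - half$rend  # stay out of right seed
    lim_gen <- if (plus) clen - half$gend else half$gstart
    k <- min(lim_read, lim_gen)
    if (k > 0L) {
      rseg <- substr(read_seq, half$rend + 1L, half$rend + k)
      gseg <- if (plus) .gseq(genome, half$chrom, half$gend, half$gend + k)
              else revcomp(.gseq(genome, half$chrom, half$gstart - k, half$gstart))
      ext <- .first_mismatch(rseg, gseg) - 1L
      half$rend <- half$rend + ext
      if (plus) half$gend <- half$gend + ext else half$gstart <- half$gstart - ext
    }
  } else {
    lim_read <- half$rstart - (if (lone) 0L else a)  # stay out of left seed
    lim_gen <- if (plus) half$gstart else clen - half$gend
    k <- min(lim_read, lim_gen)
    if (k > 0L) {
      rseg <- substr(read_seq, half$rstart - k + 1L, half$rstart)
      gseg <- if (plus) .gseq(genome, half$chrom, half$gstart - k, half$gstart)
              else revcomp(.gseq(genome, half$chrom, half$gend, half$gend + k))
      # walk backwards: reverse both segments and find the first mismatch
      rev1 <- paste(rev(strsplit(rseg, "", fixed = TRUE)[[1]]), collapse = "")
      rev2 <- paste(rev(strsplit(gseg, "", fixed = TRUE)[[1]]), collapse = "")
      ext <- .first_mismatch(rev1, rev2) - 1L
      half$rstart <- half$rstart - ext
      if (plus) half$gstart <- half$gstart - ext else half$gend <- half$gend + ext
    }
  }
  half
}

# ---- whole-read split alignment ---------------------------------------------

.half_row <- function(read_id, half, chrom, strand, gstart, gend,
                      rstart, rend, mismatches, unique) {
  data.frame(read_id = read_id, half = half, chrom = chrom, strand = strand,
             gstart = gstart, gend = gend, rstart = rstart, rend = rend,
             mismatches = mismatches, unique = unique)
}

# seed half-alignment from an anchor hit; read coordinates of the seed and
# genomic interval of length a
.seed_half <- function(read_id, which_half, hit, L, a) {
  if (which_half == "left") { rs <- 0L; re <- a } else { rs <- L - a; re <- L }
  .half_row(read_id, which_half, hit$chrom, hit$strand,
            hit$start, hit$start + a, rs, re, hit$mismatches, TRUE)
}

#' Align a batch of reads by the split-anchor strategy
#'
#' Splits every read into two anchors, aligns all anchors in one batch
#' (both strands, bounded seed mismatches), keeps halves that align
#' uniquely, and extends each kept half maximally toward the read
#' interior. When the two extended halves of a read overlap on the read
#' (overextension across a shared sequence), one half is trimmed back so
#' the halves abut at the genomically leftmost consistent breakpoint,
#' making the derived breakpoint pair independent of the strand the read
#' happened to come from.
#'
#' @param reads data.frame with `read_id` and `seq` (all of length `L`).
#' @param genome a [genome] object.
#' @param config an [anchor_config()].
#' @param verbose print progress counts.
#' @return data.frame of extended half alignments, one row per retained
#'   half, with columns `read_id`, `half`, `chrom`, `strand`, `gstart`,
#'   `gend`, `rstart`, `rend`, `mismatches`, `unique`, `paired` (TRUE when
#'   the read's other half was also uniquely aligned).
#' @export
align_split_reads <- function(reads, genome, config = anchor_config(),
                              verbose = FALSE) {
  L <- config$read_length; a <- config$anchor_length
  if (any(nchar(reads$seq) != L))
    .stopf("all reads must have length %d (config read_length)", L)
  left <- substr(reads$seq, 1L, a)
  right <- substr(reads$seq, L - a + 1L, L)
  anchors <- unique(c(left, right))
  hits <- .match_anchors(anchors, genome, config$max_mismatches)

  # uniqueness per anchor sequence: one locus at the minimum mismatch count
  uni_row <- integer(length(anchors))   # row index of unique best hit, 0 if none
  if (nrow(hits)) {
    sp <- split(seq_len(nrow(hits)), hits$anchor)
    for (nm in names(sp)) {
      mm <- hits$mismatches[sp[[nm]]]
      mn_hits <- sp[[nm]][mm == min(mm)]
      if (length(mn_hits) == 1L) uni_row[as.integer(nm)] <- mn_hits
    }
  }
  aidx <- stats::setNames(seq_along(anchors), anchors)
  lrow <- uni_row[aidx[left]]           # unique hit row per read, 0 = none
  rrow <- uni_row[aidx[right]]
  keepL <- lrow > 0L; keepR <- rrow > 0L
  keep <- keepL | keepR

  # assemble retained halves as flat vectors: left halves then right halves
  idx <- c(which(keepL), which(keepR))
  n_l <- sum(keepL)
  hrow <- c(lrow[keepL], rrow[keepR])
  half <- rep(c("left", "right"), c(n_l, length(idx) - n_l))
  chrom <- hits$chrom[hrow]
  strand <- hits$strand[hrow]
  gstart <- hits$start[hrow]
  gend <- gstart + a
  rstart <- ifelse(half == "left", 0L, L - a)
  rend <- rstart + a
  mism <- hits$mismatches[hrow]
  seqs <- reads$seq[idx]
  clen <- genome$lengths[chrom]
  paired <- idx %in% which(keepL & keepR)

  # maximal exact extension toward the read interior (scalar loop); lone
  # halves may extend past the failed anchor's seed, up to the read end
  for (j in seq_along(idx)) {
    plus <- strand[j] == "+"
    rlim <- if (paired[j]) a else 0L
    if (half[j] == "left") {
      k <- min((L - rlim) - rend[j], if (plus) clen[j] - gend[j] else gstart[j])
      if (k > 0L) {
        rseg <- substr(seqs[j], rend[j] + 1L, rend[j] + k)
        gseg <- if (plus) .gseq(genome, chrom[j], gend[j], gend[j] + k)
                else revcomp(.gseq(genome, chrom[j], gstart[j] - k, gstart[j]))
        ext <- .first_mismatch(rseg, gseg) - 1L
        rend[j] <- rend[j] + ext
        if (plus) gend[j] <- gend[j] + ext else gstart[j] <- gstart[j] - ext
      }
    } else {
      k <- min(rstart[j] - rlim, if (plus) gstart[j] else clen[j] - gend[j])
      if (k > 0L) {
        rseg <- substr(seqs[j], rstart[j] - k + 1L, rstart[j])
        gseg <- if (plus) .gseq(genome, chrom[j], gstart[j] - k, gstart[j])
                else revcomp(.gseq(genome, chrom[j], gend[j], gend[j] + k))
        ext <- .first_mismatch(.strrev(rseg), .strrev(gseg)) - 1L
        rstart[j] <- rstart[j] - ext
        if (plus) gstart[j] <- gstart[j] - ext else gend[j] <- gend[j] + ext
      }
    }
  }

  # when the two extended halves overlap on the read (overextension across
  # shared sequence) the breakpoint may sit anywhere in the overlap; take
  # the genomically leftmost consistent cut so both strands of the same
  # junction yield identical breakpoint pairs: on "+" trim the left half
  # back, on "-" trim the right half forward
  pos_l <- match(which(keepL & keepR), which(keepL))
  pos_r <- n_l + match(which(keepL & keepR), which(keepR))
  ovl <- rend[pos_l] - rstart[pos_r]
  fix <- which(ovl > 0L)
  for (f in fix) {
    j <- pos_l[f]; r <- pos_r[f]; k <- ovl[f]
    if (strand[j] == "+") {
      rend[j] <- rend[j] - k
      gend[j] <- gend[j] - k
    } else {
      rstart[r] <- rstart[r] + k
      if (strand[r] == "-") gend[r] <- gend[r] - k else gstart[r] <- gstart[r] + k
    }
  }

  res <- data.frame(read_id = reads$read_id[idx], half = half, chrom = chrom,
                    strand = strand, gstart = gstart, gend = gend,
                    rstart = rstart, rend = rend, mismatches = mism,
                    unique = TRUE, paired = paired)
  res <- res[order(res$read_id, res$half), , drop = FALSE]
  rownames(res) <- NULL
  .msg(verbose, sprintf("aligned %d reads: %d split, %d lone halves, %d unaligned",
                        nrow(reads), sum(keepL & keepR), sum(xor(keepL, keepR)),
                        sum(!keep)))
  res
}

.strrev <- function(x) paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = "")

#' Write/read the intermediate half-alignment table
#'
#' Tab-separated with a header comment; the hand-off format between the
#' alignment stage and candidate detection.
#'
#' @param halves half-alignment data.frame from [align_split_reads()].
#' @param path file path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_half_alignments <- function(halves, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste0("#", paste(names(halves), collapse = "\t")), con)
  if (nrow(halves))
    utils::write.table(halves, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_half_alignments
#' @export
read_half_alignments <- function(path) {
  lines <- readLines(path)
  hdr <- sub("^#", "", lines[1])
  cols <- strsplit(hdr, "\t", fixed = TRUE)[[1]]
  body <- lines[-1]
  if (!length(body)) {
    tab <- data.frame(read_id = character(0), half = character(0),
                      chrom = character(0), strand = character(0),
                      gstart = integer(0), gend = integer(0),
                      rstart = integer(0), rend = integer(0),
                      mismatches = integer(0), unique = logical(0),
                      paired = logical(0))
    return(tab[, cols, drop = FALSE])
  }
  utils::read.table(text = body, sep = "\t", header = FALSE,
                    col.names = cols,
                    colClasses = c(read_id = "character", half = "character",
                                   chrom = "character", strand = "character"))
}
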