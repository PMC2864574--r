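# Stage 2: group candidate junction reads by genomic coordinate, apply
# support thresholds, refine breakpoints, classify.

#' Clustering and classification parameters
#'
#' @param min_reads minimum total reads per reported event (default 2).
#' @param min_unique_starts minimum reads with distinct starting points
#'   per reported event (default 2); guards against amplification
#'   duplicates.
#' @param max_join_distance maximum distance d (bp) between two candidate
#'   reads joined into one event, applied on both breakpoints (default 5).
#' @param max_span optional maximum junction span (bp, e.g. 100000).
#'   Events exceeding it, and interchromosomal events, are withheld from
#'   the junction output and reported on the long-range side channel;
#'   `NULL` = unlimited.
#' @param max_insertion_len maximum insertion length (bp, default 6; for
#'   50-bp reads and 22-bp anchors this is also the geometric bound).
#' @param max_deletion_len maximum deletion length (bp) used for deletion
#'   calling when no exon annotation is supplied (default 20).
#' @param annotation optional exon annotation: data.frame with `chrom`,
#'   `start`, `end` (0-based half-open). When supplied, a gap event is a
#'   deletion only if both breakpoints fall inside one annotated exon.
#' @return an object of class `cluster_params`.
#' @export
cluster_params <- function(min_reads = 2L, min_unique_starts = 2L,
                           max_join_distance = 5L, max_span = NULL,
                           max_insertion_len = 6L, max_deletion_len = 20L,
                           annotation = NULL) {
  if (min_reads < 1L || min_unique_starts < 1L) .stopf("count thresholds must be >= 1")
  if (max_join_distance < 0L) .stopf("max_join_distance must be >= 0")
  if (!is.null(max_span) && max_span <= 0L) .stopf("max_span must be positive")
  structure(list(min_reads = as.integer(min_reads),
                 min_unique_starts = as.integer(min_unique_starts),
                 max_join_distance = as.integer(max_join_distance),
                 max_span = if (is.null(max_span)) NULL else as.integer(max_span),
                 max_insertion_len = as.integer(max_insertion_len),
                 max_deletion_len = as.integer(max_deletion_len),
                 annotation = annotation),
            class = "cluster_params")
}

#' Group candidate reads by genomic coordinate
#'
#' Traverses candidates in canonical coordinate order and joins a
#' candidate to the open cluster when both its breakpoints are within
#' `max_join_distance` of the cluster's running representative (its first
#' member) and the chromosomes agree on both sides; otherwise a new
#' cluster starts. Single-linkage in traversal order; canonical sorting
#' first makes the result independent of input read order. Every
#' candidate lands in exactly one cluster.
#'
#' @param candidates candidate data.frame (any order).
#' @param params a [cluster_params()].
#' @return the candidates with an added integer `cluster` column, sorted
#'   canonically.
#' @export
group_candidates <- function(candidates, params = cluster_params()) {
  x <- sort_candidates(candidates)
  n <- nrow(x)
  if (!n) { x$cluster <- integer(0); return(x) }
  d <- params$max_join_distance
  cl <- integer(n)
  cl[1] <- 1L
  rep_l <- x$end1[1]; rep_r <- x$start2[1]
  rep_c1 <- x$chrom1[1]; rep_c2 <- x$chrom2[1]
  k <- 1L
  for (i in seq_len(n)[-1]) {
    if (x$chrom1[i] == rep_c1 && x$chrom2[i] == rep_c2 &&
        abs(x$end1[i] - rep_l) <= d && abs(x$start2[i] - rep_r) <= d) {
      cl[i] <- k
    } else {
      k <- k + 1L
      cl[i] <- k
      rep_l <- x$end1[i]; rep_r <- x$start2[i]
      rep_c1 <- x$chrom1[i]; rep_c2 <- x$chrom2[i]
    }
  }
  x$cluster <- cl
  x
}

#' Refine a cluster's breakpoints
#'
#' The representative breakpoint pair is the most frequent
#' (left, right) pair among members, ties broken by leftmost left then
#' leftmost right breakpoint. The ambiguity width on each side is the
#' span of member breakpoints, nonzero typically when the first intron
#' bases coincide with the first bases of the next exon (overextension).
#'
#' @param members candidate rows of one cluster.
#' @return list with `bp_left`, `bp_right`, `ambiguity_left`,
#'   `ambiguity_right`, `tie` (logical).
#' @export
refine_breakpoints <- function(members) {
  if (!nrow(members)) .stopf("empty cluster")
  key <- paste(members$end1, members$start2)
  tab <- table(key)
  best <- names(tab)[tab == max(tab)]
  pairs <- do.call(rbind, lapply(strsplit(best, " ", fixed = TRUE), as.integer))
  o <- order(pairs[, 1], pairs[, 2])
  list(bp_left = pairs[o[1], 1], bp_right = pairs[o[1], 2],
       ambiguity_left = diff(range(members$end1)),
       ambiguity_right = diff(range(members$start2)),
       tie = length(best) > 1L)
}

# does (chrom, l, r) fall inside a single annotated exon?
.in_one_exon <- function(annotation, chrom, l, r) {
  any(annotation$chrom == chrom & annotation$start <= l & annotation$end >= r)
}

#' Classify one cluster of candidate reads
#'
#' * insertion: zero genomic gap with 1..`max_insertion_len` unexplained
#'   read bases;
#' * deletion: colinear gap with, when an exon annotation is supplied,
#'   both breakpoints inside one annotated exon (a gap inside an exon is
#'   unlikely to be true splicing), or, annotation-free, a gap of at most
#'   `max_deletion_len`;
#' * junction: any other colinear same-chromosome gap;
#' * other: interchromosomal, strand-discordant, or non-colinear clusters
#'   (reported as "other rearrangement", not as junctions).
#'
#' @param members candidate rows of one cluster.
#' @param params a [cluster_params()].
#' @param annotated force/forbid annotation mode (default: use annotation
#'   iff supplied in `params`).
#' @return one-row data.frame (a predicted event): `class`, `chrom1`,
#'   `bp_left`, `chrom2`, `bp_right`, `span`, `n_reads`,
#'   `n_unique_starts`, `ins_len`, `ambiguity_left`, `ambiguity_right`,
#'   `strand1`, `strand2`, `extent_start`, `extent_end`, `read_ids`.
#' @export
classify_event <- function(members, params = cluster_params(),
                           annotated = !is.null(params$annotation)) {
  if (annotated && is.null(params$annotation))
    .stopf("annotation-based deletion calling requested but no annotation supplied")
  bp <- refine_breakpoints(members)
  chrom1 <- members$chrom1[1]; chrom2 <- members$chrom2[1]
  colinear <- all(members$colinear)
  same <- chrom1 == chrom2
  gap <- bp$bp_right - bp$bp_left
  ins_tab <- table(members$n_insert)
  ins_len <- as.integer(names(ins_tab)[which.max(ins_tab)])
  cls <- if (!same || !colinear) "other"
    else if (gap == 0L && ins_len >= 1L && ins_len <= params$max_insertion_len)
      "insertion"
    else if (gap > 0L &&
             (if (annotated) .in_one_exon(params$annotation, chrom1,
                                          bp$bp_left, bp$bp_right)
              else gap <= params$max_deletion_len)) "deletion"
    else if (gap > 0L) "junction"
    else "other"
  strand_tab <- table(paste(members$strand1, members$strand2))
  strands <- strsplit(names(strand_tab)[which.max(strand_tab)], " ")[[1]]
  data.frame(class = cls, chrom1 = chrom1, bp_left = bp$bp_left,
             chrom2 = chrom2, bp_right = bp$bp_right,
             span = if (same) bp$bp_right - bp$bp_left else NA_integer_,
             n_reads = nrow(members),
             n_unique_starts = length(unique(paste(members$chrom1,
                                                   members$read_start))),
             ins_len = if (cls == "insertion") ins_len else 0L,
             ambiguity_left = bp$ambiguity_left,
             ambiguity_right = bp$ambiguity_right,
             strand1 = strands[1], strand2 = strands[2],
             extent_start = min(members$start1),
             extent_end = max(members$end2),
             read_ids = paste(members$read_id, collapse = ","))
}

#' Apply support thresholds to grouped candidates
#'
#' A cluster passes when its total read count is at least `min_reads` and
#' its number of distinct read starting points is at least
#' `min_unique_starts`.
#'
#' @param grouped output of [group_candidates()] (has a `cluster` column).
#' @param params a [cluster_params()].
#' @return the grouped candidates restricted to passing clusters.
#' @export
apply_thresholds <- function(grouped, params = cluster_params()) {
  if (!nrow(grouped)) return(grouped)
  groups <- split(seq_len(nrow(grouped)), grouped$cluster)
  keep <- vapply(groups, function(i)
    length(i) >= params$min_reads &&
      length(unique(paste(grouped$chrom1[i], grouped$read_start[i]))) >=
        params$min_unique_starts, logical(1))
  grouped[grouped$cluster %in% as.integer(names(groups)[keep]), , drop = FALSE]
}

#' Group, threshold and classify candidate reads into predicted events
#'
#' Runs [group_candidates()], keeps clusters with at least `min_reads`
#' members and `min_unique_starts` distinct read starting points,
#' classifies each surviving cluster, and flags events exceeding
#' `max_span` (or interchromosomal ones) as long-range: these are
#' withheld from the junction output proper but written to a side channel
#' rather than discarded.
#'
#' @param candidates candidate data.frame.
#' @param params a [cluster_params()].
#' @param verbose print counts at each filter.
#' @return data.frame of predicted events with an `event_id` and a
#'   `long_range` flag, classed `predicted_events`.
#' @export
call_events <- function(candidates, params = cluster_params(),
                        verbose = FALSE) {
  grouped <- group_candidates(candidates, params)
  .msg(verbose, sprintf("%d candidate reads in %d clusters",
                        nrow(grouped), length(unique(grouped$cluster))))
  passed <- apply_thresholds(grouped, params)
  groups <- if (nrow(passed)) split(passed, passed$cluster) else list()
  .msg(verbose, sprintf("%d clusters pass support thresholds (>= %d reads, >= %d unique starts)",
                        length(groups), params$min_reads, params$min_unique_starts))
  if (!length(groups)) {
    ev <- classify_event(.dummy_members(), params)[0, ]
    ev$event_id <- character(0); ev$long_range <- logical(0)
    class(ev) <- c("predicted_events", "data.frame")
    return(ev)
  }
  ev <- do.call(rbind, lapply(groups, classify_event, params = params))
  ev <- ev[order(ev$chrom1, ev$bp_left, ev$chrom2, ev$bp_right), , drop = FALSE]
  rownames(ev) <- NULL
  ev$event_id <- sprintf("%s%04d", substr(ev$class, 1, 3), seq_len(nrow(ev)))
  ev$long_range <- is.na(ev$span) |
    (!is.null(params$max_span) & ev$span > (params$max_span %||% Inf))
  .msg(verbose, sprintf("%d events (%d long-range)", nrow(ev), sum(ev$long_range)))
  class(ev) <- c("predicted_events", "data.frame")
  ev
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.dummy_members <- function() {
  data.frame(chrom1 = "x", start1 = 0L, end1 = 1L, chrom2 = "x",
             start2 = 2L, end2 = 3L, read_id = "r", score = 0L,
             strand1 = "+", strand2 = "+", origin = "gap-split",
             read_start = 0L, n_insert = 0L, colinear = TRUE)
}

#' @export
print.predicted_events <- function(x, ...) {
  if (!all(c("class", "long_range") %in% names(x))) return(NextMethod())
  cat(sprintf("%d predicted events\n", nrow(x)))
  if (nrow(x)) print(table(class = x$class, long_range = x$long_range))
  invisible(x)
}

#' Stratify events by breakpoint distance and annotation match
#'
#' Counts predicted junctions by the distance between their two
#' breakpoints: same chromosome, within 1 Mb, within 100 kb (inclusive
#' bounds), and optionally the fraction matching a supplied set of known
#' junction boundary pairs within 5 bp at both ends.
#'
#' @param events `predicted_events` data.frame (pass the junction-type
#'   classes you want stratified, typically junctions including
#'   long-range ones).
#' @param boundaries optional data.frame of known boundary pairs with
#'   `chrom`, `bp_left`, `bp_right`.
#' @param tol matching tolerance at each end (bp, default 5).
#' @return data.frame with one row per stratum: `stratum`, `count`,
#'   `fraction` (of total events).
#' @export
stratify_events <- function(events, boundaries = NULL, tol = 5L) {
  n <- nrow(events)
  same <- !is.na(events$span)
  strata <- data.frame(
    stratum = c("total", "within_chromosome", "within_1Mb", "within_100kb"),
    count = c(n, sum(same), sum(same & events$span <= 1e6),
              sum(same & events$span <= 1e5)))
  if (!is.null(boundaries)) {
    hit <- vapply(seq_len(n), function(i) {
      same[i] && any(boundaries$chrom == events$chrom1[i] &
                       abs(boundaries$bp_left - events$bp_left[i]) <= tol &
                       abs(boundaries$bp_right - events$bp_right[i]) <= tol)
    }, logical(1))
    strata <- rbind(strata, data.frame(stratum = "boundary_match",
                                       count = sum(hit)))
  }
  strata$fraction <- if (n) strata$count / n else NA_real_
  strata
}

#' Read an exon annotation from BED
#'
#' Plain 3+-column BED; only chrom/start/end are used.
#'
#' @param path BED file path.
#' @return data.frame with `chrom`, `start`, `end`.
#' @export
read_exon_bed <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           comment.char = "#",
                           colClasses = list(character = 1))[, 1:3]
  names(tab) <- c("chrom", "start", "end")
  tab$start <- as.integer(tab$start); tab$end <- as.integer(tab$end)
  tab
}
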