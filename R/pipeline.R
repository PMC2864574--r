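# Two-stage pipeline drivers. Stage 1 (platform-facing): split-anchor
# alignment -> candidate junction reads -> BEDPE intermediate. Stage 2
# (general): grouping, thresholds, classification, stratification, FDR.

#' Write predicted events as BED12
#'
#' One record per event; junctions and deletions become two-block records
#' (the supporting extent on each side of the breakpoints) so that genome
#' browsers draw the familiar split-block picture; insertions are
#' single-block. Interchromosomal events cannot be represented in BED and
#' are skipped (they appear in the long-range BEDPE instead).
#'
#' @param events `predicted_events` data.frame.
#' @param path output path.
#' @param chrmap optional chromosome renaming map applied at write time.
#' @return `path`, invisibly.
#' @export
write_predictions_bed <- function(events, path, chrmap = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  ev <- events[!is.na(events$span), , drop = FALSE]
  for (i in seq_len(nrow(ev))) {
    chrom <- .apply_chrmap(ev$chrom1[i], chrmap)
    name <- sprintf("%s:%s", ev$class[i], ev$event_id[i])
    score <- min(1000L, ev$n_reads[i])
    cs <- ev$extent_start[i]; ce <- ev$extent_end[i]
    if (ev$bp_right[i] > ev$bp_left[i]) {
      sizes <- c(ev$bp_left[i] - cs, ce - ev$bp_right[i])
      starts <- c(0L, ev$bp_right[i] - cs)
      nb <- 2L
    } else {
      sizes <- ce - cs; starts <- 0L; nb <- 1L
    }
    writeLines(paste(chrom, cs, ce, name, score, ".", cs, ce, "0,0,0", nb,
                     paste0(paste(sizes, collapse = ","), ","),
                     paste0(paste(starts, collapse = ","), ","),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Write predicted events as BEDPE
#'
#' Interval 1 is the supporting extent up to the left breakpoint,
#' interval 2 from the right breakpoint; `end1`/`start2` are the
#' breakpoint pair, as in the candidate BEDPE.
#'
#' @param events `predicted_events` data.frame.
#' @param path output path.
#' @param chrmap optional chromosome renaming map.
#' @return `path`, invisibly.
#' @export
write_predictions_bedpe <- function(events, path, chrmap = NULL) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste("chrom1", "start1", "end1", "chrom2", "start2",
                               "end2", "name", "score", "strand1", "strand2",
                               "class", "n_reads", "n_unique_starts",
                               "ins_len", sep = "\t")), con)
  if (nrow(events)) {
    tab <- data.frame(.apply_chrmap(events$chrom1, chrmap),
                      events$extent_start, events$bp_left,
                      .apply_chrmap(events$chrom2, chrmap),
                      events$bp_right, events$extent_end,
                      sprintf("%s:%s", events$class, events$event_id),
                      pmin(1000L, events$n_reads),
                      events$strand1, events$strand2, events$class,
                      events$n_reads, events$n_unique_starts, events$ins_len)
    utils::write.table(tab, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Stage 1: reads to candidate BEDPE
#'
#' Aligns every read by the split-anchor strategy, derives gap-split
#' candidate junction reads, rescues half-aligned reads by the 5-base
#' rule, and writes the combined candidates to an intermediate BEDPE
#' file.
#'
#' @param reads read data.frame (`read_id`, `seq`) or path to
#'   FASTA/FASTQ.
#' @param genome a [genome] object or path to a FASTA file.
#' @param config an [anchor_config()].
#' @param out optional path for the candidate BEDPE.
#' @param verbose print counts.
#' @return the candidate data.frame, invisibly when `out` is given.
#' @export
run_stage1 <- function(reads, genome, config = anchor_config(), out = NULL,
                       verbose = FALSE) {
  if (is.character(genome)) genome <- read_genome_fasta(genome)
  if (is.character(reads)) reads <- read_reads(reads)
  halves <- align_split_reads(reads, genome, config, verbose = verbose)
  cand <- find_candidates(halves, verbose = verbose)
  idx <- build_rescue_index(cand, genome, verbose = verbose)
  resc <- rescue_half_aligned(halves, idx, reads, verbose = verbose)
  all <- sort_candidates(rbind(cand, resc))
  .msg(verbose, sprintf("%d candidates (%d gap-split, %d rescued)",
                        nrow(all), nrow(cand), nrow(resc)))
  if (!is.null(out)) {
    write_candidates_bedpe(all, out)
    return(invisible(all))
  }
  all
}

#' Stage 2: candidate BEDPE to predictions, strata and FDR
#'
#' Groups and classifies candidates, writes predictions as BED (for
#' genome-browser upload) and BEDPE (for interval tooling), long-range
#' events to a side file, and the uniform-null FDR report as TSV.
#'
#' @param candidates candidate data.frame or path to a candidate BEDPE.
#' @param params a [cluster_params()].
#' @param genome_length pooled genome length G (bp) for the FDR null.
#' @param out_prefix optional output prefix; writes
#'   `<prefix>.bed`, `<prefix>.bedpe`, `<prefix>_longrange.bedpe` and
#'   `<prefix>_fdr.tsv`.
#' @param chrmap optional chromosome renaming map (or path to a chrmap
#'   TSV) applied to all outputs at write time.
#' @param fdr_windows window half-widths (bp) for the FDR report.
#' @param verbose print counts.
#' @return an object of class `junction_calls`: list with `events`,
#'   `strata`, `fdr`, `params`.
#' @export
run_stage2 <- function(candidates, params = cluster_params(),
                       genome_length, out_prefix = NULL, chrmap = NULL,
                       fdr_windows = c(1e6, 1e5), verbose = FALSE) {
  if (is.character(candidates)) candidates <- read_candidates_bedpe(candidates)
  if (is.character(chrmap)) chrmap <- read_chrmap(chrmap)
  ok <- fdr_windows > 0 & fdr_windows < genome_length / 2
  if (!all(ok)) {
    .msg(verbose, sprintf("dropping %d FDR window(s) not in (0, G/2)", sum(!ok)))
    fdr_windows <- fdr_windows[ok]
  }
  events <- call_events(candidates, params, verbose = verbose)
  junc <- events[events$class == "junction" |
                   (events$class == "other" & events$chrom1 != events$chrom2), ,
                 drop = FALSE]
  strata <- stratify_events(junc)
  # N counts all junction-type predictions regardless of span, including
  # interchromosomal ones
  rep <- fdr_report(junc$span, genome_length, windows = fdr_windows)
  res <- structure(list(events = events, strata = strata, fdr = rep,
                        params = params), class = "junction_calls")
  if (!is.null(out_prefix)) {
    keep <- !events$long_range
    write_predictions_bed(events[keep, , drop = FALSE],
                          paste0(out_prefix, ".bed"), chrmap)
    write_predictions_bedpe(events[keep, , drop = FALSE],
                            paste0(out_prefix, ".bedpe"), chrmap)
    write_predictions_bedpe(events[!keep, , drop = FALSE],
                            paste0(out_prefix, "_longrange.bedpe"), chrmap)
    write_fdr_report(rep, paste0(out_prefix, "_fdr.tsv"))
    .msg(verbose, sprintf("wrote %d events (%d long-range) under prefix %s",
                          nrow(events), sum(!keep), out_prefix))
  }
  res
}

#' Run the whole pipeline in memory
#'
#' Equivalent to [run_stage1()] followed by [run_stage2()]; the BEDPE
#' file boundary between the two stages is semantically transparent.
#'
#' @inheritParams run_stage1
#' @inheritParams run_stage2
#' @param genome_length pooled genome length for the FDR null; defaults
#'   to the supplied genome's total length.
#' @return a `junction_calls` object with the candidate table attached as
#'   `candidates`.
#' @export
detect_junctions <- function(reads, genome, config = anchor_config(),
                             params = cluster_params(),
                             genome_length = NULL,
                             fdr_windows = c(1e6, 1e5), verbose = FALSE) {
  if (is.character(genome)) genome <- read_genome_fasta(genome)
  if (is.null(genome_length)) genome_length <- length(genome)
  cand <- run_stage1(reads, genome, config, verbose = verbose)
  res <- run_stage2(cand, params, genome_length, fdr_windows = fdr_windows,
                    verbose = verbose)
  res$candidates <- cand
  res
}

#' @export
print.junction_calls <- function(x, ...) {
  cat("junction calls\n")
  print(x$events)
  cat("\n")
  print(x$fdr)
  invisible(x)
}

#' @method summary junction_calls
#' @export
summary.junction_calls <- function(object, ...) {
  cat(sprintf("events by class:\n"))
  print(table(object$events$class))
  cat("\ndistance strata (junctions):\n")
  print(object$strata, row.names = FALSE)
  cat("\n")
  print(object$fdr)
  invisible(object)
}
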