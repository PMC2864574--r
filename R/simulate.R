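#' Simulate a random genome
#'
#' Draws i.i.d. bases at a target GC fraction for each requested chromosome.
#' Deterministic for a fixed seed.
#'
#' @param chrom_lengths named integer vector of chromosome lengths (bp).
#' @param gc target GC fraction in `[0, 1]` (default 0.42, mammalian-like).
#' @param seed optional integer seed.
#' @return a [genome] object.
#' @export
simulate_genome <- function(chrom_lengths, gc = 0.42, seed = NULL) {
  if (length(chrom_lengths) == 0L) .stopf("no chromosomes requested")
  if (any(chrom_lengths <= 0)) .stopf("chromosome lengths must be positive")
  if (is.null(names(chrom_lengths)) || any(names(chrom_lengths) == ""))
    .stopf("chromosome lengths must be named")
  if (gc < 0 || gc > 1) .stopf("gc must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  seqs <- vapply(chrom_lengths, function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
          collapse = "")
  }, character(1))
  genome(seqs)
}

#' Simulate non-overlapping multi-exon gene models
#'
#' Places `n_genes` single-isoform gene models on the genome. Exon counts
#' and exon lengths are uniform over their ranges; intron lengths are
#' log-uniform over their range, so that short introns dominate but the
#' upper end (e.g. >100 kb) is exercised. Gene loci never overlap, which
#' keeps the ground truth unambiguous for recovery tests.
#'
#' @param genome a [genome] object.
#' @param n_genes number of genes to place.
#' @param exon_length_range integer range (bp) for exon lengths.
#' @param intron_length_range integer range (bp) for intron lengths
#'   (log-uniform).
#' @param exons_per_gene_range integer range for exons per gene.
#' @param spacing minimum gap between gene loci (bp).
#' @param seed optional integer seed.
#' @return a data.frame of exons with columns `transcript_id`, `chrom`,
#'   `strand`, `exon`, `start`, `end` (0-based half-open, sorted and
#'   pairwise disjoint within each transcript).
#' @export
simulate_gene_models <- function(genome, n_genes,
                                 exon_length_range = c(150L, 300L),
                                 intron_length_range = c(200L, 20000L),
                                 exons_per_gene_range = c(2L, 5L),
                                 spacing = 200L, seed = NULL) {
  stopifnot(inherits(genome, "genome"))
  if (n_genes == 0L) {
    return(data.frame(transcript_id = character(0), chrom = character(0),
                      strand = character(0), exon = integer(0),
                      start = integer(0), end = integer(0)))
  }
  if (any(exon_length_range <= 0) || any(intron_length_range <= 0) ||
      any(exons_per_gene_range <= 0))
    .stopf("all length/count ranges must be positive")
  if (!is.null(seed)) set.seed(seed)

  rint <- function(rng) if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1L)
  rintron <- function(rng) {
    if (rng[1] == rng[2]) return(rng[1])
    as.integer(round(exp(runif(1, log(rng[1]), log(rng[2])))))
  }

  occupied <- lapply(genome$lengths, function(...) matrix(numeric(0), ncol = 2))
  rows <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    n_ex <- rint(exons_per_gene_range)
    ex_len <- vapply(seq_len(n_ex), function(i) rint(exon_length_range), integer(1))
    in_len <- if (n_ex > 1)
      vapply(seq_len(n_ex - 1L), function(i) rintron(intron_length_range), integer(1))
    else integer(0)
    span <- sum(ex_len) + sum(in_len)
    placed <- FALSE
    for (attempt in seq_len(500L)) {
      chrom <- sample(names(genome$lengths), 1L)
      room <- genome$lengths[[chrom]] - span
      if (room < 1L) next
      start <- sample.int(room, 1L) - 1L
      iv <- c(start - spacing, start + span + spacing)
      occ <- occupied[[chrom]]
      if (nrow(occ) == 0L || all(iv[2] <= occ[, 1] | iv[1] >= occ[, 2])) {
        occupied[[chrom]] <- rbind(occ, iv)
        starts <- start + cumsum(c(0L, head(ex_len, -1L) + in_len))
        rows[[g]] <- data.frame(
          transcript_id = sprintf("g%03d", g), chrom = chrom,
          strand = sample(c("+", "-"), 1L), exon = seq_len(n_ex),
          start = as.integer(starts), end = as.integer(starts + ex_len))
        placed <- TRUE
        break
      }
    }
    if (!placed) .stopf("genome too small to place gene %d (span %d bp)", g, span)
  }
  do.call(rbind, rows)
}

# spliced reference sequence of one transcript (plus-strand orientation)
.splice_reference <- function(exons, genome) {
  paste(vapply(seq_len(nrow(exons)), function(i)
    .gseq(genome, exons$chrom[i], exons$start[i], exons$end[i]), character(1)),
    collapse = "")
}

#' Introduce small insertions and deletions into transcripts
#'
#' Splices each gene model into its transcript sequence and plants small
#' insertions and deletions inside exons. Every modification, and every
#' exon-exon junction, is recorded as a truth event with genomic
#' breakpoints and transcript-space coordinates (in the orientation the
#' transcript is emitted, i.e. reverse-complemented for minus-strand
#' genes). Deletions that do not fit inside their exon are skipped with a
#' notice.
#'
#' The number of insertions (and deletions) per transcript is Poisson with
#' mean `insertion_rate` (`deletion_rate`).
#'
#' @param models exon data.frame from [simulate_gene_models()].
#' @param genome a [genome] object.
#' @param insertion_rate,deletion_rate expected events per transcript.
#' @param max_insertion_len,max_deletion_len maximum event sizes (bp).
#' @param seed optional integer seed.
#' @param verbose emit notices for skipped events.
#' @return a list with `transcripts` (named character, final orientation),
#'   `events` (data.frame: `event_id`, `class` in junction/insertion/
#'   deletion, `transcript_id`, `chrom`, `strand`, `bp_left`, `bp_right`
#'   (0-based, genomic order), `ins_len`, `ins_seq`, `tx_cut` (cut/start
#'   position in the emitted transcript)), and `n_skipped`.
#' @export
apply_variants <- function(models, genome, insertion_rate = 1,
                           deletion_rate = 1, max_insertion_len = 6L,
                           max_deletion_len = 6L, seed = NULL,
                           verbose = FALSE) {
  stopifnot(inherits(genome, "genome"))
  if (insertion_rate < 0 || deletion_rate < 0) .stopf("rates must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  margin <- 10L  # keep events away from exon edges so signatures stay clean
  tx_ids <- unique(models$transcript_id)
  n_skipped <- 0L
  transcripts <- character(0)
  ev_rows <- list()
  eid <- 0L

  for (tx in tx_ids) {
    exons <- models[models$transcript_id == tx, , drop = FALSE]
    exons <- exons[order(exons$start), , drop = FALSE]
    chrom <- exons$chrom[1]; strand <- exons$strand[1]

    # draw variant positions per exon, non-overlapping
    n_ins <- rpois(1L, insertion_rate); n_del <- rpois(1L, deletion_rate)
    vars <- list()
    blocked <- lapply(seq_len(nrow(exons)), function(i) matrix(numeric(0), ncol = 2))
    place <- function(len, class) {
      for (attempt in seq_len(30L)) {
        i <- sample.int(nrow(exons), 1L, prob = exons$end - exons$start)
        lo <- exons$start[i] + margin; hi <- exons$end[i] - margin - len
        if (hi < lo) next
        p <- lo + sample.int(hi - lo + 1L, 1L) - 1L
        iv <- c(p - 5L, p + len + 5L)
        occ <- blocked[[i]]
        if (nrow(occ) == 0L || all(iv[2] <= occ[, 1] | iv[1] >= occ[, 2])) {
          blocked[[i]] <<- rbind(occ, iv)
          return(list(exon = i, pos = p))
        }
      }
      NULL
    }
    for (k in seq_len(n_ins)) {
      len <- sample.int(max_insertion_len, 1L)
      loc <- place(len, "insertion")
      if (is.null(loc)) { n_skipped <- n_skipped + 1L
        .msg(verbose, "skipped insertion in ", tx, ": no room"); next }
      vars[[length(vars) + 1L]] <- list(class = "insertion", exon = loc$exon,
        pos = loc$pos, len = len,
        seq = paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""))
    }
    for (k in seq_len(n_del)) {
      len <- sample.int(max_deletion_len, 1L)
      loc <- place(len, "deletion")
      if (is.null(loc)) { n_skipped <- n_skipped + 1L
        .msg(verbose, "skipped deletion in ", tx, ": does not fit in exon"); next }
      vars[[length(vars) + 1L]] <- list(class = "deletion", exon = loc$exon,
        pos = loc$pos, len = len, seq = "")
    }

    # walk exons left to right building the plus-orientation sequence,
    # recording transcript coordinates of every cut
    parts <- character(0); tx_pos <- 0L
    tx_events <- list()
    for (i in seq_len(nrow(exons))) {
      cur <- exons$start[i]
      evs <- Filter(function(v) v$exon == i, vars)
      if (length(evs)) evs <- evs[order(vapply(evs, `[[`, numeric(1), "pos"))]
      for (v in evs) {
        parts <- c(parts, .gseq(genome, chrom, cur, v$pos))
        tx_pos <- tx_pos + (v$pos - cur)
        if (v$class == "insertion") {
          tx_events[[length(tx_events) + 1L]] <- list(class = "insertion",
            bp_left = v$pos, bp_right = v$pos, ins_len = v$len,
            ins_seq = v$seq, tx_cut = tx_pos)
          parts <- c(parts, v$seq)
          tx_pos <- tx_pos + v$len
          cur <- v$pos
        } else {
          tx_events[[length(tx_events) + 1L]] <- list(class = "deletion",
            bp_left = v$pos, bp_right = v$pos + v$len, ins_len = 0L,
            ins_seq = "", tx_cut = tx_pos)
          cur <- v$pos + v$len
        }
      }
      parts <- c(parts, .gseq(genome, chrom, cur, exons$end[i]))
      tx_pos <- tx_pos + (exons$end[i] - cur)
      if (i < nrow(exons)) {
        tx_events[[length(tx_events) + 1L]] <- list(class = "junction",
          bp_left = exons$end[i], bp_right = exons$start[i + 1L],
          ins_len = 0L, ins_seq = "", tx_cut = tx_pos)
      }
    }
    seq_plus <- paste(parts, collapse = "")
    tx_len <- nchar(seq_plus)
    transcripts[[tx]] <- if (strand == "-") revcomp(seq_plus) else seq_plus

    for (ev in tx_events) {
      eid <- eid + 1L
      cut <- if (strand == "-") tx_len - (ev$tx_cut + ev$ins_len) else ev$tx_cut
      ev_rows[[eid]] <- data.frame(
        event_id = sprintf("ev%04d", eid), class = ev$class,
        transcript_id = tx, chrom = chrom, strand = strand,
        bp_left = ev$bp_left, bp_right = ev$bp_right,
        ins_len = ev$ins_len, ins_seq = ev$ins_seq, tx_cut = cut)
    }
  }
  events <- if (length(ev_rows)) do.call(rbind, ev_rows) else
    data.frame(event_id = character(0), class = character(0),
               transcript_id = character(0), chrom = character(0),
               strand = character(0), bp_left = integer(0),
               bp_right = integer(0), ins_len = integer(0),
               ins_seq = character(0), tx_cut = integer(0))
  list(transcripts = transcripts, events = events, n_skipped = n_skipped)
}

#' Simulate single-end reads from transcripts
#'
#' Read start offsets are uniform over valid positions; sequencing errors
#' are independent substitutions; half the reads (on average) are emitted
#' as reverse complements, emulating a non-strand-specific library. Each
#' read is annotated with the truth events it overlaps and whether the
#' event's breakpoint falls in the detectable window, i.e. in the gap
#' between the two anchor seeds (see [detectable_offsets()]).
#'
#' @param transcripts named character vector of transcript sequences.
#' @param events truth event data.frame from [apply_variants()].
#' @param read_length read length L (bp).
#' @param depth mean fold coverage per transcript.
#' @param error_rate per-base substitution probability.
#' @param revcomp_fraction probability a read is emitted reverse-complemented.
#' @param anchor_length anchor length used for the detectability annotation.
#' @param seed optional integer seed.
#' @return list with `reads` (data.frame: `read_id`, `transcript_id`,
#'   `offset`, `flipped`, `seq`) and `read_events` (data.frame: `read_id`,
#'   `event_id`, `class`, `cut_in_read`, `detectable`).
#' @export
simulate_reads <- function(transcripts, events = NULL, read_length = 50L,
                           depth = 30, error_rate = 0,
                           revcomp_fraction = 0.5, anchor_length = 22L,
                           seed = NULL) {
  if (depth <= 0) .stopf("depth must be positive")
  tx_len <- nchar(transcripts)
  if (any(tx_len < read_length))
    .stopf("read_length (%d) exceeds shortest transcript (%d bp)",
           read_length, min(tx_len))
  if (!is.null(seed)) set.seed(seed)
  L <- as.integer(read_length); a <- as.integer(anchor_length)
  bases <- c("A", "C", "G", "T")

  read_rows <- vector("list", length(transcripts))
  re_rows <- list()
  for (ti in seq_along(transcripts)) {
    tx <- names(transcripts)[ti]
    len <- tx_len[[ti]]
    n <- max(1L, as.integer(round(depth * len / L)))
    offs <- sample.int(len - L + 1L, n, replace = TRUE) - 1L
    seqs <- substring(transcripts[[ti]], offs + 1L, offs + L)
    flip <- runif(n) < revcomp_fraction
    if (error_rate > 0) {
      nerr <- rbinom(n, L, error_rate)
      for (i in which(nerr > 0)) {
        pos <- sample.int(L, nerr[i])
        s <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
        s[pos] <- vapply(s[pos], function(b) sample(setdiff(bases, b), 1L),
                         character(1))
        seqs[i] <- paste(s, collapse = "")
      }
    }
    seqs[flip] <- revcomp(seqs[flip])
    ids <- sprintf("%s_r%05d", tx, seq_len(n))
    read_rows[[ti]] <- data.frame(read_id = ids, transcript_id = tx,
                                  offset = offs, flipped = flip, seq = seqs)
    if (!is.null(events)) {
      evs <- events[events$transcript_id == tx, , drop = FALSE]
      for (j in seq_len(nrow(evs))) {
        cut <- evs$tx_cut[j]; k <- evs$ins_len[j]
        if (k > 0) {
          hit <- cut < offs + L & cut + k > offs
          det <- cut - offs >= a & cut + k - offs <= L - a
        } else {
          hit <- offs < cut & cut < offs + L
          det <- cut - offs >= a & cut - offs <= L - a
        }
        if (!any(hit)) next
        cir <- cut - offs
        cir[flip] <- L - cir[flip] - k
        re_rows[[length(re_rows) + 1L]] <- data.frame(
          read_id = ids[hit], event_id = evs$event_id[j],
          class = evs$class[j], cut_in_read = cir[hit],
          detectable = det[hit])
      }
    }
  }
  reads <- do.call(rbind, read_rows)
  read_events <- if (length(re_rows)) do.call(rbind, re_rows) else
    data.frame(read_id = character(0), event_id = character(0),
               class = character(0), cut_in_read = integer(0),
               detectable = logical(0))
  list(reads = reads, read_events = read_events)
}

#' Write simulated reads to FASTQ or FASTA
#'
#' FASTQ qualities are a fixed constant (the simulator has no quality
#' model).
#'
#' @param reads read data.frame from [simulate_reads()].
#' @param path output path.
#' @param format `"fastq"` or `"fasta"`.
#' @param quality_char single character used for every base quality.
#' @return `path`, invisibly.
#' @export
write_reads <- function(reads, path, format = c("fastq", "fasta"),
                        quality_char = "I") {
  format <- match.arg(format)
  dss <- Biostrings::DNAStringSet(reads$seq)
  names(dss) <- reads$read_id
  if (format == "fastq") {
    quals <- Biostrings::BStringSet(strrep(quality_char, nchar(reads$seq)))
    Biostrings::writeXStringSet(dss, path, format = "fastq", qualities = quals)
  } else {
    Biostrings::writeXStringSet(dss, path)
  }
  invisible(path)
}

#' Read reads from FASTA/FASTQ
#'
#' @param path input path; format inferred from the extension
#'   (`.fq`/`.fastq` vs anything else).
#' @return data.frame with `read_id` and `seq`.
#' @export
read_reads <- function(path) {
  fq <- grepl("\\.(fq|fastq)(\\.gz)?$", path)
  dss <- Biostrings::readDNAStringSet(path, format = if (fq) "fastq" else "fasta")
  data.frame(read_id = sub("\\s.*$", "", names(dss)), seq = as.character(dss))
}

#' Write the truth table as BEDPE
#'
#' Uses the same BEDPE dialect as the pipeline output (the two intervals
#' are the single breakpoint bases) with the event class in an extra
#' column, so recovery comparison is a file-level join.
#'
#' @param events truth event data.frame from [apply_variants()].
#' @param path output path.
#' @param chrmap optional chromosome renaming map (see [read_chrmap()]).
#' @return `path`, invisibly.
#' @export
write_truth_bedpe <- function(events, path, chrmap = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste("#chrom1", "start1", "end1", "chrom2", "start2", "end2",
                   "name", "score", "strand1", "strand2", "class", "ins_len",
                   sep = "\t"), con)
  if (nrow(events)) {
    chrom <- .apply_chrmap(events$chrom, chrmap)
    tab <- data.frame(chrom, events$bp_left, events$bp_left + 1L,
                      chrom, events$bp_right, events$bp_right + 1L,
                      events$event_id, 0L, events$strand, events$strand,
                      events$class, events$ins_len)
    utils::write.table(tab, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Write gene models as BED12
#'
#' One record per transcript with exon block structure.
#'
#' @param models exon data.frame from [simulate_gene_models()].
#' @param path output path.
#' @param chrmap optional chromosome renaming map.
#' @return `path`, invisibly.
#' @export
write_gene_models_bed12 <- function(models, path, chrmap = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  for (tx in unique(models$transcript_id)) {
    ex <- models[models$transcript_id == tx, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    start <- ex$start[1]; end <- ex$end[nrow(ex)]
    writeLines(paste(.apply_chrmap(ex$chrom[1], chrmap), start, end, tx, 0,
                     ex$strand[1], start, end, "0,0,0", nrow(ex),
                     paste0(paste(ex$end - ex$start, collapse = ","), ","),
                     paste0(paste(ex$start - start, collapse = ","), ","),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Simulate a complete test dataset
#'
#' Convenience wrapper chaining [simulate_genome()],
#' [simulate_gene_models()], [apply_variants()] and [simulate_reads()]
#' with one master seed, optionally writing genome FASTA, reads FASTQ,
#' truth BEDPE and gene-model BED12 to a directory.
#'
#' @param chrom_lengths named chromosome lengths (bp).
#' @param n_genes number of genes.
#' @param gc genome GC fraction.
#' @param exon_length_range,intron_length_range,exons_per_gene_range
#'   gene-model geometry (see [simulate_gene_models()]).
#' @param insertion_rate,deletion_rate expected indels per transcript.
#' @param max_insertion_len,max_deletion_len maximum indel sizes (bp).
#' @param read_length,depth,error_rate,anchor_length read simulation
#'   parameters (see [simulate_reads()]).
#' @param seed master integer seed.
#' @param out_dir if non-NULL, write output files here (created if absent).
#' @param verbose print progress.
#' @return list with `genome`, `models`, `transcripts`, `events`, `reads`,
#'   `read_events`, and (if written) `paths`.
#' @export
simulate_dataset <- function(chrom_lengths = c(chr1 = 1500000L,
                                               chr2 = 1500000L,
                                               chr3 = 1000000L),
                             n_genes = 10L, gc = 0.42,
                             exon_length_range = c(150L, 300L),
                             intron_length_range = c(200L, 150000L),
                             exons_per_gene_range = c(2L, 5L),
                             insertion_rate = 1, deletion_rate = 1,
                             max_insertion_len = 6L, max_deletion_len = 6L,
                             read_length = 50L, depth = 30, error_rate = 0,
                             anchor_length = 22L, seed = 1L,
                             out_dir = NULL, verbose = FALSE) {
  gen <- simulate_genome(chrom_lengths, gc = gc, seed = seed)
  models <- simulate_gene_models(gen, n_genes,
                                 exon_length_range = exon_length_range,
                                 intron_length_range = intron_length_range,
                                 exons_per_gene_range = exons_per_gene_range,
                                 seed = seed + 1L)
  va <- apply_variants(models, gen, insertion_rate = insertion_rate,
                       deletion_rate = deletion_rate,
                       max_insertion_len = max_insertion_len,
                       max_deletion_len = max_deletion_len,
                       seed = seed + 2L, verbose = verbose)
  rd <- simulate_reads(va$transcripts, va$events, read_length = read_length,
                       depth = depth, error_rate = error_rate,
                       anchor_length = anchor_length, seed = seed + 3L)
  out <- list(genome = gen, models = models, transcripts = va$transcripts,
              events = va$events, reads = rd$reads,
              read_events = rd$read_events)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) {
      dir.create(out_dir, recursive = TRUE)
      .msg(verbose, "created output directory ", out_dir)
    }
    paths <- list(genome = file.path(out_dir, "genome.fa"),
                  reads = file.path(out_dir, "reads.fq"),
                  truth = file.path(out_dir, "truth.bedpe"),
                  models = file.path(out_dir, "genes.bed"))
    write_genome_fasta(gen, paths$genome)
    write_reads(rd$reads, paths$reads)
    write_truth_bedpe(va$events, paths$truth)
    write_gene_models_bed12(models, paths$models)
    .msg(verbose, nrow(va$events), " truth events written")
    out$paths <- paths
  }
  out
}
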