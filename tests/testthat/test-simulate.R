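test_that("genome simulation is seed-deterministic and length-exact", {
  g1 <- simulate_genome(c(chr1 = 1000L), seed = 7)
  g2 <- simulate_genome(c(chr1 = 1000L), seed = 7)
  expect_identical(g1$seq, g2$seq)
  g3 <- simulate_genome(c(chr1 = 1000L, chr2 = 500L), seed = 1)
  expect_identical(unname(g3$lengths), c(1000L, 500L))
  expect_equal(length(g3), 1500)
  expect_true(all(strsplit(g3$seq$chr1, "")[[1]] %in% c("A", "C", "G", "T")))
  expect_error(simulate_genome(c(chr1 = 0L)), "positive")
  expect_error(simulate_genome(c(chr1 = -5L)), "positive")
})

test_that("genome GC fraction is controlled", {
  g <- simulate_genome(c(chr1 = 100000L), gc = 0.5, seed = 3)
  freq <- table(strsplit(g$seq$chr1, "")[[1]])
  gc <- sum(freq[c("G", "C")]) / sum(freq)
  expect_gt(gc, 0.48)
  expect_lt(gc, 0.52)
})

test_that("gene models obey their geometry and invariants", {
  gen <- simulate_genome(c(chr1 = 50000L), seed = 2)
  expect_equal(nrow(simulate_gene_models(gen, 0L)), 0)

  m <- simulate_gene_models(gen, 1L, exon_length_range = c(200L, 200L),
                            intron_length_range = c(500L, 500L),
                            exons_per_gene_range = c(3L, 3L), seed = 5)
  expect_equal(max(m$end) - min(m$start), 3 * 200 + 2 * 500)

  m2 <- simulate_gene_models(gen, 8L, intron_length_range = c(200L, 400L),
                             seed = 9)
  for (tx in unique(m2$transcript_id)) {
    ex <- m2[m2$transcript_id == tx, ]
    expect_true(all(diff(ex$start) > 0))
    expect_true(all(ex$end[-nrow(ex)] <= ex$start[-1]))  # disjoint
    expect_true(all(ex$start >= 0 & ex$end <= 50000))
  }
  # distinct gene loci never overlap
  spans <- do.call(rbind, lapply(split(m2, m2$transcript_id), function(ex)
    data.frame(s = min(ex$start), e = max(ex$end))))
  spans <- spans[order(spans$s), ]
  expect_true(all(spans$s[-1] >= spans$e[-nrow(spans)]))

  expect_error(simulate_gene_models(gen, 500L,
                                    intron_length_range = c(5000L, 5000L),
                                    seed = 1),
               "too small")
})

test_that("long introns produce long-range truth junctions", {
  gen <- simulate_genome(c(chr1 = 800000L), seed = 4)
  m <- simulate_gene_models(gen, 2L,
                            intron_length_range = c(120000L, 150000L),
                            exons_per_gene_range = c(2L, 2L), seed = 4)
  va <- apply_variants(m, gen, insertion_rate = 0, deletion_rate = 0)
  junc <- va$events[va$events$class == "junction", ]
  expect_true(any(junc$bp_right - junc$bp_left > 100000))
})

test_that("zero-rate variants reproduce the spliced reference exactly", {
  gen <- simulate_genome(c(chr1 = 30000L), seed = 6)
  m <- simulate_gene_models(gen, 3L, intron_length_range = c(300L, 800L),
                            seed = 7)
  va <- apply_variants(m, gen, insertion_rate = 0, deletion_rate = 0)
  for (tx in unique(m$transcript_id)) {
    ex <- m[m$transcript_id == tx, ]
    ref <- paste(vapply(seq_len(nrow(ex)), function(i)
      substr(gen$seq[[ex$chrom[i]]], ex$start[i] + 1L, ex$end[i]),
      character(1)), collapse = "")
    if (ex$strand[1] == "-") ref <- revcomp(ref)
    expect_identical(va$transcripts[[tx]], ref)
  }
  expect_true(all(va$events$class == "junction"))
})

test_that("every indel is recorded and transcript lengths are conserved", {
  gen <- simulate_genome(c(chr1 = 60000L), seed = 8)
  m <- simulate_gene_models(gen, 5L, intron_length_range = c(300L, 800L),
                            seed = 8)
  va <- apply_variants(m, gen, insertion_rate = 2, deletion_rate = 2,
                       seed = 11)
  for (tx in unique(m$transcript_id)) {
    ex <- m[m$transcript_id == tx, ]
    ev <- va$events[va$events$transcript_id == tx, ]
    expected <- sum(ex$end - ex$start) +
      sum(ev$ins_len[ev$class == "insertion"]) -
      sum(ev$bp_right[ev$class == "deletion"] - ev$bp_left[ev$class == "deletion"])
    expect_equal(nchar(va$transcripts[[tx]]), expected)
  }
  ins <- va$events[va$events$class == "insertion", ]
  expect_true(all(nchar(ins$ins_seq) == ins$ins_len))
  expect_true(all(ins$ins_len >= 1 & ins$ins_len <= 6))
  expect_true(all(va$events$bp_left <= va$events$bp_right))
})

test_that("a planted insertion is reconstructible by sequence diff", {
  # independent oracle: locate the single diff between reference splice
  # and emitted transcript by scanning from both ends
  gen <- simulate_genome(c(chr1 = 5000L), seed = 12)
  m <- data.frame(transcript_id = "t1", chrom = "chr1", strand = "+",
                  exon = 1L, start = 1000L, end = 1600L)
  va <- NULL
  for (s in 1:20) {   # first seed giving exactly one insertion
    cand <- apply_variants(m, gen, insertion_rate = 1, deletion_rate = 0,
                           max_insertion_len = 4L, seed = s)
    if (sum(cand$events$class == "insertion") == 1L) { va <- cand; break }
  }
  expect_false(is.null(va))
  ins <- va$events[va$events$class == "insertion", ][1, ]
  ref <- substr(gen$seq$chr1, 1001L, 1600L)
  mut <- va$transcripts[["t1"]]
  k <- nchar(mut) - nchar(ref)
  pre <- 0L
  while (substr(ref, pre + 1L, pre + 1L) == substr(mut, pre + 1L, pre + 1L))
    pre <- pre + 1L
  suf <- 0L
  while (substr(ref, nchar(ref) - suf, nchar(ref) - suf) ==
         substr(mut, nchar(mut) - suf, nchar(mut) - suf))
    suf <- suf + 1L
  # diff window [pre, len-suf) must contain the recorded insertion point
  ins_tx <- ins$tx_cut
  expect_gte(ins_tx + ins$ins_len, pre - k + 1)
  expect_lte(ins_tx, nchar(mut) - suf)
  expect_equal(k, ins$ins_len)
})

test_that("indel counts follow the configured Poisson rate", {
  gen <- simulate_genome(c(chr1 = 300000L), seed = 13)
  m <- simulate_gene_models(gen, 100L, exon_length_range = c(400L, 400L),
                            exons_per_gene_range = c(1L, 1L),
                            intron_length_range = c(200L, 200L), seed = 13)
  va <- apply_variants(m, gen, insertion_rate = 0.2, deletion_rate = 0,
                       seed = 14)
  n_ins <- sum(va$events$class == "insertion")
  # E = 100 x 0.2 = 20; 99% Poisson interval
  expect_gte(n_ins, qpois(0.005, 20))
  expect_lte(n_ins, qpois(0.995, 20))
})

test_that("error-free reads are exact transcript substrings at the right depth", {
  fx <- two_exon_fixture(seed = 21)
  txs <- c(t1 = fx$transcript)   # 600 bp
  rd <- simulate_reads(txs, read_length = 50L, depth = 30, error_rate = 0,
                       seed = 15)
  expect_equal(nrow(rd$reads), round(30 * 600 / 50))
  rc <- revcomp(fx$transcript)
  for (i in seq_len(nrow(rd$reads))) {
    s <- rd$reads$seq[i]
    expect_true(grepl(s, fx$transcript, fixed = TRUE) ||
                  grepl(s, rc, fixed = TRUE))
  }
  expect_error(simulate_reads(txs, depth = 0), "positive")
  expect_error(simulate_reads(c(t2 = "ACGT"), read_length = 50L), "shortest")
})

test_that("the detectable fraction of junction reads is about 14% for L=50, a=22", {
  gen <- simulate_genome(c(chr1 = 20000L), seed = 16)
  m <- data.frame(transcript_id = rep("t1", 2), chrom = "chr1", strand = "+",
                  exon = 1:2, start = c(1000L, 3000L), end = c(1500L, 3500L))
  va <- apply_variants(m, gen, insertion_rate = 0, deletion_rate = 0)
  rd <- simulate_reads(va$transcripts, va$events, read_length = 50L,
                       depth = 400, error_rate = 0, seed = 17)
  re <- rd$read_events
  frac <- mean(re$detectable)
  expect_gt(nrow(re), 200)
  expect_lt(abs(frac - detectable_offsets(50, 22) / 50), 0.03)
})

test_that("the simulated dataset is reproducible and its files round-trip", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  s1 <- simulate_dataset(chrom_lengths = c(chr1 = 60000L), n_genes = 2L,
                         intron_length_range = c(300L, 2000L), depth = 5,
                         seed = 19, out_dir = dir1)
  s2 <- simulate_dataset(chrom_lengths = c(chr1 = 60000L), n_genes = 2L,
                         intron_length_range = c(300L, 2000L), depth = 5,
                         seed = 19, out_dir = dir2)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$events, s2$events)
  expect_identical(unname(tools::md5sum(file.path(dir1, "reads.fq"))),
                   unname(tools::md5sum(file.path(dir2, "reads.fq"))))
  # FASTA/FASTQ round trips preserve sequence
  gen2 <- read_genome_fasta(file.path(dir1, "genome.fa"))
  expect_identical(gen2$seq, s1$genome$seq)
  rd2 <- read_reads(file.path(dir1, "reads.fq"))
  expect_identical(rd2$seq, s1$reads$seq)
  # truth BEDPE has one row per event
  truth_lines <- readLines(file.path(dir1, "truth.bedpe"))
  expect_equal(sum(!grepl("^#", truth_lines)), nrow(s1$events))
})
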