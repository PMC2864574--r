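test_that("read splitting yields the expected anchor gap", {
  cfg50 <- anchor_config(50, 22)
  s <- split_read(strrep("A", 50), cfg50)
  expect_equal(nchar(s$left), 22)
  expect_equal(nchar(s$right), 22)
  expect_equal(s$gap, 6)
  expect_equal(split_read(strrep("A", 44), anchor_config(44, 22))$gap, 0)
  expect_equal(split_read(strrep("A", 75), anchor_config(75, 22))$gap, 31)
  expect_error(split_read(strrep("A", 43), cfg50), "below")
  expect_error(anchor_config(43, 22), "twice")
  expect_error(anchor_config(50, 22, -1), ">= 0")
})

test_that("the detectable window has L - 2a + 1 offsets", {
  expect_equal(detectable_offsets(50, 22), 7)
  expect_equal(detectable_offsets(75, 22), 32)
  expect_equal(detectable_offsets(44, 22), 1)
  expect_equal(detectable_offsets(40, 22), 0)
})

test_that("anchor uniqueness follows the minimum-mismatch rule", {
  g <- rand_dna(2000, seed = 31)
  anchor <- substr(g, 501, 522)
  gen <- genome(c(c1 = g))
  res <- align_anchor(anchor, gen, 0)
  expect_true(res$unique)
  expect_equal(res$hits$start, 500)

  # implant an exact second copy: non-unique
  g2 <- g
  substr(g2, 1401, 1422) <- anchor
  res2 <- align_anchor(anchor, genome(c(c1 = g2)), 0)
  expect_false(res2$unique)
  expect_equal(nrow(res2$hits), 2)

  # a second copy with 2 mismatches does not break uniqueness at mm=2
  g3 <- g
  copy <- anchor
  substr(copy, 3, 3) <- setdiff(c("A", "C", "G", "T"), substr(copy, 3, 3))[1]
  substr(copy, 9, 9) <- setdiff(c("A", "C", "G", "T"), substr(copy, 9, 9))[1]
  substr(g3, 1401, 1422) <- copy
  res3 <- align_anchor(anchor, genome(c(c1 = g3)), 2)
  expect_gte(nrow(res3$hits), 2)
  expect_true(res3$unique)
})

test_that("non-ACGT anchor letters never match the reference", {
  g <- rand_dna(1000, seed = 32)
  anchor <- substr(g, 301, 322)
  substr(anchor, 5, 5) <- "N"
  res <- align_anchor(anchor, genome(c(c1 = g)), 2)
  hit <- res$hits[res$hits$start == 300 & res$hits$strand == "+", ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$mismatches, 1)  # the N position counts as a mismatch
  expect_equal(nrow(align_anchor(strrep("N", 22), genome(c(c1 = g)), 2)$hits), 0)
})

test_that("batch anchor matching agrees exactly with the brute-force scan", {
  gen <- genome(c(c1 = rand_dna(4000, seed = 41), c2 = rand_dna(2000, seed = 42)))
  set.seed(43)
  anchors <- unique(c(
    vapply(sample(3979, 40), function(s) substr(gen$seq$c1, s, s + 21), character(1)),
    vapply(seq_len(10), function(i) rand_dna(22), character(1))))
  for (mm in 0:2) {
    got <- anchorsplice:::.match_anchors(anchors, gen, mm)
    for (i in seq_along(anchors)) {
      mine <- got[got$anchor == i, c("chrom", "strand", "start", "mismatches")]
      rownames(mine) <- NULL
      oracle <- brute_force_hits(anchors[i], gen$seq, mm)
      rownames(oracle) <- NULL
      expect_identical(mine, oracle)
    }
  }
})

test_that("extension stops exactly at a junction and overruns shared prefixes", {
  cfg <- anchor_config(50, 22)
  # single-half extension: exact stop at the exon boundary
  fx <- two_exon_fixture(seed = 101)
  rd <- tx_read(fx, fx$junction_tx - 25L)   # cut at read offset 25
  half <- list(half = "left", chrom = "chrA", strand = "+",
               gstart = fx$bp_left - 25L, gend = fx$bp_left - 3L,
               rstart = 0L, rend = 22L)
  ext <- extend_alignment(half, rd$seq, fx$genome, cfg)
  expect_equal(ext$gend, fx$bp_left)
  expect_equal(ext$rend, 25L)

  # a 2-base shared intron/exon prefix makes the same half overrun by 2
  fx2 <- two_exon_fixture(seed = 102, shared_prefix = 2L)
  rd2 <- tx_read(fx2, fx2$junction_tx - 25L)
  half2 <- list(half = "left", chrom = "chrA", strand = "+",
                gstart = fx2$bp_left - 25L, gend = fx2$bp_left - 3L,
                rstart = 0L, rend = 22L)
  ext2 <- extend_alignment(half2, rd2$seq, fx2$genome, cfg)
  g2 <- fx2$genome$seq$chrA
  k <- 0L   # actual shared prefix (at least the 2 implanted bases)
  while (substr(g2, fx2$bp_left + k + 1L, fx2$bp_left + k + 1L) ==
         substr(g2, fx2$bp_right + k + 1L, fx2$bp_right + k + 1L)) k <- k + 1L
  expect_gte(k, 2L)
  expect_equal(ext2$gend, fx2$bp_left + k)

  # whole-read path: breakpoints recovered up to the trim ambiguity j,
  # the length of the shared suffix between exon 1 and the intron
  g <- fx$genome$seq$chrA
  j <- 0L
  while (substr(g, fx$bp_left - j, fx$bp_left - j) ==
         substr(g, fx$bp_right - j, fx$bp_right - j)) j <- j + 1L
  h <- align_split_reads(rd, fx$genome, cfg)
  expect_equal(nrow(h), 2)
  hl <- h[h$half == "left", ]; hr <- h[h$half == "right", ]
  expect_equal(hl$gend, fx$bp_left - j)
  expect_equal(hr$gstart, fx$bp_right - j)
  expect_equal(hl$rend, hr$rstart)     # read fully explained
})

test_that("a fully exonic read yields abutting halves and no residual gap", {
  fx <- two_exon_fixture(seed = 103)
  rd <- data.frame(read_id = "e1",
                   seq = substr(fx$genome$seq$chrA, 601, 650))
  h <- align_split_reads(rd, fx$genome, anchor_config(50, 22))
  hl <- h[h$half == "left", ]; hr <- h[h$half == "right", ]
  expect_equal(hl$rend, hr$rstart)
  expect_equal(hl$gend, hr$gstart)     # genomically contiguous
  expect_equal(find_candidates(h), anchorsplice:::.empty_candidates(),
               ignore_attr = TRUE)
})

test_that("extensions are maximal and mismatch bounds hold on simulated data", {
  sim <- simulate_dataset(chrom_lengths = c(chr1 = 80000L), n_genes = 3L,
                          intron_length_range = c(300L, 3000L), depth = 8,
                          error_rate = 0.01, seed = 51)
  cfg <- anchor_config(50, 22)
  h <- align_split_reads(sim$reads, sim$genome, cfg)
  seqs <- setNames(sim$reads$seq, sim$reads$read_id)
  gseq <- sim$genome$seq
  base_at <- function(chrom, pos, strand, flip = FALSE) {
    b <- substr(gseq[[chrom]], pos + 1, pos + 1)
    if (flip) revcomp(b) else b
  }
  for (i in seq_len(nrow(h))) {
    r <- h[i, ]; s <- seqs[[r$read_id]]
    a <- cfg$anchor_length; L <- cfg$read_length
    # seed region: at most max_mismatches; recompute from the genome
    if (r$half == "left") { srs <- 0L } else { srs <- L - a }
    gs_seed <- if (r$half == "left") {
      if (r$strand == "+") r$gstart else r$gend - a
    } else {
      if (r$strand == "+") r$gend - a else r$gstart
    }
    gseed <- substr(gseq[[r$chrom]], gs_seed + 1, gs_seed + a)
    if (r$strand == "-") gseed <- revcomp(gseed)
    rseed <- substr(s, srs + 1, srs + a)
    mm <- sum(charToRaw(rseed) != charToRaw(gseed))
    expect_lte(mm, cfg$max_mismatches)
    expect_equal(mm, r$mismatches)
    # extended region beyond the seed matches exactly
    if (r$half == "left" && r$rend > a) {
      ext_r <- substr(s, a + 1, r$rend)
      ext_g <- if (r$strand == "+")
        substr(gseq[[r$chrom]], r$gstart + a + 1, r$gend)
      else revcomp(substr(gseq[[r$chrom]], r$gstart + 1, r$gend - a))
      expect_identical(ext_r, ext_g)
    }
    # maximality: the next base past the extension mismatches or is a limit
    if (r$half == "left" && !(r$paired && r$rend == L - a) && r$rend < L) {
      np <- if (r$strand == "+") r$gend else r$gstart - 1
      if (np >= 0 && np < nchar(gseq[[r$chrom]])) {
        nx <- base_at(r$chrom, np, r$strand, flip = r$strand == "-")
        # paired halves may instead have been trimmed back at the overlap
        if (!r$paired)
          expect_false(nx == substr(s, r$rend + 1, r$rend + 1))
      }
    }
  }
})

test_that("alignment is mirror-symmetric under reverse complement", {
  # seed 121: the junction has no shared exon/intron sequence, so the
  # canonical breakpoint cut is unambiguous and the mirror image is exact
  # for junction reads; for contiguous reads only the genomic footprint
  # mirrors (the canonical cut direction follows the genomic axis)
  fx <- two_exon_fixture(seed = 121)
  cfg <- anchor_config(50, 22)
  rds <- do.call(rbind, lapply(c(fx$junction_tx - 25L, fx$junction_tx - 24L,
                                 100L, 150L),
                               function(o) tx_read(fx, o, id = sprintf("o%d", o))))
  n <- nchar(fx$genome$seq$chrA)
  gen_rc <- genome(c(chrA = revcomp(fx$genome$seq$chrA)))
  h1 <- align_split_reads(rds, fx$genome, cfg)
  h2 <- align_split_reads(rds, gen_rc, cfg)
  expect_equal(nrow(h1), nrow(h2))
  for (id in unique(h1$read_id)) {
    a <- h1[h1$read_id == id, ]; b <- h2[h2$read_id == id, ]
    expect_true(all(b$strand != a$strand[match(b$half, a$half)]))
    # genomic footprint of the whole read mirrors exactly
    expect_equal(min(b$gstart), n - max(a$gend))
    expect_equal(max(b$gend), n - min(a$gstart))
  }
  # candidate breakpoint pairs mirror exactly: (l, r) -> (n - r, n - l)
  c1 <- find_candidates(h1); c2 <- find_candidates(h2)
  expect_equal(nrow(c1), nrow(c2))
  expect_setequal(paste(n - c2$start2, n - c2$end1),
                  paste(c1$end1, c1$start2))
})

test_that("the half-alignment table round-trips through its TSV format", {
  fx <- two_exon_fixture(seed = 105)
  h <- align_split_reads(tx_read(fx, fx$junction_tx - 25L), fx$genome,
                         anchor_config(50, 22))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_half_alignments(h, path)
  expect_identical(read_half_alignments(path), h)
  write_half_alignments(h[0, ], path)
  expect_equal(nrow(read_half_alignments(path)), 0)
})
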