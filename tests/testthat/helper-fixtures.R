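# Fixtures are built in code; nothing is read from disk except round-trip
# temporaries created by the tests themselves.

# random DNA string (independent of the package's genome simulator)
rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# brute-force anchor matcher: slides every window on both strands and
# counts character mismatches; the independent oracle for anchor alignment
brute_force_hits <- function(anchor, genome_seqs, max_mm) {
  a <- nchar(anchor)
  q_plus <- utf8ToInt(anchor)
  q_minus <- utf8ToInt(as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(anchor))))
  out <- list()
  for (chrom in names(genome_seqs)) {
    g <- utf8ToInt(genome_seqs[[chrom]])
    n <- length(g) - a + 1L
    if (n < 1L) next
    win <- vapply(seq_len(a), function(j) g[j:(j + n - 1L)],
                  integer(n))           # n x a window matrix
    tw <- t(win)
    for (strand in c("+", "-")) {
      q <- if (strand == "+") q_plus else q_minus
      mm <- colSums(tw != q)
      hit <- which(mm <= max_mm)
      if (length(hit))
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, strand = strand, start = hit - 1L,
          mismatches = as.integer(mm[hit]))
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), strand = character(0),
                      start = integer(0), mismatches = integer(0)))
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start, res$strand), , drop = FALSE]
}

# two-exon fixture: a random genome with one gene whose junction and exon
# boundaries are known exactly; reads are cut from the spliced transcript
two_exon_fixture <- function(seed = 101, chrom_len = 4000L,
                             exon1 = c(500L, 800L), exon2 = c(2000L, 2300L),
                             shared_prefix = 0L) {
  g <- rand_dna(chrom_len, seed)
  if (shared_prefix > 0L) {
    # make the first bases of the intron equal the first bases of exon 2,
    # provoking overextension of the left half
    pre <- substr(g, exon2[1] + 1L, exon2[1] + shared_prefix)
    substr(g, exon1[2] + 1L, exon1[2] + shared_prefix) <- pre
  }
  gen <- genome(c(chrA = g))
  tx <- paste0(substr(g, exon1[1] + 1L, exon1[2]),
               substr(g, exon2[1] + 1L, exon2[2]))
  list(genome = gen, transcript = tx, exon1 = exon1, exon2 = exon2,
       junction_tx = exon1[2] - exon1[1],      # cut position on transcript
       bp_left = exon1[2], bp_right = exon2[1])
}

# cut a read of length L starting at 0-based transcript offset
tx_read <- function(fx, offset, L = 50L, id = sprintf("r%03d", offset)) {
  data.frame(read_id = id, seq = substr(fx$transcript, offset + 1L, offset + L))
}

# minimal hand-made candidate row for clustering tests
cand_row <- function(bp_left, bp_right, read_id = "r1", chrom = "chr1",
                     read_start = bp_left - 30L, n_insert = 0L,
                     strand = "+", chrom2 = chrom, colinear = TRUE) {
  data.frame(chrom1 = chrom, start1 = read_start, end1 = bp_left,
             chrom2 = chrom2, start2 = bp_right, end2 = bp_right + 30L,
             read_id = read_id, score = 0L, strand1 = strand,
             strand2 = strand, origin = "gap-split", read_start = read_start,
             n_insert = n_insert, colinear = colinear)
}

# truth events cleanly supported in a simulation: detectable breakpoint,
# read overlaps no other event, and at least min_n distinct start offsets
clean_supported_events <- function(sim, min_n = 2L) {
  re <- sim$read_events
  multi <- names(which(table(re$read_id) > 1L))
  reu <- re[re$detectable & !(re$read_id %in% multi), , drop = FALSE]
  reu <- merge(reu, sim$reads[, c("read_id", "offset")])
  if (!nrow(reu)) return(character(0))
  supp <- aggregate(offset ~ event_id, data = reu,
                    FUN = function(x) length(unique(x)))
  supp$event_id[supp$offset >= min_n]
}

# does a predicted event match a truth event within tol at both ends?
matches_truth <- function(ev, truth, tol = 5L, class_must_match = TRUE) {
  vapply(seq_len(nrow(ev)), function(i) {
    ok <- truth$chrom == ev$chrom1[i] &
      abs(truth$bp_left - ev$bp_left[i]) <= tol &
      abs(truth$bp_right - ev$bp_right[i]) <= tol
    if (class_must_match) ok <- ok & truth$class == ev$class[i]
    any(ok)
  }, logical(1))
}
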