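#' Genome container
#'
#' A genome is a set of named chromosome sequences. It is the single source
#' of coordinate truth for the whole pipeline: every interval elsewhere is
#' 0-based half-open on one of these chromosomes.
#'
#' @param seqs named character vector of chromosome sequences (A/C/G/T).
#' @return an object of class `genome`: a list with elements `seq` (named
#'   list of sequences) and `lengths` (named integer vector, bp).
#' @export
genome <- function(seqs) {
  if (length(seqs) == 0L) .stopf("a genome needs at least one chromosome")
  nm <- names(seqs)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
    .stopf("chromosome names must be present and unique")
  seqs <- as.list(toupper(as.character(seqs)))
  names(seqs) <- nm
  structure(list(seq = seqs, lengths = vapply(seqs, nchar, integer(1))),
            class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("genome: %d chromosome(s), %s bp total\n",
              length(x$seq), format(sum(as.numeric(x$lengths)), big.mark = ",")))
  for (nm in names(x$lengths))
    cat(sprintf("  %s  %s bp\n", nm, format(x$lengths[[nm]], big.mark = ",")))
  invisible(x)
}

#' @export
length.genome <- function(x) sum(as.numeric(x$lengths))

# DNAStringSet view used by the batch anchor matcher
.as_dss <- function(genome) {
  Biostrings::DNAStringSet(unlist(genome$seq))
}

#' Read a genome from FASTA
#'
#' @param path FASTA file (optionally gzip-compressed).
#' @return a [genome] object.
#' @export
read_genome_fasta <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  names(dss) <- sub("\\s.*$", "", names(dss))
  genome(as.character(dss))
}

#' Write a genome to FASTA
#'
#' @param genome a [genome] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(.as_dss(genome), path)
  invisible(path)
}
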