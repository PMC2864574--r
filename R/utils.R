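# internal helpers shared across modules

#' @importFrom stats rbinom rpois runif setNames
#' @importFrom utils head
#' @importFrom utils read.table write.table
NULL

.msg <- function(verbose, ...) {
  if (isTRUE(verbose)) message(...)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Reverse-complement nucleotide strings
#'
#' Vectorised reverse complement over plain character vectors.
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# substring of one chromosome, 0-based half-open coordinates
.gseq <- function(genome, chrom, start0, end0) {
  substr(genome$seq[[chrom]], start0 + 1L, end0)
}

# count mismatching characters between two equal-length strings; N never matches N
.nmismatch <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  n <- sum(ra != rb)
  # positions where both are non-ACGT still count as mismatches
  amb <- ra == charToRaw("N") & rb == charToRaw("N")
  n + sum(amb)
}

# apply a chromosome renaming map (named character vector) to a vector of names
.apply_chrmap <- function(chroms, chrmap) {
  if (is.null(chrmap)) return(chroms)
  hit <- chroms %in% names(chrmap)
  chroms[hit] <- unname(chrmap[chroms[hit]])
  chroms
}

#' Read a chromosome-name mapping file
#'
#' A chrmap file is a two-column tab-separated table mapping internal
#' chromosome names (as used during alignment) to the names expected by
#' genome databases, applied to all coordinates at write time.
#'
#' @param path path to a two-column TSV (internal name, output name).
#' @return named character vector (names = internal, values = output).
#' @export
read_chrmap <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("from", "to"),
                           colClasses = "character", comment.char = "#")
  if (anyDuplicated(tab$from)) .stopf("duplicate internal names in chrmap '%s'", path)
  stats::setNames(tab$to, tab$from)
}
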