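# False-discovery-rate estimate for distance-stratified junction calls
# under a uniform-placement null: the two breakpoints of a false call are
# modelled as independent uniform positions on the pooled genome, so the
# probability that they land within +/- w of each other is 2w/G (edge
# effects ignored).

#' Null probability that two uniform breakpoints fall within a window
#'
#' Given that the first breakpoint is placed anywhere on a genome of
#' pooled length `G`, the second must land in a `+/- w` window around it,
#' of size `2w`, so the probability is `2w / G`. Chromosome-edge and
#' cross-chromosome effects are deliberately ignored; for `w` much
#' smaller than a chromosome they are negligible.
#'
#' @param w window half-width (bp), e.g. `1e6`.
#' @param G pooled genome length (bp), e.g. `2.7e9` for mouse mm9.
#' @return probability `2w / G`.
#' @export
null_probability <- function(w, G) {
  if (G <= 0) .stopf("genome length must be positive")
  if (w <= 0 || w >= G / 2) .stopf("window half-width must be in (0, G/2)")
  2 * w / G
}

#' Expected number of false calls under the uniform null
#'
#' @param N total number of predicted junctions (all spans).
#' @param p null probability for the window (see [null_probability()]).
#' @return `N * p`.
#' @export
expected_false <- function(N, p) {
  if (N < 0) .stopf("N must be >= 0")
  N * p
}

#' False discovery rate as expected over observed
#'
#' @param expected expected number of false calls within the window.
#' @param observed observed number of calls within the window.
#' @return `expected / observed`; `NA` (not applicable) when `observed`
#'   is 0.
#' @export
fdr <- function(expected, observed) {
  if (observed < 0) .stopf("observed must be >= 0")
  if (observed == 0) return(NA_real_)
  expected / observed
}

#' FDR report for a set of predicted junctions
#'
#' For each window half-width, computes the uniform-null probability, the
#' observed number of junctions whose breakpoints lie within the window,
#' the expected number of false calls `N * p` (`N` counts all predicted
#' junctions regardless of span), and the FDR = expected / observed.
#' Computation uses the unrounded probability ratio; the print method
#' rounds expected counts to one decimal and FDR to two significant
#' figures.
#'
#' @param events `predicted_events` data.frame, or a numeric vector of
#'   junction spans (bp, `NA` = interchromosomal). Junction-class events
#'   (including long-range ones) enter the report.
#' @param genome_length pooled genome length G (bp).
#' @param windows numeric vector of window half-widths (bp).
#' @return data.frame of class `fdr_report` with one row per window:
#'   `window`, `p_null`, `n_total`, `observed`, `expected`, `fdr`.
#' @export
fdr_report <- function(events, genome_length, windows = c(1e6, 1e5)) {
  spans <- if (is.data.frame(events)) {
    ev <- events
    if ("class" %in% names(ev)) ev <- ev[ev$class == "junction", , drop = FALSE]
    ev$span
  } else as.numeric(events)
  N <- length(spans)
  rows <- lapply(windows, function(w) {
    p <- null_probability(w, genome_length)
    obs <- sum(!is.na(spans) & spans <= w)
    e <- expected_false(N, p)
    data.frame(window = w, p_null = p, n_total = N, observed = obs,
               expected = e, fdr = fdr(e, obs))
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(window = numeric(0), p_null = numeric(0), n_total = integer(0),
               observed = integer(0), expected = numeric(0), fdr = numeric(0))
  attr(out, "genome_length") <- genome_length
  class(out) <- c("fdr_report", "data.frame")
  out
}

#' @export
print.fdr_report <- function(x, ...) {
  cat(sprintf("FDR under uniform-placement null (pooled G = %s bp)\n",
              format(attr(x, "genome_length"), big.mark = ",")))
  cat(sprintf("total predicted junctions N = %d\n",
              if (nrow(x)) x$n_total[1] else 0L))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  within %s bp: observed %d, expected false %.1f (FDR %s)\n",
                format(x$window[i], big.mark = ",", scientific = FALSE),
                x$observed[i], x$expected[i],
                if (is.na(x$fdr[i])) "n/a" else signif(x$fdr[i], 2)))
  }
  invisible(x)
}

#' Write an FDR report as TSV
#'
#' @param report an `fdr_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fdr_report <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
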