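#' One-sided upper-tail Fisher probability for a 2x2 table
#'
#' Probability of observing the top-left cell value or a larger one under
#' the hypergeometric distribution fixed at the table margins, i.e.
#' `P(X >= a)` with `X ~ Hypergeometric(a + c, b + d, a + b)`. This is the
#' one-sided Fisher exact test used throughout the competitive enrichment
#' pipeline: `a` articles in the SCP set mentioning the gene, `a + b`
#' articles in the SCP set, `c` background articles mentioning the gene,
#' `c + d` background articles.
#'
#' @param a,b,c,d non-negative integer cell counts (vectorized).
#' @return numeric vector of upper-tail probabilities in (0, 1].
#' @examples
#' fisher_upper_tail(2, 0, 0, 2)   # 1/6
#' fisher_upper_tail(0, 10, 5, 85) # P(X >= 0) = 1
#' @export
fisher_upper_tail <- function(a, b, c, d) {
  if (any(a < 0 | b < 0 | c < 0 | d < 0, na.rm = TRUE))
    stop("all cell counts must be non-negative", call. = FALSE)
  if (any(a + b + c + d <= 0))
    stop("degenerate table: grand total must be positive", call. = FALSE)
  stats::phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
}

#' Largest-gap cutoff over a gene's -log10 p-values
#'
#' Given one gene's enrichment p-values across a background set of SCPs,
#' sorts the -log10(p) values in decreasing order, finds the largest gap
#' between adjacent values and keeps only the SCPs above that gap. Ties
#' between equally large gaps are broken toward the top of the list (the
#' most stringent cut). A single value is always kept, and when all values
#' are identical (every gap is zero) no informative cut exists and all SCPs
#' are kept, preserving symmetry between identically-scored siblings.
#'
#' @param values named numeric vector of -log10(p) values (names are SCP
#'   ids), or a data.frame with columns `scp` and `neglog_p`.
#' @return character vector of kept SCP ids.
#' @examples
#' largest_gap_filter(c(A = 8.1, B = 7.9, C = 2.0, D = 1.5)) # A, B
#' @export
largest_gap_filter <- function(values) {
  if (is.data.frame(values))
    values <- stats::setNames(values$neglog_p, values$scp)
  if (!length(values)) stop("empty input", call. = FALSE)
  if (any(!is.finite(values)))
    stop("-log10(p) values must be finite", call. = FALSE)
  o <- stable_order(-values, names(values))
  v <- values[o]
  if (length(v) == 1L) return(names(v))
  gaps <- v[-length(v)] - v[-1L]
  mg <- max(gaps)
  if (mg <= 0) return(names(v))
  keep <- which(gaps == mg)[1L]
  names(v)[seq_len(keep)]
}

# -log10 with protection against p underflowing to 0
neglog10 <- function(p) -log10(pmax(p, .Machine$double.xmin))
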