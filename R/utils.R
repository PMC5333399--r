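# Numerical helpers shared across the package. Everything likelihood-related
# is kept in log space; these are the only places exp() is applied to
# potentially large-magnitude sums.

#' Numerically stable log(sum(exp(x)))
#'
#' @param x Numeric vector (may contain -Inf).
#' @return A single numeric value.
#' @keywords internal
logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Row-wise log-sum-exp of a matrix
#'
#' @param m Numeric matrix.
#' @return Numeric vector with one value per row.
#' @keywords internal
rowLogSumExp <- function(m) {
  mx <- apply(m, 1L, max)
  out <- mx + log(rowSums(exp(m - mx)))
  out[!is.finite(mx)] <- mx[!is.finite(mx)]
  out
}

# Gumbel-max categorical draw from unnormalized log weights; immune to
# underflow when all weights are tiny.
gumbelMaxDraw <- function(logw) {
  which.max(logw - log(-log(stats::runif(length(logw)))))
}

# Canonicalize integer cluster labels to first-appearance order so that
# identical partitions compare equal.
canonicalLabels <- function(labels) {
  match(labels, unique(labels))
}

assertProb <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("'%s' must lie in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}
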