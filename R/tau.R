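#' Kendall tau-a rank correlation
#'
#' Rank correlation with the full pair count as denominator:
#' `(concordant - discordant) / (m(m-1)/2)`. Tied pairs contribute zero to
#' the numerator but are counted in the denominator, so tau-a (unlike
#' tau-b) penalizes predictors that do not discriminate between pairs --
#' the appropriate measure when comparing models that may predict tied
#' dissimilarities. Computed in O(m log m) via Knight's algorithm.
#'
#' A constant input vector has no discordant or concordant pairs; tau is
#' then 0 by convention and a warning is raised.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return Kendall tau-a in \[-1, 1\].
#' @export
kendall_tau_a <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need vectors of length >= 2")
  if (min(x) == max(x) || min(y) == max(y)) {
    warning("constant input vector: tau-a is 0 by convention")
    return(0)
  }
  .tau_a_cpp(x, y)
}
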