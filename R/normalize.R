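#' Cyclic loess normalization of a log-scale quantification matrix
#'
#' Removes sample loading bias by cyclic loess on MA coordinates,
#' delegating to `limma::normalizeCyclicLoess`. In the default `fast`
#' mode each column is regressed (local linear fit, tricube weights)
#' against the row-wise mean reference and the fitted trend subtracted,
#' cycling over columns for `iterations` rounds; `pairs` is the classic
#' all-pairs variant with half-corrections. Missing cells stay missing
#' and the missingness pattern is preserved exactly.
#'
#' @param x Numeric features x runs matrix in log scale, or a
#'   `spied_matrix` (its `values` are normalized in place).
#' @param span Loess span as a fraction of the data in (0, 1]; default 0.7.
#' @param iterations Number of normalization cycles; default 3.
#' @param method `"fast"` (reference-based, default) or `"pairs"`.
#' @param min_shared Minimum complete pairs a column must share with the
#'   reference; columns below it raise an error naming the column.
#' @return Same type as `x`, normalized.
#' @export
normalize_cyclic_loess <- function(x, span = 0.7, iterations = 3,
                                   method = c("fast", "pairs"),
                                   min_shared = 10L) {
  method <- match.arg(method)
  stopifnot(span > 0, span <= 1, iterations >= 1)
  if (inherits(x, "spied_matrix")) {
    x$values <- normalize_cyclic_loess(x$values, span = span,
                                       iterations = iterations,
                                       method = method,
                                       min_shared = min_shared)
    return(x)
  }
  stopifnot(is.matrix(x), is.numeric(x))
  if (ncol(x) < 2L) stop("need at least 2 columns to normalize")
  obs <- !is.na(x)
  ref_obs <- rowSums(obs) > 0L
  shared <- colSums(obs & ref_obs)
  low <- shared < min_shared
  if (any(low)) {
    nm <- colnames(x)[low]
    if (is.null(nm)) nm <- which(low)
    stop("column(s) share fewer than ", min_shared,
         " complete pairs with the reference: ", paste(nm, collapse = ", "))
  }
  out <- limma::normalizeCyclicLoess(x, span = span, iterations = iterations,
                                     method = method)
  dimnames(out) <- dimnames(x)
  stopifnot(identical(is.na(out), is.na(x)))
  out
}
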