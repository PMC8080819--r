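#' Pearson correlation with two-sided p value
#'
#' Sample Pearson coefficient together with the two-sided tail probability
#' of `t = r * sqrt((n - 2) / (1 - r^2))` under a t distribution with
#' `n - 2` degrees of freedom. At numerically perfect correlation
#' (`|r| == 1`) the returned p is 0.
#'
#' @param x,y Numeric vectors of equal length `n >= 3` with nonzero
#'   variance.
#' @return List with elements `r`, `p`, `n`.
#' @export
pearson_with_p <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y)) {
    ddpp_validation_error("x and y must be numeric vectors of equal length")
  }
  n <- length(x)
  if (n < 3L) ddpp_validation_error("Pearson test requires n >= 3")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    ddpp_validation_error("x and y must be finite")
  }
  xc <- x - mean(x)
  yc <- y - mean(y)
  sxx <- sum(xc^2)
  syy <- sum(yc^2)
  if (sxx == 0 || syy == 0) {
    ddpp_degenerate_error("zero variance in correlation input")
  }
  r <- sum(xc * yc) / sqrt(sxx * syy)
  r <- max(-1, min(1, r))
  df <- n - 2L
  if (1 - r^2 <= .Machine$double.eps) {
    p <- 0
  } else {
    tstat <- r * sqrt(df / (1 - r^2))
    p <- 2 * pt(-abs(tstat), df)
  }
  list(r = r, p = p, n = n)
}

ddpp_methods_all <- c("sum", "mean", "median", "fold", "fold_abs")

#' The five parameter-free summation methods
#'
#' @return Character vector `c("sum", "mean", "median", "fold", "fold_abs")`
#'   in the canonical (tie-break) order.
#' @export
ddpp_methods <- function() ddpp_methods_all

#' Collapse per-gene features into one scalar
#'
#' The parameter-free vector summations: `sum`, `mean`, `median` (even
#' lengths average the two middle values), `fold` (signed product) and
#' `fold_abs` (product of absolute values). No coefficients are estimated,
#' which is what makes the approach usable on cohorts of three to ten
#' patients.
#'
#' @param features Non-empty numeric vector of per-gene feature values for
#'   one patient.
#' @param method One of [ddpp_methods()].
#' @return A single finite number.
#' @export
summate <- function(features, method = ddpp_methods()) {
  method <- match.arg(method)
  if (!is.numeric(features) || !length(features)) {
    ddpp_validation_error("features must be a non-empty numeric vector")
  }
  if (any(!is.finite(features))) {
    ddpp_validation_error("features must be finite")
  }
  out <- switch(method,
    sum = sum(features),
    mean = mean(features),
    median = median(features),
    fold = prod(features),
    fold_abs = prod(abs(features))
  )
  if (!is.finite(out)) {
    ddpp_validation_error(sprintf(
      "summation method '%s' overflowed to a non-finite value", method
    ))
  }
  out
}

# Row-wise summation over a patients x genes matrix; the hot path of the
# null scan, so sum/mean/fold avoid per-row apply().
summate_rows <- function(values, method) {
  n <- nrow(values)
  switch(method,
    sum = rowSums(values),
    mean = rowMeans(values),
    median = apply(values, 1L, median),
    fold = {
      out <- rep(1, n)
      for (j in seq_len(ncol(values))) out <- out * values[, j]
      out
    },
    fold_abs = {
      out <- rep(1, n)
      for (j in seq_len(ncol(values))) out <- out * abs(values[, j])
      out
    },
    ddpp_validation_error(sprintf("unknown summation method '%s'", method))
  )
}
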