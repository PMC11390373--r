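#' Stick-breaking map from unconstrained coordinates to the 3-simplex
#'
#' Bijection between `K-1` unconstrained real coordinates and the interior
#' of the `K`-simplex, used to parameterize the sum-to-one constrained
#' drift-rate means and start-point upper bounds. The k-th stick proportion
#' is `plogis(y_k - log(K - k))`; the shift centers the map so that
#' `y = 0` gives the uniform simplex point.
#'
#' @param y Numeric vector of length `K - 1` of unconstrained coordinates.
#' @return Numeric vector of length `K` on the open simplex.
#' @seealso [simplex_inverse()], [simplex_log_jacobian()]
#' @export
simplex_forward <- function(y) {
  K <- length(y) + 1L
  x <- numeric(K)
  remaining <- 1
  for (k in seq_len(K - 1L)) {
    z <- plogis(y[k] - log(K - k))
    x[k] <- remaining * z
    remaining <- remaining - x[k]
  }
  x[K] <- remaining
  x
}

#' Inverse stick-breaking map
#'
#' @param x Numeric vector of length `K` on the open simplex.
#' @return Numeric vector of length `K - 1` of unconstrained coordinates.
#' @export
simplex_inverse <- function(x) {
  K <- length(x)
  if (any(x <= 0) || abs(sum(x) - 1) > 1e-8)
    stop("`x` must lie in the interior of the simplex")
  y <- numeric(K - 1L)
  remaining <- 1
  for (k in seq_len(K - 1L)) {
    z <- x[k] / remaining
    y[k] <- qlogis(z) + log(K - k)
    remaining <- remaining - x[k]
  }
  y
}

#' Log absolute determinant of the stick-breaking Jacobian
#'
#' Volume correction `log |d x / d y|` for priors placed on the simplex
#' coordinates while sampling on the unconstrained scale.
#'
#' @inheritParams simplex_forward
#' @return Scalar log-Jacobian.
#' @export
simplex_log_jacobian <- function(y) {
  K <- length(y) + 1L
  lj <- 0
  remaining <- 1
  for (k in seq_len(K - 1L)) {
    z <- plogis(y[k] - log(K - k))
    lj <- lj + log(z) + log1p(-z) + log(remaining)
    remaining <- remaining * (1 - z)
  }
  lj
}
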