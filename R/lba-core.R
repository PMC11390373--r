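#' Construct and validate a set of three-accumulator LBA parameters
#'
#' The model has one linear ballistic accumulator per response
#' (Repeat, Lure, Foil). On each trial, accumulator \eqn{r} starts at a
#' uniform draw from \eqn{[0, \min(A_r, b)]} and rises linearly at a rate
#' drawn from \eqn{N(v_r, s)}; the first accumulator to reach the common
#' boundary \eqn{b} determines the response, and the observed response time
#' is its crossing time plus the non-decision time \eqn{\tau}. For
#' identifiability the drift-rate means and the start-point upper bounds are
#' each constrained to the 3-simplex (\eqn{\sum_r v_r = 1},
#' \eqn{\sum_r A_r = 1}) and the drift-rate standard deviation is fixed at
#' \eqn{s = 1}.
#'
#' @param v Numeric 3-vector of mean drift rates in canonical response order
#'   (repeat, lure, foil); strictly positive, summing to 1.
#' @param A Numeric 3-vector of start-point upper bounds, same order and
#'   constraints as `v`.
#' @param b Response boundary (evidence units), positive scalar.
#' @param tau Non-decision time in seconds, non-negative scalar.
#' @param s Trial-level drift-rate standard deviation; fixed to 1 in the
#'   model, but exposed for limit checks in tests.
#' @return An object of class `lba_parameters`.
#' @examples
#' lba_parameters(v = c(0.47, 0.23, 0.30), A = c(0.49, 0.12, 0.39),
#'                b = 0.8, tau = 0.5)
#' @export
lba_parameters <- function(v, A, b, tau, s = 1) {
  stopifnot(length(v) == 3L, length(A) == 3L,
            length(b) == 1L, length(tau) == 1L, length(s) == 1L)
  if (!all(is.finite(v)) || any(v <= 0))
    stop("all drift-rate means `v` must be finite and strictly positive")
  if (!all(is.finite(A)) || any(A <= 0))
    stop("all start-point bounds `A` must be finite and strictly positive")
  if (abs(sum(v) - 1) > 1e-8)
    stop("drift-rate means `v` must sum to 1 (simplex constraint)")
  if (abs(sum(A) - 1) > 1e-8)
    stop("start-point bounds `A` must sum to 1 (simplex constraint)")
  if (!is.finite(b) || b <= 0) stop("boundary `b` must be positive")
  if (!is.finite(tau) || tau < 0) stop("non-decision time `tau` must be >= 0")
  if (!is.finite(s) || s <= 0) stop("drift SD `s` must be positive")
  structure(
    list(v = setNames(as.numeric(v), RESPONSE_LEVELS),
         A = setNames(as.numeric(A), RESPONSE_LEVELS),
         b = as.numeric(b), tau = as.numeric(tau), s = as.numeric(s)),
    class = "lba_parameters")
}

#' @export
print.lba_parameters <- function(x, ...) {
  cat("3-accumulator LBA parameters (repeat, lure, foil)\n")
  cat(sprintf("  v   : %s\n", paste(sprintf("%.3f", x$v), collapse = " ")))
  cat(sprintf("  A   : %s\n", paste(sprintf("%.3f", x$A), collapse = " ")))
  cat(sprintf("  b   : %.3f   tau: %.3f   s: %.1f\n", x$b, x$tau, x$s))
  invisible(x)
}

check_accumulator_args <- function(t_dec, v, A, b, s) {
  if (any(!is.finite(t_dec)) || any(t_dec <= 0))
    stop("decision time `t_dec` must be positive")
  if (any(A < 0)) stop("start-point bound `A` must be non-negative")
  if (b <= 0) stop("boundary `b` must be positive")
  if (s <= 0) stop("drift SD `s` must be positive")
}

#' Single-accumulator first-passage CDF
#'
#' Probability that one linear ballistic accumulator with start point
#' uniform on \eqn{[0, \min(A, b)]} and drift rate \eqn{N(v, s)} has crossed
#' the boundary `b` by decision time `t_dec`. The distribution is defective:
#' its limit as `t_dec` grows is \eqn{\Phi(v/s) < 1}, because trials whose
#' sampled drift is negative never finish.
#'
#' @param t_dec Decision time in seconds (vectorized), strictly positive.
#' @param v Mean drift rate of this accumulator.
#' @param A Start-point upper bound of this accumulator.
#' @param b Boundary.
#' @param s Drift-rate standard deviation.
#' @return Vector of probabilities in `[0, 1)`.
#' @export
plba_accumulator <- function(t_dec, v, A, b, s = 1) {
  check_accumulator_args(t_dec, v, A, b, s)
  A_eff <- min(A, b)                     # start point is truncated below b
  ts <- t_dec * s
  if (A_eff < 1e-10) {
    # degenerate start at 0: crossing iff sampled drift >= b / t
    p <- pnorm((t_dec * v - b) / ts)
  } else {
    z1 <- (b - A_eff - t_dec * v) / ts
    z2 <- (b - t_dec * v) / ts
    p <- 1 +
      (b - A_eff - t_dec * v) / A_eff * pnorm(z1) -
      (b - t_dec * v) / A_eff * pnorm(z2) +
      ts / A_eff * (dnorm(z1) - dnorm(z2))
  }
  pmin(pmax(p, 0), 1)
}

#' Single-accumulator first-passage density
#'
#' Derivative of [plba_accumulator()] in `t_dec`; the defective density of
#' boundary-crossing times for one accumulator.
#'
#' @inheritParams plba_accumulator
#' @return Vector of non-negative densities (per second).
#' @export
dlba_accumulator <- function(t_dec, v, A, b, s = 1) {
  check_accumulator_args(t_dec, v, A, b, s)
  A_eff <- min(A, b)
  ts <- t_dec * s
  if (A_eff < 1e-10) {
    d <- dnorm((b - t_dec * v) / ts) * b / (s * t_dec^2)
  } else {
    z1 <- (b - A_eff - t_dec * v) / ts
    z2 <- (b - t_dec * v) / ts
    d <- (-v * pnorm(z1) + s * dnorm(z1) + v * pnorm(z2) - s * dnorm(z2)) / A_eff
  }
  pmax(d, 0)
}

#' Probability that at least one accumulator eventually finishes
#'
#' Complement of the probability that every trial-level drift draw is
#' negative; the normalizing constant used when the race likelihood is
#' conditioned on a response occurring.
#'
#' @param params An [lba_parameters()] object.
#' @return Scalar probability.
#' @export
lba_finish_probability <- function(params) {
  1 - prod(pnorm(-params$v / params$s))
}

#' Race-model likelihood of one observed (response, RT) pair
#'
#' Density of observing `response` at time `rt` under the three-accumulator
#' race: the winning accumulator's first-passage density at the decision
#' time `rt - tau`, times the survival probabilities of the two losers at
#' that same time. Evidence is accumulated independently for each response,
#' so the race factorizes. An RT at or below the non-decision time has
#' likelihood zero (not an error): no decision can complete that fast under
#' the model.
#'
#' @param response Response identity: `"repeat"`, `"lure"`, or `"foil"`
#'   (or index 1-3 in canonical order).
#' @param rt Observed response time in seconds (vectorized), positive.
#' @param params An [lba_parameters()] object.
#' @param renormalize If `TRUE`, condition on at least one accumulator
#'   finishing by dividing by [lba_finish_probability()]; the default keeps
#'   the conventional unnormalized defective likelihood.
#' @return Likelihood density (per second), zero when `rt <= tau`.
#' @export
dlba_race <- function(response, rt, params, renormalize = FALSE) {
  r <- match_response(response)
  if (any(!is.finite(rt)) || any(rt <= 0)) stop("`rt` must be positive")
  t_dec <- rt - params$tau
  out <- numeric(length(rt))
  ok <- t_dec > 0
  if (any(ok)) {
    td <- t_dec[ok]
    dens <- dlba_accumulator(td, params$v[r], params$A[r], params$b, params$s)
    for (j in seq_len(3L)[-r]) {
      dens <- dens *
        (1 - plba_accumulator(td, params$v[j], params$A[j], params$b, params$s))
    }
    out[ok] <- dens
  }
  if (renormalize) out <- out / lba_finish_probability(params)
  out
}

match_response <- function(response) {
  if (is.numeric(response)) {
    r <- as.integer(response)
  } else {
    r <- match(tolower(as.character(response)), RESPONSE_LEVELS)
  }
  if (any(is.na(r)) || any(r < 1L) || any(r > 3L))
    stop("`response` must be one of ", paste(RESPONSE_LEVELS, collapse = ", "))
  r
}

#' Joint log-likelihood of a set of trials
#'
#' Sum of per-trial log race densities. The model is deliberately blind to
#' the stimulus condition: drift means and start points vary per response
#' accumulator, not per trial type, so only the observed (response, RT)
#' pairs enter the likelihood.
#'
#' @param trials Data frame with columns `response` and `rt`; every row must
#'   carry a response and a positive RT.
#' @param params An [lba_parameters()] object.
#' @inheritParams dlba_race
#' @return Scalar log-likelihood; `-Inf` when any trial has zero likelihood
#'   (e.g. an RT at or below `tau`). No numerical flooring is applied: the
#'   objective reports impossibility honestly.
#' @export
lba_loglik <- function(trials, params, renormalize = FALSE) {
  if (NROW(trials) == 0L) stop("`trials` must contain at least one trial")
  resp <- match_response(trials$response)
  rt <- trials$rt
  if (any(is.na(resp)) || any(is.na(rt)))
    stop("all trials must have a response and an RT; drop missing rows first")
  t_dec <- rt - params$tau
  if (any(t_dec <= 0)) return(-Inf)
  # vectorized over trials: densities and survivals for all 3 accumulators,
  # sharing the normal CDF/PDF evaluations between the two
  n <- NROW(trials)
  dens <- matrix(0, n, 3L)
  surv <- matrix(0, n, 3L)
  b <- params$b
  s <- params$s
  ts <- t_dec * s
  for (j in 1:3) {
    A_eff <- min(params$A[j], b)
    vj <- params$v[j]
    if (A_eff < 1e-10) {
      z2 <- (b - t_dec * vj) / ts
      P2 <- pnorm(z2)
      dens[, j] <- dnorm(z2) * b / (s * t_dec^2)
      surv[, j] <- pmin(pmax(P2, 0), 1)
    } else {
      z1 <- (b - A_eff - t_dec * vj) / ts
      z2 <- (b - t_dec * vj) / ts
      P1 <- pnorm(z1); P2 <- pnorm(z2)
      D1 <- dnorm(z1); D2 <- dnorm(z2)
      dens[, j] <- pmax((-vj * P1 + s * D1 + vj * P2 - s * D2) / A_eff, 0)
      Fj <- 1 + (b - A_eff - t_dec * vj) / A_eff * P1 -
        (b - t_dec * vj) / A_eff * P2 + ts / A_eff * (D1 - D2)
      surv[, j] <- 1 - pmin(pmax(Fj, 0), 1)
    }
  }
  idx <- cbind(seq_len(NROW(trials)), resp)
  lik <- dens[idx]
  for (j in 1:3) {
    other <- resp != j
    lik[other] <- lik[other] * surv[other, j]
  }
  if (renormalize) lik <- lik / lba_finish_probability(params)
  if (any(lik <= 0)) return(-Inf)
  sum(log(lik))
}

#' Simulate trials from the three-accumulator race
#'
#' Draws, for each trial and accumulator, a start point uniform on
#' \eqn{[0, \min(A_r, b)]} and a drift rate \eqn{N(v_r, s)}; finishing time
#' is \eqn{(b - start)/drift} for positive drifts and infinite otherwise.
#' The accumulator with the smallest finishing time wins; the RT adds the
#' non-decision time.
#'
#' @param n Number of trials.
#' @param params An [lba_parameters()] object.
#' @param renormalize If `TRUE`, trials on which no accumulator finishes
#'   (all three drift draws negative) are redrawn, matching the
#'   renormalized likelihood; if `FALSE` (default, matching the defective
#'   likelihood) such trials are emitted with `NA` response and RT.
#' @return Data frame with columns `response` (character, or `NA`) and
#'   `rt` (seconds, or `NA`).
#' @export
rlba <- function(n, params, renormalize = FALSE) {
  stopifnot(n >= 1)
  A_eff <- pmin(params$A, params$b)
  draw <- function(m) {
    start <- matrix(runif(m * 3L), m, 3L) %*% diag(A_eff)
    drift <- matrix(rnorm(m * 3L, mean = rep(params$v, each = m),
                          sd = params$s), m, 3L)
    tt <- (params$b - start) / drift
    tt[drift <= 0] <- Inf
    winner <- max.col(-tt, ties.method = "first")  # argmin finishing time
    tmin <- tt[cbind(seq_len(m), winner)]
    list(winner = winner, tmin = tmin)
  }
  d <- draw(n)
  if (renormalize) {
    bad <- which(!is.finite(d$tmin))
    while (length(bad) > 0L) {
      rd <- draw(length(bad))
      d$winner[bad] <- rd$winner
      d$tmin[bad] <- rd$tmin
      bad <- bad[!is.finite(rd$tmin)]
    }
  }
  finished <- is.finite(d$tmin)
  data.frame(
    response = ifelse(finished, RESPONSE_LEVELS[d$winner], NA_character_),
    rt = ifelse(finished, d$tmin + params$tau, NA_real_),
    stringsAsFactors = FALSE)
}

#' Analytic choice probabilities of the race
#'
#' Integrates the race density of each response over decision time by
#' adaptive quadrature. Under the defective convention the three
#' probabilities sum to [lba_finish_probability()]; under renormalization
#' they sum to 1.
#'
#' @inheritParams dlba_race
#' @param upper Upper integration limit on the decision-time axis, seconds.
#' @return Named numeric 3-vector of choice probabilities.
#' @export
lba_choice_probabilities <- function(params, renormalize = FALSE,
                                     upper = Inf) {
  p <- vapply(1:3, function(r) {
    integrate(function(t)
      dlba_race(r, t + params$tau, params, renormalize = renormalize),
      lower = 1e-9, upper = upper, rel.tol = 1e-8,
      stop.on.error = FALSE)$value
  }, numeric(1))
  setNames(p, RESPONSE_LEVELS)
}
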