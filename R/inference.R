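#' Sampler and prior configuration for per-subject Bayesian fits
#'
#' Defaults follow the estimation setup used throughout the package: three
#' chains of 7000 iterations each with the first 3500 discarded as warmup,
#' weakly informative Normal priors — `Normal(0.5, 1)` on the boundary and
#' the non-decision time (both truncated to their supports) and
#' `Normal(0.5, 0.5)` element-wise on the simplex coordinates of the
#' drift-rate means and start-point upper bounds — and a convergence gate of
#' split-chain Rhat below 1.01 on every parameter.
#'
#' @param n_chains Number of MCMC chains.
#' @param n_iterations Total iterations per chain (including warmup).
#' @param n_warmup Warmup iterations discarded per chain.
#' @param prior_boundary,prior_ndt Length-2 vectors `(location, scale)` of
#'   the truncated-Normal priors on `b` and `tau`.
#' @param prior_drift_mean,prior_start_upper Length-2 vectors
#'   `(location, scale)` of the element-wise Normal priors applied to the
#'   simplex components of `v` and `A`.
#' @param rhat_threshold Convergence gate: every parameter's split-chain
#'   Rhat must fall below this for `converged = TRUE`.
#' @param seed Integer seed; fits are bit-reproducible given the seed.
#' @param renormalize Passed to [lba_loglik()]: condition the likelihood on
#'   at least one accumulator finishing.
#' @return A list of class `lba_fit_config`.
#' @export
fit_config <- function(n_chains = 3L, n_iterations = 7000L, n_warmup = 3500L,
                       prior_boundary = c(0.5, 1), prior_ndt = c(0.5, 1),
                       prior_drift_mean = c(0.5, 0.5),
                       prior_start_upper = c(0.5, 0.5),
                       rhat_threshold = 1.01, seed = 1L,
                       renormalize = FALSE) {
  stopifnot(n_chains >= 1L, n_warmup < n_iterations,
            prior_boundary[2] > 0, prior_ndt[2] > 0,
            prior_drift_mean[2] > 0, prior_start_upper[2] > 0)
  structure(list(n_chains = as.integer(n_chains),
                 n_iterations = as.integer(n_iterations),
                 n_warmup = as.integer(n_warmup),
                 prior_boundary = prior_boundary, prior_ndt = prior_ndt,
                 prior_drift_mean = prior_drift_mean,
                 prior_start_upper = prior_start_upper,
                 rhat_threshold = rhat_threshold, seed = as.integer(seed),
                 renormalize = isTRUE(renormalize)),
            class = "lba_fit_config")
}

PARAM_NAMES <- c("v_repeat", "v_lure", "v_foil",
                 "A_repeat", "A_lure", "A_foil", "b", "tau")

# Unconstrained parameterization: theta = (y_v[1:2], y_A[1:2], log b, y_tau)
# with tau = tau_max * plogis(y_tau); tau_max is the subject's minimum RT,
# since any larger tau has zero likelihood.
theta_to_params <- function(theta, tau_max) {
  lba_parameters(v = simplex_forward(theta[1:2]),
                 A = simplex_forward(theta[3:4]),
                 b = exp(theta[5]),
                 tau = tau_max * plogis(theta[6]))
}

params_to_theta <- function(params, tau_max) {
  c(simplex_inverse(unname(params$v)),
    simplex_inverse(unname(params$A)),
    log(params$b),
    qlogis(min(max(params$tau / tau_max, 1e-6), 1 - 1e-6)))
}

validate_fit_trials <- function(trials, min_trials = 20L) {
  trials <- trials[!is.na(trials$response) & !is.na(trials$rt), , drop = FALSE]
  if (NROW(trials) < min_trials)
    stop("need at least ", min_trials, " responded trials to fit; got ",
         NROW(trials))
  if (any(trials$rt <= 0)) stop("all RTs must be positive")
  if (max(trials$rt) <= 0.05)
    stop("all RTs are at or below 50 ms; no non-decision time is ",
         "compatible with such data (check the RT unit)")
  trials
}

# Heuristic starting parameters: response proportions seed the simplexes.
mle_start <- function(trials) {
  prop <- table(factor(trials$response, levels = RESPONSE_LEVELS))
  prop <- pmax(as.numeric(prop) / sum(prop), 0.05)
  prop <- prop / sum(prop)
  lba_parameters(v = prop, A = prop, b = 0.8,
                 tau = 0.5 * min(trials$rt))
}

#' Maximum-likelihood estimation of subject-level LBA parameters
#'
#' Multi-start local optimization of [lba_loglik()] on the unconstrained
#' transform of the parameter space (stick-breaking coordinates for the two
#' simplexes, log boundary, logit-scaled non-decision time bounded above by
#' the subject's minimum RT). Intended for recovery studies and fast
#' pipeline runs; [fit_lba_bayes()] is the full estimator.
#'
#' @param trials Data frame of one subject's trials with `response`, `rt`;
#'   rows with missing responses are dropped. At least 20 responded trials.
#' @param renormalize Passed to [lba_loglik()].
#' @param n_restarts Number of random restarts around the heuristic start.
#' @param seed Integer seed for restart jitter.
#' @return A list of class `lba_mle` with elements `params`
#'   ([lba_parameters()]), `loglik`, `n_trials`, `convergence_codes`.
#' @export
fit_lba_mle <- function(trials, renormalize = FALSE, n_restarts = 4L,
                        seed = 1L) {
  trials <- validate_fit_trials(trials)
  tau_max <- min(trials$rt)
  negll <- function(theta) {
    p <- try(theta_to_params(theta, tau_max), silent = TRUE)
    if (inherits(p, "try-error")) return(1e10)
    ll <- lba_loglik(trials, p, renormalize = renormalize)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  set.seed(seed)
  theta0 <- params_to_theta(mle_start(trials), tau_max)
  starts <- lapply(seq_len(n_restarts), function(i) {
    if (i == 1L) theta0 else theta0 + rnorm(6, sd = 0.5)
  })
  best <- NULL
  codes <- integer(0)
  for (st in starts) {
    fit <- try(optim(st, negll, method = "Nelder-Mead",
                     control = list(maxit = 500, reltol = 1e-8)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    codes <- c(codes, fit$convergence)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best) || best$value >= 1e10)
    stop("all optimization restarts failed; check the data scale")
  polish <- try(optim(best$par, negll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10)),
                silent = TRUE)
  if (!inherits(polish, "try-error") && polish$value <= best$value)
    best <- polish
  structure(list(params = theta_to_params(best$par, tau_max),
                 theta = best$par, tau_max = tau_max,
                 loglik = -best$value, n_trials = NROW(trials),
                 convergence_codes = codes),
            class = "lba_mle")
}

#' Bayesian estimation of subject-level LBA parameters
#'
#' Samples the posterior of the constrained three-accumulator LBA for one
#' subject with differential-evolution MCMC, the sampler family standard
#' for accumulator-model posteriors. Each reporting chain is an
#' interacting population of particles moving directly in the constrained
#' space (two free simplex coordinates each for `v` and `A`, `b`, `tau`);
#' proposals along the difference of two other randomly chosen particles
#' align themselves with correlated and ridge-shaped posteriors, and
#' simplex/positivity violations are simply rejected. A heavy-tailed
#' independence proposal — initialized from the curvature at the
#' maximum-likelihood estimate and re-estimated once from the warmup
#' population — decorrelates the particles wherever the posterior is
#' well-approximated. Non-convergence is reported via the `converged`
#' flag, not raised as an error.
#'
#' @param trials Data frame of one subject's trials (`response`, `rt`);
#'   at least 20 responded trials.
#' @param config An [fit_config()] object.
#' @return A list of class `lba_fit`: `draws` (array
#'   post-warmup-iterations x chains x 8 parameters on the constrained
#'   scale), `summary` (data frame of mean/median/2.5%/97.5%/Rhat/ESS per
#'   parameter), `rhat`, `ess`, `converged`, `accept_rate`, `config`.
#' @export
fit_lba_bayes <- function(trials, config = fit_config()) {
  trials <- validate_fit_trials(trials)
  tau_max <- min(trials$rt)
  set.seed(config$seed)
  # The sampler works directly on the constrained coordinates
  # theta_c = (v1, v2, A1, A2, b, tau) with v3 = 1 - v1 - v2 and
  # A3 = 1 - A1 - A2. The simplex carries a uniform base measure, so the
  # element-wise Normal priors need no Jacobian, and the posterior near a
  # boundary stays a bounded, well-scaled density (the logit stretch of an
  # unconstrained parameterization would turn it into an infinite tail).
  cpar <- function(theta_c) {
    lba_parameters(v = c(theta_c[1], theta_c[2], 1 - theta_c[1] - theta_c[2]),
                   A = c(theta_c[3], theta_c[4], 1 - theta_c[3] - theta_c[4]),
                   b = theta_c[5], tau = theta_c[6])
  }
  in_support <- function(theta_c) {
    all(is.finite(theta_c)) &&
      theta_c[1] > 0 && theta_c[2] > 0 && theta_c[1] + theta_c[2] < 1 &&
      theta_c[3] > 0 && theta_c[4] > 0 && theta_c[3] + theta_c[4] < 1 &&
      theta_c[5] > 0 && theta_c[6] >= 0 && theta_c[6] < tau_max
  }
  log_post <- function(theta_c) {
    if (!in_support(theta_c)) return(-Inf)
    p <- cpar(theta_c)
    ll <- lba_loglik(trials, p, renormalize = config$renormalize)
    if (!is.finite(ll)) return(-Inf)
    v <- c(theta_c[1], theta_c[2], 1 - theta_c[1] - theta_c[2])
    A <- c(theta_c[3], theta_c[4], 1 - theta_c[3] - theta_c[4])
    ll +
      sum(dnorm(v, config$prior_drift_mean[1], config$prior_drift_mean[2],
                log = TRUE)) +
      sum(dnorm(A, config$prior_start_upper[1], config$prior_start_upper[2],
                log = TRUE)) +
      dnorm(theta_c[5], config$prior_boundary[1], config$prior_boundary[2],
            log = TRUE) +
      dnorm(theta_c[6], config$prior_ndt[1], config$prior_ndt[2],
            log = TRUE)
  }
  mle <- fit_lba_mle(trials, renormalize = config$renormalize,
                     n_restarts = 2L, seed = config$seed)
  # nudge a boundary MLE into the interior for initialization/curvature
  nudge <- function(x2) {
    x2 <- pmax(x2, 0.01)
    excess <- sum(x2) - 0.98
    if (excess > 0) x2 <- x2 * 0.98 / sum(x2)
    x2
  }
  center <- c(nudge(unname(mle$params$v[1:2])),
              nudge(unname(mle$params$A[1:2])),
              mle$params$b,
              min(max(mle$params$tau, 0.01 * tau_max), 0.97 * tau_max))
  prop_cov <- diag(c(rep(4e-3, 4), 4e-3, 1e-3))
  H <- try(optimHess(center, function(th) -log_post(th)), silent = TRUE)
  if (!inherits(H, "try-error")) {
    cv <- try(solve(H), silent = TRUE)
    if (!inherits(cv, "try-error") &&
        all(is.finite(cv)) && all(eigen(cv, TRUE, TRUE)$values > 0))
      prop_cov <- cv
  }
  # Differential-evolution MCMC (the standard sampler family for LBA-type
  # posteriors): each reporting chain is an interacting population of
  # particles; a particle's proposal moves along the difference of two
  # other randomly chosen particles, so the proposal distribution aligns
  # itself with ridge-shaped and correlated posteriors automatically.
  n_keep <- config$n_iterations - config$n_warmup
  n_part <- 12L
  t_keep <- max(2L, ceiling(n_keep / n_part))
  t_warm <- max(2L, ceiling(config$n_warmup / n_part))
  gamma0 <- 2.38 / sqrt(2 * 6)
  prop_chol <- chol(prop_cov)
  # Independence component: heavy-tailed (t, df = 4) proposal, started
  # from the Laplace approximation at the mode and re-estimated from the
  # warmup population before sampling begins (the interacting particles
  # explore tails and ridges the local curvature misses). Wherever the
  # proposal matches the posterior these moves decorrelate the particles
  # almost instantly; elsewhere they are rejected and the
  # differential-evolution moves do the work.
  ind_df <- 4
  p_ind <- 0.3
  draws <- array(NA_real_,
                 dim = c(n_keep, config$n_chains, length(PARAM_NAMES)),
                 dimnames = list(NULL, NULL, PARAM_NAMES))
  accept <- numeric(config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    # Overdispersed initialization: half the population carries
    # curvature-shaped heavy-tailed jitter around the mode, the other
    # half spreads the simplex coordinates broadly so the difference
    # vectors span any likelihood ridge from the start.
    part <- matrix(NA_real_, n_part, 6L)
    lp <- numeric(n_part)
    for (i in seq_len(n_part)) {
      lpc <- -Inf
      for (try_k in 1:50) {
        u <- rnorm(6) / sqrt(rchisq(1, 4) / 4)
        cand <- center + drop(u %*% prop_chol)
        if (i %% 2L == 0L) {
          gv <- rgamma(3, 1)
          gA <- rgamma(3, 1)
          cand[1:4] <- c((gv / sum(gv))[1:2], (gA / sum(gA))[1:2])
          cand[6] <- runif(1, 0, tau_max)
        }
        lpc <- log_post(cand)
        if (is.finite(lpc)) break
      }
      if (!is.finite(lpc)) {
        cand <- center
        lpc <- log_post(cand)
      }
      part[i, ] <- cand
      lp[i] <- lpc
    }
    ind_center <- center
    ind_chol <- chol(prop_cov * 1.5)
    ind_logdet <- sum(log(diag(ind_chol)))
    log_q_ind <- function(th) {
      u <- backsolve(ind_chol, th - ind_center, transpose = TRUE)
      -0.5 * (ind_df + 6) * log1p(sum(u^2) / ind_df) - ind_logdet
    }
    r_ind <- function() {
      u <- rnorm(6) / sqrt(rchisq(1, ind_df) / ind_df)
      ind_center + drop(u %*% ind_chol)
    }
    n_acc <- 0L
    n_prop <- 0L
    keep_buf <- array(NA_real_, dim = c(t_keep, n_part, 6L))
    warm_buf <- array(NA_real_, dim = c(t_warm, n_part, 6L))
    for (it in seq_len(t_warm + t_keep)) {
      for (i in seq_len(n_part)) {
        kind <- runif(1)
        if (kind < 0.08) {
          # single-coordinate uniform refresh: teleports across the flat
          # likelihood shelves that arise when A_r exceeds b (the start
          # truncation makes the likelihood insensitive to A_r there)
          k <- sample.int(6L, 1L)
          prop <- part[i, ]
          lim <- switch(k,
                        1 - prop[2], 1 - prop[1],
                        1 - prop[4], 1 - prop[3],
                        5, tau_max)
          prop[k] <- runif(1, 0, lim)
          if (k == 5L && part[i, 5] > 5) {
            lp_prop <- -Inf             # outside the refresh window
          } else {
            lp_prop <- log_post(prop)
          }
          log_ratio <- lp_prop - lp[i]
        } else if (kind < 0.08 + p_ind) {
          prop <- r_ind()
          lp_prop <- log_post(prop)
          log_ratio <- lp_prop - lp[i] -
            log_q_ind(prop) + log_q_ind(part[i, ])
        } else {
          jk <- sample(seq_len(n_part)[-i], 2L)
          # occasional gamma = 1 moves allow jumps between posterior lobes
          g <- if (runif(1) < 0.1) 1 else gamma0 * exp(runif(1, -0.5, 0.5))
          prop <- part[i, ] + g * (part[jk[1], ] - part[jk[2], ]) +
            rnorm(6, sd = 1e-3)
          lp_prop <- log_post(prop)
          log_ratio <- lp_prop - lp[i]
        }
        if (is.finite(lp_prop) && log(runif(1)) < log_ratio) {
          part[i, ] <- prop
          lp[i] <- lp_prop
          if (it > t_warm) n_acc <- n_acc + 1L
        }
        if (it > t_warm) n_prop <- n_prop + 1L
      }
      if (it <= t_warm && it %% 20L == 0L) {
        # purge stuck outlier particles during warmup only
        good <- which(lp >= max(lp) - 30)
        for (i in which(lp < max(lp) - 30)) {
          donor <- if (length(good) == 1L) good else sample(good, 1L)
          part[i, ] <- part[donor, ] + rnorm(6, sd = 1e-3)
          lp[i] <- log_post(part[i, ])
        }
      }
      if (it <= t_warm) {
        warm_buf[it, , ] <- part
        if (it == t_warm) {
          # freeze an independence proposal shaped like the posterior as
          # the warmup population saw it
          half <- warm_buf[seq(max(1L, floor(t_warm / 2)), t_warm), , ,
                           drop = FALSE]
          pool <- matrix(half, ncol = 6L)
          emp <- 0.85 * var(pool) + 0.15 * prop_cov + diag(1e-8, 6)
          ec <- try(chol(emp * 1.5), silent = TRUE)
          if (!inherits(ec, "try-error")) {
            ind_center <- colMeans(pool)
            ind_chol <- ec
            ind_logdet <- sum(log(diag(ind_chol)))
          }
        }
      } else {
        keep_buf[it - t_warm, , ] <- part
      }
    }
    # particle-major ordering keeps the autocorrelation structure of each
    # particle's trajectory visible to the ESS estimator
    flat <- do.call(rbind, lapply(seq_len(n_part), function(i)
      keep_buf[, i, ]))[seq_len(n_keep), , drop = FALSE]
    draws[, ch, ] <- cbind(flat[, 1], flat[, 2],
                           1 - flat[, 1] - flat[, 2],
                           flat[, 3], flat[, 4],
                           1 - flat[, 3] - flat[, 4],
                           flat[, 5], flat[, 6])
    accept[ch] <- n_acc / n_prop
  }
  rhat <- apply(draws, 3, function(m) compute_rhat(m))
  ess <- apply(draws, 3, function(m) compute_ess(m))
  summ <- data.frame(
    parameter = PARAM_NAMES,
    mean = apply(draws, 3, mean),
    median = apply(draws, 3, median),
    q2.5 = apply(draws, 3, quantile, probs = 0.025),
    q97.5 = apply(draws, 3, quantile, probs = 0.975),
    rhat = rhat, ess = ess, row.names = NULL)
  structure(list(draws = draws, summary = summ, rhat = rhat, ess = ess,
                 converged = all(rhat < config$rhat_threshold),
                 accept_rate = accept, tau_max = tau_max,
                 n_trials = NROW(trials), config = config),
            class = "lba_fit")
}

#' @export
print.lba_fit <- function(x, ...) {
  cat(sprintf("Bayesian LBA fit: %d trials, %d chains x %d kept draws\n",
              x$n_trials, dim(x$draws)[2], dim(x$draws)[1]))
  cat(sprintf("converged (all Rhat < %.2f): %s\n",
              x$config$rhat_threshold, x$converged))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Split-chain potential scale reduction statistic (Rhat)
#'
#' Each chain is split in half and the classical between/within variance
#' ratio is computed over the resulting half-chains, so that trending
#' single chains are also detected.
#'
#' @param draws Matrix of posterior draws, iterations x chains (at least 2
#'   chains, at least 4 draws each).
#' @return Scalar Rhat; 1 up to floating-point error for well-mixed chains.
#' @export
compute_rhat <- function(draws) {
  draws <- as.matrix(draws)
  if (ncol(draws) < 2L) stop("Rhat requires at least 2 chains")
  if (nrow(draws) < 4L) stop("Rhat requires at least 4 draws per chain")
  half <- floor(nrow(draws) / 2)
  split <- do.call(cbind, lapply(seq_len(ncol(draws)), function(j)
    cbind(draws[seq_len(half), j],
          draws[(nrow(draws) - half + 1):nrow(draws), j])))
  n <- nrow(split)
  m <- ncol(split)
  chain_means <- colMeans(split)
  W <- mean(apply(split, 2, var))
  B <- n * var(chain_means)
  if (W == 0) return(if (B == 0) 1 else Inf)
  var_plus <- (n - 1) / n * W + B / n
  sqrt(var_plus / W)
}

#' Effective sample size across chains
#'
#' Autocorrelation-based ESS: per-chain autocorrelations are averaged,
#' summed with Geyer's initial-positive-sequence truncation, and the total
#' draw count is deflated accordingly.
#'
#' @inheritParams compute_rhat
#' @return Scalar effective sample size.
#' @export
compute_ess <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  m <- ncol(draws)
  if (n < 4L) stop("ESS requires at least 4 draws per chain")
  max_lag <- min(n - 1L, 500L)
  rho <- rowMeans(vapply(seq_len(m), function(j)
    drop(acf(draws[, j], lag.max = max_lag, plot = FALSE,
             demean = TRUE)$acf), numeric(max_lag + 1L)))
  # Geyer initial positive sequence on paired autocorrelations
  s <- 0
  t <- 1L
  while (t + 1L <= max_lag) {
    pair <- rho[t + 1L] + rho[t + 2L]
    if (!is.finite(pair) || pair < 0) break
    s <- s + pair
    t <- t + 2L
  }
  ess <- m * n / (1 + 2 * s)
  min(ess, m * n)
}
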