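test_that("parameter constructor enforces the simplex and positivity", {
  expect_s3_class(typical_params(), "lba_parameters")
  expect_error(lba_parameters(c(0.5, 0.3, 0.3), c(0.4, 0.3, 0.3), 1, 0.3),
               "sum to 1")
  expect_error(lba_parameters(c(0.5, 0.5, 0), c(0.4, 0.3, 0.3), 1, 0.3),
               "positive")
  expect_error(lba_parameters(c(0.5, 0.3, 0.2), c(0.4, 0.3, 0.3), -1, 0.3),
               "boundary")
  expect_error(lba_parameters(c(0.5, 0.3, 0.2), c(0.4, 0.3, 0.3), 1, -0.1),
               "tau")
})

test_that("accumulator CDF has the right limits and monotonicity", {
  expect_equal(plba_accumulator(1e-12, 0.47, 0.49, 0.8), 0)
  # deterministic positive drift always crosses
  expect_equal(plba_accumulator(1e6, 0.5, 0.3, 0.8, s = 1e-9), 1)
  # defective limit: crossing probability tends to P(drift > 0)
  expect_equal(plba_accumulator(1e7, 0.47, 0.49, 0.8), pnorm(0.47),
               tolerance = 1e-6)
  tg <- seq(0.05, 5, length.out = 120)
  p <- plba_accumulator(tg, 0.47, 0.49, 0.8)
  expect_true(all(diff(p) >= -1e-12))
  expect_true(all(p >= 0 & p < 1))
  expect_error(plba_accumulator(-1, 0.47, 0.49, 0.8), "positive")
  expect_error(plba_accumulator(1, 0.47, 0.49, -0.8), "boundary")
})

test_that("accumulator CDF matches a brute-force path simulation", {
  # start ~ U[0, 0.49], drift ~ N(0.47, 1), boundary 0.8, horizon t = 1
  set.seed(101)
  n <- 1e6
  start <- runif(n, 0, 0.49)
  drift <- rnorm(n, 0.47, 1)
  tt <- (0.8 - start) / drift
  tt[drift <= 0] <- Inf
  emp <- mean(tt <= 1.0)
  mc_se <- sqrt(emp * (1 - emp) / n)
  expect_equal(plba_accumulator(1.0, 0.47, 0.49, 0.8), emp,
               tolerance = 3 * mc_se / emp)
})

test_that("accumulator PDF is the derivative of the CDF", {
  for (pars in list(c(0.47, 0.49, 0.8), c(0.23, 0.12, 1.2),
                    c(0.9, 0.7, 0.5))) {
    tg <- seq(0.1, 4, length.out = 60)
    h <- 1e-6
    fd <- (plba_accumulator(tg + h, pars[1], pars[2], pars[3]) -
             plba_accumulator(tg - h, pars[1], pars[2], pars[3])) / (2 * h)
    expect_equal(dlba_accumulator(tg, pars[1], pars[2], pars[3]), fd,
                 tolerance = 1e-4)
  }
  # cannot finish instantly from below the boundary
  expect_equal(dlba_accumulator(1e-9, 0.47, 0.49, 0.8), 0)
  # density integrates to its CDF
  q <- integrate(dlba_accumulator, 0, 5, v = 0.47, A = 0.49, b = 0.8)
  expect_equal(q$value, plba_accumulator(5, 0.47, 0.49, 0.8),
               tolerance = 1e-6)
})

test_that("start-point truncation caps the start below the boundary", {
  # with A > b the start is uniform on [0, b]; compare with a simulation
  set.seed(11)
  n <- 5e5
  start <- runif(n, 0, 0.6)            # min(A = 0.9, b = 0.6)
  drift <- rnorm(n, 0.5, 1)
  tt <- (0.6 - start) / drift
  tt[drift <= 0] <- Inf
  emp <- mean(tt <= 0.8)
  expect_equal(plba_accumulator(0.8, 0.5, 0.9, 0.6), emp,
               tolerance = 3 * sqrt(emp * (1 - emp) / n) / emp)
})

test_that("race likelihood is zero at or before the non-decision time", {
  p <- typical_params()                 # tau = 0.5
  expect_equal(dlba_race("repeat", 0.3, p), 0)
  expect_equal(dlba_race("lure", 0.5, p), 0)
  expect_gt(dlba_race("repeat", 1.0, p), 0)
})

test_that("race densities integrate to the defective total mass", {
  set.seed(202)
  for (i in 1:5) {
    p <- random_params()
    total <- sum(lba_choice_probabilities(p))
    expect_equal(total, lba_finish_probability(p), tolerance = 1e-3)
    expect_equal(sum(lba_choice_probabilities(p, renormalize = TRUE)), 1,
                 tolerance = 1e-3)
  }
})

test_that("dataset log-likelihood composes per-trial race densities", {
  p <- typical_params()
  trials <- simulated_trials(p, n = 10, seed = 3)
  ll <- lba_loglik(trials, p)
  by_hand <- sum(log(mapply(function(r, t) dlba_race(r, t, p),
                            trials$response, trials$rt)))
  expect_equal(ll, by_hand, tolerance = 1e-10)
  # order invariance
  expect_equal(lba_loglik(trials[sample(10), ], p), ll)
  # a single impossible trial makes the whole dataset impossible
  trials$rt[1] <- 0.2                   # below tau = 0.5
  expect_equal(lba_loglik(trials, p), -Inf)
  expect_error(lba_loglik(trials[0, ], p), "at least one")
})

test_that("simulator respects the model's deterministic limits", {
  # near-zero drift noise and near-degenerate start: repeat always wins
  # with rt = b / v_repeat + tau
  eps <- 1e-4
  p <- lba_parameters(v = c(1 - 2 * eps, eps, eps),
                      A = c(1, 1, 1) / 3, b = 0.8, tau = 0.5, s = 1e-9)
  p$A <- setNames(rep(1e-12, 3), names(p$A))  # pin starts at 0 for the limit
  set.seed(5)
  sim <- rlba(200, p)
  expect_true(all(sim$response == "repeat"))
  expect_equal(sim$rt, rep(0.8 / (1 - 2 * eps) + 0.5, 200),
               tolerance = 1e-3)
  # rt always exceeds tau
  set.seed(6)
  sim2 <- rlba(5000, typical_params(), renormalize = TRUE)
  expect_true(all(sim2$rt > 0.5))
})

test_that("simulated choice and RT distributions match the analytic race", {
  set.seed(303)
  n <- 1e5
  for (rep in 1:3) {
    p <- random_params()
    sim <- rlba(n, p, renormalize = FALSE)
    p_fin <- lba_finish_probability(p)
    cp <- lba_choice_probabilities(p)
    expect_lt(abs(mean(is.na(sim$response)) - (1 - p_fin)), 0.01)
    for (r in 1:3) {
      emp <- sum(sim$response == RESPONSE_LEVELS_TEST[r], na.rm = TRUE) / n
      se <- sqrt(max(cp[r] * (1 - cp[r]), 1e-12) / n)
      expect_lt(abs(emp - cp[r]), 3 * se + 1e-4)
    }
    # per-response RT CDF: Kolmogorov distance below 4 / sqrt(n_r)
    for (r in 1:3) {
      rts <- sim$rt[!is.na(sim$response) &
                      sim$response == RESPONSE_LEVELS_TEST[r]]
      if (length(rts) < 100) next
      grid <- quantile(rts, seq(0.05, 0.95, by = 0.1), names = FALSE)
      ana <- vapply(grid, function(g)
        integrate(function(t) dlba_race(r, t, p), lower = p$tau + 1e-9,
                  upper = g, rel.tol = 1e-7)$value, numeric(1)) / cp[r]
      emp_cdf <- ecdf(rts)(grid)
      expect_lt(max(abs(emp_cdf - ana)), 4 / sqrt(length(rts)))
    }
  }
})

test_that("renormalized simulator and likelihood stay consistent", {
  set.seed(404)
  p <- lba_parameters(v = c(0.2, 0.3, 0.5), A = c(0.3, 0.3, 0.4),
                      b = 1.2, tau = 0.3)
  sim <- rlba(5e4, p, renormalize = TRUE)
  expect_true(all(!is.na(sim$response)))
  cp <- lba_choice_probabilities(p, renormalize = TRUE)
  for (r in 1:3) {
    emp <- mean(sim$response == RESPONSE_LEVELS_TEST[r])
    expect_lt(abs(emp - cp[r]), 3 * sqrt(cp[r] * (1 - cp[r]) / 5e4) + 1e-4)
  }
})

test_that("the constrained parameterization leaves no scale freedom", {
  # multiplying boundary and start bounds by a common factor (the gauge
  # the simplex constraints remove) changes the likelihood: the gradient
  # along that direction is nonzero at random points
  set.seed(55)
  p <- typical_params()
  trials <- simulated_trials(p, n = 50, seed = 8)
  ll0 <- lba_loglik(trials, p)
  scaled <- p
  scaled$b <- p$b * 1.05
  expect_gt(abs(lba_loglik(trials, scaled) - ll0), 1e-6)
})
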