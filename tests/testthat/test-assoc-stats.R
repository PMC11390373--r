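test_that("Kendall tau equals the brute-force tau-b count", {
  set.seed(11)
  for (i in 1:5) {
    n <- sample(10:50, 1)
    x <- rnorm(n)
    y <- 0.4 * x + rnorm(n)
    if (i >= 4) {                        # force ties
      x <- round(x, 1)
      y <- round(y, 1)
    }
    res <- kendall_tau(x, y)
    expect_equal(res$tau, brute_force_tau(x, y), tolerance = 1e-12)
    expect_equal(res$n, n)
  }
  x <- 1:15
  expect_equal(kendall_tau(x, x)$tau, 1)
  expect_equal(kendall_tau(x, -x)$tau, -1)
  expect_error(kendall_tau(x, rep(2, 15)), "constant")
  expect_error(kendall_tau(1:2, 2:1), "at least 3")
})

test_that("Kendall tau is invariant under strictly monotone transforms", {
  set.seed(12)
  x <- rnorm(20)
  y <- rnorm(20)
  t0 <- kendall_tau(x, y)$tau
  expect_equal(kendall_tau(exp(x), y)$tau, t0)
  expect_equal(kendall_tau(x, y^3 + 5 * y)$tau, t0)
  expect_equal(kendall_tau(rank(x), y)$tau, t0)
})

test_that("Holm adjustment matches the step-down definition", {
  expect_equal(holm_adjust(0.03), 0.03)
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  # independent implementation of the step-down definition
  holm_by_hand <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- pmin((m - seq_len(m) + 1) * p[o], 1)
    adj <- cummax(adj)
    out <- numeric(m)
    out[o] <- adj
    out
  }
  set.seed(13)
  for (i in 1:5) {
    p <- runif(8)
    adj <- holm_adjust(p)
    expect_equal(adj, holm_by_hand(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    expect_equal(order(adj[order(p)]), seq_along(p))  # order-preserving
  }
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("measure-family correlations carry Holm-adjusted p-values", {
  set.seed(14)
  tab <- data.frame(ldi = rnorm(40))
  for (nm in c("v_repeat", "v_lure", "b", "tau"))
    tab[[nm]] <- 0.3 * tab$ldi + rnorm(40)
  res <- correlate_measures(tab, "ldi", c("v_repeat", "v_lure", "b", "tau"))
  expect_equal(nrow(res), 4L)
  expect_true(all(res$p_adjusted >= res$p_value))
  expect_equal(res$p_adjusted, holm_adjust(res$p_value))
})

test_that("bootstrap tau-difference CI behaves under identity and nulls", {
  set.seed(15)
  x <- rnorm(30)
  yA <- 0.5 * x + rnorm(30)
  # identical competitors: interval must contain 0
  ci <- bootstrap_tau_difference(x, yA, yA, n_boot = 400, seed = 2)
  expect_lte(ci$lower, 0)
  expect_gte(ci$upper, 0)
  expect_false(ci$excludes_zero)
  expect_equal(ci$difference, 0)
  # determinism
  yB <- rnorm(30)
  c1 <- bootstrap_tau_difference(x, yA, yB, n_boot = 300, seed = 9)
  c2 <- bootstrap_tau_difference(x, yA, yB, n_boot = 300, seed = 9)
  expect_identical(c1, c2)
  expect_lte(c1$lower, c1$upper)
  # BCa variant returns a valid interval too
  c3 <- bootstrap_tau_difference(x, yA, yB, n_boot = 300, seed = 9,
                                 method = "bca")
  expect_lte(c3$lower, c3$upper)
})

test_that("a constructed correlation difference is detected", {
  # yA strongly tied to x, yB independent: CI should exclude zero
  set.seed(16)
  n <- 200
  x <- rnorm(n)
  yA <- x + 0.8 * rnorm(n)
  yB <- rnorm(n)
  hits <- 0L
  for (rep in 1:10) {
    set.seed(300 + rep)
    idx <- sample.int(n)                 # fresh subject labelling
    ci <- bootstrap_tau_difference(x[idx], yA[idx], yB[idx],
                                   n_boot = 400, seed = rep)
    if (ci$excludes_zero) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("Wilcoxon rank-sum matches the exhaustive permutation law", {
  a <- c(1.2, 3.1, 2.2, 5.0)
  b <- c(2.5, 4.4, 6.1, 7.0, 8.2)
  res <- wilcoxon_rank_sum(a, b)
  # exhaustive permutation distribution of the Mann-Whitney U
  pooled <- c(a, b)
  combs <- combn(9, 4)
  u_obs <- sum(rank(pooled)[1:4]) - 4 * 5 / 2
  u_all <- apply(combs, 2, function(ix)
    sum(rank(pooled)[ix]) - 4 * 5 / 2)
  p_exact <- mean(abs(u_all - 10) >= abs(u_obs - 10))  # center = n1*n2/2
  expect_equal(res$W, u_obs)
  expect_equal(res$p_value, p_exact, tolerance = 1e-12)
  # extremes
  sep <- wilcoxon_rank_sum(1:10, 101:110)
  expect_equal(sep$W, 0)
  expect_lt(sep$p_value, 0.001)
  same <- wilcoxon_rank_sum(1:10 + 0.5, 1:10 + 0.51)
  expect_gt(same$p_value, 0.6)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "nonempty")
})

test_that("test-retest report has the right identities and sign convention", {
  set.seed(17)
  s1 <- data.frame(subject = sprintf("S%02d", 1:25),
                   ldi = rnorm(25), b = rlnorm(25), tau = runif(25))
  # identical sessions
  rep0 <- test_retest_report(s1, s1)
  expect_true(all(rep0$tau == 1))
  expect_true(all(rep0$median_diff == 0))
  # session2 = session1 + constant: tau 1, median_diff = -constant
  s2 <- s1
  s2$ldi <- s1$ldi + 0.3
  rep1 <- test_retest_report(s1, s2, measures = "ldi")
  expect_equal(rep1$tau, 1)
  expect_equal(rep1$median_diff, -0.3)
  expect_error(test_retest_report(s1, data.frame(subject = "X", ldi = 1)),
               "overlap")
})

test_that("persistent parameters rank-correlate across sessions, redrawn ones do not", {
  # boundary and NDT held fixed within subject, drifts redrawn: the
  # stability report must rank b/tau above every drift
  cfg <- population_config(
    n_subjects = 60, seed = 18,
    retest_model = list(rho = c(v = 0, A = 0.3, b = 1, tau = 1)))
  truth <- sample_population(cfg)
  s1 <- truth[truth$session == "test1", ]
  s2 <- truth[truth$session == "test2", ]
  rep <- test_retest_report(s1, s2,
                            measures = c("v_repeat", "v_lure", "v_foil",
                                         "b", "tau"))
  stab <- setNames(rep$tau, rep$measure)
  expect_gt(min(stab[c("b", "tau")]), max(stab[c("v_repeat", "v_lure",
                                                 "v_foil")]))
  expect_equal(unname(stab[c("b", "tau")]), c(1, 1), tolerance = 1e-12)
})
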