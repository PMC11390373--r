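test_that("LDI has the forced arithmetic values", {
  # perfect discrimination
  perfect <- data.frame(trial_type = rep(c("lure", "foil"), each = 4),
                        response = c(rep("lure", 4), rep("foil", 4)))
  expect_equal(compute_ldi(perfect), 1)
  # equal conditional counts cancel exactly
  flat <- data.frame(trial_type = rep(c("lure", "foil"), each = 4),
                     response = rep(c("lure", "repeat"), 4))
  expect_equal(compute_ldi(flat), 0)
  # 6 lure trials with 4 lure responses; 6 foil with 1 lure response
  mixed <- data.frame(
    trial_type = rep(c("lure", "foil"), each = 6),
    response = c(rep("lure", 4), "repeat", "foil",
                 "lure", rep("foil", 5)))
  expect_equal(compute_ldi(mixed), 4 / 6 - 1 / 6)
  expect_error(compute_ldi(data.frame(trial_type = "repeat",
                                      response = "repeat")), "lure")
})

test_that("LDI ignores trial order, repeat trials, and missing responses", {
  set.seed(61)
  trials <- simulated_trials(typical_params(), n = 96, seed = 61)
  ldi <- compute_ldi(trials)
  expect_true(ldi >= -1 && ldi <= 1)
  expect_equal(compute_ldi(trials[sample(NROW(trials)), ]), ldi)
  expect_equal(compute_ldi(trials[trials$trial_type != "repeat", ]), ldi)
  # a missing response leaves only the denominators changed
  trials2 <- trials
  drop_row <- which(trials2$trial_type == "lure")[1]
  trials2$response[drop_row] <- NA
  trials2$rt[drop_row] <- NA
  expect_equal(compute_ldi(trials2), compute_ldi(
    trials[-drop_row, , drop = FALSE]))
})

test_that("behavioral summary matches hand computation on a fixture", {
  s <- summarize_behavior(hand_fixture())
  expect_equal(s$accuracy_repeat, 3 / 4)
  expect_equal(s$accuracy_lure, 2 / 4)
  expect_equal(s$accuracy_foil, 3 / 4)
  expect_equal(s$ldi, 2 / 4 - 1 / 4)
  expect_equal(s$median_rt_repeat, median(c(1.0, 1.2, 1.1, 1.3)))
  expect_equal(s$median_rt_lure, median(c(1.6, 1.5, 1.8)))
  expect_equal(s$median_rt_foil, median(c(1.4, 1.7, 1.2, 1.3, 1.25)))
  expect_equal(s$prop_repeat + s$prop_lure + s$prop_foil, 1)
  expect_equal(s$n_trials, 12L)
  expect_equal(s$n_missing, 0L)
})

test_that("summary handles perfect and degenerate response patterns", {
  allright <- data.frame(trial_type = rep(c("repeat", "lure", "foil"), 4),
                         response = rep(c("repeat", "lure", "foil"), 4),
                         rt = rep(1, 12))
  s <- summarize_behavior(allright)
  expect_equal(unlist(s[c("accuracy_repeat", "accuracy_lure",
                          "accuracy_foil")], use.names = FALSE),
               c(1, 1, 1))
  expect_equal(s$ldi, 1)
  onetype <- data.frame(trial_type = rep(c("repeat", "lure", "foil"), 2),
                        response = rep("repeat", 6), rt = rep(1, 6))
  s2 <- summarize_behavior(onetype)
  expect_equal(s2$prop_repeat, 1)
  expect_equal(s2$prop_lure, 0)
  expect_true(is.na(s2$median_rt_lure) && is.na(s2$median_rt_foil))
})

test_that("RT-binned choices conserve counts and find the modal response", {
  set.seed(71)
  n <- 300
  rt <- runif(n, 0.5, 2.5)
  resp <- ifelse(rt < median(rt), "repeat",
                 sample(c("lure", "foil"), n, replace = TRUE))
  trials <- data.frame(response = resp, rt = rt)
  for (scheme in c("equal_width", "quantile")) {
    prof <- rt_binned_choices(trials, n_bins = 15, scheme = scheme)
    expect_equal(sum(prof$counts), n)
    expect_equal(length(prof$bin_edges), 16L)
    expect_equal(nrow(prof$counts), 15L)
    # all fast responses are repeats, so early bins are modal-repeat
    early <- which(prof$bin_edges[-1] < median(rt))
    expect_true(all(prof$modal_response[early] == "repeat"))
  }
  expect_error(rt_binned_choices(trials[1:10, ]), "n_bins")
  tied <- data.frame(response = rep("foil", 40), rt = rep(1, 40))
  expect_error(rt_binned_choices(tied, scheme = "quantile"), "equal_width")
})

test_that("LBA populations answer fast with repeats, slow with foils", {
  # repeat accumulator with high drift and start bias finishes early;
  # foil responses dominate the slow tail
  set.seed(81)
  p <- lba_parameters(v = c(0.55, 0.15, 0.30), A = c(0.55, 0.15, 0.30),
                      b = 0.8, tau = 0.5)
  sim <- rlba(5000, p, renormalize = TRUE)
  prof <- rt_binned_choices(sim, n_bins = 15)
  occupied <- rowSums(prof$counts) > 0
  first_bins <- head(which(occupied), 2)
  expect_true(all(prof$modal_response[first_bins] == "repeat"))
  # foils overtake repeats among the slowest decisions
  slow <- sim$rt > quantile(sim$rt, 0.9)
  expect_gt(sum(sim$response[slow] == "foil"),
            sum(sim$response[slow] == "repeat"))
})

test_that("median (IQR) report tables format correctly by group", {
  tab <- data.frame(ldi = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6),
                    grp = rep(c("younger", "older"), each = 3))
  out <- median_iqr_table(tab, "ldi", by = "grp")
  expect_equal(out$ldi[out$group == "younger"], "0.20 (0.10)")
  expect_equal(out$ldi[out$group == "older"], "0.50 (0.10)")
  expect_equal(out$n, c(3L, 3L))
  whole <- median_iqr_table(tab, "ldi")
  expect_equal(whole$ldi, "0.35 (0.25)")
})

test_that("age dichotomization handles thresholds, ties, and bimodality", {
  expect_equal(assign_age_group(c(20, 21, 22, 65, 66), "two_means"),
               c("younger", "younger", "younger", "older", "older"))
  expect_equal(assign_age_group(c(39.9, 40, 40.1), "threshold"),
               c("younger", "older", "older"))
  expect_error(assign_age_group(rep(30, 5), "two_means"), "distinct")
  expect_error(assign_age_group(c(-1, 30), "threshold"), "non-negative")
  # bimodal lifespan sample: split point lands between the modes
  set.seed(91)
  ages <- c(rnorm(60, 23, 4), rnorm(40, 62, 6))
  grp <- assign_age_group(ages, "two_means")
  expect_true(all(grp[ages < 35] == "younger"))
  expect_true(all(grp[ages > 50] == "older"))
  # agrees with the threshold rule for this clean separation
  expect_equal(grp, assign_age_group(ages, "threshold", threshold = 40))
})
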