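# Shared fixtures: typical subject-level parameters and small datasets.

RESPONSE_LEVELS_TEST <- c("repeat", "lure", "foil")

typical_params <- function() {
  lba_parameters(v = c(0.47, 0.23, 0.30), A = c(0.49, 0.12, 0.39),
                 b = 0.8, tau = 0.5)
}

# Random valid parameter set drawn from broad ranges.
random_params <- function() {
  v <- rgamma(3, 2); v <- v / sum(v)
  A <- rgamma(3, 2); A <- A / sum(A)
  lba_parameters(v = v, A = A, b = runif(1, 0.4, 1.5),
                 tau = runif(1, 0.2, 0.8))
}

# Simulated single-subject trial set with balanced trial types.
simulated_trials <- function(params, n = 192, seed = 1,
                             renormalize = TRUE) {
  set.seed(seed)
  sim <- rlba(n, params, renormalize = renormalize)
  data.frame(subject = "S001",
             trial_index = seq_len(n),
             trial_type = sample(rep(c("repeat", "lure", "foil"),
                                     length.out = n)),
             response = sim$response, rt = sim$rt,
             stringsAsFactors = FALSE)
}

# Hand-built 12-trial fixture with known summary values.
hand_fixture <- function() {
  data.frame(
    subject = "S001",
    trial_type = c(rep("repeat", 4), rep("lure", 4), rep("foil", 4)),
    response   = c("repeat", "repeat", "foil", "repeat",
                   "lure", "lure", "repeat", "foil",
                   "foil", "foil", "lure", "foil"),
    rt = c(1.0, 1.2, 1.4, 1.1,
           1.6, 1.5, 1.3, 1.7,
           1.2, 1.3, 1.8, 1.25),
    stringsAsFactors = FALSE)
}

# Brute-force Kendall tau-b: O(n^2) concordant/discordant counting with
# tie corrections; the independent oracle for the package implementation.
brute_force_tau <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
      if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  tx <- sum(sapply(table(x), function(t) t * (t - 1) / 2))
  ty <- sum(sapply(table(y), function(t) t * (t - 1) / 2))
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}
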