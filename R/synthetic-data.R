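#' Configuration of a ground-truth-known synthetic MST population
#'
#' The generator emulates the statistical structure the pipeline assumes:
#' balanced Repeat/Lure/Foil trial types, 192 test trials per subject (108
#' in the shorter task variant), LBA-generated RTs with subject-level
#' parameter heterogeneity, an optional bimodal age structure with an
#' additive non-decision-time shift in the older group, optional two-session
#' retest structure with per-parameter within-subject persistence, and
#' optional connectivity matrices with designated edges coupled to a chosen
#' parameter.
#'
#' Population centers default to typical subject-level estimates for this
#' task: drift-rate means near (0.47, 0.23, 0.30) and start-point bounds
#' near (0.49, 0.12, 0.39) for (Repeat, Lure, Foil), boundary near 0.8 and
#' non-decision time near 0.55 s, which together place median RTs in the
#' empirically familiar 1-2 s range. Heterogeneity scales act on the
#' unconstrained (stick-breaking / log) coordinates.
#'
#' @param n_subjects Number of subjects.
#' @param n_trials Test trials per subject (default 192; the short variant
#'   uses 108).
#' @param ranges `"typical"` (default) centers the population on the
#'   subject-level estimates described above, emulating an empirical
#'   cohort; `"broad"` spreads subjects across the whole valid parameter
#'   space (uniform simplex center, roughly doubled heterogeneity), the
#'   appropriate design for parameter-recovery studies. Explicitly supplied
#'   centers/scales override either preset.
#' @param trial_type_mix Proportions of repeat/lure/foil trials (sum to 1).
#' @param drift_center,start_center Simplex centers of the drift means and
#'   start-point bounds.
#' @param drift_sd,start_sd Population SDs on the stick-breaking scale.
#' @param boundary_meanlog,boundary_sdlog Log-normal population parameters
#'   of the boundary.
#' @param ndt_meanlog,ndt_sdlog Log-normal population parameters of the
#'   non-decision time (seconds).
#' @param age_model `NULL`, or a list with elements `p_older` (mixture
#'   weight), `younger`/`older` (`c(mean, sd)` of age in years),
#'   `ndt_shift` (additive seconds added to the older group's
#'   non-decision time).
#' @param retest_model `NULL`, or a list with element `rho`: named vector
#'   with entries `v`, `A`, `b`, `tau` giving the within-subject
#'   correlation of each parameter block's unconstrained coordinates across
#'   the two sessions (1 = held fixed, 0 = redrawn).
#' @param connectivity_model `NULL`, or a list with `n_regions`,
#'   `edge` (length-2 integer vector naming the coupled region pair),
#'   `coupled_parameter` (a column of the truth table, e.g. `"v_lure"`),
#'   `coupling_strength`, `noise_sd`.
#' @param ldi_coupling `NULL` for the well-specified model, or a list with
#'   `strength` (how strongly the trial-type-conditioned response
#'   perturbation follows the coupled parameter), `parameter` (default
#'   `"v_lure"`), `base` (baseline probability of a forced lure response
#'   on lure and foil trials) and `gain` (maximal modulation). This is the
#'   misspecification mode: the fitted model is trial-type-blind, so the
#'   perturbation creates realistic between-subject LDI variation tied to
#'   a known parameter.
#' @param renormalize Passed to [rlba()]: redraw never-finishing trials
#'   instead of emitting missing responses.
#' @param seed Integer seed; everything downstream is reproducible from
#'   the configuration.
#' @return List of class `population_config`.
#' @export
population_config <- function(n_subjects = 40L, n_trials = 192L,
                              ranges = c("typical", "broad"),
                              trial_type_mix = c(1, 1, 1) / 3,
                              drift_center = NULL, start_center = NULL,
                              drift_sd = NULL, start_sd = NULL,
                              boundary_meanlog = NULL,
                              boundary_sdlog = NULL,
                              ndt_meanlog = NULL, ndt_sdlog = NULL,
                              age_model = NULL, retest_model = NULL,
                              connectivity_model = NULL,
                              ldi_coupling = NULL,
                              renormalize = FALSE, seed = 1L) {
  ranges <- match.arg(ranges)
  preset <- if (ranges == "typical") {
    list(drift_center = c(0.47, 0.23, 0.30),
         start_center = c(0.49, 0.12, 0.39),
         drift_sd = 0.4, start_sd = 0.4,
         boundary_meanlog = log(0.8), boundary_sdlog = 0.25,
         ndt_meanlog = log(0.55), ndt_sdlog = 0.2)
  } else {
    list(drift_center = c(1, 1, 1) / 3, start_center = c(1, 1, 1) / 3,
         drift_sd = 1.0, start_sd = 1.0,
         boundary_meanlog = log(0.8), boundary_sdlog = 0.35,
         ndt_meanlog = log(0.5), ndt_sdlog = 0.3)
  }
  if (is.null(drift_center)) drift_center <- preset$drift_center
  if (is.null(start_center)) start_center <- preset$start_center
  if (is.null(drift_sd)) drift_sd <- preset$drift_sd
  if (is.null(start_sd)) start_sd <- preset$start_sd
  if (is.null(boundary_meanlog)) boundary_meanlog <- preset$boundary_meanlog
  if (is.null(boundary_sdlog)) boundary_sdlog <- preset$boundary_sdlog
  if (is.null(ndt_meanlog)) ndt_meanlog <- preset$ndt_meanlog
  if (is.null(ndt_sdlog)) ndt_sdlog <- preset$ndt_sdlog
  stopifnot(n_subjects >= 1L, n_trials >= 3L,
            abs(sum(trial_type_mix) - 1) < 1e-8,
            drift_sd > 0, start_sd > 0, boundary_sdlog > 0, ndt_sdlog > 0)
  if (!is.null(connectivity_model)) {
    connectivity_model <- utils::modifyList(
      list(n_regions = 8L, edge = c(1L, 2L), coupled_parameter = "v_lure",
           coupling_strength = 0.6, noise_sd = 0.3), connectivity_model)
    if (connectivity_model$n_regions < 2L)
      stop("connectivity model needs at least 2 regions")
  }
  if (!is.null(ldi_coupling)) {
    ldi_coupling <- utils::modifyList(
      list(strength = 1, parameter = "v_lure", base = 0.3, gain = 0.25),
      ldi_coupling)
  }
  if (!is.null(age_model)) {
    age_model <- utils::modifyList(
      list(p_older = 0.45, younger = c(23, 3), older = c(65, 5),
           ndt_shift = 0.1), age_model)
  }
  if (!is.null(retest_model)) {
    retest_model <- utils::modifyList(
      list(rho = c(v = 0.5, A = 0.5, b = 0.9, tau = 0.9)), retest_model)
  }
  cfg <- as.list(environment())
  cfg$preset <- NULL
  structure(cfg, class = "population_config")
}

# Draw one session's unconstrained coordinates for all subjects.
draw_unconstrained <- function(config, n) {
  mu <- c(simplex_inverse(config$drift_center),
          simplex_inverse(config$start_center),
          config$boundary_meanlog, config$ndt_meanlog)
  sds <- c(rep(config$drift_sd, 2), rep(config$start_sd, 2),
           config$boundary_sdlog, config$ndt_sdlog)
  z <- matrix(rnorm(n * 6L), n, 6L)
  list(theta = sweep(sweep(z, 2, sds, `*`), 2, mu, `+`), z = z,
       mu = mu, sds = sds)
}

unconstrained_to_truth_row <- function(theta) {
  v <- simplex_forward(theta[1:2])
  A <- simplex_forward(theta[3:4])
  c(v_repeat = v[1], v_lure = v[2], v_foil = v[3],
    A_repeat = A[1], A_lure = A[2], A_foil = A[3],
    b = exp(theta[5]), tau = exp(theta[6]))
}

#' Sample a population of true subject-level parameters
#'
#' Draws per-subject parameters on unconstrained scales and maps them to
#' the constrained space; optionally attaches ages (with the older group's
#' non-decision-time shift) and a correlated second session.
#'
#' @param config A [population_config()] object.
#' @return Data frame of class `mst_truth`, one row per subject per
#'   session: `subject`, `session`, `v_*`, `A_*`, `b`, `tau`, and when the
#'   age model is active `age` and `age_group`.
#' @export
sample_population <- function(config) {
  stopifnot(inherits(config, "population_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  d1 <- draw_unconstrained(config, n)
  truth <- as.data.frame(t(apply(d1$theta, 1, unconstrained_to_truth_row)))
  truth <- cbind(data.frame(subject = sprintf("S%03d", seq_len(n)),
                            session = "test1", stringsAsFactors = FALSE),
                 truth)
  if (!is.null(config$age_model)) {
    am <- config$age_model
    older <- runif(n) < am$p_older
    age <- ifelse(older,
                  rnorm(n, am$older[1], am$older[2]),
                  rnorm(n, am$younger[1], am$younger[2]))
    truth$age <- pmax(round(age), 18)
    truth$age_group <- ifelse(older, "older", "younger")
    truth$tau <- truth$tau + ifelse(older, am$ndt_shift, 0)
  }
  if (!is.null(config$retest_model)) {
    rho <- config$retest_model$rho
    rho6 <- c(rep(rho[["v"]], 2), rep(rho[["A"]], 2),
              rho[["b"]], rho[["tau"]])
    z2 <- matrix(rnorm(n * 6L), n, 6L)
    z2 <- sweep(d1$z, 2, rho6, `*`) +
      sweep(z2, 2, sqrt(1 - rho6^2), `*`)
    theta2 <- sweep(sweep(z2, 2, d1$sds, `*`), 2, d1$mu, `+`)
    truth2 <- as.data.frame(t(apply(theta2, 1, unconstrained_to_truth_row)))
    truth2 <- cbind(data.frame(subject = truth$subject, session = "test2",
                               stringsAsFactors = FALSE), truth2)
    if (!is.null(config$age_model)) {
      truth2$age <- truth$age
      truth2$age_group <- truth$age_group
      truth2$tau <- truth2$tau +
        ifelse(truth$age_group == "older", config$age_model$ndt_shift, 0)
    }
    truth <- rbind(truth, truth2)
  }
  class(truth) <- c("mst_truth", class(truth))
  truth
}

#' Rebuild an [lba_parameters()] object from one truth-table row
#'
#' @param row One row of an `mst_truth` data frame (or any data frame with
#'   columns `v_repeat`, `v_lure`, `v_foil`, `A_repeat`, `A_lure`,
#'   `A_foil`, `b`, `tau`).
#' @return An [lba_parameters()] object.
#' @export
as_lba_parameters <- function(row) {
  lba_parameters(v = as.numeric(row[c("v_repeat", "v_lure", "v_foil")]),
                 A = as.numeric(row[c("A_repeat", "A_lure", "A_foil")]),
                 b = as.numeric(row[["b"]]), tau = as.numeric(row[["tau"]]))
}

truth_row_params <- as_lba_parameters

#' Generate test-phase trials for one subject
#'
#' Assigns balanced, shuffled trial types and simulates responses and RTs
#' from the subject's accumulator race. When the configuration's
#' `ldi_coupling` is active, the response is additionally perturbed
#' conditional on trial type: on lure trials a forced lure response occurs
#' with probability `base + gain * tanh(strength * zp)` and on foil trials
#' with probability `base - gain * tanh(strength * zp)`, where `zp` is the
#' subject's standardized coupled parameter (supplied via `z_couple`). At
#' zero coupling the two probabilities coincide, so the perturbation
#' cancels out of the LDI in expectation.
#'
#' @param params An [lba_parameters()] object (the subject's truth).
#' @param config A [population_config()] object.
#' @param z_couple Standardized coupled-parameter value for this subject
#'   (only used when `ldi_coupling` is set).
#' @return Data frame of trials: `trial_index`, `trial_type`, `response`,
#'   `rt`.
#' @export
generate_trials <- function(params, config, z_couple = 0) {
  n <- config$n_trials
  base_counts <- floor(n * config$trial_type_mix)
  rest <- n - sum(base_counts)
  if (rest > 0) {
    top_up <- order(n * config$trial_type_mix - base_counts,
                    decreasing = TRUE)[seq_len(rest)]
    base_counts[top_up] <- base_counts[top_up] + 1L
  }
  types <- sample(rep(RESPONSE_LEVELS, times = base_counts))
  sim <- rlba(n, params, renormalize = config$renormalize)
  out <- data.frame(trial_index = seq_len(n), trial_type = types,
                    response = sim$response, rt = sim$rt,
                    stringsAsFactors = FALSE)
  lc <- config$ldi_coupling
  if (!is.null(lc)) {
    shift <- lc$gain * tanh(lc$strength * z_couple)
    p_lure_trial <- min(max(lc$base + shift, 0), 1)
    p_foil_trial <- min(max(lc$base - shift, 0), 1)
    responded <- !is.na(out$response)
    u <- runif(n)
    force_lure <- responded &
      ((out$trial_type == "lure" & u < p_lure_trial) |
         (out$trial_type == "foil" & u < p_foil_trial))
    out$response[force_lure] <- "lure"
  }
  out
}

#' Generate per-subject connectivity matrices coupled to the truth
#'
#' Produces symmetric Fisher-z-scale matrices whose designated edge equals
#' `coupling_strength` times the subject's standardized coupled parameter
#' plus Gaussian noise; every other edge is pure noise. The diagonal is
#' zero and ignored by all analyses.
#'
#' @param truth An `mst_truth` data frame (one session).
#' @param config A [population_config()] with `connectivity_model` set.
#' @return Named list of [connectivity_matrix()] objects, one per subject.
#' @export
generate_connectivity <- function(truth, config) {
  cm <- config$connectivity_model
  if (is.null(cm)) stop("`connectivity_model` is not set in the config")
  R <- cm$n_regions
  labels <- paste0("R", seq_len(R))
  zp <- scale(truth[[cm$coupled_parameter]])[, 1]
  out <- lapply(seq_len(NROW(truth)), function(i) {
    m <- matrix(0, R, R)
    noise <- rnorm(R * (R - 1) / 2, sd = cm$noise_sd)
    m[upper.tri(m)] <- noise
    m[cm$edge[1], cm$edge[2]] <- cm$coupling_strength * zp[i] +
      rnorm(1, sd = cm$noise_sd)
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    connectivity_matrix(m, labels, subject_id = truth$subject[i])
  })
  names(out) <- truth$subject
  out
}

#' Generate a complete synthetic MST dataset
#'
#' Orchestrates [sample_population()], [generate_trials()] per subject and
#' session, and (when configured) [generate_connectivity()], all
#' reproducible from the configuration seed.
#'
#' @param config A [population_config()] object.
#' @return List of class `mst_synthetic`: `trials` (all subjects/sessions),
#'   `truth`, `connectivity` (or `NULL`), `config`.
#' @export
generate_dataset <- function(config) {
  truth <- sample_population(config)
  zc <- if (!is.null(config$ldi_coupling)) {
    zp <- scale(truth[[config$ldi_coupling$parameter]][
      truth$session == "test1"])[, 1]
    setNames(zp, truth$subject[truth$session == "test1"])
  }
  trial_sets <- lapply(seq_len(NROW(truth)), function(i) {
    tr <- generate_trials(truth_row_params(truth[i, ]), config,
                          z_couple = if (is.null(zc)) 0
                                     else zc[[truth$subject[i]]])
    tr <- cbind(data.frame(subject = truth$subject[i],
                           session = truth$session[i],
                           stringsAsFactors = FALSE), tr)
    if (!is.null(truth$age)) tr$age <- truth$age[i]
    tr
  })
  trials <- do.call(rbind, trial_sets)
  connectivity <- if (!is.null(config$connectivity_model))
    generate_connectivity(truth[truth$session == "test1", ], config)
  structure(list(trials = trials, truth = truth,
                 connectivity = connectivity, config = config),
            class = "mst_synthetic")
}
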