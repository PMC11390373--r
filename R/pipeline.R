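#' Fit every subject in a trial table
#'
#' Convenience wrapper running [fit_lba_mle()] or [fit_lba_bayes()] per
#' subject (and per session when a `session` column is present) and
#' collecting point estimates in a subject-level measure table alongside
#' the behavioral summaries.
#'
#' @param trials Data frame of trials for several subjects.
#' @param method `"mle"` (fast point estimates) or `"bayes"` (posterior
#'   medians from the full sampler).
#' @param config An [fit_config()] object (used by both methods for the
#'   seed and renormalization convention).
#' @param min_trials Minimum responded trials per subject.
#' @return Data frame, one row per subject/session: `subject`, `session`,
#'   `ldi`, `v_*`, `A_*`, `b`, `tau`, plus `loglik` (MLE) or `converged`
#'   and worst-case `rhat_max` (Bayes), plus `age` when available.
#' @export
fit_all_subjects <- function(trials, method = c("mle", "bayes"),
                             config = fit_config(), min_trials = 20L) {
  method <- match.arg(method)
  if (is.null(trials$session)) trials$session <- "test1"
  keys <- unique(trials[, c("subject", "session")])
  rows <- lapply(seq_len(NROW(keys)), function(i) {
    sub <- trials[trials$subject == keys$subject[i] &
                    trials$session == keys$session[i], , drop = FALSE]
    beh <- summarize_behavior(sub)
    base <- data.frame(subject = keys$subject[i],
                       session = keys$session[i], ldi = beh$ldi,
                       stringsAsFactors = FALSE)
    if (method == "mle") {
      fit <- fit_lba_mle(sub, renormalize = config$renormalize,
                         seed = config$seed + i)
      est <- c(fit$params$v, fit$params$A, fit$params$b, fit$params$tau)
      extra <- data.frame(loglik = fit$loglik)
    } else {
      cfg_i <- config
      cfg_i$seed <- config$seed + i
      fit <- fit_lba_bayes(sub, cfg_i)
      est <- fit$summary$median
      extra <- data.frame(converged = fit$converged,
                          rhat_max = max(fit$rhat))
    }
    est <- setNames(as.numeric(est), PARAM_NAMES)
    out <- cbind(base, as.data.frame(as.list(est)), extra)
    if (!is.null(sub$age)) out$age <- sub$age[1]
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline on a trial table
#'
#' Per-subject model fits and behavioral summaries, LDI-parameter Kendall
#' correlations with Holm correction, optional age-group comparisons,
#' optional test-retest stability report (when two sessions are present),
#' and optional connectivity-behavior correlation maps. Deterministic
#' given the seed in `config`.
#'
#' @param trials Data frame of trials (as returned by [read_trials()] or
#'   [generate_dataset()]).
#' @param method Fitting method, `"mle"` or `"bayes"`.
#' @param config An [fit_config()] object.
#' @param connectivity Optional named list of [connectivity_matrix()]
#'   objects aligned by subject id.
#' @param age_threshold Cutoff for [assign_age_group()] when ages are
#'   present.
#' @return List of class `mst_report`: `measures` (subject-level table),
#'   `behavior` (model-free summaries), `associations` (LDI-parameter
#'   correlation family), `age_comparison` (or `NULL`), `retest` (or
#'   `NULL`), `rsfc` (or `NULL`), `manifest`.
#' @export
run_pipeline <- function(trials, method = c("mle", "bayes"),
                         config = fit_config(), connectivity = NULL,
                         age_threshold = 40) {
  method <- match.arg(method)
  behavior <- summarize_behavior_all(trials)
  measures <- fit_all_subjects(trials, method = method, config = config)
  first_session <- measures[measures$session == measures$session[1], ,
                            drop = FALSE]
  param_cols <- PARAM_NAMES
  associations <- correlate_measures(first_session, "ldi", param_cols)
  age_comparison <- NULL
  if (!is.null(measures$age)) {
    grp <- assign_age_group(first_session$age, threshold = age_threshold)
    age_comparison <- list(
      groups = data.frame(subject = first_session$subject,
                          age = first_session$age, age_group = grp),
      ldi = wilcoxon_rank_sum(first_session$ldi[grp == "younger"],
                              first_session$ldi[grp == "older"]),
      ndt = wilcoxon_rank_sum(first_session$tau[grp == "younger"],
                              first_session$tau[grp == "older"]))
  }
  retest <- NULL
  sessions <- unique(measures$session)
  if (length(sessions) >= 2L) {
    retest <- test_retest_report(
      measures[measures$session == sessions[1], , drop = FALSE],
      measures[measures$session == sessions[2], , drop = FALSE],
      measures = c("ldi", param_cols))
  }
  rsfc <- NULL
  if (!is.null(connectivity)) {
    ids <- intersect(first_session$subject, names(connectivity))
    if (length(ids) >= 4L) {
      mats <- connectivity[ids]
      ms <- first_session[match(ids, first_session$subject), , drop = FALSE]
      rsfc <- list(
        ldi = edge_behavior_correlation(mats, ms$ldi, method = "kendall"),
        drift_lure = edge_behavior_correlation(mats, ms$v_lure,
                                               method = "kendall"),
        drift_vs_start_repeat = compare_edge_correlations(
          mats, ms$v_repeat, ms$A_repeat))
    }
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("mstlba")),
    method = method, seed = config$seed,
    renormalize = config$renormalize,
    n_subjects = length(unique(measures$subject)),
    n_sessions = length(sessions),
    n_fits = NROW(measures),
    n_converged = if (method == "bayes") sum(measures$converged) else NA,
    timestamp = format(Sys.time(), tz = "UTC"))
  structure(list(measures = measures, behavior = behavior,
                 associations = associations,
                 age_comparison = age_comparison, retest = retest,
                 rsfc = rsfc, manifest = manifest),
            class = "mst_report")
}

#' @export
print.mst_report <- function(x, ...) {
  cat(sprintf("MST LBA pipeline report: %d subjects, %d fits (%s)\n",
              x$manifest$n_subjects, x$manifest$n_fits,
              x$manifest$method))
  cat("\nLDI-parameter correlations (Holm-adjusted):\n")
  print(x$associations, digits = 3)
  if (!is.null(x$retest)) {
    cat("\nTest-retest stability:\n")
    print(x$retest, digits = 3)
  }
  invisible(x)
}

#' Write a pipeline report bundle to a directory
#'
#' Emits the subject-level measure table, behavioral summaries,
#' association table, optional retest/RSFC tables, and a JSON manifest.
#'
#' @param report An `mst_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$measures, file.path(dir, "measures.csv"),
            row.names = FALSE)
  write.csv(report$behavior, file.path(dir, "behavior.csv"),
            row.names = FALSE)
  write.csv(report$associations, file.path(dir, "associations.csv"),
            row.names = FALSE)
  if (!is.null(report$retest))
    write.csv(report$retest, file.path(dir, "retest.csv"),
              row.names = FALSE)
  if (!is.null(report$rsfc)) {
    write.csv(report$rsfc$ldi, file.path(dir, "rsfc_ldi.csv"),
              row.names = FALSE)
    write.csv(report$rsfc$drift_vs_start_repeat,
              file.path(dir, "rsfc_drift_vs_start_repeat.csv"),
              row.names = FALSE)
  }
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
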