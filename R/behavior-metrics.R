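#' Lure Discrimination Index
#'
#' `LDI = P(Lure response | Lure trial) - P(Lure response | Foil trial)`:
#' the lure "hit rate" corrected for the bias of calling a genuinely novel
#' item a lure. Trials without a response are excluded from both
#' denominators.
#'
#' @param trials Data frame with columns `trial_type` and `response`
#'   (values `"repeat"`, `"lure"`, `"foil"`; `NA` response allowed).
#' @return Scalar in `[-1, 1]`.
#' @examples
#' trials <- data.frame(
#'   trial_type = rep(c("lure", "foil"), each = 6),
#'   response   = c(rep("lure", 4), "foil", "repeat",
#'                  "lure", rep("foil", 5)))
#' compute_ldi(trials)  # 4/6 - 1/6 = 0.5
#' @export
compute_ldi <- function(trials) {
  tt <- tolower(as.character(trials$trial_type))
  resp <- tolower(as.character(trials$response))
  ok <- !is.na(resp)
  lure_n <- sum(ok & tt == "lure")
  foil_n <- sum(ok & tt == "foil")
  if (lure_n == 0L) stop("no responded lure trials: LDI is undefined")
  if (foil_n == 0L) stop("no responded foil trials: LDI is undefined")
  sum(ok & tt == "lure" & resp == "lure") / lure_n -
    sum(ok & tt == "foil" & resp == "lure") / foil_n
}

#' Model-free behavioral summary for one subject
#'
#' Per-trial-type accuracy (proportion of trials answered with the matching
#' response), per-response median RT and response proportions over
#' responded trials, the LDI, and missing-response counts.
#'
#' @param trials Data frame with columns `trial_type`, `response`, `rt`
#'   (and optionally `subject`).
#' @return A one-row data frame of class `behavioral_summary` with columns
#'   `subject` (if present), `ldi`, `accuracy_repeat/lure/foil`,
#'   `median_rt_repeat/lure/foil`, `prop_repeat/lure/foil`, `n_trials`,
#'   `n_missing`. Absent categories yield `NA`.
#' @export
summarize_behavior <- function(trials) {
  if (NROW(trials) == 0L) stop("`trials` must be nonempty")
  tt <- tolower(as.character(trials$trial_type))
  resp <- tolower(as.character(trials$response))
  ok <- !is.na(resp)
  acc <- vapply(RESPONSE_LEVELS, function(lv) {
    denom <- sum(ok & tt == lv)
    if (denom == 0L) NA_real_ else sum(ok & tt == lv & resp == lv) / denom
  }, numeric(1))
  med_rt <- vapply(RESPONSE_LEVELS, function(lv) {
    rts <- trials$rt[ok & resp == lv]
    if (length(rts) == 0L) NA_real_ else median(rts)
  }, numeric(1))
  prop <- vapply(RESPONSE_LEVELS, function(lv) {
    if (sum(ok) == 0L) NA_real_ else sum(ok & resp == lv) / sum(ok)
  }, numeric(1))
  ldi <- tryCatch(compute_ldi(trials), error = function(e) NA_real_)
  out <- data.frame(
    ldi = ldi,
    accuracy_repeat = acc[1], accuracy_lure = acc[2], accuracy_foil = acc[3],
    median_rt_repeat = med_rt[1], median_rt_lure = med_rt[2],
    median_rt_foil = med_rt[3],
    prop_repeat = prop[1], prop_lure = prop[2], prop_foil = prop[3],
    n_trials = NROW(trials), n_missing = sum(!ok), row.names = NULL)
  if (!is.null(trials$subject))
    out <- cbind(data.frame(subject = trials$subject[1]), out)
  class(out) <- c("behavioral_summary", class(out))
  out
}

#' Behavioral summaries for every subject in a trial table
#'
#' @param trials Data frame of trials for several subjects (column
#'   `subject` required; optional `session` is kept as a grouping key).
#' @return Data frame, one row per subject (per session when present).
#' @export
summarize_behavior_all <- function(trials) {
  keys <- trials["subject"]
  if (!is.null(trials$session)) keys$session <- trials$session
  split_idx <- split(seq_len(NROW(trials)), keys, drop = TRUE)
  rows <- lapply(split_idx, function(ix) {
    one <- summarize_behavior(trials[ix, , drop = FALSE])
    if (!is.null(trials$session)) one$session <- trials$session[ix[1]]
    if (!is.null(trials$age)) one$age <- trials$age[ix[1]]
    one
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Format group medians with IQR for report tables
#'
#' Produces the `median (IQR)` strings conventional in behavioral summary
#' tables, optionally split by a grouping column.
#'
#' @param table Data frame of subject-level measures.
#' @param columns Character vector of numeric columns to summarize.
#' @param by Optional name of a grouping column (e.g. `"age_group"`).
#' @param digits Significant decimal places (default 2).
#' @return Data frame with one row per group and one formatted column per
#'   measure.
#' @export
median_iqr_table <- function(table, columns, by = NULL, digits = 2) {
  fmt <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) == 0L) return(NA_character_)
    sprintf("%.*f (%.*f)", digits, median(x), digits,
            diff(quantile(x, c(0.25, 0.75), names = FALSE)))
  }
  groups <- if (is.null(by)) list(all = seq_len(NROW(table)))
            else split(seq_len(NROW(table)), table[[by]])
  rows <- lapply(names(groups), function(g) {
    vals <- lapply(columns, function(cl) fmt(table[[cl]][groups[[g]]]))
    out <- as.data.frame(setNames(vals, columns),
                         stringsAsFactors = FALSE)
    cbind(data.frame(group = g, n = length(groups[[g]]),
                     stringsAsFactors = FALSE), out)
  })
  do.call(rbind, rows)
}

#' Choice counts in response-time bins
#'
#' Partitions responded trials into RT bins and counts each response type
#' per bin, following the question "which response dominates fast versus
#' slow decisions?". With the default `equal_width` scheme the inner bin
#' edges span the 1st-99th RT percentile and the first/last bins absorb the
#' tails, so empty bins are possible and are reported with zero counts.
#'
#' @param trials Data frame with `response` and `rt`.
#' @param n_bins Number of bins (default 15).
#' @param scheme `"equal_width"` (default) or `"quantile"`.
#' @return List of class `rt_bin_profile`: `bin_edges` (length
#'   `n_bins + 1`), `counts` (`n_bins` x 3 matrix), `modal_response`
#'   (character, `NA` for empty bins).
#' @export
rt_binned_choices <- function(trials, n_bins = 15L,
                              scheme = c("equal_width", "quantile")) {
  scheme <- match.arg(scheme)
  ok <- !is.na(trials$response) & !is.na(trials$rt)
  rt <- trials$rt[ok]
  resp <- tolower(as.character(trials$response[ok]))
  if (length(rt) < n_bins)
    stop("need at least `n_bins` responded trials")
  if (scheme == "equal_width") {
    qs <- quantile(rt, c(0.01, 0.99), names = FALSE)
    inner <- seq(qs[1], qs[2], length.out = n_bins - 1L)
    edges <- c(min(rt), inner, max(rt))
    edges[1] <- edges[1] - 1e-9         # include the minimum
    if (any(diff(edges) <= 0))
      stop("degenerate RT spread for equal-width bins")
  } else {
    edges <- quantile(rt, seq(0, 1, length.out = n_bins + 1L), names = FALSE)
    edges[1] <- edges[1] - 1e-9
    if (any(diff(edges) <= 0))
      stop("tied RT quantiles: too many identical RTs for the quantile ",
           "scheme; use scheme = \"equal_width\"")
  }
  bin <- cut(rt, breaks = edges, labels = FALSE, include.lowest = TRUE)
  counts <- matrix(0L, n_bins, 3L,
                   dimnames = list(NULL, RESPONSE_LEVELS))
  for (j in seq_along(RESPONSE_LEVELS)) {
    tb <- tabulate(bin[resp == RESPONSE_LEVELS[j]], nbins = n_bins)
    counts[, j] <- tb
  }
  modal <- apply(counts, 1, function(r)
    if (sum(r) == 0L) NA_character_ else RESPONSE_LEVELS[which.max(r)])
  structure(list(bin_edges = edges, counts = counts, modal_response = modal),
            class = "rt_bin_profile")
}

#' Dichotomize subjects into younger and older age groups
#'
#' Lifespan samples in this task are typically bimodal in age, so analyses
#' split subjects into two groups. The `threshold` method assigns ages at
#' or above the cutoff (default 40 years, between the young-adult and
#' older-adult modes) to the older group. The `two_means` method finds the
#' exact 1-D two-cluster partition minimizing within-group variance by
#' scanning all split points of the sorted ages.
#'
#' @param ages Numeric vector of non-negative ages in years.
#' @param method `"threshold"` (default) or `"two_means"`.
#' @param threshold Cutoff in years for the threshold method; ages equal to
#'   the cutoff go to the older group.
#' @return Character vector (`"younger"`/`"older"`), same length as `ages`.
#' @export
assign_age_group <- function(ages, method = c("threshold", "two_means"),
                             threshold = 40) {
  method <- match.arg(method)
  if (any(!is.finite(ages)) || any(ages < 0))
    stop("`ages` must be finite and non-negative")
  if (method == "threshold")
    return(ifelse(ages >= threshold, "older", "younger"))
  if (length(unique(ages)) < 2L)
    stop("two_means needs at least 2 distinct ages")
  ord <- order(ages)
  x <- ages[ord]
  n <- length(x)
  wss <- vapply(seq_len(n - 1L), function(k) {
    lo <- x[seq_len(k)]
    hi <- x[(k + 1L):n]
    sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
  }, numeric(1))
  k <- which.min(wss)
  split_age <- (x[k] + x[k + 1L]) / 2
  ifelse(ages > split_age, "older", "younger")
}
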