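#' Kendall rank correlation between two subject-level measures
#'
#' Tie-corrected Kendall tau (tau-b) with a two-sided p-value: exact
#' enumeration for small samples without ties (`n <= 10`), the
#' tie-corrected normal approximation otherwise.
#'
#' @param x,y Paired finite numeric vectors, `n >= 3`.
#' @param label Optional label describing the pair.
#' @return One-row data frame of class `correlation_result`: `pair`, `tau`,
#'   `p_value`, `n`.
#' @export
kendall_tau <- function(x, y, label = NULL) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("Kendall tau needs at least 3 complete pairs")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("correlation undefined for a constant vector")
  has_ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  ct <- suppressWarnings(
    cor.test(x, y, method = "kendall", exact = (n <= 10L && !has_ties)))
  out <- data.frame(pair = if (is.null(label)) NA_character_ else label,
                    tau = unname(ct$estimate), p_value = ct$p.value, n = n,
                    row.names = NULL)
  class(out) <- c("correlation_result", class(out))
  out
}

#' Bonferroni-Holm step-down adjustment
#'
#' Step-down multiplicative adjustment with monotonicity enforcement;
#' controls the family-wise error rate for a family of tests.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order, each `>=` its raw value.
#' @export
holm_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "holm")
}

#' Correlate one measure with a family of measures, Holm-corrected
#'
#' Computes Kendall tau between `x_col` and each column in `y_cols` of a
#' subject-level measure table, then adjusts the p-values as one family.
#' The canonical family is the LDI against all eight model parameters
#' (three drift means, three start-point bounds, boundary, non-decision
#' time) within one experiment.
#'
#' @param table Data frame, one row per subject.
#' @param x_col Name of the reference column (e.g. `"ldi"`).
#' @param y_cols Character vector of column names to correlate with.
#' @param adjust Adjustment method passed to [p.adjust()] (default
#'   `"holm"`).
#' @return Data frame: `pair`, `tau`, `p_value`, `p_adjusted`, `n`.
#' @export
correlate_measures <- function(table, x_col, y_cols, adjust = "holm") {
  rows <- lapply(y_cols, function(yc)
    kendall_tau(table[[x_col]], table[[yc]],
                label = paste(x_col, yc, sep = "-")))
  out <- do.call(rbind, rows)
  out$p_adjusted <- p.adjust(out$p_value, method = adjust)
  out
}

tau_only <- function(x, y) suppressWarnings(cor(x, y, method = "kendall"))

#' Bootstrap confidence interval for a difference of Kendall correlations
#'
#' Resamples subjects with replacement and, per replicate, computes
#' `tau(x, yA) - tau(x, yB)`; used to ask whether one measure (e.g. a drift
#' rate) correlates more strongly with the reference (e.g. the LDI) than
#' another (e.g. a start-point bound). Replicates in which fewer than three
#' distinct subjects are drawn, or a resampled vector is constant, are
#' skipped and counted.
#'
#' @param x Reference measure (per subject).
#' @param yA,yB Competing measures (per subject, aligned with `x`).
#' @param n_boot Number of bootstrap replicates.
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @param method `"percentile"` (default) or `"bca"` (bias-corrected and
#'   accelerated, with jackknife acceleration).
#' @return One-row data frame of class `tau_difference_ci`: `tau_A`,
#'   `tau_B`, `difference`, `lower`, `upper`, `excludes_zero`, `n_boot`,
#'   `n_skipped`, `n`.
#' @export
bootstrap_tau_difference <- function(x, yA, yB, n_boot = 5000L, seed = 1L,
                                     conf = 0.95,
                                     method = c("percentile", "bca")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(yA), length(x) == length(yB))
  keep <- is.finite(x) & is.finite(yA) & is.finite(yB)
  x <- x[keep]; yA <- yA[keep]; yB <- yB[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete subjects")
  stat <- function(ix) {
    if (length(unique(ix)) < 3L) return(NA_real_)
    xs <- x[ix]
    if (length(unique(xs)) < 2L || length(unique(yA[ix])) < 2L ||
        length(unique(yB[ix])) < 2L) return(NA_real_)
    tau_only(xs, yA[ix]) - tau_only(xs, yB[ix])
  }
  set.seed(seed)
  reps <- vapply(seq_len(n_boot), function(i)
    stat(sample.int(n, n, replace = TRUE)), numeric(1))
  skipped <- sum(is.na(reps))
  reps <- reps[!is.na(reps)]
  alpha <- 1 - conf
  observed <- stat(seq_len(n))
  if (method == "percentile") {
    ci <- quantile(reps, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  } else {
    z0 <- qnorm(mean(reps < observed))
    jack <- vapply(seq_len(n), function(i) stat(setdiff(seq_len(n), i)),
                   numeric(1))
    jm <- mean(jack, na.rm = TRUE)
    num <- sum((jm - jack)^3, na.rm = TRUE)
    den <- 6 * sum((jm - jack)^2, na.rm = TRUE)^1.5
    a <- if (den == 0) 0 else num / den
    adj <- function(q) pnorm(z0 + (z0 + qnorm(q)) / (1 - a * (z0 + qnorm(q))))
    ci <- quantile(reps, c(adj(alpha / 2), adj(1 - alpha / 2)),
                   names = FALSE)
  }
  out <- data.frame(tau_A = tau_only(x, yA), tau_B = tau_only(x, yB),
                    difference = observed,
                    lower = ci[1], upper = ci[2],
                    excludes_zero = (ci[1] > 0 || ci[2] < 0),
                    n_boot = n_boot, n_skipped = skipped, n = n,
                    row.names = NULL)
  class(out) <- c("tau_difference_ci", class(out))
  out
}

#' Wilcoxon rank-sum comparison of two groups
#'
#' Two-sided rank-sum test (Mann-Whitney), exact for small tie-free
#' samples and tie-corrected normal approximation otherwise. The reported
#' `W` follows the convention of the rank sum of the first group minus its
#' minimum possible value (the Mann-Whitney U of group A over group B).
#'
#' @param group_a,group_b Nonempty numeric vectors.
#' @return One-row data frame: `W`, `p_value`, `n_a`, `n_b`,
#'   `median_a`, `median_b`.
#' @export
wilcoxon_rank_sum <- function(group_a, group_b) {
  group_a <- group_a[is.finite(group_a)]
  group_b <- group_b[is.finite(group_b)]
  if (length(group_a) == 0L || length(group_b) == 0L)
    stop("both groups must be nonempty")
  wt <- suppressWarnings(wilcox.test(group_a, group_b,
                                     alternative = "two.sided"))
  data.frame(W = unname(wt$statistic), p_value = wt$p.value,
             n_a = length(group_a), n_b = length(group_b),
             median_a = median(group_a), median_b = median(group_b),
             row.names = NULL)
}

#' Test-retest stability report across two sessions
#'
#' For every shared measure, computes the within-subject Kendall rank
#' correlation across sessions (how well subjects keep their ordering) and
#' the median and IQR of the per-subject session1 - session2 differences
#' (how much the magnitude drifts). Rank stability and magnitude stability
#' are deliberately reported side by side: a parameter can preserve ranks
#' while shifting in level.
#'
#' @param session1,session2 Data frames with a `subject` column and shared
#'   numeric measure columns (e.g. `ldi`, `v_repeat`, ..., `b`, `tau`).
#' @param measures Character vector of measure columns; defaults to all
#'   numeric columns present in both tables.
#' @return Data frame: `measure`, `tau`, `p_value`, `median_diff`,
#'   `iqr_diff`, `n`.
#' @export
test_retest_report <- function(session1, session2, measures = NULL) {
  common <- intersect(session1$subject, session2$subject)
  if (length(common) == 0L) stop("no overlapping subjects across sessions")
  s1 <- session1[match(common, session1$subject), , drop = FALSE]
  s2 <- session2[match(common, session2$subject), , drop = FALSE]
  if (is.null(measures)) {
    shared <- intersect(names(session1), names(session2))
    measures <- shared[vapply(shared, function(cl)
      is.numeric(session1[[cl]]) && cl != "subject", logical(1))]
  }
  rows <- lapply(measures, function(m) {
    ct <- kendall_tau(s1[[m]], s2[[m]], label = m)
    d <- s1[[m]] - s2[[m]]
    data.frame(measure = m, tau = ct$tau, p_value = ct$p_value,
               median_diff = median(d, na.rm = TRUE),
               iqr_diff = unname(diff(quantile(d, c(0.25, 0.75),
                                               na.rm = TRUE))),
               n = ct$n, row.names = NULL)
  })
  do.call(rbind, rows)
}
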