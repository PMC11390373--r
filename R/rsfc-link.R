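#' Fisher z-transform of a correlation coefficient
#'
#' Variance-stabilizing `atanh(r)`; connectivity matrices in this package
#' carry values on this scale.
#'
#' @param r Correlation coefficient(s), strictly inside `(-1, 1)`.
#' @return Transformed value(s).
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) >= 1))
    stop("`r` must lie strictly inside (-1, 1)")
  atanh(r)
}

#' Validate and label one subject's connectivity matrix
#'
#' @param values Square symmetric numeric matrix of Fisher-z connectivity
#'   values; the diagonal is ignored by all analyses.
#' @param region_labels Character vector of region names, one per row.
#' @param subject_id Optional subject identifier.
#' @return The matrix with dimnames set, class `connectivity_matrix` and a
#'   `subject_id` attribute.
#' @export
connectivity_matrix <- function(values, region_labels = NULL,
                                subject_id = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("matrix must be square")
  if (nrow(values) < 2L) stop("need at least 2 regions")
  od <- values[upper.tri(values) | lower.tri(values)]
  if (any(!is.finite(od))) stop("off-diagonal values must be finite")
  if (max(abs(values - t(values))) > 1e-8) stop("matrix must be symmetric")
  if (is.null(region_labels)) {
    region_labels <- rownames(values)
    if (is.null(region_labels))
      region_labels <- paste0("R", seq_len(nrow(values)))
  }
  stopifnot(length(region_labels) == nrow(values))
  dimnames(values) <- list(region_labels, region_labels)
  structure(values, class = c("connectivity_matrix", "matrix", "array"),
            subject_id = subject_id)
}

edge_index <- function(labels) {
  n <- length(labels)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  data.frame(region_i = labels[ij[, 1]], region_j = labels[ij[, 2]],
             i = ij[, 1], j = ij[, 2], stringsAsFactors = FALSE)
}

# Stack per-subject matrices into a subjects x edges matrix (upper triangle).
edge_matrix <- function(matrices) {
  labels <- rownames(matrices[[1]])
  idx <- edge_index(labels)
  em <- t(vapply(matrices, function(m) {
    m <- as.matrix(m)
    if (!identical(dim(m), dim(as.matrix(matrices[[1]]))))
      stop("all connectivity matrices must share dimensions")
    m[cbind(idx$i, idx$j)]
  }, numeric(nrow(idx))))
  list(edges = em, index = idx, labels = labels)
}

#' Correlate each connectivity edge with a behavioral measure
#'
#' For every unordered off-diagonal region pair, correlates that edge's
#' Fisher-z value across subjects with a per-subject behavioral measure
#' (LDI or a model parameter). Significance is uncorrected at `alpha`,
#' matching the exploratory use of these maps; [fdr_threshold()] can be
#' applied to the returned p-values for a corrected map.
#'
#' @param matrices List of per-subject [connectivity_matrix()] objects (or
#'   plain symmetric matrices), aligned with `measure`.
#' @param measure Numeric vector, one value per subject.
#' @param method `"pearson"` or `"kendall"`.
#' @param alpha Uncorrected significance threshold (default 0.05).
#' @return Data frame of class `edge_correlation_map`: `region_i`,
#'   `region_j`, `estimate`, `p_value`, `significant`, `method`, `n`.
#'   Edges constant across subjects get `NA` estimates and are never
#'   flagged.
#' @export
edge_behavior_correlation <- function(matrices, measure,
                                      method = c("pearson", "kendall"),
                                      alpha = 0.05) {
  method <- match.arg(method)
  if (length(matrices) != length(measure))
    stop("`matrices` and `measure` must be aligned per subject")
  if (length(measure) < 4L) stop("need at least 4 subjects")
  em <- edge_matrix(matrices)
  n_sub <- length(measure)
  res <- lapply(seq_len(nrow(em$index)), function(e) {
    v <- em$edges[, e]
    if (length(unique(v)) == 1L)
      return(c(est = NA_real_, p = NA_real_))
    ct <- suppressWarnings(cor.test(v, measure, method = method,
                                    exact = FALSE))
    c(est = unname(ct$estimate), p = ct$p.value)
  })
  res <- do.call(rbind, res)
  out <- data.frame(em$index[, c("region_i", "region_j")],
                    estimate = res[, "est"], p_value = res[, "p"],
                    significant = !is.na(res[, "p"]) & res[, "p"] < alpha,
                    method = method, n = n_sub, row.names = NULL)
  class(out) <- c("edge_correlation_map", class(out))
  out
}

#' Pearson-Filon z for two dependent overlapping correlations
#'
#' Compares `cor(edge, measure1)` with `cor(edge, measure2)` when both
#' correlations are computed on the same subjects and share the edge
#' variable, using the classical asymptotic z statistic for dependent
#' overlapping correlations.
#'
#' @param r_jk Correlation of the shared variable with measure 1.
#' @param r_jh Correlation of the shared variable with measure 2.
#' @param r_kh Correlation between the two measures.
#' @param n Number of subjects (> 4).
#' @return One-row data frame: `z`, `p_value`.
#' @export
pearson_filon_z <- function(r_jk, r_jh, r_kh, n) {
  if (any(abs(c(r_jk, r_jh, r_kh)) >= 1))
    stop("correlations must lie strictly inside (-1, 1)")
  if (n <= 4L) stop("need n > 4 subjects")
  R <- matrix(c(1, r_jk, r_jh,
                r_jk, 1, r_kh,
                r_jh, r_kh, 1), 3, 3)
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
    stop("the three correlations do not form a positive semidefinite matrix")
  k <- r_kh * (1 - r_jk^2 - r_jh^2) -
    0.5 * (r_jk * r_jh) * (1 - r_jk^2 - r_jh^2 - r_kh^2)
  z <- sqrt(n) * (r_jk - r_jh) /
    sqrt((1 - r_jk^2)^2 + (1 - r_jh^2)^2 - 2 * k)
  data.frame(z = z, p_value = 2 * pnorm(-abs(z)), row.names = NULL)
}

#' Benjamini-Hochberg FDR thresholding
#'
#' Step-up significance flags controlling the false discovery rate at
#' level `q`.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` allowed; never
#'   flagged).
#' @param q FDR level (default 0.05).
#' @return Logical vector of flags, same length and order as `p`.
#' @export
fdr_threshold <- function(p, q = 0.05) {
  pp <- p[!is.na(p)]
  if (any(!is.finite(pp)) || any(pp < 0) || any(pp > 1))
    stop("p-values must lie in [0, 1]")
  adj <- p.adjust(p, method = "BH")
  !is.na(adj) & adj <= q
}

#' Compare edge-behavior correlations between two measures
#'
#' For each connectivity edge, computes the Pearson correlation of the
#' edge with each of two behavioral measures, their difference, the
#' [pearson_filon_z()] statistic for the dependent overlapping comparison,
#' and FDR-thresholded significance across all edges.
#'
#' @inheritParams edge_behavior_correlation
#' @param measureA,measureB Numeric per-subject vectors (e.g. a drift rate
#'   and a start-point bound, or a drift rate and the LDI).
#' @param q FDR level for the significance flags.
#' @return Data frame: `region_i`, `region_j`, `corr_A`, `corr_B`,
#'   `corr_diff`, `z`, `p_value`, `significant`.
#' @export
compare_edge_correlations <- function(matrices, measureA, measureB,
                                      q = 0.05) {
  mapA <- edge_behavior_correlation(matrices, measureA, method = "pearson")
  mapB <- edge_behavior_correlation(matrices, measureB, method = "pearson")
  n <- length(measureA)
  r_kh <- cor(measureA, measureB)
  rows <- lapply(seq_len(nrow(mapA)), function(e) {
    rA <- mapA$estimate[e]
    rB <- mapB$estimate[e]
    if (is.na(rA) || is.na(rB))
      return(data.frame(z = NA_real_, p_value = NA_real_))
    if (abs(rA - rB) < 1e-12) return(data.frame(z = 0, p_value = 1))
    pearson_filon_z(rA, rB, r_kh, n)
  })
  pf <- do.call(rbind, rows)
  data.frame(mapA[, c("region_i", "region_j")],
             corr_A = mapA$estimate, corr_B = mapB$estimate,
             corr_diff = mapA$estimate - mapB$estimate,
             z = pf$z, p_value = pf$p_value,
             significant = fdr_threshold(pf$p_value, q = q),
             row.names = NULL)
}
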