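#' Read a trial-level MST table from delimited text
#'
#' Expects a CSV with header columns `subject`, `trial_index`,
#' `trial_type`, `response`, `rt`, and optionally `session` and `age`.
#' Trial types and responses are matched case-insensitively against
#' `repeat`/`lure`/`foil`; an empty response field denotes a missing
#' response (its `rt` must then be empty too). RTs are in seconds;
#' millisecond-scale input (median responded RT above 50) is rejected with
#' a conversion hint rather than silently rescaled.
#'
#' @param path Path to the CSV file.
#' @return Validated data frame of trials.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(subject = "character"))
  required <- c("subject", "trial_index", "trial_type", "response", "rt")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L)
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  rowlab <- function(i) paste0("row ", i + 1L)  # +1 for the header line
  df$trial_type <- tolower(trimws(as.character(df$trial_type)))
  bad <- which(!df$trial_type %in% RESPONSE_LEVELS)
  if (length(bad) > 0L)
    stop("unknown trial_type at ", rowlab(bad[1]), ": '",
         df$trial_type[bad[1]], "'")
  resp <- tolower(trimws(as.character(df$response)))
  resp[resp == "" | is.na(resp)] <- NA_character_
  bad <- which(!is.na(resp) & !resp %in% RESPONSE_LEVELS)
  if (length(bad) > 0L)
    stop("unknown response at ", rowlab(bad[1]), ": '", resp[bad[1]], "'")
  df$response <- resp
  df$rt <- suppressWarnings(as.numeric(df$rt))
  bad <- which(!is.na(df$response) & (is.na(df$rt) | df$rt <= 0))
  if (length(bad) > 0L)
    stop("non-positive or missing rt for a responded trial at ",
         rowlab(bad[1]))
  bad <- which(is.na(df$response) & !is.na(df$rt))
  if (length(bad) > 0L)
    stop("rt present without a response at ", rowlab(bad[1]))
  key <- if (is.null(df$session)) paste(df$subject, df$trial_index)
         else paste(df$subject, df$session, df$trial_index)
  dup <- which(duplicated(key))
  if (length(dup) > 0L)
    stop("duplicate (subject, session, trial_index) at ", rowlab(dup[1]))
  med_rt <- median(df$rt, na.rm = TRUE)
  if (is.finite(med_rt) && med_rt > 50)
    stop("median RT is ", round(med_rt), ": these look like milliseconds; ",
         "divide the rt column by 1000 before reading")
  df
}

#' Write a trial-level table to delimited text
#'
#' Counterpart of [read_trials()]; round-trips losslessly.
#'
#' @param trials Data frame of trials.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  write.csv(trials, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read per-subject connectivity matrices from a long-format table
#'
#' Expects a CSV with columns `subject`, `region_i`, `region_j`, `z`
#' listing each unordered off-diagonal region pair once per subject on the
#' Fisher-z scale.
#'
#' @param path Path to the CSV file.
#' @return Named list of [connectivity_matrix()] objects.
#' @export
read_connectivity <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(subject = "character"))
  required <- c("subject", "region_i", "region_j", "z")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L)
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  labels <- sort(unique(c(df$region_i, df$region_j)))
  lapply(split(df, df$subject), function(sub) {
    m <- matrix(0, length(labels), length(labels),
                dimnames = list(labels, labels))
    i <- match(sub$region_i, labels)
    j <- match(sub$region_j, labels)
    m[cbind(i, j)] <- sub$z
    m[cbind(j, i)] <- sub$z
    connectivity_matrix(m, labels, subject_id = sub$subject[1])
  })
}

#' Write per-subject connectivity matrices to a long-format table
#'
#' @param matrices Named list of [connectivity_matrix()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_connectivity <- function(matrices, path) {
  rows <- lapply(names(matrices), function(id) {
    m <- matrices[[id]]
    idx <- edge_index(rownames(m))
    data.frame(subject = id, region_i = idx$region_i,
               region_j = idx$region_j, z = m[cbind(idx$i, idx$j)],
               stringsAsFactors = FALSE)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Serialize posterior fit summaries for a set of subjects
#'
#' Writes a delimited summary table (one row per subject and parameter)
#' and a JSON sidecar with the same content plus convergence metadata.
#'
#' @param fits Named list of `lba_fit` objects (names = subject ids).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_fit_summaries <- function(fits, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- do.call(rbind, lapply(names(fits), function(id) {
    s <- fits[[id]]$summary
    cbind(data.frame(subject = id, stringsAsFactors = FALSE), s,
          converged = fits[[id]]$converged)
  }))
  csv_path <- file.path(dir, "fit_summaries.csv")
  write.csv(tab, csv_path, row.names = FALSE)
  json_path <- file.path(dir, "fit_summaries.json")
  jsonlite::write_json(
    lapply(fits, function(f)
      list(summary = f$summary, converged = f$converged,
           accept_rate = f$accept_rate)),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv_path, json_path))
}
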