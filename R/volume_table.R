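#' Long-format volume measurement table
#'
#' The universal input of the pipeline: one row per (subject, method, ROI,
#' session) volume observation. `volume_table()` validates a data frame and
#' stamps it with the `volume_table` class; all generators and readers in
#' the package return this structure.
#'
#' @param df data frame with columns `subject_id`, `method`, `roi`,
#'   `session` (character), `time_months` (non-negative numeric) and
#'   `volume` (numeric).
#' @param require_positive if `TRUE` (default), reject non-positive
#'   volumes. Tables simulated on a standardized scale (grand mean zero)
#'   legitimately contain non-positive values and are validated with
#'   `require_positive = FALSE`.
#' @return the validated data frame with class `volume_table`.
#' @export
volume_table <- function(df, require_positive = TRUE) {
  if (!is.data.frame(df)) stop("volume table must be a data frame")
  needed <- c("subject_id", "method", "roi", "session", "time_months", "volume")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0L) {
    stop("volume table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)[, needed]
  for (col in c("subject_id", "method", "roi", "session")) {
    df[[col]] <- as.character(df[[col]])
  }
  if (!is.numeric(df$time_months) || anyNA(df$time_months)) {
    stop("column 'time_months' must be numeric with no missing values")
  }
  if (any(df$time_months < 0)) {
    bad <- which(df$time_months < 0)[1L]
    stop("negative time_months on row ", bad)
  }
  if (!is.numeric(df$volume) || anyNA(df$volume)) {
    stop("column 'volume' must be numeric with no missing values")
  }
  if (require_positive && any(df$volume <= 0)) {
    bad <- which(df$volume <= 0)[1L]
    stop("non-positive volume on row ", bad, " (column 'volume')")
  }
  key <- paste(df$subject_id, df$method, df$roi, df$session, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- df[which(duplicated(key))[1L], ]
    stop(sprintf(
      "duplicate (subject_id, method, roi, session) key: (%s, %s, %s, %s)",
      dup$subject_id, dup$method, dup$roi, dup$session
    ))
  }
  class(df) <- c("volume_table", "data.frame")
  df
}

#' Read a volume table from CSV or TSV
#'
#' Expects the canonical header `subject_id,method,roi,session,time_months,
#' volume`. The delimiter is inferred from the file extension (`.tsv`/`.txt`
#' read as tab-separated, anything else as comma-separated). Schema
#' violations are reported with the offending row and column.
#'
#' @param path file path.
#' @param require_positive passed to [volume_table()].
#' @return a `volume_table`.
#' @export
read_volume_table <- function(path, require_positive = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  needed <- c("subject_id", "method", "roi", "session", "time_months", "volume")
  if (!all(needed %in% names(df))) {
    stop("header must contain columns: ", paste(needed, collapse = ","))
  }
  df <- df[, needed]
  for (col in c("time_months", "volume")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L]
      stop("malformed numeric in column '", col, "' on row ", bad)
    }
    df[[col]] <- v
  }
  volume_table(df, require_positive = require_positive)
}

#' Write a volume table as canonical CSV
#'
#' @param table a `volume_table`.
#' @param path output path (`.tsv` extension writes tab-separated).
#' @return `path`, invisibly.
#' @export
write_volume_table <- function(table, path) {
  stopifnot(inherits(table, "volume_table") || is.data.frame(table))
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(table, path, sep = sep, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.volume_table <- function(x, ...) {
  cat(sprintf(
    "volume_table: %d records, %d subject(s), %d method(s), %d ROI(s), %d session label(s)\n",
    nrow(x), length(unique(x$subject_id)), length(unique(x$method)),
    length(unique(x$roi)), length(unique(x$session))
  ))
  NextMethod()
}

# pivot one (method, roi) slice into a subjects x sessions matrix;
# errors unless every subject has exactly the same set of sessions
pivot_sessions <- function(table, method = NULL, roi = NULL) {
  df <- as.data.frame(table)
  if (!is.null(method)) df <- df[df$method == method, , drop = FALSE]
  if (!is.null(roi)) df <- df[df$roi == roi, , drop = FALSE]
  if (nrow(df) == 0L) stop("no records for the requested method/roi slice")
  sessions <- sort(unique(df$session))
  subjects <- sort(unique(df$subject_id))
  m <- matrix(NA_real_, nrow = length(subjects), ncol = length(sessions),
              dimnames = list(subjects, sessions))
  m[cbind(match(df$subject_id, subjects), match(df$session, sessions))] <- df$volume
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop("incomplete sessions: subject ", subjects[bad[1L]],
         " lacks session ", sessions[bad[2L]])
  }
  m
}
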