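#' Regional time-series container
#'
#' Wraps one subject's ROI time-series matrix (timepoints x regions) with its
#' region labels and repetition time. All downstream operations take either
#' this class or a plain numeric matrix.
#'
#' @param data numeric matrix, `T` timepoints (rows) x `R` regions (columns);
#'   no missing values, `T >= 2`, `R >= 2`.
#' @param subject_id character scalar identifying the subject.
#' @param roi_labels character vector of `R` unique region labels; defaults
#'   to the column names of `data`, or `ROI001...` when absent.
#' @param tr_seconds positive repetition time in seconds (default 2, the
#'   usual resting-state EPI value).
#' @return An object of class `roi_ts` with fields `subject_id`, `data`
#'   (labelled matrix), `roi_labels` and `tr_seconds`.
#' @export
roi_ts <- function(data, subject_id = "subject", roi_labels = NULL,
                   tr_seconds = 2) {
  data <- as.matrix(data)
  if (!is.numeric(data))
    stop_hn("hn_parse_error", "time-series data must be numeric")
  if (nrow(data) < 2L || ncol(data) < 2L)
    stop_hn("hn_schema_error",
            "need at least 2 timepoints and 2 regions, got %d x %d",
            nrow(data), ncol(data))
  if (anyNA(data) || any(!is.finite(data)))
    stop_hn("hn_parse_error", "time-series data contains missing or non-finite values")
  if (is.null(roi_labels)) roi_labels <- colnames(data)
  if (is.null(roi_labels)) roi_labels <- sprintf("ROI%03d", seq_len(ncol(data)))
  roi_labels <- as.character(roi_labels)
  if (length(roi_labels) != ncol(data))
    stop_hn("hn_schema_error", "%d labels for %d regions",
            length(roi_labels), ncol(data))
  if (anyDuplicated(roi_labels))
    stop_hn("hn_schema_error", "ROI labels must be unique")
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L || tr_seconds <= 0)
    stop_hn("hn_schema_error", "tr_seconds must be a positive scalar")
  colnames(data) <- roi_labels
  structure(
    list(subject_id = as.character(subject_id), data = data,
         roi_labels = roi_labels, tr_seconds = tr_seconds),
    class = "roi_ts"
  )
}

#' @export
print.roi_ts <- function(x, ...) {
  cat(sprintf("<roi_ts> subject '%s': %d timepoints x %d regions (TR = %gs)\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$tr_seconds))
  invisible(x)
}

ts_matrix <- function(x) {
  if (inherits(x, "roi_ts")) x$data else as.matrix(x)
}

#' Multi-subject cohort with group labels
#'
#' @param subjects list of [roi_ts()] objects sharing region count and label
#'   order.
#' @param labels character vector, one of `"control"`/`"patient"` per
#'   subject.
#' @return An object of class `cohort`.
#' @export
cohort <- function(subjects, labels) {
  if (length(subjects) == 0L)
    stop_hn("hn_schema_error", "a cohort needs at least one subject")
  if (!all(vapply(subjects, inherits, logical(1), "roi_ts")))
    stop_hn("hn_schema_error", "subjects must all be roi_ts objects")
  labels <- as.character(labels)
  if (length(labels) != length(subjects))
    stop_hn("hn_schema_error", "labels length (%d) != number of subjects (%d)",
            length(labels), length(subjects))
  bad <- setdiff(unique(labels), c("control", "patient"))
  if (length(bad))
    stop_hn("hn_schema_error", "unknown group label(s): %s",
            paste(bad, collapse = ", "))
  ref <- subjects[[1L]]$roi_labels
  for (i in seq_along(subjects)) {
    if (!identical(subjects[[i]]$roi_labels, ref))
      stop_hn("hn_schema_error",
              "subject '%s' has inconsistent ROI labels or region count",
              subjects[[i]]$subject_id)
  }
  structure(list(subjects = subjects, labels = labels), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects (%d control, %d patient), %d regions\n",
              length(x$subjects), sum(x$labels == "control"),
              sum(x$labels == "patient"), length(x$subjects[[1L]]$roi_labels)))
  invisible(x)
}

#' Nuisance regressor set
#'
#' Per-subject nuisance signals (e.g. mean CSF and white-matter time series,
#' six motion parameters) to be regressed out of every ROI column.
#'
#' @param data numeric matrix `T x q` (`q >= 0` columns).
#' @param names optional character vector of `q` regressor names.
#' @return Object of class `nuisance_regressors`.
#' @export
nuisance_regressors <- function(data, names = NULL) {
  data <- as.matrix(data)
  if (ncol(data) > 0 && (!is.numeric(data) || anyNA(data)))
    stop_hn("hn_parse_error", "nuisance regressors must be numeric and complete")
  if (is.null(names)) {
    names <- if (!is.null(colnames(data))) colnames(data)
             else sprintf("nuis%d", seq_len(ncol(data)))
  }
  if (length(names) != ncol(data))
    stop_hn("hn_schema_error", "regressor names do not match column count")
  if (ncol(data) > 0) colnames(data) <- names
  structure(list(data = data, names = as.character(names)),
            class = "nuisance_regressors")
}

read_numeric_table <- function(path) {
  if (!file.exists(path))
    stop_hn("hn_input_error", "file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          colClasses = "character")
  mat <- matrix(NA_real_, nrow(df), ncol(df),
                dimnames = list(NULL, names(df)))
  for (j in seq_len(ncol(df))) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v) & !is.na(df[[j]]))
    if (length(bad))
      stop_hn("hn_parse_error",
              "non-numeric value '%s' at row %d, column '%s' of %s",
              df[[j]][bad[1L]], bad[1L], names(df)[j], path)
    mat[, j] <- v
  }
  mat
}

#' Read a cohort from a manifest file
#'
#' The manifest is a tab-separated table with columns `subject_id`, `group`,
#' `timeseries_path` and optionally `nuisance_path` and `tr_seconds`. Each
#' time-series file is a TSV with a header row of ROI labels and one row per
#' timepoint. Relative paths are resolved against the manifest's directory.
#' When a `nuisance_path` is present, the subject's columns are replaced by
#' their residuals against those regressors (see
#' [residualize_nuisance()]).
#'
#' @param manifest_path path to the manifest TSV.
#' @return A [cohort()] with subjects in manifest order.
#' @export
read_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stop_hn("hn_input_error", "manifest not found: %s", manifest_path)
  man <- utils::read.delim(manifest_path, header = TRUE,
                           check.names = FALSE, colClasses = "character")
  need <- c("subject_id", "group", "timeseries_path")
  miss <- setdiff(need, names(man))
  if (length(miss))
    stop_hn("hn_schema_error", "manifest missing column(s): %s",
            paste(miss, collapse = ", "))
  base <- dirname(normalizePath(manifest_path))
  resolve <- function(p) if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
  subjects <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    mat <- read_numeric_table(resolve(man$timeseries_path[i]))
    tr <- if ("tr_seconds" %in% names(man)) as.numeric(man$tr_seconds[i]) else 2
    ts <- roi_ts(mat, subject_id = man$subject_id[i], tr_seconds = tr)
    if ("nuisance_path" %in% names(man) && nzchar(man$nuisance_path[i]) &&
        !is.na(man$nuisance_path[i])) {
      nm <- read_numeric_table(resolve(man$nuisance_path[i]))
      ts <- residualize_nuisance(ts, nuisance_regressors(nm))
    }
    subjects[[i]] <- ts
  }
  cohort(subjects, man$group)
}

write_numeric_table <- function(mat, path) {
  # %.17g round-trips IEEE doubles exactly through text
  chr <- matrix(sprintf("%.17g", mat), nrow(mat), ncol(mat))
  lines <- c(paste(colnames(mat), collapse = "\t"),
             apply(chr, 1L, paste, collapse = "\t"))
  writeLines(lines, path)
}

#' Write a cohort as per-subject TSV tables plus a manifest
#'
#' Inverse of [read_cohort()]: values survive the text round-trip exactly
#' (17 significant digits).
#'
#' @param x a [cohort()].
#' @param out_dir output directory (created if needed).
#' @return The manifest path, invisibly usable by [read_cohort()].
#' @export
write_cohort <- function(x, out_dir) {
  if (!inherits(x, "cohort") || length(x$subjects) == 0L)
    stop_hn("hn_schema_error", "refusing to write an empty or invalid cohort")
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop_hn("hn_io_error", "cannot create directory %s", out_dir)
  files <- character(length(x$subjects))
  for (i in seq_along(x$subjects)) {
    s <- x$subjects[[i]]
    files[i] <- sprintf("%s.tsv", s$subject_id)
    write_numeric_table(s$data, file.path(out_dir, files[i]))
  }
  man <- data.frame(
    subject_id = vapply(x$subjects, `[[`, character(1), "subject_id"),
    group = x$labels,
    timeseries_path = files,
    tr_seconds = vapply(x$subjects, `[[`, numeric(1), "tr_seconds"),
    stringsAsFactors = FALSE
  )
  manifest_path <- file.path(out_dir, "manifest.tsv")
  utils::write.table(man, manifest_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(manifest_path)
}

#' Regress nuisance signals out of every ROI column
#'
#' Each ROI column is replaced by its ordinary-least-squares residual against
#' an intercept plus the nuisance design. Residuals are exactly orthogonal to
#' every nuisance column and have zero mean. With zero regressors this
#' reduces to column demeaning.
#'
#' @param ts an [roi_ts()] (or numeric matrix).
#' @param nuis a [nuisance_regressors()] (or numeric matrix) with the same
#'   number of rows as `ts`.
#' @return Object of the same type as `ts`, residualized.
#' @export
residualize_nuisance <- function(ts, nuis) {
  mat <- ts_matrix(ts)
  nm <- if (inherits(nuis, "nuisance_regressors")) nuis$data else as.matrix(nuis)
  if (ncol(nm) > 0 && nrow(nm) != nrow(mat))
    stop_hn("hn_schema_error",
            "nuisance rows (%d) != timepoints (%d)", nrow(nm), nrow(mat))
  design <- cbind(intercept = 1, nm)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    dropped <- colnames(design)[qrd$pivot[(qrd$rank + 1L):ncol(design)]]
    stop_hn("hn_numerical_error",
            "nuisance design is rank deficient; collinear column(s): %s",
            paste(dropped, collapse = ", "))
  }
  res <- qr.resid(qrd, mat)
  if (inherits(ts, "roi_ts")) {
    out <- ts
    out$data <- res
    colnames(out$data) <- ts$roi_labels
    out
  } else res
}

#' Z-score every ROI column
#'
#' Columns are centred and scaled to unit sample standard deviation
#' (denominator `n - 1`). Applied before every sparse regression solve so the
#' penalty normalization to a fraction of lambda_max is comparable across
#' regions and subjects.
#'
#' @param ts an [roi_ts()] or numeric matrix with column variance > 0.
#' @return Standardized object of the same type.
#' @export
standardize_columns <- function(ts) {
  mat <- ts_matrix(ts)
  sds <- apply(mat, 2L, stats::sd)
  if (any(sds == 0)) {
    lab <- colnames(mat)[which(sds == 0)]
    if (is.null(lab)) lab <- which(sds == 0)
    stop_hn("hn_numerical_error", "zero-variance ROI column(s): %s",
            paste(lab, collapse = ", "))
  }
  out <- sweep(sweep(mat, 2L, colMeans(mat), "-"), 2L, sds, "/")
  if (inherits(ts, "roi_ts")) {
    ts$data <- out
    colnames(ts$data) <- ts$roi_labels
    ts
  } else out
}
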