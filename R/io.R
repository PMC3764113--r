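#' Interval series for one subject
#'
#' An `interval_series` holds the ordered intervals (one value per event:
#' beat or breath) recorded from a single subject, together with subject,
#' group and modality metadata. The index is acquisition order; nothing in
#' the pipeline ever re-sorts it. Physiological modalities must have strictly
#' positive intervals (they are durations in seconds); synthetic series may
#' be signed.
#'
#' @param values numeric vector of intervals, length >= 3, all finite.
#' @param subject_id subject identifier.
#' @param group group label (e.g. `"healthy"`, `"UCAA"`); may be `NA`.
#' @param modality one of `"synthetic"`, `"cardiac"`, `"respiratory"`.
#' @return an object of class `interval_series`.
#' @examples
#' s <- interval_series(c(0.8, 0.9, 0.85), subject_id = "s1", modality = "cardiac")
#' s
#' @export
interval_series <- function(values, subject_id = "s1", group = NA_character_,
                            modality = c("synthetic", "cardiac", "respiratory")) {
  modality <- match.arg(modality)
  values <- as.numeric(values)
  if (length(values) < 3L)
    stop(sprintf("subject '%s': need at least 3 intervals, got %d",
                 subject_id, length(values)), call. = FALSE)
  if (!all(is.finite(values)))
    stop(sprintf("subject '%s': intervals must all be finite", subject_id),
         call. = FALSE)
  if (modality != "synthetic" && any(values <= 0))
    stop(sprintf("subject '%s': %s intervals must be positive",
                 subject_id, modality), call. = FALSE)
  structure(list(values = values,
                 subject_id = as.character(subject_id),
                 group = as.character(group),
                 modality = modality),
            class = "interval_series")
}

#' @export
print.interval_series <- function(x, ...) {
  cat(sprintf("<interval_series> subject '%s' (%s%s), %d intervals\n",
              x$subject_id, x$modality,
              if (is.na(x$group)) "" else paste0(", group ", x$group),
              length(x$values)))
  invisible(x)
}

# Accept an interval_series, a normalized_series or a bare numeric vector
# wherever a series is expected.
series_values <- function(x) {
  if (inherits(x, c("interval_series", "normalized_series"))) return(x$values)
  if (is.numeric(x)) return(as.numeric(x))
  stop("expected an interval_series, normalized_series or numeric vector",
       call. = FALSE)
}

series_meta <- function(x) {
  if (inherits(x, c("interval_series", "normalized_series")))
    list(subject_id = x$subject_id, group = x$group %||% NA_character_,
         modality = x$modality %||% "synthetic")
  else
    list(subject_id = NA_character_, group = NA_character_, modality = "synthetic")
}

#' Read interval series from disk
#'
#' Two plain-text layouts are supported. `format = "plain"` is one interval
#' per line for a single subject (the subject id defaults to the file name).
#' `format = "csv"` is a comma-separated table with a header and columns
#' `interval_s`, `subject_id` and optionally `group` and `modality`; rows are
#' partitioned by `subject_id` in order of first appearance, preserving the
#' within-subject acquisition order exactly.
#'
#' @param path file to read.
#' @param format `"plain"` or `"csv"`.
#' @param modality default modality for files that do not carry one.
#' @return a list of [interval_series()] objects, one per subject.
#' @export
read_intervals <- function(path, format = c("plain", "csv"),
                           modality = "synthetic") {
  format <- match.arg(format)
  if (!file.exists(path))
    stop(sprintf("input file not found: %s", path), call. = FALSE)
  if (format == "plain") {
    lines <- readLines(path)
    keep <- nzchar(trimws(lines))
    idx <- which(keep)
    vals <- suppressWarnings(as.numeric(trimws(lines[idx])))
    if (anyNA(vals)) {
      bad <- idx[which(is.na(vals))[1L]]
      stop(sprintf("%s: line %d: cannot parse '%s' as a number",
                   path, bad, trimws(lines[bad])), call. = FALSE)
    }
    sid <- tools::file_path_sans_ext(basename(path))
    return(list(interval_series(vals, subject_id = sid, modality = modality)))
  }
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  need <- c("interval_s", "subject_id")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("%s: missing required column(s): %s",
                 path, paste(miss, collapse = ", ")), call. = FALSE)
  vals <- suppressWarnings(as.numeric(df$interval_s))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1L]
    # +1 for the header line
    stop(sprintf("%s: line %d: cannot parse '%s' as a number",
                 path, bad + 1L, df$interval_s[bad]), call. = FALSE)
  }
  ids <- factor(df$subject_id, levels = unique(df$subject_id))
  lapply(levels(ids), function(sid) {
    rows <- which(ids == sid)
    grp <- if ("group" %in% names(df)) df$group[rows[1L]] else NA_character_
    mod <- if ("modality" %in% names(df)) df$modality[rows[1L]] else modality
    interval_series(vals[rows], subject_id = sid, group = grp, modality = mod)
  })
}

#' Write interval series to a CSV file
#'
#' Writes the standard cohort CSV (`interval_s`, `subject_id`, `group`,
#' `modality`). Values are serialized with 17 significant digits so that a
#' read/write round trip reproduces them to full double precision.
#'
#' @param series an [interval_series()] or a list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(series, path) {
  if (inherits(series, "interval_series")) series <- list(series)
  rows <- lapply(series, function(s) {
    data.frame(interval_s = sprintf("%.17g", s$values),
               subject_id = s$subject_id,
               group = ifelse(is.na(s$group), "", s$group),
               modality = s$modality,
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = ",",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Normalize a series to unit standard deviation
#'
#' Divides the series by its sample standard deviation (denominator n - 1) so
#' that jump levels stated in sigma units apply directly as absolute jumps.
#' The mean is deliberately not removed: exit times depend only on differences
#' \eqn{B_{t+\tau} - B_t}, so centering is irrelevant, and pure division keeps
#' the scale equivariance exact (exit times at `rho` on the normalized series
#' equal exit times at `rho * sigma_original` on the raw one).
#'
#' @param series an [interval_series()], `normalized_series` or numeric vector.
#' @return an object of class `normalized_series` with fields `values`
#'   (standard deviation 1), `sigma_original` (seconds) and the parent
#'   metadata.
#' @examples
#' normalize_sigma(interval_series(c(1, 3, 1), modality = "cardiac"))
#' @export
normalize_sigma <- function(series) {
  x <- series_values(series)
  meta <- series_meta(series)
  if (length(x) < 2L)
    stop("cannot normalize a series with fewer than 2 points", call. = FALSE)
  s <- stats::sd(x)
  if (!is.finite(s) || s <= 0)
    stop(sprintf("subject '%s': constant series (sigma = 0) cannot be normalized",
                 meta$subject_id), call. = FALSE)
  structure(list(values = x / s,
                 sigma_original = s,
                 subject_id = meta$subject_id,
                 group = meta$group,
                 modality = meta$modality),
            class = "normalized_series")
}

#' @export
print.normalized_series <- function(x, ...) {
  cat(sprintf("<normalized_series> subject '%s', %d points, sigma_original = %.6g\n",
              x$subject_id, length(x$values), x$sigma_original))
  invisible(x)
}
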