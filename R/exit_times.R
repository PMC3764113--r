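#' Exit times at a jump level rho
#'
#' For every start index \eqn{t \in 1..N-1} the exit time is the smallest
#' \eqn{\Delta t \ge 1} such that \eqn{B_{t+\Delta t} - B_t \ge \rho}
#' (`direction = "decelerating"`: the interval lengthens, e.g. bradycardia /
#' bradypnea) or \eqn{B_{t+\Delta t} - B_t \le -\rho} (`"accelerating"`:
#' tachycardia / tachypnea). The crossing criterion is "at or beyond rho": with
#' continuous data an exact hit has probability zero. Starts for which no
#' qualifying jump occurs before the series ends are censored; they contribute
#' no exit time but are counted in `n_censored`. Starts slide over every index
#' (overlapping), which is what makes the count of one-step exits a
#' permutation-invariant quantity shared exactly with any increment-shuffled
#' surrogate.
#'
#' `rho` is interpreted as an absolute jump on the values given; pass a
#' [normalize_sigma()] output to work in sigma units.
#'
#' @param series a `normalized_series`, [interval_series()] or numeric vector.
#' @param rho positive jump level (sigma units on a normalized series).
#' @param direction `"decelerating"` (upward jump) or `"accelerating"`
#'   (downward jump).
#' @return an object of class `exit_time_set` with fields `taus` (completed
#'   exit times, integer steps, in start order), `tau_by_start` (length
#'   `N - 1`, `NA` for censored starts), `rho`, `direction`, `n_starts`,
#'   `n_censored` and `subject_id`.
#' @examples
#' compute_exit_times(c(0, 1, 2, 3), rho = 1, direction = "decelerating")
#' @export
compute_exit_times <- function(series, rho,
                               direction = c("decelerating", "accelerating")) {
  direction <- match.arg(direction)
  x <- series_values(series)
  meta <- series_meta(series)
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) || rho <= 0)
    stop("`rho` must be a single positive number", call. = FALSE)
  if (length(x) < 2L)
    stop("series must have at least 2 points", call. = FALSE)
  if (!all(is.finite(x)))
    stop("series values must all be finite", call. = FALSE)
  tb <- if (direction == "decelerating") .exit_times_up(x, rho)
        else .exit_times_up(-x, rho)
  structure(list(taus = tb[!is.na(tb)],
                 tau_by_start = tb,
                 rho = rho,
                 direction = direction,
                 n_starts = length(x) - 1L,
                 n_censored = sum(is.na(tb)),
                 subject_id = meta$subject_id),
            class = "exit_time_set")
}

#' @export
print.exit_time_set <- function(x, ...) {
  cat(sprintf("<exit_time_set> %s rho = %g: %d/%d starts completed (%d censored)\n",
              x$direction, x$rho, length(x$taus), x$n_starts, x$n_censored))
  if (length(x$taus))
    cat(sprintf("  tau: min %d, median %g, max %d\n",
                min(x$taus), stats::median(x$taus), max(x$taus)))
  invisible(x)
}

#' @export
as.data.frame.exit_time_set <- function(x, ...) {
  keep <- which(!is.na(x$tau_by_start))
  data.frame(subject_id = x$subject_id,
             rho = x$rho,
             direction = x$direction,
             start_index = keep,
             tau = x$tau_by_start[keep],
             stringsAsFactors = FALSE)
}

# Completed exit times only, skipping the S3 wrapper (hot path).
exit_taus <- function(x, rho, direction) {
  tb <- if (direction == "decelerating") .exit_times_up(x, rho)
        else .exit_times_up(-x, rho)
  tb[!is.na(tb)]
}
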