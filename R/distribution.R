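#' Empirical exit-time distribution
#'
#' Turns completed exit times into a probability mass function over
#' \eqn{\tau = 1..\tau_{max}}. The PMF is normalized over completed exits only
#' (censored starts are excluded from the denominator), so
#' \eqn{\sum_\tau pmf(\tau) \le 1}, with equality when `tau_max` covers all
#' completed exits. Given several sets the per-set PMFs are combined pointwise:
#' `aggregate = "subjects"` returns the cross-subject mean with its per-tau
#' standard error (the mean +/- SEM curves of a cohort), `"ensemble"` returns
#' the surrogate-ensemble mean with the per-tau ensemble standard deviation in
#' `spread` (the noise scale used by the merge test).
#'
#' @param exits an `exit_time_set` or a list of them (one per subject or per
#'   surrogate).
#' @param tau_max integer, or `NULL` for the automatic rule: the smallest tau
#'   covering at least 99% of the completed exits, capped at 100 steps (tail
#'   bins holding a handful of counts would otherwise dominate the merge test
#'   with noise).
#' @return an object of class `exit_time_distribution` with fields `pmf`,
#'   `tau_max`, `n_exits`, `sem` (subjects) or `spread` (ensemble), plus the
#'   `rho`/`direction` carried from the input.
#' @examples
#' s <- compute_exit_times(c(0, 1, 0, 2, 0), rho = 1)
#' estimate_exit_distribution(s, tau_max = 3)
#' @export
estimate_exit_distribution <- function(exits, tau_max = NULL,
                                       aggregate = c("subjects", "ensemble")) {
  aggregate <- match.arg(aggregate)
  if (inherits(exits, "exit_time_set")) {
    if (!length(exits$taus))
      stop(sprintf("no completed exits for subject '%s' at rho = %g (%s)",
                   exits$subject_id, exits$rho, exits$direction), call. = FALSE)
    tau_max <- tau_max %||% auto_tau_max(exits$taus)
    return(structure(list(pmf = pmf_of(exits$taus, tau_max),
                          tau_max = as.integer(tau_max),
                          n_exits = length(exits$taus),
                          sem = NULL, spread = NULL,
                          rho = exits$rho, direction = exits$direction,
                          subject_id = exits$subject_id),
                     class = "exit_time_distribution"))
  }
  if (!is.list(exits) || !length(exits) ||
      !all(vapply(exits, inherits, logical(1), "exit_time_set")))
    stop("`exits` must be an exit_time_set or a non-empty list of them",
         call. = FALSE)
  n_each <- vapply(exits, function(e) length(e$taus), integer(1))
  if (aggregate == "subjects" && any(n_each == 0L)) {
    bad <- exits[[which(n_each == 0L)[1L]]]
    stop(sprintf("no completed exits for subject '%s' at rho = %g (%s)",
                 bad$subject_id, bad$rho, bad$direction), call. = FALSE)
  }
  if (all(n_each == 0L))
    stop("no completed exits in any set", call. = FALSE)
  tau_max <- as.integer(tau_max %||%
                          auto_tau_max(unlist(lapply(exits, `[[`, "taus"))))
  # a surrogate with zero completed exits contributes an all-zero PMF
  mat <- vapply(exits, function(e) {
    if (length(e$taus)) pmf_of(e$taus, tau_max) else numeric(tau_max)
  }, numeric(tau_max))
  mat <- matrix(mat, nrow = tau_max)
  m <- rowMeans(mat)
  k <- ncol(mat)
  disp <- if (k > 1L) apply(mat, 1L, stats::sd) else numeric(tau_max)
  structure(list(pmf = m,
                 tau_max = tau_max,
                 n_exits = sum(n_each),
                 sem = if (aggregate == "subjects") disp / sqrt(k) else NULL,
                 spread = if (aggregate == "ensemble") disp else NULL,
                 rho = exits[[1L]]$rho, direction = exits[[1L]]$direction,
                 subject_id = NA_character_),
            class = "exit_time_distribution")
}

pmf_of <- function(taus, tau_max) {
  tabulate(taus[taus <= tau_max], nbins = tau_max) / length(taus)
}

# Smallest tau covering >= 99% of completed exits, capped at 100 steps.
auto_tau_max <- function(taus) {
  if (!length(taus)) return(1L)
  min(as.integer(stats::quantile(taus, 0.99, type = 1L, names = FALSE)), 100L)
}

#' @export
print.exit_time_distribution <- function(x, ...) {
  cat(sprintf("<exit_time_distribution> tau = 1..%d, %d exits, sum(pmf) = %.4f\n",
              x$tau_max, x$n_exits, sum(x$pmf)))
  invisible(x)
}
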