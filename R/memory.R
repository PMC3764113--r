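#' Memory length from the merge point of two exit-time distributions
#'
#' The original and surrogate exit-time distributions differ only while joint
#' probabilities longer than one step still shape the dynamics; beyond the
#' merge point every longer joint probability factorises into one-step ones.
#' The memory length is defined as the first tau from which the two
#' distributions coincide for all larger tau (i.e. the last non-overlapping
#' point plus one), so `tau_m = 1` is the Markov case: shuffling preserves
#' one-step joint probabilities, and a series indistinguishable from its
#' shuffle retains nothing longer.
#'
#' Empirical PMFs never coincide exactly, so "coincide" means the absolute
#' difference \eqn{D(\tau) = |pmf_{orig}(\tau) - pmf_{shuf}(\tau)|} stays
#' within the per-tau tolerance
#' \eqn{\epsilon(\tau) = \max(k_{tol} \cdot spread_{shuf}(\tau),
#' \epsilon_{floor}, c_{floor} / n_{exits})}. The three components are: the
#' surrogate ensemble's per-tau standard deviation (the natural null scale),
#' an absolute floor guarding zero-spread bins, and a resolution floor of a
#' couple of counts -- a bin difference smaller than ~2 events is below what
#' the empirical PMF can resolve. Because the merge test inspects up to
#' `tau_max` (~100) bins jointly, `k_tol` is calibrated family-wise: the
#' default 3.5 is approximately the two-sided normal quantile for a 5%
#' family-wise exceedance over 100 bins (Bonferroni), so a memoryless series
#' merges at tau 1 with high probability while genuine low-tau structure,
#' which is far larger than the null scale, is still detected. If no merge
#' point exists within `tau_max` the result is flagged `merged = FALSE` and
#' `tau_m` is set to `tau_max` (unreliable).
#'
#' @param orig exit-time distribution of the original series.
#' @param shuf surrogate exit-time distribution on the same `tau_max`
#'   (typically `estimate_exit_distribution(..., aggregate = "ensemble")`).
#' @param k_tol multiplier on the surrogate ensemble spread (default 3.5,
#'   family-wise calibrated as described above).
#' @param eps_floor absolute tolerance floor (default 1e-3).
#' @param count_floor resolution floor in event counts (default 2.5); applied
#'   as `count_floor / n_exits` of the original distribution, skipped when
#'   `n_exits` is unknown.
#' @return an object of class `memory_length` with fields `tau_m`, `merged`,
#'   `rho`, `direction`, `subject_id`, `tau_max` and `diagnostics` (per-tau
#'   `difference` and `tolerance` vectors).
#' @examples
#' p <- c(0.5, 0.3, 0.2)
#' d1 <- structure(list(pmf = p, tau_max = 3L), class = "exit_time_distribution")
#' estimate_memory_length(d1, d1)$tau_m  # identical PMFs merge from the start
#' @export
estimate_memory_length <- function(orig, shuf, k_tol = 3.5, eps_floor = 1e-3,
                                   count_floor = 2.5) {
  if (!inherits(orig, "exit_time_distribution") ||
      !inherits(shuf, "exit_time_distribution"))
    stop("`orig` and `shuf` must be exit_time_distribution objects",
         call. = FALSE)
  if (orig$tau_max != shuf$tau_max)
    stop(sprintf("tau_max mismatch: original %d, shuffled %d",
                 orig$tau_max, shuf$tau_max), call. = FALSE)
  tm_max <- as.integer(orig$tau_max)
  spread <- shuf$spread %||% numeric(tm_max)
  spread[!is.finite(spread)] <- 0
  D <- abs(orig$pmf - shuf$pmf)
  floor_eff <- eps_floor
  nex <- orig$n_exits
  if (!is.null(nex) && length(nex) == 1L && is.finite(nex) && nex > 0)
    floor_eff <- max(eps_floor, count_floor / nex)
  eps <- pmax(k_tol * spread, floor_eff)
  ok <- D <= eps
  if (!ok[tm_max]) {
    tau_m <- tm_max
    merged <- FALSE
  } else {
    last_bad <- if (any(!ok)) max(which(!ok)) else 0L
    tau_m <- last_bad + 1L
    merged <- TRUE
  }
  structure(list(tau_m = as.integer(tau_m),
                 merged = merged,
                 rho = orig$rho %||% shuf$rho,
                 direction = orig$direction %||% shuf$direction,
                 subject_id = orig$subject_id %||% NA_character_,
                 tau_max = tm_max,
                 diagnostics = list(difference = D, tolerance = eps)),
            class = "memory_length")
}

#' @export
print.memory_length <- function(x, ...) {
  cat(sprintf("<memory_length> tau_m = %d steps%s (rho = %s, %s, tau_max = %d)\n",
              x$tau_m,
              if (isTRUE(x$merged)) "" else " [distributions never merge]",
              if (is.null(x$rho)) "?" else format(x$rho),
              x$direction %||% "?", x$tau_max))
  invisible(x)
}

#' Memory-length profile of a cohort over a grid of rho levels
#'
#' The main fitting function. For every subject and every jump level in
#' `rho_grid` (sigma units) it normalizes the series to unit standard
#' deviation, computes original exit times, builds an increment-shuffled
#' surrogate ensemble (one ensemble per subject, shared across rho levels --
#' surrogates do not depend on rho), estimates both exit-time distributions on
#' a common `tau_max`, and locates the merge point with
#' [estimate_memory_length()]. Group-level summaries are the per-group mean
#' +/- SEM of the per-subject `tau_m` at each rho; pooling across subjects
#' happens only at this last stage.
#'
#' Cells with zero completed exits are kept in the table with `tau_m = NA` and
#' reported in a warning rather than silently dropped; unmerged cells keep
#' their (unreliable) `tau_m = tau_max` and are flagged by `merged = FALSE`.
#'
#' @param cohort a list of [interval_series()] (or a single series / numeric
#'   vector). Raw series are sigma-normalized internally, so `rho_grid` is in
#'   sigma units for real and synthetic data alike.
#' @param rho_grid strictly positive jump levels, sigma units. The default is
#'   the respiratory grid `c(0.25, 0.5, 0.75, 1)`; cardiac analyses typically
#'   use `c(0.5, 1, 1.5, 2)`.
#' @param direction `"accelerating"` or `"decelerating"`.
#' @param M surrogate ensemble size per subject.
#' @param seed integer seed for the surrogate permutations.
#' @param k_tol,eps_floor,count_floor merge tolerance parameters, see
#'   [estimate_memory_length()].
#' @param tau_max fixed tau range, or `NULL` for the automatic per-cell rule
#'   (99% coverage of the original's completed exits, capped at 100).
#' @return an object of class `memory_profile`: a list with `table` (one row
#'   per subject x rho: `subject_id`, `group`, `rho`, `direction`, `tau_m`,
#'   `merged`, `n_exits`, `n_censored`, `tau_max`), `group_summary` (per group
#'   x rho mean, SEM, n, unmerged and missing counts) and the call parameters.
#'   Methods: `print`, `summary` (adds the two-way ANOVA when the design
#'   allows), `coef` (subject x rho matrix of tau_m), `plot`.
#' @examples
#' cohort <- gen_random_walk(n = 300, n_subjects = 3, seed = 1)
#' mp <- memory_profile(cohort, rho_grid = c(0.25, 0.5), M = 20, seed = 1)
#' mp
#' @export
memory_profile <- function(cohort,
                           rho_grid = c(0.25, 0.5, 0.75, 1),
                           direction = c("accelerating", "decelerating"),
                           M = 100L, seed = 1L,
                           k_tol = 3.5, eps_floor = 1e-3, count_floor = 2.5,
                           tau_max = NULL) {
  direction <- match.arg(direction)
  if (inherits(cohort, c("interval_series", "normalized_series")) ||
      is.numeric(cohort))
    cohort <- list(cohort)
  if (!length(cohort)) stop("`cohort` is empty", call. = FALSE)
  if (!is.numeric(rho_grid) || !length(rho_grid) || any(rho_grid <= 0))
    stop("`rho_grid` must be a non-empty vector of positive sigma multiples",
         call. = FALSE)
  rows <- vector("list", length(cohort) * length(rho_grid))
  ri <- 0L
  for (i in seq_along(cohort)) {
    s <- cohort[[i]]
    meta <- series_meta(s)
    if (is.na(meta$subject_id)) meta$subject_id <- sprintf("s%02d", i)
    norm <- if (inherits(s, "normalized_series")) s else normalize_sigma(s)
    ens <- shuffle_returns(norm, M = M, seed = sub_seed(seed, i))
    for (j in seq_along(rho_grid)) {
      rho <- rho_grid[j]
      orig_set <- compute_exit_times(norm, rho, direction)
      ri <- ri + 1L
      if (!length(orig_set$taus)) {
        rows[[ri]] <- data.frame(subject_id = meta$subject_id,
                                 group = meta$group, rho = rho,
                                 direction = direction,
                                 tau_m = NA_integer_, merged = NA,
                                 n_exits = 0L,
                                 n_censored = orig_set$n_censored,
                                 tau_max = NA_integer_,
                                 stringsAsFactors = FALSE)
        next
      }
      tm <- as.integer(tau_max %||% auto_tau_max(orig_set$taus))
      orig_dist <- estimate_exit_distribution(orig_set, tau_max = tm)
      surr_pmf <- vapply(ens$surrogates, function(v) {
        taus <- exit_taus(v, rho, direction)
        if (length(taus)) pmf_of(taus, tm) else numeric(tm)
      }, numeric(tm))
      surr_pmf <- matrix(surr_pmf, nrow = tm)
      shuf_dist <- structure(list(pmf = rowMeans(surr_pmf),
                                  tau_max = tm,
                                  n_exits = NA_integer_,
                                  sem = NULL,
                                  spread = if (M > 1L) apply(surr_pmf, 1L, stats::sd)
                                           else numeric(tm),
                                  rho = rho, direction = direction,
                                  subject_id = meta$subject_id),
                             class = "exit_time_distribution")
      ml <- estimate_memory_length(orig_dist, shuf_dist, k_tol = k_tol,
                                   eps_floor = eps_floor,
                                   count_floor = count_floor)
      rows[[ri]] <- data.frame(subject_id = meta$subject_id,
                               group = meta$group, rho = rho,
                               direction = direction,
                               tau_m = ml$tau_m, merged = ml$merged,
                               n_exits = length(orig_set$taus),
                               n_censored = orig_set$n_censored,
                               tau_max = tm,
                               stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  n_missing <- sum(tab$n_exits == 0L)
  if (n_missing)
    warning(sprintf("%d (subject, rho) cell(s) had zero completed exits; tau_m is NA there: %s",
                    n_missing,
                    paste(sprintf("(%s, %g)", tab$subject_id[tab$n_exits == 0L],
                                  tab$rho[tab$n_exits == 0L]), collapse = ", ")),
            call. = FALSE)
  structure(list(table = tab,
                 group_summary = summarize_groups(tab),
                 rho_grid = rho_grid, direction = direction,
                 M = as.integer(M), seed = as.integer(seed),
                 k_tol = k_tol, eps_floor = eps_floor,
                 count_floor = count_floor,
                 n_subjects = length(cohort),
                 call = match.call()),
            class = "memory_profile")
}

# Group x rho mean +/- SEM of tau_m over merged cells.
summarize_groups <- function(tab) {
  tab$group[is.na(tab$group)] <- "(all)"
  key <- interaction(tab$group, tab$rho, drop = TRUE, lex.order = TRUE)
  out <- do.call(rbind, lapply(split(tab, key), function(d) {
    ok <- !is.na(d$tau_m) & d$merged %in% TRUE
    y <- d$tau_m[ok]
    data.frame(group = d$group[1L], rho = d$rho[1L],
               n = length(y),
               mean_tau_m = if (length(y)) mean(y) else NA_real_,
               sem_tau_m = if (length(y) > 1L) stats::sd(y) / sqrt(length(y))
                           else NA_real_,
               n_unmerged = sum(d$merged %in% FALSE),
               n_missing = sum(is.na(d$tau_m)),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$group, out$rho), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.memory_profile <- function(x, ...) {
  cat(sprintf("Memory-length profile: %d subject(s) x %d rho level(s), %s events\n",
              x$n_subjects, length(x$rho_grid), x$direction))
  cat(sprintf("  M = %d surrogates/subject, k_tol = %g, eps_floor = %g, seed = %d\n\n",
              x$M, x$k_tol, x$eps_floor, x$seed))
  print(x$group_summary, digits = 4)
  invisible(x)
}

#' @export
coef.memory_profile <- function(object, ...) {
  tab <- object$table
  subj <- unique(tab$subject_id)
  rhos <- sort(unique(tab$rho))
  m <- matrix(NA_real_, length(subj), length(rhos),
              dimnames = list(subj, paste0("rho=", rhos)))
  m[cbind(match(tab$subject_id, subj), match(tab$rho, rhos))] <- tab$tau_m
  m
}

#' @export
summary.memory_profile <- function(object, alpha = 0.05, ...) {
  tab <- object$table
  anova_fit <- NULL
  posthoc <- NULL
  groups <- unique(tab$group[!is.na(tab$group)])
  if (length(groups) >= 2L && length(unique(tab$rho)) >= 2L) {
    anova_fit <- tryCatch(suppressWarnings(two_way_anova(tab)),
                          error = function(e) e$message)
    if (inherits(anova_fit, "memory_anova"))
      posthoc <- tryCatch(suppressWarnings(
        bonferroni_posthoc(tab, alpha = alpha)), error = function(e) NULL)
  }
  structure(list(profile = object, anova = anova_fit, posthoc = posthoc),
            class = "summary.memory_profile")
}

#' @export
print.summary.memory_profile <- function(x, ...) {
  print(x$profile)
  if (inherits(x$anova, "memory_anova")) {
    cat("\n")
    print(x$anova)
  } else if (is.character(x$anova)) {
    cat("\nTwo-way ANOVA unavailable:", x$anova, "\n")
  }
  if (!is.null(x$posthoc)) {
    cat("\nBonferroni post-hoc comparisons:\n")
    print(x$posthoc, digits = 4)
  }
  invisible(x)
}

#' Plot group mean memory length against the jump level
#'
#' Draws the per-group mean tau_m (+/- SEM error bars) as a function of rho,
#' one line per group.
#'
#' @param x a [memory_profile()] object.
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.memory_profile <- function(x, ...) {
  gs <- x$group_summary
  gs <- gs[!is.na(gs$mean_tau_m), , drop = FALSE]
  if (!nrow(gs)) stop("nothing to plot: no merged cells", call. = FALSE)
  groups <- unique(gs$group)
  rhos <- sort(unique(gs$rho))
  m <- matrix(NA_real_, length(rhos), length(groups),
              dimnames = list(NULL, groups))
  se <- m
  for (g in seq_along(groups)) {
    d <- gs[gs$group == groups[g], ]
    m[match(d$rho, rhos), g] <- d$mean_tau_m
    se[match(d$rho, rhos), g] <- d$sem_tau_m
  }
  ylim <- range(c(m - se, m + se, m), na.rm = TRUE)
  graphics::matplot(rhos, m, type = "b", pch = 19, lty = 1,
                    xlab = expression(rho ~ "(" * sigma ~ "units)"),
                    ylab = expression("memory length" ~ tau[m] ~ "(steps)"),
                    ylim = ylim, ...)
  for (g in seq_along(groups)) {
    ok <- !is.na(se[, g]) & se[, g] > 0
    if (any(ok))
      graphics::arrows(rhos[ok], m[ok, g] - se[ok, g],
                       rhos[ok], m[ok, g] + se[ok, g],
                       angle = 90, code = 3, length = 0.04, col = g)
  }
  graphics::legend("topleft", legend = groups, col = seq_along(groups),
                   pch = 19, lty = 1, bty = "n")
  invisible(x)
}
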