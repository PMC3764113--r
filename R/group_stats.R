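# Coerce a memory_profile or data.frame into the tau_m table used by the
# group statistics, dropping unmerged and missing cells (with a warning, per
# the estimator's convention: an unmerged tau_m equals tau_max by construction
# and would bias group means).
as_tau_table <- function(table) {
  if (inherits(table, "memory_profile")) table <- table$table
  if (!is.data.frame(table))
    stop("`table` must be a data.frame or memory_profile", call. = FALSE)
  need <- c("subject_id", "group", "rho", "tau_m")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop(sprintf("`table` is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  drop <- is.na(table$tau_m)
  if ("merged" %in% names(table)) drop <- drop | !(table$merged %in% TRUE)
  if (any(drop))
    warning(sprintf("excluding %d unmerged/missing tau_m value(s) from the group analysis",
                    sum(drop)), call. = FALSE)
  tab <- table[!drop, , drop = FALSE]
  if (anyDuplicated(tab[c("subject_id", "rho")]))
    stop("duplicate (subject_id, rho) rows in `table`", call. = FALSE)
  tab
}

#' Two-way ANOVA of memory length over groups and rho levels
#'
#' Fixed-effects two-factor decomposition of `tau_m ~ group + rho` without an
#' interaction term: the reported statistics are the two main-effect F values
#' (group and rho). Effect sums of squares are computed by comparing the full
#' two-factor fit against each single-factor submodel (Type II), which reduces
#' to the classical balanced decomposition when the design is balanced. The
#' repeated-measures structure over rho within subject is deliberately
#' ignored; this matches how cohort tau_m tables are conventionally analysed
#' in this literature, trading rigor for comparability.
#'
#' @param table a [memory_profile()] object or a data.frame with columns
#'   `subject_id`, `group`, `rho`, `tau_m` (and optionally `merged`; unmerged
#'   rows are excluded with a warning).
#' @param interaction if `TRUE`, additionally report the group x rho
#'   interaction sum of squares (never part of the headline statistics).
#' @return an object of class `memory_anova` with fields `F_group`, `F_rho`,
#'   `p_group`, `p_rho`, `df` (per-effect numerator/denominator degrees of
#'   freedom), `ss` (sums-of-squares table) and the design dimensions.
#' @examples
#' tab <- expand.grid(subject_id = paste0("s", 1:6), rho = c(0.5, 1))
#' tab$group <- rep(c("a", "b"), each = 3)
#' tab$tau_m <- c(1, 2, 1, 4, 5, 4, 2, 2, 3, 6, 7, 6)
#' two_way_anova(tab)
#' @export
two_way_anova <- function(table, interaction = FALSE) {
  tab <- as_tau_table(table)
  g <- factor(tab$group)
  r <- factor(tab$rho)
  y <- as.numeric(tab$tau_m)
  if (nlevels(g) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (nlevels(r) < 2L) stop("need at least 2 rho levels", call. = FALSE)
  cells <- table(g, r)
  if (any(cells == 0L)) {
    empty <- which(cells == 0L, arr.ind = TRUE)
    stop(sprintf("empty design cell(s): %s",
                 paste(sprintf("(%s, rho=%s)", rownames(cells)[empty[, 1L]],
                               colnames(cells)[empty[, 2L]]), collapse = ", ")),
         call. = FALSE)
  }
  if (any(cells < 2L))
    stop("need at least 2 subjects in every (group, rho) cell", call. = FALSE)
  fit_full <- stats::lm(y ~ g + r)
  rss_full <- stats::deviance(fit_full)
  df_err <- stats::df.residual(fit_full)
  ss_group <- max(0, stats::deviance(stats::lm(y ~ r)) - rss_full)
  ss_rho <- max(0, stats::deviance(stats::lm(y ~ g)) - rss_full)
  df_group <- nlevels(g) - 1L
  df_rho <- nlevels(r) - 1L
  ms_err <- rss_full / df_err
  # SS below float noise (relative to the total) count as exactly zero
  tol <- 1e-12 * (sum((y - mean(y))^2) + 1)
  f_of <- function(ss, df) {
    if (ss <= tol) ss <- 0
    if (ms_err > tol) return((ss / df) / ms_err)
    if (ss == 0) 0 else Inf   # convention: F = 0 when both SS vanish
  }
  F_group <- f_of(ss_group, df_group)
  F_rho <- f_of(ss_rho, df_rho)
  ss_int <- NULL
  if (interaction)
    ss_int <- max(0, rss_full - stats::deviance(stats::lm(y ~ g * r)))
  structure(list(F_group = F_group, F_rho = F_rho,
                 p_group = stats::pf(F_group, df_group, df_err,
                                     lower.tail = FALSE),
                 p_rho = stats::pf(F_rho, df_rho, df_err, lower.tail = FALSE),
                 df = list(group = c(df_group, df_err),
                           rho = c(df_rho, df_err)),
                 ss = c(group = ss_group, rho = ss_rho, error = rss_full),
                 ss_interaction = ss_int,
                 groups = levels(g), rho_levels = as.numeric(levels(r)),
                 n = length(y)),
            class = "memory_anova")
}

#' @export
print.memory_anova <- function(x, ...) {
  cat("Two-way ANOVA of tau_m (group + rho, no interaction)\n")
  cat(sprintf("  F_group = %.4g on (%d, %d) df, p = %.4g\n",
              x$F_group, x$df$group[1L], x$df$group[2L], x$p_group))
  cat(sprintf("  F_rho   = %.4g on (%d, %d) df, p = %.4g\n",
              x$F_rho, x$df$rho[1L], x$df$rho[2L], x$p_rho))
  cat(sprintf("  %d observations, groups: %s; rho levels: %s\n",
              x$n, paste(x$groups, collapse = ", "),
              paste(x$rho_levels, collapse = ", ")))
  invisible(x)
}

#' Bonferroni post-hoc pairwise group comparisons
#'
#' Pairwise pooled-variance two-sample t statistics on tau_m for every pair of
#' groups at every rho level. Raw p values are multiplied by the total number
#' of comparisons performed and clipped at 1 (classical Bonferroni). Pairs in
#' which either group has fewer than 2 subjects at that level are skipped and
#' reported in the `"skipped"` attribute.
#'
#' @inheritParams two_way_anova
#' @param alpha significance level for the `significant` flag.
#' @return a data.frame with one row per comparison: `group1`, `group2`,
#'   `rho`, `diff` (mean tau_m difference), `t`, `df`, `p`, `p_adj`,
#'   `significant`. Attributes: `m` (comparisons performed), `alpha`,
#'   `skipped`.
#' @export
bonferroni_posthoc <- function(table, alpha = 0.05) {
  tab <- as_tau_table(table)
  groups <- sort(unique(tab$group))
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  rhos <- sort(unique(tab$rho))
  pairs <- utils::combn(groups, 2L, simplify = FALSE)
  rows <- list()
  skipped <- list()
  for (lv in rhos) {
    for (pr in pairs) {
      ya <- tab$tau_m[tab$group == pr[1L] & tab$rho == lv]
      yb <- tab$tau_m[tab$group == pr[2L] & tab$rho == lv]
      if (length(ya) < 2L || length(yb) < 2L) {
        skipped[[length(skipped) + 1L]] <-
          data.frame(group1 = pr[1L], group2 = pr[2L], rho = lv,
                     n1 = length(ya), n2 = length(yb),
                     stringsAsFactors = FALSE)
        next
      }
      df <- length(ya) + length(yb) - 2L
      sp2 <- (sum((ya - mean(ya))^2) + sum((yb - mean(yb))^2)) / df
      se <- sqrt(sp2 * (1 / length(ya) + 1 / length(yb)))
      d <- mean(ya) - mean(yb)
      tstat <- if (se == 0) (if (d == 0) 0 else sign(d) * Inf) else d / se
      rows[[length(rows) + 1L]] <-
        data.frame(group1 = pr[1L], group2 = pr[2L], rho = lv,
                   diff = d, t = tstat, df = df,
                   p = 2 * stats::pt(-abs(tstat), df),
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    stop("no comparison had at least 2 subjects per group", call. = FALSE)
  out <- do.call(rbind, rows)
  m <- nrow(out)
  out$p_adj <- pmin(1, m * out$p)
  out$significant <- out$p_adj < alpha
  if (length(skipped)) {
    sk <- do.call(rbind, skipped)
    message(sprintf("skipped %d comparison(s) with fewer than 2 subjects per group",
                    nrow(sk)))
    attr(out, "skipped") <- sk
  }
  attr(out, "m") <- m
  attr(out, "alpha") <- alpha
  out
}
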