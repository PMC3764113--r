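# Independent oracles used across the suite. These deliberately share no code
# with the package internals.

# Naive O(n^2) double-loop exit-time scan.
naive_exit_times <- function(x, rho, direction) {
  n <- length(x)
  out <- rep(NA_integer_, n - 1L)
  for (t in seq_len(n - 1L)) {
    for (dt in seq_len(n - t)) {
      d <- x[t + dt] - x[t]
      hit <- if (direction == "decelerating") d >= rho else d <= -rho
      if (hit) {
        out[t] <- dt
        break
      }
    }
  }
  out
}

# Direct sums-of-squares two-way ANOVA for a BALANCED design (classical
# textbook decomposition), as an oracle for the model-comparison fit.
balanced_anova_oracle <- function(y, g, r) {
  g <- factor(g)
  r <- factor(r)
  N <- length(y)
  gm <- mean(y)
  ss_g <- sum(tapply(y, g, function(v) length(v) * (mean(v) - gm)^2))
  ss_r <- sum(tapply(y, r, function(v) length(v) * (mean(v) - gm)^2))
  cell_means <- tapply(y, list(g, r), mean)
  ss_err <- sum((y - (tapply(y, g, mean)[g] + tapply(y, r, mean)[r] - gm))^2)
  # error df for the additive model
  df_err <- N - (nlevels(g) - 1L) - (nlevels(r) - 1L) - 1L
  list(F_group = (ss_g / (nlevels(g) - 1L)) / (ss_err / df_err),
       F_rho = (ss_r / (nlevels(r) - 1L)) / (ss_err / df_err),
       ss_group = ss_g, ss_rho = ss_r, ss_err = ss_err)
}

# Random balanced tau_m table.
random_tau_table <- function(n_groups = 2L, n_rho = 2L, n_per_cell = 3L) {
  groups <- paste0("g", seq_len(n_groups))
  rhos <- seq_len(n_rho) / 4
  tab <- expand.grid(subject_rep = seq_len(n_per_cell), group = groups,
                     rho = rhos, stringsAsFactors = FALSE)
  tab$subject_id <- paste0(tab$group, "_s", tab$subject_rep)
  tab$tau_m <- sample(1:12, nrow(tab), replace = TRUE)
  tab
}

# Bare exit-time distribution for merge-point tests with fully controlled
# PMFs and spread.
dist_of <- function(pmf, spread = NULL, n_exits = NA_integer_) {
  structure(list(pmf = pmf, tau_max = length(pmf), n_exits = n_exits,
                 sem = NULL, spread = spread,
                 rho = NA_real_, direction = "accelerating",
                 subject_id = NA_character_),
            class = "exit_time_distribution")
}
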