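test_that("PMFs are relative frequencies over completed exits", {
  es <- structure(list(taus = c(1L, 1L, 2L), tau_by_start = c(1L, 1L, 2L, NA),
                       rho = 1, direction = "accelerating", n_starts = 4L,
                       n_censored = 1L, subject_id = "s"),
                  class = "exit_time_set")
  d <- estimate_exit_distribution(es, tau_max = 3L)
  expect_equal(d$pmf, c(2 / 3, 1 / 3, 0))
  expect_identical(d$n_exits, 3L)
  expect_equal(sum(d$pmf), 1)

  # truncation below max(taus) leaves mass outside the window
  d2 <- estimate_exit_distribution(es, tau_max = 1L)
  expect_equal(sum(d2$pmf), 2 / 3)
})

test_that("cross-subject aggregation gives mean and SEM pointwise", {
  mk <- function(taus, id) structure(
    list(taus = as.integer(taus), rho = 1, direction = "accelerating",
         n_starts = length(taus), n_censored = 0L, subject_id = id),
    class = "exit_time_set")
  d <- estimate_exit_distribution(list(mk(c(1, 1), "a"), mk(c(2, 2), "b")),
                                  tau_max = 2L)
  # subject PMFs are (1,0) and (0,1): mean 0.5, SEM = sd(c(1,0))/sqrt(2)
  expect_equal(d$pmf, c(0.5, 0.5))
  expect_equal(d$sem, rep(sd(c(1, 0)) / sqrt(2), 2L))
  expect_error(estimate_exit_distribution(list(mk(integer(0), "bad")),
                                          tau_max = 2L), "bad")
})

test_that("the automatic tau range covers 99% of exits and is capped at 100", {
  taus <- c(rep(1L, 99), 500L)
  es <- structure(list(taus = taus, rho = 1, direction = "accelerating",
                       n_starts = 100L, n_censored = 0L, subject_id = "s"),
                  class = "exit_time_set")
  expect_identical(estimate_exit_distribution(es)$tau_max, 1L)
  es$taus <- c(rep(1L, 50), rep(400L, 50))
  expect_identical(estimate_exit_distribution(es)$tau_max, 100L)
})

test_that("merge point: identical, locally different and never-merging PMFs", {
  p <- c(0.4, 0.3, 0.15, 0.1, 0.05)
  # identical distributions merge from the start (Markov case)
  expect_identical(estimate_memory_length(dist_of(p), dist_of(p))$tau_m, 1L)

  # difference beyond tolerance only at tau = 3 puts the merge at 4
  q <- p + c(0, 0, 0.05, 0, 0)
  r <- estimate_memory_length(dist_of(p), dist_of(q))
  expect_identical(r$tau_m, 4L)
  expect_true(r$merged)

  # difference persisting at tau_max means no merge; tau_m flagged
  q2 <- p + 0.05
  r2 <- estimate_memory_length(dist_of(p), dist_of(q2))
  expect_false(r2$merged)
  expect_identical(r2$tau_m, 5L)

  expect_error(estimate_memory_length(dist_of(p), dist_of(p[1:3])),
               "tau_max mismatch")
})

test_that("the tolerance combines ensemble spread, floor and count resolution", {
  p <- c(0.5, 0.3, 0.2)
  q <- p + c(0, 0.004, 0)
  # spread-dominated: 3.5 * 0.002 = 0.007 covers the 0.004 difference
  r <- estimate_memory_length(dist_of(p), dist_of(q, spread = rep(0.002, 3)))
  expect_identical(r$tau_m, 1L)
  # zero spread: only the absolute floor remains and 0.004 exceeds 1e-3
  r2 <- estimate_memory_length(dist_of(p), dist_of(q, spread = rep(0, 3)))
  expect_identical(r2$tau_m, 3L)
  # count resolution: with 100 exits, 2.5/100 = 0.025 covers it again
  r3 <- estimate_memory_length(dist_of(p, n_exits = 100L),
                               dist_of(q, spread = rep(0, 3)))
  expect_identical(r3$tau_m, 1L)
})

test_that("merge point is symmetric in its arguments when spreads are equal", {
  set.seed(31)
  p <- prop.table(runif(10))
  q <- prop.table(runif(10))
  sp <- rep(0.01, 10)
  a <- estimate_memory_length(dist_of(p, spread = sp), dist_of(q, spread = sp))
  b <- estimate_memory_length(dist_of(q, spread = sp), dist_of(p, spread = sp))
  expect_identical(a$tau_m, b$tau_m)
  expect_equal(a$diagnostics$difference, b$diagnostics$difference)
})

test_that("a constant-increment ramp is its own surrogate: tau_m = 1 at all rho", {
  ramp <- interval_series(seq(0.5, 5, by = 0.5), "ramp")
  prof <- memory_profile(ramp, rho_grid = c(0.25, 0.5), M = 10L, seed = 1,
                         direction = "decelerating")
  expect_true(all(prof$table$tau_m == 1L))
  expect_true(all(prof$table$merged))
})

test_that("tau_m is invariant under rescaling of the raw series", {
  set.seed(41)
  x <- cumsum(rnorm(400))
  a <- memory_profile(interval_series(x, "s"), rho_grid = 0.5, M = 30L,
                      seed = 2)
  b <- memory_profile(interval_series(100 * x, "s"), rho_grid = 0.5, M = 30L,
                      seed = 2)
  expect_identical(a$table$tau_m, b$table$tau_m)
})

test_that("cells with no completed exits are reported, not dropped", {
  # strictly decreasing series: no decelerating exits at all
  s <- interval_series(seq(10, 1, length.out = 30), "down")
  expect_warning(prof <- memory_profile(s, rho_grid = 1, M = 5L,
                                        direction = "decelerating"),
                 "zero completed exits")
  expect_identical(nrow(prof$table), 1L)
  expect_true(is.na(prof$table$tau_m))
  expect_identical(prof$table$n_exits, 0L)
})

test_that("the profile table and group summary line up with the cohort", {
  cohort <- c(gen_random_walk(200, 2L, seed = 1, group = "a"),
              gen_random_walk(200, 2L, seed = 99, group = "b"))
  prof <- memory_profile(cohort, rho_grid = c(0.5, 1), M = 20L, seed = 3)
  expect_identical(nrow(prof$table), 8L)
  expect_identical(dim(coef(prof)), c(4L, 2L))
  gs <- prof$group_summary
  expect_setequal(gs$group, c("a", "b"))
  expect_identical(nrow(gs), 4L)
  # deterministic given the seed
  prof2 <- memory_profile(cohort, rho_grid = c(0.5, 1), M = 20L, seed = 3)
  expect_identical(prof$table, prof2$table)
})
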