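test_that("generators are bit-reproducible and carry metadata", {
  a <- gen_random_walk(100, n_subjects = 3L, seed = 7, group = "hv")
  b <- gen_random_walk(100, n_subjects = 3L, seed = 7, group = "hv")
  expect_identical(a, b)
  expect_identical(vapply(a, function(s) s$subject_id, ""),
                   c("hv_s01", "hv_s02", "hv_s03"))
  expect_false(identical(a[[1L]]$values, a[[2L]]$values))
  expect_false(identical(a, gen_random_walk(100, n_subjects = 3L, seed = 8,
                                            group = "hv")))
})

test_that("random-walk increments behave like iid standard normals", {
  s <- gen_random_walk(10000, seed = 3)[[1L]]
  inc <- diff(s$values)
  expect_lt(abs(mean(inc)), 3 / sqrt(10000))
  expect_lt(abs(sd(inc) - 1), 0.05)
  expect_lt(abs(cor(inc[-1], inc[-length(inc)])), 0.05)
})

test_that("order-0 autoregression reproduces the random walk bitwise", {
  expect_identical(gen_ar_increments(0L, numeric(0), 500, 2L, seed = 5),
                   lapply(gen_random_walk(500, 2L, seed = 5), function(s) {
                     s$subject_id <- sub("rw", "ar", s$subject_id)
                     s$group <- "ar"
                     s
                   }))
})

test_that("order-1 increments recover the prescribed lag-1 autocorrelation", {
  s <- gen_ar_increments(1L, 0.8, 50000, seed = 11)[[1L]]
  inc <- diff(s$values)
  r1 <- cor(inc[-1], inc[-length(inc)])
  expect_lt(abs(r1 - 0.8), 0.02)
})

test_that("non-stationary coefficients are rejected with the root modulus", {
  expect_error(gen_ar_increments(1L, 1.05, 100), "root modulus")
  expect_error(gen_ar_increments(2L, c(0.6, 0.6), 100), "root modulus")
  expect_error(gen_ar_increments(2L, 0.5, 100), "length")
  expect_silent(gen_ar_increments(5L, c(0.15, 0.08, 0.05, 0.04, 0.03), 50))
})

test_that("event regimes degenerate correctly", {
  # zero rate: identical to the random walk at the same seed
  expect_identical(gen_clustered_events(0, 8L, -1.5, 300, 2L, seed = 9,
                                        group = "rw"),
                   gen_random_walk(300, 2L, seed = 9, group = "rw"))
  # zero shift: the event regime is invisible, whatever the rate
  expect_identical(gen_clustered_events(0.3, 8L, 0, 300, seed = 9),
                   gen_clustered_events(0.01, 4L, 0, 300, seed = 9))
})

test_that("clustered events fatten the accelerating increment tail", {
  s <- gen_clustered_events(0.02, 8L, -1.5, 5000, seed = 13)[[1L]]
  inc <- diff(s$values)
  # the standard-normal baseline alone would give ~pnorm(-1) = 15.9%
  expect_gt(mean(inc <= -1), pnorm(-1) + 0.03)
})

test_that("parameter validation of the clustered generator", {
  expect_error(gen_clustered_events(1.2, 8L, -1, 100), "probability")
  expect_error(gen_clustered_events(0.1, 0L, -1, 100), ">= 1")
  expect_error(gen_random_walk(5), ">= 10")
})
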