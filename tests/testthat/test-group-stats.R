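test_that("two-way ANOVA matches the direct sums-of-squares oracle", {
  set.seed(61)
  for (i in 1:10) {
    tab <- random_tau_table(n_groups = sample(2:4, 1L),
                            n_rho = sample(2:4, 1L),
                            n_per_cell = sample(2:5, 1L))
    fit <- two_way_anova(tab)
    orc <- balanced_anova_oracle(tab$tau_m, tab$group, tab$rho)
    expect_equal(fit$F_group, orc$F_group, tolerance = 1e-8)
    expect_equal(fit$F_rho, orc$F_rho, tolerance = 1e-8)
  }
})

test_that("degenerate and shifted designs behave as the decomposition demands", {
  tab <- random_tau_table(2L, 2L, 3L)
  tab$tau_m <- 4
  fit <- two_way_anova(tab)
  expect_identical(fit$F_group, 0)
  expect_identical(fit$F_rho, 0)
  expect_identical(fit$p_group, 1)

  # adding a constant to one group raises F_group, leaves F_rho unchanged
  set.seed(71)
  tab <- random_tau_table(2L, 3L, 4L)
  base <- two_way_anova(tab)
  tab2 <- tab
  tab2$tau_m <- tab2$tau_m + ifelse(tab2$group == "g1", 5, 0)
  shifted <- two_way_anova(tab2)
  expect_gt(shifted$F_group, base$F_group)
  expect_equal(shifted$F_rho, base$F_rho)
})

test_that("F statistics are invariant to group relabeling and affine rescaling", {
  set.seed(81)
  tab <- random_tau_table(3L, 2L, 3L)
  fit <- two_way_anova(tab)
  rel <- tab
  rel$group <- c(g1 = "zebra", g2 = "ant", g3 = "mole")[rel$group]
  expect_equal(two_way_anova(rel)$F_group, fit$F_group)
  scl <- tab
  scl$tau_m <- 3.7 * scl$tau_m + 11
  expect_equal(two_way_anova(scl)$F_group, fit$F_group)
  expect_equal(two_way_anova(scl)$F_rho, fit$F_rho)
})

test_that("design errors: empty cells, too few groups, unmerged exclusion", {
  tab <- random_tau_table(2L, 2L, 3L)
  expect_error(two_way_anova(tab[tab$group == "g1", ]), "2 groups")
  expect_error(two_way_anova(tab[!(tab$group == "g2" & tab$rho == 0.25), ]),
               "empty design cell.*g2")
  tab4 <- random_tau_table(2L, 2L, 4L)
  tab4$merged <- TRUE
  tab4$merged[1:2] <- FALSE      # same cell keeps 2 subjects
  expect_warning(two_way_anova(tab4), "excluding 2 unmerged")
})

test_that("Bonferroni post-hoc multiplies raw p by the comparison count", {
  set.seed(91)
  tab <- random_tau_table(3L, 2L, 4L)
  ph <- bonferroni_posthoc(tab, alpha = 0.05)
  m <- attr(ph, "m")
  expect_identical(m, nrow(ph))          # 3 pairs x 2 levels
  expect_identical(m, 6L)
  expect_equal(ph$p_adj, pmin(1, m * ph$p))
  # oracle: pooled-variance t-test per comparison
  i <- 3L
  ya <- tab$tau_m[tab$group == ph$group1[i] & tab$rho == ph$rho[i]]
  yb <- tab$tau_m[tab$group == ph$group2[i] & tab$rho == ph$rho[i]]
  tt <- t.test(ya, yb, var.equal = TRUE)
  expect_equal(ph$p[i], tt$p.value, tolerance = 1e-12)
})

test_that("identical groups are never significant; tiny groups are skipped", {
  tab <- random_tau_table(2L, 2L, 3L)
  tab$tau_m <- rep(c(2, 3, 4), 4L)     # both groups identical per level
  ph <- bonferroni_posthoc(tab)
  expect_true(all(ph$p_adj == 1))
  expect_false(any(ph$significant))

  tab3 <- random_tau_table(3L, 2L, 3L)
  solo <- tab3[!(tab3$group == "g3" & tab3$subject_rep > 1L), ]
  expect_message(ph2 <- bonferroni_posthoc(solo), "skipped")
  # both pairs involving the singleton group, at each of the two levels
  expect_identical(nrow(attr(ph2, "skipped")), 4L)
})

test_that("a real group difference is detected through the full pipeline", {
  # one clustered-event cohort vs one memoryless cohort
  hv <- gen_random_walk(120, 10L, seed = 5, group = "hv")
  ce <- gen_clustered_events(0.02, 8L, -1.5, 120, 10L, seed = 6, group = "ce")
  prof <- suppressWarnings(
    memory_profile(c(hv, ce), rho_grid = c(0.5, 1), M = 50L, seed = 77))
  fit <- suppressWarnings(two_way_anova(prof$table))
  expect_lt(fit$p_group, 0.05)
})
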