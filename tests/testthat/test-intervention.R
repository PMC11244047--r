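test_that("synthetic cohorts have the designed sizes, seeding and marginal means", {
  cohort <- synth_cohort(cohort_spec(), seed = 1)
  sizes <- dplyr::count(dplyr::distinct(cohort, subject_id, group), group)
  expect_equal(sizes$n[sizes$group == "precision"], 21)
  expect_equal(sizes$n[sizes$group == "standard"], 29)
  expect_setequal(unique(cohort$measure), c("balance_s", "grip_kg", "sf12", "bdi"))
  expect_identical(cohort, synth_cohort(cohort_spec(), seed = 1))
  expect_false(identical(cohort, synth_cohort(cohort_spec(), seed = 2)))

  # CLT bound: sample pre-mean within 3 sd / sqrt(n) of the spec mean in
  # (essentially) all seeds
  spec <- cohort_spec()
  bound <- 3 * 4.21 / sqrt(21)
  hits <- vapply(1:200, function(s) {
    d <- synth_cohort(spec, seed = s)
    v <- d$pre[d$group == "precision" & d$measure == "balance_s"]
    abs(mean(v) - 8.61) <= bound
  }, logical(1))
  expect_gte(mean(hits), 0.97)

  # empirical pre/post correlation tracks rho
  big <- synth_cohort(cohort_spec(n_precision = 2000, n_standard = 2), seed = 3)
  d <- big[big$group == "precision" & big$measure == "grip_kg", ]
  expect_equal(stats::cor(d$pre, d$post), 0.7, tolerance = 0.05)

  expect_error(cohort_spec(rho = 1), "rho")
  bad <- reported_outcomes()
  bad$pre_sd[1] <- 0
  expect_error(cohort_spec(params = bad), "positive")
})

test_that("Shapiro-Wilk wrapper matches the reference value and is affine invariant", {
  # classic men's-weights sample; W frozen from the reference implementation
  w11 <- c(148, 154, 158, 160, 161, 162, 166, 170, 182, 195, 236)
  res <- normality_test(w11)
  expect_equal(res$W, 0.7888, tolerance = 1e-3)
  expect_true(res$W > 0 && res$W <= 1)

  withr::with_seed(4, x <- stats::rnorm(40))
  expect_equal(normality_test(3 * x - 10)$W, normality_test(x)$W, tolerance = 1e-10)
  expect_error(normality_test(c(1, 2)), "between 3 and 5000")
})

test_that("mixed ANOVA matches the brute-force sums-of-squares oracle on a balanced toy", {
  pre1 <- c(3, 5, 4, 6)
  post1 <- c(6, 9, 7, 10)
  pre2 <- c(4, 6, 5, 7)
  post2 <- c(5, 6, 6, 8)
  oracle <- brute_force_mixed_anova(pre1, post1, pre2, post2)
  res <- tidy(mixed_anova(toy_cohort(pre1, post1, pre2, post2)))
  expect_equal(res$statistic[res$effect == "group"], oracle$f_group, tolerance = 1e-9)
  expect_equal(res$statistic[res$effect == "time"], oracle$f_time, tolerance = 1e-9)
  expect_equal(res$statistic[res$effect == "group:time"], oracle$f_int, tolerance = 1e-9)
  expect_equal(res$pes[res$effect == "group:time"], oracle$pes_int, tolerance = 1e-9)

  # the five components partition the total sum of squares exactly
  y <- c(pre1, post1, pre2, post2)
  expect_equal(sum(oracle$ss), sum((y - mean(y))^2), tolerance = 1e-9)
})

test_that("Type III F values agree with car on unbalanced groups", {
  skip_if_not_installed("car")
  cohort <- synth_cohort(cohort_spec(), seed = 8)
  d <- cohort[cohort$measure == "bdi", ]
  res <- tidy(mixed_anova(d))

  # Type III requires sum-to-zero contrasts
  av <- withr::with_options(
    list(contrasts = c("contr.sum", "contr.poly")),
    {
      mod <- stats::lm(cbind(pre, post) ~ group, data = d)
      idata <- data.frame(time = factor(c("pre", "post"), levels = c("pre", "post")))
      summary(
        car::Anova(mod, idata = idata, idesign = ~time, type = 3),
        multivariate = FALSE
      )$univariate.tests
    }
  )
  expect_equal(res$statistic[res$effect == "group"], av["group", "F value"], tolerance = 1e-8)
  expect_equal(res$statistic[res$effect == "time"], av["time", "F value"], tolerance = 1e-8)
  expect_equal(
    res$statistic[res$effect == "group:time"], av["group:time", "F value"],
    tolerance = 1e-8
  )
})

test_that("degenerate and random inputs keep the ANOVA well behaved", {
  pre <- c(2, 4, 6, 8, 1, 3, 5)
  cohort <- tibble::tibble(
    group = rep(c("precision", "standard"), c(4, 3)),
    pre = pre, post = pre
  )
  res <- tidy(mixed_anova(cohort))
  expect_equal(res$statistic[res$effect == "time"], 0)
  expect_equal(res$statistic[res$effect == "group:time"], 0)

  for (s in 1:50) {
    d <- synth_cohort(cohort_spec(n_precision = 5, n_standard = 6), seed = s)
    res <- tidy(mixed_anova(d, measure = "sf12"))
    expect_true(all(res$pes >= 0 & res$pes <= 1))
    expect_true(all(res$statistic >= 0))
  }

  expect_error(
    mixed_anova(tibble::tibble(group = "a", pre = 1, post = 2)),
    class = "bafawubu_data_error"
  )
})

test_that("contrasts match hand arithmetic and flip sign under group relabeling", {
  d <- toy_cohort(c(1, 2, 3), c(2, 4, 3), c(1, 1, 2), c(1, 2, 2))
  ct <- outcome_contrasts(d)
  paired_p1 <- ct[ct$contrast == "pre vs post (paired)" & ct$group == "precision", ]
  # diffs (1, 2, 0): t = mean / (sd / sqrt(3)) = sqrt(3)
  expect_equal(paired_p1$statistic, sqrt(3), tolerance = 1e-12)
  expect_equal(paired_p1$df, 2)

  same <- toy_cohort(c(1, 2, 3), c(1, 2, 3), c(2, 3), c(2, 3))
  cts <- outcome_contrasts(same)
  paired_rows <- cts[cts$contrast == "pre vs post (paired)", ]
  expect_equal(paired_rows$statistic, c(0, 0))
  expect_equal(paired_rows$p_value, c(1, 1))

  swapped <- d
  swapped$group <- ifelse(d$group == "precision", "standard", "precision")
  t_orig <- ct$statistic[ct$contrast == "post between groups (Welch)"]
  t_swap <- outcome_contrasts(swapped)$statistic[ct$contrast == "post between groups (Welch)"]
  expect_equal(t_swap, -t_orig, tolerance = 1e-12)
})

test_that("the full intervention table summarizes every measure", {
  cohort <- synth_cohort(cohort_spec(), seed = 2)
  tab <- intervention_table(cohort)
  expect_equal(nrow(tab), 4)
  expect_setequal(tab$measure, c("balance_s", "grip_kg", "sf12", "bdi"))
  expect_true(all(tab$interaction_pes >= 0 & tab$interaction_pes <= 1))
  expect_match(tab$precision_pre[1], "±")
})
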