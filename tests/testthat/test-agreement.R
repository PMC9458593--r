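# Bland-Altman, ICC, weighted kappa, subgroup tests, relevance flags.

test_that("a constant offset gives degenerate limits and zero slope", {
  p <- c(10, 20, 30, 40)
  ba <- bland_altman(p + 5, p)
  expect_equal(ba$mean_diff, 5)
  expect_equal(ba$sd_diff, 0)
  expect_equal(c(ba$loa_low, ba$loa_high), c(5, 5))
  expect_equal(ba$bias_slope_beta, 0)
})

test_that("Bland-Altman moments and slope match an explicit-sum oracle", {
  for (seed in 1:20) {
    set.seed(800 + seed)
    p <- runif(20, 10, 60); f <- p + rnorm(20, 7.8, 5)
    ba <- bland_altman(f, p)
    o <- bf_bland_altman(f, p)
    expect_equal(ba$mean_diff, o$mean_diff, tolerance = 1e-12)
    expect_equal(ba$sd_diff, o$sd_diff, tolerance = 1e-12)
    expect_equal(c(ba$loa_low, ba$loa_high), o$loa, tolerance = 1e-12)
    expect_equal(ba$bias_slope_beta, o$beta, tolerance = 1e-10)
    expect_equal(ba$bias_p, o$p, tolerance = 1e-10)
    # structural invariants hold to machine precision on every input
    expect_equal(ba$loa_low + ba$loa_high, 2 * ba$mean_diff)
    expect_equal(ba$loa_high - ba$loa_low, 2 * 1.96 * ba$sd_diff)
  }
  expect_error(bland_altman(1:2, 1:2), "at least 3")
})

test_that("consistency ICC is exact for agreement, shift-blind, and affine-stable", {
  x <- c(12, 25, 31, 44, 50, 62, 9)
  expect_equal(icc_consistency_average(x, x)$icc, 1)
  expect_equal(icc_consistency_average(x, x + 7.8)$icc, 1)
  set.seed(810)
  y <- x + rnorm(7, 0, 6)
  base <- icc_consistency_average(x, y)
  shifted <- icc_consistency_average(x, y + 123)
  scaled <- icc_consistency_average(3 * x - 40, 3 * y - 40)
  expect_equal(shifted$icc, base$icc, tolerance = 1e-12)
  expect_equal(scaled$icc, base$icc, tolerance = 1e-12)
  # ANOVA path and F-identity path agree (closing the reporting loop)
  from_f <- icc_from_f(base$f_value, base$df1, base$df2)
  expect_equal(from_f$icc, base$icc, tolerance = 1e-12)
  expect_equal(c(from_f$ci_low, from_f$ci_high),
               c(base$ci_low, base$ci_high), tolerance = 1e-12)
  expect_true(base$ci_low <= base$icc && base$icc <= base$ci_high)
})

test_that("quadratic kappa matches the confusion-matrix oracle and its limits", {
  expect_equal(weighted_kappa(c(0, 1, 2, 3, 2), c(0, 1, 2, 3, 2))$kappa, 1)
  expect_equal(weighted_kappa(c(0L, 3L), c(3L, 0L), levels = 0:3)$kappa, -1)
  for (seed in 1:20) {
    set.seed(820 + seed)
    a <- sample(0:3, 40, replace = TRUE)
    b <- pmin(pmax(a + sample(-1:1, 40, replace = TRUE), 0), 3)
    k <- weighted_kappa(a, b, levels = 0:3)
    expect_equal(k$kappa, bf_weighted_kappa(a, b, 0:3), tolerance = 1e-12)
    expect_equal(sum(k$confusion), 40L)
  }
  # on two categories the quadratic weights reduce to unweighted kappa
  set.seed(841)
  a2 <- sample(0:1, 60, replace = TRUE)
  b2 <- ifelse(runif(60) < 0.8, a2, 1 - a2)
  po <- mean(a2 == b2)
  pe <- mean(a2) * mean(b2) + mean(1 - a2) * mean(1 - b2)
  expect_equal(weighted_kappa(a2, b2, levels = 0:1)$kappa,
               (po - pe) / (1 - pe), tolerance = 1e-12)
  expect_error(weighted_kappa(rep(1L, 5), rep(1L, 5)), "single category")
})

test_that("subgroup comparison gates on normality and degrades gracefully", {
  # heavily tied, skewed values in both groups -> Mann-Whitney branch,
  # exchangeable groups give U = n1 n2 / 2 and p ~ 1
  v <- c(0, 0, 0, 1, 5, 20)
  r <- subgroup_difference(c(v, v), rep(c(TRUE, FALSE), each = 6))
  expect_identical(r$test_used, "mann_whitney")
  expect_equal(unname(r$statistic), 6 * 6 / 2)
  expect_gt(r$p, 0.9)
  # normal-looking groups take the t-test branch
  set.seed(850)
  r2 <- subgroup_difference(c(rnorm(15, 7, 2), rnorm(15, 8, 2)),
                            rep(c(TRUE, FALSE), each = 15))
  expect_identical(r2$test_used, "t_test")
  expect_error(subgroup_difference(1:6, rep(TRUE, 6)), "two non-empty")
})

test_that("exact Mann-Whitney p agrees with exhaustive enumeration", {
  r <- subgroup_difference(c(1, 2, 3, 4, 5, 6), rep(c(TRUE, FALSE), each = 3),
                           test = "mann_whitney")
  expect_equal(r$p, 0.1, tolerance = 1e-12)
  expect_equal(r$p, bf_mann_whitney_exact(c(1, 2, 3), c(4, 5, 6)),
               tolerance = 1e-12)
  for (seed in 1:20) {
    set.seed(860 + seed)
    x1 <- rnorm(5); x2 <- rnorm(5, 0.5)
    r <- subgroup_difference(c(x1, x2), rep(c("a", "b"), each = 5),
                             test = "mann_whitney")
    expect_equal(r$p, bf_mann_whitney_exact(x1, x2), tolerance = 1e-12)
  }
})

test_that("a factor-independent artefact rarely looks significant", {
  set.seed(870)
  reject <- 0L
  for (rep in 1:100) {
    d <- rnorm(40, 7.8, 5)                   # additive artefact, no subgroup link
    g <- rep(c(TRUE, FALSE), each = 20)
    if (subgroup_difference(d, g)$p <= 0.05) reject <- reject + 1L
  }
  expect_gte(100L - reject, 90L)
})

test_that("an additive-only artefact leaves no proportional bias at large n", {
  # pairs with a (nearly) constant additive artefact: the regression of the
  # difference on the pair mean converges to slope 0
  for (seed in 1:10) {
    co <- generate_cohort(cohort_sim_config(n_patients = 500L,
                                            frozen_delta_sd_pct = 1,
                                            seed = 880L + seed))
    ba <- bland_altman(co$sria_frozen_pct, co$sria_paraffin_pct)
    expect_lt(abs(ba$bias_slope_beta), 0.05)
  }
})

test_that("relevant-difference flags follow the 10 pp / any-grade rule", {
  expect_false(relevant_difference_flags(41, 32)$sria_flag)
  expect_true(relevant_difference_flags(45, 30)$sria_flag)
  expect_true(relevant_difference_flags(42, 32)$sria_flag)   # boundary: >= 10
  expect_false(relevant_difference_flags(30, 25, 2L, 2L)$score_flag)
  expect_true(relevant_difference_flags(30, 25, 2L, 1L)$score_flag)
  expect_true(is.na(relevant_difference_flags(30, 25)$score_flag))
})
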