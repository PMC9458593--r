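# Logistic DGF models, univariate screen, VIF.

test_that("the intercept-only model is the logit of the event fraction", {
  # 29 events among 71 patients: logit(29/42)
  f <- fit_logistic(data.frame(dgf = rep(c(TRUE, FALSE), c(29, 42))))
  expect_equal(f$intercept, log(29 / 42), tolerance = 1e-6)
  expect_equal(round(f$intercept, 2), -0.37)
  expect_identical(nrow(f$terms), 0L)
})

test_that("coefficients match direct likelihood maximisation", {
  for (seed in 1:20) {
    cohort <- generate_cohort(cohort_sim_config(n_patients = 200L,
                                                seed = 2000L + seed))
    f <- fit_logistic(cohort, "dgf", c("sria_paraffin_pct", "cit_hours"))
    oracle <- bf_logistic(as.integer(cohort$dgf),
                          cohort[c("sria_paraffin_pct", "cit_hours")])
    expect_equal(unname(coef(f)), oracle, tolerance = 1e-6)
    # Wald OR/CI arithmetic holds for every term
    expect_equal(f$terms$odds_ratio, exp(f$terms$coefficient))
    expect_equal(f$terms$ci_low, exp(f$terms$coefficient - 1.96 * f$terms$se))
    expect_equal(f$terms$ci_high, exp(f$terms$coefficient + 1.96 * f$terms$se))
    expect_true(all(f$terms$ci_low <= f$terms$odds_ratio &
                      f$terms$odds_ratio <= f$terms$ci_high))
    probs <- fitted(f$fit)
    expect_true(all(probs > 0 & probs < 1))
  }
})

test_that("separation and single-class outcomes are flagged, not reported as fits", {
  d <- data.frame(dgf = rep(c(TRUE, FALSE), each = 20),
                  leak = rep(c(1, 0), each = 20))
  f <- fit_logistic(d, "dgf", "leak")
  expect_false(f$converged)
  expect_match(f$diagnostic, "separation")
  expect_error(fit_logistic(data.frame(dgf = rep(TRUE, 10))), "single class")
})

test_that("the screen retains candidates iff their Wald p is under the rule", {
  cohort <- generate_cohort(cohort_sim_config(n_patients = 300L, seed = 77L))
  scr <- univariate_screen(cohort, c("sria_paraffin_pct", "cit_hours",
                                     "donor_age", "donor_male"), alpha_in = 0.1)
  expect_identical(scr$table$retained, scr$table$p < 0.1)
  # a failing candidate is recorded without aborting the screen
  cohort$flat <- 1
  scr2 <- univariate_screen(cohort, c("sria_paraffin_pct", "flat"))
  expect_false(scr2$table$retained[scr2$table$name == "flat"])
  expect_true(is.character(scr2$table$error[scr2$table$name == "flat"]))
  expect_true("sria_paraffin_pct" %in% scr2$table$name[!is.na(scr2$table$p)])
})

test_that("screen-then-fit with alpha 1 equals fitting all candidates", {
  cohort <- generate_cohort(cohort_sim_config(n_patients = 250L, seed = 88L))
  cands <- c("sria_paraffin_pct", "cit_hours", "donor_age")
  m1 <- dgf_model(cohort, cands, alpha_in = 1.0)$multivariate
  m2 <- fit_logistic(cohort, "dgf", cands)
  expect_equal(coef(m1), coef(m2), tolerance = 1e-12)
  # empty retained set degenerates to the intercept-only model
  cohort$noise1 <- rnorm(250); cohort$noise2 <- rnorm(250)
  set.seed(1); cohort$dgf_rand <- runif(250) < 0.4
  m3 <- dgf_model(cohort, c("noise1", "noise2"), outcome = "dgf_rand",
                  alpha_in = 1e-6)$multivariate
  expect_identical(nrow(m3$terms), 0L)
})

test_that("VIF equals the normal-equations oracle; collinearity is flagged", {
  orth <- data.frame(a = c(1, 1, -1, -1), b = c(1, -1, 1, -1))
  expect_equal(vif(orth)$vif, c(1, 1))
  dup <- data.frame(a = rnorm(20))
  dup$b <- dup$a
  expect_true(all(is.infinite(vif(dup)$vif)))
  for (seed in 1:20) {
    set.seed(900 + seed)
    X <- matrix(rnorm(60), 20, 3)
    X[, 3] <- X[, 3] + 0.6 * X[, 1]
    expect_equal(vif(as.data.frame(X))$vif, bf_vif(X), tolerance = 1e-8)
  }
  expect_error(vif(data.frame(a = rep(1, 5), b = rnorm(5))), "constant")
})
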