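# Ground-truth behaviour of the paired-section generator.

recomputed_fraction <- function(truth) {
  excl <- Reduce(`|`, truth$exclusion_masks)
  eff <- truth$cortex_mask & !excl
  100 * sum(truth$collagen_mask & eff) / sum(eff)
}

test_that("zero collagen gives empty masks and no red signal in the cortex", {
  pair <- small_pair(seed = 31L, truth = 0, delta = 0, size = 128L, mpp = 8)
  expect_equal(pair$paraffin_truth$realised_fraction_pct, 0)
  expect_equal(pair$frozen_truth$realised_fraction_pct, 0)
  expect_false(any(pair$paraffin_truth$collagen_mask))
  # no cortex pixel outside the embedded structures should look Sirius red
  ch <- collagen_channel(pair$paraffin)
  eff <- pair$paraffin_truth$cortex_mask &
    !Reduce(`|`, pair$paraffin_truth$exclusion_masks)
  expect_lt(max(ch[eff]), 0.5)
})

test_that("paraffin and frozen truths land on the configured fractions", {
  pair <- small_pair(seed = 32L, truth = 30, delta = 7.8, size = 256L, mpp = 4)
  expect_lt(abs(pair$paraffin_truth$realised_fraction_pct - 30), 0.5)
  expect_lt(abs(pair$frozen_truth$realised_fraction_pct - 37.8), 0.5)
  # mask arithmetic closes exactly: fractions recomputed from the emitted
  # masks match the reported ground truth to machine precision
  expect_equal(recomputed_fraction(pair$paraffin_truth),
               pair$paraffin_truth$realised_fraction_pct)
  expect_equal(recomputed_fraction(pair$frozen_truth),
               pair$frozen_truth$realised_fraction_pct)
  # collagen never leaves the cortex
  expect_false(any(pair$paraffin_truth$collagen_mask &
                     !pair$paraffin_truth$cortex_mask))
  expect_false(any(pair$frozen_truth$collagen_mask &
                     !pair$frozen_truth$cortex_mask))
})

test_that("identical config and seed is bit-reproducible; seeds differ", {
  cfg <- section_sim_config(width_px = 128L, height_px = 128L,
                            microns_per_pixel = 8, true_fraction_pct = 25,
                            frozen_delta_pct = 5, seed = 99L)
  a <- simulate_section_pair(cfg)
  b <- simulate_section_pair(cfg)
  expect_identical(a$frozen$pixels, b$frozen$pixels)
  expect_identical(a$paraffin$pixels, b$paraffin$pixels)
  expect_identical(a$frozen_truth$collagen_mask, b$frozen_truth$collagen_mask)
  cfg2 <- section_sim_config(width_px = 128L, height_px = 128L,
                             microns_per_pixel = 8, true_fraction_pct = 25,
                             frozen_delta_pct = 5, seed = 100L)
  c <- simulate_section_pair(cfg2)
  expect_false(identical(a$paraffin$pixels, c$paraffin$pixels))
})

test_that("infeasible fraction plus artefact is rejected up front", {
  expect_error(section_sim_config(true_fraction_pct = 95, frozen_delta_pct = 7.8),
               "\\[0, 100\\]")
  expect_error(section_sim_config(true_fraction_pct = 3, frozen_delta_pct = -5),
               "\\[0, 100\\]")
})

test_that("the frozen artefact is additive in ground truth, independent of the level", {
  set.seed(501)
  truths <- runif(30, 10, 45)
  diffs <- numeric(30); means <- numeric(30)
  for (i in 1:30) {
    pair <- small_pair(seed = 600L + i, truth = round(truths[i], 1),
                       delta = 7.8, size = 128L, mpp = 8)
    diffs[i] <- pair$frozen_truth$realised_fraction_pct -
      pair$paraffin_truth$realised_fraction_pct
    means[i] <- (pair$frozen_truth$realised_fraction_pct +
                   pair$paraffin_truth$realised_fraction_pct) / 2
  }
  expect_lt(abs(mean(diffs) - 7.8), 1.5)
  slope <- unname(coef(lm(diffs ~ means))[2L])
  expect_lt(abs(slope), 0.1)
})
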