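# Colour separation and threshold selection.

test_that("unstained white maps to zero and red outranks picric yellow", {
  one_px <- function(rgb) array(as.integer(rgb), dim = c(1L, 1L, 3L))
  for (m in c("deconvolution", "hue_saturation")) {
    expect_lt(collagen_channel(one_px(c(255, 255, 255)), m)[1L, 1L], 0.02)
    red <- collagen_channel(one_px(c(185, 40, 55)), m)[1L, 1L]
    yellow <- collagen_channel(one_px(c(230, 205, 110)), m)[1L, 1L]
    expect_gt(red, yellow)
  }
  # all-black input is a defined (zero) channel under deconvolution scaling
  black <- collagen_channel(array(0L, dim = c(2L, 2L, 3L)), "hue_saturation")
  expect_equal(max(black), 0)
})

test_that("channel ranking separates ground-truth collagen nearly perfectly", {
  pair <- small_pair(seed = 41L, truth = 30, delta = 7.8, size = 256L, mpp = 4)
  truth <- pair$paraffin_truth
  eff <- truth$cortex_mask & !Reduce(`|`, truth$exclusion_masks)
  for (m in c("deconvolution", "hue_saturation")) {
    ch <- collagen_channel(pair$paraffin, m)
    lab <- truth$collagen_mask[eff]; v <- ch[eff]
    r <- rank(v)
    auc <- (mean(r[lab]) - (sum(lab) + 1) / 2) / sum(!lab)
    expect_gt(auc, 0.99)
  }
})

test_that("channel output is deterministic with the input's dimensions", {
  pair <- small_pair(seed = 41L, truth = 30, delta = 7.8, size = 256L, mpp = 4)
  a <- collagen_channel(pair$frozen)
  expect_identical(dim(a), dim(pair$frozen$pixels)[1:2])
  expect_identical(a, collagen_channel(pair$frozen))
  expect_true(all(a >= 0 & a <= 1))
})

test_that("Otsu bisects a two-level image and honours fixed overrides", {
  two <- matrix(rep(c(0, 1), each = 50), ncol = 1L)
  thr <- select_threshold(two, NULL, "otsu")
  expect_gt(thr, 0); expect_lt(thr, 1)
  expect_equal(thr, 0.5, tolerance = 0.01)
  expect_identical(select_threshold(two, NULL, "fixed", fixed_value = 0.5), 0.5)
  expect_error(select_threshold(matrix(0.3, 4, 4), NULL, "otsu"), "fixed")
})

test_that("Otsu matches an exhaustive between-class variance search on bimodal data", {
  for (seed in 1:5) {
    set.seed(700 + seed)
    v <- c(rnorm(400, 0.2, 0.04), rnorm(250, 0.8, 0.05))
    v <- pmin(pmax(v, 0), 1)
    thr <- select_threshold(matrix(v, ncol = 1L), NULL, "otsu")
    expect_gt(thr, 0.2); expect_lt(thr, 0.8)
    # oracle: brute-force search over all 256-bin splits; ties (empty
    # histogram gaps) resolve to the plateau midpoint
    bins <- pmin(floor(v * 256), 255)
    sb <- rep(-Inf, 255)
    for (k in 1:255) {
      lo <- bins < k
      w0 <- mean(lo); w1 <- 1 - w0
      if (w0 == 0 || w1 == 0) next
      sb[k] <- w0 * w1 * (mean(bins[lo]) - mean(bins[!lo]))^2
    }
    best_ks <- which(sb >= max(sb) - 1e-9)
    expect_equal(thr, mean(best_ks) / 256, tolerance = 1e-12)
  }
})

test_that("lowering the threshold never decreases the stained count", {
  sec <- small_pair(seed = 41L, truth = 30, delta = 7.8, size = 256L, mpp = 4)$paraffin
  ch <- collagen_channel(sec)
  fractions <- vapply(seq(0.9, 0.1, by = -0.1), function(t)
    compute_sria(ch, t, sec)$fraction_pct, numeric(1L))
  expect_true(all(diff(fractions) >= 0))
})
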