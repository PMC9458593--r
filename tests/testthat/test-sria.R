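# SRIA measurement, inclusion rule and Remuzzi translation.

test_that("pixel counting is exact on handcrafted rasters", {
  # 10 x 10 cortex in a 12 x 12 image; paint exactly half the cortex red
  sec <- rect_section(12L, 12L, cortex = c(1, 1, 11, 11))
  ch <- matrix(0, 12L, 12L)
  ch[2:11, 2:6] <- 1                      # 50 of the 100 cortex pixels
  m <- compute_sria(ch, 0.5, sec)
  expect_identical(m$stained_px, 50L)
  expect_identical(m$cortex_px, 100L)
  expect_equal(m$fraction_pct, 50.0)
  expect_equal(m$analysed_area_mm2, 100 * 1 / 1e6)
})

test_that("exclusion polygons remove their pixels from both counts", {
  # exclusion that covers every stained pixel -> fraction 0
  sec <- rect_section(12L, 12L, cortex = c(1, 1, 11, 11),
                      exclusions = list(list(bounds = c(1, 1, 6, 11),
                                             role = "glomerulus")))
  ch <- matrix(0, 12L, 12L); ch[2:11, 2:6] <- 1
  m <- compute_sria(ch, 0.5, sec)
  expect_equal(m$fraction_pct, 0)
  expect_identical(m$cortex_px, 50L)
  # exclusion of only-unstained pixels strictly raises the fraction,
  # exclusion of only-stained pixels strictly lowers it
  base <- compute_sria(ch, 0.5, rect_section(12L, 12L, cortex = c(1, 1, 11, 11)))
  ex_unstained <- compute_sria(ch, 0.5, rect_section(
    12L, 12L, cortex = c(1, 1, 11, 11),
    exclusions = list(list(bounds = c(6, 1, 11, 11), role = "fold"))))
  expect_gt(ex_unstained$fraction_pct, base$fraction_pct)
  expect_lt(m$fraction_pct, base$fraction_pct)
})

test_that("fractions equal a brute-force double loop over pixels", {
  set.seed(404)
  for (rep in 1:5) {
    ch <- matrix(runif(30 * 30), 30L, 30L)
    sec <- rect_section(30L, 30L, cortex = c(2, 3, 27, 25),
                        exclusions = list(list(bounds = c(10, 10, 16, 14),
                                               role = "vessel")))
    thr <- runif(1, 0.2, 0.8)
    m <- compute_sria(ch, thr, sec)
    stained <- 0L; cortex <- 0L
    for (i in 1:30) for (j in 1:30) {
      xc <- j - 0.5; yc <- i - 0.5
      inc <- xc > 2 && xc < 27 && yc > 3 && yc < 25
      exc <- xc > 10 && xc < 16 && yc > 10 && yc < 14
      if (inc && !exc) {
        cortex <- cortex + 1L
        if (ch[i, j] >= thr) stained <- stained + 1L
      }
    }
    expect_identical(m$stained_px, stained)
    expect_identical(m$cortex_px, cortex)
    expect_equal(m$fraction_pct, 100 * stained / cortex)
  }
})

test_that("measured SRIA matches simulator ground truth through the full path", {
  pair <- small_pair(seed = 42L, truth = 35, delta = 7.8, size = 256L, mpp = 4)
  q <- quantify_pair(pair$frozen, pair$paraffin)
  expect_lt(abs(q$paraffin$fraction_pct -
                  pair$paraffin_truth$realised_fraction_pct), 2)
  expect_lt(abs(q$frozen$fraction_pct -
                  pair$frozen_truth$realised_fraction_pct), 2)
})

test_that("the 1 mm2 rule excludes small pairs, boundary inclusive", {
  fake_pair <- function(a_f, a_p) {
    meas <- function(a, kind) structure(
      list(fraction_pct = 30, analysed_area_mm2 = a, biopsy_id = "x",
           section_kind = kind), class = "srq_sria")
    structure(list(frozen = meas(a_f, "frozen"), paraffin = meas(a_p, "paraffin"),
                   covariates = list(), included = NA,
                   exclusion_reason = NA_character_), class = "srq_pair")
  }
  p1 <- check_pair_inclusion(fake_pair(0.9, 2.0))
  expect_false(p1$included)
  expect_match(p1$exclusion_reason, "below 1 mm2")
  expect_true(check_pair_inclusion(fake_pair(1.0, 1.0))$included)
  # 2048 x 2048 px fully analysed at 1 um/px is 4.19 mm^2 -> included
  a <- 2048 * 2048 * 1^2 / 1e6
  expect_equal(round(a, 2), 4.19)
  expect_true(check_pair_inclusion(fake_pair(a, a))$included)
})

test_that("Remuzzi translation is the documented step function", {
  expect_identical(remuzzi_if_grade(c(0, 4.999, 5, 19.9, 20, 32, 49.9, 50, 55, 100)),
                   c(0L, 0L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L))
  # total and deterministic over a fine grid, for arbitrary valid cutpoints
  g <- remuzzi_if_grade(seq(0, 100, by = 0.25), cutpoints = c(3, 25, 60))
  expect_true(all(g %in% 0:3))
  expect_true(all(diff(g) >= 0))
  expect_error(remuzzi_if_grade(10, cutpoints = c(20, 5, 50)), "increasing")
  expect_error(remuzzi_if_grade(10, cutpoints = c(0, 20, 50)), "increasing")
})
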