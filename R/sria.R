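# SRIA measurement: stained pixels as a percentage of the analysed cortex.

#' Measure the Sirius red-stained interstitial area of a section
#'
#' Counts pixels with `channel >= threshold` inside the cortex after
#' removing exclusion regions (glomeruli, vessels, folds).  Polygons
#' include a pixel iff the pixel centre lies inside (0-based coordinates,
#' x right, y down).
#'
#' @param channel Collagen intensity matrix from [collagen_channel()].
#' @param threshold Classification threshold in \[0, 1\].
#' @param image The `srq_section` the channel was computed from (supplies
#'   calibration and annotations).
#' @param channel_method Method label recorded in the result.
#' @return Object of class `"srq_sria"` with fields `stained_px`,
#'   `cortex_px`, `fraction_pct`, `threshold`, `analysed_area_mm2`,
#'   `channel_method`, `biopsy_id`, `section_kind`.
#' @export
compute_sria <- function(channel, threshold, image,
                         channel_method = "deconvolution") {
  stopifnot_scalar_number(threshold, "threshold", 0, 1)
  if (!inherits(image, "srq_section"))
    stop("`image` must be an srq_section", call. = FALSE)
  if (!identical(dim(channel), dim(image$pixels)[1:2]))
    stop("channel dimensions do not match the image", call. = FALSE)
  masks <- section_masks(image)
  cortex_px <- sum(masks$effective)
  if (cortex_px == 0L)
    stop("effective cortex is empty after exclusions", call. = FALSE)
  stained_px <- sum(channel >= threshold & masks$effective)
  structure(list(
    stained_px = stained_px,
    cortex_px = cortex_px,
    fraction_pct = 100 * stained_px / cortex_px,
    threshold = threshold,
    analysed_area_mm2 = cortex_px * image$microns_per_pixel^2 / 1e6,
    channel_method = channel_method,
    biopsy_id = image$biopsy_id,
    section_kind = image$section_kind), class = "srq_sria")
}

#' @export
print.srq_sria <- function(x, ...) {
  cat(sprintf("<srq_sria> %s [%s]: SRIA %.2f%% (%d / %d px, %.2f mm2, threshold %.3f, %s)\n",
              x$biopsy_id, x$section_kind, x$fraction_pct, x$stained_px,
              x$cortex_px, x$analysed_area_mm2, x$threshold, x$channel_method))
  invisible(x)
}

#' Quantify one section end to end
#'
#' Convenience wrapper: colour separation, threshold selection over the
#' effective cortex, then [compute_sria()].
#'
#' @inheritParams collagen_channel
#' @param threshold `"otsu"` or a fixed numeric threshold in \[0, 1\].
#' @return An `srq_sria`.
#' @export
quantify_section <- function(image, method = c("deconvolution", "hue_saturation"),
                             threshold = "otsu") {
  method <- match.arg(method)
  ch <- collagen_channel(image, method)
  masks <- section_masks(image)
  thr <- if (identical(threshold, "otsu"))
    select_threshold(ch, masks$effective, "otsu")
  else select_threshold(ch, masks$effective, "fixed", fixed_value = threshold)
  compute_sria(ch, thr, image, channel_method = method)
}

#' Quantify a frozen/paraffin section pair
#'
#' The default threshold policy follows per-pair thresholding: one Otsu
#' threshold is computed on the pooled masked intensities of both members
#' and applied to each.  Per-section (`pooled = FALSE`) and fixed-value
#' thresholds are available as overrides.
#'
#' @param frozen,paraffin `srq_section` objects of one biopsy.
#' @param method Colour-separation method.
#' @param threshold `"otsu"` or a fixed numeric value.
#' @param pooled Pool both members' masked intensities for one common Otsu
#'   threshold (default) or threshold each member separately.
#' @param covariates Optional named list of donor covariates
#'   (`donor_age`, `donor_male`, `donor_type`, `cit_hours`) carried on the
#'   pair.
#' @param original_if_frozen,original_if_paraffin Optional pathologist IF
#'   grades (0-3) from the original reports.
#' @return Object of class `"srq_pair"`.
#' @export
quantify_pair <- function(frozen, paraffin,
                          method = c("deconvolution", "hue_saturation"),
                          threshold = "otsu", pooled = TRUE,
                          covariates = list(),
                          original_if_frozen = NA_integer_,
                          original_if_paraffin = NA_integer_) {
  method <- match.arg(method)
  if (!identical(frozen$biopsy_id, paraffin$biopsy_id))
    stop("frozen and paraffin members have different biopsy ids", call. = FALSE)
  if (frozen$section_kind != "frozen" || paraffin$section_kind != "paraffin")
    stop("section kinds must be frozen and paraffin as named", call. = FALSE)
  ch_f <- collagen_channel(frozen, method)
  ch_p <- collagen_channel(paraffin, method)
  m_f <- section_masks(frozen); m_p <- section_masks(paraffin)
  if (identical(threshold, "otsu")) {
    if (pooled) {
      pool <- c(ch_f[m_f$effective], ch_p[m_p$effective])
      thr_f <- thr_p <- select_threshold(matrix(pool, ncol = 1L), NULL, "otsu")
    } else {
      thr_f <- select_threshold(ch_f, m_f$effective, "otsu")
      thr_p <- select_threshold(ch_p, m_p$effective, "otsu")
    }
  } else {
    thr_f <- thr_p <- select_threshold(ch_f, NULL, "fixed", fixed_value = threshold)
  }
  structure(list(
    frozen = compute_sria(ch_f, thr_f, frozen, method),
    paraffin = compute_sria(ch_p, thr_p, paraffin, method),
    original_if_frozen = original_if_frozen,
    original_if_paraffin = original_if_paraffin,
    covariates = covariates,
    included = NA, exclusion_reason = NA_character_), class = "srq_pair")
}

#' Apply the minimum-analysed-area inclusion rule to a pair
#'
#' A pair is analysable only if both members offer at least `min_area_mm2`
#' of analysed cortex (boundary inclusive); the default reproduces the
#' 1 mm^2 rule used for real section pairs.
#'
#' @param pair An `srq_pair`.
#' @param min_area_mm2 Minimum analysed area per member, mm^2.
#' @return The pair with `included` and `exclusion_reason` set.
#' @export
check_pair_inclusion <- function(pair, min_area_mm2 = 1.0) {
  if (!inherits(pair, "srq_pair")) stop("`pair` must be an srq_pair", call. = FALSE)
  if (is.null(pair$frozen) || is.null(pair$paraffin))
    stop("pair is missing a measurement", call. = FALSE)
  a <- min(pair$frozen$analysed_area_mm2, pair$paraffin$analysed_area_mm2)
  pair$included <- a >= min_area_mm2
  pair$exclusion_reason <- if (pair$included) NA_character_ else
    sprintf("analysed area below %g mm2", min_area_mm2)
  pair
}

#' @export
print.srq_pair <- function(x, ...) {
  cat(sprintf("<srq_pair> %s: frozen %.2f%% vs paraffin %.2f%% (diff %+0.2f pp)%s\n",
              x$frozen$biopsy_id, x$frozen$fraction_pct, x$paraffin$fraction_pct,
              x$frozen$fraction_pct - x$paraffin$fraction_pct,
              if (isTRUE(x$included)) ", included"
              else if (isFALSE(x$included)) paste0(", EXCLUDED: ", x$exclusion_reason)
              else ""))
  invisible(x)
}

#' Translate a fibrosis percentage into the Remuzzi IF grade
#'
#' Step function: grade 0 for `fraction < c1`, 1 for `c1 <= fraction < c2`,
#' 2 for `c2 <= fraction < c3`, 3 otherwise.  The default cutpoints
#' (5, 20, 50)% are package defaults — the percentage boundaries behind the
#' published semi-quantitative grade are not standardised — and should be
#' set explicitly when a centre uses different ones.
#'
#' @param fraction_pct Numeric vector of fibrosis percentages.
#' @param cutpoints Strictly increasing triple inside (0, 100).
#' @return Integer vector of grades in 0..3.
#' @export
remuzzi_if_grade <- function(fraction_pct, cutpoints = c(5, 20, 50)) {
  if (length(cutpoints) != 3L || any(diff(cutpoints) <= 0) ||
      cutpoints[1L] <= 0 || cutpoints[3L] >= 100)
    stop("`cutpoints` must be strictly increasing within (0, 100)", call. = FALSE)
  if (any(fraction_pct < 0 | fraction_pct > 100, na.rm = TRUE))
    stop("fractions must lie in [0, 100]", call. = FALSE)
  findInterval(fraction_pct, cutpoints)
}

#' Flatten quantified pairs into the per-pair analysis table
#'
#' @param pairs List of `srq_pair` objects.
#' @param cutpoints Remuzzi IF cutpoints for the translated grades.
#' @return Data frame with one row per pair: SRIA values, difference,
#'   analysed areas, inclusion flag, translated and original IF grades, and
#'   donor covariates.
#' @export
pairs_table <- function(pairs, cutpoints = c(5, 20, 50)) {
  rows <- lapply(pairs, function(p) {
    cov <- p$covariates
    data.frame(
      biopsy_id = p$frozen$biopsy_id,
      sria_frozen = p$frozen$fraction_pct,
      sria_paraffin = p$paraffin$fraction_pct,
      diff = p$frozen$fraction_pct - p$paraffin$fraction_pct,
      area_frozen_mm2 = p$frozen$analysed_area_mm2,
      area_paraffin_mm2 = p$paraffin$analysed_area_mm2,
      included = p$included,
      exclusion_reason = p$exclusion_reason,
      if_frozen = remuzzi_if_grade(p$frozen$fraction_pct, cutpoints),
      if_paraffin = remuzzi_if_grade(p$paraffin$fraction_pct, cutpoints),
      original_if_frozen = p$original_if_frozen,
      original_if_paraffin = p$original_if_paraffin,
      donor_age = if (!is.null(cov$donor_age)) cov$donor_age else NA_real_,
      donor_male = if (!is.null(cov$donor_male)) cov$donor_male else NA,
      donor_type = if (!is.null(cov$donor_type)) cov$donor_type else NA_character_,
      cit_hours = if (!is.null(cov$cit_hours)) cov$cit_hours else NA_real_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
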