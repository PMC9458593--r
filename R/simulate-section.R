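# Synthetic Sirius red histology.
#
# The generator emits paired frozen/paraffin cortex images with pixel-exact
# ground truth.  Collagen geometry is a thresholded smoothed Gaussian random
# field inside the analysed cortex; the threshold is the order statistic
# that lands the target area fraction exactly.  The frozen-section artefact
# is modelled as (a) morphological dilation of the paraffin collagen
# skeleton until the stained fraction reaches truth + frozen_delta_pct
# (an additive, not proportional, inflation), (b) elliptical white
# ice-crystal holes and (c) a 20% blend of all tissue colours toward the
# tissue mean (stain-contrast loss).

.srq_colors <- list(collagen  = c(185L, 40L, 55L),   # Sirius red
                    background = c(230L, 205L, 110L),  # picric yellow
                    tuft       = c(200L, 90L, 80L),
                    white      = c(255L, 255L, 255L))

#' Configuration for one simulated frozen/paraffin section pair
#'
#' Defaults give a 2048 x 2048 field at 1 um/px (about 4.2 mm^2), so the
#' 1 mm^2 minimum-analysed-area rule is exercisable, and an additive frozen
#' artefact of +7.8 percentage points, the mean frozen-vs-paraffin
#' inflation reported for real section pairs.
#'
#' @param width_px,height_px Image size in pixels.
#' @param microns_per_pixel Calibration, um per pixel.
#' @param true_fraction_pct Target collagen area percentage of the analysed
#'   cortex in the paraffin member, in \[0, 100\].
#' @param frozen_delta_pct Additive inflation (percentage points) applied to
#'   the frozen member; `true_fraction_pct + frozen_delta_pct` must stay in
#'   \[0, 100\].
#' @param ice_crystal_density Ice-crystal holes per mm^2 of cortex in the
#'   frozen member.
#' @param n_glomeruli,n_vessels Number of renal corpuscles / prominent
#'   vessels embedded (each is also emitted as an exclusion annotation).
#' @param field_scale_um Correlation length of the collagen random field, um.
#' @param seed Integer seed; identical config + seed is bit-reproducible.
#' @return Object of class `"srq_sim_config"`.
#' @export
section_sim_config <- function(width_px = 2048L, height_px = 2048L,
                               microns_per_pixel = 1,
                               true_fraction_pct = 30,
                               frozen_delta_pct = 7.8,
                               ice_crystal_density = 2,
                               n_glomeruli = 3L, n_vessels = 1L,
                               field_scale_um = 10,
                               seed = 1L) {
  stopifnot_scalar_number(width_px, "width_px", 8)
  stopifnot_scalar_number(height_px, "height_px", 8)
  stopifnot_scalar_number(microns_per_pixel, "microns_per_pixel", 1e-9)
  stopifnot_scalar_number(true_fraction_pct, "true_fraction_pct", 0, 100)
  stopifnot_scalar_number(frozen_delta_pct, "frozen_delta_pct", -100, 100)
  if (true_fraction_pct + frozen_delta_pct < 0 ||
      true_fraction_pct + frozen_delta_pct > 100)
    stop("true_fraction_pct + frozen_delta_pct must lie in [0, 100]",
         call. = FALSE)
  stopifnot_scalar_number(ice_crystal_density, "ice_crystal_density", 0)
  stopifnot_scalar_number(n_glomeruli, "n_glomeruli", 0)
  stopifnot_scalar_number(n_vessels, "n_vessels", 0)
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 microns_per_pixel = microns_per_pixel,
                 true_fraction_pct = true_fraction_pct,
                 frozen_delta_pct = frozen_delta_pct,
                 ice_crystal_density = ice_crystal_density,
                 n_glomeruli = as.integer(n_glomeruli),
                 n_vessels = as.integer(n_vessels),
                 field_scale_um = field_scale_um,
                 seed = as.integer(seed)),
            class = "srq_sim_config")
}

# --- low-level raster helpers -------------------------------------------

# 8-neighbourhood (3x3 box) dilation, separable: horizontal then vertical.
dilate3x3 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  x <- m
  x[, -1L] <- x[, -1L, drop = FALSE] | m[, -w, drop = FALSE]
  x[, -w] <- x[, -w, drop = FALSE] | m[, -1L, drop = FALSE]
  out <- x
  out[-1L, ] <- out[-1L, , drop = FALSE] | x[-h, , drop = FALSE]
  out[-h, ] <- out[-h, , drop = FALSE] | x[-1L, , drop = FALSE]
  out
}

erode3x3 <- function(m) !dilate3x3(!m)

# iterated erosion restricted to the mask's bounding box (structures are
# small relative to the field; avoids repeated full-image passes)
erode_iter <- function(m, iters) {
  idx <- which(m, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(m)
  r0 <- max(1L, min(idx[, 1L]) - 1L); r1 <- min(nrow(m), max(idx[, 1L]) + 1L)
  c0 <- max(1L, min(idx[, 2L]) - 1L); c1 <- min(ncol(m), max(idx[, 2L]) + 1L)
  sub <- m[r0:r1, c0:c1, drop = FALSE]
  for (k in seq_len(iters)) sub <- erode3x3(sub)
  out <- m & FALSE
  out[r0:r1, c0:c1] <- sub
  out
}

# Smoothed periodic Gaussian random field, unit-variance white noise input.
gaussian_field <- function(h, w, sigma_px) {
  noise <- matrix(stats::rnorm(h * w), h, w)
  fy <- seq_len(h) - 1L; fy <- ifelse(fy > h / 2, fy - h, fy) / h
  fx <- seq_len(w) - 1L; fx <- ifelse(fx > w / 2, fx - w, fx) / w
  transfer <- exp(-2 * pi^2 * sigma_px^2 * outer(fy^2, fx^2, `+`))
  Re(stats::fft(stats::fft(noise) * transfer, inverse = TRUE)) / (h * w)
}

# Grow (or shrink) a collagen mask inside `allowed` until it has exactly
# `target` pixels; the final partial ring/shell is subsampled at random.
resize_mask_to_count <- function(mask, allowed, target) {
  count <- sum(mask)
  while (count < target) {
    ring <- dilate3x3(mask) & allowed & !mask
    n_ring <- sum(ring)
    if (n_ring == 0L)
      stop("cannot reach target stained fraction: dilation saturated",
           call. = FALSE)
    if (count + n_ring <= target) {
      mask <- mask | ring
    } else {
      idx <- which(ring)
      mask[idx[sample.int(n_ring, target - count)]] <- TRUE
    }
    count <- sum(mask)
  }
  while (count > target) {
    shell <- mask & !erode3x3(mask)        # boundary pixels of the mask
    n_shell <- sum(shell)
    if (n_shell == 0L) stop("cannot shrink mask further", call. = FALSE)
    if (count - n_shell >= target) {
      mask <- mask & !shell
    } else {
      idx <- which(shell)
      mask[idx[sample.int(n_shell, count - target)]] <- FALSE
    }
    count <- sum(mask)
  }
  mask
}

# Irregular smooth blob polygon for the cortex region.
cortex_blob_polygon <- function(w, h, n = 96L) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  r0 <- 0.44 * min(w, h)
  wig <- numeric(n)
  for (k in 2:4)
    wig <- wig + stats::runif(1, 0.02, 0.06) *
      cos(k * t + stats::runif(1, 0, 2 * pi))
  r <- r0 * (1 + wig)
  annotation_polygon(w / 2 + r * cos(t), h / 2 + r * sin(t), role = "cortex")
}

render_section <- function(collagen, cortex, glom_polys, vessel_polys,
                           holes, contrast_blend, w, h) {
  n <- h * w
  px <- matrix(255L, n, 3L)                       # slide background: white
  cor_idx <- which(cortex)
  px[cor_idx, ] <- rep(.srq_colors$background, each = length(cor_idx))
  col_idx <- which(collagen)
  px[col_idx, ] <- rep(.srq_colors$collagen, each = length(col_idx))
  for (p in glom_polys) {
    m <- rasterize_polygon(p, w, h)
    # Bowman capsule space renders white; the tuft a muted red blend
    inner <- erode_iter(m, 6L)
    ring_idx <- which(m & !inner); tuft_idx <- which(inner)
    px[ring_idx, ] <- rep(.srq_colors$white, each = length(ring_idx))
    px[tuft_idx, ] <- rep(.srq_colors$tuft, each = length(tuft_idx))
  }
  for (p in vessel_polys) {
    m <- rasterize_polygon(p, w, h)
    inner <- erode_iter(m, 4L)
    wall_idx <- which(m & !inner); lum_idx <- which(inner)
    px[wall_idx, ] <- rep(.srq_colors$collagen, each = length(wall_idx))
    px[lum_idx, ] <- rep(.srq_colors$white, each = length(lum_idx))
  }
  if (contrast_blend > 0) {
    tis_idx <- which(cortex)
    mean_col <- colMeans(px[tis_idx, , drop = FALSE])
    px[tis_idx, ] <- (1 - contrast_blend) * px[tis_idx, , drop = FALSE] +
      contrast_blend * rep(mean_col, each = length(tis_idx))
  }
  hole_idx <- which(holes)
  if (length(hole_idx))
    px[hole_idx, ] <- rep(.srq_colors$white, each = length(hole_idx))
  px <- round(px + matrix(sample(-10:10, n * 3L, replace = TRUE), n, 3L))
  px[px < 0] <- 0; px[px > 255] <- 255
  array(as.integer(px), dim = c(h, w, 3L))
}

ground_truth <- function(collagen, cortex, exclusions) {
  eff <- cortex & !exclusions$any
  structure(list(collagen_mask = collagen, cortex_mask = cortex,
                 exclusion_masks = exclusions$by_role,
                 realised_fraction_pct = 100 * sum(collagen & eff) / sum(eff)),
            class = "srq_truth")
}

#' Simulate one frozen/paraffin section pair with ground truth
#'
#' The paraffin member realises `true_fraction_pct` exactly (to one pixel in
#' the analysed cortex); the frozen member realises
#' `true_fraction_pct + frozen_delta_pct` by dilating the same collagen
#' skeleton, carries elliptical white ice-crystal holes, and has its stain
#' contrast reduced by a 20% blend toward the tissue mean colour.  Both
#' members share the cortex and exclusion annotations, mirroring adjacent
#' sections of one biopsy core.
#'
#' @param config A [section_sim_config()].
#' @param biopsy_id Identifier stamped on both sections.
#' @return List with elements `frozen`, `paraffin` (class `srq_section`),
#'   `frozen_truth`, `paraffin_truth` (class `srq_truth`).
#' @export
simulate_section_pair <- function(config, biopsy_id = "sim") {
  if (!inherits(config, "srq_sim_config"))
    stop("`config` must come from section_sim_config()", call. = FALSE)
  with_local_seed(config$seed, {
    w <- config$width_px; h <- config$height_px
    mpp <- config$microns_per_pixel
    cortex_poly <- cortex_blob_polygon(w, h)
    cortex <- rasterize_polygon(cortex_poly, w, h)
    if (!any(cortex)) stop("zero cortex area", call. = FALSE)
    cx0 <- w / 2; cy0 <- h / 2; r_place <- 0.30 * min(w, h)

    glom_polys <- list()
    if (config$n_glomeruli > 0L) for (g in seq_len(config$n_glomeruli)) {
      ang <- stats::runif(1, 0, 2 * pi); rad <- stats::runif(1, 0.2, 1) * r_place
      r_g <- stats::runif(1, 60, 110) / mpp
      glom_polys[[g]] <- ellipse_polygon(cx0 + rad * cos(ang),
                                         cy0 + rad * sin(ang),
                                         r_g, r_g, role = "glomerulus",
                                         id = sprintf("glom-%d", g))
    }
    vessel_polys <- list()
    if (config$n_vessels > 0L) for (v in seq_len(config$n_vessels)) {
      ang <- stats::runif(1, 0, 2 * pi); rad <- stats::runif(1, 0.2, 1) * r_place
      vessel_polys[[v]] <- ellipse_polygon(cx0 + rad * cos(ang),
                                           cy0 + rad * sin(ang),
                                           stats::runif(1, 80, 140) / mpp,
                                           stats::runif(1, 40, 70) / mpp,
                                           role = "vessel",
                                           angle = stats::runif(1, 0, pi),
                                           id = sprintf("vessel-%d", v))
    }
    excl_by_role <- list(
      glomerulus = Reduce(`|`, lapply(glom_polys, rasterize_polygon, w, h),
                          matrix(FALSE, h, w)),
      vessel = Reduce(`|`, lapply(vessel_polys, rasterize_polygon, w, h),
                      matrix(FALSE, h, w)),
      fold = matrix(FALSE, h, w))
    exclusions <- list(by_role = excl_by_role,
                       any = excl_by_role$glomerulus | excl_by_role$vessel)
    effective <- cortex & !exclusions$any
    n_eff <- sum(effective)
    if (n_eff == 0L) stop("zero analysed cortex area", call. = FALSE)

    # paraffin collagen: top-k order statistic of the smoothed field
    field <- gaussian_field(h, w, config$field_scale_um / mpp)
    k_par <- round(config$true_fraction_pct / 100 * n_eff)
    collagen_p <- matrix(FALSE, h, w)
    if (k_par > 0L) {
      eff_idx <- which(effective)
      ord <- eff_idx[order(field[eff_idx], decreasing = TRUE)[seq_len(k_par)]]
      collagen_p[ord] <- TRUE
    }

    # frozen member: ice-crystal holes, then dilation to the inflated target
    area_mm2 <- sum(cortex) * mpp^2 / 1e6
    n_holes <- round(config$ice_crystal_density * area_mm2)
    holes <- matrix(FALSE, h, w)
    if (n_holes > 0L) for (k in seq_len(n_holes)) {
      ang <- stats::runif(1, 0, 2 * pi); rad <- stats::runif(1, 0, 0.95) * r_place
      hp <- ellipse_polygon(cx0 + rad * cos(ang), cy0 + rad * sin(ang),
                            stats::runif(1, 15, 40) / mpp,
                            stats::runif(1, 10, 25) / mpp,
                            role = "fold", angle = stats::runif(1, 0, pi))
      holes <- holes | rasterize_polygon(hp, w, h)
    }
    holes <- holes & cortex
    k_fro <- round((config$true_fraction_pct + config$frozen_delta_pct) / 100 * n_eff)
    collagen_f <- if (k_fro == 0L) matrix(FALSE, h, w) else
      resize_mask_to_count(collagen_p & !holes, effective & !holes, k_fro)

    anns <- c(list(cortex_poly), glom_polys, vessel_polys)
    par_img <- render_section(collagen_p, cortex, glom_polys, vessel_polys,
                              holes = matrix(FALSE, h, w), contrast_blend = 0,
                              w, h)
    fro_img <- render_section(collagen_f, cortex, glom_polys, vessel_polys,
                              holes = holes, contrast_blend = 0.2, w, h)
    list(frozen = section_image(fro_img, mpp, "frozen", anns, biopsy_id),
         paraffin = section_image(par_img, mpp, "paraffin", anns, biopsy_id),
         frozen_truth = ground_truth(collagen_f, cortex, exclusions),
         paraffin_truth = ground_truth(collagen_p, cortex, exclusions))
  })
}
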