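# Colour separation: stained-collagen intensity channel from an RGB raster.
#
# Two interchangeable methods:
#  * "deconvolution" — two-stain optical-density unmixing in the style of
#    Ruifrok & Johnston: RGB is converted to optical density, projected onto
#    a stain basis (Sirius red collagen vector, picric-yellow background
#    vector, their complement), and the collagen concentration is rescaled
#    so a pure collagen pixel maps to 1 and unstained white to 0.
#  * "hue_saturation" — HSV gating: saturation weighted by closeness of the
#    hue to the red pole (hue 0), which separates red collagen from the
#    yellow counter-stain.

# unit optical-density vector of an 8-bit RGB colour
.od_vector <- function(rgb) {
  od <- -log10((rgb + 1) / 256)
  od / sqrt(sum(od^2))
}

# default stain basis: rows = unit OD vectors (collagen, background, residual)
.stain_basis <- function(collagen_rgb = c(185, 40, 55),
                         background_rgb = c(230, 205, 110)) {
  v1 <- .od_vector(collagen_rgb)
  v2 <- .od_vector(background_rgb)
  v3 <- c(v1[2] * v2[3] - v1[3] * v2[2],
          v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  v3 <- v3 / sqrt(sum(v3^2))
  rbind(v1, v2, v3)
}

#' Extract the collagen intensity channel from a section image
#'
#' @param image An `srq_section` (or a bare `height x width x 3` array).
#' @param method `"deconvolution"` (default) or `"hue_saturation"`.
#' @return Numeric `height x width` matrix in \[0, 1\]; higher values mean
#'   stronger Sirius red signal.  Deterministic; dimensions equal the input.
#' @export
collagen_channel <- function(image, method = c("deconvolution", "hue_saturation")) {
  method <- match.arg(method)
  pixels <- if (inherits(image, "srq_section")) image$pixels else image
  d <- dim(pixels)
  if (length(d) != 3L || d[3L] != 3L)
    stop("image must be a height x width x 3 RGB raster", call. = FALSE)
  h <- d[1L]; w <- d[2L]; n <- h * w
  px <- matrix(as.numeric(pixels), n, 3L)
  if (method == "deconvolution") {
    od <- -log10((px + 1) / 256)
    basis <- .stain_basis()
    conc <- od %*% solve(basis)           # per-pixel stain concentrations
    # rescale so a pure collagen pixel has channel 1
    ref <- sqrt(sum((-log10((c(185, 40, 55) + 1) / 256))^2))
    ch <- clamp(conc[, 1L] / ref, 0, 1)
  } else {
    hsv <- grDevices::rgb2hsv(t(px), maxColorValue = 255)
    hdist <- pmin(hsv[1L, ], 1 - hsv[1L, ])       # circular distance to red
    ch <- clamp(hsv[2L, ] * pmax(0, 1 - hdist / 0.12), 0, 1)
    ch[hsv[2L, ] == 0] <- 0                        # greys carry no stain
  }
  matrix(ch, h, w)
}

#' Select an intensity threshold over a masked region
#'
#' Otsu's method on a 256-bin histogram of the masked channel values:
#' returns the boundary maximising between-class variance (the midpoint of
#' the plateau when several splits tie).  Pixels with
#' `channel >= threshold` are classified as stained.
#'
#' @param channel Numeric matrix in \[0, 1\].
#' @param mask Logical matrix of the same size selecting analysed pixels;
#'   `NULL` uses all pixels.
#' @param method `"otsu"` or `"fixed"`.
#' @param fixed_value Threshold returned unchanged when `method = "fixed"`.
#' @return A single threshold in \[0, 1\].
#' @export
select_threshold <- function(channel, mask = NULL,
                             method = c("otsu", "fixed"), fixed_value = NULL) {
  method <- match.arg(method)
  if (method == "fixed") {
    if (is.null(fixed_value))
      stop("method = \"fixed\" needs `fixed_value`", call. = FALSE)
    stopifnot_scalar_number(fixed_value, "fixed_value", 0, 1)
    return(fixed_value)
  }
  v <- if (is.null(mask)) as.numeric(channel) else channel[mask]
  if (length(v) < 2L || diff(range(v)) == 0)
    stop("masked intensities are constant; use method = \"fixed\" with a fixed_value",
         call. = FALSE)
  bins <- pmin(floor(v * 256), 255)
  counts <- tabulate(bins + 1L, nbins = 256L)
  p <- counts / sum(counts)
  omega <- cumsum(p)
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256L]
  k <- 1:255
  denom <- omega[k] * (1 - omega[k])
  sigma_b <- ifelse(denom > 0, (mu_t * omega[k] - mu[k])^2 / denom, -Inf)
  best <- which(sigma_b >= max(sigma_b) - 1e-12)
  (mean(best)) / 256         # split after bin k => boundary at k/256
}
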