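# Polygon handling for region-of-interest annotations.
#
# Coordinate convention (documented so annotation files are portable):
# 0-based pixel coordinates, x to the right, y down.  The pixel at matrix
# position [row i, col j] (1-based in R) has its centre at
# (x, y) = (j - 0.5, i - 0.5).  A polygon includes a pixel iff the pixel
# centre lies inside it (even-odd rule).

#' Create a labelled annotation polygon
#'
#' @param x,y Numeric vertex coordinates (0-based pixel units, x right,
#'   y down).  The polygon is closed implicitly.
#' @param role Region role: `"cortex"` (inclusion) or one of the exclusion
#'   roles `"glomerulus"`, `"vessel"`, `"fold"`.
#' @param id Optional identifier carried into GeoJSON properties.
#' @return An object of class `"srq_polygon"`.
#' @export
annotation_polygon <- function(x, y, role = c("cortex", "glomerulus", "vessel", "fold"),
                               id = NULL) {
  role <- match.arg(role)
  if (length(x) != length(y) || length(x) < 3L)
    stop("a polygon needs at least 3 vertices with matching x/y", call. = FALSE)
  structure(list(x = as.numeric(x), y = as.numeric(y), role = role, id = id),
            class = "srq_polygon")
}

#' Rasterise an annotation polygon
#'
#' Even-odd scanline rasterisation: a pixel is covered iff its centre lies
#' inside the polygon (0-based coordinates, x right, y down; the pixel at
#' matrix position \[i, j\] has centre (j - 0.5, i - 0.5)).
#'
#' @param poly An [annotation_polygon()].
#' @param width,height Raster size in pixels.
#' @return Logical `height x width` matrix.
#' @export
rasterize_polygon <- function(poly, width, height) {
  x <- poly$x; y <- poly$y
  n <- length(x)
  mask <- matrix(FALSE, nrow = height, ncol = width)
  x2 <- c(x[-1L], x[1L]); y2 <- c(y[-1L], y[1L])
  ylo <- pmin(y, y2); yhi <- pmax(y, y2)
  rows <- max(1L, floor(min(ylo) + 0.5) + 1L):min(height, ceiling(max(yhi) - 0.5) + 1L)
  if (rows[1L] > rows[length(rows)]) return(mask)
  for (i in rows) {
    yc <- i - 0.5
    # edges straddling the scanline (half-open rule avoids double-count at vertices)
    hit <- (y <= yc & y2 > yc) | (y2 <= yc & y > yc)
    if (!any(hit)) next
    xs <- x[hit] + (yc - y[hit]) * (x2[hit] - x[hit]) / (y2[hit] - y[hit])
    xs <- sort(xs)
    for (k in seq(1L, length(xs) - 1L, by = 2L)) {
      j1 <- floor(xs[k] + 0.5) + 1L        # first pixel whose centre > xs[k]
      j2 <- ceiling(xs[k + 1L] - 0.5)      # last pixel whose centre < xs[k+1]
      if (j2 >= j1) {
        j1 <- max(1L, j1); j2 <- min(width, j2)
        if (j2 >= j1) mask[i, j1:j2] <- TRUE
      }
    }
  }
  mask
}

# Rasterise a list of polygons with a given role into one mask (union).
rasterize_role <- function(annotations, role, width, height) {
  mask <- matrix(FALSE, nrow = height, ncol = width)
  for (p in annotations) if (p$role == role)
    mask <- mask | rasterize_polygon(p, width, height)
  mask
}

#' Elliptical annotation polygon
#'
#' Regular 64-gon approximation of an ellipse, as used by the simulator for
#' glomerulus, vessel and ice-crystal outlines.
#'
#' @param cx,cy Centre (0-based pixel coordinates).
#' @param rx,ry Semi-axes in pixels.
#' @param role,id Passed to [annotation_polygon()].
#' @param angle Rotation in radians.
#' @param n Number of vertices.
#' @return An `srq_polygon`.
#' @export
ellipse_polygon <- function(cx, cy, rx, ry, role, angle = 0, n = 64L, id = NULL) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  x0 <- rx * cos(t); y0 <- ry * sin(t)
  annotation_polygon(cx + x0 * cos(angle) - y0 * sin(angle),
                     cy + x0 * sin(angle) + y0 * cos(angle),
                     role = role, id = id)
}

#' Write annotations to a GeoJSON FeatureCollection
#'
#' Each polygon becomes a Feature with a `"role"` property; coordinates are
#' 0-based pixel units (x right, y down).
#'
#' @param annotations List of [annotation_polygon()] objects.
#' @param path Output file path.
#' @export
write_annotations <- function(annotations, path) {
  feats <- lapply(annotations, function(p) {
    ring <- cbind(p$x, p$y)
    ring <- rbind(ring, ring[1L, , drop = FALSE])  # closed ring per GeoJSON
    list(type = "Feature",
         properties = c(list(role = p$role), if (!is.null(p$id)) list(id = p$id)),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  obj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read annotations from a GeoJSON FeatureCollection
#'
#' @param path GeoJSON file written by [write_annotations()] or compatible
#'   (Polygon geometries with a `role` property).
#' @return List of [annotation_polygon()] objects.
#' @export
read_annotations <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$type, "FeatureCollection"))
    stop("not a GeoJSON FeatureCollection: ", path, call. = FALSE)
  lapply(obj$features, function(f) {
    if (!identical(f$geometry$type, "Polygon"))
      stop("only Polygon geometries are supported", call. = FALSE)
    ring <- f$geometry$coordinates[[1L]]
    xy <- do.call(rbind, lapply(ring, function(pt) c(pt[[1L]], pt[[2L]])))
    # drop the closing vertex if present
    n <- nrow(xy)
    if (n > 1L && all(xy[1L, ] == xy[n, ])) xy <- xy[-n, , drop = FALSE]
    annotation_polygon(xy[, 1L], xy[, 2L], role = f$properties$role,
                       id = f$properties$id)
  })
}
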