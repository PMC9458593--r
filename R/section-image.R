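#' Calibrated section image
#'
#' Bundles the RGB raster of one stained biopsy section with its spatial
#' calibration and region annotations.  Exactly one `"cortex"` inclusion
#' polygon (possibly several polygons forming a multi-region) must be
#' present before quantification; exclusion polygons (`"glomerulus"`,
#' `"vessel"`, `"fold"`) are optional.
#'
#' @param pixels Integer array `height x width x 3`, values 0..255.
#' @param microns_per_pixel Positive calibration in micrometres per pixel.
#' @param section_kind `"frozen"` or `"paraffin"`.
#' @param annotations List of [annotation_polygon()] objects.
#' @param biopsy_id Identifier linking the two members of a section pair.
#' @return Object of class `"srq_section"`.
#' @export
section_image <- function(pixels, microns_per_pixel,
                          section_kind = c("paraffin", "frozen"),
                          annotations = list(), biopsy_id = "biopsy") {
  section_kind <- match.arg(section_kind)
  d <- dim(pixels)
  if (length(d) != 3L || d[3L] != 3L)
    stop("`pixels` must be a height x width x 3 array", call. = FALSE)
  stopifnot_scalar_number(microns_per_pixel, "microns_per_pixel", lo = 1e-9)
  structure(list(pixels = pixels, microns_per_pixel = microns_per_pixel,
                 section_kind = section_kind, annotations = annotations,
                 biopsy_id = as.character(biopsy_id)),
            class = "srq_section")
}

#' @export
print.srq_section <- function(x, ...) {
  d <- dim(x$pixels)
  roles <- vapply(x$annotations, `[[`, "", "role")
  cat(sprintf("<srq_section> %s [%s] %dx%d px @ %.3g um/px; annotations: %s\n",
              x$biopsy_id, x$section_kind, d[2L], d[1L], x$microns_per_pixel,
              if (length(roles)) paste(names(table(roles)), table(roles),
                                       sep = ":", collapse = ", ") else "none"))
  invisible(x)
}

#' Write a section image to disk
#'
#' Emits three sibling files: `<stem>.tif` (uncompressed RGB TIFF),
#' `<stem>.json` (calibration/provenance sidecar) and `<stem>.geojson`
#' (annotations).
#'
#' @param section An `srq_section`.
#' @param stem Path stem without extension.
#' @param extra Optional named list merged into the JSON sidecar
#'   (e.g. simulation seed and config for provenance).
#' @return The stem, invisibly.
#' @export
write_section_image <- function(section, stem, extra = list()) {
  write_rgb_tiff(section$pixels, paste0(stem, ".tif"))
  sidecar <- c(list(microns_per_pixel = section$microns_per_pixel,
                    section_kind = section$section_kind,
                    biopsy_id = section$biopsy_id), extra)
  jsonlite::write_json(sidecar, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  write_annotations(section$annotations, paste0(stem, ".geojson"))
  invisible(stem)
}

#' Read a section image written by [write_section_image()]
#'
#' @param stem Path stem without extension (expects `<stem>.tif`,
#'   `<stem>.json`, `<stem>.geojson`).
#' @return An `srq_section`.
#' @export
read_section_image <- function(stem) {
  pixels <- read_rgb_tiff(paste0(stem, ".tif"))
  sidecar <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  ann_path <- paste0(stem, ".geojson")
  anns <- if (file.exists(ann_path)) read_annotations(ann_path) else list()
  section_image(pixels, sidecar$microns_per_pixel,
                section_kind = sidecar$section_kind,
                annotations = anns, biopsy_id = sidecar$biopsy_id)
}

# Effective analysis masks for one section: cortex minus exclusions.
section_masks <- function(section) {
  d <- dim(section$pixels); h <- d[1L]; w <- d[2L]
  roles <- vapply(section$annotations, `[[`, "", "role")
  if (!any(roles == "cortex"))
    stop("section has no cortex annotation", call. = FALSE)
  cortex <- rasterize_role(section$annotations, "cortex", w, h)
  excl <- matrix(FALSE, h, w)
  for (r in c("glomerulus", "vessel", "fold"))
    excl <- excl | rasterize_role(section$annotations, r, w, h)
  list(cortex = cortex, exclusions = excl, effective = cortex & !excl)
}
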