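# Nodule measurement: size, voxel count, roundness, solidity type.

#' Foreground voxel count of a mask
#' @param mask logical array (any dimensionality).
#' @export
voxel_count <- function(mask) {
  sum(mask != 0)
}

#' Equivalent diameter of a mask
#'
#' 2D: diameter of the circle with the mask's area; 3D: diameter of the
#' sphere with the mask's volume. Physical spacing is applied per axis, so
#' anisotropic voxels are handled.
#'
#' @param mask logical matrix or 3D array.
#' @param spacing_mm per-axis voxel spacing in mm (scalar recycled).
#' @return diameter in mm.
#' @export
equivalent_diameter <- function(mask, spacing_mm = 1) {
  n <- voxel_count(mask)
  if (n == 0) stop("empty mask has no diameter")
  nd <- if (is.matrix(mask)) 2L else length(dim(mask))
  spacing_mm <- rep_len(as.numeric(spacing_mm), nd)
  if (nd == 2L) {
    area <- n * prod(spacing_mm)
    2 * sqrt(area / pi)
  } else {
    vol <- n * prod(spacing_mm)
    (6 * vol / pi)^(1 / 3)
  }
}

#' Maximal in-plane equivalent diameter of a 3D mask
#'
#' TNM tumor size is a longest-dimension convention, so staging uses the
#' largest per-slice equivalent diameter rather than the 3D volume
#' equivalent (a thin slab truncates thick nodules in depth).
#'
#' @param mask 3D logical array.
#' @param spacing_mm per-axis spacing in mm.
#' @export
max_inplane_diameter <- function(mask, spacing_mm = 1) {
  if (is.matrix(mask)) return(equivalent_diameter(mask, spacing_mm))
  spacing_mm <- rep_len(as.numeric(spacing_mm), 3)
  areas <- apply(mask, 3, sum)
  if (all(areas == 0)) stop("empty mask has no diameter")
  k <- which.max(areas)
  equivalent_diameter(mask[, , k], spacing_mm[1:2])
}

mask_perimeter <- function(mask, smooth_sigma = 1) {
  z <- gaussian_blur(mask + 0, smooth_sigma)
  cts <- extract_contour(z, level = 0.5)
  if (!length(cts)) cts <- extract_contour(mask + 0, level = 0.5)
  if (!length(cts)) stop("mask has no measurable boundary")
  sum(vapply(cts, arc_length, numeric(1)))
}

#' Roundness (compactness) of a mask
#'
#' `4 pi A / P^2`: approximately 1 for discs, smaller for elongated or
#' irregular shapes. The perimeter is measured on the sub-pixel 0.5-level
#' contour of the Gaussian-smoothed mask, an unbiased estimate that makes
#' disc roundness converge to 1 (a naive pixel-edge count would not);
#' structures thinner than the smoothing kernel fall back to the raw mask
#' contour. For a 3D mask the slice of maximal area is measured.
#'
#' @param mask logical matrix or 3D array, one connected component.
#' @param smooth_sigma Gaussian width (pixels) for the sub-pixel boundary.
#' @return unitless roundness in (0, ~1].
#' @export
roundness <- function(mask, smooth_sigma = 1) {
  if (!is.matrix(mask) && length(dim(mask)) == 3L) {
    areas <- apply(mask, 3, sum)
    mask <- mask[, , which.max(areas)]
  }
  mask <- mask != 0
  if (!any(mask)) stop("empty mask has no roundness")
  lab <- label_components_cpp(as.vector(mask), dim(mask))
  if (max(lab) > 1L) {
    stop("mask has ", max(lab), " connected components; ",
         "measure each component separately")
  }
  a <- sum(mask)
  p <- mask_perimeter(mask, smooth_sigma)
  4 * pi * a / p^2
}

#' Classify nodule solidity type
#'
#' Mean in-mask contrast over the background, expressed as a fraction of a
#' reference (full solid) contrast: at or above the solid threshold the
#' nodule is solid, at or above the nonsolid threshold semisolid, below it
#' nonsolid. Ties go to the upper class. When no reference contrast is
#' supplied it is estimated as the 99th percentile of the in-mask contrast,
#' which is appropriate for solid-core nodules but cannot recognize a
#' uniformly faint (nonsolid) nodule as such; pass the nominal tissue
#' contrast when it is known.
#'
#' @param mask logical mask of the nodule.
#' @param image intensity array congruent with the mask.
#' @param background_estimate background (parenchyma) intensity.
#' @param reference_contrast full-contrast reference; `NULL` to estimate.
#' @param thresholds named fractions `c(solid = , nonsolid = )`.
#' @return one of `"solid"`, `"semisolid"`, `"nonsolid"`.
#' @export
classify_nodule_type <- function(mask, image, background_estimate,
                                 reference_contrast = NULL,
                                 thresholds = c(solid = 0.75,
                                                nonsolid = 0.40)) {
  stopifnot(identical(dim(mask), dim(image)))
  if (!any(mask)) stop("empty mask cannot be typed")
  if (!is.finite(background_estimate)) stop("background estimate required")
  vals <- image[mask != 0] - background_estimate
  if (is.null(reference_contrast)) {
    reference_contrast <- stats::quantile(vals, 0.99, names = FALSE)
  }
  if (reference_contrast <= 0) {
    stop("reference contrast must be positive (zero background contrast?)")
  }
  ratio <- mean(vals) / reference_contrast
  if (ratio >= thresholds["solid"]) "solid"
  else if (ratio >= thresholds["nonsolid"]) "semisolid"
  else "nonsolid"
}

#' Measure a segmented nodule
#'
#' Bundles the measurements consumed by staging and reporting: equivalent
#' diameter (3D), maximal in-plane diameter (used for TU staging), voxel
#' count, roundness, bounding box and (when an image and background are
#' given) the solidity type.
#'
#' @param mask logical mask (2D or 3D).
#' @param spacing_mm per-axis voxel spacing in mm.
#' @param image optional intensity array for solidity typing.
#' @param background_estimate background intensity (required with `image`).
#' @param reference_contrast see [classify_nodule_type()].
#' @return object of class `nodule_measurements`.
#' @export
measure_nodule <- function(mask, spacing_mm = 1, image = NULL,
                           background_estimate = NULL,
                           reference_contrast = NULL) {
  if (voxel_count(mask) == 0) stop("empty mask: nothing to measure")
  nd <- if (is.matrix(mask)) 2L else length(dim(mask))
  spacing_mm <- rep_len(as.numeric(spacing_mm), nd)
  idx <- which(mask != 0, arr.ind = TRUE)
  bbox <- (apply(idx, 2, max) - apply(idx, 2, min) + 1) * spacing_mm
  type <- if (!is.null(image)) {
    classify_nodule_type(mask, image, background_estimate,
                         reference_contrast)
  } else {
    NA_character_
  }
  structure(list(
    equivalent_diameter_mm = equivalent_diameter(mask, spacing_mm),
    staging_diameter_mm = max_inplane_diameter(mask, spacing_mm),
    voxel_count = voxel_count(mask),
    roundness = roundness(mask),
    nodule_type = type,
    bounding_box_mm = unname(bbox)), class = "nodule_measurements")
}

#' @export
print.nodule_measurements <- function(x, ...) {
  cat(sprintf(paste0(
    "<nodule_measurements> d_eq %.2f mm (staging %.2f mm), %d voxels, ",
    "roundness %.3f, type %s\n"),
    x$equivalent_diameter_mm, x$staging_diameter_mm, x$voxel_count,
    x$roundness, x$nodule_type))
  invisible(x)
}

#' Measurements table for a set of nodules
#'
#' One CSV-ready row per nodule: id, diameter, voxels, roundness, type.
#'
#' @param measurements list of `nodule_measurements`.
#' @param ids optional row ids.
#' @export
measurements_table <- function(measurements, ids = NULL) {
  if (inherits(measurements, "nodule_measurements")) {
    measurements <- list(measurements)
  }
  if (is.null(ids)) ids <- seq_along(measurements)
  data.frame(
    id = ids,
    diameter_mm = vapply(measurements, `[[`, 0, "staging_diameter_mm"),
    voxels = vapply(measurements, `[[`, 0L, "voxel_count"),
    roundness = vapply(measurements, `[[`, 0, "roundness"),
    type = vapply(measurements, `[[`, "", "nodule_type"))
}
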