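# Synthetic lung-slab phantoms.
#
# A phantom is a uniform parenchyma background with one embedded
# disc/ellipsoid nodule of stated diameter and contrast plus additive
# Gaussian noise. The generator mirrors the published characteristics of the
# simulated-nodule benchmark (diameters 4-20 mm, contrasts 20-65, solid /
# semisolid / nonsolid types) and emits the noise-free mask, the true
# diameter and the TNM stage as ground truth, so every downstream stage is
# testable without external data. Intensity units are arbitrary (recorded in
# the volume metadata); the noise model is additive Gaussian.

NODULE_CLASSES <- c("solid", "semisolid", "nonsolid")

#' Phantom specification
#'
#' @param nodule_diameter_mm nodule diameter in mm (> 0).
#' @param contrast intensity difference between the (solid) nodule and the
#'   parenchyma background, arbitrary units (> 0).
#' @param background_intensity background level.
#' @param noise_sigma standard deviation of the additive Gaussian noise
#'   (>= 0).
#' @param slab_shape integer triple (rows, cols, slices).
#' @param voxel_spacing_mm per-axis spacing in mm (scalar recycled).
#' @param nodule_center 0-based (row, col, slice) grid coordinates of the
#'   nodule centre; defaults to the slab centre (the real-data protocol
#'   centres the region of interest on the nodule).
#' @param nodule_class one of `"solid"`, `"semisolid"`, `"nonsolid"`.
#' @param axis_ratio in-plane ellipticity (semi-axis along rows multiplied,
#'   along columns divided, by this factor); 1 = sphere/disc.
#' @param semisolid_rim_fraction fraction of the radius occupied by the
#'   reduced-contrast rim of a semisolid nodule.
#' @param semisolid_rim_contrast rim contrast as a fraction of full contrast.
#' @param nonsolid_fraction uniform contrast fraction of a nonsolid nodule
#'   (kept strictly below the nonsolid classification threshold).
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(nodule_diameter_mm, contrast,
                         background_intensity = 100, noise_sigma = 0,
                         slab_shape = c(256L, 256L, 8L),
                         voxel_spacing_mm = 1,
                         nodule_center = NULL,
                         nodule_class = "solid",
                         axis_ratio = 1,
                         semisolid_rim_fraction = 0.3,
                         semisolid_rim_contrast = 0.5,
                         nonsolid_fraction = 0.35) {
  if (!is.numeric(nodule_diameter_mm) || nodule_diameter_mm <= 0) {
    stop("nodule_diameter_mm must be > 0")
  }
  if (!is.numeric(contrast) || contrast <= 0) stop("contrast must be > 0")
  if (!is.numeric(noise_sigma) || noise_sigma < 0) {
    stop("noise_sigma must be >= 0")
  }
  slab_shape <- as.integer(rep_len(slab_shape, 3L))
  spacing <- rep_len(as.numeric(voxel_spacing_mm), 3L)
  if (any(spacing <= 0)) stop("voxel spacing must be positive")
  nodule_class <- match.arg(nodule_class, NODULE_CLASSES)
  if (is.null(nodule_center)) nodule_center <- (slab_shape - 1) / 2
  nodule_center <- rep_len(as.numeric(nodule_center), 3L)
  # in-plane extent must fit inside the slab (depth may truncate thick
  # nodules: a slab is a thin axial window)
  r_mm <- nodule_diameter_mm / 2
  extent_vox <- r_mm / spacing[1:2] * c(axis_ratio, 1 / axis_ratio)
  if (any(nodule_center[1:2] - extent_vox < -0.5) ||
      any(nodule_center[1:2] + extent_vox > slab_shape[1:2] - 0.5)) {
    stop("nodule (diameter ", nodule_diameter_mm,
         " mm) does not fit in the slab at the given spacing")
  }
  structure(list(nodule_diameter_mm = nodule_diameter_mm, contrast = contrast,
                 background_intensity = background_intensity,
                 noise_sigma = noise_sigma, slab_shape = slab_shape,
                 voxel_spacing_mm = spacing, nodule_center = nodule_center,
                 nodule_class = nodule_class, axis_ratio = axis_ratio,
                 semisolid_rim_fraction = semisolid_rim_fraction,
                 semisolid_rim_contrast = semisolid_rim_contrast,
                 nonsolid_fraction = nonsolid_fraction),
            class = "phantom_spec")
}

# normalized squared ellipsoidal radius of every voxel (1 = nodule surface)
phantom_radius2 <- function(spec) {
  d <- spec$slab_shape
  sp <- spec$voxel_spacing_mm
  ct <- spec$nodule_center
  r <- spec$nodule_diameter_mm / 2
  a <- r * spec$axis_ratio      # semi-axis along rows (mm)
  b <- r / spec$axis_ratio      # semi-axis along cols (mm)
  u <- ((seq_len(d[1]) - 1 - ct[1]) * sp[1] / a)^2
  v <- ((seq_len(d[2]) - 1 - ct[2]) * sp[2] / b)^2
  w <- ((seq_len(d[3]) - 1 - ct[3]) * sp[3] / r)^2
  outer(outer(u, v, `+`), w, `+`)
}

#' Generate a phantom image and its ground truth
#'
#' The image is `background + contrast * nodule_profile + N(0, sigma)`.
#' Solid nodules have a uniform full-contrast profile; semisolid nodules a
#' full-contrast core with a reduced-contrast rim; nonsolid nodules a
#' uniform sub-threshold contrast. The ground-truth mask is the noise-free
#' nodule indicator (full extent, independent of class).
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed; the same spec and seed give bit-identical
#'   images. `NULL` uses the current RNG state.
#' @param ln_code,dm_code nodal/metastasis metadata codes attached to the
#'   ground truth (phantoms carry no nodal anatomy; these are labels only).
#' @return list with `volume` (an [image_volume()]) and `truth`
#'   (mask, true_diameter_mm, tnm, stage).
#' @export
generate_phantom <- function(spec, seed = NULL, ln_code = "LN0",
                             dm_code = "DM0") {
  stopifnot(inherits(spec, "phantom_spec"))
  rho2 <- phantom_radius2(spec)
  mask <- rho2 <= 1
  profile <- switch(spec$nodule_class,
    solid = mask * 1,
    semisolid = {
      core <- rho2 <= (1 - spec$semisolid_rim_fraction)^2
      core * 1 + (mask & !core) * spec$semisolid_rim_contrast
    },
    nonsolid = mask * spec$nonsolid_fraction)
  img <- spec$background_intensity + spec$contrast * profile
  if (spec$noise_sigma > 0) {
    noise <- with_seed(seed, stats::rnorm(length(img), 0, spec$noise_sigma))
    img <- img + array(noise, dim(img))
  }
  vol <- image_volume(img, spacing_mm = spec$voxel_spacing_mm,
                      modality = "synthetic",
                      origin = list(generator = "phantom",
                                    nodule_class = spec$nodule_class,
                                    seed = seed))
  tnm <- tnm_descriptor(tu_category(spec$nodule_diameter_mm / 10),
                        ln_code, dm_code)
  truth <- list(mask = mask,
                true_diameter_mm = spec$nodule_diameter_mm,
                nodule_class = spec$nodule_class,
                tnm = tnm, stage = stage_group(tnm))
  list(volume = vol, truth = truth, spec = spec)
}

#' Draw a random phantom specification
#'
#' Uniform draws of diameter and contrast inside the stated intervals
#' (defaults cover the published simulated-nodule ranges, 4-20 mm and
#' 20-65).
#'
#' @param seed integer seed (`NULL` = current RNG state).
#' @param diameter_range_mm,contrast_range closed intervals to sample from.
#' @param ... further arguments passed to [phantom_spec()].
#' @return a [phantom_spec()].
#' @export
sample_spec <- function(seed = NULL, diameter_range_mm = c(4, 20),
                        contrast_range = c(20, 65), ...) {
  check_interval <- function(x, what) {
    if (length(x) != 2 || x[1] > x[2]) {
      stop(what, " must be an interval c(lo, hi) with lo <= hi")
    }
  }
  check_interval(diameter_range_mm, "diameter_range_mm")
  check_interval(contrast_range, "contrast_range")
  draws <- with_seed(seed, stats::runif(2))
  d <- diameter_range_mm[1] + draws[1] * diff(diameter_range_mm)
  ct <- contrast_range[1] + draws[2] * diff(contrast_range)
  phantom_spec(nodule_diameter_mm = d, contrast = ct, ...)
}

#' Default 9-class size-binned dataset map
#'
#' Nine disjoint diameter bins, each mapping to a distinct stage label:
#' seven bins follow the TU size boundaries with LN0/DM0 (stages 1A1..3A)
#' and the two largest bins carry DM1 and DM2 metadata (stages 4A, 4B), so
#' the label set has 9 distinct classes that are separable by nodule size
#' alone. Bin edges never straddle a TU boundary.
#'
#' @export
default_class_map <- function() {
  list(
    `1A1` = list(diameter_cm = c(0.4, 1.0),  ln = "LN0", dm = "DM0"),
    `1A2` = list(diameter_cm = c(1.0, 2.0),  ln = "LN0", dm = "DM0"),
    `1A3` = list(diameter_cm = c(2.0, 3.0),  ln = "LN0", dm = "DM0"),
    `1B`  = list(diameter_cm = c(3.0, 4.0),  ln = "LN0", dm = "DM0"),
    `2A`  = list(diameter_cm = c(4.0, 5.0),  ln = "LN0", dm = "DM0"),
    `2B`  = list(diameter_cm = c(5.0, 7.0),  ln = "LN0", dm = "DM0"),
    `3A`  = list(diameter_cm = c(7.0, 8.5),  ln = "LN0", dm = "DM0"),
    `4A`  = list(diameter_cm = c(8.5, 10.0), ln = "LN0", dm = "DM1"),
    `4B`  = list(diameter_cm = c(10.0, 12.0), ln = "LN0", dm = "DM2")
  )
}

#' Generate a labelled phantom dataset
#'
#' Draws `n_per_class` phantoms per class of `class_map`. Each class is a
#' half-open diameter interval `(lo, hi]` in cm plus LN/DM metadata codes;
#' the stage label of every item is derived from its true diameter via
#' [tu_category()] and [stage_group()], never assigned directly, and classes
#' whose interval straddles a TU size boundary (which would make the label
#' ambiguous) are rejected unless `allow_straddle = TRUE`.
#'
#' @param n_per_class items per class.
#' @param class_map named list of class definitions (see
#'   [default_class_map()]).
#' @param seed integer seed; the whole collection is reproducible.
#' @param slab_shape,voxel_spacing_mm slab geometry (defaults sized for the
#'   desk-scale benchmark: 64 x 64 x 8 voxels at 2.5 mm).
#' @param contrast_range contrast sampling interval.
#' @param noise_sigma noise level; the default `NULL` uses `contrast / 8`
#'   per item (the stated noisy test condition).
#' @param background_intensity background level.
#' @param allow_straddle permit class intervals crossing a TU boundary.
#' @return list of items (each as returned by [generate_phantom()], plus
#'   `$label`), with the class map and seed as attributes.
#' @export
generate_dataset <- function(n_per_class, class_map = default_class_map(),
                             seed = NULL,
                             slab_shape = c(64L, 64L, 8L),
                             voxel_spacing_mm = 2.5,
                             contrast_range = c(20, 65),
                             noise_sigma = NULL,
                             background_intensity = 100,
                             allow_straddle = FALSE) {
  stopifnot(length(class_map) >= 1, !is.null(names(class_map)))
  eps <- 1e-9
  for (nm in names(class_map)) {
    iv <- class_map[[nm]]$diameter_cm
    if (length(iv) != 2 || iv[1] >= iv[2]) {
      stop("class '", nm, "': diameter_cm must be an increasing interval")
    }
    if (!allow_straddle &&
        tu_category(iv[1] + eps) != tu_category(iv[2])) {
      stop("class '", nm, "' straddles a TU size boundary (",
           tu_category(iv[1] + eps), " vs ", tu_category(iv[2]),
           "); split it or set allow_straddle = TRUE")
    }
  }
  n_items <- n_per_class * length(class_map)
  seeds <- derive_seeds(seed, n_items + 1L)
  draws <- with_seed(seeds[n_items + 1L],
                     matrix(stats::runif(2 * n_items), ncol = 2))
  items <- vector("list", n_items)
  i <- 0L
  for (nm in names(class_map)) {
    cls <- class_map[[nm]]
    ln <- if (is.character(cls$ln)) cls$ln else "LN0"
    dm <- if (is.character(cls$dm)) cls$dm else "DM0"
    for (j in seq_len(n_per_class)) {
      i <- i + 1L
      iv_mm <- cls$diameter_cm * 10
      d <- iv_mm[1] + draws[i, 1] * diff(iv_mm)
      ct <- contrast_range[1] + draws[i, 2] * diff(contrast_range)
      sg <- if (is.null(noise_sigma)) ct / 8 else noise_sigma
      spec <- phantom_spec(nodule_diameter_mm = d, contrast = ct,
                           background_intensity = background_intensity,
                           noise_sigma = sg, slab_shape = slab_shape,
                           voxel_spacing_mm = voxel_spacing_mm)
      it <- generate_phantom(spec, seed = seeds[i], ln_code = ln,
                             dm_code = dm)
      it$label <- it$truth$stage
      it$class <- nm
      items[[i]] <- it
    }
  }
  structure(items, class_map = class_map, seed = seed)
}
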