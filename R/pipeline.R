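# End-to-end pipeline: input -> segmentation -> measurement -> staging ->
# (optional) classification -> case record. Local, deterministic, with a
# content-hash cache taking the place of any remote record matching.

#' Case record of one analyzed volume
#'
#' The record's stage label must equal `stage_group` of its descriptor;
#' this invariant is enforced here and again at write time.
#'
#' @param case_id identifier string.
#' @param measurements a `nodule_measurements` (or NULL if nothing found).
#' @param tnm a [tnm_descriptor()].
#' @param stage stage label.
#' @param probabilities optional named classifier probabilities.
#' @param provenance list (config hash, seed, package version, timestamp).
#' @export
case_record <- function(case_id, measurements, tnm, stage,
                        probabilities = NULL, provenance = list()) {
  if (!is.null(tnm)) {
    expected <- stage_group(tnm)
    if (!identical(stage, expected)) {
      stop("inconsistent record: stage '", stage, "' but descriptor ",
           format(tnm), " maps to '", expected, "'")
    }
  }
  structure(list(case_id = case_id, measurements = measurements, tnm = tnm,
                 stage = stage, probabilities = probabilities,
                 provenance = provenance, schema = "pulmostage-record-v1"),
            class = "case_record")
}

#' @export
print.case_record <- function(x, ...) {
  cat(sprintf("<case_record> %s: %s -> stage %s\n", x$case_id,
              if (is.null(x$tnm)) "no descriptor" else format(x$tnm),
              x$stage))
  invisible(x)
}

config_hash <- function(obj) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(obj, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Serialize / deserialize a case record as JSON
#'
#' Writing refuses records whose stage label contradicts their TNM
#' descriptor.
#'
#' @param record a [case_record()].
#' @param path JSON file path.
#' @export
write_case_record <- function(record, path) {
  stopifnot(inherits(record, "case_record"))
  if (!is.null(record$tnm) &&
      !identical(record$stage, stage_group(record$tnm))) {
    stop("refusing to write record with stage/descriptor mismatch")
  }
  obj <- record
  class(obj) <- NULL
  obj$measurements <- unclass(obj$measurements)
  obj$tnm <- if (!is.null(obj$tnm)) unclass(obj$tnm)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_case_record
#' @export
read_case_record <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tnm <- if (!is.null(obj$tnm)) {
    tnm_descriptor(obj$tnm$tu, obj$tnm$ln, obj$tnm$dm)
  }
  meas <- obj$measurements
  if (!is.null(meas)) class(meas) <- "nodule_measurements"
  case_record(obj$case_id, meas, tnm, obj$stage,
              probabilities = obj$probabilities,
              provenance = obj$provenance)
}

#' Run the full analysis pipeline on one input
#'
#' Segments the volume slice by slice with the level-set active contour,
#' keeps the largest connected component, measures it, assigns the TNM
#' categories and stage group (nodal/metastasis codes are metadata inputs;
#' images carry no nodal information), optionally applies a trained stage
#' classifier, and assembles a provenance-stamped [case_record()]. A
#' content-hash cache short-circuits repeated runs of an identical
#' input/configuration pair.
#'
#' @param input an [image_volume()], a [phantom_spec()] (generated on the
#'   fly), or a path readable by [read_image_series()].
#' @param ln_code,dm_code nodal/metastasis metadata codes.
#' @param params segmentation [levelset_params()].
#' @param classifier optional trained `mcnn_model`.
#' @param case_id record identifier.
#' @param seed seed for phantom generation.
#' @param cache_dir optional directory of cached records (content hash).
#' @param skip_classifier bypass classification even if a model is given.
#' @return a [case_record()] (with the mask attached as attribute `mask`).
#' @export
run_pipeline <- function(input, ln_code = "LN0", dm_code = "DM0",
                         params = levelset_params(), classifier = NULL,
                         case_id = "case", seed = NULL, cache_dir = NULL,
                         skip_classifier = FALSE) {
  if (inherits(input, "phantom_spec")) {
    vol <- generate_phantom(input, seed = seed)$volume
  } else if (inherits(input, "image_volume")) {
    vol <- input
  } else if (is.character(input) && dir.exists(input)) {
    vol <- read_image_series(input)
  } else {
    stop("input must be an image_volume, phantom_spec or series directory")
  }

  key <- config_hash(list(dims = dim(vol$intensities),
                          sum = sum(vol$intensities),
                          sumsq = sum(vol$intensities^2),
                          spacing = vol$spacing_mm, ln = ln_code,
                          dm = dm_code, params = unclass(params),
                          seed = seed))
  if (!is.null(cache_dir)) {
    hit <- file.path(cache_dir, paste0(key, ".json"))
    if (file.exists(hit)) {
      rec <- read_case_record(hit)
      rec$provenance$cache_hit <- TRUE
      return(rec)
    }
  }

  seg <- segment_volume(vol, params = params)
  if (!any(seg$mask)) {
    rec <- case_record(case_id, NULL, NULL, STAGE_NONE,
                       provenance = list(config_hash = key, seed = seed,
                                         note = "no object segmented"))
    attr(rec, "mask") <- seg$mask
    return(rec)
  }
  bg <- stats::median(vol$intensities[!seg$mask])
  meas <- measure_nodule(seg$mask, spacing_mm = vol$spacing_mm,
                         image = vol$intensities, background_estimate = bg)
  staged <- stage_from_measurement(meas, ln_code, dm_code)

  probs <- NULL
  if (!is.null(classifier) && !skip_classifier) {
    xin <- classifier_input_volume(vol, seg$mask)
    pr <- predict(classifier, xin)
    probs <- as.list(pr$probabilities[1, ])
  }
  rec <- case_record(case_id, meas, staged$tnm, staged$stage,
                     probabilities = probs,
                     provenance = list(config_hash = key, seed = seed,
                                       package = "pulmostage",
                                       version = as.character(
                                         utils::packageVersion("pulmostage")),
                                       timestamp = format(Sys.time(),
                                                          tz = "UTC")))
  attr(rec, "mask") <- seg$mask
  if (!is.null(cache_dir)) {
    dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
    write_case_record(rec, file.path(cache_dir, paste0(key, ".json")))
  }
  rec
}

# classifier input: masked image, max-normalized per volume so nodule tissue
# sits near 1 regardless of acquisition contrast
classifier_input_volume <- function(vol, mask) {
  x <- vol$intensities
  bg <- stats::median(x[!mask])
  x <- (x - bg) * mask
  m <- max(abs(x))
  if (m > 0) x <- x / m
  x
}

#' Assemble classifier inputs from a phantom dataset
#'
#' For `segmented = TRUE` each volume is segmented with the level-set model
#' and the classifier consumes the background-subtracted masked image
#' (max-normalized); for `segmented = FALSE` it consumes the raw noisy slab
#' (same normalization, no mask) — the ablation comparison input.
#'
#' @param items dataset from [generate_dataset()].
#' @param segmented feed ACM-segmented masked images (TRUE) or raw slabs.
#' @param params segmentation parameters.
#' @param verbose progress messages every 100 items.
#' @return list: `x` array (H, W, depth, N), `labels`, `diameters_mm`.
#' @export
prepare_classifier_input <- function(items, segmented = TRUE,
                                     params = levelset_params(),
                                     verbose = FALSE) {
  d <- dim(items[[1]]$volume$intensities)
  x <- array(0, c(d, length(items)))
  labels <- character(length(items))
  diam <- numeric(length(items))
  for (i in seq_along(items)) {
    vol <- items[[i]]$volume
    if (segmented) {
      seg <- segment_volume(vol, params = params)
      x[, , , i] <- classifier_input_volume(vol, seg$mask)
    } else {
      v <- vol$intensities
      bg <- stats::median(v)
      v <- v - bg
      m <- max(abs(v))
      x[, , , i] <- if (m > 0) v / m else v
    }
    labels[i] <- items[[i]]$label
    diam[i] <- items[[i]]$truth$true_diameter_mm
    if (verbose && i %% 100 == 0) message(i, " / ", length(items))
  }
  list(x = x, labels = labels, diameters_mm = diam)
}
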