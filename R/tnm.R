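#' @useDynLib pulmostage, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- TNM vocabulary -------------------------------------------------------

TU_LEVELS <- c("TU0", "TU1a", "TU1b", "TU1c", "TU2a", "TU2b", "TU3", "TU4")
LN_LEVELS <- c("LN0", "LN1", "LN2", "LN3")
DM_LEVELS <- c("DM0", "DM1", "DM2")

STAGE_LEVELS <- c("1A1", "1A2", "1A3", "1B", "2A", "2B",
                  "3A", "3B", "3C", "4A", "4B")

#' Sentinel returned when a descriptor carries no tumor (TU0, DM0)
#' @export
STAGE_NONE <- "no_tumor"

LN_DESCRIPTIONS <- c(
  LN0 = "Absence of regional node metastasis",
  LN1 = paste("Metastasis is in the ipsilateral peribronchial or perihilar",
              "lymph nodes and intrapulmonary nodes"),
  LN2 = "Metastasis is in the ipsilateral mediastinal or subcarinal lymph nodes",
  LN3 = paste("Metastasis is in the contralateral mediastinal lymph nodes,",
              "perihilar lymph nodes, or supraclavicular nodes")
)

DM_DESCRIPTIONS <- c(
  DM0 = "Absence of distant metastasis",
  DM1 = paste("Malignant pleural/pericardial effusion or pleural/pericardial",
              "nodule or separate tumor nodule in a contralateral lobes"),
  DM2 = "Distant metastasis was found"
)

# Stage-group grid, row = TU subcategory, column = LN category (DM0 case).
# DM1/DM2 override the whole grid (handled in stage_group).
STAGE_GRID <- matrix(
  c("1A1", "2B", "3A", "3B",   # TU1a
    "1A2", "2B", "3A", "3B",   # TU1b
    "1A3", "2B", "3A", "3B",   # TU1c
    "1B",  "2B", "3A", "3B",   # TU2a
    "2A",  "2B", "3A", "3B",   # TU2b
    "2B",  "3A", "3B", "3C",   # TU3
    "3A",  "3A", "3B", "3C"),  # TU4  (LN0 and LN1 cells both 3A, as published)
  nrow = 7, byrow = TRUE,
  dimnames = list(setdiff(TU_LEVELS, "TU0"), LN_LEVELS)
)

# ---- Categorizers ---------------------------------------------------------

#' Primary-tumor (TU) size category
#'
#' Maps the maximal tumor diameter in centimetres to the TU subcategory used
#' by the NSCLC staging tables. All interval upper bounds are inclusive
#' ("less than or equal to"): sizes of exactly 1, 2, 3, 4, 5 and 7 cm fall in
#' the lower category. A size of exactly 0 means no tumor (TU0).
#'
#' @param size_cm numeric vector of tumor diameters in cm (>= 0).
#' @return character vector of TU subcategories
#'   (`TU0`, `TU1a`, `TU1b`, `TU1c`, `TU2a`, `TU2b`, `TU3`, `TU4`).
#' @examples
#' tu_category(c(0.8, 2.5, 3, 7.01))
#' @export
tu_category <- function(size_cm) {
  if (!is.numeric(size_cm) || anyNA(size_cm)) {
    stop("`size_cm` must be numeric and free of NA")
  }
  if (any(size_cm < 0)) stop("tumor size must be >= 0 cm")
  breaks <- c(0, 1, 2, 3, 4, 5, 7, Inf)
  labels <- c("TU1a", "TU1b", "TU1c", "TU2a", "TU2b", "TU3", "TU4")
  idx <- findInterval(size_cm, breaks, left.open = TRUE) # (lo, hi] bins
  out <- ifelse(size_cm == 0, "TU0", labels[pmax(idx, 1L)])
  out
}

#' Parent TU grouping (TU1 / TU2) of a subcategory
#'
#' The staging table lists TU1 and TU2 as parents of their lettered
#' subcategories; they are never returned by [tu_category()] but can be
#' derived from it.
#'
#' @param tu character vector of TU subcategories.
#' @return character vector with `TU1a/b/c` collapsed to `TU1` and
#'   `TU2a/b` to `TU2`; other categories unchanged.
#' @export
tu_parent <- function(tu) {
  tu <- match.arg(tu, TU_LEVELS, several.ok = TRUE)
  out <- tu
  out[tu %in% c("TU1a", "TU1b", "TU1c")] <- "TU1"
  out[tu %in% c("TU2a", "TU2b")] <- "TU2"
  out
}

normalize_code <- function(code, prefix) {
  # accepts "LN0", "LN_0", "ln0" etc.
  toupper(gsub("_", "", trimws(code)))
}

#' Regional lymph-node (LN) category
#'
#' Validates a coded LN descriptor (`LN0`..`LN3`, underscore and case
#' variants accepted) and attaches its clinical description.
#'
#' @param code character vector of LN codes.
#' @return character vector of canonical codes with a `description` attribute.
#' @export
ln_category <- function(code) {
  x <- normalize_code(code)
  bad <- !(x %in% LN_LEVELS)
  if (any(bad)) {
    stop("unknown LN code(s): ", paste(unique(code[bad]), collapse = ", "),
         "; valid codes are ", paste(LN_LEVELS, collapse = ", "))
  }
  structure(x, description = unname(LN_DESCRIPTIONS[x]))
}

#' Distant-metastasis (DM) category
#'
#' @param code character vector of DM codes (`DM0`..`DM2`).
#' @return character vector of canonical codes with a `description` attribute.
#' @export
dm_category <- function(code) {
  x <- normalize_code(code)
  bad <- !(x %in% DM_LEVELS)
  if (any(bad)) {
    stop("unknown DM code(s): ", paste(unique(code[bad]), collapse = ", "),
         "; valid codes are ", paste(DM_LEVELS, collapse = ", "))
  }
  structure(x, description = unname(DM_DESCRIPTIONS[x]))
}

#' TNM descriptor
#'
#' Bundles the TU/LN/DM triple after validation.
#'
#' @param tu TU subcategory (see [tu_category()]).
#' @param ln LN code.
#' @param dm DM code.
#' @return object of class `tnm_descriptor` (named list `tu`, `ln`, `dm`).
#' @export
tnm_descriptor <- function(tu, ln, dm) {
  tu <- match.arg(tu, TU_LEVELS)
  structure(list(tu = tu,
                 ln = as.character(ln_category(ln)),
                 dm = as.character(dm_category(dm))),
            class = "tnm_descriptor")
}

#' @export
format.tnm_descriptor <- function(x, ...) {
  paste0(x$tu, "/", x$ln, "/", x$dm)
}

#' @export
print.tnm_descriptor <- function(x, ...) {
  cat("<TNM>", format(x), "\n")
  invisible(x)
}

#' Stage group of a TNM descriptor
#'
#' Deterministic lookup of the published stage-group grid. Any distant
#' metastasis overrides the TU/LN combination: DM1 maps to stage 4A and DM2
#' to 4B regardless of tumor size or nodal involvement. Otherwise the row is
#' the TU subcategory and the column the LN category. A descriptor with TU0
#' and DM0 describes no tumor and yields the sentinel [STAGE_NONE].
#'
#' @param tnm a [tnm_descriptor()], or a TU subcategory when `ln`/`dm` given.
#' @param ln,dm optional LN/DM codes when `tnm` is a bare TU string.
#' @return a stage label among `r paste(STAGE_LEVELS, collapse = ", ")`,
#'   or [STAGE_NONE].
#' @examples
#' stage_group(tnm_descriptor("TU1a", "LN0", "DM0")) # "1A1"
#' stage_group("TU3", "LN3", "DM0")                  # "3C"
#' stage_group("TU2b", "LN2", "DM1")                 # "4A"
#' @export
stage_group <- function(tnm, ln = NULL, dm = NULL) {
  if (!inherits(tnm, "tnm_descriptor")) {
    tnm <- tnm_descriptor(tnm, ln, dm)
  }
  if (tnm$dm == "DM1") return("4A")
  if (tnm$dm == "DM2") return("4B")
  if (tnm$tu == "TU0") return(STAGE_NONE)
  STAGE_GRID[tnm$tu, tnm$ln]
}

#' Ordered factor of stage labels
#'
#' Severity order `1A1 < 1A2 < ... < 4B`, used for monotonicity checks and
#' report sorting.
#'
#' @param labels character vector of stage labels.
#' @export
stage_factor <- function(labels) {
  factor(labels, levels = STAGE_LEVELS, ordered = TRUE)
}

#' Coarse stage grouping
#'
#' Collapses `1A1/1A2/1A3` to `1A` and `4A/4B` to `4`, the grouping used when
#' a classifier is configured with fewer classes than the full 11-label table
#' (this yields 8 coarse labels).
#'
#' @param labels character vector of fine stage labels.
#' @export
stage_coarse <- function(labels) {
  out <- labels
  out[labels %in% c("1A1", "1A2", "1A3")] <- "1A"
  out[labels %in% c("4A", "4B")] <- "4"
  out
}

#' Stage a measured nodule
#'
#' Composes nodule measurement with TNM categorization: the equivalent
#' diameter (mm) is converted to cm, categorized with [tu_category()], and
#' combined with the supplied nodal/metastasis codes via [stage_group()].
#'
#' @param measurements a `nodule_measurements` object (see
#'   [measure_nodule()]), or a bare diameter in mm.
#' @param ln_code,dm_code LN and DM codes (metadata; not derived from images).
#' @return list with elements `tnm` ([tnm_descriptor()]) and `stage`.
#' @examples
#' stage_from_measurement(12, "LN0", "DM0")  # stage "1A2"
#' @export
stage_from_measurement <- function(measurements, ln_code, dm_code) {
  diameter_mm <- if (is.numeric(measurements)) {
    measurements
  } else if (inherits(measurements, "nodule_measurements")) {
    measurements$staging_diameter_mm
  } else {
    stop("`measurements` must be numeric (mm) or a nodule_measurements object")
  }
  if (length(diameter_mm) != 1L || !is.finite(diameter_mm)) {
    stop("a single finite diameter is required")
  }
  tu <- tu_category(diameter_mm / 10)  # mm -> cm at the composition boundary
  tnm <- tnm_descriptor(tu, ln_code, dm_code)
  list(tnm = tnm, stage = stage_group(tnm))
}
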