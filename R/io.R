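# Image container and plain-text I/O.
#
# Coordinate convention used package-wide: 0-based (row, column, slice)
# indices; a voxel's physical position is index * spacing_mm. Images are
# stored as R arrays with dim (rows, cols, slices); a single-slice image may
# be a plain matrix.

#' Scalar image volume with physical voxel spacing
#'
#' @param intensities numeric matrix (2D) or 3D array of intensities.
#' @param spacing_mm numeric vector of per-axis voxel spacing in mm
#'   (length 2 or 3; recycled from a scalar).
#' @param modality one of `"CT"`, `"PET"`, `"synthetic"`.
#' @param units intensity units tag (phantoms use `"arbitrary"`).
#' @param origin free-form origin/provenance metadata list.
#' @return object of class `image_volume`.
#' @export
image_volume <- function(intensities, spacing_mm = 1, modality = "synthetic",
                         units = "arbitrary", origin = list()) {
  if (is.matrix(intensities)) intensities <- array(intensities, c(dim(intensities), 1L))
  stopifnot(is.array(intensities), length(dim(intensities)) == 3L)
  if (!all(is.finite(intensities))) stop("intensities must be finite")
  nd <- 3L
  spacing_mm <- rep_len(as.numeric(spacing_mm), nd)
  if (any(spacing_mm <= 0)) stop("voxel spacing must be positive")
  modality <- match.arg(modality, c("CT", "PET", "synthetic"))
  structure(list(intensities = intensities, spacing_mm = spacing_mm,
                 modality = modality, units = units, origin = origin),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<image_volume> %d x %d x %d voxels, spacing %s mm, %s\n",
              d[1], d[2], d[3],
              paste(format(x$spacing_mm, digits = 4), collapse = " x "),
              x$modality))
  invisible(x)
}

#' Extract one slice of a volume as a matrix
#' @param vol an [image_volume()].
#' @param k slice index (1-based).
#' @export
volume_slice <- function(vol, k = 1L) {
  vol$intensities[, , k]
}

# ---- ASCII PGM (portable graymap, P2) -------------------------------------
# The slice format for images and masks. Text-only on disk; intensities are
# quantized to 16-bit integers over a stored range so image round-trips are
# exact for integer-valued data and masks (0/255) are lossless.

write_pgm <- function(m, path, maxval = NULL) {
  stopifnot(is.matrix(m))
  if (is.null(maxval)) maxval <- max(1L, ceiling(max(m)))
  vals <- round(m)
  if (any(vals < 0) || any(vals > maxval)) {
    stop("PGM values must lie in [0, maxval]; rescale before writing")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(m), nrow(m)), as.character(maxval)), con)
  # one image row per line, row-major as PGM requires
  apply(vals, 1, function(row) writeLines(paste(row, collapse = " "), con))
  invisible(path)
}

read_pgm <- function(path) {
  txt <- readLines(path)
  txt <- txt[!grepl("^#", txt)]
  if (txt[1] != "P2") stop("only ASCII PGM (P2) is supported: ", path)
  nums <- as.numeric(scan(text = paste(txt[-1], collapse = " "), quiet = TRUE))
  w <- nums[1]; h <- nums[2]
  px <- nums[-(1:3)]
  if (length(px) != w * h) stop("corrupt PGM: ", path)
  matrix(px, nrow = h, ncol = w, byrow = TRUE)
}

# ---- image series (one file per slice + JSON sidecar) ---------------------

#' Write an image volume as a slice series
#'
#' One ASCII PGM file per slice plus a JSON sidecar holding spacing,
#' modality, intensity offset/scale and slice positions. This mirrors the
#' contract of a medical slice series (per-slice files, spacing metadata,
#' position-based ordering) in a text-only format.
#'
#' @param vol an [image_volume()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix for the slices.
#' @export
write_image_series <- function(vol, dir, prefix = "slice") {
  stopifnot(inherits(vol, "image_volume"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  x <- vol$intensities
  lo <- min(x); hi <- max(x)
  # integer-valued volumes that fit 16 bits are stored losslessly; anything
  # else is quantized to 65536 levels over the observed range
  integral <- all(x == round(x)) && (hi - lo) <= 65535
  scale <- if (integral) 1 else if (hi > lo) 65535 / (hi - lo) else 1
  files <- character(dim(x)[3])
  for (k in seq_len(dim(x)[3])) {
    q <- round((x[, , k] - lo) * scale)
    files[k] <- sprintf("%s_%03d.pgm", prefix, k)
    write_pgm(q, file.path(dir, files[k]),
              maxval = if (integral) max(1, hi - lo) else 65535)
  }
  meta <- list(format = "pulmostage-series-v1",
               spacing_mm = vol$spacing_mm, modality = vol$modality,
               units = vol$units, intensity_offset = lo,
               intensity_scale = scale,
               slices = lapply(seq_along(files), function(k) {
                 list(file = files[k], position_mm = (k - 1) * vol$spacing_mm[3])
               }))
  jsonlite::write_json(meta, file.path(dir, "series.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a slice series written by [write_image_series()]
#'
#' Slices are assembled in order of their recorded physical position, so a
#' shuffled directory listing yields an identical volume.
#'
#' @param dir directory containing `series.json` and the slice files.
#' @return an [image_volume()].
#' @export
read_image_series <- function(dir) {
  sidecar <- file.path(dir, "series.json")
  if (!file.exists(sidecar)) stop("no series.json sidecar in ", dir)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  sl <- meta$slices
  ord <- order(sl$position_mm)
  mats <- lapply(sl$file[ord], function(f) read_pgm(file.path(dir, f)))
  dims <- dim(mats[[1]])
  x <- array(0, c(dims, length(mats)))
  for (k in seq_along(mats)) x[, , k] <- mats[[k]]
  x <- x / meta$intensity_scale + meta$intensity_offset
  image_volume(x, spacing_mm = meta$spacing_mm, modality = meta$modality,
               units = meta$units, origin = list(source = dir))
}

#' Write a binary mask as PGM slices (0/255)
#' @param mask logical matrix or 3D array.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @export
write_mask <- function(mask, dir, prefix = "mask") {
  if (is.matrix(mask)) mask <- array(mask, c(dim(mask), 1L))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(dim(mask)[3])
  for (k in seq_len(dim(mask)[3])) {
    files[k] <- sprintf("%s_%03d.pgm", prefix, k)
    write_pgm((mask[, , k] != 0) * 255, file.path(dir, files[k]), maxval = 255)
  }
  invisible(file.path(dir, files))
}

#' Read a mask written by [write_mask()]
#' @param files character vector of PGM paths, in slice order.
#' @export
read_mask <- function(files) {
  mats <- lapply(files, function(f) read_pgm(f) > 127)
  out <- array(FALSE, c(dim(mats[[1]]), length(mats)))
  for (k in seq_along(mats)) out[, , k] <- mats[[k]]
  out
}

#' Read a single-frame raster image (ASCII PGM)
#'
#' @param path path to a `.pgm` file.
#' @param spacing_mm voxel spacing to attach (PGM carries none).
#' @param modality modality tag.
#' @export
read_raster <- function(path, spacing_mm = 1, modality = "synthetic") {
  ext <- tolower(tools::file_ext(path))
  if (ext != "pgm") {
    stop("unsupported raster format '.", ext, "'; supported: .pgm (ASCII P2)")
  }
  image_volume(read_pgm(path), spacing_mm = spacing_mm, modality = modality,
               origin = list(source = path))
}
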