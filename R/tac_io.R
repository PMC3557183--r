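#' Time-activity curve for one volume of interest
#'
#' @param frame_bounds n x 2 matrix of `[start, end]` frame boundaries in
#'   minutes since end of irradiation.
#' @param values Mean count rate per frame; finite and >= 0.
#' @param voi_label Text label for the region.
#' @return An object of class `tac`.
#' @export
tac <- function(frame_bounds, values, voi_label = "") {
  fb <- as.matrix(frame_bounds)
  if (ncol(fb) != 2) stop_input("frame_bounds must have two columns")
  colnames(fb) <- c("start", "end")
  validate_frame_bounds(fb)
  values <- as.numeric(values)
  if (length(values) != nrow(fb)) {
    stop_input("need one value per frame (%d frames, %d values)",
               nrow(fb), length(values))
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop_input("TAC values must be finite and non-negative")
  }
  structure(list(frame_bounds = fb, values = values, voi_label = voi_label),
            class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("<tac> '%s': %d frames, %.3g-%.3g min\n", x$voi_label,
              nrow(x$frame_bounds), x$frame_bounds[1, 1],
              x$frame_bounds[nrow(x$frame_bounds), 2]))
  print(data.frame(start = x$frame_bounds[, 1], end = x$frame_bounds[, 2],
                   mean_rate = signif(x$values, 6)))
  invisible(x)
}

#' @export
as.data.frame.tac <- function(x, ...) {
  data.frame(frame_start_min = x$frame_bounds[, 1],
             frame_end_min = x$frame_bounds[, 2],
             mean_rate = x$values)
}

tac_csv_header <- "frame_start_min,frame_end_min,mean_rate"

#' Read a time-activity curve from CSV
#'
#' The dialect is fixed: UTF-8, comma separator, decimal point, exactly the
#' header `frame_start_min,frame_end_min,mean_rate`, one row per frame.
#' Frames must be strictly increasing and non-overlapping.
#'
#' @param path File to read.
#' @param voi_label Label for the returned curve (default: file name).
#' @return A [tac()].
#' @export
read_tac_csv <- function(path, voi_label = basename(path)) {
  if (!file.exists(path)) stop_input("TAC file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0 || trimws(lines[1]) != tac_csv_header) {
    stop_input("line 1 of %s: expected header '%s'", path, tac_csv_header)
  }
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0) stop_input("%s contains a header but no frames", path)
  rows <- lapply(seq_along(body), function(i) {
    parts <- strsplit(body[i], ",", fixed = TRUE)[[1]]
    vals <- suppressWarnings(as.numeric(parts))
    if (length(vals) != 3 || any(is.na(vals))) {
      stop_input("line %d of %s: expected 3 numeric fields, got '%s'",
                 i + 1, path, body[i])
    }
    vals
  })
  m <- do.call(rbind, rows)
  tac(m[, 1:2, drop = FALSE], m[, 3], voi_label = voi_label)
}

#' Write a time-activity curve as CSV
#'
#' Values are written with 17 significant digits so a write/read cycle is an
#' exact round trip.
#'
#' @param x A [tac()].
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_tac_csv <- function(x, path) {
  stopifnot(inherits(x, "tac"))
  rows <- sprintf("%.17g,%.17g,%.17g",
                  x$frame_bounds[, 1], x$frame_bounds[, 2], x$values)
  writeLines(c(tac_csv_header, rows), path, useBytes = TRUE)
  invisible(path)
}

#' 4-D dynamic image volume
#'
#' @param data 4-D numeric array (x, y, z, frame).
#' @param frame_bounds n x 2 matrix matching the 4th dimension.
#' @param voxel_mm Isotropic voxel size in mm (or length-3 vector).
#' @return An object of class `dynamic_volume`.
#' @export
dynamic_volume <- function(data, frame_bounds, voxel_mm = 4) {
  if (length(dim(data)) != 4) stop_input("volume data must be 4-D (x,y,z,frame)")
  fb <- as.matrix(frame_bounds)
  validate_frame_bounds(fb)
  if (dim(data)[4] != nrow(fb)) {
    stop_input("4th dimension (%d) does not match frame count (%d)",
               dim(data)[4], nrow(fb))
  }
  if (length(voxel_mm) == 1) voxel_mm <- rep(voxel_mm, 3)
  structure(list(data = data, frame_bounds = fb, voxel_mm = voxel_mm),
            class = "dynamic_volume")
}

#' 3-D volume-of-interest mask
#'
#' @param mask 3-D logical (or 0/1) array congruent with the volume grid.
#' @param label Text label.
#' @return An object of class `voi_mask`.
#' @export
voi_mask <- function(mask, label = "VOI") {
  if (length(dim(mask)) != 3) stop_input("mask must be a 3-D array")
  mask <- array(as.logical(mask), dim = dim(mask))
  if (!any(mask)) stop_input("mask '%s' selects no voxels", label)
  structure(list(mask = mask, label = label), class = "voi_mask")
}

#' Extract a VOI time-activity curve from a dynamic volume
#'
#' The per-frame statistic is the mean over the mask voxels (not the sum):
#' the analysis works on relative count rates, and a sum differs only by the
#' constant voxel count. No decay correction is applied here -- frame values
#' stay raw, and all decay handling lives in the model and the fitter.
#'
#' @param volume A [dynamic_volume()].
#' @param mask A [voi_mask()] with the same spatial grid.
#' @return A [tac()] labelled with the mask's label.
#' @export
extract_tac <- function(volume, mask) {
  stopifnot(inherits(volume, "dynamic_volume"), inherits(mask, "voi_mask"))
  if (!identical(dim(volume$data)[1:3], dim(mask$mask))) {
    stop_input("mask grid %s does not match volume grid %s",
               paste(dim(mask$mask), collapse = "x"),
               paste(dim(volume$data)[1:3], collapse = "x"))
  }
  idx <- which(mask$mask)
  nvox <- prod(dim(volume$data)[1:3])
  vals <- vapply(seq_len(nrow(volume$frame_bounds)), function(f) {
    frame <- volume$data[, , , f, drop = FALSE]
    mean(frame[idx])
  }, numeric(1))
  tac(volume$frame_bounds, vals, voi_label = mask$label)
}

#' Write / read a dynamic volume as NIfTI-1
#'
#' NIfTI-1 stores voxel size but not the frame timing, so the frame bounds
#' must travel separately (a JSON sidecar written next to the image).
#'
#' @param volume A [dynamic_volume()].
#' @param path Destination `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_dynamic_volume <- function(volume, path) {
  stopifnot(inherits(volume, "dynamic_volume"))
  img <- RNifti::asNifti(volume$data,
                         pixdim = c(volume$voxel_mm, 1))
  RNifti::writeNifti(img, path)
  sidecar <- paste0(sub("\\.nii(\\.gz)?$", "", path), "_frames.json")
  jsonlite::write_json(
    list(frame_start_min = volume$frame_bounds[, 1],
         frame_end_min = volume$frame_bounds[, 2]),
    sidecar, digits = NA)
  invisible(path)
}

#' @rdname write_dynamic_volume
#' @param frame_bounds Frame bounds; if `NULL`, the JSON sidecar written by
#'   [write_dynamic_volume()] is read.
#' @export
read_dynamic_volume <- function(path, frame_bounds = NULL) {
  if (!file.exists(path)) stop_input("image not found: %s", path)
  img <- RNifti::readNifti(path)
  if (is.null(frame_bounds)) {
    sidecar <- paste0(sub("\\.nii(\\.gz)?$", "", path), "_frames.json")
    if (!file.exists(sidecar)) {
      stop_input("no frame_bounds given and no sidecar %s", sidecar)
    }
    fr <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    frame_bounds <- cbind(fr$frame_start_min, fr$frame_end_min)
  }
  voxel_mm <- attr(img, "pixdim")[1:3]
  dynamic_volume(array(as.numeric(img), dim = dim(img)), frame_bounds,
                 voxel_mm = voxel_mm)
}

#' Write / read a VOI mask as NIfTI-1
#'
#' @param mask A [voi_mask()].
#' @param path Destination `.nii` / `.nii.gz` path.
#' @export
write_voi_mask <- function(mask, path) {
  stopifnot(inherits(mask, "voi_mask"))
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(mask$mask),
                                           dim = dim(mask$mask))), path)
  invisible(path)
}

#' @rdname write_voi_mask
#' @param label Label for the returned mask (default: file name).
#' @export
read_voi_mask <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop_input("mask not found: %s", path)
  img <- RNifti::readNifti(path)
  voi_mask(array(as.numeric(img), dim = dim(img)) != 0, label = label)
}
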