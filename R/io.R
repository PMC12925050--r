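# Readers/writers for the pipeline's file formats: multi-frame TIFF
# projection stacks (16-bit, with the quantization recorded in a JSON
# sidecar), segmentation and trajectory CSVs with fixed headers, and the
# ground-truth CSV. Headers are validated strictly so malformed inputs fail
# by name, not downstream.

SEGS_HEADER <- c("index", "gantry_deg", "col_px", "row_px", "ncc", "rot_deg",
                 "scale", "accepted")
TRAJ_HEADER <- c("index", "gantry_deg", "lr_mm", "si_mm", "ap_mm", "source")
TRUTH_HEADER <- c("index", "time_s", "gantry_deg", "lr_mm", "si_mm", "ap_mm",
                  "u_px", "v_px")

check_header <- function(d, expected, what, path) {
  if (!identical(names(d), expected)) {
    abort(sprintf(
      "%s '%s' has columns [%s]; expected exactly [%s].",
      what, path, paste(names(d), collapse = ","),
      paste(expected, collapse = ",")))
  }
  invisible(d)
}

#' Write or read a multi-frame TIFF projection stack
#'
#' Frames are float images quantized to 16 bits; the affine reconstruction
#' `value = stored * scale + offset` is recorded in a JSON sidecar
#' (`intensity.json` next to the stack by default) and applied on read.
#'
#' @param frames List of numeric matrices, one per projection, in
#'   projection-index order.
#' @param path Path of the `.tif` file.
#' @param intensity_path Path of the quantization sidecar.
#' @return `write_projection_stack()`: the path, invisibly.
#'   `read_projection_stack()`: a list of numeric matrices.
#' @export
write_projection_stack <- function(frames, path,
                                   intensity_path = file.path(dirname(path),
                                                              "intensity.json")) {
  stopifnot(is.list(frames), length(frames) > 0)
  lo <- min(vapply(frames, min, numeric(1)))
  hi <- max(vapply(frames, max, numeric(1)))
  scale <- max(hi - lo, .Machine$double.eps)
  norm <- purrr::map(frames, function(f) (f - lo) / scale)
  tiff::writeTIFF(norm, path, bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(
    list(offset = lo, scale = scale, n_frames = length(frames)),
    intensity_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_projection_stack
#' @export
read_projection_stack <- function(path,
                                  intensity_path = file.path(dirname(path),
                                                             "intensity.json")) {
  if (!file.exists(path)) abort(sprintf("projection stack not found: %s", path))
  frames <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(frames)) frames <- list(frames)
  if (file.exists(intensity_path)) {
    q <- jsonlite::read_json(intensity_path, simplifyVector = TRUE)
    if (!is.null(q$n_frames) && q$n_frames != length(frames)) {
      abort(sprintf("stack '%s' has %d frames but sidecar records %d.",
                    path, length(frames), q$n_frames))
    }
    frames <- purrr::map(frames, function(f) f * q$scale + q$offset)
  }
  frames
}

#' Read or write pipeline CSV tables
#'
#' Fixed-header CSVs: segmentations
#' (`index,gantry_deg,col_px,row_px,ncc,rot_deg,scale,accepted`),
#' trajectories (`index,gantry_deg,lr_mm,si_mm,ap_mm,source`, where `source`
#' is one of `truth`, `filtered`, `raw`) and phantom ground truth
#' (`index,time_s,gantry_deg,lr_mm,si_mm,ap_mm,u_px,v_px`). Unexpected or
#' missing columns are rejected by name.
#'
#' @param path CSV path.
#' @return The validated tibble.
#' @export
read_segmentations <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(.default = readr::col_double(),
                                               accepted = readr::col_logical()))
  check_header(d, SEGS_HEADER, "segmentations CSV", path)
  d$index <- as.integer(d$index)
  d
}

#' @rdname read_segmentations
#' @param segs Segmentations tibble ([segment_scan()] output, filtered or not).
#' @export
write_segmentations <- function(segs, path) {
  out <- dplyr::select(segs, dplyr::all_of(SEGS_HEADER))
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname read_segmentations
#' @export
read_trajectory <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(.default = readr::col_double(),
                                               source = readr::col_character()))
  check_header(d, TRAJ_HEADER, "trajectory CSV", path)
  d$index <- as.integer(d$index)
  d
}

#' @rdname read_segmentations
#' @param traj Trajectory tibble; a `source` column is added if absent.
#' @param source Label recorded in the `source` column when missing.
#' @export
write_trajectory <- function(traj, path, source = "filtered") {
  if (!"source" %in% names(traj)) traj$source <- source
  out <- dplyr::select(traj, dplyr::all_of(TRAJ_HEADER))
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname read_segmentations
#' @export
read_truth <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(.default = readr::col_double()))
  check_header(d, TRUTH_HEADER, "ground-truth CSV", path)
  d$index <- as.integer(d$index)
  d
}
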