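# Interchange: multi-channel TIFF with a JSON sidecar (pixel size, channel
# roles, per-channel intensity scale, optional timestamps), manifests as
# JSON, tables as headed CSV.

#' Write / read a spindle image as TIFF + JSON sidecar
#'
#' Channels are written as one 32-bit float TIFF directory each.  TIFF
#' storage here is confined to `[0, 1]`, so each channel is divided by its
#' maximum on write and the scale is recorded in the sidecar; reading
#' restores the original photon units.
#'
#' @param image a `spindle_image`.
#' @param path path to the `.tif` file; the sidecar is written next to it
#'   as `<path>.json`.
#' @param timestamps_s optional frame timestamps to record (for stacks
#'   written frame-by-frame).
#' @return `write_spindle_image` returns `path` invisibly;
#'   `read_spindle_image` returns the `spindle_image`.
#' @export
write_spindle_image <- function(image, path, timestamps_s = NULL) {
  stopifnot(inherits(image, "spindle_image"))
  mats <- lapply(image$channels, function(ch) image$data[, , ch])
  scales <- vapply(mats, function(m) max(m, 1e-12), numeric(1))
  tiff::writeTIFF(Map(function(m, s) m / s, mats, scales), path,
                  bits.per.sample = 32L, reduce = FALSE)
  sidecar <- list(pixel_size_um = image$pixel_size_um,
                  channels = image$channels,
                  channel_scale_max = as.list(setNames(scales,
                                                       image$channels)))
  if (!is.null(timestamps_s)) sidecar$timestamps_s <- timestamps_s
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_spindle_image
#' @export
read_spindle_image <- function(path) {
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  mats <- tiff::readTIFF(path, all = TRUE)
  channels <- as.character(sidecar$channels)
  if (length(mats) != length(channels))
    stopf("TIFF has %d directories but sidecar names %d channels",
          length(mats), length(channels))
  scaled <- Map(function(m, ch) m * sidecar$channel_scale_max[[ch]],
                mats, channels)
  names(scaled) <- channels
  new_spindle_image(scaled, sidecar$pixel_size_um)
}

#' Write / read a ground-truth manifest as JSON
#'
#' Function-valued fields (time-dependence of a time-lapse spec) are not
#' serialisable and are dropped with a note; the per-frame values actually
#' applied are already recorded in the manifest.
#'
#' @param m a `ground_truth_manifest`.
#' @param path JSON path.
#' @return `write_manifest` returns `path` invisibly; `read_manifest` the
#'   manifest list.
#' @export
write_manifest <- function(m, path) {
  stopifnot(inherits(m, "ground_truth_manifest"))
  drop_funs <- function(x) {
    if (is.function(x)) return("<function: not serialised>")
    if (is.list(x)) return(lapply(x, drop_funs))
    x
  }
  jsonlite::write_json(drop_funs(unclass(m)), path, auto_unbox = TRUE,
                       digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "ground_truth_manifest")
}

read_checked_csv <- function(path, need) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(need %in% names(df)))
    stopf("%s must have columns: %s", basename(path),
          paste(need, collapse = ", "))
  df
}

#' Readers for the pipeline's CSV interchange formats
#'
#' Thin wrappers around [utils::read.csv()] that validate the expected
#' header: per-field counts (`condition, replicate, field_id, total,
#' mitotic, multipolar`), growth curves (`condition, well_id, time_h,
#' count`), dose-response wells (`concentration_nM, replicate, signal`,
#' optional `role`), and line specifications (`cell_id, anchor_row,
#' anchor_col, toward_row, toward_col, length_um, width_px`, coordinates in
#' micrometres).
#'
#' @param path CSV path.
#' @return A validated data.frame.
#' @export
read_counts_csv <- function(path) {
  read_checked_csv(path, c("condition", "replicate", "field_id", "total",
                           "mitotic", "multipolar"))
}

#' @rdname read_counts_csv
#' @export
read_growth_csv <- function(path) {
  read_checked_csv(path, c("condition", "well_id", "time_h", "count"))
}

#' @rdname read_counts_csv
#' @export
read_dose_csv <- function(path) {
  read_checked_csv(path, c("concentration_nM", "replicate", "signal"))
}

#' @rdname read_counts_csv
#' @export
read_lines_csv <- function(path) {
  read_checked_csv(path, c("cell_id", "anchor_row", "anchor_col",
                           "toward_row", "toward_col", "length_um",
                           "width_px"))
}
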