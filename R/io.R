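# Movie I/O: multi-frame TIFF plus a JSON sidecar carrying calibration and
# (for synthetic movies) ground truth. TIFF samples are stored in [0, 1]
# and rescaled through an explicit scale recorded in the sidecar — height
# maps as 32-bit float (nm after rescaling), fluorescence as 16-bit
# unsigned integers (counts).

#' Write an AFM height movie as TIFF + JSON sidecar
#'
#' @param x a `ring_movie`, or a (rows, cols, frames) numeric array.
#' @param path output TIFF path; the sidecar is written next to it as
#'   `<path>.json`.
#' @param pixel_size,frame_rate required when `x` is a bare array.
#' @return `path`, invisibly.
#' @export
write_height_movie <- function(x, path, pixel_size = NULL, frame_rate = NULL) {
  if (inherits(x, "ring_movie")) {
    arr <- x$movie; pixel_size <- x$pixel_size; frame_rate <- x$frame_rate
    truth <- list(molecules = x$molecules,
                  open_subunits = lapply(x$truth, function(s)
                    lapply(s$open, as.integer)))
  } else {
    arr <- x; truth <- NULL
    stop_if(is.null(pixel_size) || is.null(frame_rate),
            "pixel_size and frame_rate required for a bare array")
  }
  offset <- min(arr)
  scale <- max(max(arr) - offset, 1e-12)
  frames <- lapply(seq_len(dim(arr)[3]), function(f)
    (arr[, , f] - offset) / scale)
  tiff::writeTIFF(frames, path, bits.per.sample = 32L)
  meta <- list(kind = "afm_height_movie", pixel_size_nm = pixel_size,
               frame_rate_hz = frame_rate, height_scale_nm = scale,
               height_offset_nm = offset,
               n_frames = dim(arr)[3], truth = truth)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' Read an AFM height movie written by [write_height_movie()]
#'
#' @param path TIFF path (sidecar expected at `<path>.json`).
#' @return list: `movie` (array, nm), `pixel_size`, `frame_rate`, `truth`
#'   (NULL for instrument data).
#' @export
read_height_movie <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  frames <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, dim = c(dim(frames[[1]]), length(frames)))
  for (f in seq_along(frames))
    arr[, , f] <- frames[[f]] * meta$height_scale_nm +
      (meta$height_offset_nm %||% 0)
  truth <- meta$truth
  if (!is.null(truth$open_subunits)) {
    truth$series <- lapply(truth$open_subunits, function(s)
      ring_state_series(lapply(s, function(v)
        if (length(v) == 0) integer(0) else as.integer(v)),
        meta$frame_rate_hz))
  }
  list(movie = arr, pixel_size = meta$pixel_size_nm,
       frame_rate = meta$frame_rate_hz, truth = truth)
}

#' Write a two-channel curtain movie as TIFFs + JSON sidecar
#'
#' @param x a `curtain_movie`.
#' @param prefix output prefix: writes `<prefix>_green.tif`,
#'   `<prefix>_red.tif` and `<prefix>.json`.
#' @return `prefix`, invisibly.
#' @export
write_curtain_movie <- function(x, prefix) {
  stopifnot(inherits(x, "curtain_movie"))
  scale <- max(x$green, x$red, 1)
  wr <- function(arr, path) {
    frames <- lapply(seq_len(dim(arr)[3]), function(f)
      pmin(pmax(arr[, , f] / scale, 0), 1))
    tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  }
  wr(x$green, paste0(prefix, "_green.tif"))
  wr(x$red, paste0(prefix, "_red.tif"))
  meta <- list(kind = "curtain_movie", intensity_scale = scale,
               flow_schedule = x$flow_schedule, barrier_row = x$barrier_row,
               dna_length_px = x$dna_length_px, bp_per_px = x$bp_per_px,
               dna = x$dna, spots = x$spots, distractors = x$distractors)
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(prefix)
}

#' Read a curtain movie written by [write_curtain_movie()]
#'
#' @param prefix prefix used at write time.
#' @return An object of class `curtain_movie` (intensities in counts,
#'   quantised by the 16-bit storage).
#' @export
read_curtain_movie <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  rd <- function(path) {
    frames <- tiff::readTIFF(path, all = TRUE)
    arr <- array(0, dim = c(dim(frames[[1]]), length(frames)))
    for (f in seq_along(frames)) arr[, , f] <- frames[[f]] * meta$intensity_scale
    arr
  }
  structure(list(green = rd(paste0(prefix, "_green.tif")),
                 red = rd(paste0(prefix, "_red.tif")),
                 flow_schedule = as.logical(meta$flow_schedule),
                 dna = as.data.frame(meta$dna),
                 spots = as.data.frame(meta$spots),
                 distractors = as.data.frame(meta$distractors),
                 barrier_row = meta$barrier_row,
                 dna_length_px = meta$dna_length_px,
                 bp_per_px = meta$bp_per_px, params = NULL),
            class = "curtain_movie")
}
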