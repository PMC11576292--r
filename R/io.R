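# File formats: trace CSV, multi-page TIFF stacks with JSON sidecar
# metadata, run-length-encoded masks.

#' Write traces to CSV
#'
#' Long format with columns `time_s, intensity, roi_id, compartment,
#' condition, cell_class` (the schema shared by the generator and the
#' extraction step).
#'
#' @param traces A single [fluorescence_trace()] or a list of them.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_traces_csv <- function(traces, path) {
  if (inherits(traces, "fluorescence_trace")) traces <- list(traces)
  rows <- lapply(traces, function(tr) {
    md <- tr$metadata
    data.frame(time_s = tr$time, intensity = tr$intensity,
               roi_id = md$roi_id %||% NA_character_,
               compartment = md$compartment %||% NA_character_,
               condition = md$condition %||% NA_character_,
               cell_class = md$cell_class %||% NA_character_,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read traces from CSV
#'
#' Inverse of [write_traces_csv()]; one trace per (roi_id, compartment).
#'
#' @param path CSV path.
#' @return Named list of [fluorescence_trace()] objects
#'   (`"<roi_id>/<compartment>"`).
#' @export
read_traces_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "intensity", "roi_id", "compartment")
  if (!all(need %in% names(df)))
    stop("trace CSV must contain columns ", paste(need, collapse = ", "))
  keys <- unique(df[, c("roi_id", "compartment")])
  out <- list()
  for (i in seq_len(nrow(keys))) {
    sub <- df[df$roi_id == keys$roi_id[i] &
                df$compartment == keys$compartment[i], ]
    sub <- sub[order(sub$time_s), ]
    out[[paste(keys$roi_id[i], keys$compartment[i], sep = "/")]] <-
      fluorescence_trace(sub$time_s, sub$intensity, metadata = list(
        roi_id = keys$roi_id[i], compartment = keys$compartment[i],
        condition = sub$condition[1], cell_class = sub$cell_class[1]))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct an image stack
#'
#' A two-channel time-lapse: channel 1 is the EGFP morphology channel,
#' channel 2 the TMRE potentiometric channel.
#'
#' @param data Numeric array `[T, C, Y, X]`, non-negative, `T >= 2`, `C == 2`.
#' @param frame_interval Physical frame interval (s).
#' @param pixel_size Pixel size (um).
#' @param treatment_time Treatment application time after recording start (s).
#' @param channels Channel labels.
#' @return Object of class `image_stack` with a `time` vector in seconds
#'   relative to treatment.
#' @export
image_stack <- function(data, frame_interval, pixel_size,
                        treatment_time = 0,
                        channels = c("EGFP", "TMRE")) {
  d <- dim(data)
  if (length(d) != 4) stop("data must be a [T, C, Y, X] array")
  if (d[1] < 2) stop("stack must contain at least 2 frames")
  if (d[2] != 2) stop("stack must contain exactly 2 channels")
  if (any(data < 0)) stop("intensities must be non-negative")
  structure(list(data = data, frame_interval = frame_interval,
                 pixel_size = pixel_size, treatment_time = treatment_time,
                 channels = channels,
                 time = (seq_len(d[1]) - 1) * frame_interval - treatment_time),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_stack> %d frames x %d ch x %d x %d px; dt = %g s; %g um/px\n",
              d[1], d[2], d[3], d[4], x$frame_interval, x$pixel_size))
  invisible(x)
}

#' Write an image stack as multi-page TIFF plus JSON metadata sidecar
#'
#' Pages are ordered frame-major (`T` outer, channel inner: EGFP then TMRE).
#' Intensities are stored as 32-bit floats scaled to `[0, 1]` by `scale`
#' (recorded in the sidecar so reading restores original units).
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path; the sidecar is written at `<path>.json`.
#' @param scale Intensity divisor used for storage.
#' @return Invisibly, `path`.
#' @export
write_stack_tiff <- function(stack, path, scale = max(stack$data, 1)) {
  d <- dim(stack$data)
  pages <- vector("list", d[1] * d[2])
  k <- 0
  for (t in seq_len(d[1])) for (c in seq_len(d[2])) {
    k <- k + 1
    pages[[k]] <- stack$data[t, c, , ] / scale
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32)
  jsonlite::write_json(
    list(frames = d[1], channels = stack$channels,
         frame_interval = stack$frame_interval,
         pixel_size = stack$pixel_size,
         treatment_time = stack$treatment_time, scale = scale),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image stack written by [write_stack_tiff()]
#'
#' @param path TIFF path (expects the `<path>.json` sidecar).
#' @return An [image_stack()].
#' @export
read_stack_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  nt <- meta$frames; nc <- length(meta$channels)
  if (length(pages) != nt * nc) stop("page count does not match sidecar metadata")
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  arr <- array(0, c(nt, nc, ny, nx))
  k <- 0
  for (t in seq_len(nt)) for (c in seq_len(nc)) {
    k <- k + 1
    arr[t, c, , ] <- pages[[k]] * meta$scale
  }
  image_stack(arr, meta$frame_interval, meta$pixel_size,
              meta$treatment_time, meta$channels)
}

# Run-length encode a logical mask (column-major over the [Y, X] grid).
mask_to_rle <- function(mask) {
  r <- rle(as.vector(mask))
  list(dim = dim(mask), lengths = r$lengths, values = as.integer(r$values))
}

rle_to_mask <- function(x) {
  m <- matrix(inverse.rle(list(lengths = x$lengths,
                               values = as.logical(x$values))),
              x$dim[1], x$dim[2])
  m
}

#' Write compartment masks as run-length JSON
#'
#' Serializes one or more compartment mask sets (logical `[Y, X]` matrices,
#' pixel-centred, 0-based row-major convention documented per mask) to a
#' plain-text JSON file.
#'
#' @param mask_sets Named list of mask sets, each a named list of logical
#'   matrices.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_masks_json <- function(mask_sets, path) {
  enc <- lapply(mask_sets, function(set) lapply(set, mask_to_rle))
  jsonlite::write_json(enc, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read masks written by [write_masks_json()]
#' @param path JSON path.
#' @return Named list of mask sets of logical matrices.
#' @export
read_masks_json <- function(path) {
  enc <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(enc, function(set) lapply(set, function(x)
    rle_to_mask(list(dim = unlist(x$dim), lengths = unlist(x$lengths),
                     values = unlist(x$values)))))
}
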