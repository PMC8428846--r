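#' Construct a frame stack
#'
#' A frame stack is the carrier for all pixel-level analysis: a
#' `frames x height x width` array of 8-bit grayscale values (stored as
#' numeric 0-255) with the frame rate and the 0-based stimulus-onset frame
#' attached as attributes.
#'
#' @param data 3-d numeric array (`frames x height x width`), or a list of
#'   equally sized matrices (one per frame).
#' @param fps Frames per second.
#' @param onset_frame 0-based stimulus-onset frame index; must lie within the
#'   stack.
#' @return A `frame_stack` object.
#' @examples
#' fs <- frame_stack(array(0, dim = c(3, 4, 4)), fps = 1000, onset_frame = 1)
#' dim(fs)
#' @export
frame_stack <- function(data, fps, onset_frame) {
  if (is.list(data)) {
    dims <- unique(lapply(data, dim))
    if (length(dims) != 1L) abort("all frames must have identical dimensions.",
                                  class = "pawkit_format_error")
    arr <- array(0, dim = c(length(data), dims[[1]]))
    for (i in seq_along(data)) arr[i, , ] <- data[[i]]
    data <- arr
  }
  if (length(dim(data)) != 3L) abort("`data` must be a frames x height x width array.",
                                     class = "pawkit_format_error")
  if (fps <= 0) abort("`fps` must be > 0.", class = "pawkit_config_error")
  onset_frame <- as.integer(onset_frame)
  if (onset_frame < 0 || onset_frame >= dim(data)[1]) {
    abort(sprintf("onset frame %d outside stack of %d frames.", onset_frame,
                  dim(data)[1]),
          class = "pawkit_config_error")
  }
  structure(data, fps = fps, onset_frame = onset_frame,
            class = c("frame_stack", "array"))
}

n_frames <- function(stack) dim(stack)[1]

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<frame_stack> %d frames of %d x %d @ %g fps, onset frame %d\n",
              d[1], d[2], d[3], attr(x, "fps"), attr(x, "onset_frame")))
  invisible(x)
}

#' Read a frame stack from disk
#'
#' Reads high-speed grayscale recordings stored either as a directory of
#' per-frame PNG images (lexicographic frame order) or as a multi-page TIFF.
#' Multi-channel images are collapsed to luminance (Rec. 601 weights).
#'
#' @param path Directory of `.png` frames or a `.tif`/`.tiff` file.
#' @param config A [run_config()]; supplies `fps` and `onset_frame`.
#' @return A [frame_stack()].
#' @export
read_frame_stack <- function(path, config) {
  stopifnot(inherits(config, "pawkit_config"))
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (length(files) == 0L) {
      abort(sprintf("no PNG frames found in '%s'.", path),
            class = "pawkit_format_error")
    }
    frames <- lapply(files, function(f) to_gray8(png::readPNG(f)))
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!file.exists(path)) abort(sprintf("file '%s' does not exist.", path),
                                  class = "pawkit_format_error")
    imgs <- tiff::readTIFF(path, all = TRUE)
    if (is.array(imgs) && !is.list(imgs)) imgs <- list(imgs)
    frames <- lapply(imgs, to_gray8)
  } else {
    abort(sprintf("'%s' is neither a PNG directory nor a TIFF file.", path),
          class = "pawkit_format_error")
  }
  frame_stack(frames, fps = config$fps, onset_frame = config$onset_frame)
}

# collapse [0,1]-scaled image (possibly multi-channel) to 8-bit luminance
to_gray8 <- function(img) {
  if (length(dim(img)) == 3L) {
    nc <- dim(img)[3]
    w <- switch(as.character(min(nc, 3L)),
                "1" = 1, "2" = c(1, 0), "3" = c(0.299, 0.587, 0.114))
    g <- matrix(0, nrow(img), ncol(img))
    for (k in seq_along(w)) g <- g + w[k] * img[, , k]
    img <- g
  }
  round(img * 255)
}

#' Write a frame stack to disk
#'
#' Inverse of [read_frame_stack()]: writes per-frame PNGs into a directory
#' (created if missing) or a multi-page TIFF, after clipping to 0-255 and
#' rounding to integers. Round-tripping an 8-bit integer stack is lossless.
#'
#' @param stack A [frame_stack()].
#' @param path Output directory (PNG mode) or `.tif` path.
#' @param format `"png"` or `"tiff"`.
#' @return `path`, invisibly.
#' @export
write_frame_stack <- function(stack, path, format = c("png", "tiff")) {
  format <- match.arg(format)
  vals <- pmin(pmax(round(unclass(stack)), 0), 255) / 255
  if (format == "png") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_len(n_frames(stack))) {
      png::writePNG(vals[i, , ], file.path(path, sprintf("frame_%06d.png", i - 1L)))
    }
  } else {
    tiff::writeTIFF(lapply(seq_len(n_frames(stack)), function(i) vals[i, , ]),
                    path, bits.per.sample = 8L)
  }
  invisible(path)
}
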