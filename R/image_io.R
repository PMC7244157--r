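#' Load a single grayscale channel image, normalized to \[0, 1\]
#'
#' Reads a single-plane grayscale TIFF or PNG and rescales intensities to
#' \[0, 1\] by dividing by the maximum representable value of the source
#' bit depth (255 for 8-bit, 65535 for 16-bit).  Floating-point images must
#' already lie in \[0, 1\] and are passed through unchanged.
#'
#' @param path Path to a single-page grayscale TIFF or PNG file.
#' @param bit_depth_policy How to choose the normalization divisor:
#'   `"auto"` (default) infers it from the stored sample format, `"u8"`
#'   forces 255, `"u16"` forces 65535, `"float"` requires values already in
#'   \[0, 1\].
#' @return A numeric matrix with values in \[0, 1\].
#' @examples
#' f <- tempfile(fileext = ".tif")
#' write_channel(matrix(runif(64), 8, 8), f)
#' x <- load_channel(f)
#' range(x)
#' @export
load_channel <- function(path, bit_depth_policy = c("auto", "u8", "u16", "float")) {
  bit_depth_policy <- match.arg(bit_depth_policy)
  if (!file.exists(path)) abort(sprintf("file does not exist: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    raw <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE),
      error = function(e) abort(sprintf("cannot read TIFF %s: %s", path, conditionMessage(e))))
    if (length(raw) != 1L) abort(sprintf("multi-page TIFF not supported: %s", path))
    raw <- raw[[1L]]
    # as.is = TRUE keeps raw integer sample values; float samples come back
    # unchanged (already in [0, 1])
    bps <- attr(raw, "bits.per.sample")
    fmt <- attr(raw, "sample.format")
    is_float <- identical(fmt, "float") ||
      (max(raw) <= 1 && (is.null(bps) || bps > 16))
  } else if (ext == "png") {
    raw <- tryCatch(png::readPNG(path, native = FALSE),
      error = function(e) abort(sprintf("cannot read PNG %s: %s", path, conditionMessage(e))))
    # readPNG already divides by the bit-depth maximum.
    if (length(dim(raw)) == 3L) abort(sprintf("RGB/multi-channel image not supported: %s", path))
    return(unclass(raw))
  } else {
    abort(sprintf("unsupported image format '%s' (use TIFF or PNG)", ext))
  }
  if (length(dim(raw)) == 3L) abort(sprintf("RGB/multi-channel image not supported: %s", path))
  raw <- matrix(as.numeric(raw), nrow(raw), ncol(raw))
  divisor <- switch(bit_depth_policy,
    u8 = 255,
    u16 = 65535,
    float = 1,
    auto = {
      if (is_float) 1
      else if (!is.null(bps) && bps <= 8) 255
      else 65535
    }
  )
  out <- raw / divisor
  if (min(out) < 0 || max(out) > 1) {
    abort(sprintf("intensities outside [0, 1] after normalization (policy '%s'): %s",
                  bit_depth_policy, path))
  }
  out
}

#' Write a \[0, 1\] intensity matrix to disk
#'
#' Intensities are written as 16-bit grayscale TIFF (the round trip with
#' [load_channel()] reproduces values within 1/65535) or as grayscale PNG.
#'
#' @param x Numeric matrix with values in \[0, 1\].
#' @param path Output path; extension selects TIFF (`.tif`/`.tiff`) or PNG.
#' @param bits Bits per sample for TIFF output (8 or 16; default 16).
#' @return `path`, invisibly.
#' @export
write_channel <- function(x, path, bits = 16L) {
  assert_intensity_matrix(x)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(x, path, bits.per.sample = as.integer(bits))
  } else if (ext == "png") {
    png::writePNG(x, path)
  } else {
    abort(sprintf("unsupported output format '%s'", ext))
  }
  invisible(path)
}

#' Bundle per-channel matrices into a validated multi-channel image
#'
#' @param channels Named list of numeric matrices in \[0, 1\]; must contain
#'   exactly one each of `DAPI`, `SOX10`, `EdU` and `VIME` (extra channels
#'   are allowed) and all matrices must share the same dimensions.
#' @param source_paths Optional named character vector of per-channel
#'   provenance strings.
#' @return A `cyto_image` object: a list with elements `channels`,
#'   `height`, `width`, `channel_names` and `source_paths`.
#' @export
cyto_image <- function(channels, source_paths = NULL) {
  if (is.null(names(channels)) || any(!nzchar(names(channels)))) {
    abort("`channels` must be a fully named list")
  }
  for (ch in CHANNELS) {
    if (sum(names(channels) == ch) != 1L) {
      abort(sprintf("channel '%s' must be present exactly once", ch))
    }
  }
  dims <- vapply(channels, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    abort("all channels must share identical height x width")
  }
  for (ch in names(channels)) assert_intensity_matrix(channels[[ch]], ch)
  if (is.null(source_paths)) {
    source_paths <- stats::setNames(rep("<in-memory>", length(channels)), names(channels))
  }
  structure(
    list(
      channels = channels,
      height = unname(dims[1, 1]),
      width = unname(dims[2, 1]),
      channel_names = names(channels),
      source_paths = source_paths
    ),
    class = "cyto_image"
  )
}

#' Assemble a multi-channel image from per-channel files
#'
#' @param channel_paths Named character vector or list mapping channel name
#'   (`DAPI`, `SOX10`, `EdU`, `VIME`, ...) to a file path.
#' @param bit_depth_policy Passed to [load_channel()].
#' @return A [cyto_image()] object.
#' @export
assemble_image <- function(channel_paths, bit_depth_policy = "auto") {
  channel_paths <- unlist(channel_paths)
  missing <- setdiff(CHANNELS, names(channel_paths))
  if (length(missing)) {
    abort(sprintf("missing required channel(s): %s", paste(missing, collapse = ", ")))
  }
  channels <- lapply(channel_paths, load_channel, bit_depth_policy = bit_depth_policy)
  cyto_image(channels, source_paths = stats::setNames(as.character(channel_paths),
                                                      names(channel_paths)))
}

#' @export
print.cyto_image <- function(x, ...) {
  cat(sprintf("<cyto_image> %d x %d px, %d channels: %s\n",
              x$height, x$width, length(x$channels),
              paste(x$channel_names, collapse = ", ")))
  invisible(x)
}
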