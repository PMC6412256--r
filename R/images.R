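#' Load a colour image as a normalised RGB array
#'
#' Reads a PNG or JPEG file (decided by file extension, falling back to the
#' PNG magic bytes) into an `H x W x 3` array of sRGB components in `[0, 1]`.
#' 8-bit and 16-bit inputs are both normalised to `[0, 1]` by the decoders.
#' An alpha channel is dropped with a warning; greyscale images are an error
#' because the sensor needs all three colour channels.
#'
#' @param path path to a PNG or JPEG file.
#' @return an `image_rgb` object: numeric array `H x W x 3` in `[0, 1]`.
#' @seealso [write_image()], [rgb_to_lab()]
#' @export
load_image <- function(path) {
  if (!is.character(path) || length(path) != 1L)
    stop("`path` must be a single file path")
  if (!file.exists(path)) stop("image file does not exist: ", path)
  ext <- tolower(tools::file_ext(path))
  kind <- if (ext %in% c("png")) "png"
          else if (ext %in% c("jpg", "jpeg")) "jpeg"
          else .sniff_image_kind(path)
  px <- tryCatch(
    switch(kind, png = png::readPNG(path), jpeg = jpeg::readJPEG(path)),
    error = function(e) stop("cannot decode '", path, "': ", conditionMessage(e))
  )
  as_image_rgb(px, what = path)
}

# Magic-byte sniffing for files with unhelpful extensions.
.sniff_image_kind <- function(path) {
  magic <- readBin(path, "raw", n = 4L)
  if (length(magic) >= 4L && identical(magic[1:4],
      as.raw(c(0x89, 0x50, 0x4e, 0x47)))) return("png")
  if (length(magic) >= 2L && identical(magic[1:2], as.raw(c(0xff, 0xd8))))
    return("jpeg")
  stop("not a PNG or JPEG file: ", path)
}

#' Coerce an array to a validated `image_rgb`
#'
#' @param px numeric array, `H x W x 3` (or `H x W x 4`; alpha dropped with a
#'   warning). Values must lie in `[0, 1]`.
#' @param what label used in error messages.
#' @return an `image_rgb` array.
#' @export
as_image_rgb <- function(px, what = "image") {
  if (is.matrix(px))
    stop("'", what, "' is single-channel; a 3-channel colour image is required")
  if (!is.array(px) || length(dim(px)) != 3L)
    stop("'", what, "' is not an H x W x channel image array")
  nc <- dim(px)[3L]
  if (nc == 4L) {
    warning("'", what, "': alpha channel dropped")
    px <- px[, , 1:3, drop = FALSE]
  } else if (nc != 3L) {
    stop("'", what, "' has ", nc, " channels; 3 (RGB) required")
  }
  if (anyNA(px) || min(px) < 0 || max(px) > 1)
    stop("'", what, "': RGB components must be finite and within [0, 1]")
  structure(px, class = "image_rgb")
}

#' Write an RGB array to a PNG file
#'
#' @param img `image_rgb` array (values in `[0, 1]`).
#' @param path output path; the format is always PNG (lossless).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  px <- unclass(img)
  storage.mode(px) <- "double"
  png::writePNG(pmin(pmax(px, 0), 1), path)
  invisible(path)
}

#' Read or write a binary pixel mask
#'
#' Masks are stored as single-channel PNGs with 0 = excluded and
#' 255 = included (any value > 127 counts as included on read).
#'
#' @param path PNG path.
#' @return `read_mask()`: a logical `H x W` matrix.
#' @export
read_mask <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1L]
  px > 0.5
}

#' @rdname read_mask
#' @param mask logical `H x W` matrix.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.matrix(mask))
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}
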