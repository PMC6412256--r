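# sRGB (D65) <-> CIE 1976 L*a*b* conversion.
#
# Pipeline: sRGB in [0,1] -> linear RGB (IEC 61966-2-1 transfer curve)
# -> CIE XYZ (sRGB primaries, D65 white) -> CIELAB with D65 reference white.
# D65 is the white point the sRGB standard assumes for consumer-camera images.

# sRGB linear RGB -> XYZ matrix (rows X, Y, Z), D65.
.M_RGB2XYZ <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041), nrow = 3, byrow = TRUE)
.M_XYZ2RGB <- solve(.M_RGB2XYZ)
.WHITE_D65 <- c(X = 0.950470, Y = 1.000000, Z = 1.088830)

.srgb_decode <- function(u) {
  ifelse(u <= 0.04045, u / 12.92, ((u + 0.055) / 1.055)^2.4)
}
.srgb_encode <- function(u) {
  ifelse(u <= 0.0031308, 12.92 * u, 1.055 * u^(1 / 2.4) - 0.055)
}

# CIELAB companding function and inverse; delta = 6/29.
.lab_f <- function(t) {
  d3 <- (6 / 29)^3
  ifelse(t > d3, t^(1 / 3), t / (3 * (6 / 29)^2) + 4 / 29)
}
.lab_finv <- function(t) {
  d <- 6 / 29
  ifelse(t > d, t^3, 3 * d^2 * (t - 4 / 29))
}

#' Convert sRGB to CIELAB
#'
#' Accepts either an [load_image()] result (`H x W x 3` array) or an `n x 3`
#' matrix of sRGB triples in `[0, 1]`. Conversion assumes sRGB primaries and
#' the D65 reference white; output channels are `L` in `[0, 100]` and the
#' opponent channels `a` (green-red) and `b` (blue-yellow).
#'
#' @param img `image_rgb` array or `n x 3` numeric matrix in `[0, 1]`.
#' @return an `image_lab` array of the same spatial shape, or an `n x 3`
#'   matrix with columns `L`, `a`, `b`.
#' @export
rgb_to_lab <- function(img) {
  dims <- dim(img)
  m <- .channels_as_matrix(img)
  if (min(m) < -1e-9 || max(m) > 1 + 1e-9)
    stop("RGB components must lie in [0, 1]")
  xyz <- .srgb_decode(m) %*% t(.M_RGB2XYZ)
  fx <- .lab_f(xyz[, 1] / .WHITE_D65[1])
  fy <- .lab_f(xyz[, 2] / .WHITE_D65[2])
  fz <- .lab_f(xyz[, 3] / .WHITE_D65[3])
  lab <- cbind(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
  .matrix_as_channels(lab, dims, class = "image_lab")
}

#' Convert CIELAB to sRGB
#'
#' Inverse of [rgb_to_lab()]. Out-of-gamut results are clipped to `[0, 1]`
#' (relevant when synthetic noise pushes colours outside the sRGB gamut).
#'
#' @param lab `image_lab` array or `n x 3` matrix with columns `L`, `a`, `b`.
#' @return `image_rgb` array or `n x 3` sRGB matrix in `[0, 1]`.
#' @export
lab_to_rgb <- function(lab) {
  dims <- dim(lab)
  m <- .channels_as_matrix(lab)
  fy <- (m[, 1] + 16) / 116
  fx <- fy + m[, 2] / 500
  fz <- fy - m[, 3] / 200
  xyz <- cbind(.lab_finv(fx) * .WHITE_D65[1],
               .lab_finv(fy) * .WHITE_D65[2],
               .lab_finv(fz) * .WHITE_D65[3])
  rgb <- .srgb_encode(pmin(pmax(xyz %*% t(.M_XYZ2RGB), 0), 1))
  rgb <- pmin(pmax(rgb, 0), 1)
  .matrix_as_channels(rgb, dims, class = "image_rgb")
}

# Flatten H x W x 3 to (H*W) x 3 (or pass an n x 3 matrix through).
.channels_as_matrix <- function(x) {
  if (is.matrix(x)) {
    if (ncol(x) != 3L) stop("matrix input must have 3 columns")
    return(unclass(x))
  }
  d <- dim(x)
  if (length(d) != 3L || d[3L] != 3L) stop("expected an H x W x 3 array")
  matrix(as.numeric(x), d[1L] * d[2L], 3L)
}

.matrix_as_channels <- function(m, dims, class) {
  if (is.null(dims) || length(dims) == 2L) {  # matrix in, matrix out
    colnames(m) <- switch(class, image_lab = c("L", "a", "b"),
                          c("R", "G", "B"))
    return(m)
  }
  structure(array(m, dims), class = class)
}

#' Pixels of a Lab image as an `n x 3` matrix
#'
#' @param img `image_lab` array.
#' @param mask optional logical `H x W` matrix selecting pixels.
#' @return matrix with columns `L`, `a`, `b`, one row per (selected) pixel.
#' @export
lab_pixels <- function(img, mask = NULL) {
  m <- .channels_as_matrix(img)
  colnames(m) <- c("L", "a", "b")
  if (!is.null(mask)) {
    d <- dim(img)
    if (!is.matrix(mask) || !all(dim(mask) == d[1:2]))
      stop("mask dimensions must match the image")
    m <- m[as.vector(mask), , drop = FALSE]
  }
  m
}

#' Mean CIELAB colour of an image or pixel subset
#'
#' Arithmetic mean per channel over all pixels, or over the pixels selected
#' by `mask`. The whole-image mean is the illumination reference
#' (`Lref`, `aref`, `bref`) used as regression covariates.
#'
#' @param img `image_lab` array (or `n x 3` Lab matrix).
#' @param mask optional logical `H x W` matrix; must select at least 1 pixel.
#' @return named numeric vector `c(L=, a=, b=)`.
#' @export
mean_lab <- function(img, mask = NULL) {
  m <- if (is.matrix(img) && is.null(mask)) .channels_as_matrix(img)
       else lab_pixels(img, mask)
  if (nrow(m) == 0L) stop("mask selects no pixels")
  setNames(colMeans(m), c("L", "a", "b"))
}
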