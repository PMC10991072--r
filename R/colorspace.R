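# sRGB <-> CIELAB (D65, 2 degree observer) and the log-lightness domain.
# All editing happens on log(L); the a/b opponent channels are carried
# through untouched so hue and chroma are preserved.

# sRGB (linear) -> XYZ, D65. The reference white is taken as the row sums
# so that RGB (1,1,1) maps exactly onto the white point (a = b = 0).
.M_rgb2xyz <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041
), nrow = 3, byrow = TRUE)
.white_xyz <- rowSums(.M_rgb2xyz)
.M_xyz2rgb <- solve(.M_rgb2xyz)

.srgb_decode <- function(u) {
  ifelse(u <= 0.04045, u / 12.92, ((u + 0.055) / 1.055)^2.4)
}

.srgb_encode <- function(u) {
  u <- pmax(u, 0)
  ifelse(u <= 0.0031308, 12.92 * u, 1.055 * u^(1 / 2.4) - 0.055)
}

.lab_f <- function(t) {
  d <- 6 / 29
  ifelse(t > d^3, t^(1 / 3), t / (3 * d^2) + 4 / 29)
}

.lab_finv <- function(t) {
  d <- 6 / 29
  ifelse(t > d, t^3, 3 * d^2 * (t - 4 / 29))
}

#' Convert an sRGB image to CIELAB
#'
#' Standard pipeline: IEC 61966-2-1 piecewise gamma decoding, linear RGB to
#' XYZ (D65), XYZ to CIELAB against the D65 white point.
#'
#' @param image `H x W x 3` numeric array in `[0, 1]`.
#' @return An object of class `"bs_lab"`: a list with `H x W` matrices
#'   `L` (lightness, 0--100), `a` and `b` (opponent channels).
#' @seealso [lab_to_srgb()]
#' @export
srgb_to_lab <- function(image) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3)
  h <- dim(image)[1]; w <- dim(image)[2]
  rgb_lin <- .srgb_decode(matrix(image, ncol = 3))
  xyz <- rgb_lin %*% t(.M_rgb2xyz)
  fx <- .lab_f(xyz[, 1] / .white_xyz[1])
  fy <- .lab_f(xyz[, 2] / .white_xyz[2])
  fz <- .lab_f(xyz[, 3] / .white_xyz[3])
  structure(list(
    L = matrix(pmin(pmax(116 * fy - 16, 0), 100), h, w),
    a = matrix(500 * (fx - fy), h, w),
    b = matrix(200 * (fy - fz), h, w)
  ), class = "bs_lab")
}

#' Convert a CIELAB image back to sRGB
#'
#' Inverse of [srgb_to_lab()]; out-of-gamut results are clipped
#' channel-wise to `[0, 1]`.
#'
#' @param lab A `"bs_lab"` object (list with matrices `L`, `a`, `b`).
#' @return An `H x W x 3` numeric array in `[0, 1]`.
#' @export
lab_to_srgb <- function(lab) {
  h <- nrow(lab$L); w <- ncol(lab$L)
  fy <- (as.vector(lab$L) + 16) / 116
  fx <- fy + as.vector(lab$a) / 500
  fz <- fy - as.vector(lab$b) / 200
  xyz <- cbind(.lab_finv(fx) * .white_xyz[1],
               .lab_finv(fy) * .white_xyz[2],
               .lab_finv(fz) * .white_xyz[3])
  rgb_lin <- xyz %*% t(.M_xyz2rgb)
  srgb <- pmin(pmax(.srgb_encode(rgb_lin), 0), 1)
  array(srgb, c(h, w, 3L))
}

#' Lightness to log-lightness
#'
#' Natural log of lightness, floored at `epsilon` so black pixels stay
#' finite; the floor is recorded for exact inversion of all values at or
#' above it.
#'
#' @param L `H x W` lightness matrix, values in `[0, 100]`.
#' @param epsilon Positive floor in L units (default `1e-4`).
#' @return An object of class `"bs_loglight"`: list with the `values`
#'   matrix and the recorded `epsilon`.
#' @export
to_log_lightness <- function(L, epsilon = 1e-4) {
  if (!is.numeric(epsilon) || length(epsilon) != 1 || epsilon <= 0)
    stop_arg("epsilon must be a positive number")
  structure(list(values = log(pmax(L, epsilon)), epsilon = epsilon),
            class = "bs_loglight")
}

#' Log-lightness back to lightness
#'
#' @param x A `"bs_loglight"` object or a bare matrix of natural-log
#'   lightness values.
#' @return `H x W` lightness matrix, exponentiated and clipped to
#'   `[0, 100]`.
#' @export
from_log_lightness <- function(x) {
  v <- if (inherits(x, "bs_loglight")) x$values else x
  pmin(pmax(exp(v), 0), 100)
}
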