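# Deterministic procedural fixture images. Each carries the image
# structure one family of effects targets — small bright highlights
# (gloss), small dark blobs (spots/blemishes), or large-scale shading —
# so the whole pipeline is testable without photographs. All randomness
# comes from R's default generator, seeded locally so global RNG state is
# never touched.

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Smooth random field in [-1, 1]: white noise blurred by repeated box
# filtering (radius ~ size/16), rescaled to unit max amplitude.
.smooth_noise <- function(size, passes = 3) {
  x <- matrix(stats::runif(size^2, -1, 1), size, size)
  r <- max(2L, size %/% 16L)
  n <- .box_sum(matrix(1, size, size), r)
  for (i in seq_len(passes)) x <- .box_sum(x, r) / n
  m <- max(abs(x))
  if (m > 0) x / m else x
}

# Stamp radially symmetric Gaussian bumps (truncated at 3 sigma) at the
# given centres; returns the bump field and the exact stamped-support mask.
.stamp_bumps <- function(size, centers, sigma, amplitude) {
  field <- matrix(0, size, size)
  mask <- matrix(0, size, size)
  rad <- ceiling(3 * sigma)
  for (k in seq_len(nrow(centers))) {
    cy <- centers[k, 1]; cx <- centers[k, 2]
    ys <- max(1, cy - rad):min(size, cy + rad)
    xs <- max(1, cx - rad):min(size, cx + rad)
    d2 <- outer((ys - cy)^2, (xs - cx)^2, `+`)
    bump <- amplitude * exp(-d2 / (2 * sigma^2)) * (d2 <= rad^2)
    field[ys, xs] <- field[ys, xs] + bump
    mask[ys, xs] <- pmax(mask[ys, xs], (d2 <= rad^2) * 1)
  }
  list(field = field, mask = mask)
}

# Spot centres drawn pairwise (y then x per spot), so a fixture with more
# spots reuses the first n centres of a fixture with fewer: feature energy
# grows monotonically with n at a fixed seed.
.draw_centers <- function(n, size, margin) {
  u <- stats::runif(2 * n)
  cbind(
    y = floor(margin + u[seq(1, by = 2, length.out = n)] * (size - 2 * margin)) + 1L,
    x = floor(margin + u[seq(2, by = 2, length.out = n)] * (size - 2 * margin)) + 1L
  )
}

.as_rgb <- function(gray) {
  array(rep(pmin(pmax(gray, 0), 1), 3L), c(dim(gray), 3L))
}

.check_fixture_size <- function(size) {
  if (!is.numeric(size) || length(size) != 1 || size < 64)
    stop_arg("fixture size must be >= 64 px")
  as.integer(size)
}

#' Procedural glossy surface
#'
#' A mid-gray textured base with small, bright, high-contrast Gaussian
#' highlights — the image structure the shine (HHP) effect targets. The
#' ground-truth highlight support is returned alongside the image.
#' Identical arguments always produce the identical image.
#'
#' @param size Square side in pixels (>= 64).
#' @param seed Integer seed; the fixture is a pure function of its
#'   arguments.
#' @param n_highlights Number of stamped highlights.
#' @param highlight_sigma Gaussian radius of each highlight in px
#'   (default `size/64`).
#' @param highlight_amp Peak amplitude added to the base (default 0.45).
#' @return List with `image` (`size x size x 3` array) and `mask`
#'   (`size x size` matrix, 1 on stamped highlight pixels).
#' @export
make_glossy_surface <- function(size = 256, seed = 1, n_highlights = 16,
                                highlight_sigma = size / 64,
                                highlight_amp = 0.45) {
  size <- .check_fixture_size(size)
  with_local_seed(seed, {
    base <- 0.45 + 0.08 * .smooth_noise(size)
    centers <- .draw_centers(n_highlights, size,
                             margin = ceiling(3 * highlight_sigma) + 1)
    st <- if (n_highlights > 0)
      .stamp_bumps(size, centers, highlight_sigma, highlight_amp)
    else list(field = matrix(0, size, size), mask = matrix(0, size, size))
    list(image = .as_rgb(base + st$field), mask = st$mask)
  })
}

#' Procedural spotted surface
#'
#' A bright base carrying small dark blobs — the structure the spots
#' (HHN) effect targets. Blob centres are drawn pairwise from the seeded
#' generator, so increasing `n_spots` at a fixed seed adds blobs without
#' moving the existing ones.
#'
#' @param size,seed As in [make_glossy_surface()].
#' @param n_spots Number of dark blobs (0 allowed).
#' @param spot_sigma Gaussian radius in px (default `size/64`).
#' @param spot_amp Peak darkening (default 0.4).
#' @return List with `image` and the ground-truth `mask` of spot pixels.
#' @export
make_spotted_surface <- function(size = 256, seed = 1, n_spots = 16,
                                 spot_sigma = size / 64, spot_amp = 0.4) {
  size <- .check_fixture_size(size)
  with_local_seed(seed, {
    base <- 0.75 + 0.06 * .smooth_noise(size)
    centers <- .draw_centers(n_spots, size,
                             margin = ceiling(3 * spot_sigma) + 1)
    st <- if (n_spots > 0)
      .stamp_bumps(size, centers, spot_sigma, spot_amp)
    else list(field = matrix(0, size, size), mask = matrix(0, size, size))
    list(image = .as_rgb(base - st$field), mask = st$mask)
  })
}

#' Procedural shaded surface
#'
#' Weak fine texture under a smooth large-scale illumination gradient (a
#' diagonal ramp plus a broad sinusoid), so the image's energy lands
#' predominantly in the low-frequency subbands and the residual. With
#' `illumination_amp = 0` and `texture_amp = 0` the image is constant.
#'
#' @param size,seed As in [make_glossy_surface()].
#' @param illumination_amp Amplitude of the large-scale gradient
#'   (default 0.25).
#' @param texture_amp Amplitude of the fine texture (default 0.02).
#' @return A `size x size x 3` image array.
#' @export
make_shaded_surface <- function(size = 256, seed = 1,
                                illumination_amp = 0.25,
                                texture_amp = 0.02) {
  size <- .check_fixture_size(size)
  with_local_seed(seed, {
    u <- (seq_len(size) - 1) / (size - 1)
    ramp <- outer(u, u, function(a, b) (a + b) / 2)
    wave <- outer(sin(pi * u), cos(pi * u))
    illum <- illumination_amp * (ramp + 0.5 * wave - 0.5)
    texture <- texture_amp * matrix(stats::runif(size^2, -1, 1), size, size)
    .as_rgb(0.55 + illum + texture)
  })
}
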