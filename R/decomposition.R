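# Scale decomposition of log-lightness: iterated edge-preserving guided
# filtering peels off subbands from the highest spatial frequency down,
# leaving a low-frequency residual. Sum of subbands + residual telescopes
# back to the input exactly.

#' Number of scale subbands for a given shorter side
#'
#' An image whose shorter side has `n_short` pixels is decomposed into
#' `floor(log2(n_short)) - 1` subbands (512 px -> 8 subbands, 500 px -> 7).
#'
#' @param n_short Shorter side of the image, in pixels (>= 4).
#' @return Integer subband count `K`.
#' @export
subband_count <- function(n_short) {
  if (!is.numeric(n_short) || length(n_short) != 1 || n_short < 4)
    stop_arg("n_short must be a single number >= 4")
  as.integer(floor(log2(n_short))) - 1L
}

#' Split subband indices into high- and low-frequency groups
#'
#' Of `K` subbands (index 1 = highest spatial frequency), the first
#' `floor(K/2)` are the high-frequency group and the rest the
#' low-frequency group. For `K = 7` this gives high = 1:3, low = 4:7.
#'
#' @param K Number of subbands (>= 1).
#' @return List with integer vectors `high` and `low`.
#' @export
scale_groups <- function(K) {
  if (!is.numeric(K) || length(K) != 1 || K < 1)
    stop_arg("K must be a single integer >= 1")
  K <- as.integer(K)
  nh <- K %/% 2L
  list(high = seq_len(nh), low = seq.int(nh + 1L, K))
}

# Truncated-window box sum via running sums: each output pixel holds the
# sum of x over the window of half-width r clipped to the image. O(HW)
# regardless of r.
.box_sum <- function(x, r) {
  h <- nrow(x); w <- ncol(x)
  idx_lo <- pmax(seq_len(h) - r, 1L)
  idx_hi <- pmin(seq_len(h) + r, h)
  cs <- rbind(0, apply(x, 2, cumsum))
  xr <- cs[idx_hi + 1L, , drop = FALSE] - cs[idx_lo, , drop = FALSE]
  jdx_lo <- pmax(seq_len(w) - r, 1L)
  jdx_hi <- pmin(seq_len(w) + r, w)
  cs2 <- cbind(0, t(apply(xr, 1, cumsum)))
  cs2[, jdx_hi + 1L, drop = FALSE] - cs2[, jdx_lo, drop = FALSE]
}

#' Guided filter (edge-preserving smoothing)
#'
#' Local-linear-model smoother: within each sliding window of half-width
#' `radius`, the output is modelled as an affine function of the guide,
#' with slope `cov(guide, input) / (var(guide) + eps)`; each pixel's
#' output averages the models of all windows covering it. Windows at the
#' image border are truncated to the image (no padding), so no halo bias
#' is introduced at strong border edges. With `guide = input`
#' (self-guided) this behaves as an edge-preserving blur whose strength
#' is set by `eps`.
#'
#' @param input `H x W` numeric matrix to be filtered.
#' @param guide `H x W` guide matrix (same shape; typically `input`).
#' @param radius Window half-width in pixels (>= 1, < min(H, W)).
#' @param eps Regularization, in squared units of the guide (> 0).
#' @return Filtered `H x W` matrix.
#' @references He, K., Sun, J., & Tang, X. (2013). Guided image filtering.
#'   IEEE TPAMI, 35(6), 1397-1409.
#' @export
guided_filter <- function(input, guide, radius, eps) {
  if (!is.matrix(input) || !is.matrix(guide) || !all(dim(input) == dim(guide)))
    stop_arg("input and guide must be matrices of identical shape")
  if (!is.numeric(radius) || length(radius) != 1 || radius < 1)
    stop_arg("radius must be a single integer >= 1")
  if (radius >= min(dim(input)))
    stop_arg("radius (", radius, ") must be smaller than the shorter side (",
             min(dim(input)), ")")
  if (!is.numeric(eps) || length(eps) != 1 || eps <= 0)
    stop_arg("eps must be a single positive number")
  r <- as.integer(radius)
  n <- .box_sum(matrix(1, nrow(input), ncol(input)), r)
  m_g <- .box_sum(guide, r) / n
  m_p <- .box_sum(input, r) / n
  cov_gp <- .box_sum(guide * input, r) / n - m_g * m_p
  var_g <- .box_sum(guide * guide, r) / n - m_g^2
  a <- cov_gp / (var_g + eps)
  b <- m_p - a * m_g
  (.box_sum(a, r) / n) * guide + .box_sum(b, r) / n
}

# Geometric radius schedule: subband i is peeled with radius base^i, so
# consecutive subbands are one octave apart (matching the log2 count).
default_schedule <- function(K, config = bs_config()) {
  lapply(seq_len(K), function(i)
    list(radius = config$radius_base^i, eps = config$guided_filter_eps))
}

#' Decompose log-lightness into scale subbands
#'
#' Repeatedly smooths with a self-guided [guided_filter()] at doubling
#' radii; each subband is the detail removed at that level (subband 1 =
#' highest spatial frequency), and the final smooth is the low-frequency
#' residual. The decomposition is exactly invertible:
#' `sum(subbands) + residual == input`.
#'
#' @param x A `"bs_loglight"` object or bare `H x W` matrix.
#' @param schedule Optional list of `list(radius, eps)` per level, radii
#'   strictly increasing and of length `subband_count(min(H, W))`; by
#'   default built from `config`.
#' @param config A [bs_config()].
#' @return An object of class `"bs_pyramid"`: list with `subbands` (list
#'   of `K` matrices), `residual` (matrix), `dims` (a `"bs_dims"`), and
#'   the log-floor `epsilon` carried from the input.
#' @export
bs_decompose <- function(x, schedule = NULL, config = bs_config()) {
  epsilon <- if (inherits(x, "bs_loglight")) x$epsilon else config$log_epsilon
  v <- if (inherits(x, "bs_loglight")) x$values else x
  stopifnot(is.matrix(v))
  K <- subband_count(min(dim(v)))
  if (is.null(schedule)) schedule <- default_schedule(K, config)
  if (length(schedule) != K)
    stop_arg("schedule has ", length(schedule), " levels but the image needs ", K)
  radii <- vapply(schedule, `[[`, 0, "radius")
  if (any(diff(radii) <= 0)) stop_arg("schedule radii must be strictly increasing")
  subbands <- vector("list", K)
  current <- v
  for (i in seq_len(K)) {
    smooth <- guided_filter(current, current, schedule[[i]]$radius,
                            schedule[[i]]$eps)
    subbands[[i]] <- current - smooth
    current <- smooth
  }
  g <- scale_groups(K)
  structure(list(
    subbands = subbands,
    residual = current,
    dims = structure(list(K = K, high = g$high, low = g$low),
                     class = "bs_dims"),
    epsilon = epsilon
  ), class = "bs_pyramid")
}

#' Subband bookkeeping for an image
#'
#' Reports how many scale subbands the decomposition of an image will
#' produce and which indices fall in the high- and low-frequency groups —
#' the information needed to write explicit `freq` index selectors.
#'
#' @param image `H x W x 3` image array (after any [resize_to_max()]),
#'   an `H x W` matrix, or a file path.
#' @return An object of class `"bs_dims"`: list with `K`, `high`, `low`.
#' @examples
#' modif_dim(make_shaded_surface(size = 64, seed = 1))
#' @export
modif_dim <- function(image) {
  if (is.character(image)) image <- im_load(image)
  n_short <- min(dim(image)[1:2])
  K <- subband_count(n_short)
  g <- scale_groups(K)
  structure(list(K = K, high = g$high, low = g$low), class = "bs_dims")
}

#' @export
print.bs_dims <- function(x, ...) {
  cat("scale subbands:", x$K, "\n")
  cat("  high-frequency indices:",
      if (length(x$high)) paste(x$high, collapse = ", ") else "(none)", "\n")
  cat("  low-frequency indices: ", paste(x$low, collapse = ", "), "\n")
  invisible(x)
}

#' Export the subbands of a pyramid as PNG files
#'
#' Debug aid: each subband (and the residual) is affinely mapped to
#' `[0, 1]` and written as a grayscale PNG; the mapping used for each file
#' is recorded in a sidecar text file so values can be recovered.
#'
#' @param pyramid A `"bs_pyramid"`.
#' @param out_dir Output directory (created if needed).
#' @param prefix Filename prefix.
#' @return Paths of the written PNGs, invisibly.
#' @export
export_subbands <- function(pyramid, out_dir, prefix = "subband") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  layers <- c(pyramid$subbands, list(pyramid$residual))
  names(layers) <- c(sprintf("%s_%02d", prefix, seq_along(pyramid$subbands)),
                     paste0(prefix, "_residual"))
  sidecar <- file.path(out_dir, paste0(prefix, "_scaling.txt"))
  lines <- character(0)
  paths <- character(0)
  for (nm in names(layers)) {
    v <- layers[[nm]]
    lo <- min(v); hi <- max(v)
    scaled <- if (hi > lo) (v - lo) / (hi - lo) else matrix(0.5, nrow(v), ncol(v))
    p <- file.path(out_dir, paste0(nm, ".png"))
    png::writePNG(scaled, p)
    lines <- c(lines, sprintf("%s min=%.10g max=%.10g", nm, lo, hi))
    paths <- c(paths, p)
  }
  writeLines(lines, sidecar)
  invisible(paths)
}
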