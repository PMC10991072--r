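# Independent oracles, written before the implementations they check and
# kept free of the package's fast paths (no box-filter tricks, literal
# per-window loops).

# Literal per-pixel guided filter: for every window centre, fit the local
# linear model on the truncated window, then average the models of all
# windows covering each pixel.
brute_guided_filter <- function(input, guide, r, eps) {
  h <- nrow(input); w <- ncol(input)
  a_sum <- matrix(0, h, w); b_sum <- matrix(0, h, w); cnt <- matrix(0, h, w)
  for (ci in seq_len(h)) for (cj in seq_len(w)) {
    ys <- max(1, ci - r):min(h, ci + r)
    xs <- max(1, cj - r):min(w, cj + r)
    g <- guide[ys, xs]; p <- input[ys, xs]
    mg <- mean(g); mp <- mean(p)
    a <- (mean(g * p) - mg * mp) / (mean(g * g) - mg^2 + eps)
    b <- mp - a * mg
    a_sum[ys, xs] <- a_sum[ys, xs] + a
    b_sum[ys, xs] <- b_sum[ys, xs] + b
    cnt[ys, xs] <- cnt[ys, xs] + 1
  }
  (a_sum / cnt) * guide + b_sum / cnt
}

# Large-eps limit of the same construction: slope 0, intercept the
# truncated window mean, averaged over covering windows (pure box
# averaging, no edge preservation).
brute_box_limit <- function(input, r) {
  h <- nrow(input); w <- ncol(input)
  b_sum <- matrix(0, h, w); cnt <- matrix(0, h, w)
  for (ci in seq_len(h)) for (cj in seq_len(w)) {
    ys <- max(1, ci - r):min(h, ci + r)
    xs <- max(1, cj - r):min(w, cj + r)
    b_sum[ys, xs] <- b_sum[ys, xs] + mean(input[ys, xs])
    cnt[ys, xs] <- cnt[ys, xs] + 1
  }
  b_sum / cnt
}

# Reference CIELAB conversion via grDevices (independent of the package's
# closed-form implementation).
oracle_lab <- function(image) {
  m <- grDevices::convertColor(matrix(image, ncol = 3), from = "sRGB",
                               to = "Lab")
  list(L = matrix(m[, 1], dim(image)[1], dim(image)[2]),
       a = matrix(m[, 2], dim(image)[1], dim(image)[2]),
       b = matrix(m[, 3], dim(image)[1], dim(image)[2]))
}

# Full pipeline state up to the sifted quadrants, shared by several tests.
pipeline_state <- function(image, config = bs_config()) {
  lab <- srgb_to_lab(image)
  ll <- to_log_lightness(lab$L, config$log_epsilon)
  pyr <- bs_decompose(ll, config = config)
  quads <- lapply(pyr$subbands, sift_subband)
  list(lab = lab, ll = ll, pyr = pyr, quads = quads,
       features = group_bs_features(quads, pyr$dims))
}

# Sum of squares of one BS feature of an image (decomposition route).
feature_energy <- function(image, feature) {
  st <- pipeline_state(image)
  sum(st$features[[feature]]^2)
}

random_image <- function(h, w, seed = 1) {
  set.seed(seed)
  array(runif(h * w * 3), c(h, w, 3L))
}
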