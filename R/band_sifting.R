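# Band sifting: split each scale subband by amplitude (against a one-SD
# threshold) and sign into four complementary quadrant images, group the
# quadrants of all subbands into the eight BS features, scale quadrants by
# the factor table, and reconstruct log-lightness.

#' The eight band-sift feature names
#'
#' Acronym order is scale (High/Low frequency), amplitude (High/Low),
#' sign (Positive/Negative): HHP, HHN, HLP, HLN, LHP, LHN, LLP, LLN.
#' @return Character vector of length 8.
#' @export
bs_feature_names <- function() {
  as.vector(outer(c("HH", "HL", "LH", "LL"), c("P", "N"), paste0))[c(1, 5, 2, 6, 3, 7, 4, 8)]
}

#' Sift one subband into amplitude/sign quadrants
#'
#' The population standard deviation of the subband's pixel values is the
#' amplitude threshold: a pixel is high-amplitude iff its absolute value
#' exceeds one SD (ties count as low-amplitude). Each amplitude class is
#' further split by sign, giving four images with disjoint supports that
#' sum back to the subband exactly.
#'
#' @param subband `H x W` numeric matrix (log-lightness units).
#' @return An object of class `"bs_quadrants"`: list with the threshold
#'   `sigma` and matrices `hp`, `hn`, `lp`, `ln` (high/low amplitude x
#'   positive/negative sign).
#' @export
sift_subband <- function(subband) {
  stopifnot(is.matrix(subband), all(is.finite(subband)))
  v <- subband
  sigma <- sqrt(mean((v - mean(v))^2))  # population SD, all pixels
  high <- abs(v) > sigma
  pos <- v > 0
  structure(list(
    sigma = sigma,
    hp = v * (high & pos),
    hn = v * (high & !pos),
    lp = v * (!high & pos),
    ln = v * (!high & !pos)
  ), class = "bs_quadrants")
}

#' Group quadrants into the eight BS features
#'
#' Quadrants of subbands in the high-frequency group sum into the H*
#' features, those in the low-frequency group into the L* features.
#' There are always eight features regardless of how many subbands the
#' image produced; features over an empty group are all-zero.
#'
#' @param all_quadrants List of `"bs_quadrants"`, one per subband 1..K.
#' @param dims A `"bs_dims"` consistent with the list length.
#' @return An object of class `"bs_features"`: named list of eight
#'   `H x W` matrices (HHP, HHN, HLP, HLN, LHP, LHN, LLP, LLN).
#' @export
group_bs_features <- function(all_quadrants, dims) {
  if (length(all_quadrants) != dims$K)
    stop_arg("got ", length(all_quadrants), " quadrant sets for K = ", dims$K)
  shape <- dim(all_quadrants[[1]]$hp)
  zero <- matrix(0, shape[1], shape[2])
  sum_over <- function(idx, slot) {
    Reduce(`+`, lapply(all_quadrants[idx], `[[`, slot), zero)
  }
  feats <- list(
    HHP = sum_over(dims$high, "hp"), HHN = sum_over(dims$high, "hn"),
    HLP = sum_over(dims$high, "lp"), HLN = sum_over(dims$high, "ln"),
    LHP = sum_over(dims$low, "hp"),  LHN = sum_over(dims$low, "hn"),
    LLP = sum_over(dims$low, "lp"),  LLN = sum_over(dims$low, "ln")
  )
  structure(feats, class = "bs_features")
}

#' Multiplicative factor table over (subband, amplitude, sign)
#'
#' The editing engine's sole control surface: one factor per subband index
#' x amplitude class (H/L) x sign class (P/N), default 1 (identity).
#' Stored as a `K x 4` matrix with columns HP, HN, LP, LN.
#'
#' @param K Number of subbands.
#' @return An object of class `"bs_factor_table"`.
#' @export
feature_factor_table <- function(K) {
  if (!is.numeric(K) || length(K) != 1 || K < 1)
    stop_arg("K must be a single integer >= 1")
  structure(matrix(1, as.integer(K), 4L,
                   dimnames = list(NULL, c("HP", "HN", "LP", "LN"))),
            class = "bs_factor_table")
}

is_identity_table <- function(table) all(unclass(table) == 1)

#' Apply a factor table and reconstruct log-lightness
#'
#' Each quadrant is multiplied by its factor and all quadrants plus the
#' residual are summed. Because the eight BS features are sums of
#' quadrants, multiplying every quadrant of a BS group by `f` is exactly
#' equivalent to multiplying the grouped feature image by `f`. With the
#' identity table the original log-lightness is recovered.
#'
#' @param all_quadrants List of `"bs_quadrants"`, one per subband.
#' @param residual `H x W` residual matrix from the decomposition.
#' @param table A `"bs_factor_table"` with `K` rows.
#' @param epsilon Log floor to record in the result (see
#'   [to_log_lightness()]).
#' @return A `"bs_loglight"` object.
#' @export
apply_factors_and_reconstruct <- function(all_quadrants, residual, table,
                                          epsilon = 1e-4) {
  tab <- unclass(table)
  if (nrow(tab) != length(all_quadrants))
    stop_arg("factor table has ", nrow(tab), " rows for ",
             length(all_quadrants), " subbands")
  if (!all(is.finite(tab))) stop_arg("factors must be finite")
  out <- residual
  for (i in seq_along(all_quadrants)) {
    q <- all_quadrants[[i]]
    out <- out + tab[i, "HP"] * q$hp + tab[i, "HN"] * q$hn +
                 tab[i, "LP"] * q$lp + tab[i, "LN"] * q$ln
  }
  structure(list(values = out, epsilon = epsilon), class = "bs_loglight")
}

#' Export the eight BS feature images as PNGs
#'
#' Same affine-mapping convention as [export_subbands()]: each feature is
#' mapped to `[0, 1]` and the mapping recorded in a sidecar text file.
#'
#' @param features A `"bs_features"` object.
#' @param out_dir Output directory.
#' @param prefix Filename prefix.
#' @return Paths written, invisibly.
#' @export
export_features <- function(features, out_dir, prefix = "feature") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sidecar <- file.path(out_dir, paste0(prefix, "_scaling.txt"))
  lines <- character(0); paths <- character(0)
  for (nm in names(features)) {
    v <- features[[nm]]
    lo <- min(v); hi <- max(v)
    scaled <- if (hi > lo) (v - lo) / (hi - lo) else matrix(0.5, nrow(v), ncol(v))
    p <- file.path(out_dir, paste0(prefix, "_", nm, ".png"))
    png::writePNG(scaled, p)
    lines <- c(lines, sprintf("%s min=%.10g max=%.10g", nm, lo, hi))
    paths <- c(paths, p)
  }
  writeLines(lines, sidecar)
  invisible(paths)
}
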