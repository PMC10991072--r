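# The user-facing editing engine: named effects and low-level feature
# selectors are compiled to a factor table, applied in one pass over a
# single decomposition, and blended back under an optional mask.

# effect alias -> BS feature acronym(s)
.bs_aliases <- list(
  shine   = "HHP",
  spots   = "HHN",
  rough   = "HLP",
  stain   = "HLN",
  blemish = "HLA",           # = rough + stain
  shadow  = "LLN",           # provisional mapping: large-scale dark gradients
  aging   = c("HLA", "HHN")
)

.parse_acronym <- function(name) {
  ch <- strsplit(name, "")[[1]]
  if (length(ch) != 3 || !ch[1] %in% c("H", "L", "A") ||
      !ch[2] %in% c("H", "L", "A") || !ch[3] %in% c("P", "N", "A"))
    return(NULL)
  list(freq = ch[1], amp = ch[2], sign = ch[3])
}

.valid_effect_names <- function() {
  c(names(.bs_aliases), "and any scale/amplitude/sign acronym such as HHP or HLA")
}

#' Expand an effect name into feature selectors
#'
#' Effect aliases name the BS features most useful for perceptual editing:
#' shine = HHP (small bright spots: gloss, highlights), spots = HHN (small
#' dark blobs: wrinkles, blemishes), rough = HLP, stain = HLN, blemish =
#' HLA (rough and stain together), shadow = LLN (large-scale dark
#' gradients), and aging = HLA + HHN. A three-letter acronym is parsed
#' positionally into (frequency, amplitude, sign) with `A` as the
#' wildcard.
#'
#' @param name Effect alias or BS acronym.
#' @param strength Finite multiplicative factor carried by each returned
#'   selector (1 = no-op, > 1 boosts, < 1 reduces, negative inverts).
#' @return A list of selectors, each a list with `freq`, `amp`, `sign`,
#'   `strength`.
#' @export
alias_to_selectors <- function(name, strength) {
  if (!is.numeric(strength) || length(strength) != 1 || !is.finite(strength))
    stop_arg("strength must be a single finite number")
  acronyms <- if (name %in% names(.bs_aliases)) .bs_aliases[[name]] else name
  sels <- lapply(acronyms, function(a) {
    p <- .parse_acronym(a)
    if (is.null(p))
      stop_arg("unknown effect '", name, "'; valid effects: ",
               paste(names(.bs_aliases), collapse = ", "),
               ", or a BS acronym (scale H/L/A, amplitude H/L/A, sign P/N/A)")
    c(p, list(strength = strength))
  })
  sels
}

.expand_freq <- function(freq, dims) {
  if (is.numeric(freq)) {
    idx <- as.integer(freq)
    if (any(idx < 1 | idx > dims$K))
      stop_arg("freq indices must lie in 1..", dims$K)
    return(idx)
  }
  switch(as.character(freq),
    H = dims$high,
    L = dims$low,
    A = seq_len(dims$K),
    stop_arg("freq must be 'H', 'L', 'A' or a vector of subband indices")
  )
}

.expand_amp <- function(amp) {
  switch(as.character(amp), H = "H", L = "L", A = c("H", "L"),
         stop_arg("amp must be 'H', 'L' or 'A'"))
}

.expand_sign <- function(sign) {
  # the negative sign is canonically 'N'; 'L' is accepted as a synonym
  switch(as.character(sign), P = "P", N = , L = "N", A = c("P", "N"),
         stop_arg("sign must be 'P', 'N' (or 'L') or 'A'"))
}

#' Expand a feature selector into a factor table
#'
#' Frequency `H`/`L` expand to the image's high/low index groups, `A` to
#' all subbands; explicit integer indices are used as given. Amplitude
#' and sign wildcards expand to both classes. Every targeted
#' (subband, amplitude, sign) cell receives the selector's strength; all
#' other cells stay 1.
#'
#' @param sel Selector: list with `freq`, `amp`, `sign`, `strength`.
#' @param dims A `"bs_dims"` for the image being edited.
#' @return A `"bs_factor_table"`.
#' @export
expand_selector <- function(sel, dims) {
  if (is.null(sel$strength) || !is.finite(sel$strength))
    stop_arg("selector needs a finite strength")
  idx <- .expand_freq(sel$freq, dims)
  amps <- .expand_amp(sel$amp)
  signs <- .expand_sign(sel$sign)
  tab <- feature_factor_table(dims$K)
  for (a in amps) for (s in signs)
    tab[idx, paste0(a, s)] <- sel$strength
  tab
}

#' Combine factor tables multiplicatively
#'
#' Cell-wise product, so combining is commutative and associative: the
#' order in which effects are specified never changes the result, and two
#' selectors hitting the same cell compose into the product of their
#' strengths.
#'
#' @param tables List of `"bs_factor_table"` objects with equal `K`.
#' @return A single `"bs_factor_table"`.
#' @export
combine_factor_tables <- function(tables) {
  if (!length(tables)) stop_arg("need at least one factor table")
  K <- nrow(tables[[1]])
  if (!all(vapply(tables, nrow, 0L) == K))
    stop_arg("factor tables disagree on the number of subbands")
  out <- Reduce(`*`, lapply(tables, unclass))
  structure(out, class = "bs_factor_table")
}

# Shared pipeline: selectors -> factor table -> one-pass edit -> blend.
.modif_core <- function(image, selectors, mask, max_size, config) {
  image <- resize_to_max(image, max_size)
  dims <- modif_dim(image)
  tab <- combine_factor_tables(lapply(selectors, expand_selector, dims = dims))
  if (!is.null(mask)) {
    if (is.character(mask))
      mask <- load_mask(mask, dim(image)[1], dim(image)[2])
    if (!all(dim(mask) == dim(image)[1:2]))
      stop_shape("mask is ", nrow(mask), " x ", ncol(mask),
                 " but the image is ", dim(image)[1], " x ", dim(image)[2])
  }
  # no-op contract: with every factor 1 the (resized) input is returned
  # bit-identically, avoiding colorspace round-off
  if (is_identity_table(tab)) return(image)
  lab <- srgb_to_lab(image)
  lab_out <- edit_lab(lab, tab, config)
  edited <- lab_to_srgb(lab_out)
  blend_with_mask(image, edited, mask)
}

#' Edit the lightness channel of a Lab image
#'
#' The engine core, exposed for inspection: log-transforms L, decomposes,
#' sifts each subband, applies the factor table, reconstructs, and
#' exponentiates. The `a` and `b` channels are returned untouched, so
#' chroma is preserved by construction.
#'
#' @param lab A `"bs_lab"` object.
#' @param table A `"bs_factor_table"` for this image's `K`.
#' @param config A [bs_config()].
#' @return A `"bs_lab"` object with edited `L` and the original `a`, `b`.
#' @export
edit_lab <- function(lab, table, config = bs_config()) {
  ll <- to_log_lightness(lab$L, config$log_epsilon)
  pyr <- bs_decompose(ll, config = config)
  quads <- lapply(pyr$subbands, sift_subband)
  ll2 <- apply_factors_and_reconstruct(quads, pyr$residual, table,
                                       epsilon = ll$epsilon)
  structure(list(L = from_log_lightness(ll2), a = lab$a, b = lab$b),
            class = "bs_lab")
}

#' Apply material-editing effects to an image
#'
#' Boosts or reduces named surface features of the photograph: `effect`
#' names one or more effects and `strength` gives the multiplicative
#' factor for each (1 = unchanged, 1.5--4 typical boosts, values below 1
#' reduce, negative values invert). Multiple effects are applied
#' simultaneously on a single decomposition, so their order is
#' irrelevant. With a mask, editing is restricted to the white region of
#' the mask (grays alpha-blend).
#'
#' @param image `H x W x 3` array in `[0, 1]`, or a file path.
#' @param effect Character vector of effect names (aliases such as
#'   `"shine"`, `"aging"`, or BS acronyms such as `"HHP"`).
#' @param strength Numeric vector of factors, recycled to
#'   `length(effect)`.
#' @param mask Optional `H x W` matrix in `[0, 1]` or mask file path;
#'   must match the image size after any resize.
#' @param max_size Shorter-side cap applied before editing (default
#'   1280 px; `NA` disables). See [resize_to_max()].
#' @param config A [bs_config()].
#' @return The edited `H x W x 3` image array.
#' @examples
#' img <- make_glossy_surface(size = 128, seed = 7)$image
#' shiny <- modif(img, effect = "shine", strength = 3)
#' dull <- modif(img, effect = "shine", strength = 0.2)
#' aged <- modif(img, effect = c("shine", "aging"), strength = c(0.2, 3))
#' @export
modif <- function(image, effect, strength = 1, mask = NULL,
                  max_size = 1280L, config = bs_config()) {
  if (is.character(image)) image <- im_load(image)
  if (!is.character(effect) || !length(effect))
    stop_arg("effect must be a non-empty character vector")
  strength <- rep_len(as.numeric(strength), length(effect))
  selectors <- do.call(c, Map(alias_to_selectors, effect, strength))
  .modif_core(image, selectors, mask, max_size, config)
}

# Normalise modif2 params: one selector list or a list of them; the
# 'feature' acronym form is translated to freq/amp/sign.
.normalise_params <- function(params) {
  if (!is.list(params) || !length(params))
    stop_arg("params must be a selector list or a list of selector lists")
  if (!is.null(names(params)) &&
      any(c("feature", "freq") %in% names(params)))
    params <- list(params)
  lapply(params, function(p) {
    if (!is.null(p$feature)) {
      sels <- alias_to_selectors(p$feature,
                                 if (is.null(p$strength)) NA_real_ else p$strength)
      if (length(sels) != 1)
        stop_arg("the feature parameter takes a single acronym")
      return(sels[[1]])
    }
    if (is.null(p$freq) || is.null(p$amp) || is.null(p$sign) ||
        is.null(p$strength))
      stop_arg("each params entry needs freq, amp, sign and strength ",
               "(or feature and strength)")
    list(freq = p$freq, amp = p$amp, sign = p$sign,
         strength = as.numeric(p$strength))
  })
}

#' Edit an image by explicit feature selectors
#'
#' The low-level companion to [modif()]: each selector names the
#' frequency band (`'H'`, `'L'`, `'A'`, or explicit subband indices such
#' as `1:2`), amplitude class, sign class, and a strength. Explicit
#' indices allow finer control than the alias effects, e.g. excluding the
#' noisy highest-frequency subband. Several selectors may be given as a
#' list of lists; they are compiled into one factor table and applied in
#' a single pass.
#'
#' @param image `H x W x 3` array or file path.
#' @param params One selector — `list(freq=, amp=, sign=, strength=)` or
#'   `list(feature = "HHP", strength=)` — or a list of such lists.
#' @param mask,max_size,config As in [modif()].
#' @return The edited image array.
#' @examples
#' img <- make_glossy_surface(size = 128, seed = 7)$image
#' # equivalent to modif(img, "shine", 3):
#' out <- modif2(img, list(freq = "H", amp = "H", sign = "P", strength = 3))
#' @export
modif2 <- function(image, params, mask = NULL, max_size = 1280L,
                   config = bs_config()) {
  if (is.character(image)) image <- im_load(image)
  selectors <- .normalise_params(params)
  .modif_core(image, selectors, mask, max_size, config)
}

#' Alpha-blend an edited image with its original under a mask
#'
#' Per pixel and channel, `out = mask * edited + (1 - mask) * original`,
#' computed in sRGB. Wherever the mask is 0 the original is returned
#' bit-identically; wherever it is 1, the edit.
#'
#' @param original,edited `H x W x 3` arrays of equal shape.
#' @param mask `H x W` matrix in `[0, 1]`, or `NULL` to return `edited`.
#' @return The blended `H x W x 3` array.
#' @export
blend_with_mask <- function(original, edited, mask = NULL) {
  if (is.null(mask)) return(edited)
  if (!all(dim(original) == dim(edited)))
    stop_shape("original and edited images differ in shape")
  if (!all(dim(mask) == dim(original)[1:2]))
    stop_shape("mask is ", nrow(mask), " x ", ncol(mask),
               " but the images are ", dim(original)[1], " x ",
               dim(original)[2])
  m3 <- array(mask, dim(original))  # H x W x 3 by recycling over channels
  m3 * edited + (1 - m3) * original
}
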