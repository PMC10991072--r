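# Image input/output and geometry. Images are plain numeric arrays of
# dimension H x W x 3 with values in [0, 1] (sRGB-encoded); masks are
# H x W matrices in [0, 1].

.supported_ext <- c("jpg", "jpeg", "png", "bmp")

.check_ext <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% .supported_ext)
    stop_format("unsupported image format '.", ext,
                "' (supported: ", paste(.supported_ext, collapse = ", "), ")")
  ext
}

# Decode any supported file into an H x W x C array in [0, 1].
.decode <- function(path) {
  ext <- .check_ext(path)
  if (!file.exists(path)) stop_io("file not found: ", path)
  out <- tryCatch(
    switch(ext,
      png  = png::readPNG(path),
      jpg  = ,
      jpeg = jpeg::readJPEG(path),
      bmp  = read_bmp(path)
    ),
    error = function(e) {
      if (inherits(e, "bs_error")) stop(e)
      stop_format("could not decode ", path, ": ", conditionMessage(e))
    }
  )
  out
}

# Normalise decoder output to H x W x 3: replicate grayscale, drop alpha.
.to_rgb3 <- function(x, path = "<array>") {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  nch <- dim(x)[3]
  if (nch %in% c(2L, 4L)) {
    warning("alpha channel in ", path, " dropped", call. = FALSE)
    x <- x[, , -nch, drop = FALSE]
    nch <- dim(x)[3]
  }
  if (nch == 1L) {
    x <- array(rep(x, 3L), c(dim(x)[1:2], 3L))
  } else if (nch != 3L) {
    stop_format("unsupported channel count (", nch, ") in ", path)
  }
  x
}

#' Load an image from disk
#'
#' Reads a JPEG, PNG or BMP file into an `H x W x 3` numeric array with
#' values in `[0, 1]` (integer pixel codes are mapped linearly: 8-bit 255
#' and 16-bit 65535 both map to 1.0). Grayscale images are replicated to
#' three channels; an alpha channel, if present, is dropped with a warning.
#'
#' @param path Path to a `.jpg`, `.jpeg`, `.png` or `.bmp` file
#'   (case-insensitive extension).
#' @return An `H x W x 3` numeric array in `[0, 1]`.
#' @examples
#' f <- tempfile(fileext = ".png")
#' im_save(make_shaded_surface(size = 64, seed = 1), f)
#' img <- im_load(f)
#' dim(img)
#' @export
im_load <- function(path) {
  img <- .to_rgb3(.decode(path), path)
  if (dim(img)[1] < 4 || dim(img)[2] < 4)
    stop_shape("image must be at least 4 x 4 px, got ",
               dim(img)[1], " x ", dim(img)[2])
  stopifnot(all(is.finite(img)))
  img
}

#' Save an image to disk
#'
#' Values are clipped to `[0, 1]` and quantized to 8 bits. PNG and BMP
#' round-trip losslessly at 8-bit precision; JPEG is saved at the quality
#' set in `config` (default 95).
#'
#' @param image `H x W x 3` numeric array (a single-channel matrix is
#'   replicated to RGB).
#' @param path Output path; extension selects the format.
#' @param config A [bs_config()] (JPEG quality only).
#' @return `path`, invisibly.
#' @export
im_save <- function(image, path, config = bs_config()) {
  image <- .to_rgb3(image, "<image>")
  ext <- .check_ext(path)
  if (!dir.exists(dirname(path)))
    stop_io("directory does not exist: ", dirname(path))
  codes <- round(pmin(pmax(image, 0), 1) * 255)
  quantized <- codes / 255
  switch(ext,
    png  = png::writePNG(quantized, path),
    jpg  = ,
    jpeg = jpeg::writeJPEG(quantized, path, quality = config$jpeg_quality / 100),
    bmp  = write_bmp(quantized, path)
  )
  invisible(path)
}

# Sparse overlap weights mapping n_in samples onto n_out (area averaging).
# Row j holds the fraction of output cell j covered by each input cell.
.area_weights <- function(n_in, n_out) {
  b <- seq(0, n_in, length.out = n_out + 1)  # output cell boundaries, input units
  i_all <- lapply(seq_len(n_out), function(j) {
    lo <- b[j]; hi <- b[j + 1]
    i <- seq(floor(lo) + 1, ceiling(hi))
    i <- i[i >= 1 & i <= n_in]
    w <- pmin(hi, i) - pmax(lo, i - 1)
    keep <- w > 0
    list(i = i[keep], w = w[keep] / (hi - lo))
  })
  Matrix::sparseMatrix(
    i = rep(seq_len(n_out), vapply(i_all, function(z) length(z$i), 1L)),
    j = unlist(lapply(i_all, `[[`, "i")),
    x = unlist(lapply(i_all, `[[`, "w")),
    dims = c(n_out, n_in)
  )
}

# Anti-aliased (area-average) resampling of an H x W x C array.
.resize_area <- function(image, h_out, w_out) {
  wr <- .area_weights(dim(image)[1], h_out)
  wc <- Matrix::t(.area_weights(dim(image)[2], w_out))
  out <- array(0, c(h_out, w_out, dim(image)[3]))
  for (ch in seq_len(dim(image)[3]))
    out[, , ch] <- as.matrix(wr %*% image[, , ch] %*% wc)
  out
}

#' Cap the shorter side of an image
#'
#' If the shorter side exceeds `max_size`, the image is scaled down
#' (area-averaged, anti-aliased) so the shorter side equals `max_size`,
#' preserving aspect ratio; the longer side is rounded half away from zero.
#' Otherwise the image is returned unchanged. With the default cap of
#' 1280 px, a 2000 x 3000 px input comes out 1280 x 1920 px. Never
#' upscales, and is idempotent.
#'
#' @param image `H x W x 3` numeric array.
#' @param max_size Positive integer cap (>= 4), or `NA`/`NULL` to disable.
#' @return The (possibly downscaled) image array.
#' @export
resize_to_max <- function(image, max_size = 1280L) {
  if (is.null(max_size) || (length(max_size) == 1 && is.na(max_size)))
    return(image)
  if (!is.numeric(max_size) || length(max_size) != 1 || max_size < 4)
    stop_arg("max_size must be >= 4 or NA")
  h <- dim(image)[1]; w <- dim(image)[2]
  short <- min(h, w)
  if (short <= max_size) return(image)
  s <- max_size / short
  # round half away from zero so e.g. 3000 * 0.64 -> exactly 1920
  rhafz <- function(x) floor(x + 0.5)
  if (h <= w) {
    .resize_area(image, as.integer(max_size), as.integer(rhafz(w * s)))
  } else {
    .resize_area(image, as.integer(rhafz(h * s)), as.integer(max_size))
  }
}

#' Load a mask image
#'
#' A mask selects the region to edit: weight 1 (white) marks fully edited
#' pixels, 0 (black) untouched pixels, and intermediate grays alpha-blend
#' the edit. Multi-channel mask files are reduced to one channel by the
#' channel mean; pixel codes map linearly to `[0, 1]`.
#'
#' @param path Mask file (same formats as [im_load()]).
#' @param expected_height,expected_width Dimensions the mask must match
#'   (those of the image being edited, after any resize).
#' @return An `H x W` numeric matrix in `[0, 1]`.
#' @export
load_mask <- function(path, expected_height, expected_width) {
  x <- .decode(path)
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  nch <- dim(x)[3]
  if (nch %in% c(2L, 4L)) {  # drop alpha before averaging colour channels
    x <- x[, , -nch, drop = FALSE]
    nch <- dim(x)[3]
  }
  m <- if (nch == 1L) x[, , 1L] else apply(x, c(1, 2), mean)
  if (nrow(m) != expected_height || ncol(m) != expected_width)
    stop_shape("mask is ", nrow(m), " x ", ncol(m), " but the image is ",
               expected_height, " x ", expected_width)
  m
}
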