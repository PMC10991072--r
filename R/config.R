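#' Engine configuration
#'
#' Collects the numerical knobs of the editing engine in one object.
#' All editing functions accept a `config` argument built by this
#' constructor; fields not supplied keep their defaults.
#'
#' @param guided_filter_eps Regularization of the guided filter, in squared
#'   log-lightness units. Larger values smooth more aggressively across
#'   edges; the default 0.01 preserves strong shading boundaries while
#'   smoothing surface texture.
#' @param radius_base Base of the geometric radius schedule used by the
#'   scale decomposition: subband `i` is peeled off with window half-width
#'   `radius_base^i` pixels, so the default 2 gives octave spacing.
#' @param log_epsilon Floor (in CIELAB L units, 0--100 scale) applied to
#'   lightness before the log transform, so that black pixels stay finite.
#'   Recorded and inverted exactly for all L at or above the floor.
#' @param max_size Default shorter-side cap applied before editing; see
#'   [resize_to_max()]. Use `NA` to disable.
#' @param jpeg_quality JPEG save quality in percent (fixed default 95 for
#'   reproducibility of compression artifacts).
#' @return A list of class `"bs_config"`.
#' @seealso [bs_config_from_file()]
#' @export
bs_config <- function(guided_filter_eps = 0.01,
                      radius_base = 2L,
                      log_epsilon = 1e-4,
                      max_size = 1280L,
                      jpeg_quality = 95L) {
  if (!is.numeric(guided_filter_eps) || guided_filter_eps <= 0)
    stop_arg("guided_filter_eps must be a positive number")
  if (!is.numeric(radius_base) || radius_base < 2)
    stop_arg("radius_base must be an integer >= 2")
  if (!is.numeric(log_epsilon) || log_epsilon <= 0)
    stop_arg("log_epsilon must be a positive number")
  structure(list(
    guided_filter_eps = as.numeric(guided_filter_eps),
    radius_base = as.integer(radius_base),
    log_epsilon = as.numeric(log_epsilon),
    max_size = if (is.null(max_size) || is.na(max_size)) NA else as.integer(max_size),
    jpeg_quality = as.integer(jpeg_quality)
  ), class = "bs_config")
}

#' Read an engine configuration from a YAML or JSON file
#'
#' Recognised keys match the arguments of [bs_config()]; the nested form
#' `guided_filter: {eps: ..., radius_base: ...}` is also accepted.
#' Unknown keys are an error so that typos do not silently fall back to
#' defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `"bs_config"` object.
#' @export
bs_config_from_file <- function(path) {
  if (!file.exists(path)) stop_io("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stop_format("unsupported config format '.", ext, "' (use yaml or json)")
  )
  if (!is.null(raw$guided_filter)) {
    gf <- raw$guided_filter
    raw$guided_filter <- NULL
    if (!is.null(gf$eps)) raw$guided_filter_eps <- gf$eps
    if (!is.null(gf$radius_base)) raw$radius_base <- gf$radius_base
  }
  known <- names(formals(bs_config))
  extra <- setdiff(names(raw), known)
  if (length(extra))
    stop_arg("unknown config keys: ", paste(extra, collapse = ", "))
  do.call(bs_config, raw)
}

#' @export
print.bs_config <- function(x, ...) {
  cat("band-sift engine configuration\n")
  cat(sprintf("  guided filter: eps = %g, radius base = %d\n",
              x$guided_filter_eps, x$radius_base))
  cat(sprintf("  log-lightness floor: %g L units\n", x$log_epsilon))
  cat(sprintf("  default max_size: %s px\n",
              if (is.na(x$max_size)) "none" else x$max_size))
  cat(sprintf("  jpeg quality: %d\n", x$jpeg_quality))
  invisible(x)
}
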