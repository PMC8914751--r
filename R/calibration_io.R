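#' Read and write multi-camera calibration files
#'
#' The calibration file is JSON (or YAML when the `yaml` package is
#' available) holding a list of cameras, each with `id`, `image_size`
#' `[width, height]`, `K` as 9 row-major floats, `dist` as
#' `[k1, k2, p1, p2]`, `R` as 9 row-major floats, `t` as 3 floats, and a
#' file-level `units` field (`"m"` or `"mm"`). Translations declared in mm
#' are converted to meters on read; the writer always emits meters at full
#' double precision, so write -> read round-trips are bit-exact.
#'
#' @param path file path. `read_calibration` treats `.yml`/`.yaml`
#'   extensions as YAML, everything else as JSON.
#' @return `read_calibration`: a named list of [camera_model()] objects.
#' @export
read_calibration <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML calibration requires the 'yaml' package; use JSON instead")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  units <- raw$units
  if (is.null(units)) units <- "m"
  if (!units %in% c("m", "mm")) stop("calibration units must be 'm' or 'mm'")
  scale <- if (units == "mm") 1e-3 else 1
  cams <- lapply(raw$cameras, function(cc) {
    camera_model(
      camera_id = cc$id,
      K = matrix(as.numeric(cc$K), 3, 3, byrow = TRUE),
      R = matrix(as.numeric(cc$R), 3, 3, byrow = TRUE),
      t = as.numeric(cc$t) * scale,
      dist = if (is.null(cc$dist)) c(0, 0, 0, 0) else as.numeric(cc$dist),
      image_size = as.numeric(cc$image_size))
  })
  stats::setNames(cams, vapply(cams, function(c) c$camera_id, character(1)))
}

#' @rdname read_calibration
#' @param cameras named list of `camera_model` objects.
#' @export
write_calibration <- function(cameras, path) {
  payload <- list(
    units = "m",
    cameras = lapply(unname(cameras), function(cam) {
      list(id = cam$camera_id,
           image_size = cam$image_size,
           K = as.vector(t(cam$K)),
           dist = cam$dist,
           R = as.vector(t(cam$R)),
           t = cam$t)
    }))
  # digits = I(17): 17 significant digits round-trip doubles bit-exactly
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}
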