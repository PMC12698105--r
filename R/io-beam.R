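# Beam-map serialization: 16-bit grayscale TIFF or plain-text CSV matrix,
# plus a YAML sidecar carrying the physical calibration (pixel pitch and
# total power), so shape files round-trip into calibrated profiles.

.sidecar_path <- function(path) paste0(path, ".yaml")

#' Write a beam profile to disk
#'
#' `.tif`/`.tiff` writes a 16-bit grayscale TIFF of the normalized map;
#' any other extension writes a plain CSV matrix. A YAML sidecar
#' (`<path>.yaml`) records `pixel_pitch_mm`, `total_power_W` and the
#' normalization, so [read_beam_profile()] restores the calibrated
#' profile.
#'
#' @param profile A [beam_profile()].
#' @param path Output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_beam_profile <- function(profile, path) {
  stopifnot(inherits(profile, "beam_profile"))
  ext <- tolower(tools::file_ext(path))
  peak <- max(profile$irradiance)
  if (peak <= 0) stop("all-zero beam profile")
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(profile$irradiance / peak, path, bits.per.sample = 16L)
  } else {
    utils::write.table(profile$irradiance / peak, path, sep = ",",
                       row.names = FALSE, col.names = FALSE)
  }
  yaml::write_yaml(list(pixel_pitch_mm = profile$pixel_pitch,
                        total_power_W = profile$total_power,
                        peak_irradiance = peak,
                        format = if (ext %in% c("tif", "tiff")) "tiff16"
                                 else "csv"),
                   .sidecar_path(path))
  invisible(path)
}

#' Read a beam profile from disk
#'
#' Reads a TIFF or CSV beam map written by [write_beam_profile()] (or any
#' grayscale TIFF/CSV matrix) and applies the YAML sidecar calibration.
#' Without a sidecar, `pixel_pitch` must be given and the map is returned
#' in its stored units.
#'
#' @param path Input path.
#' @param pixel_pitch Pixel pitch, mm, when no sidecar exists.
#' @return A [beam_profile()].
#' @export
read_beam_profile <- function(path, pixel_pitch = NULL) {
  ext <- tolower(tools::file_ext(path))
  map <- if (ext %in% c("tif", "tiff")) {
    m <- tiff::readTIFF(path)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    m
  } else {
    as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  }
  dimnames(map) <- NULL
  side <- .sidecar_path(path)
  if (file.exists(side)) {
    meta <- yaml::read_yaml(side)
    map <- map * meta$peak_irradiance / max(map)
    return(beam_profile(map, meta$pixel_pitch_mm))
  }
  if (is.null(pixel_pitch))
    stop("no sidecar found; supply `pixel_pitch` explicitly")
  beam_profile(map, pixel_pitch)
}
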