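#' 2-D beam irradiance profile
#'
#' An irradiance map on a regular pixel grid with physical pixel pitch.
#' Used for beam-uniformity analysis and limiting-aperture safety
#' calculations; irradiance may be in W/cm^2 or arbitrary units for
#' shape-only analyses.
#'
#' @param irradiance Numeric matrix, >= 0.
#' @param pixel_pitch Pixel pitch, mm, > 0.
#' @return An object of class `beam_profile` with derived `total_power`
#'   (irradiance sum times pixel area; W when irradiance is W/cm^2).
#' @export
beam_profile <- function(irradiance, pixel_pitch) {
  irradiance <- as.matrix(irradiance)
  if (any(irradiance < 0)) stop("irradiance must be >= 0 everywhere")
  if (pixel_pitch <= 0) stop("`pixel_pitch` must be > 0 (mm)")
  pixel_area_cm2 <- (pixel_pitch / 10)^2
  structure(list(irradiance = irradiance, pixel_pitch = pixel_pitch,
                 total_power = sum(irradiance) * pixel_area_cm2),
            class = "beam_profile")
}

#' @export
print.beam_profile <- function(x, ...) {
  cat(sprintf(paste0("<beam_profile> %d x %d px @ %.4g mm/px ",
                     "(%.3g x %.3g mm), peak %.4g, total power %.4g\n"),
              nrow(x$irradiance), ncol(x$irradiance), x$pixel_pitch,
              nrow(x$irradiance) * x$pixel_pitch,
              ncol(x$irradiance) * x$pixel_pitch,
              max(x$irradiance), x$total_power))
  invisible(x)
}

#' Laser-safety standard for skin exposure
#'
#' Holds the maximum-permissible-exposure irradiance and the limiting
#' aperture over which compliance is assessed. The default is the IEC skin
#' CW limit for the 700-1050 nm band,
#' `MPE = 0.2 * 10^(0.002 (lambda - 700)) W/cm^2` (0.2958 W/cm^2 at
#' 785 nm), averaged over a 3.5 mm aperture; `"ansi"` selects the flat
#' 0.28 W/cm^2 figure often quoted for prolonged 785 nm skin exposure.
#'
#' @param name `"iec"` (default) or `"ansi"`, or any label when
#'   `mpe_irradiance` is given explicitly.
#' @param wavelength Wavelength, nm (used by the IEC formula).
#' @param mpe_irradiance Explicit MPE irradiance, W/cm^2 (overrides the
#'   named formula).
#' @param limiting_aperture_diameter Limiting aperture, mm (default 3.5,
#'   skin).
#' @return An object of class `safety_standard`.
#' @examples
#' safety_standard()            # IEC at 785 nm: 0.2958 W/cm^2
#' safety_standard("ansi")      # 0.28 W/cm^2
#' @export
safety_standard <- function(name = c("iec", "ansi"), wavelength = 785,
                            mpe_irradiance = NULL,
                            limiting_aperture_diameter = 3.5) {
  if (limiting_aperture_diameter <= 0)
    stop("`limiting_aperture_diameter` must be > 0 (mm)")
  if (is.null(mpe_irradiance)) {
    name <- match.arg(name)
    mpe_irradiance <- switch(name,
      iec = 0.2 * 10^(0.002 * (wavelength - 700)),
      ansi = 0.28)
  } else {
    name <- if (is.character(name)) name[1] else "custom"
  }
  if (mpe_irradiance <= 0) stop("`mpe_irradiance` must be > 0 (W/cm^2)")
  structure(list(name = name, wavelength = wavelength,
                 mpe_irradiance = mpe_irradiance,
                 limiting_aperture_diameter = limiting_aperture_diameter),
            class = "safety_standard")
}

#' @export
print.safety_standard <- function(x, ...) {
  cat(sprintf(paste0("<safety_standard> %s: MPE %.4g W/cm^2 at %g nm, ",
                     "%.3g mm limiting aperture\n"),
              x$name, x$mpe_irradiance, x$wavelength,
              x$limiting_aperture_diameter))
  invisible(x)
}

#' Fiber-to-camera distance for a target beam diameter
#'
#' Distance at which the cone emerging from a fiber of numerical aperture
#' NA expands to diameter D: `L = D / (2 tan(asin(NA)))`.
#'
#' @param D Target beam diameter, mm, > 0.
#' @param NA_fiber Fiber numerical aperture, in (0, 1).
#' @return Distance L, mm.
#' @examples
#' fiber_to_camera_distance(5, 0.22)
#' @export
fiber_to_camera_distance <- function(D, NA_fiber) {
  if (D <= 0) stop("`D` must be > 0 (mm)")
  if (NA_fiber <= 0 || NA_fiber >= 1) stop("`NA_fiber` must lie in (0, 1)")
  D / (2 * tan(asin(NA_fiber)))
}

# 2-D "same"-size cross-correlation with a centered kernel, via FFT
.conv2_same <- function(x, kern) {
  nr <- nrow(x) + nrow(kern) - 1L
  nc <- ncol(x) + ncol(kern) - 1L
  xp <- matrix(0, nr, nc); xp[seq_len(nrow(x)), seq_len(ncol(x))] <- x
  kp <- matrix(0, nr, nc); kp[seq_len(nrow(kern)), seq_len(ncol(kern))] <- kern
  full <- Re(stats::fft(stats::fft(xp) * stats::fft(kp), inverse = TRUE)) /
    (nr * nc)
  r0 <- (nrow(kern) - 1L) %/% 2L
  c0 <- (ncol(kern) - 1L) %/% 2L
  pmax(full[r0 + seq_len(nrow(x)), c0 + seq_len(ncol(x))], 0)
}

# disk membership kernel: pixel centers within radius_px of the center pixel
.disk_kernel <- function(radius_px) {
  r <- ceiling(radius_px)
  d <- seq(-r, r)
  (outer(d^2, d^2, "+") <= radius_px^2) * 1
}

#' Maximum aperture-averaged irradiance of a beam profile
#'
#' Scans a circular aperture centered at every pixel of the map; each
#' aperture's value is the enclosed power divided by the full aperture
#' area. Safety standards assess compliance against this maximum: for a
#' beam smaller than the aperture it equals total power over the aperture
#' area regardless of spot size, and for a larger beam it is the hottest
#' sub-aperture average (at the beam center for centrally peaked beams).
#'
#' @param profile A [beam_profile()] with irradiance in W/cm^2.
#' @param aperture_diameter Aperture diameter, mm (default 3.5).
#' @return A list with `max_irradiance` (W/cm^2), `center` (row/col pixel
#'   indices of the maximizing aperture) and `aperture_diameter`.
#' @export
max_aperture_averaged_irradiance <- function(profile,
                                             aperture_diameter = 3.5) {
  stopifnot(inherits(profile, "beam_profile"))
  irr <- profile$irradiance
  radius_px <- (aperture_diameter / 2) / profile$pixel_pitch
  peak <- max(irr)
  if (peak <= 0) stop("all-zero beam profile")
  sup <- which(irr > 0.01 * peak, arr.ind = TRUE)
  margin <- min(sup[, 1] - 1, nrow(irr) - sup[, 1],
                sup[, 2] - 1, ncol(irr) - sup[, 2])
  if (margin < radius_px)
    stop(sprintf(paste0("insufficient dark margin for the aperture scan: ",
                        "need >= %.1f px around the beam support, have %d"),
                 radius_px, margin))
  pixel_area_cm2 <- (profile$pixel_pitch / 10)^2
  power_map <- .conv2_same(irr * pixel_area_cm2, .disk_kernel(radius_px))
  aperture_area_cm2 <- pi * (aperture_diameter / 2 / 10)^2
  avg_map <- power_map / aperture_area_cm2
  imax <- which.max(avg_map)
  list(max_irradiance = avg_map[imax],
       center = c(row = row(avg_map)[imax], col = col(avg_map)[imax]),
       aperture_diameter = aperture_diameter)
}

#' Maximum permissible total power for a beam shape
#'
#' The total power at which the beam, scaled without changing its shape,
#' reaches the standard's MPE irradiance in the hottest limiting-aperture
#' position: `P_allowed = MPE * P_shape / max_aperture_avg(shape)`.
#' Depends on the shape only (invariant under rescaling the input's
#' power) and is linear in the MPE irradiance.
#'
#' @param profile_shape A [beam_profile()] with nonzero power (any units).
#' @param standard A [safety_standard()].
#' @return Allowed total power, W.
#' @export
allowed_power <- function(profile_shape, standard = safety_standard()) {
  stopifnot(inherits(profile_shape, "beam_profile"),
            inherits(standard, "safety_standard"))
  if (profile_shape$total_power <= 0) stop("zero-power beam profile")
  m <- max_aperture_averaged_irradiance(
    profile_shape, standard$limiting_aperture_diameter)
  standard$mpe_irradiance * profile_shape$total_power / m$max_irradiance
}

#' Point-source power limit of a safety standard
#'
#' For a beam confined well inside the limiting aperture the
#' aperture-averaged irradiance is total power over aperture area, so the
#' allowed power is simply `MPE * aperture area` — the small-source limit
#' of [allowed_power()].
#'
#' @param standard A [safety_standard()].
#' @return Allowed total power, W.
#' @examples
#' point_source_power_limit(safety_standard())  # ~0.0285 W at 785 nm
#' @export
point_source_power_limit <- function(standard = safety_standard()) {
  standard$mpe_irradiance *
    pi * (standard$limiting_aperture_diameter / 2 / 10)^2
}

#' Power fraction inside a circular aperture
#'
#' @param profile A [beam_profile()].
#' @param aperture_diameter Aperture diameter, mm.
#' @param center `"centroid"` (default) to center the aperture on the
#'   intensity-weighted centroid, or a `c(row, col)` pixel position.
#' @return Fraction of total power inside the aperture, in \[0, 1\]
#'   (pixel-center membership).
#' @export
fraction_in_aperture <- function(profile, aperture_diameter = 3.5,
                                 center = "centroid") {
  stopifnot(inherits(profile, "beam_profile"))
  irr <- profile$irradiance
  if (sum(irr) <= 0) stop("all-zero beam profile")
  if (identical(center, "centroid")) {
    center <- c(sum(row(irr) * irr), sum(col(irr) * irr)) / sum(irr)
  }
  radius_px <- (aperture_diameter / 2) / profile$pixel_pitch
  inside <- (row(irr) - center[1])^2 + (col(irr) - center[2])^2 <=
    radius_px^2
  sum(irr[inside]) / sum(irr)
}

#' Permissible-power headroom from an aperture power fraction
#'
#' For a centrally peaked beam wider than the limiting aperture whose
#' hottest aperture captures fraction `f` of the total power, the allowed
#' total power is the point-source limit divided by `f` — e.g. a Gaussian
#' with 91.1% of its power in the central 3.5 mm permits only ~1.10x the
#' point-source power.
#'
#' @param fraction Power fraction in the hottest limiting aperture, (0, 1].
#' @return Headroom factor relative to the point-source limit, >= 1.
#' @examples
#' aperture_power_headroom(0.911)
#' @export
aperture_power_headroom <- function(fraction) {
  if (any(fraction <= 0) || any(fraction > 1))
    stop("`fraction` must lie in (0, 1]")
  1 / fraction
}

#' Count-rate-proportional SNR gain of flat-top vs Gaussian illumination
#'
#' Under the photon-counting noise model the g2 standard deviation scales
#' as 1/I, so SNR is proportional to the delivered count rate. Switching
#' from a Gaussian beam (limited by its hot center) to a flat-top conduit
#' changes the usable count rate by
#' `gain = power_ratio * transmission / gaussian_aperture_fraction`.
#'
#' @param power_ratio_flat_vs_point Allowed-power ratio of the flat-top
#'   beam to the point-source limit (~2 for a 5 mm flat-top and 3.5 mm
#'   aperture).
#' @param llg_transmission Relative photon throughput of the flat-top
#'   conduit at equal power (~0.8 for a liquid light guide).
#' @param gaussian_aperture_fraction Power fraction of the Gaussian beam
#'   inside the limiting aperture (~0.911 for a 5 mm Gaussian).
#' @return SNR gain factor (dimensionless), linear in each argument.
#' @examples
#' theoretical_snr_gain(2, 0.8, 0.911)  # ~1.76
#' @export
theoretical_snr_gain <- function(power_ratio_flat_vs_point,
                                 llg_transmission,
                                 gaussian_aperture_fraction) {
  args <- c(power_ratio_flat_vs_point, llg_transmission,
            gaussian_aperture_fraction)
  if (any(args <= 0)) stop("all arguments must be > 0")
  power_ratio_flat_vs_point * llg_transmission / gaussian_aperture_fraction
}

#' Beam-geometry and uniformity report
#'
#' Intensity-weighted centroid, radial profile (annulus means about the
#' centroid), centroid cross-sections after moving-average smoothing, and
#' the smoothed peak irradiance, for a background-subtracted profile.
#'
#' @param profile A [beam_profile()].
#' @param smooth_px Moving-average window for cross-sections and peak, in
#'   pixels (default 50).
#' @return A list with `peak_irradiance`, `centroid` (row/col, px),
#'   `centroid_mm`, `radial_profile` (data.frame `radius_mm`,
#'   `mean_irradiance`) and `cross_sections` (data.frame `offset_mm`,
#'   `horizontal`, `vertical`).
#' @export
beam_uniformity_report <- function(profile, smooth_px = 50) {
  stopifnot(inherits(profile, "beam_profile"))
  irr <- profile$irradiance
  if (sum(irr) <= 0) stop("all-zero beam profile")
  ctr <- c(sum(row(irr) * irr), sum(col(irr) * irr)) / sum(irr)

  r_px <- sqrt((row(irr) - ctr[1])^2 + (col(irr) - ctr[2])^2)
  shell <- floor(r_px)  # annuli one pixel pitch wide
  means <- tapply(irr, shell, mean)
  radial <- data.frame(
    radius_mm = (as.numeric(names(means)) + 0.5) * profile$pixel_pitch,
    mean_irradiance = as.numeric(means))

  smooth <- function(v) {
    k <- min(max(1L, round(smooth_px)), length(v))
    as.numeric(stats::filter(v, rep(1 / k, k), sides = 2))
  }
  h <- smooth(irr[round(ctr[1]), ])
  v <- smooth(irr[, round(ctr[2])])
  n <- max(length(h), length(v))
  cross <- data.frame(
    offset_h_mm = (seq_along(h) - ctr[2]) * profile$pixel_pitch,
    horizontal = h,
    offset_v_mm = (seq_along(v) - ctr[1]) * profile$pixel_pitch,
    vertical = v)

  sm_map_peak <- max(stats::na.omit(c(h, v)))
  list(peak_irradiance = sm_map_peak,
       centroid = ctr,
       centroid_mm = ctr * profile$pixel_pitch,
       radial_profile = radial,
       cross_sections = cross)
}

#' Average camera frames and subtract background
#'
#' Pixelwise mean over frames minus a dark/background frame, clipped at
#' zero — the standard preprocessing for speckled beam images acquired as
#' many short exposures. When no background frame is supplied, the median
#' of the outer 5% border of the averaged frame is used as a uniform
#' background estimate.
#'
#' @param frames List of numeric matrices, all the same shape.
#' @param background Background frame (matrix), a scalar, or `NULL` for
#'   the border-median estimate.
#' @param pixel_pitch Pixel pitch, mm.
#' @return A [beam_profile()].
#' @export
preprocess_frames <- function(frames, background = NULL, pixel_pitch) {
  if (!length(frames)) stop("need >= 1 frame")
  dims <- dim(frames[[1]])
  for (f in frames)
    if (!identical(dim(f), dims)) stop("all frames must share one shape")
  avg <- Reduce(`+`, frames) / length(frames)
  if (is.null(background)) {
    b <- pmax(1L, round(0.05 * dims))
    border <- c(avg[c(seq_len(b[1]), nrow(avg) - seq_len(b[1]) + 1L), ],
                avg[, c(seq_len(b[2]), ncol(avg) - seq_len(b[2]) + 1L)])
    background <- stats::median(border)
  } else if (is.matrix(background) && !identical(dim(background), dims)) {
    stop("background frame shape must match the frames")
  }
  beam_profile(pmax(avg - background, 0), pixel_pitch)
}
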