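# Seeded generators standing in for the instrument: speckle photon streams,
# noisy g2 curves, beam images, and cuff-occlusion flow protocols.

# run `expr` under a fixed RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Specification of a synthetic speckle photon stream
#'
#' Parameters of the speckle/photon simulator: a single-rate exponential
#' field decorrelation `g1 = exp(-Gamma tau)` detected as `M` independent
#' speckle modes (so the coherence factor is `beta = 1/M`), with Poisson
#' photon detection at a target mean count rate.
#'
#' @param Gamma Field decay rate, s^-1, > 0.
#' @param mean_count_rate Target detected count rate, photons/s, > 0.
#' @param n_modes_M Number of detected speckle modes, integer >= 1.
#' @param duration Stream duration, s, > 0.
#' @param sim_bin Simulation bin width, s; must resolve the field decay
#'   (`sim_bin <= 0.05 / Gamma`).
#' @param seed Integer RNG seed.
#' @return An object of class `speckle_stream_spec`.
#' @export
speckle_stream_spec <- function(Gamma, mean_count_rate, n_modes_M = 1L,
                                duration, sim_bin, seed = 1L) {
  if (Gamma <= 0 || mean_count_rate <= 0 || duration <= 0 || sim_bin <= 0)
    stop("Gamma, mean_count_rate, duration and sim_bin must all be > 0")
  if (n_modes_M < 1 || n_modes_M != round(n_modes_M))
    stop("`n_modes_M` must be an integer >= 1")
  if (sim_bin > 0.05 / Gamma)
    stop(sprintf("sim_bin = %.3g s is too coarse for Gamma = %.3g /s: need sim_bin <= 0.05/Gamma = %.3g s",
                 sim_bin, Gamma, 0.05 / Gamma))
  structure(list(Gamma = Gamma, mean_count_rate = mean_count_rate,
                 n_modes_M = as.integer(n_modes_M), duration = duration,
                 sim_bin = sim_bin, seed = as.integer(seed)),
            class = "speckle_stream_spec")
}

#' Simulate a speckle photon-count stream
#'
#' Each speckle mode is a complex Gaussian field evolving as a first-order
#' autoregressive process with autocorrelation `exp(-Gamma tau)`; the
#' detected intensity is the mode-average of `|E|^2`, and photon counts are
#' Poisson draws at a rate proportional to the intensity, calibrated to the
#' target mean count rate. The resulting stream has
#' `g2(tau) ~ 1 + (1/M) exp(-2 Gamma tau)`.
#'
#' @param spec A [speckle_stream_spec()].
#' @return A [photon_count_series()] at the spec's `sim_bin` resolution.
#' @examples
#' s <- generate_speckle_stream(
#'   speckle_stream_spec(Gamma = 2000, mean_count_rate = 5e4,
#'                       duration = 0.5, sim_bin = 2e-5, seed = 7))
#' @export
generate_speckle_stream <- function(spec) {
  stopifnot(inherits(spec, "speckle_stream_spec"))
  n <- round(spec$duration / spec$sim_bin)
  a <- exp(-spec$Gamma * spec$sim_bin)
  innov_sd <- sqrt((1 - a^2) / 2)
  .with_seed(spec$seed, {
    intensity <- numeric(n)
    for (m in seq_len(spec$n_modes_M)) {
      re <- stats::filter(stats::rnorm(n, 0, innov_sd), a,
                          method = "recursive",
                          init = stats::rnorm(1, 0, sqrt(0.5)))
      im <- stats::filter(stats::rnorm(n, 0, innov_sd), a,
                          method = "recursive",
                          init = stats::rnorm(1, 0, sqrt(0.5)))
      intensity <- intensity + re^2 + im^2
    }
    intensity <- intensity / spec$n_modes_M  # mean 1
    counts <- stats::rpois(n, spec$mean_count_rate * spec$sim_bin * intensity)
    photon_count_series(counts, spec$sim_bin)
  })
}

#' Replicated noisy g2 curves from a model curve
#'
#' Adds independent zero-mean Gaussian noise with the per-lag standard
#' deviation of the full analytic noise model to a noise-free model curve —
#' the standard way to emulate repeated correlation measurements without
#' simulating photon streams.
#'
#' @param model_curve A noise-free [correlation_curve()].
#' @param params A [noise_params()] (pass a per-lag `bin_width_T` vector
#'   for multi-tau grids).
#' @param n_replicates Number of replicate curves.
#' @param seed Master seed; replicate r uses sub-seed `seed + r`.
#' @param sigma_scale Multiplier on the model sigma (0 gives noise-free
#'   replicates).
#' @return List of [correlation_curve()] objects carrying the generating
#'   sigma in their `sigma` column.
#' @export
generate_g2_curves <- function(model_curve, params, n_replicates,
                               seed = 1L, sigma_scale = 1) {
  stopifnot(inherits(model_curve, "correlation_curve"))
  sd_lag <- sigma_full(model_curve$tau, params) * sigma_scale
  lapply(seq_len(n_replicates), function(r) {
    noise <- .with_seed(seed + r,
                        stats::rnorm(length(sd_lag), 0, sd_lag))
    correlation_curve(model_curve$tau, model_curve$g2 + noise,
                      beta = curve_beta(model_curve), sigma = sd_lag)
  })
}

#' Generate a synthetic beam-irradiance image
#'
#' Circular Gaussian (1/e^2 diameter = `diameter`) or flat-top (uniform
#' disk, optional raised-cosine edge) beam on a square grid, normalized so
#' the integrated power equals `total_power` exactly.
#'
#' @param kind `"gaussian"` or `"flattop"`.
#' @param diameter Beam diameter, mm (must span >= 50 pixels).
#' @param pixel_pitch Pixel pitch, mm.
#' @param total_power Integrated power, W (default 1).
#' @param edge_softness Width of the flat-top's raised-cosine edge, mm
#'   (default 0: hard edge).
#' @param noise_level Additive Gaussian noise, as a fraction of the peak
#'   (default 0).
#' @param image_width Image side length, mm (default `2.5 * diameter`,
#'   leaving dark margin for aperture scans).
#' @param seed RNG seed used when `noise_level > 0`.
#' @return A [beam_profile()].
#' @examples
#' generate_beam_image("flattop", diameter = 5, pixel_pitch = 0.05)
#' @export
generate_beam_image <- function(kind = c("gaussian", "flattop"), diameter,
                                pixel_pitch, total_power = 1,
                                edge_softness = 0, noise_level = 0,
                                image_width = 2.5 * diameter, seed = 1L) {
  kind <- match.arg(kind)
  if (diameter / pixel_pitch < 50)
    stop("grid too coarse: the beam diameter must span >= 50 pixels")
  n <- round(image_width / pixel_pitch)
  ctr <- (n + 1) / 2
  r_mm <- sqrt((row(matrix(0, n, n)) - ctr)^2 +
                 (col(matrix(0, n, n)) - ctr)^2) * pixel_pitch
  irr <- if (kind == "gaussian") {
    w <- diameter / 2  # 1/e^2 radius
    exp(-2 * r_mm^2 / w^2)
  } else {
    R <- diameter / 2
    if (edge_softness > 0) {
      s <- edge_softness
      x <- (r_mm - R) / s + 0.5  # 0 at inner edge, 1 at outer edge
      ifelse(x <= 0, 1, ifelse(x >= 1, 0, 0.5 * (1 + cos(pi * x))))
    } else {
      (r_mm <= R) * 1
    }
  }
  if (noise_level > 0) {
    irr <- pmax(irr + .with_seed(seed,
      matrix(stats::rnorm(n * n, 0, noise_level * max(irr)), n, n)), 0)
  }
  pixel_area_cm2 <- (pixel_pitch / 10)^2
  beam_profile(irr * total_power / (sum(irr) * pixel_area_cm2), pixel_pitch)
}

#' Specification of a cuff-occlusion flow protocol
#'
#' Three consecutive phases — baseline, occlusion, recovery — with
#' per-phase relative flow levels and a transient hyperemic overshoot at
#' cuff release that decays exponentially back to the recovery level.
#'
#' @param phase_durations Durations of (baseline, occlusion, recovery), s.
#' @param relative_levels Relative flow levels of the three phases
#'   (default `c(1, 0.2, 1)`).
#' @param overshoot Peak relative flow at release (default 1.5); must be
#'   >= the recovery level.
#' @param overshoot_decay Exponential decay time of the overshoot, s
#'   (default a quarter of the recovery phase; 0 gives a step recovery).
#' @return An object of class `occlusion_protocol_spec`.
#' @export
occlusion_protocol_spec <- function(phase_durations = c(40, 40, 40),
                                    relative_levels = c(1, 0.2, 1),
                                    overshoot = 1.5,
                                    overshoot_decay = phase_durations[3] / 4) {
  if (length(phase_durations) != 3 || any(phase_durations <= 0))
    stop("`phase_durations` must be three positive durations")
  if (length(relative_levels) != 3 || any(relative_levels <= 0))
    stop("`relative_levels` must be three positive levels")
  if (relative_levels[2] >= relative_levels[1])
    stop("the occlusion level must be below the baseline level")
  if (overshoot < relative_levels[3])
    stop("`overshoot` must be >= the recovery level")
  if (overshoot_decay < 0) stop("`overshoot_decay` must be >= 0")
  structure(list(phase_durations = phase_durations,
                 relative_levels = relative_levels,
                 overshoot = overshoot, overshoot_decay = overshoot_decay),
            class = "occlusion_protocol_spec")
}

# relative flow level at absolute time t (s) under the protocol
.occlusion_level <- function(t, spec) {
  d <- cumsum(spec$phase_durations)
  lv <- spec$relative_levels
  ifelse(t < d[1], lv[1],
    ifelse(t < d[2], lv[2],
      if (spec$overshoot_decay > 0)
        lv[3] + (spec$overshoot - lv[3]) *
          exp(-(t - d[2]) / spec$overshoot_decay)
      else lv[3]))
}

#' Synthetic BFi time course for a cuff-occlusion protocol
#'
#' Evaluates the protocol's relative flow level at each acquisition-window
#' midpoint, scales it by a baseline diffusion coefficient, and generates a
#' per-window model g2 curve at that flow through the semi-infinite forward
#' model — a controlled stand-in for an in-vivo occlusion recording.
#'
#' @param spec An [occlusion_protocol_spec()].
#' @param window Acquisition window length, s.
#' @param DB_baseline Baseline diffusion coefficient, cm^2/s.
#' @param props An [optical_properties()] (defaults to the aqueous-phantom
#'   values).
#' @param rho Source-detector separation, mm (default 20).
#' @param beta Coherence factor of the generated curves (default 0.5).
#' @param noise_params Optional [noise_params()]; when supplied each
#'   window's curve gets Gaussian noise at the model sigma.
#' @param seed Seed for the optional noise.
#' @return A list with `trace` (data.frame `window_start`, `relative_BFi`,
#'   `BFi`) and `curves` (list of per-window [correlation_curve()]).
#' @export
generate_occlusion_bfi <- function(spec, window = 2, DB_baseline = 2.8e-7,
                                   props = optical_properties(0.0025, 1.0),
                                   rho = 20, beta = 0.5,
                                   noise_params = NULL, seed = 1L) {
  stopifnot(inherits(spec, "occlusion_protocol_spec"))
  total <- sum(spec$phase_durations)
  starts <- seq(0, total - window, by = window)
  rel <- .occlusion_level(starts + window / 2, spec)
  geom <- semi_infinite_geometry(rho, props)
  tau <- default_lag_grid(geom, props, flow_model(DB_baseline))
  curves <- lapply(seq_along(rel), function(i) {
    cv <- model_g2_curve(geom, props, flow_model(DB_baseline * rel[i]),
                         tau, beta = beta)
    if (!is.null(noise_params))
      cv <- generate_g2_curves(cv, noise_params, 1, seed = seed * 1000 + i)[[1]]
    cv
  })
  list(trace = data.frame(window_start = starts, relative_BFi = rel,
                          BFi = DB_baseline * rel),
       curves = curves)
}
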