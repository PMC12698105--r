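# Configuration and staged pipeline runner tying the analysis stages into
# reproducible seeded runs. The YAML config round-trips losslessly; every
# run logs the resolved configuration and seed next to its outputs.

#' Read a run configuration
#'
#' YAML configuration with blocks `optics`, `geometry`, `scheme`, `noise`,
#' `fit`, `safety`, `synth`, plus top-level `seed` and `paths` (`input`,
#' `output_dir`). Unknown top-level keys are rejected.
#'
#' @param path YAML file.
#' @return A named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("optics", "geometry", "scheme", "noise", "fit", "safety",
             "synth", "seed", "paths")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("invalid config keys: ", paste(bad, collapse = ", "),
         " (known: ", paste(known, collapse = ", "), ")")
  if (is.null(cfg$seed)) cfg$seed <- 1L
  structure(cfg, class = c("run_config", "list"))
}

#' Write a run configuration
#'
#' @param config A `run_config` (or plain named list).
#' @param path Output YAML file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

.cfg_optics <- function(cfg) {
  o <- cfg$optics
  if (is.null(o)) stop("config is missing the `optics` block")
  optical_properties(mu_a = o$mu_a, mu_s_prime = o$mu_s_prime,
                     n0 = o$n0 %||% 1.33, n_air = o$n_air %||% 1.0,
                     wavelength = o$wavelength %||% 785)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.log_line <- function(...) cat(sprintf(...), "\n", sep = "")

#' Run one pipeline stage
#'
#' Staged, file-based runner: each stage reads the inputs named in the
#' config, executes the corresponding package functions, and writes its
#' artifacts (plus a `run-<stage>.yaml` log of the resolved config and
#' seed) into the output directory.
#'
#' Stages: `simulate` (speckle stream or model curve per `config$synth`),
#' `correlate` (multi-tau g2 from a count/timestamp file), `fit` (flow
#' index from a curve file), `noise` (model sigma report for a curve),
#' `mpe` (limiting-aperture power analysis of a beam map), `beam`
#' (uniformity report of a beam map).
#'
#' @param config A `run_config` from [read_run_config()] (or equivalent
#'   list).
#' @param stage One of `"simulate"`, `"correlate"`, `"fit"`, `"noise"`,
#'   `"mpe"`, `"beam"`.
#' @return Invisibly, a named list of output paths and key results; errors
#'   on missing inputs, invalid stages, or flagged non-convergence.
#' @export
run_pipeline <- function(config, stage) {
  stages <- c("simulate", "correlate", "fit", "noise", "mpe", "beam")
  if (length(stage) != 1L || !stage %in% stages)
    stop("unknown stage '", stage, "'; expected one of: ",
         paste(stages, collapse = ", "))
  out_dir <- config$paths$output_dir %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- config$seed %||% 1L
  input <- config$paths$input
  if (stage %in% c("correlate", "fit", "noise", "mpe", "beam")) {
    if (is.null(input) || !file.exists(input))
      stop("stage '", stage, "' needs an existing config$paths$input file",
           if (!is.null(input)) paste0(" (got: ", input, ")") else "")
  }
  res <- switch(stage,
    simulate = {
      what <- config$synth$what %||% "curve"
      if (what == "stream") {
        spec <- speckle_stream_spec(
          Gamma = config$synth$Gamma, mean_count_rate = config$synth$rate,
          n_modes_M = config$synth$modes %||% 1L,
          duration = config$synth$duration,
          sim_bin = config$synth$sim_bin, seed = seed)
        s <- generate_speckle_stream(spec)
        p <- file.path(out_dir, "stream-counts.csv")
        utils::write.csv(data.frame(counts = s$counts), p, row.names = FALSE)
        list(stream = p, bin_width = s$bin_width)
      } else {
        props <- .cfg_optics(config)
        geom <- semi_infinite_geometry(config$geometry$rho, props)
        flow <- flow_model(config$synth$DB, config$synth$alpha %||% 1)
        tau <- default_lag_grid(geom, props, flow)
        cv <- model_g2_curve(geom, props, flow, tau,
                             beta = config$synth$beta %||% 0.5,
                             model_kind = config$synth$model %||% "point",
                             source_radius = config$synth$source_radius %||% 0)
        p <- file.path(out_dir, "model-curve.csv")
        write_correlation_curve(cv, p)
        list(curve = p)
      }
    },
    correlate = {
      sch <- multi_tau_scheme(
        base_bin = config$scheme$base_bin %||% 6.145e-9,
        lags_per_block = config$scheme$lags_per_block %||% 16L,
        widening_factor = config$scheme$widening_factor %||% 3L,
        n_blocks = config$scheme$n_blocks %||% 8L)
      counts <- utils::read.csv(input)$counts
      series <- photon_count_series(counts, sch$base_bin)
      cv <- autocorrelate(series, sch)
      p <- file.path(out_dir, "g2-curve.csv")
      write_correlation_curve(cv, p)
      list(curve = p)
    },
    fit = {
      props <- .cfg_optics(config)
      cv <- read_correlation_curve(input)
      fit <- fit_g2(cv, props, rho = config$geometry$rho,
                    model_kind = config$fit$model %||% "point",
                    source_radius = config$fit$source_radius %||% 0,
                    beta = config$fit$beta,
                    DB_init = config$fit$DB_init %||% 1e-7)
      if (!fit$converged)
        stop("fit did not converge: ", fit$message)
      p <- file.path(out_dir, "fit-result.yaml")
      yaml::write_yaml(list(DB_cm2_s = fit$DB_fit, beta = fit$beta_fit,
                            residual_norm = fit$residual_norm,
                            model = fit$model_kind), p)
      list(result = p, DB_fit = fit$DB_fit, beta_fit = fit$beta_fit)
    },
    noise = {
      cv <- read_correlation_curve(input)
      np <- noise_params(
        bin_width_T = config$noise$bin_width %||% 6.145e-9,
        integration_time_t = config$noise$integration_time %||% 1,
        beta = config$noise$beta %||% 0.5,
        Gamma = config$noise$Gamma,
        count_rate_I = config$noise$count_rate)
      sig <- sigma_full(cv$tau, np)
      p <- file.path(out_dir, "noise-report.csv")
      write_noise_report(cv$tau, sig, snr = (cv$g2 - 1) / sig, path = p)
      list(report = p)
    },
    mpe = {
      prof <- read_beam_profile(input,
                                pixel_pitch = config$safety$pixel_pitch)
      std <- safety_standard(
        name = config$safety$standard %||% "iec",
        wavelength = config$safety$wavelength %||% 785,
        limiting_aperture_diameter = config$safety$aperture %||% 3.5)
      pw <- allowed_power(prof, std)
      frac <- fraction_in_aperture(prof, std$limiting_aperture_diameter)
      p <- file.path(out_dir, "mpe-report.yaml")
      yaml::write_yaml(list(standard = std$name,
                            mpe_irradiance_W_cm2 = std$mpe_irradiance,
                            allowed_power_W = pw,
                            point_limit_W = point_source_power_limit(std),
                            fraction_in_aperture = frac), p)
      list(report = p, allowed_power_W = pw)
    },
    beam = {
      prof <- read_beam_profile(input,
                                pixel_pitch = config$safety$pixel_pitch)
      rep_ <- beam_uniformity_report(prof)
      p1 <- file.path(out_dir, "beam-radial.csv")
      utils::write.csv(rep_$radial_profile, p1, row.names = FALSE)
      p2 <- file.path(out_dir, "beam-cross-sections.csv")
      utils::write.csv(rep_$cross_sections, p2, row.names = FALSE)
      list(radial = p1, cross_sections = p2,
           peak_irradiance = rep_$peak_irradiance)
    })
  log_path <- file.path(out_dir, paste0("run-", stage, ".yaml"))
  yaml::write_yaml(list(stage = stage, seed = seed,
                        timestamp = format(Sys.time(), tz = "UTC"),
                        package_version = as.character(
                          utils::packageVersion("dcsflow")),
                        config = unclass(config)), log_path)
  .log_line("[dcsflow] stage '%s' complete; log: %s", stage, log_path)
  invisible(c(res, list(log = log_path)))
}
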