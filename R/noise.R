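#' Parameters of the analytic g2 noise model
#'
#' Inputs of the photon-counting noise model for the standard deviation of
#' a measured intensity autocorrelation: correlator bin width, integration
#' time, coherence factor, field decay rate and detected count rate. The
#' model assumes a single-exponential field correlation `g1 = exp(-Gamma
#' tau)`, so the noise-free intensity correlation is
#' `g2 = 1 + beta exp(-2 Gamma tau)`.
#'
#' The symbol T is overloaded in the literature (temperature vs bin width);
#' here the bin width is always `bin_width_T` and temperatures elsewhere in
#' the package are explicit `temperature` arguments in K.
#'
#' @param bin_width_T Correlator bin width, s. May be a vector (one value
#'   per lag) for multi-tau grids whose bin width widens with the block.
#' @param integration_time_t Total measurement time, s, >= max(bin_width_T).
#' @param beta Coherence factor, (0, 1].
#' @param Gamma Field decay rate, s^-1, >= 0.
#' @param count_rate_I Detected photon count rate, s^-1, >= 0.
#' @return An object of class `noise_params`; the mean photon count per bin
#'   `mean_count_n = count_rate_I * bin_width_T` is derived.
#' @examples
#' noise_params(6.145e-9, 1, beta = 0.5, Gamma = 5000, count_rate_I = 1e5)
#' @export
noise_params <- function(bin_width_T, integration_time_t, beta, Gamma,
                         count_rate_I) {
  if (any(bin_width_T <= 0)) stop("`bin_width_T` must be > 0 (s)")
  if (integration_time_t < max(bin_width_T))
    stop("`integration_time_t` must be >= the bin width")
  if (beta <= 0 || beta > 1) stop("`beta` must lie in (0, 1]")
  if (Gamma < 0) stop("`Gamma` must be >= 0 (s^-1)")
  if (count_rate_I < 0) stop("`count_rate_I` must be >= 0 (s^-1)")
  structure(list(bin_width_T = bin_width_T,
                 integration_time_t = integration_time_t,
                 beta = beta, Gamma = Gamma, count_rate_I = count_rate_I,
                 mean_count_n = count_rate_I * bin_width_T),
            class = "noise_params")
}

#' @export
print.noise_params <- function(x, ...) {
  cat(sprintf(paste0("<noise_params> T = %.4g s, t = %.4g s, beta = %.3g, ",
                     "Gamma = %.4g /s, I = %.4g /s, <n> = %.4g\n"),
              x$bin_width_T[1], x$integration_time_t, x$beta, x$Gamma,
              x$count_rate_I, x$mean_count_n[1]))
  invisible(x)
}

#' Full analytic standard deviation of measured g2
#'
#' Photon-counting noise model for the per-lag standard deviation of the
#' intensity autocorrelation estimated over an integration time `t` with
#' correlator bin width `T`:
#' \deqn{\sigma(\tau) = \sqrt{T/t}\,\Big[
#'   \beta^2 \frac{(1+e^{-2\Gamma T})(1+e^{-2\Gamma\tau})
#'                 + 2m(1-e^{-2\Gamma T})e^{-2\Gamma\tau}}{1-e^{-2\Gamma T}}
#'   + 2\langle n\rangle^{-1}\beta(1+e^{-2\Gamma\tau})
#'   + \langle n\rangle^{-2}(1+\beta e^{-\Gamma\tau})\Big]^{1/2}}
#' with `m = round(tau / T)` the delay-bin index and
#' `<n> = I T` the mean photon count per bin. For multi-tau lag grids pass
#' the per-lag widened bin width as a vector in `params$bin_width_T`; each
#' lag then uses its own `T`, `m` and `<n>`.
#'
#' @param tau Lag times, s, > 0.
#' @param params A [noise_params()]; `bin_width_T` scalar or one value per
#'   lag.
#' @return Per-lag standard deviation of g2, same length as `tau`.
#' @examples
#' p <- noise_params(1e-6, 1, beta = 0.5, Gamma = 5000, count_rate_I = 1e5)
#' sigma_full(10^seq(-6, -3, 0.5), p)
#' @export
sigma_full <- function(tau, params) {
  stopifnot(inherits(params, "noise_params"))
  if (any(tau <= 0)) stop("lag times must be > 0")
  T_ <- params$bin_width_T
  if (length(T_) != 1L && length(T_) != length(tau))
    stop("`bin_width_T` must be scalar or one value per lag")
  G <- params$Gamma
  if (any(G * T_ == 0))
    stop(paste0("Gamma * T is exactly 0: the model's leading term is ",
                "singular; use the small-Gamma*T expansion via ",
                "sigma_simplified() instead"))
  t_ <- params$integration_time_t
  beta <- params$beta
  n_mean <- params$count_rate_I * T_
  m <- round(tau / T_)
  e2T <- exp(-2 * G * T_)
  e2tau <- exp(-2 * G * tau)
  e1tau <- exp(-G * tau)
  bracket <- beta^2 * ((1 + e2T) * (1 + e2tau) + 2 * m * (1 - e2T) * e2tau) /
    (1 - e2T) +
    2 * n_mean^-1 * beta * (1 + e2tau) +
    n_mean^-2 * (1 + beta * e1tau)
  sqrt(T_ / t_) * sqrt(bracket)
}

#' Simplified noise model for slow decorrelation at low count rates
#'
#' Limit of the full model when the per-bin count is small and the decay is
#' slow on the bin timescale:
#' `sigma(tau) = (1/I) sqrt((1 + beta exp(-Gamma tau)) / (t T))`.
#'
#' @inheritParams sigma_full
#' @return Per-lag standard deviation of g2.
#' @examples
#' p <- noise_params(6.145e-9, 1, beta = 0.5, Gamma = 5000, count_rate_I = 1e5)
#' sigma_simplified(1e-5, p)
#' @export
sigma_simplified <- function(tau, params) {
  stopifnot(inherits(params, "noise_params"))
  if (params$count_rate_I == 0)
    stop("count_rate_I = 0: noise is unbounded in the simplified model")
  (1 / params$count_rate_I) *
    sqrt((1 + params$beta * exp(-params$Gamma * tau)) /
           (params$integration_time_t * params$bin_width_T))
}

#' Signal-to-noise ratio of a correlation measurement
#'
#' `SNR(tau) = (g2(tau) - 1) / sigma(tau)`.
#'
#' @param curve A [correlation_curve()].
#' @param sigma Per-lag standard deviation, > 0, same length as the curve.
#' @return Numeric vector of per-lag SNR values.
#' @export
snr_curve <- function(curve, sigma) {
  stopifnot(inherits(curve, "correlation_curve"))
  if (length(sigma) != nrow(curve))
    stop("`sigma` length must match the curve's lag grid")
  if (any(sigma <= 0)) stop("`sigma` must be > 0 elementwise")
  (curve$g2 - 1) / sigma
}

#' Per-lag sample standard deviation across repeated curves
#'
#' Unbiased (n-1) standard deviation of g2 at each lag across a set of
#' repeated measurements on an identical lag grid — the empirical
#' counterpart of [sigma_full()].
#'
#' @param curves List of >= 2 [correlation_curve()] objects sharing one lag
#'   grid.
#' @return Numeric vector of per-lag standard deviations.
#' @export
empirical_sigma <- function(curves) {
  if (length(curves) < 2L) stop("need >= 2 curves")
  tau0 <- curves[[1]]$tau
  for (cv in curves) {
    stopifnot(inherits(cv, "correlation_curve"))
    if (length(cv$tau) != length(tau0) ||
        any(abs(cv$tau - tau0) > 1e-12 * pmax(tau0, 1e-300)))
      stop("all curves must share an identical lag grid")
  }
  g2_mat <- vapply(curves, function(cv) cv$g2, numeric(length(tau0)))
  apply(g2_mat, 1, stats::sd)
}

#' Write a per-lag noise/SNR report as delimited text
#'
#' @param tau Lag times, s.
#' @param sigma_model Model standard deviation per lag.
#' @param sigma_empirical Optional empirical standard deviation per lag.
#' @param snr Optional per-lag SNR.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_noise_report <- function(tau, sigma_model, sigma_empirical = NULL,
                               snr = NULL, path) {
  df <- data.frame(tau_s = tau, sigma_model = sigma_model)
  if (!is.null(sigma_empirical)) df$sigma_empirical <- sigma_empirical
  if (!is.null(snr)) df$snr <- snr
  utils::write.csv(format(df, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
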