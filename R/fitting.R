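# Recovery of the Brownian diffusion coefficient (and BFi) from measured or
# synthetic g2 curves, via bounded Levenberg-Marquardt on the semi-infinite
# forward model.

#' Logarithmic lag grid covering the model decay
#'
#' Convenience grid for generating model curves: logarithmically spaced
#' lags spanning the g2 decay at the given geometry/optics/flow, from well
#' before the decay knee to where the field correlation has essentially
#' vanished.
#'
#' @inheritParams g1_point
#' @param n Number of lags (default 60).
#' @return Numeric vector of lag times, s.
#' @export
default_lag_grid <- function(geometry, props, flow, n = 60) {
  rate <- g1_decay_rate(geometry, props, flow)
  if (!is.finite(rate) || rate <= 0)
    stop("flow model has no decay (DB = 0?); supply an explicit lag grid")
  10^seq(log10(0.01 / rate), log10(10 / rate), length.out = n)
}

#' Fit the semi-infinite model to a measured g2 curve
#'
#' Least-squares recovery of the Brownian diffusion coefficient `DB` (and
#' optionally the coherence factor `beta`) by fitting
#' `g2(tau) = 1 + beta g1(tau; DB)^2` with the point- or disk-source
#' semi-infinite forward model. Bounded Levenberg-Marquardt in `log10(DB)`;
#' DB constrained to `[1e-10, 1e-4]` cm^2/s and beta to (0, 1].
#'
#' @param curve A [correlation_curve()] with >= 10 lags spanning the decay.
#' @param props An [optical_properties()].
#' @param rho Source-detector separation, mm.
#' @param model_kind `"point"` (default) or `"disk"`.
#' @param source_radius Disk radius, mm (disk model only).
#' @param beta `NULL` (default) to fit beta freely, or a fixed numeric value.
#' @param DB_init Initial diffusion coefficient, cm^2/s (default 1e-7).
#' @param weights `"uniform"` (default) or `"sigma"` for 1/sigma^2 weights
#'   from the curve's `sigma` column.
#' @param fit_window `NULL` for the default window — all lags from the first
#'   up to where `g2 - 1` first falls below 5% of its initial amplitude — or
#'   a `c(tau_min, tau_max)` pair in s.
#' @param quadrature_tol Disk-quadrature tolerance (disk model only).
#' @return An object of class `fit_result` with fields `DB_fit` (cm^2/s),
#'   `beta_fit`, `BFi_fit`, `residual_norm`, `model_kind`, `converged`,
#'   `fit_window`, `n_lags_used`, and `message`.
#' @examples
#' props <- optical_properties(0.0025, 1.0)
#' geom <- semi_infinite_geometry(20, props)
#' flow <- flow_model(3e-7)
#' tau <- default_lag_grid(geom, props, flow)
#' curve <- model_g2_curve(geom, props, flow, tau, beta = 0.5)
#' fit_g2(curve, props, rho = 20)
#' @export
fit_g2 <- function(curve, props, rho, model_kind = c("point", "disk"),
                   source_radius = 0, beta = NULL, DB_init = 1e-7,
                   weights = c("uniform", "sigma"), fit_window = NULL,
                   quadrature_tol = 1e-6) {
  stopifnot(inherits(curve, "correlation_curve"),
            inherits(props, "optical_properties"))
  model_kind <- match.arg(model_kind)
  weights <- match.arg(weights)
  if (DB_init <= 0) stop("`DB_init` must be > 0")
  geometry <- semi_infinite_geometry(rho, props)

  amp0 <- curve$g2[1] - 1
  if (is.null(fit_window)) {
    below <- which(curve$g2 - 1 < 0.05 * amp0)
    i_max <- if (length(below)) max(below[1], 10L) else nrow(curve)
    fit_window <- c(curve$tau[1], curve$tau[min(i_max, nrow(curve))])
  }
  keep <- curve$tau >= fit_window[1] & curve$tau <= fit_window[2]
  tau <- curve$tau[keep]
  g2_meas <- curve$g2[keep]
  if (length(tau) < 10L)
    stop("fit window leaves fewer than 10 lags; widen the window")
  w <- if (weights == "sigma") {
    if (!"sigma" %in% names(curve)) stop("curve has no sigma column")
    s <- curve$sigma[keep]
    if (any(s <= 0)) stop("sigma weights require sigma > 0 at all kept lags")
    1 / s
  } else rep(1, length(tau))

  g1_fun <- function(DB) {
    fl <- flow_model(DB)
    if (model_kind == "point") g1_point(geometry, props, fl, tau)
    else g1_disk(geometry, props, fl, tau, source_radius,
                 quadrature_tol = quadrature_tol)
  }

  beta_free <- is.null(beta)
  beta_init <- if (beta_free) min(max(amp0, 1e-3), 1) else beta
  par0 <- if (beta_free) c(l10DB = log10(DB_init), beta = beta_init)
          else c(l10DB = log10(DB_init))
  lower <- if (beta_free) c(-10, 1e-6) else -10
  upper <- if (beta_free) c(-4, 1) else -4

  resid_fun <- function(par) {
    b <- if (beta_free) par[2] else beta
    w * (1 + b * g1_fun(10^par[1])^2 - g2_meas)
  }
  fit <- minpack.lm::nls.lm(
    par = par0, lower = lower, upper = upper, fn = resid_fun,
    control = minpack.lm::nls.lm.control(ftol = 1e-14, ptol = 1e-14,
                                         maxiter = 200))
  converged <- fit$info %in% 1:4
  structure(
    list(DB_fit = 10^fit$par[[1]],
         beta_fit = if (beta_free) fit$par[[2]] else beta,
         BFi_fit = 10^fit$par[[1]],
         residual_norm = sqrt(sum(fit$fvec^2)),
         model_kind = model_kind, converged = converged,
         fit_window = fit_window, n_lags_used = length(tau),
         message = fit$message),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s model%s\n", x$model_kind,
              if (x$converged) "" else "  ** NOT CONVERGED **"))
  cat(sprintf("  DB = %.6g cm^2/s, beta = %.4g\n", x$DB_fit, x$beta_fit))
  cat(sprintf("  residual norm %.3g over %d lags (window %.3g .. %.3g s)\n",
              x$residual_norm, x$n_lags_used, x$fit_window[1],
              x$fit_window[2]))
  if (!x$converged) cat("  optimizer message: ", x$message, "\n")
  invisible(x)
}

#' Blood-flow-index time course from a sequence of g2 curves
#'
#' Fits each windowed curve with [fit_g2()] and normalizes the recovered
#' BFi by the mean over the baseline windows.
#'
#' @param curves Ordered list of [correlation_curve()] objects, one per
#'   acquisition window.
#' @param window_start Start time of each window, s (default `0, 1, 2, ...`
#'   in units of one window).
#' @param baseline_window Integer index range of the baseline windows
#'   (default the first window only).
#' @param ... Passed to [fit_g2()] (at minimum `props` and `rho`).
#' @return An object of class `bfi_time_course`: a data.frame with columns
#'   `window_start`, `BFi`, `beta`, `converged` and `relative_BFi`
#'   (baseline mean = 1 by construction).
#' @export
fit_time_course <- function(curves, window_start = NULL,
                            baseline_window = 1L, ...) {
  if (!length(curves)) stop("no curves supplied")
  if (is.null(window_start)) window_start <- seq_along(curves) - 1
  if (length(window_start) != length(curves))
    stop("`window_start` must match the number of curves")
  if (!length(baseline_window) || any(baseline_window < 1) ||
      any(baseline_window > length(curves)))
    stop("`baseline_window` must be a non-empty index range into `curves`")
  fits <- lapply(curves, fit_g2, ...)
  bfi <- vapply(fits, function(f) f$BFi_fit, numeric(1))
  base_mean <- mean(bfi[baseline_window])
  if (base_mean <= 0) stop("baseline mean BFi is not positive")
  out <- data.frame(window_start = window_start, BFi = bfi,
                    beta = vapply(fits, function(f) f$beta_fit, numeric(1)),
                    converged = vapply(fits, function(f) f$converged,
                                       logical(1)),
                    relative_BFi = bfi / base_mean)
  structure(out, baseline_window = baseline_window,
            class = c("bfi_time_course", "data.frame"))
}

#' Fractional bias of point-model fits to disk-source curves
#'
#' At each source-detector separation: generate a noise-free curve with the
#' disk-source forward model at `DB_true`, fit it with the point-source
#' model, and report the fractional error `(DB_fit - DB_true) / DB_true`.
#' Quantifies the finite-source bias at short separations, which vanishes
#' as the separation grows relative to the source radius.
#'
#' @param rho_grid Source-detector separations, mm.
#' @param source_radius Disk source radius, mm.
#' @param props An [optical_properties()].
#' @param DB_true Generating diffusion coefficient, cm^2/s, > 0.
#' @param beta Coherence factor of the generated curves (default 0.5).
#' @param quadrature_tol Disk-quadrature tolerance.
#' @return A data.frame with columns `rho`, `DB_fit`, `bias` (fractional)
#'   and `converged`.
#' @export
disk_point_bias <- function(rho_grid, source_radius, props, DB_true,
                            beta = 0.5, quadrature_tol = 1e-6) {
  if (DB_true <= 0) stop("`DB_true` must be > 0")
  flow <- flow_model(DB_true)
  rows <- lapply(rho_grid, function(rho) {
    geom <- semi_infinite_geometry(rho, props)
    tau <- default_lag_grid(geom, props, flow)
    curve <- model_g2_curve(geom, props, flow, tau, beta = beta,
                            model_kind = "disk",
                            source_radius = source_radius,
                            quadrature_tol = quadrature_tol)
    fit <- fit_g2(curve, props, rho = rho, model_kind = "point",
                  DB_init = DB_true)
    data.frame(rho = rho, DB_fit = fit$DB_fit,
               bias = (fit$DB_fit - DB_true) / DB_true,
               converged = fit$converged)
  })
  do.call(rbind, rows)
}
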