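# Semi-infinite correlation diffusion equation forward models.
#
# Internal length unit is mm throughout; DB is accepted in cm^2/s and
# converted (x100) to mm^2/s before entering the decay wavenumber
# K^2(tau) = 3 mu_a mu_s' + mu_s'^2 k0^2 alpha <dr^2(tau)>,  <dr^2> = 6 DB tau.

# decay wavenumber K(tau) in mm^-1; tau in s
.cde_K <- function(tau, props, flow) {
  db_mm2_s <- flow$DB * 100  # cm^2/s -> mm^2/s
  msd <- 6 * db_mm2_s * tau  # mm^2
  sqrt(3 * props$mu_a * props$mu_s_prime +
         props$mu_s_prime^2 * props$k0^2 * flow$alpha * msd)
}

# unnormalized G1 for given real/image distances (prefactor dropped; it
# cancels under the tau = 0 normalization)
.g1_unnorm <- function(K, r1, r2) {
  exp(-K * r1) / r1 - exp(-K * r2) / r2
}

#' Normalized field autocorrelation for a point source
#'
#' Green's-function solution of the correlation diffusion equation for a
#' semi-infinite homogeneous medium in reflection geometry,
#' `G1 propto exp(-K r1)/r1 - exp(-K r2)/r2`, normalized by its `tau = 0`
#' value so that `g1(0) = 1`.
#'
#' @param geometry A [semi_infinite_geometry()].
#' @param props An [optical_properties()].
#' @param flow A [flow_model()].
#' @param tau Lag times, s, all >= 0.
#' @return Numeric vector `g1(tau)`, non-increasing, with `g1(0) = 1`.
#' @examples
#' props <- optical_properties(0.0025, 1.0)
#' geom <- semi_infinite_geometry(20, props)
#' g1_point(geom, props, flow_model(2.8e-7), tau = 10^seq(-7, -3, 0.5))
#' @export
g1_point <- function(geometry, props, flow, tau) {
  stopifnot(inherits(geometry, "semi_infinite_geometry"),
            inherits(props, "optical_properties"),
            inherits(flow, "flow_model"))
  if (any(tau < 0)) stop("lag times must be >= 0")
  K <- .cde_K(tau, props, flow)
  K0 <- .cde_K(0, props, flow)
  g <- .g1_unnorm(K, geometry$r1, geometry$r2)
  g0 <- .g1_unnorm(K0, geometry$r1, geometry$r2)
  as.numeric(g / g0)
}

#' Intensity autocorrelation from the field autocorrelation
#'
#' Siegert relation `g2 = 1 + beta |g1|^2` for a source with long coherence
#' length and `beta` set by the number of detected speckle modes.
#'
#' @param g1 Field autocorrelation values, `|g1| <= 1`.
#' @param beta Coherence factor in (0, 1].
#' @param tau Optional lag grid; when supplied a [correlation_curve()] is
#'   returned, otherwise a bare numeric vector.
#' @return `1 + beta * g1^2`, as vector or curve.
#' @examples
#' g2_from_g1(c(1, 0.5, 0), beta = 0.5)
#' @export
g2_from_g1 <- function(g1, beta, tau = NULL) {
  if (beta <= 0 || beta > 1) stop("`beta` must lie in (0, 1]")
  if (any(abs(g1) > 1 + 1e-9)) stop("|g1| must be <= 1")
  g2 <- 1 + beta * abs(g1)^2
  if (is.null(tau)) g2 else correlation_curve(tau, g2, beta = beta)
}

#' Model g2 curve for point or disk illumination
#'
#' Convenience wrapper evaluating the semi-infinite forward model on a lag
#' grid and applying the Siegert relation.
#'
#' @inheritParams g1_point
#' @param beta Coherence factor in (0, 1].
#' @param model_kind `"point"` or `"disk"`.
#' @param source_radius Disk source radius, mm (disk model only).
#' @param quadrature_tol Relative tolerance for the disk quadrature.
#' @return A [correlation_curve()].
#' @export
model_g2_curve <- function(geometry, props, flow, tau, beta,
                           model_kind = c("point", "disk"),
                           source_radius = 0, quadrature_tol = 1e-6) {
  model_kind <- match.arg(model_kind)
  g1 <- if (model_kind == "point") {
    g1_point(geometry, props, flow, tau)
  } else {
    g1_disk(geometry, props, flow, tau, source_radius,
            quadrature_tol = quadrature_tol)
  }
  g2_from_g1(g1, beta, tau = tau)
}

#' Normalized field autocorrelation for a finite disk source
#'
#' The correlation diffusion equation is linear in the source term, so the
#' extended-source solution is the area average of the point-source solution
#' over the illumination disk:
#' `G1_disk(rho, tau) = (1/(pi a^2)) \int_{|rs|<=a} G1_point(|rho - rs|, tau) d^2 rs`,
#' normalized by its own `tau = 0` value. Evaluated with Gauss-Legendre
#' quadrature in radius crossed with a uniform (trapezoid-exact, periodic)
#' grid in angle, refined until successive doublings agree to
#' `quadrature_tol` relative.
#'
#' @inheritParams g1_point
#' @param source_radius Disk radius `a`, mm, >= 0. A zero/tiny radius
#'   reduces to the point-source model.
#' @param quadrature_tol Relative self-convergence tolerance (default 1e-6).
#' @param max_refinements Number of grid doublings attempted before failing.
#' @return Numeric vector `g1(tau)` with `g1(0) = 1`.
#' @examples
#' props <- optical_properties(0.0025, 1.0)
#' geom <- semi_infinite_geometry(10, props)
#' g1_disk(geom, props, flow_model(2.87e-7), tau = c(1e-6, 1e-5), 2.5)
#' @export
g1_disk <- function(geometry, props, flow, tau, source_radius,
                    quadrature_tol = 1e-6, max_refinements = 8) {
  stopifnot(inherits(geometry, "semi_infinite_geometry"),
            inherits(props, "optical_properties"),
            inherits(flow, "flow_model"))
  if (source_radius < 0) stop("`source_radius` must be >= 0")
  if (any(tau < 0)) stop("lag times must be >= 0")
  a <- source_radius
  if (a < 1e-9) return(g1_point(geometry, props, flow, tau))

  K <- .cde_K(tau, props, flow)
  K0 <- .cde_K(0, props, flow)
  rho <- geometry$rho; z0 <- geometry$z0; zpl <- geometry$z0 + 2 * geometry$zb

  eval_on_grid <- function(n_r, n_th) {
    gl <- pracma::gaussLegendre(n_r, 0, a)
    th <- (seq_len(n_th) - 0.5) * (2 * pi / n_th)
    # lateral distance detector -> each source point (n_r x n_th)
    d2 <- outer(gl$x^2, rep(1, n_th)) + rho^2 -
      2 * rho * outer(gl$x, cos(th))
    r1 <- sqrt(d2 + z0^2)
    r2 <- sqrt(d2 + zpl^2)
    w <- outer(gl$w * gl$x, rep(2 * pi / n_th, n_th))  # area weights
    flat_r1 <- as.numeric(r1); flat_r2 <- as.numeric(r2)
    flat_w <- as.numeric(w)
    integ <- function(k) {
      sum(flat_w * (exp(-k * flat_r1) / flat_r1 - exp(-k * flat_r2) / flat_r2))
    }
    vapply(K, integ, numeric(1)) / integ(K0)
  }

  n_r <- 16L; n_th <- 32L
  g_prev <- eval_on_grid(n_r, n_th)
  for (i in seq_len(max_refinements)) {
    n_r <- n_r * 2L; n_th <- n_th * 2L
    g_new <- eval_on_grid(n_r, n_th)
    rel <- max(abs(g_new - g_prev) / pmax(abs(g_new), 1e-12))
    if (rel < quadrature_tol) return(g_new)
    g_prev <- g_new
  }
  stop(sprintf(paste0("disk-source quadrature did not converge to %.1e ",
                      "relative after %d refinements (last change %.1e, ",
                      "grid %d x %d)"),
               quadrature_tol, max_refinements, rel, n_r, n_th))
}

#' Initial decay rate of the model field autocorrelation
#'
#' Analytic `-d log g1 / d tau` at `tau = 0` for the point-source
#' semi-infinite model. Useful to map a single-exponential speckle decay
#' rate onto an equivalent Brownian diffusion coefficient at a given
#' geometry (and vice versa).
#'
#' @inheritParams g1_point
#' @return Decay rate, s^-1.
#' @export
g1_decay_rate <- function(geometry, props, flow) {
  K0 <- .cde_K(0, props, flow)
  db_mm2_s <- flow$DB * 100
  dK <- props$mu_s_prime^2 * props$k0^2 * flow$alpha * 6 * db_mm2_s / (2 * K0)
  A1 <- exp(-K0 * geometry$r1) / geometry$r1
  A2 <- exp(-K0 * geometry$r2) / geometry$r2
  dK * (geometry$r1 * A1 - geometry$r2 * A2) / (A1 - A2)
}
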