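#' Optical properties of a homogeneous turbid medium
#'
#' Bundles the absorption coefficient, reduced scattering coefficient,
#' refractive indices and wavelength that fix the wavenumber and boundary
#' terms of the correlation diffusion equation.
#'
#' @param mu_a Absorption coefficient, mm^-1.
#' @param mu_s_prime Reduced scattering coefficient, mm^-1.
#' @param n0 Refractive index of the medium (default 1.33, aqueous).
#' @param n_air Refractive index of the exterior (default 1.0).
#' @param wavelength Vacuum wavelength, nm (default 785).
#'
#' @return An object of class `optical_properties` with fields `mu_a`,
#'   `mu_s_prime`, `n0`, `n_air`, `wavelength`, and the derived in-medium
#'   wavenumber `k0` (mm^-1).
#' @examples
#' optical_properties(mu_a = 0.0025, mu_s_prime = 1.0)
#' @export
optical_properties <- function(mu_a, mu_s_prime, n0 = 1.33, n_air = 1.0,
                               wavelength = 785) {
  stopifnot(is.numeric(mu_a), length(mu_a) == 1L,
            is.numeric(mu_s_prime), length(mu_s_prime) == 1L)
  if (mu_a <= 0) stop("`mu_a` must be > 0 (mm^-1)")
  if (mu_s_prime <= 0) stop("`mu_s_prime` must be > 0 (mm^-1)")
  if (n0 < 1) stop("`n0` must be >= 1")
  if (n_air < 1) stop("`n_air` must be >= 1")
  if (wavelength <= 0) stop("`wavelength` must be > 0 (nm)")
  lambda_mm <- wavelength * 1e-6
  structure(
    list(mu_a = mu_a, mu_s_prime = mu_s_prime, n0 = n0, n_air = n_air,
         wavelength = wavelength, k0 = 2 * pi * n0 / lambda_mm),
    class = "optical_properties"
  )
}

#' @export
print.optical_properties <- function(x, ...) {
  cat("<optical_properties>\n")
  cat(sprintf("  mu_a       : %.4g mm^-1\n", x$mu_a))
  cat(sprintf("  mu_s'      : %.4g mm^-1\n", x$mu_s_prime))
  cat(sprintf("  n0 / n_air : %.3f / %.3f\n", x$n0, x$n_air))
  cat(sprintf("  wavelength : %g nm  (k0 = %.1f mm^-1)\n", x$wavelength, x$k0))
  invisible(x)
}

#' Effective reflection coefficient of the extrapolated boundary
#'
#' Polynomial approximation of the effective reflection coefficient for the
#' refractive-index mismatch at a diffusive-medium boundary,
#' `Reff = -1.44 n^-2 + 0.71 n^-1 + 0.668 + 0.064 n`, with
#' `n = n0 / n_air`.
#'
#' @param n Refractive-index ratio medium/exterior, dimensionless, > 0.
#' @return The effective reflection coefficient (dimensionless). Callers
#'   should check `0 <= Reff < 1` before using it in the extrapolated
#'   boundary distance.
#' @examples
#' effective_reflection_coefficient(1.33 / 1.0)
#' @export
effective_reflection_coefficient <- function(n) {
  if (any(!is.finite(n)) || any(n <= 0)) stop("`n` must be finite and > 0")
  -1.44 / n^2 + 0.71 / n + 0.668 + 0.064 * n
}

#' Semi-infinite measurement geometry
#'
#' Derives the source depth, extrapolated-boundary distance and real/image
#' source distances used by the semi-infinite Green's function of the
#' correlation diffusion equation.
#'
#' @param rho Source-detector separation on the surface, mm, > 0.
#' @param props An [optical_properties()] object.
#'
#' @return An object of class `semi_infinite_geometry` with fields `rho`,
#'   `z0` (= 1/(mu_a + mu_s')), `zb`, `Reff`, `r1`, `r2` (all mm except the
#'   dimensionless `Reff`).
#' @examples
#' semi_infinite_geometry(20, optical_properties(0.0025, 1.0))
#' @export
semi_infinite_geometry <- function(rho, props) {
  stopifnot(inherits(props, "optical_properties"))
  if (!is.numeric(rho) || length(rho) != 1L || rho <= 0)
    stop("`rho` must be a single positive separation in mm")
  Reff <- effective_reflection_coefficient(props$n0 / props$n_air)
  if (Reff < 0 || Reff >= 1)
    stop(sprintf("effective reflection coefficient %.3f outside [0, 1)", Reff))
  z0 <- 1 / (props$mu_a + props$mu_s_prime)
  zb <- 2 * (1 + Reff) / (3 * props$mu_s_prime * (1 - Reff))
  r1 <- sqrt(rho^2 + z0^2)
  r2 <- sqrt(rho^2 + (z0 + 2 * zb)^2)
  if (r1 <= 0 || r2 <= 0) stop("degenerate geometry: r1 and r2 must be > 0")
  structure(
    list(rho = rho, z0 = z0, zb = zb, Reff = Reff, r1 = r1, r2 = r2),
    class = "semi_infinite_geometry"
  )
}

#' @export
print.semi_infinite_geometry <- function(x, ...) {
  cat("<semi_infinite_geometry>\n")
  cat(sprintf("  rho = %g mm;  z0 = %.3f mm;  zb = %.3f mm (Reff = %.3f)\n",
              x$rho, x$z0, x$zb, x$Reff))
  cat(sprintf("  r1 = %.3f mm;  r2 = %.3f mm\n", x$r1, x$r2))
  invisible(x)
}

#' Brownian flow model
#'
#' Scatterer dynamics model with mean-square displacement
#' `<dr^2(tau)> = 6 DB tau`. The product `alpha * DB` is the blood flow
#' index (BFi).
#'
#' @param DB Brownian diffusion coefficient of the scatterers, cm^2/s, >= 0.
#' @param alpha Fraction of moving scatterers, in \[0, 1\] (default 1, the
#'   usual assumption for homogeneous phantoms).
#'
#' @return An object of class `flow_model` with fields `DB`, `alpha` and the
#'   derived `BFi = alpha * DB` (cm^2/s).
#' @examples
#' flow_model(DB = 2.87e-7)
#' @export
flow_model <- function(DB, alpha = 1) {
  if (!is.numeric(DB) || length(DB) != 1L || DB < 0)
    stop("`DB` must be a single value >= 0 (cm^2/s)")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1)
    stop("`alpha` must lie in [0, 1]")
  structure(list(DB = DB, alpha = alpha, BFi = alpha * DB),
            class = "flow_model")
}

#' @export
print.flow_model <- function(x, ...) {
  cat(sprintf("<flow_model> DB = %.4g cm^2/s, alpha = %g, BFi = %.4g cm^2/s\n",
              x$DB, x$alpha, x$BFi))
  invisible(x)
}

#' Brownian diffusion coefficient from the Einstein-Stokes relation
#'
#' `DB = kB T / (6 pi eta r)`, converted from m^2/s to the cm^2/s
#' convention used for flow indices.
#'
#' @param temperature Absolute temperature, K.
#' @param viscosity Dynamic viscosity of the suspending medium, Pa s.
#' @param particle_radius Effective hydrodynamic particle radius, m.
#' @return Diffusion coefficient in cm^2/s.
#' @examples
#' einstein_stokes_db(293.15, 1.002e-3, 50e-9)
#' @export
einstein_stokes_db <- function(temperature, viscosity, particle_radius) {
  if (any(temperature <= 0) || any(viscosity <= 0) || any(particle_radius <= 0))
    stop("temperature, viscosity and particle_radius must all be > 0")
  kB <- 1.380649e-23  # J/K
  d_m2_s <- kB * temperature / (6 * pi * viscosity * particle_radius)
  d_m2_s * 1e4
}
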