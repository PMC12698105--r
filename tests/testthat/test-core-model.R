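# Semi-infinite forward models: boundary polynomial, Green's function,
# Siegert relation, disk-source quadrature, Einstein-Stokes.

test_that("effective reflection coefficient matches hand-evaluated polynomial", {
  expect_equal(effective_reflection_coefficient(1.0), 0.002)
  expect_equal(effective_reflection_coefficient(1.33), 0.4729, tolerance = 1e-4)
  expect_equal(effective_reflection_coefficient(1.4), 0.5300, tolerance = 1e-4)
  expect_error(effective_reflection_coefficient(0), "> 0")
  expect_error(effective_reflection_coefficient(-1.3), "> 0")
})

test_that("geometry derives z0, zb, r1, r2 consistently", {
  props <- phantom_props()
  geom <- semi_infinite_geometry(20, props)
  expect_equal(geom$z0, 1 / (0.0025 + 1.0))
  Reff <- effective_reflection_coefficient(1.33)
  expect_equal(geom$zb, 2 * (1 + Reff) / (3 * 1.0 * (1 - Reff)))
  expect_equal(geom$r1, sqrt(20^2 + geom$z0^2))
  expect_equal(geom$r2, sqrt(20^2 + (geom$z0 + 2 * geom$zb)^2))
  expect_gt(geom$r2, geom$r1)
  expect_error(semi_infinite_geometry(0, props), "positive")
})

test_that("point-source g1 matches an independent closed-form evaluation", {
  props <- phantom_props()
  geom <- semi_infinite_geometry(20, props)
  flow <- flow_model(2.8e-7)
  # frozen values from an independent numpy transcription of the
  # semi-infinite Green's function at tau = 1, 10, 100 us
  g1 <- g1_point(geom, props, flow, c(1e-6, 1e-5, 1e-4))
  expect_equal(g1, c(0.33218157263540166, 0.0025433076384523646,
                     4.119074396837976e-11), tolerance = 1e-12)
  expect_true(all(diff(g1) < 0))
})

test_that("g1 limits: zero flow is flat, tau = 0 is unity", {
  props <- phantom_props()
  geom <- semi_infinite_geometry(20, props)
  tau <- c(0, 1e-6, 1e-4, 1e-2)
  expect_equal(g1_point(geom, props, flow_model(0), tau), rep(1, 4))
  expect_equal(g1_point(geom, props, flow_model(3e-7), 0), 1)
})

test_that("Siegert relation and model-curve normalization invariants hold", {
  expect_equal(g2_from_g1(1, 0.5), 1.5)
  expect_equal(g2_from_g1(0, 0.7), 1.0)
  expect_equal(g2_from_g1(0.5, 0.5), 1.125)
  expect_error(g2_from_g1(0.5, 0), "beta")
  expect_error(g2_from_g1(0.5, 1.2), "beta")

  props <- phantom_props()
  for (rho in c(10, 15, 20)) {
    geom <- semi_infinite_geometry(rho, props)
    flow <- flow_model(2.8e-7)
    tau <- c(0, 10^seq(-7, -2, 0.5))
    g2 <- g2_from_g1(g1_point(geom, props, flow, tau), beta = 0.5)
    expect_true(all(g2 >= 1 - 1e-12 & g2 <= 1.5 + 1e-12))
    expect_equal(g2[1], 1.5)
  }
})

test_that("g1 decreases with lag, flow, and separation", {
  props <- phantom_props()
  tau <- 10^seq(-7, -3, 0.25)
  geom <- semi_infinite_geometry(15, props)
  g_lo <- g1_point(geom, props, flow_model(1e-7), tau)
  g_hi <- g1_point(geom, props, flow_model(5e-7), tau)
  expect_true(all(diff(g_lo) < 0))
  expect_true(all(g_hi < g_lo))  # more flow, faster decay
  # separation decay at fixed tau and DB over rho in [10, 20] mm
  g_rho <- vapply(seq(10, 20, 2), function(rho)
    g1_point(semi_infinite_geometry(rho, props), props,
             flow_model(2.8e-7), 1e-5), numeric(1))
  expect_true(all(diff(g_rho) < 0))
})

test_that("disk source reduces to the point source as the radius vanishes", {
  props <- phantom_props()
  geom <- semi_infinite_geometry(10, props)
  flow <- flow_model(2.87e-7)
  tau <- 10^seq(-7, -4, 0.5)
  gp <- g1_point(geom, props, flow, tau)
  gd <- g1_disk(geom, props, flow, tau, source_radius = 1e-6)
  expect_equal(gd, gp, tolerance = 1e-6)
})

test_that("disk-source decay dominates the point-source decay", {
  props <- phantom_props()
  geom <- semi_infinite_geometry(10, props)
  flow <- flow_model(2.87e-7)
  tau <- 10^seq(-7, -4, 0.25)
  gp <- g1_point(geom, props, flow, tau)
  gd <- g1_disk(geom, props, flow, tau, source_radius = 2.5)
  expect_true(all(gd >= gp))
})

test_that("disk quadrature agrees with a 400x400 Riemann sum", {
  props <- phantom_props()
  geom <- semi_infinite_geometry(10, props)
  flow <- flow_model(2.87e-7)
  a <- 2.5
  xs <- seq(-a, a, length.out = 400)
  grid <- expand.grid(x = xs, y = xs)
  grid <- grid[grid$x^2 + grid$y^2 <= a^2, ]
  db_mm <- 2.87e-7 * 100
  Kfun <- function(tau) sqrt(3 * props$mu_a * props$mu_s_prime +
                               props$mu_s_prime^2 * props$k0^2 * 6 * db_mm * tau)
  zpl <- geom$z0 + 2 * geom$zb
  sum_g1 <- function(tau) {
    d2 <- (geom$rho - grid$x)^2 + grid$y^2
    r1 <- sqrt(d2 + geom$z0^2); r2 <- sqrt(d2 + zpl^2)
    K <- Kfun(tau)
    sum(exp(-K * r1) / r1 - exp(-K * r2) / r2)
  }
  oracle <- sum_g1(1e-5) / sum_g1(0)
  quad <- g1_disk(geom, props, flow, 1e-5, a)
  expect_equal(quad, oracle, tolerance = 1e-4)
})

test_that("disk quadrature is self-converged at its stated tolerance", {
  props <- phantom_props()
  geom <- semi_infinite_geometry(10, props)
  flow <- flow_model(2.87e-7)
  tau <- c(1e-6, 1e-5)
  loose <- g1_disk(geom, props, flow, tau, 2.5, quadrature_tol = 1e-4)
  tight <- g1_disk(geom, props, flow, tau, 2.5, quadrature_tol = 1e-8)
  expect_equal(loose, tight, tolerance = 1e-4)
})

test_that("Einstein-Stokes diffusion has the right value and scalings", {
  expect_equal(einstein_stokes_db(293.15, 1.002e-3, 50e-9), 4.29e-8,
               tolerance = 1e-3)
  # linear in T at fixed viscosity and radius
  expect_equal(einstein_stokes_db(308.15, 1e-3, 50e-9) /
                 einstein_stokes_db(298.15, 1e-3, 50e-9),
               308.15 / 298.15)
  # vanishes as viscosity grows
  expect_lt(einstein_stokes_db(293.15, 1e3, 50e-9), 1e-13)
  expect_error(einstein_stokes_db(-1, 1e-3, 5e-8), "> 0")
  expect_error(einstein_stokes_db(293, 0, 5e-8), "> 0")
})

test_that("model curves round-trip through delimited text losslessly", {
  props <- phantom_props()
  geom <- semi_infinite_geometry(20, props)
  flow <- flow_model(3e-7)
  tau <- default_lag_grid(geom, props, flow, n = 25)
  cv <- model_g2_curve(geom, props, flow, tau, beta = 0.5)
  cv$sigma <- rep(0.01, nrow(cv))
  path <- withr::local_tempfile(fileext = ".csv")
  write_correlation_curve(correlation_curve(cv$tau, cv$g2, 0.5, cv$sigma),
                          path)
  back <- read_correlation_curve(path, beta = 0.5)
  expect_equal(back$tau, cv$tau)
  expect_equal(back$g2, cv$g2)
  expect_equal(back$sigma, cv$sigma)
})
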