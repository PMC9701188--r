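test_that("unbioturbated single-fraction columns reduce to the advective exponential", {
  env <- sediment_environment(omega = 0.1, phi = 0.7, oc0 = 0.01)
  prof <- solve_column(env, single_fraction_spectrum(0.001))
  expect_equal(oc_at_depth(prof, 100), 0.01 * exp(-1), tolerance = 1e-12)
  expect_equal(oc_at_depth(prof, 0), 0.01, tolerance = 1e-14)
  # flux is purely advective and degradation has the matching closed form
  z <- c(0, 50, 100, 500)
  expect_equal(flux_at_depth(prof, z),
               (1 - 0.7) * 0.1 * 0.01 * exp(-0.001 * z / 0.1),
               tolerance = 1e-12)
  expect_equal(degradation_rate(prof, z),
               0.001 * 0.01 * exp(-0.001 * z / 0.1), tolerance = 1e-12)
})

test_that("inert OC is buried unchanged", {
  for (env in list(sediment_environment(omega = 0.1, phi = 0.7, oc0 = 0.01),
                   shelf_env())) {
    prof <- solve_column(env, single_fraction_spectrum(0))
    z <- c(0, 5, 10, 100, 1000)
    expect_equal(oc_at_depth(prof, z), rep(0.01, 5), tolerance = 1e-12)
    expect_equal(degradation_rate(prof, z), rep(0, 5))
  }
})

test_that("concentration and flux are continuous across the bioturbation depth", {
  for (make in list(shelf_env, margin_env, abyss_env)) {
    env <- make()
    zone <- env$zone
    prof <- solve_column(env, discretize_rcm(zone_rcm(zone)))
    zb <- env$z_bio
    eps <- zb * 1e-12
    oc_above <- oc_at_depth(prof, zb - eps)
    oc_below <- oc_at_depth(prof, zb + eps)
    expect_lt(abs(oc_above - oc_below) / oc_above, 1e-9)
    f_above <- flux_at_depth(prof, zb - eps)
    f_below <- flux_at_depth(prof, zb + eps)
    expect_lt(abs(f_above - f_below) / f_above, 1e-9)
    # at the surface the fractions sum back to the boundary condition
    expect_equal(oc_at_depth(prof, 0), env$oc0, tolerance = 1e-10)
  }
})

test_that("analytical solution matches the finite-difference oracle over an omega x Db design", {
  sp <- discretize_rcm(rcm_params(a = 0.1, nu = 0.125))
  z <- c(1, 10, 50, 100, 1000)
  for (omega in c(0.001, 0.01, 0.1)) {
    for (db in c(0, 1, 10)) {
      env <- sediment_environment(omega = omega, phi = 0.7, oc0 = 0.01,
                                  db = db, z_bio = 10)
      prof <- solve_column(env, sp)
      fd <- fd_column_solution(env, sp, z)
      an <- oc_at_depth(prof, fd$depth)
      keep <- an > 1e-12 * env$oc0
      expect_true(all(abs(fd$oc[keep] - an[keep]) / an[keep] < 0.01),
                  label = sprintf("omega=%g Db=%g", omega, db))
      # SWI flux cross-check
      expect_equal(attr(fd, "f_swi"), flux_at_depth(prof, 0),
                   tolerance = 0.01)
    }
  }
})

test_that("multi-G bulk OC follows the reactive-continuum power law when unbioturbated", {
  zones <- list(c(a = 0.1, omega = 0.1), c(a = 1, omega = 0.01),
                c(a = 20, omega = 0.001))
  z <- c(0, 10^seq(0, 3, length.out = 20))
  for (zn in zones) {
    env <- sediment_environment(omega = zn[["omega"]], phi = 0.7, oc0 = 1)
    sp <- discretize_rcm(rcm_params(a = zn[["a"]], nu = 0.125))
    ratio <- oc_at_depth(solve_column(env, sp), z)  # oc0 = 1
    closed <- (zn[["a"]] / (zn[["a"]] + z / zn[["omega"]]))^0.125
    expect_true(all(abs(ratio - closed) < 0.02),
                label = sprintf("a=%g", zn[["a"]]))
  }
})

test_that("degradation integrates to the flux divergence (mass balance)", {
  for (make in list(shelf_env, margin_env, abyss_env)) {
    env <- make()
    prof <- solve_column(env, discretize_rcm(zone_rcm(env$zone)))
    f_swi <- flux_at_depth(prof, 0)
    for (z in c(10, 100, 1000)) {
      lost <- f_swi - flux_at_depth(prof, z)
      # adaptive-quadrature oracle, split at the bioturbation depth
      quad <- stats::integrate(function(s) (1 - env$phi) *
                                 degradation_rate(prof, s),
                               0, min(z, env$z_bio), rel.tol = 1e-9,
                               subdivisions = 500L)$value
      if (z > env$z_bio) {
        quad <- quad + stats::integrate(function(s) (1 - env$phi) *
                                          degradation_rate(prof, s),
                                        env$z_bio, z, rel.tol = 1e-9,
                                        subdivisions = 500L)$value
      }
      expect_equal(lost, quad, tolerance = 1e-4)
      # the closed-form integral is exact
      expect_equal(integrated_degradation(prof, z), lost,
                   tolerance = 1e-10)
    }
  }
})

test_that("OC and flux decrease monotonically wherever degradation is active", {
  z <- c(0, 10^seq(-1, 3, length.out = 40))
  for (make in list(shelf_env, abyss_env)) {
    env <- make()
    prof <- solve_column(env, discretize_rcm(zone_rcm(env$zone)))
    expect_true(all(diff(oc_at_depth(prof, z)) < 0))
    expect_true(all(diff(flux_at_depth(prof, z)) < 0))
  }
})

test_that("the finite-difference oracle converges at second order", {
  env <- sediment_environment(omega = 0.1, phi = 0.7, oc0 = 0.01,
                              db = 10, z_bio = 10)
  sp <- single_fraction_spectrum(1)
  exact <- oc_at_depth(solve_column(env, sp), 5)
  err <- function(n) abs(fd_column_solution(env, sp, 5, n_bio = n)$oc[2] - exact)
  ratio <- err(40) / err(80)
  expect_gt(ratio, 3)
  expect_lt(ratio, 5.5)
})

test_that("domain errors are raised for unphysical inputs", {
  expect_error(sediment_environment(omega = 0, phi = 0.7, oc0 = 0.01))
  expect_error(sediment_environment(omega = 0.1, phi = 1.2, oc0 = 0.01))
  expect_error(sediment_environment(omega = 0.1, phi = 0.7, oc0 = -1))
  prof <- solve_column(shelf_env(), single_fraction_spectrum(0.001))
  expect_error(oc_at_depth(prof, -1), "z")
  expect_error(flux_at_depth(prof, -1), "z")
  expect_error(degradation_rate(prof, -1), "z")
})

test_that("stiff reactive fractions do not overflow the bioturbated solution", {
  # b1 * z_bio ~ 6e3: a naive formulation of the integration constants
  # would overflow; the factored form must stay finite and monotone
  env <- sediment_environment(omega = 0.1, phi = 0.7, oc0 = 0.01,
                              db = 0.1, z_bio = 10)
  prof <- solve_column(env, discretize_rcm(rcm_params(a = 0.1, nu = 0.125)))
  oc <- oc_at_depth(prof, c(0, 1, 5, 10, 20))
  expect_true(all(is.finite(oc)))
  expect_true(all(diff(oc) < 0))
  expect_equal(oc[1], 0.01, tolerance = 1e-10)
})
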