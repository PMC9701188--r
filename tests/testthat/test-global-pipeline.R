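# small uniform grid used by several tests
uniform_grid <- function(n_lat = 4, n_lon = 6, depth = 1000, oc0 = 1,
                         phi = 0.7, o2 = 200) {
  dlat <- 180 / n_lat; dlon <- 360 / n_lon
  global_grid(lat = seq(-90 + dlat / 2, 90 - dlat / 2, by = dlat),
              lon = seq(-180 + dlon / 2, 180 - dlon / 2, by = dlon),
              water_depth = matrix(depth, n_lat, n_lon),
              oc0 = matrix(oc0, n_lat, n_lon),
              phi = matrix(phi, n_lat, n_lon),
              o2 = matrix(o2, n_lat, n_lon))
}

test_that("sedimentation rate declines over three orders of magnitude with depth", {
  d <- seq(0, 6000, by = 50)
  w <- sedimentation_rate(d)
  expect_true(all(diff(w) < 0))
  expect_true(all(w > 0))
  p <- pipeline_config()$omega_params
  expect_equal(sedimentation_rate(0), p$omega1 + p$omega2)
  expect_gt(sedimentation_rate(100) / sedimentation_rate(6000), 100)
  expect_gt(sedimentation_rate(0) / sedimentation_rate(6000), 1000)
  expect_error(sedimentation_rate(-5))
  expect_error(sedimentation_rate(100, list(omega1 = 0, d1 = 200, c1 = 3,
                                            omega2 = 0, d2 = 4000, c2 = 10)))
})

test_that("bioturbation declines exponentially with water depth", {
  expect_equal(bioturbation_coefficient(1000, list(db0 = 2, beta = 0)), 2)
  d <- seq(0, 6000, by = 100)
  db <- bioturbation_coefficient(d)
  expect_true(all(diff(db) < 0))
  # defaults: ~10x reduction from the surf zone to ~2500 m
  expect_equal(bioturbation_coefficient(0) / bioturbation_coefficient(2517),
               10, tolerance = 0.02)
})

test_that("water depth classifies cells into depositional zones", {
  expect_identical(classify_zone(c(50, 200, 1000, 3500, 5000)),
                   c("shelf", "shelf", "margin", "margin", "abyss"))
  expect_error(classify_zone(100, thresholds = c(3500, 200)))
})

test_that("the hypoxia rule fires strictly below 60 uM and enhances preservation", {
  rcm <- rcm_params(a = 0.1, nu = 0.125)
  normo <- apply_hypoxia(shelf_env(o2 = 60), rcm)
  expect_equal(normo$rcm$a, 0.1)
  expect_equal(normo$env$z_bio, 10)
  hypo <- apply_hypoxia(shelf_env(o2 = 30), rcm)
  expect_equal(hypo$rcm$a, 1.0)
  expect_equal(hypo$env$z_bio, 1)
  # twin columns: preservation at 1 mbsf is enhanced under hypoxia
  t_n <- teff_depth(solve_column(normo$env, discretize_rcm(normo$rcm)), 100)
  t_h <- teff_depth(solve_column(hypo$env, discretize_rcm(hypo$rcm)), 100)
  expect_gt(t_h$teff, t_n$teff)
})

test_that("identical cells give identical gridded outputs", {
  res <- run_grid(uniform_grid())
  for (f in list(res$f_swi, res$teff_depth[, , 1], res$teff_age[, , 1],
                 res$flux_depth[, , 2])) {
    expect_lt(diff(range(f)), 1e-12 * max(abs(f)))
  }
  expect_equal(res$n_invalid, 0)
})

test_that("invalid cells are flagged and skipped without aborting the run", {
  g <- uniform_grid()
  g$oc0[2, 3] <- -1
  res <- run_grid(g)
  expect_equal(res$n_invalid, 1)
  expect_true(is.na(res$f_swi[2, 3]))
  expect_true(all(is.finite(res$f_swi[-(2 + 4 * 2)])))
})

test_that("synthetic grids reproduce the zonal contrasts", {
  res <- run_grid(generate_grid(synthetic_grid_spec(seed = 11)))
  j1m <- match(100, res$config$depth_horizons)
  zm <- zone_mean(res, res$teff_depth[, , j1m])
  # transfer efficiency to 1 mbsf is highest in abyssal sediments...
  expect_gt(zm[["abyss"]], zm[["shelf"]])
  # ...while absolute burial is dominated by the shelves
  b <- integrate_burial(res, 11)
  expect_gt(b$burial[b$zone == "shelf"], b$burial[b$zone == "abyss"])
  # sediment age at 10 mbsf spans >= 3 orders of magnitude
  j10m <- match(1000, res$config$age_at_depths)
  ages <- res$age_at_depth[, , j10m]
  expect_gte(log10(max(ages, na.rm = TRUE) / min(ages, na.rm = TRUE)), 3)
})

test_that("burial budgets do the unit arithmetic and partition exactly", {
  g <- uniform_grid(n_lat = 2, n_lon = 2)
  res <- run_grid(g)
  b <- integrate_burial(res, 11)
  manual <- sum(res$flux_depth[, , 1] * g$cell_area) / 1e15
  expect_equal(b$burial[b$zone == "global"], manual, tolerance = 1e-12)
  expect_equal(sum(b$burial[b$zone != "global"]),
               b$burial[b$zone == "global"], tolerance = 1e-6)
  expect_error(integrate_burial(res, 12345), "horizon")
})

test_that("budgets shrink monotonically as the horizon deepens or ages", {
  cfg <- pipeline_config(depth_horizons = c(11, 50, 100, 500, 1000),
                         age_horizons = c(100, 1e3, 1e4, 1e5))
  res <- run_grid(generate_grid(synthetic_grid_spec(seed = 4)), cfg)
  bd <- sapply(cfg$depth_horizons,
               function(h) integrate_burial(res, h)$burial[4])
  ba <- sapply(cfg$age_horizons,
               function(h) integrate_burial(res, h, "age")$burial[4])
  expect_true(all(diff(bd) < 0))
  expect_true(all(diff(ba) < 0))
})

test_that("global mass balance closes over the grid", {
  g <- generate_grid(synthetic_grid_spec(seed = 2))
  res <- run_grid(g)
  area <- g$cell_area
  dep <- sum(res$f_swi * area, na.rm = TRUE)
  sinks <- sum((res$ideg_10m + res$burial_10m) * area, na.rm = TRUE)
  expect_equal(dep, sinks, tolerance = 1e-3)
})

test_that("uncertainty envelopes bracket the nominal budget", {
  g <- generate_grid(synthetic_grid_spec(n_lat = 12, n_lon = 24, seed = 8))
  collapsed <- uncertainty_envelope(g, horizon = 11, perturbation = 0)
  expect_equal(collapsed$envelope_low, collapsed$burial, tolerance = 1e-12)
  expect_equal(collapsed$envelope_high, collapsed$burial, tolerance = 1e-12)
  env10 <- suppressWarnings(uncertainty_envelope(g, horizon = 11,
                                                 perturbation = 0.1))
  expect_true(all(env10$envelope_low <= env10$burial + 1e-12))
  expect_true(all(env10$envelope_high >= env10$burial - 1e-12))
  # more advection and more solid fraction -> the high-burial corner
  corner <- function(pm, om) {
    res <- suppressWarnings(run_grid(g, phi_mult = pm, omega_mult = om))
    integrate_burial(res, 11)$burial[4]
  }
  corners <- c(corner(0.9, 1.1), corner(0.9, 0.9), corner(1.1, 1.1),
               corner(1.1, 0.9))
  expect_equal(env10$envelope_high[4], max(corners), tolerance = 1e-10)
  expect_equal(which.max(corners), 1L)
})

test_that("gridded boundary conditions round-trip through the CSV dialect", {
  g <- generate_grid(synthetic_grid_spec(n_lat = 6, n_lon = 8, seed = 9))
  path <- withr::local_tempfile(fileext = ".csv")
  write_grid_csv(g, path)
  g2 <- read_grid_csv(path)
  expect_equal(g2$water_depth, g$water_depth, tolerance = 1e-9)
  expect_equal(g2$oc0, g$oc0, tolerance = 1e-9)
  expect_equal(g2$phi, g$phi, tolerance = 1e-9)
  expect_equal(g2$cell_area, g$cell_area, tolerance = 1e-9)
})

test_that("run configurations load from YAML with defaults for absent keys", {
  path <- withr::local_tempfile(fileext = ".yml")
  writeLines(c("nu: 0.25", "z_bio: 5",
               "zone_a:", "  shelf: 0.2", "  margin: 2", "  abyss: 40"),
             path)
  cfg <- pipeline_config_from_yaml(path)
  expect_equal(cfg$nu, 0.25)
  expect_equal(cfg$z_bio, 5)
  expect_equal(unname(cfg$zone_a["abyss"]), 40)
  expect_equal(cfg$rho_s, 2.5)  # untouched default
})
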