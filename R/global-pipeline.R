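#' Pipeline run configuration
#'
#' Collects every tunable of the gridded pipeline with its default. Defaults
#' reproduce the study conditions: Gamma shape `nu = 0.125` (fresh organic
#' matter) with zone lifetimes `a` of 0.1 / 1.0 / 20.0 yr for shelf / margin
#' / abyss, hypoxia adjustments below 60 uM bottom-water oxygen, a 10 cm
#' normoxic bioturbated layer, and depth-dependent sedimentation-rate and
#' bioturbation parameterisations (see [sedimentation_rate()],
#' [bioturbation_coefficient()]).
#'
#' @param zone_a Named lifetimes `a` (yr) per depositional zone.
#' @param nu Gamma shape parameter.
#' @param n_bins Reactivity fractions per spectrum.
#' @param k_min Lower reactivity bound, yr^-1.
#' @param zone_thresholds Water depths (m) separating shelf/margin and
#'   margin/abyss.
#' @param z_bio Normoxic bioturbation depth, cm.
#' @param o2_threshold Hypoxia threshold, uM.
#' @param rho_s Dry solid density used to convert OC from wt%% to
#'   g C cm^-3 dry sediment, g cm^-3.
#' @param omega_params,db_params Parameter lists for
#'   [sedimentation_rate()] and [bioturbation_coefficient()].
#' @param depth_horizons Depth horizons (cm) at which fluxes and T_eff are
#'   evaluated (defaults include 11 cm = 0.11 mbsf, the nominal base of the
#'   bioturbated zone, 1 mbsf, and 10 mbsf).
#' @param age_horizons Age horizons, years.
#' @param age_at_depths Depths (cm) at which sediment age maps are derived.
#' @param depth_at_ages Ages (yr) at which sediment depth maps are derived.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(zone_a = c(shelf = 0.1, margin = 1.0, abyss = 20.0),
                            nu = 0.125,
                            n_bins = 100L,
                            k_min = 1e-15,
                            zone_thresholds = c(200, 3500),
                            z_bio = 10,
                            o2_threshold = 60,
                            rho_s = 2.5,
                            omega_params = list(omega1 = 0.117, d1 = 200,
                                                c1 = 3, omega2 = 0.006,
                                                d2 = 4000, c2 = 10),
                            db_params = list(db0 = 5.338,
                                             beta = 3.9724e-4),
                            depth_horizons = c(11, 100, 1000),
                            age_horizons = c(100, 1e4, 1e5),
                            age_at_depths = c(11, 1000),
                            depth_at_ages = c(100, 1e4, 1e5)) {
  stopifnot(all(c("shelf", "margin", "abyss") %in% names(zone_a)),
            all(zone_a > 0), nu > 0, n_bins >= 2)
  if (zone_thresholds[1] >= zone_thresholds[2])
    stop("zone thresholds must be increasing (shelf < margin bound)")
  structure(list(zone_a = zone_a, nu = nu, n_bins = as.integer(n_bins),
                 k_min = k_min, zone_thresholds = zone_thresholds,
                 z_bio = z_bio, o2_threshold = o2_threshold, rho_s = rho_s,
                 omega_params = omega_params, db_params = db_params,
                 depth_horizons = depth_horizons, age_horizons = age_horizons,
                 age_at_depths = age_at_depths, depth_at_ages = depth_at_ages),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; absent keys keep their
#' defaults.
#'
#' @param path Path to a YAML file.
#' @return A `"pipeline_config"`.
#' @export
pipeline_config_from_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configurations")
  vals <- yaml::read_yaml(path)
  keep <- intersect(names(vals), names(formals(pipeline_config)))
  for (nm in c("zone_a", "zone_thresholds", "depth_horizons", "age_horizons",
               "age_at_depths", "depth_at_ages")) {
    if (nm %in% names(vals)) vals[[nm]] <- unlist(vals[[nm]])
  }
  do.call(pipeline_config, vals[keep])
}

#' Sedimentation rate from water depth
#'
#' Double-logistic empirical relationship
#' `omega(d) = omega1 / (1 + (d/d1)^c1) + omega2 / (1 + (d/d2)^c2)`
#' (cm yr^-1), monotonically nonincreasing with water depth. The defaults
#' give coastal rates near 0.12 cm/yr, abyssal rates near 1e-3 cm/yr at
#' 4000-5000 m and ~1e-4 cm/yr at 6000 m — a span of over three orders of
#' magnitude across the 0-6000 m depth range, consistent with global
#' compilations.
#'
#' @param water_depth Water depth, m (vectorized, >= 0).
#' @param params List with `omega1`, `d1`, `c1`, `omega2`, `d2`, `c2`.
#' @return Sedimentation rate(s), cm yr^-1.
#' @export
sedimentation_rate <- function(water_depth,
                               params = pipeline_config()$omega_params) {
  if (any(water_depth < 0, na.rm = TRUE)) stop("'water_depth' must be >= 0")
  w <- params$omega1 / (1 + (water_depth / params$d1)^params$c1) +
    params$omega2 / (1 + (water_depth / params$d2)^params$c2)
  if (any(w <= 0, na.rm = TRUE))
    stop("sedimentation-rate parameters produce omega <= 0")
  w
}

#' Bioturbation coefficient from water depth
#'
#' Exponential-in-depth empirical relationship
#' `Db(d) = db0 * 10^(-beta * d)` (cm^2 yr^-1). The defaults give
#' `Db(0) = 5.338` cm^2/yr with a tenfold reduction by ~2500 m.
#'
#' @param water_depth Water depth, m (vectorized, >= 0).
#' @param params List with `db0` (cm^2 yr^-1) and `beta` (m^-1).
#' @return Bioturbation coefficient(s), cm^2 yr^-1.
#' @export
bioturbation_coefficient <- function(water_depth,
                                     params = pipeline_config()$db_params) {
  if (any(water_depth < 0, na.rm = TRUE)) stop("'water_depth' must be >= 0")
  params$db0 * 10^(-params$beta * water_depth)
}

#' Classify seafloor cells into depositional zones
#'
#' @param water_depth Water depth, m (vectorized, >= 0).
#' @param thresholds Two increasing depths (m): shelf if
#'   `d <= thresholds[1]`, margin if `thresholds[1] < d <= thresholds[2]`,
#'   abyss otherwise. Defaults 200 m and 3500 m.
#' @return Character vector of `"shelf"`, `"margin"`, `"abyss"`.
#' @export
classify_zone <- function(water_depth,
                          thresholds = pipeline_config()$zone_thresholds) {
  if (thresholds[1] >= thresholds[2])
    stop("zone thresholds must be increasing")
  if (any(water_depth < 0, na.rm = TRUE)) stop("'water_depth' must be >= 0")
  ifelse(water_depth <= thresholds[1], "shelf",
         ifelse(water_depth <= thresholds[2], "margin", "abyss"))
}

#' Apply the hypoxia rule to a column
#'
#' Where bottom-water oxygen is below the hypoxia threshold (strictly
#' `o2 < 60` uM by default), organic-matter reactivity is reduced by an
#' order of magnitude — implemented as a tenfold increase of the lifetime
#' parameter, `a -> 10 a`, which lowers the apparent initial reactivity
#' `nu/a` tenfold (scaling every `k_i` by 0.1 is equivalent for the
#' continuum mean) — and the bioturbated layer collapses to `z_bio = 1` cm.
#' Normoxic columns are returned unchanged.
#'
#' @param env A [sediment_environment()] (must carry `o2`).
#' @param rcm An [rcm_params()].
#' @param o2_threshold Hypoxia threshold, uM (default 60).
#' @return A list with modified `env` and `rcm`.
#' @export
apply_hypoxia <- function(env, rcm, o2_threshold = 60) {
  stopifnot(inherits(env, "sediment_environment"),
            inherits(rcm, "rcm_params"))
  if (is.na(env$o2)) stop("'env$o2' is required to apply the hypoxia rule")
  if (env$o2 < 0) stop("'o2' must be >= 0")
  if (env$o2 < o2_threshold) {
    env$z_bio <- 1
    rcm <- rcm_params(a = 10 * rcm$a, nu = rcm$nu, n_bins = rcm$n_bins,
                      k_min = rcm$k_min)
  }
  list(env = env, rcm = rcm)
}

#' Gridded boundary conditions for the global pipeline
#'
#' @param lat,lon Cell-centre coordinates, degrees (vectors of length
#'   `n_lat`, `n_lon`; assumed regularly spaced).
#' @param water_depth,oc0,phi,o2 Matrices of shape `n_lat x n_lon`: water
#'   depth (m), SWI OC concentration, porosity, bottom-water oxygen (uM).
#'   `NA` cells are treated as land and masked.
#' @param oc0_units Either `"wt_percent"` (converted to g C cm^-3 dry
#'   sediment via the configured solid density) or `"gC_cm3"`.
#' @return An object of class `"global_grid"` including the spherical cell
#'   areas (cm^2, Earth radius 6371 km, cosine-latitude weighted).
#' @export
global_grid <- function(lat, lon, water_depth, oc0, phi, o2,
                        oc0_units = c("wt_percent", "gC_cm3")) {
  oc0_units <- match.arg(oc0_units)
  dims <- c(length(lat), length(lon))
  flds <- list(water_depth = water_depth, oc0 = oc0, phi = phi, o2 = o2)
  for (nm in names(flds)) {
    if (!identical(dim(flds[[nm]]), as.integer(dims)))
      stop("field '", nm, "' must be a ", dims[1], " x ", dims[2], " matrix")
  }
  mask <- is.finite(water_depth)
  for (nm in c("oc0", "phi", "o2")) {
    if (any(mask & !is.finite(flds[[nm]])))
      stop("ocean mask inconsistent: field '", nm,
           "' has NA where water_depth is finite")
  }
  dlat <- if (length(lat) > 1) abs(diff(lat)[1]) else 1
  dlon <- if (length(lon) > 1) abs(diff(lon)[1]) else 1
  r_cm <- 6371 * 1e5
  band <- r_cm^2 * (dlon * pi / 180) *
    abs(sin((lat + dlat / 2) * pi / 180) - sin((lat - dlat / 2) * pi / 180))
  cell_area <- matrix(band, nrow = dims[1], ncol = dims[2])
  structure(list(lat = lat, lon = lon, water_depth = water_depth,
                 oc0 = oc0, oc0_units = oc0_units, phi = phi, o2 = o2,
                 cell_area = cell_area, mask = mask),
            class = "global_grid")
}

#' @export
print.global_grid <- function(x, ...) {
  cat(sprintf("global grid: %d x %d cells (%d ocean)\n",
              length(x$lat), length(x$lon), sum(x$mask)))
  cat(sprintf("  water depth %g-%g m; OC0 (%s) %.3g-%.3g; O2 %.3g-%.3g uM\n",
              min(x$water_depth, na.rm = TRUE), max(x$water_depth, na.rm = TRUE),
              x$oc0_units, min(x$oc0, na.rm = TRUE), max(x$oc0, na.rm = TRUE),
              min(x$o2, na.rm = TRUE), max(x$o2, na.rm = TRUE)))
  invisible(x)
}

#' Read / write gridded boundary conditions as CSV
#'
#' Long-format dialect with columns `lon`, `lat`, `depth`, `oc0`, `phi`,
#' `o2` (one row per ocean cell on a regular grid).
#'
#' @param path CSV file path.
#' @param oc0_units Units flag passed to [global_grid()].
#' @return `read_grid_csv()` returns a `"global_grid"`;
#'   `write_grid_csv()` invisibly returns `path`.
#' @export
read_grid_csv <- function(path, oc0_units = c("wt_percent", "gC_cm3")) {
  oc0_units <- match.arg(oc0_units)
  df <- utils::read.csv(path)
  need <- c("lon", "lat", "depth", "oc0", "phi", "o2")
  if (!all(need %in% names(df)))
    stop("grid CSV must have columns: ", paste(need, collapse = ", "))
  lat <- sort(unique(df$lat)); lon <- sort(unique(df$lon))
  shape_field <- function(v) {
    m <- matrix(NA_real_, length(lat), length(lon))
    m[cbind(match(df$lat, lat), match(df$lon, lon))] <- v
    m
  }
  global_grid(lat, lon, shape_field(df$depth), shape_field(df$oc0),
              shape_field(df$phi), shape_field(df$o2), oc0_units = oc0_units)
}

#' @rdname read_grid_csv
#' @param grid A `"global_grid"`.
#' @export
write_grid_csv <- function(grid, path) {
  stopifnot(inherits(grid, "global_grid"))
  idx <- which(grid$mask, arr.ind = TRUE)
  df <- data.frame(lon = grid$lon[idx[, 2]], lat = grid$lat[idx[, 1]],
                   depth = grid$water_depth[idx],
                   oc0 = grid$oc0[idx], phi = grid$phi[idx],
                   o2 = grid$o2[idx])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# --- vectorized multi-cell solver core -------------------------------------
# State for m cells sharing one spectrum: coefficient matrices (m x n) with
# all exponents nonpositive on their layer (see solve_column()).
.cells_state <- function(w, db, zb, phi, oc0, k, frac) {
  m <- length(w); n <- length(k)
  adv <- db < DB_EPS | zb <= 0
  C0 <- outer(oc0, frac)
  K <- matrix(k, m, n, byrow = TRUE)
  st <- list(m = m, n = n, adv = adv, w = w, db = db, zb = zb, phi = phi,
             C0 = C0, K = K, A2adv = -K / w)
  if (any(!adv)) {
    i <- which(!adv)
    D <- sqrt(w[i]^2 + 4 * outer(db[i], k))
    a1 <- (w[i] - D) / (2 * db[i])
    b1 <- (w[i] + D) / (2 * db[i])
    A1 <- C0[i, , drop = FALSE] / (1 - (a1 / b1) * exp((a1 - b1) * zb[i]))
    beta <- -A1 * (a1 / b1) * exp(a1 * zb[i])
    st$bio <- list(idx = i, a1 = a1, b1 = b1, A1 = A1, beta = beta,
                   A2 = A1 * exp(a1 * zb[i]) + beta,
                   a2 = -K[i, , drop = FALSE] / w[i],
                   k_a1 = -(w[i] + D) / 2, k_b1 = (D - w[i]) / 2)
  }
  st
}

# bulk OC, flux and degradation rate at per-cell depths z (length m vector
# or scalar)
.cells_eval <- function(st, z) {
  z <- rep_len(z, st$m)
  oc <- flux <- rate <- numeric(st$m)
  if (any(st$adv)) {
    i <- which(st$adv)
    E <- exp(st$A2adv[i, , drop = FALSE] * z[i])
    Ci <- st$C0[i, , drop = FALSE] * E
    oc[i] <- rowSums(Ci)
    flux[i] <- (1 - st$phi[i]) * st$w[i] * oc[i]
    rate[i] <- rowSums(st$K[i, , drop = FALSE] * Ci)
  }
  if (!is.null(st$bio)) {
    b <- st$bio; i <- b$idx; zi <- z[i]
    up <- zi <= st$zb[i]
    if (any(up)) {
      j <- which(up)
      E1 <- exp(b$a1[j, , drop = FALSE] * zi[j])
      E2 <- exp(b$b1[j, , drop = FALSE] * (zi[j] - st$zb[i][j]))
      Ci <- b$A1[j, , drop = FALSE] * E1 + b$beta[j, , drop = FALSE] * E2
      dCi <- b$A1[j, , drop = FALSE] * b$a1[j, , drop = FALSE] * E1 +
        b$beta[j, , drop = FALSE] * b$b1[j, , drop = FALSE] * E2
      ii <- i[j]
      oc[ii] <- rowSums(Ci)
      flux[ii] <- (1 - st$phi[ii]) *
        (st$w[ii] * oc[ii] - st$db[ii] * rowSums(dCi))
      rate[ii] <- rowSums(st$K[ii, , drop = FALSE] * Ci)
    }
    if (any(!up)) {
      j <- which(!up)
      Ci <- b$A2[j, , drop = FALSE] *
        exp(b$a2[j, , drop = FALSE] * (zi[j] - st$zb[i][j]))
      ii <- i[j]
      oc[ii] <- rowSums(Ci)
      flux[ii] <- (1 - st$phi[ii]) * st$w[ii] * oc[ii]
      rate[ii] <- rowSums(st$K[ii, , drop = FALSE] * Ci)
    }
  }
  list(oc = oc, flux = flux, rate = rate)
}

# depth-integrated solid-phase degradation to per-cell depths z
.cells_ideg <- function(st, z) {
  z <- rep_len(z, st$m)
  out <- numeric(st$m)
  if (any(st$adv)) {
    i <- which(st$adv)
    out[i] <- (1 - st$phi[i]) * st$w[i] *
      rowSums(st$C0[i, , drop = FALSE] *
                (1 - exp(st$A2adv[i, , drop = FALSE] * z[i])))
  }
  if (!is.null(st$bio)) {
    b <- st$bio; i <- b$idx; zi <- z[i]
    z1 <- pmin(zi, st$zb[i])
    part <- rowSums(
      b$k_a1 * b$A1 * (exp(b$a1 * z1) - 1) +
        b$k_b1 * b$beta *
          (exp(b$b1 * (z1 - st$zb[i])) - exp(-b$b1 * st$zb[i])))
    below <- zi > st$zb[i]
    if (any(below)) {
      j <- which(below)
      part[j] <- part[j] - st$w[i][j] *
        rowSums(b$A2[j, , drop = FALSE] *
                  (exp(b$a2[j, , drop = FALSE] * (zi[j] - st$zb[i][j])) - 1))
    }
    out[i] <- (1 - st$phi[i]) * part
  }
  out
}

#' Run the column model over a global grid
#'
#' Derives per-cell boundary conditions (sedimentation rate and bioturbation
#' from water depth, zone kinetics, hypoxia adjustments, OC unit
#' conversion), solves every ocean column analytically, and returns gridded
#' fields: SWI flux, flux and `T_eff` at the configured depth and age
#' horizons, depth-integrated degradation, sediment age at configured depths
#' and depth at configured ages. Cells with invalid boundary conditions are
#' flagged and skipped; their count is reported.
#'
#' @param grid A [global_grid()].
#' @param config A [pipeline_config()].
#' @param phi_mult,omega_mult,db_mult Multiplicative perturbations applied
#'   cell-wise to porosity, sedimentation rate and bioturbation (used by
#'   [uncertainty_envelope()] and the sensitivity analysis). Perturbed
#'   porosity is clamped below 0.99 (with a warning if clamping occurs).
#' @param z_bio_override Absolute bioturbation depth (cm) overriding both
#'   the normoxic default and the hypoxic 1 cm, or `NULL`.
#' @return An object of class `"grid_results"`: gridded fields (matrices or
#'   `lat x lon x horizon` arrays), per-cell `zone` and `omega`, the
#'   configuration, and `n_invalid`.
#' @export
run_grid <- function(grid, config = pipeline_config(),
                     phi_mult = 1, omega_mult = 1, db_mult = 1,
                     z_bio_override = NULL) {
  stopifnot(inherits(grid, "global_grid"),
            inherits(config, "pipeline_config"))
  dims <- dim(grid$water_depth)
  ocean <- which(grid$mask)
  wd <- grid$water_depth[ocean]
  phi <- grid$phi[ocean] * phi_mult
  if (any(phi >= 1)) {
    warning("perturbed porosity >= 1 in ", sum(phi >= 1),
            " cells; clamped at 0.99")
    phi <- pmin(phi, 0.99)
  }
  o2 <- grid$o2[ocean]
  oc0 <- grid$oc0[ocean]
  if (grid$oc0_units == "wt_percent") oc0 <- oc0 / 100 * config$rho_s
  omega <- omega_mult * sedimentation_rate(wd, config$omega_params)
  db <- db_mult * bioturbation_coefficient(wd, config$db_params)
  zone <- classify_zone(wd, config$zone_thresholds)
  a <- unname(config$zone_a[zone])
  hypoxic <- o2 < config$o2_threshold
  a[hypoxic] <- 10 * a[hypoxic]
  zb <- rep(config$z_bio, length(wd))
  zb[hypoxic] <- 1
  if (!is.null(z_bio_override)) zb[] <- z_bio_override

  valid <- is.finite(omega) & omega > 0 & is.finite(oc0) & oc0 >= 0 &
    is.finite(phi) & phi >= 0
  n_invalid <- sum(!valid)

  nd <- length(config$depth_horizons); na <- length(config$age_horizons)
  cells <- length(ocean)
  f_swi <- rep(NA_real_, cells)
  flux_d <- teff_d <- matrix(NA_real_, cells, nd)
  flux_a <- teff_a <- matrix(NA_real_, cells, na)
  ideg_10m <- burial_10m <- rep(NA_real_, cells)

  for (av in unique(a[valid])) {
    sel <- which(valid & a == av)
    sp <- discretize_rcm(rcm_params(a = av, nu = config$nu,
                                    n_bins = config$n_bins,
                                    k_min = config$k_min))
    st <- .cells_state(omega[sel], db[sel], zb[sel], phi[sel], oc0[sel],
                       sp$k_values, sp$fractions)
    f_swi[sel] <- .cells_eval(st, 0)$flux
    for (j in seq_len(nd)) {
      ev <- .cells_eval(st, config$depth_horizons[j])
      flux_d[sel, j] <- ev$flux
    }
    for (j in seq_len(na)) {
      ev <- .cells_eval(st, omega[sel] * config$age_horizons[j])
      flux_a[sel, j] <- ev$flux
    }
    ideg_10m[sel] <- .cells_ideg(st, 1000)
    burial_10m[sel] <- .cells_eval(st, 1000)$flux
  }
  pos <- f_swi > 0 & !is.na(f_swi)
  teff_d[pos, ] <- 100 * flux_d[pos, , drop = FALSE] / f_swi[pos]
  teff_a[pos, ] <- 100 * flux_a[pos, , drop = FALSE] / f_swi[pos]

  to_field <- function(v) {
    m <- matrix(NA_real_, dims[1], dims[2]); m[ocean] <- v; m
  }
  to_array <- function(M, horizons) {
    arr <- array(NA_real_, c(dims, ncol(M)))
    for (j in seq_len(ncol(M))) arr[, , j][ocean] <- M[, j]
    dimnames(arr) <- list(NULL, NULL, as.character(horizons))
    arr
  }
  age_at_depth <- vapply(config$age_at_depths,
                         function(z) z / omega, numeric(cells))
  depth_at_age <- vapply(config$depth_at_ages,
                         function(t) omega * t, numeric(cells))

  structure(list(
    grid = grid, config = config, n_invalid = n_invalid,
    perturbation = c(phi = phi_mult, omega = omega_mult, db = db_mult),
    zone = to_field(match(zone, c("shelf", "margin", "abyss"))),
    omega = to_field(omega), db = to_field(db), z_bio = to_field(zb),
    hypoxic = to_field(as.numeric(hypoxic)),
    f_swi = to_field(f_swi),
    flux_depth = to_array(flux_d, config$depth_horizons),
    teff_depth = to_array(teff_d, config$depth_horizons),
    flux_age = to_array(flux_a, config$age_horizons),
    teff_age = to_array(teff_a, config$age_horizons),
    age_at_depth = to_array(age_at_depth, config$age_at_depths),
    depth_at_age = to_array(depth_at_age, config$depth_at_ages),
    ideg_10m = to_field(ideg_10m), burial_10m = to_field(burial_10m)),
    class = "grid_results")
}

#' @export
print.grid_results <- function(x, ...) {
  cat("gridded diagenetic model results\n")
  print(x$grid)
  cat(sprintf("  depth horizons (cm): %s; age horizons (yr): %s\n",
              paste(x$config$depth_horizons, collapse = ", "),
              paste(x$config$age_horizons, collapse = ", ")))
  if (x$n_invalid > 0) cat("  invalid cells skipped:", x$n_invalid, "\n")
  invisible(x)
}

.zone_names <- c("shelf", "margin", "abyss")

#' Integrate burial fluxes to zone and global budgets
#'
#' Sums `flux * cell_area` over ocean cells, per depositional zone and
#' globally, at one of the configured horizons, and converts to
#' Pg C yr^-1.
#'
#' @param results A [run_grid()] result.
#' @param horizon Horizon value: cm if `horizon_type = "depth"`, years if
#'   `"age"`. Must be one of the horizons in the run's configuration.
#' @param horizon_type `"depth"` or `"age"`.
#' @return A `"burial_budget"` data.frame with rows shelf, margin, abyss,
#'   global and columns `zone`, `horizon_type`, `horizon`, `burial`
#'   (Pg C yr^-1).
#' @export
integrate_burial <- function(results, horizon, horizon_type = c("depth", "age")) {
  stopifnot(inherits(results, "grid_results"))
  horizon_type <- match.arg(horizon_type)
  cfgh <- if (horizon_type == "depth") results$config$depth_horizons
          else results$config$age_horizons
  j <- match(horizon, cfgh)
  if (is.na(j))
    stop("horizon ", horizon, " (", horizon_type,
         ") not among the run's configured horizons")
  flux <- if (horizon_type == "depth") results$flux_depth[, , j]
          else results$flux_age[, , j]
  area <- results$grid$cell_area
  zone <- results$zone
  ok <- is.finite(flux)
  per_zone <- vapply(1:3, function(zz) {
    sel <- ok & !is.na(zone) & zone == zz
    sum(flux[sel] * area[sel]) / 1e15
  }, numeric(1))
  out <- data.frame(zone = c(.zone_names, "global"),
                    horizon_type = horizon_type, horizon = horizon,
                    burial = c(per_zone, sum(per_zone)))
  class(out) <- c("burial_budget", "data.frame")
  out
}

#' Burial budgets with uncertainty envelopes
#'
#' Reruns the pipeline at the four corner combinations of multiplicative
#' perturbations on porosity and sedimentation rate (default +/-10%, the
#' two most influential parameters identified by the sensitivity analysis)
#' plus the nominal run; the envelope is the elementwise min/max of the
#' budgets across runs.
#'
#' @param grid A [global_grid()].
#' @param config A [pipeline_config()].
#' @param horizon,horizon_type As in [integrate_burial()].
#' @param perturbation Fractional perturbation of `phi` and `omega`
#'   (default 0.1).
#' @return A `"burial_budget"` data.frame with extra columns
#'   `envelope_low` and `envelope_high` (Pg C yr^-1).
#' @export
uncertainty_envelope <- function(grid, config = pipeline_config(),
                                 horizon = 11,
                                 horizon_type = c("depth", "age"),
                                 perturbation = 0.1) {
  horizon_type <- match.arg(horizon_type)
  corners <- rbind(c(1, 1),
                   expand.grid(phi = c(1 - perturbation, 1 + perturbation),
                               omega = c(1 - perturbation, 1 + perturbation)))
  budgets <- lapply(seq_len(nrow(corners)), function(i) {
    res <- run_grid(grid, config, phi_mult = corners[i, 1],
                    omega_mult = corners[i, 2])
    integrate_burial(res, horizon, horizon_type)$burial
  })
  B <- do.call(cbind, budgets)
  out <- integrate_burial(run_grid(grid, config), horizon, horizon_type)
  out$burial <- B[, 1]
  out$envelope_low <- apply(B, 1, min)
  out$envelope_high <- apply(B, 1, max)
  out
}

#' Zone-wise summary of a gridded field
#'
#' Area-weighted mean of a gridded result field per depositional zone.
#'
#' @param results A [run_grid()] result.
#' @param field A matrix field from `results` (e.g.
#'   `results$teff_depth[, , 2]`).
#' @return Named numeric vector (shelf, margin, abyss, global).
#' @export
zone_mean <- function(results, field) {
  stopifnot(inherits(results, "grid_results"))
  area <- results$grid$cell_area
  zone <- results$zone
  ok <- is.finite(field) & !is.na(zone)
  vals <- vapply(1:3, function(zz) {
    sel <- ok & zone == zz
    if (!any(sel)) return(NA_real_)
    sum(field[sel] * area[sel]) / sum(area[sel])
  }, numeric(1))
  c(stats::setNames(vals, .zone_names),
    global = sum(field[ok] * area[ok]) / sum(area[ok]))
}
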