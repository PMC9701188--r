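#' Specification of a synthetic boundary-condition grid
#'
#' Describes the statistical structure of a synthetic global grid that
#' emulates the real boundary-condition fields the pipeline needs: a
#' bathymetry spanning shelf to abyss with a prescribed shelf areal
#' fraction, SWI organic-carbon content declining from a shelf to an
#' abyssal endmember, porosity increasing with water depth, and a
#' bottom-water oxygen field containing contiguous hypoxic
#' (`O2 < 60` uM) patches at a target areal fraction. No continents are
#' modelled: every cell is ocean.
#'
#' @param n_lat,n_lon Grid shape (defaults 36 x 72, i.e. 5 degrees).
#' @param depth_range Water-depth range, m.
#' @param shelf_fraction Target areal fraction with depth <= 200 m
#'   (default 0.08).
#' @param hypoxic_fraction Target areal fraction with O2 < 60 uM
#'   (default 0.05).
#' @param oc0_shelf,oc0_abyss SWI OC endmembers, wt%% (defaults 1.5, 0.3).
#' @param phi_range Porosity range, increasing with depth
#'   (default `[0.45, 0.90]`).
#' @param seed Integer seed; grids are reproducible under a fixed seed.
#' @return A list of class `"synthetic_grid_spec"`.
#' @export
synthetic_grid_spec <- function(n_lat = 36, n_lon = 72,
                                depth_range = c(0, 6000),
                                shelf_fraction = 0.08,
                                hypoxic_fraction = 0.05,
                                oc0_shelf = 1.5, oc0_abyss = 0.3,
                                phi_range = c(0.45, 0.90),
                                seed = 1) {
  stopifnot(n_lat >= 4, n_lon >= 4,
            depth_range[1] < depth_range[2],
            shelf_fraction > 0, shelf_fraction < 1,
            hypoxic_fraction > 0, hypoxic_fraction < 1,
            oc0_shelf > oc0_abyss, oc0_abyss > 0,
            phi_range[1] < phi_range[2], phi_range[1] >= 0,
            phi_range[2] < 1)
  if (shelf_fraction * n_lat * n_lon < 1 ||
      hypoxic_fraction * n_lat * n_lon < 1)
    stop("target areal fraction unreachable at this grid resolution")
  structure(list(n_lat = n_lat, n_lon = n_lon, depth_range = depth_range,
                 shelf_fraction = shelf_fraction,
                 hypoxic_fraction = hypoxic_fraction,
                 oc0_shelf = oc0_shelf, oc0_abyss = oc0_abyss,
                 phi_range = phi_range, seed = seed),
            class = "synthetic_grid_spec")
}

# smooth random field on the grid: superposed low-order harmonics in
# lat/lon plus a little white noise
.smooth_field <- function(lat, lon, n_modes = 6, noise_sd = 0.1) {
  latr <- lat / 180; lonr <- lon / 360
  f <- matrix(0, length(lat), length(lon))
  for (p in seq_len(n_modes)) {
    fl <- sample(0:3, 1); fn <- sample(1:3, 1)
    amp <- stats::rnorm(1)
    ph <- stats::runif(2, 0, 2 * pi)
    f <- f + amp * outer(cos(2 * pi * fl * latr + ph[1]),
                         cos(2 * pi * fn * lonr + ph[2]))
  }
  f + matrix(stats::rnorm(length(f), sd = noise_sd), nrow(f), ncol(f))
}

# area-weighted empirical quantile rank of a field, in (0, 1)
.weighted_rank <- function(x, w) {
  ord <- order(x)
  u <- numeric(length(x))
  cw <- cumsum(w[ord])
  u[ord] <- (cw - w[ord] / 2) / sum(w)
  u
}

#' Generate a synthetic global boundary-condition grid
#'
#' Realises a [synthetic_grid_spec()]: a smooth random bathymetry is
#' rank-mapped (area-weighted) onto a shelf-heavy-at-the-top,
#' abyss-heavy-at-the-bottom hypsography hitting the target shelf fraction;
#' OC content decays exponentially with water depth between the endmembers
#' and carries multiplicative lognormal noise; porosity increases with
#' depth across `phi_range`; hypoxic patches are the lowest areal quantile
#' of a second smooth field, so they form contiguous regions.
#'
#' @param spec A [synthetic_grid_spec()].
#' @return A [global_grid()] with `oc0` in wt%%.
#' @examples
#' g <- generate_grid(synthetic_grid_spec(seed = 42))
#' g
#' @export
generate_grid <- function(spec = synthetic_grid_spec()) {
  stopifnot(inherits(spec, "synthetic_grid_spec"))
  set.seed(spec$seed)
  dlat <- 180 / spec$n_lat; dlon <- 360 / spec$n_lon
  lat <- seq(-90 + dlat / 2, 90 - dlat / 2, by = dlat)
  lon <- seq(-180 + dlon / 2, 180 - dlon / 2, by = dlon)
  area_band <- abs(sin((lat + dlat / 2) * pi / 180) -
                     sin((lat - dlat / 2) * pi / 180))
  w <- matrix(area_band, spec$n_lat, spec$n_lon)

  # bathymetry: quantile-map a smooth field onto the target hypsography
  b <- .smooth_field(lat, lon)
  u <- .weighted_rank(as.vector(b), as.vector(w))
  sf <- spec$shelf_fraction
  shelf_top <- 200
  depth <- ifelse(u <= sf,
                  spec$depth_range[1] + (shelf_top - spec$depth_range[1]) *
                    u / sf,
                  shelf_top + (spec$depth_range[2] - shelf_top) *
                    ((u - sf) / (1 - sf))^0.7)
  depth <- matrix(depth, spec$n_lat, spec$n_lon)

  # SWI OC (wt%): exponential decline with depth + lognormal noise
  oc0 <- spec$oc0_abyss + (spec$oc0_shelf - spec$oc0_abyss) *
    exp(-depth / 800)
  oc0 <- oc0 * matrix(stats::rlnorm(length(oc0), meanlog = -0.02,
                                    sdlog = 0.2),
                      spec$n_lat, spec$n_lon)

  # porosity: increases with depth within phi_range, mild noise
  phi <- spec$phi_range[1] + diff(spec$phi_range) *
    sqrt(depth / spec$depth_range[2])
  phi <- phi + matrix(stats::rnorm(length(phi), sd = 0.015),
                      spec$n_lat, spec$n_lon)
  phi <- pmin(pmax(phi, spec$phi_range[1]), spec$phi_range[2])

  # oxygen: contiguous hypoxic patches from a second smooth field
  h <- .smooth_field(lat, lon)
  uh <- .weighted_rank(as.vector(h), as.vector(w))
  hyp <- uh <= spec$hypoxic_fraction
  o2 <- numeric(length(uh))
  o2[hyp] <- stats::runif(sum(hyp), 5, 55)
  o2[!hyp] <- stats::runif(sum(!hyp), 120, 300)
  o2 <- matrix(o2, spec$n_lat, spec$n_lon)

  global_grid(lat, lon, depth, oc0, phi, o2, oc0_units = "wt_percent")
}

#' Generate a toy sediment-core OC profile
#'
#' Samples the forward model at the given depths and multiplies by
#' lognormal noise of the requested coefficient of variation, emulating a
#' measured down-core OC profile for model-evaluation exercises.
#'
#' @param env A [sediment_environment()].
#' @param rcm An [rcm_params()].
#' @param depths Observation depths, cm.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   noise (>= 0; 0 returns exact forward-model values).
#' @param seed Optional integer seed.
#' @return A data.frame with columns `depth` and `oc_observed`
#'   (g C cm^-3 dry sediment), with the noiseless profile attached as
#'   attribute `"oc_true"`.
#' @export
generate_toy_core <- function(env, rcm, depths, noise_cv = 0.1,
                              seed = NULL) {
  stopifnot(inherits(env, "sediment_environment"),
            inherits(rcm, "rcm_params"), noise_cv >= 0)
  if (!is.null(seed)) set.seed(seed)
  prof <- solve_column(env, discretize_rcm(rcm))
  oc_true <- oc_at_depth(prof, depths)
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    noise <- stats::rlnorm(length(depths), meanlog = -sdlog^2 / 2,
                           sdlog = sdlog)
  } else noise <- rep(1, length(depths))
  out <- data.frame(depth = depths, oc_observed = oc_true * noise)
  attr(out, "oc_true") <- oc_true
  out
}

#' Compare a modelled profile with an observed core
#'
#' Root-mean-square error and mean bias of the model prediction at the
#' observation depths.
#'
#' @param predicted A solved [solve_column()] profile, or a numeric vector
#'   of predictions matching `core$depth`.
#' @param core A data.frame with columns `depth` and `oc_observed`
#'   (e.g. from [generate_toy_core()]).
#' @return A list with `rmse` and `bias` (predicted minus observed), both
#'   g C cm^-3 dry sediment, and `n` observations.
#' @export
evaluate_fit <- function(predicted, core) {
  stopifnot(is.data.frame(core),
            all(c("depth", "oc_observed") %in% names(core)))
  ok <- is.finite(core$depth) & is.finite(core$oc_observed)
  if (!any(ok)) stop("no overlapping observations to evaluate")
  pred <- if (inherits(predicted, "oc_profile")) {
    oc_at_depth(predicted, core$depth[ok])
  } else {
    rep_len(predicted, nrow(core))[ok]
  }
  resid <- pred - core$oc_observed[ok]
  list(rmse = sqrt(mean(resid^2)), bias = mean(resid), n = sum(ok))
}
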