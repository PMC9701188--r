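#' Radial elementary-effects design from Latin hypercube samples
#'
#' Builds the sampling design for the Morris Elementary Effects Test (EET):
#' `r` radial one-at-a-time groups, each consisting of one Latin-hypercube
#' base point and `M` perturbed points that differ from the base in exactly
#' one coordinate. The perturbed coordinate values are drawn from a second,
#' independent Latin hypercube (the radial variant), so each group `j`
#' supplies one finite-difference step `Delta_i^j` per parameter. Total
#' model cost is `N = r * (M + 1)` evaluations.
#'
#' @param ranges Named list of length-2 numeric vectors `c(low, high)`; the
#'   physical range of each parameter. All sampling happens in normalized
#'   `[0, 1]^M` space; ranges are used to map design points to physical
#'   units.
#' @param r Number of finite differences per parameter (default 30).
#' @param seed Integer seed; the design is reproducible under a fixed seed.
#' @return An object of class `"eet_design"`: `parameter_names`, `ranges`,
#'   `r`, `base_points` (`r x M`, normalized), `aux_points` (`r x M`
#'   perturbed coordinate values), `delta` (`r x M` steps, all nonzero),
#'   `n_points = r * (M + 1)`.
#' @export
eet_design <- function(ranges, r = 30, seed = 1) {
  stopifnot(is.list(ranges), length(ranges) >= 1, r >= 2)
  if (is.null(names(ranges)) || any(names(ranges) == ""))
    stop("'ranges' must be a named list")
  for (nm in names(ranges)) {
    rg <- ranges[[nm]]
    if (length(rg) != 2 || !all(is.finite(rg)) || rg[1] >= rg[2])
      stop("degenerate range for parameter '", nm, "'")
  }
  M <- length(ranges)
  set.seed(seed)
  X <- lhs::randomLHS(2 * r, M)
  base <- X[seq_len(r), , drop = FALSE]
  aux <- X[r + seq_len(r), , drop = FALSE]
  delta <- aux - base
  # LHS makes exact coincidences measure-zero, but guard anyway
  tiny <- abs(delta) < 1e-9
  if (any(tiny)) {
    aux[tiny] <- (base[tiny] + 0.5) %% 1
    delta <- aux - base
  }
  colnames(base) <- colnames(aux) <- colnames(delta) <- names(ranges)
  structure(list(parameter_names = names(ranges), ranges = ranges, r = r,
                 seed = seed, base_points = base, aux_points = aux,
                 delta = delta, n_points = r * (M + 1L)),
            class = "eet_design")
}

#' @export
print.eet_design <- function(x, ...) {
  cat(sprintf("EET radial design: M = %d parameters (%s), r = %d groups, N = %d evaluations\n",
              length(x$parameter_names),
              paste(x$parameter_names, collapse = ", "), x$r, x$n_points))
  invisible(x)
}

# map normalized [0,1] coordinates to physical units
.eet_physical <- function(design, x) {
  lows <- vapply(design$ranges, `[`, 0, 1)
  highs <- vapply(design$ranges, `[`, 0, 2)
  stats::setNames(lows + x * (highs - lows), design$parameter_names)
}

#' Elementary effects of a model over a design
#'
#' Evaluates the model at every design point and forms, for each parameter
#' `i` and group `j`, the elementary effect
#' `EE_i^j = (g(x^j with x_i + Delta_i^j) - g(x^j)) / Delta_i^j` in
#' normalized units. The mean of the `EE_i^j` over groups is the
#' sensitivity index `S_i`; their standard deviation measures the degree of
#' interaction of parameter `i` with the others. Both are relative
#' measures: they rank parameter influence but their absolute values carry
#' no meaning.
#'
#' @param model A function taking a named numeric vector of physical
#'   parameter values and returning a finite scalar.
#' @param design An [eet_design()].
#' @return An `r x M` matrix of elementary effects (class `"eet_effects"`),
#'   with the model outputs attached as attribute `"g"`.
#' @export
elementary_effects <- function(model, design) {
  stopifnot(is.function(model), inherits(design, "eet_design"))
  r <- design$r
  M <- length(design$parameter_names)
  g_base <- numeric(r)
  ee <- matrix(NA_real_, r, M, dimnames = list(NULL, design$parameter_names))
  for (j in seq_len(r)) {
    xb <- design$base_points[j, ]
    g_base[j] <- model(.eet_physical(design, xb))
    if (!is.finite(g_base[j]))
      stop("non-finite model output at base point of group ", j)
    for (i in seq_len(M)) {
      xp <- xb
      xp[i] <- design$aux_points[j, i]
      gp <- model(.eet_physical(design, xp))
      if (!is.finite(gp))
        stop("non-finite model output at perturbed point (group ", j,
             ", parameter '", design$parameter_names[i], "')")
      ee[j, i] <- (gp - g_base[j]) / design$delta[j, i]
    }
  }
  structure(ee, class = c("eet_effects", "matrix"), g = g_base)
}

#' Sensitivity indices with bootstrap confidence bounds
#'
#' Summarises elementary effects into per-parameter mean (`s_mean`) and
#' standard deviation (`s_std`), ranks parameters by `|s_mean|`, and
#' attaches bootstrap percentile confidence intervals obtained by
#' resampling the `r` groups with replacement.
#'
#' @param ee An [elementary_effects()] matrix.
#' @param n_boot Bootstrap replicates (>= 100; default 1000).
#' @param seed Integer seed for the resampling.
#' @param conf Confidence level (default 0.95).
#' @return An object of class `"eet_result"`: `s_mean`, `s_abs_mean`,
#'   `s_std`, `ranking` (parameter names by decreasing `|s_mean|`),
#'   `ci_low`/`ci_high`, and the `n_boot x M` matrix of bootstrap means
#'   (`boot_means`) for stability analyses.
#' @export
eet_bootstrap <- function(ee, n_boot = 1000, seed = 1, conf = 0.95) {
  stopifnot(is.matrix(ee))
  r <- nrow(ee)
  if (r < 2) stop("need at least 2 elementary effects per parameter")
  if (n_boot < 100) stop("'n_boot' must be >= 100")
  s_mean <- colMeans(ee)
  s_std <- apply(ee, 2, stats::sd)
  set.seed(seed)
  idx <- matrix(sample.int(r, r * n_boot, replace = TRUE), n_boot, r)
  boot_means <- t(apply(idx, 1, function(ii) colMeans(ee[ii, , drop = FALSE])))
  colnames(boot_means) <- colnames(ee)
  alpha <- (1 - conf) / 2
  ci <- apply(boot_means, 2, stats::quantile, probs = c(alpha, 1 - alpha))
  structure(list(s_mean = s_mean, s_abs_mean = abs(s_mean), s_std = s_std,
                 ranking = colnames(ee)[order(abs(s_mean),
                                              decreasing = TRUE)],
                 ci_low = ci[1, ], ci_high = ci[2, ],
                 n_boot = n_boot, boot_means = boot_means),
            class = "eet_result")
}

#' @export
print.eet_result <- function(x, ...) {
  cat("Morris elementary-effects sensitivity (ranked by |mean EE|):\n")
  ord <- order(abs(x$s_mean), decreasing = TRUE)
  df <- data.frame(parameter = names(x$s_mean)[ord],
                   s_mean = x$s_mean[ord], s_std = x$s_std[ord],
                   ci_low = x$ci_low[ord], ci_high = x$ci_high[ord],
                   row.names = NULL)
  print(df, digits = 4)
  invisible(x)
}

#' @describeIn eet_bootstrap Tabulate an EET result (columns `parameter`,
#'   `s_mean`, `s_std`, `ci_low`, `ci_high`, `rank`) for CSV export.
#' @param x An `eet_result`.
#' @param ... Unused.
#' @export
as.data.frame.eet_result <- function(x, ...) {
  rank <- match(names(x$s_mean), x$ranking)
  data.frame(parameter = names(x$s_mean), s_mean = unname(x$s_mean),
             s_std = unname(x$s_std), ci_low = unname(x$ci_low),
             ci_high = unname(x$ci_high), rank = rank)
}

#' How often a parameter set occupies the top ranks across bootstrap
#' replicates
#'
#' @param result An [eet_bootstrap()] result.
#' @param parameters Character vector of parameter names.
#' @return Fraction of bootstrap replicates in which `parameters` are
#'   exactly the top-`length(parameters)` by absolute mean effect.
#' @export
top_set_stability <- function(result, parameters) {
  stopifnot(inherits(result, "eet_result"))
  k <- length(parameters)
  hits <- apply(result$boot_means, 1, function(m) {
    setequal(names(sort(abs(m), decreasing = TRUE))[seq_len(k)], parameters)
  })
  mean(hits)
}

#' Global sensitivity of gridded OC burial to the physical parameters
#'
#' Wires the EET machinery to the gridded pipeline: the model maps
#' (`phi`, `omega`, `z_bio`, `db`) to the global OC burial rate at a stated
#' depth horizon (default 1 mbsf). Porosity, sedimentation rate and
#' bioturbation are perturbed multiplicatively per grid cell over
#' `[1 - rel_range, 1 + rel_range]` (default +/-20% of the nominal field);
#' the bioturbation depth is set absolutely over `z_bio_range`
#' (default 1-15 cm, overriding both the normoxic default and the hypoxic
#' 1 cm).
#'
#' @param grid A [global_grid()].
#' @param config A [pipeline_config()]; `horizon` must be among its
#'   `depth_horizons`.
#' @param horizon Depth horizon (cm) of the burial output (default 100).
#' @param r Finite differences per parameter (default 30, giving
#'   `N = 150` pipeline runs for `M = 4`).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @param rel_range Fractional range for the multiplicative parameters.
#' @param z_bio_range Absolute range (cm) for the bioturbation depth.
#' @return An [eet_bootstrap()] result with the design attached as
#'   attribute `"design"`.
#' @export
burial_sensitivity <- function(grid, config = pipeline_config(),
                               horizon = 100, r = 30, n_boot = 1000,
                               seed = 1, rel_range = 0.2,
                               z_bio_range = c(1, 15)) {
  stopifnot(inherits(grid, "global_grid"))
  if (!horizon %in% config$depth_horizons)
    stop("'horizon' must be among config$depth_horizons")
  ranges <- list(phi = c(1 - rel_range, 1 + rel_range),
                 omega = c(1 - rel_range, 1 + rel_range),
                 z_bio = z_bio_range,
                 db = c(1 - rel_range, 1 + rel_range))
  design <- eet_design(ranges, r = r, seed = seed)
  model <- function(p) {
    res <- run_grid(grid, config, phi_mult = p[["phi"]],
                    omega_mult = p[["omega"]], db_mult = p[["db"]],
                    z_bio_override = p[["z_bio"]])
    integrate_burial(res, horizon, "depth")$burial[4]
  }
  ee <- elementary_effects(model, design)
  out <- eet_bootstrap(ee, n_boot = n_boot, seed = seed + 1L)
  attr(out, "design") <- design
  attr(out, "effects") <- ee
  out
}
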