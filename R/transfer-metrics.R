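#' Depth-referenced transfer efficiency
#'
#' Transfer efficiency through a stated depth horizon,
#' `T_eff(SWI -> z_ref) = 100 * F(z_ref) / F_SWI` (percent): the share of
#' the OC flux deposited through the sediment-water interface that still
#' transits the reference depth. Numerically identical to a depth-referenced
#' burial efficiency, but the horizon must be stated explicitly.
#'
#' @param profile A [solve_column()] result.
#' @param z_ref Reference depth horizon, cm (>= 0).
#' @return An object of class `"teff_result"`: list with `f_swi`,
#'   `horizon_type` (`"depth"`), `horizon_value`, `f_horizon` and `teff`
#'   (percent in `[0, 100]`).
#' @examples
#' env <- sediment_environment(omega = 0.1, phi = 0.7, oc0 = 0.01)
#' sp <- discretize_rcm(rcm_params(a = 0.1, nu = 0.125))
#' teff_depth(solve_column(env, sp), 100)
#' @export
teff_depth <- function(profile, z_ref) {
  stopifnot(inherits(profile, "oc_profile"), z_ref >= 0)
  f_swi <- flux_at_depth(profile, 0)
  if (f_swi <= 0) stop("F_SWI is zero: transfer efficiency undefined")
  f_h <- flux_at_depth(profile, z_ref)
  structure(list(f_swi = f_swi, horizon_type = "depth",
                 horizon_value = z_ref, f_horizon = f_h,
                 teff = 100 * f_h / f_swi),
            class = "teff_result")
}

#' Age-referenced transfer efficiency
#'
#' `T_eff(SWI -> t_ref) = 100 * F(z(t_ref)) / F_SWI`, where the age horizon
#' is mapped to depth by steady-state plug flow, `z = omega * t` (see
#' [age_to_depth()]). For example `teff_age(profile, 1e5)` is the percentage
#' of deposited OC that has survived 100 ka of burial.
#'
#' @param profile A [solve_column()] result.
#' @param t_ref Reference age horizon, years (>= 0).
#' @return A `"teff_result"` (see [teff_depth()]) with
#'   `horizon_type = "age"`.
#' @export
teff_age <- function(profile, t_ref) {
  stopifnot(inherits(profile, "oc_profile"), t_ref >= 0)
  f_swi <- flux_at_depth(profile, 0)
  if (f_swi <= 0) stop("F_SWI is zero: transfer efficiency undefined")
  z <- age_to_depth(profile$environment, t_ref)
  f_h <- flux_at_depth(profile, z)
  structure(list(f_swi = f_swi, horizon_type = "age",
                 horizon_value = t_ref, f_horizon = f_h,
                 teff = 100 * f_h / f_swi),
            class = "teff_result")
}

#' @export
print.teff_result <- function(x, ...) {
  unit <- if (x$horizon_type == "depth") "cm" else "yr"
  cat(sprintf("T_eff(SWI -> %g %s) = %.4g%%  (F_SWI = %.4g, F_horizon = %.4g g C cm-2 yr-1)\n",
              x$horizon_value, unit, x$teff, x$f_swi, x$f_horizon))
  invisible(x)
}

#' Map a sediment age to a depth (and back)
#'
#' Steady-state plug-flow conversion `z = omega * t`. Bioturbation makes
#' particle age ill-defined inside the mixed layer; the plug-flow mapping is
#' applied everywhere for horizon conversion, consistent with steady-state
#' flux accounting.
#'
#' @param env A [sediment_environment()].
#' @param t Sediment age (transit time since deposition), years (>= 0).
#' @return Depth below seafloor, cm.
#' @export
age_to_depth <- function(env, t) {
  stopifnot(inherits(env, "sediment_environment"))
  if (any(t < 0)) stop("'t' must be >= 0")
  env$omega * t
}

#' @rdname age_to_depth
#' @param z Depth below seafloor, cm (>= 0).
#' @export
depth_to_age <- function(env, z) {
  stopifnot(inherits(env, "sediment_environment"))
  if (any(z < 0)) stop("'z' must be >= 0")
  z / env$omega
}

#' Sweep transfer efficiency over horizon grids
#'
#' Evaluates `T_eff` over log-spaced depth and/or age horizons (defaults:
#' depth 1-1000 cm, 25 points; age 10-1e6 yr, 26 points).
#'
#' @param profile A [solve_column()] result.
#' @param depths Depth horizons, cm, or `NULL` to skip.
#' @param ages Age horizons, years, or `NULL` to skip.
#' @return A data.frame with columns `horizon_type`, `horizon`, `f_horizon`
#'   and `teff`.
#' @export
teff_sweep <- function(profile,
                       depths = 10^seq(0, 3, length.out = 25),
                       ages = 10^seq(1, 6, length.out = 26)) {
  stopifnot(inherits(profile, "oc_profile"))
  out <- list()
  if (!is.null(depths)) {
    rs <- lapply(depths, function(z) teff_depth(profile, z))
    out$depth <- data.frame(horizon_type = "depth", horizon = depths,
                            f_horizon = vapply(rs, `[[`, 0, "f_horizon"),
                            teff = vapply(rs, `[[`, 0, "teff"))
  }
  if (!is.null(ages)) {
    rs <- lapply(ages, function(t) teff_age(profile, t))
    out$age <- data.frame(horizon_type = "age", horizon = ages,
                          f_horizon = vapply(rs, `[[`, 0, "f_horizon"),
                          teff = vapply(rs, `[[`, 0, "teff"))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
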