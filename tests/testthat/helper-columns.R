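# shared fixtures: representative columns and spectra built in code

shelf_env <- function(...) {
  sediment_environment(omega = 0.1, phi = 0.7, oc0 = 0.01, db = 10,
                       z_bio = 10, zone = "shelf", ...)
}
margin_env <- function(...) {
  sediment_environment(omega = 0.01, phi = 0.75, oc0 = 0.005, db = 1,
                       z_bio = 10, zone = "margin", ...)
}
abyss_env <- function(...) {
  sediment_environment(omega = 0.001, phi = 0.85, oc0 = 0.002, db = 0.05,
                       z_bio = 10, zone = "abyss", ...)
}

zone_rcm <- function(zone) {
  a <- c(shelf = 0.1, margin = 1.0, abyss = 20.0)[[zone]]
  rcm_params(a = a, nu = 0.125)
}

# a degenerate spectrum holding a single active fraction with rate k
# (k = 0 allowed); exercises the solver's closed-form limits
single_fraction_spectrum <- function(k) {
  structure(list(k_values = c(0, k), fractions = c(0, 1),
                 bin_edges = c(0, max(k / 2, 1e-32), k + 1),
                 params = list(n_bins = 2L)),
            class = "multig_spectrum")
}

# independent quadrature oracle for the Gamma reactivity CDF
quad_cdf <- function(a, nu, k) {
  if (k <= 0) return(0)
  stats::integrate(function(x) x^(nu - 1) * exp(-x), 0, a * k,
                   rel.tol = 1e-12)$value / gamma(nu)
}
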