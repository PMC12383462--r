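#' Effective neuronal Planck constant
#'
#' The action scale of the quantum-like reformulation. Two routes are
#' provided, mirroring the two definitions in circulation and tagged by
#' provenance so neither is silently preferred:
#' `hbar_from_diffusion()` sets \eqn{\hat\hbar = \sqrt{2D}} from the voltage
#' noise intensity; `hbar_from_moments()` sets \eqn{\hat\hbar = m \sigma}
#' from an effective inertial parameter and the standard deviation of
#' subthreshold voltage fluctuations. The two definitions do not coincide in
#' general (for an Ornstein-Uhlenbeck voltage with rate `k`,
#' \eqn{\sqrt{2D} \ne m\sqrt{D/k}} unless `m^2 = 2k`).
#'
#' @param value Nonnegative numeric value.
#' @param provenance One of `"from_diffusion"`, `"from_moments"`, `"user"`.
#' @return An object of class `hbar_eff` (a numeric scalar with a
#'   `provenance` attribute).
#' @examples
#' hbar_from_diffusion(0.05) # sqrt(0.1) = 0.3162278
#' hbar_from_moments(1, 0.3) # 0.3
#' @export
hbar_eff <- function(value, provenance = "user") {
  check_nonnegative(value, "value")
  provenance <- match.arg(provenance,
                          c("user", "from_diffusion", "from_moments"))
  structure(value, provenance = provenance, class = "hbar_eff")
}

#' @rdname hbar_eff
#' @param d_noise Voltage noise intensity `D >= 0`.
#' @export
hbar_from_diffusion <- function(d_noise) {
  check_nonnegative(d_noise, "d_noise")
  hbar_eff(sqrt(2 * d_noise), provenance = "from_diffusion")
}

#' @rdname hbar_eff
#' @param mass Effective inertial parameter `m > 0`.
#' @param sigma Standard deviation of the membrane voltage (`>= 0`).
#' @export
hbar_from_moments <- function(mass, sigma) {
  check_positive(mass, "mass")
  check_nonnegative(sigma, "sigma")
  hbar_eff(mass * sigma, provenance = "from_moments")
}

#' @export
print.hbar_eff <- function(x, ...) {
  cat(sprintf("<hbar_eff> %.6g (%s)\n", unclass(x), attr(x, "provenance")))
  invisible(x)
}

as_hbar <- function(x, name = "hbar") {
  if (inherits(x, "hbar_eff")) return(x)
  check_nonnegative(x, name)
  hbar_eff(x)
}

#' Osmotic velocity of a voltage density
#'
#' Nelson's osmotic velocity \eqn{u(v) = D\,\partial_v \log\rho}, computed
#' by centered finite differences of `log(rho)` (one-sided at the walls).
#' Cells with density below `floor` are masked (`u = NA`) rather than
#' extrapolated. The companion current velocity is the deterministic drift
#' itself, available from [fhn_drift()].
#'
#' @param density A `density_estimate` or `fp_solution` (tibble with `v` and
#'   a density column).
#' @param d_noise Diffusion coefficient `D`.
#' @param floor Densities below this are masked.
#' @return A tibble with columns `v`, `u`, `masked`.
#' @examples
#' g <- voltage_grid(4, 256)
#' u <- osmotic_velocity(fp_gaussian(g, 0, 1), d_noise = 0.05)
#' @export
osmotic_velocity <- function(density, d_noise, floor = 1e-12) {
  check_nonnegative(d_noise, "d_noise")
  rho <- density_column(density)
  v <- density$v
  if (all(rho <= floor)) abort_domain("density is zero everywhere.")
  n <- length(rho)
  logr <- ifelse(rho > floor, log(pmax(rho, floor)), NA_real_)
  u <- rep(NA_real_, n)
  u[2:(n - 1)] <- (logr[3:n] - logr[1:(n - 2)]) / (v[3:n] - v[1:(n - 2)])
  u[1] <- (logr[2] - logr[1]) / (v[2] - v[1])
  u[n] <- (logr[n] - logr[n - 1]) / (v[n] - v[n - 1])
  u <- d_noise * u
  tibble::tibble(v = v, u = u, masked = !is.finite(u))
}

density_column <- function(x) {
  if (!is.data.frame(x) || !"v" %in% names(x)) {
    abort_domain("expected a tibble with a `v` column and a density column.")
  }
  col <- intersect(c("rho", "density"), names(x))[1]
  if (is.na(col)) abort_domain("no `rho` or `density` column found.")
  x[[col]]
}

#' Effective potential of the Schrodinger-type voltage equation
#'
#' Tabulates \deqn{V_{\mathrm{eff}}(v; w_0) = \tfrac12 f(v, w_0)^2 -
#' \tfrac{\hat\hbar}{2}\,\partial_v f(v, w_0)} on a voltage grid, with the
#' FHN drift `f = v - v^3/3 - w0 + i_ext` and its analytic derivative
#' `1 - v^2`. The recovery variable is frozen at `w0` (it enters the
#' one-dimensional equation parametrically).
#'
#' @param params An [fhn_params()] object.
#' @param w0 Frozen recovery value.
#' @param hbar An `hbar_eff` or nonnegative numeric.
#' @param grid A [voltage_grid()].
#' @return An `effective_potential`: tibble (`v`, `v_eff`) with attributes
#'   `grid`, `w0`, `hbar`.
#' @examples
#' effective_potential(fhn_params(), w0 = 0,
#'                     hbar = hbar_from_diffusion(0.05), grid = voltage_grid())
#' @export
effective_potential <- function(params, w0, hbar, grid = voltage_grid()) {
  stopifnot(inherits(params, "fhn_params"), inherits(grid, "voltage_grid"))
  check_scalar(w0, "w0")
  hbar <- as_hbar(hbar)
  v <- grid$centers
  f <- v - v^3 / 3 - w0 + params$i_ext
  vals <- 0.5 * f^2 - (as.numeric(hbar) / 2) * (1 - v^2)
  check_finite(vals, "v_eff")
  new_effective_potential(grid, vals, w0 = w0, hbar = hbar)
}

#' Effective potential from arbitrary tabulated values
#'
#' Low-level constructor used for closed-form benchmark potentials (free
#' particle, harmonic well).
#'
#' @param grid A [voltage_grid()].
#' @param values Potential values at the cell centers.
#' @param w0 Recovery value the table corresponds to, if any.
#' @param hbar Action scale the table was built with, if any.
#' @return An `effective_potential` tibble.
#' @export
new_effective_potential <- function(grid, values, w0 = NA_real_,
                                    hbar = NULL) {
  stopifnot(inherits(grid, "voltage_grid"))
  check_finite(values, "values")
  if (length(values) != grid$n_cells) {
    abort_domain("`values` must have length n_cells.")
  }
  out <- tibble::tibble(v = grid$centers, v_eff = values)
  class(out) <- c("effective_potential", class(out))
  attr(out, "grid") <- grid
  attr(out, "w0") <- w0
  attr(out, "hbar") <- hbar
  out
}
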