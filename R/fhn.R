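#' FitzHugh-Nagumo model parameters
#'
#' Bundles the constants of the stochastic FitzHugh-Nagumo (FHN) neuron
#'
#' \deqn{dv = (v - v^3/3 - w + I_{ext})\,dt + \sqrt{2D}\,dW_t}
#' \deqn{dw = \frac{v + a - b w}{\tau}\,dt}
#'
#' where `v` is the fast membrane potential, `w` the slow recovery variable,
#' and `D` the intensity of the additive Gaussian white noise on the voltage.
#' The recovery variable carries no noise term. All quantities are in
#' dimensionless model units.
#'
#' The defaults `a = 0.7`, `b = 0.8`, `tau = 12.5` are the classic excitable
#' regime of the FHN literature.
#'
#' @param a Recovery offset (dimensionless).
#' @param b Recovery gain (dimensionless).
#' @param tau Slow time constant; must be positive.
#' @param i_ext External current (dimensionless).
#' @param d_noise Noise intensity `D` (voltage^2 / time); must be >= 0.
#'
#' @return An object of class `fhn_params`.
#' @examples
#' fhn_params()
#' fhn_params(i_ext = 0.5, d_noise = 0.05)
#' @export
fhn_params <- function(a = 0.7, b = 0.8, tau = 12.5, i_ext = 0, d_noise = 0) {
  check_scalar(a, "a")
  check_scalar(b, "b")
  check_positive(tau, "tau")
  check_scalar(i_ext, "i_ext")
  check_nonnegative(d_noise, "d_noise")
  structure(
    list(a = a, b = b, tau = tau, i_ext = i_ext, d_noise = d_noise),
    class = "fhn_params"
  )
}

#' @export
print.fhn_params <- function(x, ...) {
  cat("<fhn_params>",
      sprintf("a = %g, b = %g, tau = %g, i_ext = %g, D = %g\n",
              x$a, x$b, x$tau, x$i_ext, x$d_noise))
  invisible(x)
}

#' Uniform time grid for trajectory integration
#'
#' @param dt Step size (> 0).
#' @param n_steps Number of steps (positive integer). Exactly one of
#'   `n_steps` and `t_final` must be given.
#' @param t_final Final time; converted to `n_steps = round(t_final / dt)`.
#'
#' @return An object of class `time_grid` with fields `dt`, `n_steps`,
#'   `t_final` and the `times` vector of length `n_steps + 1`.
#' @examples
#' time_grid(dt = 0.05, t_final = 100)
#' @export
time_grid <- function(dt, n_steps = NULL, t_final = NULL) {
  check_positive(dt, "dt")
  if (is.null(n_steps) == is.null(t_final)) {
    abort_config("supply exactly one of `n_steps` or `t_final`.")
  }
  if (is.null(n_steps)) n_steps <- round(t_final / dt)
  n_steps <- check_count(n_steps, "n_steps")
  structure(
    list(dt = dt, n_steps = n_steps, t_final = dt * n_steps,
         times = dt * (0:n_steps)),
    class = "time_grid"
  )
}

#' Deterministic FHN drift fields
#'
#' Evaluates the drift of both state variables,
#' `f = v - v^3/3 - w + i_ext` and `g = (v + a - b w) / tau`.
#' Inputs are vectorised and recycled in the usual way.
#'
#' @param v Membrane potential value(s).
#' @param w Recovery variable value(s).
#' @param params An [fhn_params()] object.
#'
#' @return A tibble with columns `f` (voltage rate) and `g` (recovery rate).
#' @examples
#' fhn_drift(0, 0, fhn_params())   # f = 0, g = 0.056
#' fhn_drift(1, 0, fhn_params())$f # 2/3
#' @export
fhn_drift <- function(v, w, params = fhn_params()) {
  check_finite(v, "v")
  check_finite(w, "w")
  stopifnot(inherits(params, "fhn_params"))
  tibble::tibble(
    f = v - v^3 / 3 - w + params$i_ext,
    g = (v + params$a - params$b * w) / params$tau
  )
}

#' Fixed points of the noise-free FHN system
#'
#' Solves `f = g = 0` for the deterministic system (`d_noise` is ignored).
#' Setting `g = 0` gives `w = (v + a)/b`; substituting into `f = 0` leaves the
#' cubic `v - v^3/3 - (v + a)/b + i_ext = 0`, whose real roots are found with
#' [polyroot()] and polished by Newton iteration.
#'
#' @param params An [fhn_params()] object.
#' @param tol Residual tolerance on `max(|f|, |g|)` at the returned roots.
#'
#' @return A tibble with one row per real fixed point (columns `v`, `w`,
#'   `residual`), ordered by `v`.
#' @examples
#' fhn_fixed_point(fhn_params())             # single root near v = -1.2
#' fhn_fixed_point(fhn_params(a = 0, b = 1)) # (0, 0) among the roots
#' @export
fhn_fixed_point <- function(params = fhn_params(), tol = 1e-10) {
  stopifnot(inherits(params, "fhn_params"))
  # coefficients of -v^3/3 + (1 - 1/b) v + (i_ext - a/b), ascending order
  coefs <- c(params$i_ext - params$a / params$b, 1 - 1 / params$b, 0, -1 / 3)
  roots <- polyroot(coefs)
  v <- sort(unique(Re(roots[abs(Im(roots)) < 1e-7])))
  cubic <- function(x) x - x^3 / 3 - (x + params$a) / params$b + params$i_ext
  dcubic <- function(x) 1 - x^2 - 1 / params$b
  for (i in seq_len(50)) {
    fv <- cubic(v)
    dv <- dcubic(v)
    step <- ifelse(fv == 0 | abs(dv) < 1e-12, 0, fv / dv)
    v <- v - step
    if (all(abs(step) < 1e-15)) break
  }
  w <- (v + params$a) / params$b
  dr <- fhn_drift(v, w, params)
  residual <- pmax(abs(dr$f), abs(dr$g))
  if (any(residual > tol)) {
    abort_numeric(sprintf(
      "fixed-point refinement did not reach tolerance (max residual %.3e).",
      max(residual)))
  }
  tibble::tibble(v = v, w = w, residual = residual)
}
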