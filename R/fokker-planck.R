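#' Cell-centered voltage grid
#'
#' Symmetric finite-volume grid on `[-v_max, v_max]` with `n_cells` cells of
#' width `dv = 2 v_max / n_cells` and centers
#' `v_j = -v_max + (j + 1/2) dv`. Shared by the Fokker-Planck and
#' Schrodinger-type solvers.
#'
#' @param v_max Half-width of the voltage window (default 3).
#' @param n_cells Number of cells (default 512, which resolves
#'   features at the default initial-state width on `[-3, 3]`).
#'
#' @return An object of class `voltage_grid` with fields `v_max`, `n_cells`,
#'   `dv`, `centers`.
#' @examples
#' g <- voltage_grid(3, 512)
#' range(g$centers)
#' @export
voltage_grid <- function(v_max = 3, n_cells = 512L) {
  check_positive(v_max, "v_max")
  n_cells <- check_count(n_cells, "n_cells", min = 2L)
  dv <- 2 * v_max / n_cells
  structure(
    list(v_max = v_max, n_cells = n_cells, dv = dv,
         centers = -v_max + (seq_len(n_cells) - 0.5) * dv),
    class = "voltage_grid"
  )
}

#' @export
print.voltage_grid <- function(x, ...) {
  cat(sprintf("<voltage_grid> [-%g, %g], %d cells, dv = %g\n",
              x$v_max, x$v_max, x$n_cells, x$dv))
  invisible(x)
}

same_grid <- function(a, b) {
  a$n_cells == b$n_cells && abs(a$v_max - b$v_max) < 1e-12
}

new_fp_solution <- function(grid, rho, time, d_noise = NA_real_,
                            w0 = NA_real_) {
  out <- tibble::tibble(v = grid$centers, rho = rho)
  class(out) <- c("fp_solution", class(out))
  attr(out, "grid") <- grid
  attr(out, "time") <- time
  attr(out, "d_noise") <- d_noise
  attr(out, "w0") <- w0
  out
}

#' Initial densities on a voltage grid
#'
#' `fp_delta()` represents a point mass at `v0` (the point-initial-condition
#' counterpart of a trajectory ensemble started at `v0`), splitting the mass
#' between the two nearest cell centers so the discrete first moment equals
#' `v0` exactly (no half-cell shift when `v0` is off-center);
#' `fp_gaussian()` is a grid-renormalised Gaussian.
#'
#' @param grid A [voltage_grid()].
#' @param v0 Location of the point mass.
#' @param mean,sd Gaussian parameters.
#' @return An `fp_solution` at time 0 with unit mass.
#' @examples
#' fp_delta(voltage_grid(3, 64), v0 = -1.2)
#' @export
fp_delta <- function(grid, v0) {
  stopifnot(inherits(grid, "voltage_grid"))
  check_scalar(v0, "v0")
  if (abs(v0) > grid$v_max) abort_domain("`v0` lies outside the grid.")
  rho <- numeric(grid$n_cells)
  pos <- (v0 - grid$centers[1]) / grid$dv
  jl <- max(0L, min(grid$n_cells - 1L, floor(pos)))
  wr <- min(1, max(0, pos - jl))
  rho[jl + 1L] <- (1 - wr) / grid$dv
  if (wr > 0 && jl + 2L <= grid$n_cells) rho[jl + 2L] <- wr / grid$dv
  rho <- rho / sum(rho * grid$dv)
  new_fp_solution(grid, rho, time = 0)
}

#' @rdname fp_delta
#' @export
fp_gaussian <- function(grid, mean = 0, sd = 0.2) {
  stopifnot(inherits(grid, "voltage_grid"))
  check_scalar(mean, "mean")
  check_positive(sd, "sd")
  rho <- stats::dnorm(grid$centers, mean, sd)
  new_fp_solution(grid, rho / sum(rho * grid$dv), time = 0)
}

# Drift evaluated at the n_cells - 1 interior faces. `drift` may be a
# function of v or a per-cell vector (then faces take adjacent-cell means).
drift_at_faces <- function(drift, grid) {
  faces <- grid$centers[-grid$n_cells] + grid$dv / 2
  if (is.function(drift)) {
    f <- drift(faces)
  } else {
    check_finite(drift, "drift")
    if (length(drift) != grid$n_cells) {
      abort_domain("per-cell `drift` must have length n_cells.")
    }
    f <- (drift[-1] + drift[-grid$n_cells]) / 2
  }
  check_finite(f, "drift at faces")
  f
}

# Chang-Cooper face weight delta(x), x = f dv / D: the flux
#   F = f [ delta rho_j + (1 - delta) rho_{j+1} ] - D (rho_{j+1} - rho_j)/dv
# vanishes identically when rho_{j+1}/rho_j = exp(x), giving exact discrete
# stationarity and positivity.
cc_delta <- function(x) {
  d <- ifelse(abs(x) < 1e-4,
              0.5 + x / 12 - x^3 / 720,
              1 + 1 / expm1(x) - 1 / x)
  d[!is.finite(x)] <- ifelse(x[!is.finite(x)] > 0, 1, 0)
  d
}

cc_flux <- function(rho, f_face, d_noise, dv) {
  n <- length(rho)
  if (d_noise > 0) {
    delta <- cc_delta(f_face * dv / d_noise)
  } else {
    delta <- ifelse(f_face > 0, 1, 0) # pure advection: upwind
  }
  f_face * (delta * rho[-n] + (1 - delta) * rho[-1]) -
    d_noise * (rho[-1] - rho[-n]) / dv
}

#' Admissible explicit time step for the Fokker-Planck scheme
#'
#' Stability bound `dv^2 / (2 D + max|f| dv)` for the explicit conservative
#' update; [fp_evolve()] refuses larger steps.
#'
#' @param drift Per-cell drift vector or function of `v`.
#' @param d_noise Diffusion coefficient `D`.
#' @param grid A [voltage_grid()].
#' @return The largest admissible `dt`.
#' @export
fp_stable_dt <- function(drift, d_noise, grid) {
  f_face <- drift_at_faces(drift, grid)
  grid$dv^2 / (2 * d_noise + max(abs(f_face)) * grid$dv)
}

#' Evolve a density under the 1-D Fokker-Planck equation
#'
#' Solves \eqn{\partial_t \rho = -\partial_v [f(v)\rho] + D \partial_v^2 \rho}
#' on the bounded window of `rho0`'s grid with no-flux (reflecting)
#' boundaries: the probability current through both walls is identically
#' zero in the discrete scheme, so mass is conserved exactly. The spatial
#' discretisation is a conservative cell-centered finite volume with
#' Chang-Cooper face weighting (positivity-preserving, exactly stationary on
#' the zero-flux equilibrium); time stepping is explicit with a checked
#' stability bound.
#'
#' The slow FHN recovery variable enters only parametrically: pass the
#' voltage drift at a frozen `w0`, e.g.
#' `function(v) fhn_drift(v, w0, params)$f`.
#'
#' @param rho0 Initial `fp_solution` (normalised).
#' @param drift Per-cell drift values on `rho0`'s grid, or a function of `v`
#'   (evaluated at cell faces).
#' @param d_noise Diffusion coefficient `D >= 0`.
#' @param dt Time step; defaults to 90% of [fp_stable_dt()].
#' @param n_steps Number of steps. Give either `n_steps` or `t_final`.
#' @param t_final Target time; the step count is `ceiling(t_final / dt)` with
#'   `dt` shrunk to land exactly on `t_final`.
#'
#' @return An `fp_solution` at the advanced time. Tiny negative densities
#'   from round-off (never below `-1e-12`) are clamped to zero and the
#'   clamped mass recorded in attribute `clamped_mass`.
#' @examples
#' g <- voltage_grid(3, 128)
#' rho <- fp_evolve(fp_gaussian(g, 0, 0.3), drift = function(v) -v,
#'                  d_noise = 0.05, t_final = 10)
#' sum(rho$rho * g$dv)
#' @export
fp_evolve <- function(rho0, drift, d_noise, dt = NULL, n_steps = NULL,
                      t_final = NULL) {
  stopifnot(inherits(rho0, "fp_solution"))
  check_nonnegative(d_noise, "d_noise")
  grid <- attr(rho0, "grid")
  f_face <- drift_at_faces(drift, grid)
  dt_max <- grid$dv^2 / (2 * d_noise + max(abs(f_face)) * grid$dv)
  if (is.null(dt)) dt <- 0.9 * dt_max
  check_positive(dt, "dt")
  if (dt > dt_max) {
    abort_numeric(sprintf(
      "explicit step dt = %g violates the stability bound; use dt <= %g.",
      dt, dt_max))
  }
  if (is.null(n_steps) == is.null(t_final)) {
    abort_config("supply exactly one of `n_steps` or `t_final`.")
  }
  if (is.null(n_steps)) {
    n_steps <- max(1L, ceiling(t_final / dt))
    dt <- t_final / n_steps
  }
  n_steps <- check_count(n_steps, "n_steps")

  rho <- rho0$rho
  dv <- grid$dv
  for (k in seq_len(n_steps)) {
    flux <- c(0, cc_flux(rho, f_face, d_noise, dv), 0) # zero wall flux
    rho <- rho - dt / dv * diff(flux)
  }
  clamped <- 0
  if (any(rho < 0)) {
    if (min(rho) < -1e-12) {
      abort_numeric(sprintf(
        "scheme produced negative density %.3e beyond tolerance.", min(rho)))
    }
    clamped <- -sum(rho[rho < 0]) * dv
    rho[rho < 0] <- 0
  }
  out <- new_fp_solution(grid, rho, time = attr(rho0, "time") + dt * n_steps,
                         d_noise = d_noise)
  attr(out, "clamped_mass") <- clamped
  out
}

#' Stationary zero-flux Fokker-Planck density
#'
#' Closed-form discrete stationary solution
#' \eqn{\rho_s \propto \exp\!\big(\int f/D\,dv\big)}, built so that the
#' Chang-Cooper face flux of [fp_evolve()] vanishes exactly:
#' `log rho_{j+1} - log rho_j = f_face dv / D`.
#'
#' @inheritParams fp_evolve
#' @param grid A [voltage_grid()].
#' @return A normalised `fp_solution` (attribute `time = Inf`).
#' @examples
#' s <- fp_stationary(function(v) -v, d_noise = 0.05, grid = voltage_grid())
#' sum(s$v^2 * s$rho * attr(s, "grid")$dv) # ~ 0.05 (OU variance D/k)
#' @export
fp_stationary <- function(drift, d_noise, grid) {
  stopifnot(inherits(grid, "voltage_grid"))
  if (!is.numeric(d_noise) || length(d_noise) != 1 || d_noise <= 0) {
    abort_domain("`fp_stationary()` requires D > 0.")
  }
  f_face <- drift_at_faces(drift, grid)
  log_rho <- cumsum(c(0, f_face * grid$dv / d_noise))
  log_rho <- log_rho - max(log_rho)
  rho <- exp(log_rho)
  out <- new_fp_solution(grid, rho / sum(rho * grid$dv), time = Inf,
                         d_noise = d_noise)
  out
}
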