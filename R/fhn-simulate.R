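#' Euler-Maruyama ensemble of stochastic FHN trajectories
#'
#' Integrates the stochastic FHN system forward with the explicit
#' Euler-Maruyama scheme,
#' \deqn{v_{k+1} = v_k + f(v_k, w_k)\,dt + \sqrt{2 D\, dt}\,\xi_k,\qquad
#'       w_{k+1} = w_k + g(v_k, w_k)\,dt,}
#' with \eqn{\xi_k} i.i.d. standard normal. Only the voltage receives noise;
#' the noise amplitude follows the \eqn{\sqrt{2D}\,dW} convention.
#'
#' Reproducibility uses per-trajectory substreams: trajectory `i` draws its
#' Gaussian increments from a generator seeded with `seed + i`. Trajectory
#' `i` is therefore bit-identical whatever `n_traj` is, so ensembles can be
#' grown without perturbing earlier paths. Trajectories are not reflected at
#' any voltage boundary; reflecting walls are a property of the PDE solvers
#' only.
#'
#' @param params An [fhn_params()] object (noise intensity `d_noise` is `D`).
#' @param grid A [time_grid()].
#' @param n_traj Number of trajectories (>= 1).
#' @param v0,w0 Initial condition shared by all trajectories.
#' @param seed Integer root seed.
#' @param record `"all"` stores every time point (`n_traj x (n_steps+1)`
#'   matrices); `"final"` stores only the initial and final columns, which is
#'   enough for terminal-density work and much lighter at large `n_traj`.
#' @param drift Optional override: a function `(v, w, params)` returning a
#'   list/tibble with elements `f` and `g`. Used to integrate modified
#'   systems (e.g. the linearised drift `f = -v`, or zero drift for pure
#'   diffusion) with the same noise machinery. Default uses [fhn_drift()].
#' @param chunk_size Trajectories integrated per block (memory knob).
#'
#' @return An object of class `fhn_ensemble`: list with `times`, matrices
#'   `v` and `w` (`n_traj` rows), `seed`, `params`, `grid`, `record`.
#'   Use [tibble::as_tibble()] for a tidy (`traj_id`, `t`, `v`, `w`) view.
#' @examples
#' ens <- simulate_fhn_ensemble(fhn_params(d_noise = 0.05),
#'                              time_grid(0.05, t_final = 5),
#'                              n_traj = 10, v0 = -1.2, w0 = -0.62, seed = 1)
#' tibble::as_tibble(ens)
#' @export
simulate_fhn_ensemble <- function(params, grid, n_traj, v0, w0, seed,
                                  record = c("all", "final"),
                                  drift = NULL, chunk_size = 5000L) {
  stopifnot(inherits(params, "fhn_params"), inherits(grid, "time_grid"))
  n_traj <- check_count(n_traj, "n_traj")
  check_scalar(v0, "v0")
  check_scalar(w0, "w0")
  seed <- check_count(seed, "seed", min = 0L)
  record <- match.arg(record)
  if (is.null(drift)) {
    drift <- function(v, w, params) {
      list(f = v - v^3 / 3 - w + params$i_ext,
           g = (v + params$a - params$b * w) / params$tau)
    }
  }

  dt <- grid$dt
  n_steps <- grid$n_steps
  amp <- sqrt(2 * params$d_noise * dt)
  keep <- if (record == "all") 0:n_steps else c(0L, n_steps)
  v_out <- matrix(NA_real_, n_traj, length(keep))
  w_out <- matrix(NA_real_, n_traj, length(keep))

  for (start in seq(1L, n_traj, by = chunk_size)) {
    idx <- start:min(start + chunk_size - 1L, n_traj)
    m <- length(idx)
    xi <- matrix(0, n_steps, m)
    for (j in seq_len(m)) {
      set.seed(seed + idx[j])
      xi[, j] <- stats::rnorm(n_steps)
    }
    v <- rep(v0, m)
    w <- rep(w0, m)
    col <- 1L
    if (0L %in% keep) {
      v_out[idx, col] <- v
      w_out[idx, col] <- w
      col <- col + 1L
    }
    for (k in seq_len(n_steps)) {
      d <- drift(v, w, params)
      v <- v + d$f * dt + amp * xi[k, ]
      w <- w + d$g * dt
      if (!all(is.finite(v)) || !all(is.finite(w))) {
        abort_numeric(sprintf(
          "integration blow-up (non-finite state) at step %d (t = %g).",
          k, k * dt))
      }
      if (k %in% keep) {
        v_out[idx, col] <- v
        w_out[idx, col] <- w
        col <- col + 1L
      }
    }
  }

  structure(
    list(times = grid$times[keep + 1L], v = v_out, w = w_out,
         seed = seed, params = params, grid = grid, record = record),
    class = "fhn_ensemble"
  )
}

#' @export
print.fhn_ensemble <- function(x, ...) {
  cat(sprintf("<fhn_ensemble> %d trajectories, %d stored time points, seed %d\n",
              nrow(x$v), length(x$times), x$seed))
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.fhn_ensemble <- function(x, ...) {
  n_traj <- nrow(x$v)
  tibble::tibble(
    traj_id = rep(seq_len(n_traj), times = length(x$times)),
    t = rep(x$times, each = n_traj),
    v = as.vector(x$v),
    w = as.vector(x$w)
  )
}

#' Empirical voltage density of an ensemble at one time
#'
#' Normalised histogram of the membrane potential across trajectories at a
#' stored time point. Mass falling outside the requested voltage window is
#' reported in the `mass_outside` attribute, never silently clipped, so the
#' in-window integral plus `mass_outside` is exactly 1.
#'
#' @param ens An `fhn_ensemble`.
#' @param at_time Time at which to take the cross-section; must match a
#'   stored grid time to within `1e-9`.
#' @param bins A [voltage_grid()], or an integer bin count on the default
#'   window (then `v_max = 3`).
#'
#' @return A `density_estimate`: tibble with columns `v` (bin centers) and
#'   `density`, attributes `bin_width`, `time`, `mass_outside`, `n`.
#' @examples
#' ens <- simulate_fhn_ensemble(fhn_params(d_noise = 0.05),
#'                              time_grid(0.05, t_final = 5),
#'                              n_traj = 500, v0 = -1.2, w0 = -0.62, seed = 1)
#' d <- empirical_density(ens, at_time = 5, bins = voltage_grid(3, 60))
#' sum(d$density * attr(d, "bin_width")) + attr(d, "mass_outside")
#' @export
empirical_density <- function(ens, at_time, bins = voltage_grid()) {
  stopifnot(inherits(ens, "fhn_ensemble"))
  if (is.numeric(bins) && length(bins) == 1L) {
    bins <- voltage_grid(3, as.integer(bins))
  }
  stopifnot(inherits(bins, "voltage_grid"))
  j <- which(abs(ens$times - at_time) < 1e-9)
  if (length(j) != 1L) {
    abort_domain(sprintf(
      "`at_time` = %g is not a stored time point of the ensemble.", at_time))
  }
  v <- ens$v[, j]
  n <- length(v)
  edges <- c(bins$centers - bins$dv / 2, bins$v_max)
  inside <- v >= edges[1] & v <= edges[length(edges)]
  counts <- tabulate(findInterval(v[inside], edges, rightmost.closed = TRUE),
                     nbins = bins$n_cells)
  new_density_estimate(
    v = bins$centers,
    density = counts / (n * bins$dv),
    bin_width = bins$dv,
    time = at_time,
    mass_outside = sum(!inside) / n,
    n = n
  )
}

new_density_estimate <- function(v, density, bin_width, time = NA_real_,
                                 mass_outside = 0, n = NA_integer_) {
  out <- tibble::tibble(v = v, density = density)
  class(out) <- c("density_estimate", class(out))
  attr(out, "bin_width") <- bin_width
  attr(out, "time") <- time
  attr(out, "mass_outside") <- mass_outside
  attr(out, "n") <- n
  out
}
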