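#' Wavefunction on a voltage grid
#'
#' A complex amplitude vector \eqn{\psi(v_j)} at the cell centers of a
#' [voltage_grid()], carrying its action scale `hbar`, effective mass and
#' current time. Discrete normalisation is
#' \eqn{\sum_j |\psi_j|^2 \Delta v = 1}.
#'
#' @param grid A [voltage_grid()].
#' @param amplitudes Complex vector of length `n_cells`.
#' @param hbar An `hbar_eff` or positive numeric.
#' @param mass Effective mass (default 1, as in the dimensionless equation).
#' @param time Current time stamp.
#' @return An object of class `wavefunction`.
#' @export
wavefunction <- function(grid, amplitudes, hbar, mass = 1, time = 0) {
  stopifnot(inherits(grid, "voltage_grid"))
  if (length(amplitudes) != grid$n_cells) {
    abort_domain("`amplitudes` must have length n_cells.")
  }
  if (anyNA(amplitudes) || any(!is.finite(Mod(amplitudes)))) {
    abort_domain("`amplitudes` must be finite.")
  }
  check_positive(mass, "mass")
  structure(
    list(grid = grid, psi = as.complex(amplitudes), hbar = as_hbar(hbar),
         mass = mass, time = time),
    class = "wavefunction"
  )
}

#' @export
print.wavefunction <- function(x, ...) {
  cat(sprintf(
    "<wavefunction> %d cells on [-%g, %g], hbar = %.4g, m = %g, t = %g, norm = %.6f\n",
    x$grid$n_cells, x$grid$v_max, x$grid$v_max, as.numeric(x$hbar), x$mass,
    x$time, wf_norm(x)))
  invisible(x)
}

#' @export
as_tibble.wavefunction <- function(x, ...) {
  tibble::tibble(v = x$grid$centers, re = Re(x$psi), im = Im(x$psi),
                 rho = Mod(x$psi)^2)
}

#' Discrete norm, moments and density of a wavefunction
#'
#' `wf_norm()` returns \eqn{\sum |\psi|^2 \Delta v}; `wf_moments()` the mean
#' and standard deviation of the Born density; `wf_density()` the Born
#' density \eqn{|\psi|^2} as a `density_estimate` tibble comparable with
#' empirical and Fokker-Planck densities.
#'
#' @param psi A `wavefunction`.
#' @return See details.
#' @export
wf_norm <- function(psi) {
  stopifnot(inherits(psi, "wavefunction"))
  sum(Mod(psi$psi)^2) * psi$grid$dv
}

#' @rdname wf_norm
#' @export
wf_moments <- function(psi) {
  rho <- Mod(psi$psi)^2 * psi$grid$dv
  rho <- rho / sum(rho)
  m <- sum(psi$grid$centers * rho)
  s <- sqrt(sum((psi$grid$centers - m)^2 * rho))
  tibble::tibble(mean = m, sd = s)
}

#' @rdname wf_norm
#' @export
wf_density <- function(psi) {
  stopifnot(inherits(psi, "wavefunction"))
  new_density_estimate(
    v = psi$grid$centers,
    density = Mod(psi$psi)^2,
    bin_width = psi$grid$dv,
    time = psi$time
  )
}

#' Gaussian initial wavefunction centred at rest
#'
#' The real, nonnegative initial state
#' \deqn{\psi(v, 0) = (\pi\sigma_0^2)^{-1/4}
#'   \exp\!\big(-(v - v_{rest})^2 / (2\sigma_0^2)\big),}
#' renormalised on the discrete grid. Note the Born density then has
#' standard deviation \eqn{\sigma_0/\sqrt{2}}.
#'
#' @param v_rest Center of the packet; must lie inside the grid.
#' @param sigma0 Width parameter (> 0). The grid must resolve it: at least
#'   8 cells per `sigma0`, otherwise a resolution error is raised.
#' @param grid A [voltage_grid()].
#' @param hbar An `hbar_eff` or positive numeric.
#' @param mass Effective mass.
#' @return A normalised `wavefunction` at time 0 with attribute
#'   `peak_amplitude`, the continuum peak \eqn{(\pi\sigma_0^2)^{-1/4}}
#'   before discrete renormalisation.
#' @examples
#' psi <- initial_gaussian(-1.2, 0.2, voltage_grid(), hbar_from_diffusion(0.05))
#' wf_norm(psi)
#' @export
initial_gaussian <- function(v_rest, sigma0, grid = voltage_grid(),
                             hbar, mass = 1) {
  stopifnot(inherits(grid, "voltage_grid"))
  check_scalar(v_rest, "v_rest")
  check_positive(sigma0, "sigma0")
  if (abs(v_rest) >= grid$v_max) {
    abort_domain("`v_rest` must lie strictly inside the grid.")
  }
  if (sigma0 / grid$dv < 8) {
    abort_domain(sprintf(
      "grid undersamples the packet: %.1f cells per sigma0 (need >= 8).",
      sigma0 / grid$dv))
  }
  amp <- (pi * sigma0^2)^(-1 / 4) *
    exp(-(grid$centers - v_rest)^2 / (2 * sigma0^2))
  psi <- wavefunction(grid, amp / sqrt(sum(amp^2) * grid$dv), hbar, mass)
  attr(psi, "peak_amplitude") <- (pi * sigma0^2)^(-1 / 4)
  psi
}

# ---- cosine-basis (Neumann) spectral transforms -----------------------------
#
# DCT-II on cell-centered samples and its inverse, via length-2n FFTs so they
# work for complex input. Unnormalised forward coefficients are
#   c_m = sum_l x_l cos(pi m (l + 1/2) / n),  m = 0..n-1;
# the orthonormal pair used by the propagator rescales rows so that the
# transform is unitary (norm-preserving phases in k-space).

dct2_raw <- function(x) {
  n <- length(x)
  y <- c(x, rev(x))
  Y <- stats::fft(y)[seq_len(n)]
  0.5 * exp(-1i * pi * (0:(n - 1)) / (2 * n)) * Y
}

dct3_raw <- function(c0) {
  # x_l = sum_{m=0}^{n-1} c_m cos(pi m (l + 1/2) / n)
  n <- length(c0)
  ph <- exp(1i * pi * (0:(n - 1)) / (2 * n))
  s_minus <- stats::fft(c(c0 / ph, rep(0+0i, n)))[seq_len(n)]
  s_plus <- stats::fft(c(c0 * ph, rep(0+0i, n)), inverse = TRUE)[seq_len(n)]
  (s_plus + s_minus) / 2
}

dct_ortho <- function(x) {
  n <- length(x)
  c0 <- dct2_raw(x)
  c0 * c(sqrt(1 / n), rep(sqrt(2 / n), n - 1))
}

idct_ortho <- function(c0) {
  n <- length(c0)
  dct3_raw(c0 * c(sqrt(1 / n), rep(sqrt(2 / n), n - 1)))
}

#' Split-operator evolution of the Schrodinger-type equation
#'
#' Advances \eqn{i\hat\hbar\,\partial_t\psi =
#' -\frac{\hat\hbar^2}{2m}\partial_v^2\psi + V_{\mathrm{eff}}(v)\,\psi}
#' by Strang splitting,
#' \eqn{e^{-iV dt/2\hat\hbar}\, e^{-iT dt/\hat\hbar}\, e^{-iV dt/2\hat\hbar}},
#' with the kinetic factor applied in an orthonormal cosine (DCT) basis so
#' the Neumann condition \eqn{\partial_v\psi = 0} at \eqn{\pm V_{max}}
#' (reflecting walls) holds exactly. Every factor is a pure phase in its own
#' basis, so the discrete norm is conserved to round-off.
#'
#' @param psi0 Initial `wavefunction` (normalised).
#' @param veff An `effective_potential` on the same grid (time-independent
#'   within the solve; the recovery variable is frozen).
#' @param dt Time step (> 0).
#' @param n_steps Number of steps, or give `t_final`.
#' @param t_final Target evolution time.
#' @return The evolved `wavefunction`.
#' @examples
#' g <- voltage_grid(6, 256)
#' psi <- initial_gaussian(0, 0.5, g, hbar = 0.5)
#' free <- new_effective_potential(g, rep(0, g$n_cells))
#' wf_moments(evolve_split_operator(psi, free, dt = 0.01, t_final = 1))
#' @export
evolve_split_operator <- function(psi0, veff, dt, n_steps = NULL,
                                  t_final = NULL) {
  stopifnot(inherits(psi0, "wavefunction"),
            inherits(veff, "effective_potential"))
  if (!same_grid(psi0$grid, attr(veff, "grid"))) {
    abort_domain("`psi0` and `veff` are on different grids.")
  }
  check_positive(dt, "dt")
  if (is.null(n_steps) == is.null(t_final)) {
    abort_config("supply exactly one of `n_steps` or `t_final`.")
  }
  if (is.null(n_steps)) {
    n_steps <- max(1L, round(t_final / dt))
    dt <- t_final / n_steps
  }
  n_steps <- check_count(n_steps, "n_steps")
  hbar <- as.numeric(psi0$hbar)
  if (hbar <= 0) abort_domain("evolution requires hbar > 0.")

  grid <- psi0$grid
  k <- pi * (0:(grid$n_cells - 1)) / (2 * grid$v_max)
  kin_phase <- exp(-1i * hbar * k^2 * dt / (2 * psi0$mass))
  half_pot <- exp(-1i * veff$v_eff * dt / (2 * hbar))

  psi <- psi0$psi
  for (s in seq_len(n_steps)) {
    psi <- half_pot * psi
    psi <- idct_ortho(kin_phase * dct_ortho(psi))
    psi <- half_pot * psi
  }
  out <- wavefunction(grid, psi, psi0$hbar, psi0$mass,
                      time = psi0$time + dt * n_steps)
  out
}

#' Expected energy of a wavefunction
#'
#' \eqn{\langle\psi|H|\psi\rangle} with
#' \eqn{H = -\frac{\hat\hbar^2}{2m}\partial_v^2 + V_{\mathrm{eff}}},
#' the kinetic part evaluated in the cosine spectral basis. Conserved by
#' [evolve_split_operator()] for time-independent potentials.
#'
#' @param psi A `wavefunction`.
#' @param veff An `effective_potential` on the same grid.
#' @return Energy (numeric scalar, model units).
#' @export
wf_energy <- function(psi, veff) {
  stopifnot(inherits(psi, "wavefunction"),
            inherits(veff, "effective_potential"))
  grid <- psi$grid
  hbar <- as.numeric(psi$hbar)
  k <- pi * (0:(grid$n_cells - 1)) / (2 * grid$v_max)
  ck <- dct_ortho(psi$psi)
  kin <- sum(hbar^2 * k^2 / (2 * psi$mass) * Mod(ck)^2) * grid$dv
  pot <- sum(veff$v_eff * Mod(psi$psi)^2) * grid$dv
  kin + pot
}

#' Madelung decomposition and assembly
#'
#' `madelung_decompose()` splits \eqn{\psi = \sqrt{\rho}\,e^{iS/\hat\hbar}}
#' into the Born density \eqn{\rho = |\psi|^2} and the action
#' \eqn{S = \hat\hbar \times} (phase unwrapped outward from the density
#' maximum). Cells with \eqn{\rho} below `floor` have `S = NA` (masked, not
#' extrapolated). `madelung_assemble()` inverts the map; the pair is the
#' identity up to a global phase wherever the density is above floor.
#'
#' @param psi A `wavefunction`.
#' @param floor Density mask threshold.
#' @return For `madelung_decompose()`, a tibble (`v`, `rho`, `s`, `masked`)
#'   with attributes `hbar`, `grid`, `mass`. For `madelung_assemble()`, a
#'   `wavefunction` with \eqn{|\psi|^2 = \rho} exactly (masked cells get
#'   zero phase).
#' @examples
#' g <- voltage_grid(3, 128)
#' psi <- initial_gaussian(0, 0.4, g, hbar = 0.3)
#' m <- madelung_decompose(psi)
#' all(abs(m$s[!m$masked]) < 1e-12) # real positive psi has S = 0
#' @export
madelung_decompose <- function(psi, floor = 1e-12) {
  stopifnot(inherits(psi, "wavefunction"))
  rho <- Mod(psi$psi)^2
  phase <- Arg(psi$psi)
  j0 <- which.max(rho)
  unwrapped <- unwrap_from(phase, j0)
  s <- ifelse(rho > floor, as.numeric(psi$hbar) * unwrapped, NA_real_)
  out <- tibble::tibble(v = psi$grid$centers, rho = rho, s = s,
                        masked = rho <= floor)
  attr(out, "hbar") <- psi$hbar
  attr(out, "grid") <- psi$grid
  attr(out, "mass") <- psi$mass
  out
}

# sequential 1-D phase unwrap outward from anchor index j0
unwrap_from <- function(phase, j0) {
  n <- length(phase)
  out <- phase
  if (j0 < n) {
    for (j in (j0 + 1):n) {
      d <- out[j] - out[j - 1]
      out[j] <- out[j] - 2 * pi * round(d / (2 * pi))
    }
  }
  if (j0 > 1) {
    for (j in (j0 - 1):1) {
      d <- out[j] - out[j + 1]
      out[j] <- out[j] - 2 * pi * round(d / (2 * pi))
    }
  }
  out
}

#' @rdname madelung_decompose
#' @param rho Nonnegative density values on `grid` (or the tibble returned
#'   by `madelung_decompose()`, in which case `s`, `grid`, `hbar`, `mass`
#'   are taken from it).
#' @param s_phase Action values `S(v)`; `NA` allowed where `rho` is below
#'   floor.
#' @param hbar Action scale.
#' @param grid A [voltage_grid()] (when `rho` is a bare vector).
#' @param mass Effective mass.
#' @export
madelung_assemble <- function(rho, s_phase = NULL, hbar = NULL, grid = NULL,
                              mass = 1) {
  if (is.data.frame(rho)) {
    tab <- rho
    grid <- attr(tab, "grid")
    hbar <- attr(tab, "hbar")
    if (!is.null(attr(tab, "mass"))) mass <- attr(tab, "mass")
    s_phase <- tab$s
    rho <- tab$rho
  }
  stopifnot(inherits(grid, "voltage_grid"))
  if (any(rho < 0)) abort_domain("`rho` must be nonnegative.")
  if (length(rho) != grid$n_cells) {
    abort_domain("`rho` must have length n_cells.")
  }
  hbar <- as_hbar(hbar)
  hv <- as.numeric(hbar)
  phase <- ifelse(is.na(s_phase), 0, if (hv > 0) s_phase / hv else 0)
  wavefunction(grid, sqrt(rho) * exp(1i * phase), hbar, mass)
}
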