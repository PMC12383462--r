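# Shared small fixtures and utilities for tests.

# frozen fixed point of the default parameters (root of the resting cubic,
# computed once with uniroot at tol 1e-14 and pinned here as the oracle)
FX_V <- -1.1994080352
FX_W <- -0.6242600441

# average fine-grid cell densities into coarser bins (factor must divide)
aggregate_density <- function(fp, factor) {
  rho <- matrix(fp$rho, nrow = factor)
  v <- matrix(fp$v, nrow = factor)
  tibble::tibble(v = colMeans(v), density = colMeans(rho))
}

# gaussian density tibble on a voltage grid (for metric tests)
gaussian_density <- function(grid, mean, sd) {
  d <- stats::dnorm(grid$centers, mean, sd)
  tibble::tibble(v = grid$centers, density = d / sum(d * grid$dv))
}

frozen_fhn_drift <- function(w0, params = fhn_params()) {
  function(v, w, p) list(f = v - v^3 / 3 - w0 + params$i_ext, g = 0 * w)
}
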