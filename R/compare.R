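#' Compare two voltage densities
#'
#' Quantitative distances between two densities on a common voltage grid:
#' the L1 distance \eqn{\int |p - q|\,dv} (in `[0, 2]`), the
#' Kullback-Leibler divergence \eqn{\int p \log(p/q)\,dv} with a fixed floor
#' `eps = 1e-12` on `q` and masking of cells where `p` is below floor
#' (direction `p || q`, asymmetric by construction; floor and masked mass
#' are recorded), and the Wasserstein-1 distance
#' \eqn{\int |F_p - F_q|\,dv} via the discrete CDFs. L1 and W1 are symmetric
#' in `(p, q)`.
#'
#' @param p,q `density_estimate`, `fp_solution`, or tibbles with a `v`
#'   column and a `density`/`rho` column. Grids must match to 1e-9 unless
#'   `resample = TRUE`.
#' @param resample If `TRUE`, `q` is linearly interpolated onto `p`'s grid
#'   and renormalised; the method is recorded in the report.
#' @param kl_floor Floor applied inside the KL logarithm.
#' @return A `comparison_report`: list with `l1_distance`, `kl_divergence`,
#'   `wasserstein1`, `kl_floor`, `kl_masked_mass`, `resampled`, `n_cells`,
#'   `bin_width`. Use [generics::glance()] for a one-row tibble.
#' @examples
#' g <- voltage_grid(3, 128)
#' compare_densities(fp_gaussian(g, 0, 0.3), fp_gaussian(g, 0.5, 0.3))
#' @export
compare_densities <- function(p, q, resample = FALSE, kl_floor = 1e-12) {
  pv <- p$v
  qd <- density_column(q)
  pd <- density_column(p)
  if (length(pv) != length(q$v) || max(abs(pv - q$v)) > 1e-9) {
    if (!resample) {
      abort_domain("densities are on different grids; set `resample = TRUE`.")
    }
    qd <- stats::approx(q$v, qd, xout = pv, rule = 2)$y
  }
  dv <- diff(pv)
  if (max(abs(dv - dv[1])) > 1e-9) abort_domain("grid is not uniform.")
  dv <- dv[1]
  if (resample) {
    s <- sum(qd * dv)
    if (s <= 0) abort_domain("resampled density has no mass.")
    qd <- qd / s
  }
  mask <- pd > kl_floor
  kl <- sum(pd[mask] * log(pd[mask] / pmax(qd[mask], kl_floor))) * dv
  structure(
    list(
      l1_distance = sum(abs(pd - qd)) * dv,
      kl_divergence = kl,
      wasserstein1 = sum(abs(cumsum(pd) - cumsum(qd))) * dv^2,
      kl_floor = kl_floor,
      kl_masked_mass = sum(pd[!mask]) * dv,
      resampled = isTRUE(resample),
      n_cells = length(pv),
      bin_width = dv
    ),
    class = "comparison_report"
  )
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n")
  cat(sprintf("  L1 = %.6g   KL(p||q) = %.6g   W1 = %.6g\n",
              x$l1_distance, x$kl_divergence, x$wasserstein1))
  invisible(x)
}
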