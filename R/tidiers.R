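#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an effective-Planck-constant estimate
#'
#' One row per estimation route, with the quantities each route rests on.
#'
#' @param x An `hbar_estimate` from [estimate_hbar()].
#' @param ... Unused.
#' @return A tibble with columns `route`, `estimate`, `basis`, `policy`.
#' @export
tidy.hbar_estimate <- function(x, ...) {
  tibble::tibble(
    route = c("moment", "diffusion"),
    estimate = c(x$hbar_moment, x$hbar_diffusion),
    basis = c(sprintf("m_eff = %.4g, sigma_hat = %.4g", x$m_eff, x$sigma_hat),
              sprintf("d_hat = %.4g", x$d_hat)),
    policy = c(paste(x$provenance$mass_policy, x$provenance$detrend, sep = "/"),
               x$provenance$diffusion_method)
  )
}

#' @rdname tidy.hbar_estimate
#' @export
glance.hbar_estimate <- function(x, ...) {
  tibble::tibble(
    sigma_hat = x$sigma_hat, d_hat = x$d_hat, m_eff = x$m_eff,
    hbar_moment = x$hbar_moment, hbar_diffusion = x$hbar_diffusion,
    n_samples = x$n_samples
  )
}

#' One-row summaries of comparison and equivalence results
#'
#' @param x A `comparison_report` or `equivalence_report`.
#' @param ... Unused.
#' @return A one-row tibble of the distance metrics (for an equivalence
#'   report, one set of columns per comparison, prefixed by its name).
#' @export
glance.comparison_report <- function(x, ...) {
  tibble::tibble(
    l1_distance = x$l1_distance,
    kl_divergence = x$kl_divergence,
    wasserstein1 = x$wasserstein1,
    kl_masked_mass = x$kl_masked_mass,
    n_cells = x$n_cells
  )
}

#' @rdname glance.comparison_report
#' @export
glance.equivalence_report <- function(x, ...) {
  cols <- purrr::imap(x$comparisons, function(r, nm) {
    out <- tibble::tibble(r$l1_distance, r$kl_divergence, r$wasserstein1)
    names(out) <- paste0(nm, c("_l1", "_kl", "_w1"))
    out
  })
  dplyr::bind_cols(
    tibble::tibble(seed = x$seed, n_traj = x$config$fhn$n_traj,
                   hbar = as.numeric(x$hbar)),
    !!!unname(cols),
    tibble::tibble(config_hash = x$config_hash)
  )
}

#' @rdname tidy.hbar_estimate
#' @export
tidy.comparison_report <- function(x, ...) {
  tibble::tibble(
    metric = c("l1_distance", "kl_divergence", "wasserstein1"),
    value = c(x$l1_distance, x$kl_divergence, x$wasserstein1),
    symmetric = c(TRUE, FALSE, TRUE)
  )
}
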