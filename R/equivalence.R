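#' Run configuration
#'
#' `default_config()` returns the full nested configuration with package
#' defaults; `read_run_config()` reads a YAML file and merges it over the
#' defaults; `validate_config()` rejects unknown keys (schema-checked before
#' any run). Blocks: `fhn` (SDE ensemble), `fp` (Fokker-Planck), `schrodinger`
#' (wave solver), `circuit`, `estimate` (recording generator / estimators),
#' plus global `seed` and `output_dir`. `NULL` entries (`v0`, `w0`, `v_rest`)
#' mean "use the deterministic fixed point".
#'
#' @return A nested named list.
#' @examples
#' str(default_config(), max.level = 2)
#' @export
default_config <- function() {
  list(
    seed = 1L,
    output_dir = ".",
    fhn = list(a = 0.7, b = 0.8, tau = 12.5, i_ext = 0, d_noise = 0.05,
               dt = 0.05, t_final = 100, n_traj = 20000L,
               v0 = NULL, w0 = NULL, zero_drift = FALSE),
    fp = list(enabled = TRUE, v_max = 3, n_cells = 512L, compare_cells = 64L),
    schrodinger = list(sigma0 = 0.2, v_rest = NULL, mass = 1, dt = 0.01),
    circuit = list(builder = "trotter", steps = 10L, angle_scale = pi * 0.1,
                   n_qubits = 3L, shots = NULL),
    estimate = list(k_relax = 1, d_noise = 0.05, dt = 0.05,
                    n_samples = 40000L, v_rest = 0,
                    capacitance = 1, resistance = 1)
  )
}

#' @rdname default_config
#' @param config A (possibly partial) nested configuration list.
#' @export
validate_config <- function(config) {
  ref <- default_config()
  check_block <- function(x, ref, path) {
    unknown <- setdiff(names(x), names(ref))
    if (length(unknown) > 0) {
      abort_config(sprintf("unknown config key%s: %s",
                           if (length(unknown) > 1) "s" else "",
                           paste0(path, unknown, collapse = ", ")))
    }
    for (nm in names(x)) {
      if (is.list(ref[[nm]]) && !is.null(x[[nm]])) {
        if (!is.list(x[[nm]])) {
          abort_config(sprintf("config key %s%s must be a block.", path, nm))
        }
        check_block(x[[nm]], ref[[nm]], paste0(path, nm, "."))
      }
    }
  }
  check_block(config, ref, "")
  invisible(config)
}

#' @rdname default_config
#' @param path Path to a YAML configuration file.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_config(sprintf("config file '%s' not found.", path))
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  validate_config(user)
  merge_config(default_config(), user)
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Stochastic-versus-quantum density equivalence experiment
#'
#' The end-to-end experiment: integrate an Euler-Maruyama ensemble of the
#' stochastic FHN voltage (recovery frozen at `w0` so the one-dimensional
#' comparison is well-posed), histogram the terminal voltages, evolve the
#' Gaussian initial wavefunction under the Schrodinger-type equation with
#' the effective potential at the same `w0` and \eqn{\hat\hbar = \sqrt{2D}},
#' and optionally solve the Fokker-Planck equation as the classical
#' reference. All pairwise density distances are reported.
#'
#' No pass/fail threshold is imposed on the stochastic-versus-quantum
#' distance: the real-Gaussian initial state has zero phase, whereas exact
#' Nelson correspondence with the Fokker-Planck density requires the initial
#' phase to encode the current velocity, so the experiment reports metrics
#' rather than asserting a match. The Monte-Carlo-versus-Fokker-Planck
#' distance, by contrast, is a genuine self-consistency check that shrinks
#' as \eqn{n_{traj}^{-1/2}}.
#'
#' @param config Nested configuration (see [default_config()]); partial
#'   lists are merged over the defaults.
#' @return An `equivalence_report`: list with `densities` (long tibble:
#'   `v`, `density`, `source` in `mc`, `psi2`, `fp`), `comparisons` (named
#'   list of [compare_densities()] reports: `mc_vs_psi`, and `mc_vs_fp`,
#'   `fp_vs_psi` when the Fokker-Planck stage is enabled), `fixed_point`,
#'   `hbar`, `seed`, `config`, and `config_hash` (sha1 of the effective
#'   configuration and seed; identical config + seed reproduces the report
#'   bit-exactly). Use [generics::glance()] for a one-row metric summary.
#' @examples
#' \donttest{
#' rep <- run_equivalence_experiment(list(fhn = list(n_traj = 2000L,
#'                                                   t_final = 10)))
#' generics::glance(rep)
#' }
#' @export
run_equivalence_experiment <- function(config = list()) {
  validate_config(config)
  cfg <- merge_config(default_config(), config)
  params <- fhn_params(cfg$fhn$a, cfg$fhn$b, cfg$fhn$tau, cfg$fhn$i_ext,
                       cfg$fhn$d_noise)
  fx <- fhn_fixed_point(params)
  fx <- fx[which.min(abs(fx$v + 1)), ] # resting branch
  v0 <- cfg$fhn$v0 %||% fx$v
  w0 <- cfg$fhn$w0 %||% fx$w
  v_rest <- cfg$schrodinger$v_rest %||% fx$v
  grid <- voltage_grid(cfg$fp$v_max, cfg$fp$n_cells)
  # distance metrics are computed on a coarser histogram grid so they are not
  # dominated by per-cell Monte Carlo noise; curves keep full resolution
  if (cfg$fp$n_cells %% cfg$fp$compare_cells != 0) {
    abort_config("`fp$compare_cells` must divide `fp$n_cells`.")
  }
  cmp_grid <- voltage_grid(cfg$fp$v_max, cfg$fp$compare_cells)
  coarsen <- function(dens_values) {
    colMeans(matrix(dens_values, nrow = cfg$fp$n_cells %/% cfg$fp$compare_cells))
  }
  seed <- check_count(cfg$seed, "seed", min = 0L)
  tg <- time_grid(cfg$fhn$dt, t_final = cfg$fhn$t_final)
  zero_drift <- isTRUE(cfg$fhn$zero_drift)

  # stage 1: Monte Carlo ensemble, recovery frozen at w0
  frozen_drift <- if (zero_drift) {
    function(v, w, params) list(f = 0 * v, g = 0 * w)
  } else {
    function(v, w, params) {
      list(f = v - v^3 / 3 - w0 + params$i_ext, g = 0 * w)
    }
  }
  ens <- simulate_fhn_ensemble(params, tg, cfg$fhn$n_traj, v0, w0, seed,
                               record = "final", drift = frozen_drift)
  d_mc <- empirical_density(ens, at_time = tg$t_final, bins = cmp_grid)

  # stage 2: Schrodinger-type evolution with matched hbar and frozen w0
  hbar <- hbar_from_diffusion(params$d_noise)
  veff <- if (zero_drift) {
    new_effective_potential(grid, rep(0, grid$n_cells), w0 = w0, hbar = hbar)
  } else {
    effective_potential(params, w0 = w0, hbar = hbar, grid = grid)
  }
  psi0 <- initial_gaussian(v_rest, cfg$schrodinger$sigma0, grid, hbar,
                           mass = cfg$schrodinger$mass)
  psi <- evolve_split_operator(psi0, veff, dt = cfg$schrodinger$dt,
                               t_final = tg$t_final)
  d_psi <- wf_density(psi)

  d_psi_cmp <- tibble::tibble(v = cmp_grid$centers,
                              density = coarsen(d_psi$density))
  comparisons <- list(mc_vs_psi = compare_densities(d_mc, d_psi_cmp))
  densities <- dplyr::bind_rows(
    tibble::tibble(v = d_mc$v, density = d_mc$density, source = "mc"),
    tibble::tibble(v = d_psi$v, density = d_psi$density, source = "psi2")
  )

  # stage 3 (optional): Fokker-Planck classical reference
  if (isTRUE(cfg$fp$enabled)) {
    fp_drift <- if (zero_drift) {
      function(v) 0 * v
    } else {
      function(v) v - v^3 / 3 - w0 + params$i_ext
    }
    d_fp <- fp_evolve(fp_delta(grid, v0), fp_drift, params$d_noise,
                      t_final = tg$t_final)
    d_fp_cmp <- tibble::tibble(v = cmp_grid$centers, density = coarsen(d_fp$rho))
    comparisons$mc_vs_fp <- compare_densities(d_mc, d_fp_cmp)
    comparisons$fp_vs_psi <- compare_densities(d_fp_cmp, d_psi_cmp)
    densities <- dplyr::bind_rows(
      densities, tibble::tibble(v = d_fp$v, density = d_fp$rho, source = "fp"))
  }

  structure(
    list(
      densities = densities,
      comparisons = comparisons,
      fixed_point = fx,
      hbar = hbar,
      seed = seed,
      config = cfg,
      config_hash = digest::digest(list(cfg, seed), algo = "sha1")
    ),
    class = "equivalence_report"
  )
}

#' @export
print.equivalence_report <- function(x, ...) {
  cat(sprintf("<equivalence_report> seed %d, config %s\n", x$seed,
              substr(x$config_hash, 1, 8)))
  for (nm in names(x$comparisons)) {
    r <- x$comparisons[[nm]]
    cat(sprintf("  %-10s L1 = %.4f  KL = %.4f  W1 = %.4f\n", nm,
                r$l1_distance, r$kl_divergence, r$wasserstein1))
  }
  invisible(x)
}

#' Write an equivalence report to disk
#'
#' Writes `report.json` (all metrics, seed, config hash and the effective
#' configuration) and one CSV per density curve into `dir`.
#'
#' @param report An `equivalence_report`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_equivalence_report <- function(report, dir) {
  stopifnot(inherits(report, "equivalence_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  metrics <- lapply(report$comparisons, function(r) {
    r[c("l1_distance", "kl_divergence", "wasserstein1", "kl_masked_mass")]
  })
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(
    list(seed = report$seed, config_hash = report$config_hash,
         hbar = as.numeric(report$hbar),
         fixed_point = as.list(report$fixed_point[c("v", "w")]),
         comparisons = metrics, config = report$config),
    json_path, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  paths <- json_path
  for (src in unique(report$densities$source)) {
    p <- file.path(dir, paste0("density_", src, ".csv"))
    readr::write_csv(dplyr::filter(report$densities, .data$source == src), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
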