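test_that("drift evaluates the FHN vector field exactly", {
  p <- fhn_params() # a = 0.7, b = 0.8, tau = 12.5
  d <- fhn_drift(c(0, 1, -1), c(0, 0, 0.5), p)
  expect_equal(d$f, c(0, 2 / 3, -7 / 6))
  expect_equal(d$g[1], 0.7 / 12.5) # 0.056
  expect_error(fhn_drift(NaN, 0, p), class = "quantneuron_domain_error")
  expect_error(fhn_drift(0, Inf, p), class = "quantneuron_domain_error")
})

test_that("parameter and grid constructors enforce their invariants", {
  expect_error(fhn_params(tau = 0), class = "quantneuron_domain_error")
  expect_error(fhn_params(d_noise = -1), class = "quantneuron_domain_error")
  tg <- time_grid(0.05, t_final = 100)
  expect_equal(tg$n_steps, 2000L)
  expect_equal(tg$t_final, 100)
  expect_error(time_grid(0.05), class = "quantneuron_config_error")
})

test_that("fixed point solves f = g = 0 to high precision", {
  fx <- fhn_fixed_point(fhn_params())
  expect_equal(nrow(fx), 1L)
  expect_equal(fx$v, FX_V, tolerance = 1e-8)
  expect_equal(fx$w, FX_W, tolerance = 1e-8)
  expect_lt(fx$residual, 1e-10)

  # odd-symmetric case has the origin as a fixed point
  fx0 <- fhn_fixed_point(fhn_params(a = 0, b = 1))
  expect_true(any(abs(fx0$v) < 1e-10 & abs(fx0$w) < 1e-10))
})

test_that("ensembles are deterministic with trajectory-stable substreams", {
  p <- fhn_params(d_noise = 0.05)
  tg <- time_grid(0.05, t_final = 2)
  e1 <- simulate_fhn_ensemble(p, tg, 10, -1, -0.5, seed = 42)
  e2 <- simulate_fhn_ensemble(p, tg, 10, -1, -0.5, seed = 42)
  expect_identical(e1$v, e2$v)
  expect_identical(e1$w, e2$w)

  # growing the ensemble must not perturb earlier trajectories
  e5 <- simulate_fhn_ensemble(p, tg, 5, -1, -0.5, seed = 42)
  expect_identical(e5$v, e1$v[1:5, ])

  # chunking is invisible
  e_chunk <- simulate_fhn_ensemble(p, tg, 10, -1, -0.5, seed = 42,
                                   chunk_size = 3L)
  expect_identical(e_chunk$v, e1$v)
})

test_that("noise-free integration matches an explicit Euler reference", {
  p <- fhn_params(d_noise = 0)
  tg <- time_grid(0.05, t_final = 10)
  ens <- simulate_fhn_ensemble(p, tg, 1, 0, 0, seed = 1)
  # independent scalar Euler loop
  v <- 0; w <- 0
  ref_v <- numeric(tg$n_steps + 1); ref_w <- numeric(tg$n_steps + 1)
  ref_v[1] <- v; ref_w[1] <- w
  for (k in seq_len(tg$n_steps)) {
    f <- v - v^3 / 3 - w
    g <- (v + 0.7 - 0.8 * w) / 12.5
    v <- v + f * 0.05
    w <- w + g * 0.05
    ref_v[k + 1] <- v; ref_w[k + 1] <- w
  }
  expect_lt(max(abs(ens$v[1, ] - ref_v)), 1e-12)
  expect_lt(max(abs(ens$w[1, ] - ref_w)), 1e-12)
})

test_that("the deterministic fixed point is stationary over T = 100", {
  p <- fhn_params(d_noise = 0)
  fx <- fhn_fixed_point(p)
  ens <- simulate_fhn_ensemble(p, time_grid(0.05, t_final = 100), 1,
                               fx$v, fx$w, seed = 1)
  expect_lt(max(abs(ens$v - fx$v)), 1e-6)
  expect_lt(max(abs(ens$w - fx$w)), 1e-6)
})

test_that("trajectories stay finite and bounded at the study noise level", {
  # D = 0.05, dt = 0.05, T = 100
  p <- fhn_params(d_noise = 0.05)
  fx <- fhn_fixed_point(p)
  ens <- simulate_fhn_ensemble(p, time_grid(0.05, t_final = 100), 1000,
                               fx$v, fx$w, seed = 3, record = "final")
  expect_true(all(is.finite(ens$v)))
  expect_true(all(abs(ens$v) < 4))
})

test_that("ensemble variance matches the OU closed form under linear drift", {
  # drift override f = -v (g = 0): variance(T) = D (1 - exp(-2T)) for the
  # sqrt(2D) dW noise convention. Euler-Maruyama bias at dt is
  # ~ D dt / 2 << the 3-standard-error band sigma^2 sqrt(2/n).
  d_noise <- 0.05
  t_final <- 2
  n <- 20000
  ens <- simulate_fhn_ensemble(
    fhn_params(d_noise = d_noise), time_grid(0.005, t_final = t_final),
    n, 0, 0, seed = 11, record = "final",
    drift = function(v, w, params) list(f = -v, g = 0 * w))
  target <- d_noise * (1 - exp(-2 * t_final))
  se <- target * sqrt(2 / n)
  expect_lt(abs(stats::var(ens$v[, 2]) - target), 3 * se)
})

test_that("empirical densities normalise and report out-of-window mass", {
  p <- fhn_params(d_noise = 0)
  tg <- time_grid(0.1, n_steps = 1)
  # all trajectories pinned at v = 0 by zero drift and zero noise
  still <- simulate_fhn_ensemble(p, tg, 50, 0, 0, seed = 1,
                                 drift = function(v, w, params)
                                   list(f = 0 * v, g = 0 * w))
  g <- voltage_grid(3, 30)
  d <- empirical_density(still, at_time = 0.1, bins = g)
  expect_equal(sum(d$density * attr(d, "bin_width")), 1)
  expect_equal(sum(d$density > 0), 1L) # single occupied bin
  expect_equal(attr(d, "mass_outside"), 0)

  # start outside the window: mass is reported, in + out is exactly 1
  away <- simulate_fhn_ensemble(p, tg, 50, 5, 0, seed = 1,
                                drift = function(v, w, params)
                                  list(f = 0 * v, g = 0 * w))
  d2 <- empirical_density(away, at_time = 0.1, bins = g)
  expect_equal(attr(d2, "mass_outside"), 1)
  expect_equal(sum(d2$density * attr(d2, "bin_width")) +
                 attr(d2, "mass_outside"), 1)

  expect_error(empirical_density(still, at_time = 0.123, bins = g),
               class = "quantneuron_domain_error")
})

test_that("integration blow-up reports the failing step", {
  p <- fhn_params(d_noise = 0)
  expect_error(
    simulate_fhn_ensemble(p, time_grid(1, n_steps = 50), 1, 2, 0, seed = 1,
                          drift = function(v, w, params)
                            list(f = v^3, g = 0 * w)),
    regexp = "blow-up.*step",
    class = "quantneuron_numeric_error")
})
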