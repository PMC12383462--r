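test_that("cosine transforms match their naive definitions and are unitary", {
  set.seed(7)
  for (n in c(8L, 13L, 32L)) {
    x <- complex(real = rnorm(n), imaginary = rnorm(n))
    cosmat <- outer(0:(n - 1), 0:(n - 1),
                    function(m, l) cos(pi * m * (l + 0.5) / n))
    expect_lt(max(Mod(quantneuron:::dct2_raw(x) - cosmat %*% x)), 1e-12)
    c0 <- complex(real = rnorm(n), imaginary = rnorm(n))
    expect_lt(max(Mod(quantneuron:::dct3_raw(c0) - t(cosmat) %*% c0)), 1e-12)
    # orthonormal pair: round trip and norm preservation
    ck <- quantneuron:::dct_ortho(x)
    expect_lt(max(Mod(quantneuron:::idct_ortho(ck) - x)), 1e-12)
    expect_equal(sum(Mod(ck)^2), sum(Mod(x)^2), tolerance = 1e-12)
  }
})

test_that("free evolution follows the Gaussian spreading law", {
  # |psi|^2 width: s(t) = sqrt(s0^2 + (hbar t / (2 m s0))^2), valid while
  # the packet is >= 5 s(t) from the reflecting walls
  g <- voltage_grid(10, 1024)
  hbar <- 0.5
  s0 <- 0.5
  psi0 <- initial_gaussian(0, s0 * sqrt(2), g, hbar = hbar, mass = 1)
  free <- new_effective_potential(g, rep(0, g$n_cells))
  for (t in c(1, 2, 3)) {
    psi <- evolve_split_operator(psi0, free, dt = 0.05, t_final = t)
    s_t <- sqrt(s0^2 + (hbar * t / (2 * s0))^2)
    expect_gt(g$v_max, 5 * s_t) # wall-distance precondition
    expect_equal(wf_moments(psi)$sd, s_t, tolerance = 0.005)
  }
})

test_that("coherent oscillation in a harmonic well has period 2*pi*sqrt(m/k)", {
  g <- voltage_grid(6, 512)
  hbar <- 0.3
  k_spring <- 1
  mass <- 1
  veff <- new_effective_potential(g, 0.5 * k_spring * g$centers^2)
  # displaced ground state: sigma0 = sqrt(hbar / (m omega)), offset d = 1
  psi <- initial_gaussian(1, sqrt(hbar / sqrt(k_spring / mass)), g,
                          hbar = hbar, mass = mass)
  dt <- 0.005
  sample_every <- 10L
  n_chunks <- ceiling(3.2 * 2 * pi / (dt * sample_every))
  centers <- numeric(n_chunks)
  for (i in seq_len(n_chunks)) {
    psi <- evolve_split_operator(psi, veff, dt = dt, n_steps = sample_every)
    centers[i] <- wf_moments(psi)$mean
  }
  ts <- dt * sample_every * seq_len(n_chunks)
  # period from the maxima of <v>(t), quadratically interpolated
  peak_time <- function(j) {
    y <- centers[(j - 1):(j + 1)]
    ts[j] + (dt * sample_every) * (y[1] - y[3]) / (2 * (y[1] - 2 * y[2] + y[3]))
  }
  peaks <- which(diff(sign(diff(centers))) == -2) + 1L
  expect_gte(length(peaks), 3L)
  period <- (peak_time(peaks[3]) - peak_time(peaks[1])) / 2
  expect_equal(period, 2 * pi * sqrt(mass / k_spring), tolerance = 0.005)
  # amplitude is preserved by the coherent state
  expect_equal(max(centers), 1, tolerance = 0.01)
})

test_that("split-operator evolution is unitary and conserves energy", {
  g <- voltage_grid(3, 256)
  p <- fhn_params(d_noise = 0.05)
  hb <- hbar_from_diffusion(0.05)
  veff <- effective_potential(p, w0 = FX_W, hbar = hb, grid = g)
  psi0 <- initial_gaussian(FX_V, 0.2, g, hbar = hb)

  one <- evolve_split_operator(psi0, veff, dt = 0.01, n_steps = 1L)
  expect_lt(abs(wf_norm(one) - 1), 1e-10)

  many <- evolve_split_operator(psi0, veff, dt = 0.01, n_steps = 10000L)
  expect_lt(abs(wf_norm(many) - 1), 1e-7)

  # the splitting conserves <H> up to a bounded O(dt^2) oscillation, so the
  # 1e-6 relative bound is a statement at small dt, not at the coarse step
  e0 <- wf_energy(psi0, veff)
  fine <- evolve_split_operator(psi0, veff, dt = 1e-4, n_steps = 5000L)
  expect_lt(abs(wf_energy(fine, veff) - e0) / abs(e0), 1e-6)

  expect_error(evolve_split_operator(psi0, veff, dt = -1, n_steps = 1),
               class = "quantneuron_domain_error")
  other <- new_effective_potential(voltage_grid(4, 256), rep(0, 256))
  expect_error(evolve_split_operator(psi0, other, dt = 0.01, n_steps = 1),
               class = "quantneuron_domain_error")
})

test_that("Madelung decomposition and assembly invert each other", {
  g <- voltage_grid(3, 256)
  hb <- hbar_from_diffusion(0.05)

  # real positive state: S = 0
  psi_r <- initial_gaussian(-1.2, 0.3, g, hbar = hb)
  m_r <- madelung_decompose(psi_r)
  expect_true(all(abs(m_r$s[!m_r$masked]) < 1e-12))

  # generic complex state: round trip up to an optimal global phase
  veff <- effective_potential(fhn_params(), FX_W, hb, g)
  psi <- evolve_split_operator(psi_r, veff, dt = 0.01, t_final = 3)
  m <- madelung_decompose(psi)
  psi2 <- madelung_assemble(m)
  live <- m$rho > 1e-12
  phi <- Arg(sum(Conj(psi2$psi[live]) * psi$psi[live]))
  expect_lt(max(Mod(psi2$psi[live] * exp(1i * phi) - psi$psi[live])), 1e-12)

  # |assemble(rho, S)|^2 == rho exactly
  expect_lt(max(abs(Mod(psi2$psi)^2 - m$rho)), 1e-14)

  # plane-phase fixture: S recovered linear in v with slope k * hbar
  k_wave <- 2
  rho <- Mod(psi_r$psi)^2
  plane <- wavefunction(g, sqrt(rho) * exp(1i * k_wave * g$centers), hb)
  mp <- madelung_decompose(plane)
  slopes <- diff(mp$s[!mp$masked]) / g$dv
  expect_lt(max(abs(slopes - k_wave * as.numeric(hb))), 1e-10)

  # uniform density with zero action: constant real amplitude
  flat <- madelung_assemble(rep(1 / 6, g$n_cells), rep(0, g$n_cells),
                            hbar = hb, grid = g)
  expect_true(all(abs(flat$psi - 1 / sqrt(6)) < 1e-14))
  expect_error(madelung_assemble(rep(-1, g$n_cells), rep(0, g$n_cells),
                                 hbar = hb, grid = g),
               class = "quantneuron_domain_error")
})
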