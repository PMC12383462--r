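---
title: "Methods: from stochastic neuron dynamics to quantum-like emulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from stochastic neuron dynamics to quantum-like emulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quantneuron)
```

## The model

The package is organised around a single chain of reformulations of one
biophysical object: the fluctuating membrane potential of an excitable
neuron.

**Stochastic FitzHugh–Nagumo (FHN).** The dimensionless two-variable model
with additive Gaussian white noise on the fast (voltage) variable:

$$dv = \Big(v - \tfrac{v^3}{3} - w + I_{ext}\Big)\,dt + \sqrt{2D}\,dW_t,
\qquad dw = \frac{v + a - b\,w}{\tau}\,dt .$$

The recovery variable carries no noise. Note the $\sqrt{2D}$ amplitude
convention: some of the FHN literature writes $\sqrt{D}\,dW$; everything in
this package (the Fokker–Planck diffusion coefficient, the
quadratic-variation estimator, $\hat\hbar = \sqrt{2D}$) is consistent with
the $\sqrt{2D}$ form, and the Euler–Maruyama increment is
$\sqrt{2 D\,dt}\,\xi$.

**Fokker–Planck.** Conditional on a frozen recovery value $w_0$ the voltage
density obeys
$$\partial_t \rho = -\partial_v\big[f(v, w_0)\,\rho\big] + D\,\partial_v^2
\rho$$
on $v \in [-V_{max}, V_{max}]$ with *no-flux* (reflecting) walls: the
probability current $J = f\rho - D\,\partial_v\rho$ vanishes at both
boundaries. We enforce $J = 0$ itself; a boundary condition sometimes
written as $\partial_v\rho + (f/D)\rho = 0$ has the sign inconsistent with
zero current and is read as reflecting intent. Freezing $w$ is the reading
adopted throughout: the slow variable enters the one-dimensional problem
parametrically, and all three stages of the equivalence experiment use the
same $w_0$ (the resting fixed-point value by default) so the comparison is
well-posed.

**Nelson/Madelung map.** With the current velocity identified with the
drift $f$ and the osmotic velocity $u = D\,\partial_v \log\rho$, the
polar decomposition $\psi = \sqrt{\rho}\, e^{iS/\hat\hbar}$ with
$$\hat\hbar = \sqrt{2D}$$
converts the pair (continuity, Hamilton–Jacobi) into one linear
Schrödinger-type equation
$$i\hat\hbar\,\partial_t\psi = -\frac{\hat\hbar^2}{2m}\,\partial_v^2\psi +
V_{\mathrm{eff}}(v; w_0)\,\psi, \qquad
V_{\mathrm{eff}} = \tfrac12 f^2 - \frac{\hat\hbar}{2}\,\partial_v f,$$
with $\partial_v f = 1 - v^2$ available analytically. The reflecting
condition becomes Neumann, $\partial_v\psi = 0$ at $\pm V_{max}$. The
initial state is the real Gaussian
$\psi(v, 0) = (\pi\sigma_0^2)^{-1/4} e^{-(v - v_{rest})^2/(2\sigma_0^2)}$.

Two inequivalent definitions of the effective Planck constant circulate: the
diffusion route $\hat\hbar = \sqrt{2D}$ above, and a moment route
$\hat\hbar = m\sigma$ built from an effective inertial parameter and the
voltage standard deviation. They are not reconciled by the theory — for an
Ornstein–Uhlenbeck voltage with relaxation rate $k$ they differ unless
$m^2 = 2k$ — so the package computes both, provenance-tagged, and
`estimate_hbar()` always reports them side by side rather than silently
choosing.

## Default parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `a`, `b`, `tau` | 0.7, 0.8, 12.5 | – | the community-standard excitable regime; the reformulation itself leaves them symbolic |
| `i_ext` | 0 | – | resting, input-free neuron |
| `d_noise` (D) | 0.05 | v²/time | study noise intensity |
| `dt`, `t_final` | 0.05, 100 | time | study integration conditions |
| `n_traj` | 20000 | – | puts Monte Carlo L1 error well under the 0.05 envelope |
| `v_max` | 3 | v | window comfortably containing both drift wells |
| `n_cells` | 512 | – | resolves $\sigma_0$-scale features on $[-3,3]$ at negligible cost |
| `compare_cells` | 64 | – | histogram resolution for distance metrics (below) |
| `sigma0` | 0.2 | v | initial packet width; narrow relative to well separation, still ≥ 8 cells on the default grid |
| `v_rest`, `w0` | fixed point | v | deterministic resting state $(v^*, w^*) \approx (-1.1994, -0.6243)$ |
| `m` (mass) | 1 | – | the dimensionless equation omits it; kept as a first-class parameter |

All quantities are dimensionless "model units"; nominal mV/ms labels can be
attached by the user but are never used in computation.

## Numerical methods and their verification

**Euler–Maruyama ensembles.** Explicit first-order stepping is adequate for
additive noise at the study `dt`. Reproducibility uses per-trajectory
substreams: trajectory $i$ is generated from a generator seeded `seed + i`,
so ensembles can be grown without perturbing existing paths, and identical
(seed, parameters, grid) reproduce bit-identical ensembles. A consequence
worth knowing: root seeds closer together than `n_traj` share substreams, so
replicate studies should space their seeds. Trajectories are *not* reflected
at $\pm V_{max}$ — the walls belong to the PDE formulations — and
`empirical_density()` reports out-of-window mass explicitly instead of
clipping (in-window integral plus reported outside mass is exactly 1).

**Chang–Cooper finite volume.** The Fokker–Planck solver is a conservative
cell-centered scheme whose face flux uses the exponential-fitting weight
$\delta(x) = 1 + 1/(e^x - 1) - 1/x$, $x = f\,\Delta v / D$ (series for
$|x| < 10^{-4}$, upwind limits for $D = 0$). This makes the discrete flux
vanish identically on $\rho_{j+1}/\rho_j = e^{x}$, so the closed-form
stationary solution `fp_stationary()` is *exactly* stationary for the
scheme, positivity is preserved, and mass is conserved to round-off with
boundary fluxes pinned to zero. Stepping is explicit with a checked
stability bound `fp_stable_dt()`; violating it is an error naming the
admissible step. An implicit variant was considered and dropped: at the
study conditions the stable explicit step completes the full `T = 100`
solve on the default grid in a few seconds, so an implicit path would add
solver machinery without measurable benefit. Point initial conditions
(`fp_delta()`) split their mass
between the two adjacent cell centers so the discrete first moment equals
the requested location — without this, a start halfway between centers
costs a spurious half-cell shift that is clearly visible in L1 at fine
binning.

**Split-operator wave solver.** Strang splitting
$e^{-iV dt/2\hat\hbar}\, e^{-iT dt/\hat\hbar}\, e^{-iV dt/2\hat\hbar}$, with
the kinetic factor applied in an orthonormal DCT-II basis (cell-centered
cosine modes $k_m = \pi m / 2V_{max}$). A periodic-FFT kinetic step was
rejected because it imposes the wrong (periodic) boundary condition; the
cosine basis satisfies the Neumann condition exactly. Each factor is a pure
phase in its own orthonormal basis, so the discrete norm is conserved to
round-off per step (measured drift over $10^4$ steps: $<10^{-12}$). Energy
$\langle\psi|H|\psi\rangle$ is *not* exactly conserved by splitting — it
oscillates with a bounded $O(dt^2)$ amplitude set by the commutator of the
kinetic and potential factors — so the $10^{-6}$-relative conservation
property is checked (and holds with two orders to spare) at `dt = 1e-4`,
while coarse-step runs show the expected $10^{-3}$-scale oscillation. Both
closed-form benchmarks — free Gaussian spreading
$s(t) = \sqrt{s_0^2 + (\hat\hbar t / 2 m s_0)^2}$ while ≥ 5 widths from the
walls, and a coherent state in a harmonic well with period
$2\pi\sqrt{m/k}$ — are reproduced within 0.5%.

**Madelung decomposition.** $S = \hat\hbar \times$ phase unwrapped
sequentially outward from the density maximum; cells with
$\rho \le 10^{-12}$ are masked (`NA`), never extrapolated.
`madelung_assemble()` inverts the map exactly up to a global phase on
unmasked cells.

**Statevector circuits.** Gates are applied by index arithmetic on the full
$2^n$ amplitude vector (little-endian: qubit 0 is the least significant
bit; both label conventions are available and explicitly tagged). The RZ
convention is $\mathrm{diag}(e^{-i\theta/2}, e^{+i\theta/2})$; global phase
is declared irrelevant and tests compare up to it. The test suite checks
every circuit against an independent dense-matrix oracle to $10^{-12}$.
Two diagnostics address a question the low-depth neuron circuit raises:
`product_structure_test()` checks all conditional 2×2 odds ratios implied by
bitwise independence — a circuit without entangling gates *must* pass, so a
published outcome table that fails it cannot have come from a plain
single-qubit-gate circuit — and `register_mutual_information()` computes
quantum (von Neumann) mutual information between registers, the right
notion here because a diagonal CRZ coupling changes no computational-basis
probability and is invisible to classical mutual information of measured
bitstrings. The Hadamard layers are a kinetic *surrogate* in the
Trotterized circuit family; no claim is made that a Hadamard equals a
kinetic propagator (a documented limitation of the construction, not of the
simulator). Notably, the exact distribution of the default 3-qubit,
10-step circuit has its two modes at `000` (27.7%) and `100` (24.5%) —
while the remaining probabilities necessarily factorise over bits.

## The synthetic recording generator

`generate_synthetic_recording()` produces an Ornstein–Uhlenbeck voltage
path, $dv = -k(v - v_{rest})dt + \sqrt{2D}\,dW$, via the *exact* discrete
transition (no integration bias at any `dt`). The OU process is the
linearisation of the FHN voltage equation about rest and is the standard
minimal model of subthreshold fluctuations under weak synaptic drive; its
closed-form moments (stationary s.d. $\sqrt{D/k}$, AR(1) autocorrelation
$e^{-k\,dt}$) provide the oracles for every estimator test. What it does
*not* emulate: spikes and their afterpotentials, synaptic shot noise,
channel-state nonstationarity, electrode drift, or measurement noise. A
passing estimator suite therefore demonstrates correct recovery of a known
diffusion from an idealised stationary trace — a necessary condition — and
says nothing about robustness to the artefacts of real recordings, which is
why the detrending policy and estimation window are explicit, recorded
parameters rather than hidden defaults.

The quadratic-variation estimator $\hat D = \sum(\Delta v)^2 / 2T$ carries a
documented $O(k\,dt)$ mean-reversion bias (expectation
$D(1 - e^{-k dt})/(k dt)$, about 2.5% low at the study design point); the
`drift_adjusted` alternative fits the exact AR(1) form and removes it. At
$D = 0.05$, $k = 1$, $dt = 0.05$, $n = 40000$, the diffusion route recovers
$\hat\hbar = \sqrt{0.1}$ within 5% in all of 50 seeded replicates and the
moment route recovers $\sqrt{D/k}$ with ~1.4% median error. The effective
mass has no formula in the underlying theory ("capacitive and resistive
membrane properties" is as far as it goes), so it is a named policy —
default `m = C` — recorded in the output provenance, with user functions
accepted for alternatives.

## The equivalence experiment and what it shows

`run_equivalence_experiment()` runs all three representations under one
configuration and seed: (1) Euler–Maruyama ensemble of the frozen-$w_0$
voltage SDE → terminal histogram; (2) Fokker–Planck density from a
first-moment-preserving point mass at the same start; (3) split-operator
evolution of the real Gaussian initial state under
$V_{\mathrm{eff}}(\cdot; w_0)$ with $\hat\hbar = \sqrt{2D}$ → $|\psi|^2$.
Distances (L1, KL with a fixed $10^{-12}$ floor and recorded masking,
Wasserstein-1) are computed on a coarser `compare_cells` histogram grid so
the metric is not dominated by per-cell Monte Carlo noise, while the
exported curves keep solver resolution.

Two deliberate design decisions:

* **No pass/fail threshold on the stochastic-versus-quantum distance.**
  Exact Nelson correspondence requires the initial phase $S(v, 0)$ to encode
  the current velocity; the prescribed initial state is real ($S = 0$), so
  $|\psi|^2$ is not guaranteed to track the Fokker–Planck density, and under
  the default conditions it measurably does not (run
  `scripts/acceptance.R` to compute the distances). The experiment
  quantifies the gap instead of asserting a match; the overlay figure is for
  inspection.

* **The Monte-Carlo-versus-Fokker-Planck leg *is* asserted** (L1 ≤ 0.05 at
  20000 trajectories) — it is a genuine self-consistency check between two
  independent solvers of the same classical problem. One subtlety: with
  $w$ frozen at rest, the voltage drift is bistable with a small barrier
  ($\Delta U / D \approx 0.23$), and by $T = 100$ most mass has crossed into
  the much deeper depolarised well near $v \approx 1.99$, where
  $|f'| \approx 2.9$ makes the Euler–Maruyama stationary variance biased by
  roughly $|f'|\,dt/2 \approx 7\%$. The resulting L1 floor (~0.04 at
  `dt = 0.05`) is a *time-discretisation* bias, independent of ensemble
  size, so the $n^{-1/2}$ sampling-error scaling is verified in the
  pure-diffusion configuration, where the Euler–Maruyama terminal law is
  exactly Gaussian and sampling is the only error (measured L1 ratio at 4×
  trajectories: ≈ 0.5).

## Problem sizes

The test suite and acceptance script run the study conditions as stated
(`D = 0.05`, `dt = 0.05`, `T = 100`, 20000 and 80000 trajectories; 50
estimator replicates at 40000 samples; $10^4$-step unitarity runs), with
auxiliary checks on smaller grids chosen to keep each property sharp: the
free-spreading test uses a wide 1024-cell window so wall effects stay below
the 0.5% tolerance, and CLI/plumbing tests use few-thousand-trajectory
configurations since they assert reproducibility, not statistics.

## Known limitations

* The recovery variable is frozen during PDE and wave solves (a quasi-static
  $w$ update would be a straightforward extension; the one-dimensional
  formulation treats $w$ as a parameter).
* Only the single-neuron Schrödinger-type equation is solved on a grid;
  multi-neuron coherence lives exclusively in the circuit representation.
* The circuit layer simulates ideal statevectors: no hardware noise models,
  transpilation, or variational optimisation loops (the variational skeleton
  is built with fixed parameters).
* Real electrophysiology formats (ABF/NWB), spike removal and artefact
  rejection are out of scope for the estimators; input is plain (t, v) CSV.
* Euler–Maruyama at the study `dt` carries the variance bias quantified
  above; users probing fine distributional structure should reduce `dt` in
  the configuration.
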