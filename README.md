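# quantneuron

Quantum-inspired emulation of stochastic single-neuron dynamics in R.

Subthreshold membrane-voltage fluctuations are noisy, and that noise can be
treated as a modelling resource rather than a nuisance. `quantneuron`
implements, end to end, the mapping from a noisy excitable-neuron model to a
quantum-like formalism and the numerical machinery to interrogate it:

1. **Stochastic FitzHugh–Nagumo (FHN) model.** The fast membrane potential
   `v` and slow recovery variable `w` evolve as

   ```
   dv = (v - v^3/3 - w + I_ext) dt + sqrt(2D) dW_t
   dw = ((v + a - b w) / tau) dt
   ```

   with additive Gaussian white noise of intensity `D` on the voltage only.
   Seeded Euler–Maruyama ensembles with per-trajectory substreams
   (`simulate_fhn_ensemble()`, `empirical_density()`).

2. **Fokker–Planck equation.** The voltage density (recovery frozen at `w0`)
   obeys `∂t ρ = -∂v [f(v, w0) ρ] + D ∂v² ρ` on a bounded window with
   no-flux (reflecting) walls. Solved by a conservative Chang–Cooper
   finite-volume scheme that is positivity-preserving and exactly stationary
   on the zero-flux equilibrium (`fp_evolve()`, `fp_stationary()`).

3. **Nelson/Madelung reformulation.** Writing `ψ = sqrt(ρ) exp(iS/ħ̂)` with
   the *effective neuronal Planck constant* `ħ̂ = sqrt(2D)` (an alternative
   moment-based definition `ħ̂ = m·σ` is provided side by side) turns the
   stochastic dynamics into a Schrödinger-type equation

   ```
   i ħ̂ ∂t ψ = -(ħ̂²/2m) ∂v² ψ + V_eff(v; w0) ψ,
   V_eff = f²/2 - (ħ̂/2) ∂v f
   ```

   solved by a norm-preserving split-operator method in a cosine (Neumann)
   spectral basis so the reflecting boundary `∂v ψ = 0` holds exactly
   (`effective_potential()`, `evolve_split_operator()`,
   `madelung_decompose()`).

4. **Qubit-circuit emulation.** A dense statevector simulator (≤ 12 qubits)
   for the low-depth Trotterized neuron circuit family — Hadamard layers as
   the kinetic surrogate, per-qubit `RZ(θ/2^i)` phases (or a controlled-RZ
   variant) as the potential surrogate — plus two-neuron networks coupled by
   an entangling CRZ "synapse". Includes a bitwise product-structure
   diagnostic and register mutual information, JSON and OpenQASM 2.0 export
   (`build_neuron_circuit()`, `simulate_statevector()`,
   `product_structure_test()`, `register_mutual_information()`).

5. **Estimating ħ̂ from recordings.** Both routes from a voltage trace:
   `ħ̂ = sqrt(2 D̂)` via realised quadratic variation and `ħ̂ = m·σ̂` via the
   subthreshold voltage s.d. and an effective-mass policy, with a synthetic
   Ornstein–Uhlenbeck recording generator providing ground truth
   (`estimate_hbar()`, `generate_synthetic_recording()`).

6. **The equivalence experiment.** One call runs Monte Carlo ensemble →
   terminal histogram, the Fokker–Planck density, and `|ψ(v,T)|²`, and
   reports L1, Kullback–Leibler and Wasserstein-1 distances with full
   provenance and bit-reproducibility (`run_equivalence_experiment()`).

Everything is tidyverse-native: results are tibbles or carry `tidy()` /
`glance()` methods and `ggplot2::autoplot()` plots.

## Worked example

```r
library(quantneuron)

params <- fhn_params(d_noise = 0.05)   # classic excitable regime, D = 0.05
fhn_fixed_point(params)
#>       v      w residual
#> 1 -1.20 -0.624 1.11e-16
```

The resting state sits at `v* ≈ -1.199`. The diffusion route gives the
action scale directly:

```r
hbar_from_diffusion(0.05)
#> <hbar_eff> 0.316228 (from_diffusion)
```

Estimate the same constant from a synthetic subthreshold recording with
known ground truth (`D = 0.05`, relaxation rate `k = 1`):

```r
rec <- generate_synthetic_recording(k_relax = 1, d_noise = 0.05, dt = 0.05,
                                    n_samples = 40000, seed = 42)
estimate_hbar(rec, membrane_rc(capacitance = 1, resistance = 1))
#> <hbar_estimate>
#>   hbar (moment, m*sigma)      : 0.225432
#>   hbar (diffusion, sqrt(2D))  : 0.31516
#>   sigma_hat = 0.225432, d_hat = 0.0496631, m_eff = 1, n = 40000
```

The diffusion route recovers `sqrt(0.1) ≈ 0.3162` to 0.3%; the moment route
recovers `m sqrt(D/k) = sqrt(0.05) ≈ 0.2236`. The two definitions measure
different things on the same trace — both are always reported.

The three-qubit Trotterized neuron circuit (10 steps, 63 gates):

```r
probs <- measurement_probabilities(simulate_statevector(build_neuron_circuit()))
probs
#>   state probability
#> 1 000        0.277
#> 2 001        0.0484
#> 3 010        0.174
#> 4 011        0.0305
#> 5 100        0.245
#> 6 101        0.0429
#> 7 110        0.155
#> 8 111        0.0270
product_structure_test(probs)$is_product_over_bits
#> [1] TRUE
```

The modal outcomes `000` (27.7%) and `100` (24.5%) emerge from the phase
pattern, and — because the circuit contains no entangling gate — the full
distribution factorises exactly over the three qubits, which
`product_structure_test()` verifies through its conditional odds ratios.
Any published outcome table can be entered with `prob_table()` and checked
against the same diagnostic.

The end-to-end stochastic-versus-quantum comparison (here scaled down to
5000 trajectories, `T = 20`):

```r
rep <- run_equivalence_experiment(list(seed = 1L,
                                       fhn = list(n_traj = 5000L, t_final = 20)))
rep
#> <equivalence_report> seed 1, config 8b742911
#>   mc_vs_psi  L1 = 1.4378  KL = 2.1541  W1 = 2.0809
#>   mc_vs_fp   L1 = 0.0810  KL = 0.0067  W1 = 0.0163
#>   fp_vs_psi  L1 = 1.4380  KL = 2.1934  W1 = 2.0914
autoplot(rep)   # histogram + |psi|^2 + Fokker-Planck overlay
```

The Monte Carlo and Fokker–Planck densities agree closely (L1 = 0.08 at
5000 trajectories, shrinking as `n^(-1/2)`), while the wavefunction density
with the zero-phase Gaussian initial state is far from both — the initial
phase must encode the current velocity for exact correspondence, so the
experiment reports distances rather than asserting a match (see the methods
vignette).

## Command line

A thin CLI wraps the same functions (`simulate-sde`, `solve-fp`,
`solve-schrodinger`, `circuit`, `estimate-hbar`, `make-recording`,
`compare`, `equivalence`):

```sh
CLI=$(Rscript -e 'cat(system.file("cli/quantneuron", package = "quantneuron"))')
Rscript "$CLI" equivalence --config cfg.yaml --out results/
Rscript "$CLI" circuit --build trotter --steps 10 --out probs.json --export-qasm circuit.qasm
```

Configuration is one YAML schema (see `default_config()`); unknown keys are
rejected, every run logs its seed and config hash to stderr, and identical
config + seed reproduces outputs byte-for-byte.

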