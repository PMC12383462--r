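# Example run configuration for the quantneuron CLI and
# run_equivalence_experiment(). Omitted keys take package defaults
# (see default_config()); unknown keys are rejected.
seed: 1
fhn:
  a: 0.7
  b: 0.8
  tau: 12.5
  i_ext: 0.0
  d_noise: 0.05     # noise intensity D (hbar = sqrt(2D) = 0.3162)
  dt: 0.05
  t_final: 100
  n_traj: 20000
fp:
  v_max: 3
  n_cells: 512
  compare_cells: 64 # histogram resolution for the distance metrics
schrodinger:
  sigma0: 0.2       # initial Gaussian width
  mass: 1
  dt: 0.01
estimate:
  k_relax: 1
  d_noise: 0.05
  dt: 0.05
  n_samples: 40000
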