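K: 2.0
M: 2.0
preset: desk
a: 100.0
mu: 0.5
sigma: 1.0
x0: 0.4
xth: 1.0
xminus: 0.0
eta:
- 50.0
- 25.0
- 40.0
- 15.0
kernel_label: bursting
beta:
- 65.0
- 75.0
gamma: 20.0
tpm:
- - 0.8
  - 0.2
- - 0.2
  - 0.8
switching: discrete
poisson_rate: 2.0
v: 0.1
duration: 0.5
burn_in: 1.0
dt_stim: 0.01
sim_dt: 0.0001
pde:
  dt: 0.002
  dx: 0.04
  t_max: 2.0
propagation:
  V_lambda: 0.02
  V_gamma: 1.0
  V_beta: 4.0
  delta: 0.95
  v: 0.1
init:
  max_gamma: 40.0
  max_beta: 200.0
  max_S: 200.0
n_particles: 100.0
n_repetitions: 10.0
lag: 10.0
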