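# smcdecode

Sequential Monte Carlo decoding of stochastic stimulus mixtures from
leaky integrate-and-fire (LIF) spike trains, under the
probability-mixing model of visual attention.

## The problem

A neuron watching several simultaneous stimuli responds, at any given
moment, to exactly one of them; attention switches between the stimuli
following a Markov chain.  Given only the observed spike times, the
decoding task is to reconstruct the stochastic stimulus trajectories —
and the parameters of their law — online, as spikes arrive.  The
package is aimed at computational neuroscientists studying attention
schemes (serial vs parallel processing) and at anyone needing
first-passage-time likelihoods for diffusion neuron models.

## The model in brief

* **Encoding**: membrane potential
  `dX = (-a(X - mu) + I(t) + H(t)) dt + sigma dW`, spike and reset at a
  threshold; `I(t)` is the attended stimulus, `H(t)` a spike-response
  current with kernel `k_h(t) = eta1 e^(-eta2 t) - eta3 e^(-eta4 t)`
  (bursting / decaying / delaying presets).
* **Stimuli**: K Ornstein–Uhlenbeck components
  `dS^k = (beta^k - S^k) dt + gamma dW`; attention index `C_n` switches
  between 0.1 s intervals with transition matrix `Gamma`.
* **Likelihood**: products of interspike-interval first-passage-time
  densities obtained by a Crank–Nicolson solve of the cumulative
  Fokker–Planck equation; interval boundary terms are conditioned on
  survival so that interval log-likelihoods add exactly.
* **Decoders**: bootstrap filter (BF), auxiliary particle filter (APF)
  with Liu–West parameter learning, attention-marginalized variants
  (mBF/mAPF), serial and parallel population modes, k-medoids
  combination of individual decodes, fixed-lag and
  forward-filtering-backward-smoothing estimates.

## Worked example

```r
library(smcdecode)
set.seed(1)
sc  <- scenario_config(K = 2, preset = "desk")   # two-stimulus scenario
sim <- simulate_trial(sc, "single")              # stimuli + one spike train
res <- smc_decode(sim$trains, sc, method = "bf", mode = "single",
                  n_particles = 100, smoother = "lag", lag = 10)
res
#> <smc_decoding> bf / single / lag, 20 intervals of 0.100 s, K=2
#>   mean ESS 33.0, final gamma 35.34 +/- 2.61
evaluate_decoding(res, sim)
#> $rrmsd
#> [1] 1.860906
#> $rrmsd_smoothed
#> [1] 1.948962
```

The simulated train has 61 spikes over the 2 s window.  `res$estimates`
holds the posterior-mean attended stimulus per 0.1 s interval (here it
starts `78.2, 67.3, 68.8, ...`, tracking a mixture whose components
revert to 65 and 75); `mean ESS` is the average effective sample size
of the particle weights, and `rrmsd` is the root-mean-square decoding
error relative to the best interval-constant oracle, whose ideal value
is 1 (values around 2 are typical for a single short train at 100
particles; population decoding in serial mode reaches ~1.4).  The
`final gamma` line is the posterior mean ± sd of the stimulus diffusion
parameter (truth 20 here; single short trains leave it uncertain —
see the vignette).

A command-line front-end for decoding CSV spike trains, reproducing the
simulation scenarios and dumping ISI-density tables lives at
`inst/cli/smcdecode.R`.

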