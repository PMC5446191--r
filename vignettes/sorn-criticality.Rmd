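---
title: "Self-organized criticality signatures in a plastic recurrent network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-organized criticality signatures in a plastic recurrent network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`sorncrit` simulates a self-organizing recurrent network (SORN) of binary
threshold units: `N_E` excitatory units `x` and `N_I = 0.2 N_E` inhibitory
units `y`, updated in discrete time. An excitatory unit fires when its
recurrent excitatory drive minus its inhibitory drive, plus external input
and Gaussian membrane noise, reaches its adaptive threshold:

    x_i(t+1) = Theta[ sum_j W^EE_ij x_j(t) - sum_k W^EI_ik y_k(t)
                      + u^ext_i(t) + xi_i(t) - T^E_i(t) ]

Inhibitory units are simple threshold units driven by the excitatory
population. In this implementation their state follows the *newly
computed* excitatory state within the same step, so the
excitatory-inhibitory loop acts with a delay of one step:

    y_k(t+1) = Theta[ sum_j W^IE_kj x_j(t+1) - T^I_k ]

This is the convention of the classic SORN simulators. The alternative
reading — inhibition driven by the one-step-older excitatory state — gives
the loop a delay of two steps and produces a period-2 ringing of the
population activity whose statistics (activity mode far below the target
rate, duration exponents near 2.7) are unlike the regime this model family
is known for; we therefore fix the one-step convention and document it
here.

Five plasticity rules act on every step, in this order: STDP on existing
E→E synapses (±`eta_stdp` by spike order, with pruning of non-positive
weights), inhibitory STDP on existing I→E synapses (growing by
`eta_inh/mu_ip` when the target fired despite inhibition, shrinking by
`eta_inh` when inhibition succeeded), structural plasticity (one Bernoulli
trial per step, probability `p_SP`, creating one uniformly chosen missing
synapse at weight `eta_sp`), intrinsic plasticity (thresholds move by
`eta_ip (x_i - H_i)` toward per-unit target rates), and synaptic
normalization last (each unit's incoming E weights, and separately its
incoming I weights, rescaled to sum 1).

### Default parameters

| parameter | default | meaning |
|---|---|---|
| `N_E` | 200 | excitatory units (`N_I = 40`) |
| `eta_stdp` | 0.004 | STDP step per causal spike pair |
| `eta_inh` | 0.001 | iSTDP depression step (potentiation `eta_inh/mu_ip` = 0.01) |
| `eta_ip` | 0.01 | threshold adaptation step |
| `eta_sp` | 0.001 | weight of a newly created synapse |
| `p_sp_200` | 0.1 | synapse-creation probability per step at `N_E = 200`, scaled by `N_E(N_E-1)/(200·199)` |
| `mu_ip` | 0.1 | target rate: 10% of units fire per step (≈ 5–10 Hz at 10–20 ms per step) |
| `sigma_sq` | 0.05 | membrane-noise variance for the spontaneous-activity experiments |
| `T_E_max`, `T_I_max` | 0.5, 1.0 | initial/fixed threshold ceilings |
| `p_ee_init`, `p_ei_init` | 0.1, 0.2 | initial wiring probabilities |

### Where the noise enters

By default only the excitatory units draw membrane noise. This is a
deliberate dynamical choice. With noise-free inhibitory units and fixed
thresholds uniform on [0, 1], the fraction of inhibitory units that
responds to a population activity `a` is exactly `a / N_E` — an inhibitory
feedback that is *linear in the activity with unit gain*, which places the
excitatory-inhibitory loop at the marginal balance where the
avalanche-style activity fluctuations live. Smearing the inhibitory
response with noise of standard deviation ≈ 0.22 flattens that response
(effective gain ≈ 0.67), leaving net positive feedback; in simulation this
reliably produces a runaway into strongly bursty stable states whose
activity mode sits far below the target rate. `noise_model(inhibitory =
TRUE)` restores the noisy-inhibition variant for comparison.

## Avalanches and fitting

Network activity `a(t)` (the number of excitatory spikes per step) rarely
falls to zero at the homeostatic target, so avalanches are defined by
thresholding: `theta` is half the mean activity (rounded half-up), an
avalanche is a maximal run of steps with `a(t) > theta`, its duration `T`
is the run length and its size `S` the summed exceedance. Runs touching
either end of the trace are censored — their true extent is unknown. An
alternative size `S'` sums `a(t)` without subtracting `theta`.

Durations and sizes are integers, so all fits use discrete likelihoods.
The truncated power-law MLE maximizes
`sum log[ x^-alpha / sum_{k=x_min}^{x_max} k^-alpha ]`
by bounded one-dimensional optimization (tolerance 1e-6, recorded in the
fit object); the reference windows are T ∈ [6, 60] and S ∈ [10, 1500] for
`N_E = 200`, with the size ceiling scaled proportionally to `N_E` and the
duration ceiling with `sqrt(N_E/200)` for larger networks. The power law
with exponential cutoff `x^-alpha* exp(-beta* x)` is fitted by bounded
two-dimensional optimization with the normalizer summed to a documented
bound (ten times the largest sample, at least 1e5). Model comparison uses
the signed log-likelihood ratio on the shared in-window samples: positive
values favor the power law. A discrete truncated exponential serves as the
alternative model. Exponential binning (log10 bin width `b_s = 0.1`) is
used for plotting-style densities; the fitted exponents do not depend on
the bin width, which the test suite checks.

The crackling-noise relation predicts that mean size scales with duration
as `T^((alpha-1)/(tau-1))`. The package computes both the prediction and
the directly fitted slope `gamma` of `log <S>(T)` versus `log T`; in this
model the two disagree by more than 0.2, a mismatch that is itself one of
the reproduced findings.

## The pooled measurement protocol

A single network self-organizes through three phases of its E→E
connection fraction — fast decay of the random initial graph over the
first ~1e5 steps, slow regrowth through structural plasticity, and a
plateau reached around 2e6 steps. All measurements discard the first 2e6
steps. Individual self-organized networks settle into stable states whose
fine statistics differ from run to run (plateau connection fractions
roughly 0.06–0.17, with correspondingly flatter or steeper single-run
avalanche distributions); the headline exponents are therefore properties
of the *pooled ensemble*, and `run_criticality_protocol()` implements
exactly that: independent networks, one measurement window each,
avalanches pooled before fitting. At full scale the ensemble holds 50 runs
of 1e6 measured steps; the test suite and the acceptance script use 6–8
runs. With the default settings the pooled duration exponent lands in
the 1.5–1.8 range, the size exponent in 1.35–1.55, the alternative-size
exponent `tau'` more tightly in 1.28–1.43, `gamma` in 1.2–1.45, and the
pooled activity distribution peaks at 8.5–10% of `N_E`. The pooled
estimates still move noticeably between ensemble seeds because the
attractor mixture varies; `tau'` (the size definition without the
threshold subtraction) is the most stable of the exponents, since the
threshold-subtracted size carries a long left cutoff in the
sparse-network stable states.

## Learning tasks and the readout

Two tasks probe sequence learning. The Counting Task alternates the
letter sequences `ABB…BC` and `DEE…EF` (`n` middle repeats, coin-flip
choice); the Random Sequence Task cycles one fixed random word of length
`L` over a 10-letter alphabet. Each letter drives a fixed random subset
of `0.05 N_E` excitatory units with a supra-threshold input.

The protocol: 5e4 plastic steps under the task input; then a linear
readout is trained for 5000 steps by the Moore–Penrose pseudo-inverse on
one-hot letter targets and scored on 5000 further steps (fraction of
correctly predicted letters; for the Counting Task each sequence's first
letter is excluded, since sequence identity is random). The readout
feature `x'(t)` is the network's internal prediction of its own next
state: the thresholded recurrent drive with the external-input term
removed.

Three aspects of the evaluation are underdetermined by the verbal
protocol, and we fix them as follows, as the package's design choices:

* **Plasticity is frozen after the plastic phase.** The readout maps a
  fixed feature dictionary to letters; if the reservoir keeps rewiring
  between training and test, the dictionary drifts and performance
  reflects the drift rather than the learned structure.
* **The readout windows run noise-free.** The `noise` argument shapes
  self-organization; the evaluation asks what the self-organized
  reservoir encodes. Keeping the per-step noise active during evaluation
  lowers Random-Sequence performance at `L = 100` from ≈ 92% to ≈ 62–73%,
  far below what this architecture demonstrably encodes; membrane noise
  still exerts its documented degrading effect through the plastic phase
  (the noise level that produces the criticality signatures, variance
  0.05, measurably lowers Counting-Task performance relative to the
  noise-free arm).
* **`x'(t)` is deterministic.** The feature excludes both the input term
  and the noise draw, making it a pure function of the previous network
  state — the quantity a downstream readout could actually compute.

Both alternatives remain available (`freeze_after_plastic`,
`readout_noise_free`, `features_with_noise`).

A note on noise units: the spontaneous-activity experiments specify the
Gaussian noise by its *variance* (0.05); the task experiments specify a
*standard deviation* of 0.05 (variance 0.0025) and a noise-free control.
The package keeps `sigma_sq` as the single parameter and the task helpers
default to `sigma_sq = 0.0025`.

## Numerical and implementation notes

* The stepping loop is compiled (Rcpp). Weights are stored with per-row
  scale factors so that synaptic normalization is O(N_E) per step; the
  scales are folded into the matrix every 256 steps and before any state
  is returned, which is algebraically identical to per-step division.
  Pure-R implementations of every rule are exported, and a test pins the
  engine to their composition step for step.
* All randomness flows through named, seeded streams — initialization,
  membrane noise, structural-plasticity choices, input letters — so a
  frozen-network comparison can share its noise stream between arms, and
  every run is bit-reproducible. The compiled streams are xoshiro256**
  with explicit uniform and polar-normal transforms, independent of any
  standard-library distribution implementation.
* The step function fires at exact equality (`Theta(0) = 1`); thresholds
  are not clipped; a unit that loses all incoming synapses of a class is
  left unnormalized; at most one synapse is created per step; iSTDP
  floors weights at zero but keeps the connection slot.
* Degenerate fits (all samples at the window floor) are flagged rather
  than reported as exponents; fits require at least 50 in-window samples.

## What the generator does and does not emulate

All inputs are generated internally: the synthetic power-law sampler
validates the fitting stack against exactly known distributions, and the
network itself generates the avalanche data. Passing tests therefore
demonstrate internal consistency of model, detector and fits — they do
not validate the model against biological recordings, and the binary,
fully-observed, discrete-time network omits known features of cortical
data (subsampling, refractoriness, conduction delays, continuous time).
The qualitative transient-flattening after input onset is reproduced; no
quantitative match to in vivo exponents is claimed.

## Known limitations

* Single-run exponents are attractor-dependent (see the pooling section);
  quantitative statements should always be made on pooled ensembles.
* The exponential-cutoff fit can sit at its `beta = 0` boundary for pure
  power-law samples; the likelihood-ratio against the pure power law is
  the meaningful comparison there.
* Very large networks (`N_E` in the thousands) are simulated with dense
  weight storage; memory grows as `N_E^2`.
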