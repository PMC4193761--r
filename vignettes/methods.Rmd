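---
title: "Models, distortions and compensation strategies in spikefidelity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, distortions and compensation strategies in spikefidelity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(spikefidelity)
```

`spikefidelity` studies how network-level imperfections of imperfect
simulation substrates — analog neuromorphic systems being the motivating
case — distort the dynamics of spiking network models, and how those
distortions can be compensated by adjusting the model configuration. The
package follows a five-stage workflow: define a benchmark network with
quantitative functionality criteria; measure those criteria on the
undistorted ("reference") model; inject a distortion mechanism; measure
again; apply a compensation strategy and verify that the criteria recover.

This vignette explains the models, the numerical choices, and the design
decisions that were genuinely open, in the package's own words. Everything
quantitative claimed here is computed by the test suite or by
`scripts/acceptance.R`; the vignette itself states no measurement that the
code does not reproduce.

## Neuron and synapse model

All neurons are adaptive exponential integrate-and-fire (AdEx) point
neurons with two conductance-based synaptic input channels:

$$C_m \dot V = -g_L (V - E_L) + g_L \Delta_T e^{(V - V_T)/\Delta_T}
  - g_e (V - E_e) - g_i (V - E_i) - w + I_{ext},$$
$$\tau_w \dot w = a (V - E_L) - w,$$

with a spike emitted when $V$ crosses $V_{spike}$ (or $V_T$ when
$\Delta_T = 0$, the leaky integrate-and-fire reduction used by several
benchmark cell types), followed by a reset to $V_{reset}$, the increment
$w \to w + b$, and a refractory clamp of $V$ at $V_{reset}$ for
$\tau_{ref}$. Each neuron has one excitatory and one inhibitory conductance
channel with a single exponential decay constant each; synapses carry
non-negative peak conductances, and the sign of their effect lives entirely
in the reversal potential. This mirrors substrates that implement one input
circuit per receptor class and cannot flip a synapse's sign.

Short-term plasticity follows the Tsodyks–Markram formulation, evaluated
with the exact inter-spike recursions for the utilization $u_n$ and the
recovered resource $R_n$ at presynaptic events only. Depression and
facilitation are exclusive modes: depression holds $u_n = U$; facilitation
evolves $u_n$ with $\tau_{facil}$ while resource recovery stays active.

### Integration scheme

The simulator (C++ core, `simulate_network()`) uses exponential-Euler
stepping for membrane and adaptation with event-driven conductance jumps on
a fixed grid, $dt = 0.01$ ms by default. The exponential spike-initiation
term is treated explicitly with its argument bounded; divergence is caught
and reported, never silently propagated. Synaptic delays are rounded to the
nearest step with a one-step minimum. For the homogeneous leak equation the
stepping is exact, which the tests exploit by asserting the passive
relaxation at $10^{-9}$ mV; the full single-neuron dynamics are held to a
0.5 mV sup-norm against an independent adaptive-step `deSolve` integration.
Network experiments use $dt = 0.02$–$0.05$ ms, a deliberate trade of
single-spike timing precision (still well below every synaptic time
constant) for tractable sweep sizes; the per-model problem sizes quoted
below are the package's chosen defaults.

All randomness — connectivity, Poisson background, stimuli, distortion
draws — is generated on the R side under explicit seeds; the core loop is
bitwise deterministic, and re-instantiating a network with the same seed
reproduces the identical synapse table. The iterative compensation depends
on this determinism.

## The three benchmark architectures

Parameter values that the benchmark descriptions leave to supplementary
material are **config entries with placeholder defaults** taken from the
standard modeling literature for each architecture (`synfire_config()`,
`l23_config()`, `ai_config()`). They are deliberately labeled
non-authoritative: they were chosen once, so that each undistorted model
exhibits the published qualitative regime, and are exposed for users who
possess the original tables.

### Synfire chain with feed-forward inhibition

Six groups of 100 regular-spiking (RS) excitatory and 25 fast-spiking (FS)
inhibitory LIF neurons. Each RS population projects to the RS and FS
populations of the next group (fixed in-degree 60, intergroup delay 20 ms —
a visualization convention without dynamical consequence, since both
intergroup projections share it); FS inhibit their local RS population with
an adjustable delay `d_inh` (default 4 ms). Every neuron receives an
independent 2 kHz, 1 nS Poisson background. A stimulus population of 100
sources, wired like an upstream RS group, delivers a Gaussian pulse packet
parameterized by spikes-per-source $a$ and spread $\sigma$.

The chain acts as a filter in the $(\sigma, a)$ plane: packets inside the
stable basin sharpen into full synchronous volleys ($a_6 \approx 1$,
$\sigma_6 < 0.5$ ms); packets outside die out. Propagation is classified at
the sixth group with a closed success boundary $a_6 \ge 0.5$, halfway
between the two activation clusters. The feed-forward weight (0.7 nS) was
calibrated once so that the default chain propagates an $(a=1, \sigma=1$
ms$)$ packet with a silent background between volleys; under homogeneous
synapse loss of the internal and stimulus projections the first
majority-vote failure then falls at the 30% grid point, inside the
published 30–40% window, and the $1/(1-p)$ weight compensation restores
propagation through 90% loss.

### Layer 2/3 attractor memory

A columnar patch of `n_hc` hypercolumns (HCs) on a hexagonal grid, each
with `n_mc_per_hc` minicolumns (MCs) of 30 pyramidal (PYR), 2 regular
spiking non-pyramidal (RSNP) and 1 basket (BAS) cell — 2673 neurons at the
default 9×9. Same-index MCs across HCs form orthogonal patterns
(attractors). PYR within an MC connect recurrently at 25%; long-range
PYR–PYR runs within a pattern; BAS cells implement a soft winner-take-all
per HC (input from the 8 ring-closest other MCs, output to all PYR of the
HC); disynaptic PYR→RSNP→PYR inhibition mediates rivalry between patterns.
PYR–PYR synapses depress (Tsodyks–Markram), and PYR cells adapt, limiting
attractor dwell times. Five layer-4 source cells per MC provide pattern
stimulation; one diffuse Poisson source per PYR provides background.

Two design points the architecture text leaves open: "the 8 closest MCs"
is measured on the HC-internal MC index ring (no intra-HC geometry is
specified), degrading to "all other MCs" with a warning below 9 MCs per
HC; axonal delays are HC-centroid distances at 0.2 m/ms with the intra-HC
delay at the configured minimum, spanning roughly 0.5–8 ms at the default
spacing.

Attractor episodes are detected from per-pattern PYR rates smoothed with a
20 ms Gaussian kernel and a hysteresis rule (activation at 3× the
all-pattern mean rate, deactivation at 2×, winner-take-all on ties); all
constants are arguments of `detect_attractors()`. This detector is this
package's own substitute for an unavailable published algorithm, validated
on scripted rasters with known episode boundaries.

### Self-sustained asynchronous-irregular (AI) network

3920 AdEx neurons (3136 excitatory PY, 784 inhibitory INH — the 4:1
cortical convention, since the source ratio is not stated) scattered
uniformly on a 2 mm torus. Every neuron draws exactly 63 excitatory and 16
inhibitory afferents — fixed in-degrees, chosen with Gaussian distance
weights of width $\sigma_{space}$, so afferent counts are identical across
neurons while connectivity stays local. Conduction delays are torus
distance over 0.2 mm/ms with $\sigma_{space} = 0.2437$ mm calibrated so
the mean instantiated delay is 1.55 ms, the stated property of the
reference geometry. A stimulus population near the origin kick-starts
activity for 50 ms; afterwards the network must sustain itself.

PY adaptation was fixed at $b = 20$ pA (within the regular-spiking range of
the cited parameter lineage) during baseline calibration: with weak
adaptation the model sustained marginal states below 8 Hz, contradicting
the published property that self-sustained states occur only above that
rate; with $b = 20$ pA the survival boundary sits near 10 Hz and marginal
states die out. The default operating point is $(g_{exc}, g_{inh}) =
(9, 90)$ nS.

The statistics bundle (`ai_statistics()`) reports survival (spikes within
100 ms of the end of the run), mean PY rate, the rate CV across neurons,
the mean per-neuron ISI CV, the mean pairwise Pearson correlation of 2 ms
binned counts over 1000 sampled pairs, and the non-zero peak of the
Gaussian-smoothed (2 Hz) population-rate power spectrum binned at 1 ms.
Bin sizes and smoothing widths are package defaults (the source values are
unavailable), config-exposed throughout.

A note on regime: the package's AI default sits in a locally-clustered,
somewhat bursty corner of the asynchronous-irregular family (ISI CV ≈ 2,
rate CV ≈ 0.3) rather than the maximally homogeneous one; pairwise
correlations stay in the published ≤ 0.03 band. This is a consequence of
the dense local connectivity footprint that the delay calibration implies
at 0.2 mm/ms.

## Distortion mechanisms

Three mechanisms, each seedable and composable in the canonical order loss
→ weight noise → uniform delays (`apply_distortions()`):

* **Synapse loss** deletes each instantiated synapse independently with
  probability $p$, globally or per projection label (so heterogeneous,
  mapping-derived loss tables can be replayed). Synapses mediating
  external input can be exempted, reflecting substrates that prioritize
  them.
* **Weight noise** replaces each weight by a draw from
  $\mathcal N(w, (r w)^2)$ clipped at zero; receptor identity never flips.
  Clipping raises the mean by $\Phi(1/r) + r\,\varphi(1/r) - 1$ — 0.425%
  at $r = 0.5$ (`expected_clipped_mean_shift()`); re-centering is off by
  default because the shift is negligible at the studied levels, but
  available. A `frozen` flag distinguishes fixed-pattern noise (redrawn
  only with the network seed; required by the iterative compensation) from
  trial-to-trial noise.
* **Uniform delays** overwrite every delay with one value (default use
  case: 1.5 ms), keeping the original distribution in a report. For the
  default AI geometry this is a near-null distortion, since the mean
  distance-derived delay is 1.55 ms by construction.

## Compensation strategies

* **Loss → weight rescaling** (`compensate_loss_by_weights()`): surviving
  weights of projection $j$ are multiplied by $1/(1-p_j)$, restoring the
  expected product of weight and afferent rate per target exactly in
  expectation. The residual effect is an increased variance of the summed
  conductance — visible as the gradual widening of the synfire volley
  before failure.
* **Multi-source background** (`multi_source_background()`): the
  single-synapse background of each neuron is replaced by `k` sources
  drawn from a shared pool, each at `1/k` of the aggregate rate with the
  weight unchanged, preserving the expected background conductance exactly
  while averaging single-synapse weight noise. Source sets of two neurons
  overlap by $k^2/N_{pool}$ in expectation.
* **Membrane-statistics matching** (`compensate_noise_via_rest_potential()`):
  under weight noise the second moment of the background weight grows by
  $(1+r^2)$. Scaling the background weight by $1/\sqrt{1+r^2}$ restores
  the free-membrane variance, and raising $E_L$ by the lost mean drive
  over $g_L$ restores the mean, both in the effective-current
  approximation valid for high-rate, small-weight background. The tests
  verify the restored moments by simulation to 2% (mean) / 5% (variance).
* **Inhibition reshaping** (`compensate_delay_via_inhibition()`): when the
  local inhibition delay is not configurable, its synaptic time constant
  is stretched (default ×3) and its weight scaled, extending the
  inhibition window; the inhibitory charge per event ($\propto w\tau$) is
  reported so equal-charge settings can be compared.
* **Mean-field time rescaling** (`measure_gain_function()`,
  `self_consistent_rate()`, `mean_field_compensate()`): the single-neuron
  gain function — output rate against the rate of its $(1-p)K_E$
  excitatory and $(1-p)K_I$ inhibitory Poisson afferents — predicts the
  self-sustained network rate as its stable fixed point. The compensation
  factor is $\lambda = \nu^*_{ref} / \nu^*_{dist}$, and the network is
  time-rescaled by $\lambda$. The exact rescaling multiplies $g_L$, $a$,
  $b$, $I_{ext}$ and the synaptic conductance jumps by $\lambda$ and
  divides every time constant and delay by it: compressing a Dirac spike
  train in time carries a $1/\lambda$ density factor, so the jump must
  scale for the rescaled system to replay the original trajectories with
  time divided by $\lambda$ — equivalently, the jump is unchanged
  *relative to the rescaled leak*. The tests pin this identity to
  machine precision on a deterministic single neuron.
* **Iterative threshold calibration** (`iterative_compensate()`): under
  frozen distortions, each neuron's threshold moves by
  $\alpha(\nu_i - \nu_{target,i})$ per iteration (mV per Hz), with an
  optional per-iteration step decay and a divergence guard. Two details
  matter in recurrent networks and were settled empirically during design:
  the offset shifts the spike-initiation threshold *and*, for AdEx cells,
  the detection threshold with it (moving only the exponential takeoff
  leaves barrage-driven neurons uncontrollable, and the population mean
  then equilibrates several percent above target), and *both* cell
  populations are calibrated toward their own reference rates (calibrating
  the excitatory cells alone opens a disinhibition feedback with the same
  bias). Targets may be per-neuron vectors for exactly this reason. On a
  single neuron with an analytically known rate–threshold relation the
  loop lands on the closed-form threshold; on the default-size AI network
  under 50% frozen weight noise, 14 iterations restore the pyramidal rate
  to within the 5% contract with the rate CV back at its reference value.
  The stable step range is set by the population-level rate sensitivity
  (roughly $\alpha < 1/S$ with $S$ in Hz/mV).

## Experiment orchestration

`run_experiment()` executes build → distort → compensate → simulate →
analyze over named parameter grids with per-cell derived seeds (a cell can
be regenerated bit-identically in isolation) and per-cell error capture.
`synfire_loss_scan()` and `pattern_protocols()` (pattern completion and
attentional blink, with a pluggable simulation backend that the tests
exercise with scripted mock dynamics) wrap the two protocol families; the
trial counts default to 25 (completion) and 14 (blink) per grid point,
config-exposed. A thin command-line wrapper (`inst/cli/spikefidelity`)
exposes build/simulate/sweep/analyze over YAML configs; the R functions are
the tested surface.

## What the synthetic conditions do and do not show

The package's generators emulate the *published study conditions*: network
sizes (750-neuron chain, 2673-neuron columnar patch, 3920-neuron AI sheet),
background statistics, distortion magnitudes (loss and noise up to 50%,
uniform 1.5 ms delays) and protocol shapes. They do not emulate substrate
effects outside scope — bandwidth-induced spike loss, spike-time jitter,
parameter noise on non-weight parameters, or heterogeneous per-neuron
calibration error — so passing tests demonstrate correctness of the
modeling and compensation machinery under idealized distortions, not
performance of any physical device. Supplementary-only parameter values are
placeholders; users with the authoritative tables should override the
config defaults before interpreting absolute numbers such as dwell times.

Problem sizes in the always-on test suite are chosen for desk-scale runs:
synfire scans use 5 repetitions per 10%-step loss value; AI grids use
$\{5,6,9,12\} \times \{50,90,130\}$ nS at 4 s per state; the large-scale
(22 445 neuron) reference statistics and the columnar gamma-peak analysis
are long-running optional studies that the builders support
(`scale_model("ai", 22445)` constructs in minutes) but the suite does not
execute.

## Known limitations

* The AI default regime is burstier than the most homogeneous AI states;
  mean-rate control by per-neuron thresholds is correspondingly noisy at
  small network sizes, and the iterative compensation's contract is
  asserted at the default (3920) size, not on fluctuation-dominated
  downscaled variants.
* The mean-field gain function assumes Poisson afferents at a common rate;
  in strongly clustered states it underestimates recurrent synchrony and
  its fixed point can disagree with the network rate. It is exposed as a
  measurement tool plus the exact rescaling operator, and validated on
  constructed gain tables and deterministic rescaling identities.
* `rule_gaussian_in` keeps in-degrees exact by weighted sampling without
  replacement; for very small pools this slightly fattens the connected
  distance distribution relative to the Bernoulli profile, which the delay
  calibration absorbs.
* The attractor detector, separatrix fit (logistic regression in
  $(\sigma_0, a_0)$ with the 5–95% probability band as transition width),
  volley filter, and spectrum settings are declared substitutes for
  unavailable published procedures, validated against scripted ground
  truth rather than against the original implementations.
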