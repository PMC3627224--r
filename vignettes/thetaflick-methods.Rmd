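---
title: "Methods: theta-cycle assembly flickering and pyramidal-interneuron coupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: theta-cycle assembly flickering and pyramidal-interneuron coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thetaflick)
```

## The problem

During goal-directed spatial learning on a cheeseboard arena, CA1 place
cells partially remap: a "new" spatial map develops alongside the "old"
one, and within single theta cycles (5-12 Hz) the pyramidal population
expresses one map or the other - flickering between them, with the new
map's prevalence growing across learning trials. This package implements
the analysis chain used to study that phenomenon and its circuit
consequences from extracellular recordings (spike times, position
tracking, LFP):

1. behavioral-state segmentation and oscillation detection from the LFP;
2. occupancy-normalized place-field rate maps with tuning screens;
3. per-theta-cycle population-vector scoring of which map is expressed;
4. classification of interneurons by the association of their firing with
   map expression;
5. cross-correlogram (CCG) detection of monosynaptic pyramidal-to-
   interneuron connections, with spike-transmission probability and
   latency tracked across sessions;
6. predictors of connection change (spike pairing, goal-area split,
   coincident spike density).

Because such analyses can only be validated against ground truth, the
package also ships a synthetic five-session generator
(`simulate_session()`): every estimator has a known recovery target.

## The assembly-expression score

Probe-session rate maps of the recorded pyramidal cells are stacked into
population-vector arrays (one vector of per-cell rates per spatial bin),
separately for the probe before learning (old map) and after learning
(new map). For a theta cycle at location bin $b$ with instantaneous-rate
vector $v$ (spike count / cycle duration per cell), two Pearson
correlations are taken across cells: $r_{pre} = \mathrm{cor}(v, P_b)$
and $r_{post} = \mathrm{cor}(v, Q_b)$ with $P, Q$ the pre/post stacks.
The score is Fisher's comparison of the two correlations,

$$ z = \frac{\operatorname{atanh}(r_{post}) - \operatorname{atanh}(r_{pre})}{\sqrt{2/(n-3)}}, $$

with $n$ the number of cells. Positive $z$ means the cycle expresses the
new map. Two caveats are deliberate design choices:

* The two correlations share the cycle vector, so they are statistically
  dependent; the independent-samples Fisher form is nevertheless used
  because it is the field's convention for this score. Its *sign* - the
  quantity actually decoded - is unaffected.
* Cells silent in both the cycle and the probe vectors are retained
  (configurable); cycles whose vectors are constant (for instance
  all-zero) are flagged invalid rather than imputed.

The score has two exact symmetries that the tests assert: swapping the
stacks negates $z$, and identical stacks give $z = 0$.

## Interneuron firing associations

For each interneuron, the instantaneous firing rate (IFR) per theta cycle
is correlated (Pearson) with $z$ over the valid cycles of the last 10
learning trials. Units with $p < 0.05$ are classed `pInt` ($r > 0$) or
`nInt` ($r < 0$), otherwise `uInt`. A logistic regression of the new-map
indicator ($z > 0$) on the IFR is reported as confirmation (Wald
$|z| > 1.960$) but never drives the class. The p-values are deliberately
uncorrected for multiplicity, matching the original screen. Serial
autocorrelation of the IFR could in principle inflate the nominal type-I
rate; with homogeneous-within-cycle synthetic interneurons the empirical
false-positive rate is at its nominal 5% (the acceptance benchmarks
check this with 200 uncoupled units).

The rate-change index per unit is $(r_{last} - r_{first}) /
(r_{last} + r_{first})$ over the first and last 10 minutes of learning,
undefined (flagged) when both are zero.

## Monosynaptic coupling

CCGs use 0.5 ms bins over ±50 ms, counts normalized by the number of
reference (pyramidal) spikes, so a bin's value is the probability of an
interneuron spike at that lag per pyramidal spike. The bin width is a
design choice: it makes the monosynaptic window (0.5-2.5 ms), the 5 ms
control bin and the 30-50 ms chance bins exactly addressable. Chance is
the mean over the 30-50 ms bins on both sides; a pair is significant
when the peak probability in the 0.5-2.5 ms bins exceeds chance by 3
baseline SDs. Spike-transmission probability is the baseline-subtracted
mass over the monosynaptic bins; latency is its center of mass (sub-bin
precision; the peak-bin center is retained as an alternative). Detection
is decided on the full-day pooled CCG; per-epoch values (probes, learning
quartiles, sleep sessions) are then computed for detected pairs, with
epochs under 100 reference spikes flagged and excluded from deltas.

Two dialects appear in the source literature for the chance window
(30-50 ms vs the first/last 20 ms of the histogram); the 30-50 ms form is
normative here and the alternative is reachable through
`chance_baseline(from=, to=)`. The coincidence correlation coefficient -
per-lag covariance of the binned trains divided by the geometric mean of
their SDs - is provided as the rate-independent companion measure; the
printed formula in the source is ambiguous ("square root of standard
deviation"), and the Pearson-style normalization is our documented
interpretation.

**Small-count caveat.** The 3 SD rule behaves like a $p \approx 10^{-3}$
Gaussian test only when baseline bins hold tens of counts. With ~600
reference spikes and a 10 Hz partner (about 3 counts per baseline bin)
the Poisson tail is heavier: the false-positive rate over independent
pairs is ~2-4%, not below 1%. This is a property of the published rule at
desk-scale spike counts, and the package reports it rather than altering
the rule.

## Plasticity predictors

Pairing events are presynaptic spikes (during theta epochs of learning)
preceded and/or followed by an interneuron spike within an open 20 ms
window, counted per presynaptic spike (binary: multiple followers in one
window count once - the "events" reading; the alternative is a
configuration away). Events are positioned by track interpolation and
split by goal areas (radius 20 cm by default; the source never defines
the area numerically, so the radius is an explicit free parameter).
Interneuron spike density is the sum of unit-integral Gaussian kernels
($\sigma$ = 20 ms), evaluated by exact summation (kernels truncated at
10$\sigma$, error < 1e-20 of a kernel). Partial correlations are
computed by residualization: both variables are regressed on the control
and the residuals correlated.

## The synthetic generator

`sim_config()` defines the simulated day; its defaults are the study
conditions, not tuning knobs:

* **Protocol**: preprobe, presleep, 40 learning trials, postsleep,
  postprobe; 25 min probes and rests, 45 s trials. Trial duration and
  inter-trial structure are free parameters (the protocol source does not
  state them).
* **Population**: 40 pyramidal cells (the recorded median; 14-71 is the
  plausible range), interneurons at 15 Hz baseline.
* **Place fields**: Gaussian, $\sigma$ = 12 cm, peak 12 Hz, multiplied by
  theta modulation of depth 0.5 - typical CA1 values on a 120 cm arena.
  A remap fraction of 0.8 of cells redraw their new-map center at least
  2$\sigma$ away (a "different field" by construction); the rest keep
  their field.
* **Flickering**: the latent map state is assigned per theta cycle
  (constant within a cycle - the analysis granularity), Bernoulli with
  per-trial probability rising linearly 0.1 to 0.9 across learning;
  probes are pure old/new.
* **Interneurons**: baseline rate modulated by the latent state,
  $r = r_0(1 \pm g)$ with gain $g = 0.3$ for pInt/nInt and 0 for uInt.
  The gain stands for the net drive from the whole (unrecorded) assembly:
  the handful of simulated monosynaptic inputs alone could not move
  per-cycle rates at the scale seen in vivo. Ground-truth class is the
  gain's sign. Consistently, pInt receive connections from remapped cells
  with weights rising 0.05 to 0.15 across learning, nInt falling 0.15 to
  0.05, uInt none.
* **Connections**: each presynaptic spike evokes, with probability
  $w(t)$, one interneuron spike at delay + N(0, jitter); $w$ ramps only
  inside the learning span (learning-restricted plasticity) and evoked
  spikes are additive - the simplest generative model with a CCG peak of
  known height.
* **Mechanics**: position at 40 Hz (OU-velocity walk confined to the
  disc, goal-seeking during trials); pyramidal spikes by thinning a 1 kHz
  rate grid with uniform sub-ms jitter (CCG fidelity below the bin
  width); LFP at 1250 Hz: speed-modulated 8 Hz theta plus pink noise,
  a 3 Hz component and optional 200 Hz ripple transients during rest.

What the generator does **not** emulate: theta phase precession,
theta-sequence structure within cycles, SWR replay content, bursting and
refractoriness, interneuron subtypes, electrode drift, or clustering
errors. Passing recovery benchmarks therefore shows the estimators are
correct on their stated model, not that real data meet that model.

## Problem sizes and numerical choices

Tests and the acceptance script use a scaled day - 360 s probes, 180 s
rests, 20 x 60 s trials (20 min of learning, so the rate-change windows
fit) - chosen as the package's benchmark size; the generator's defaults
remain the full-scale protocol. Filters are zero-phase Butterworth
(order 3, forward-backward) so peak times are undistorted; the
theta/delta ratio uses a sine-taper multitaper spectrum (K = 5, the
analogue of time-bandwidth 3) on 1600 ms windows stepped by 800 ms. Rate
maps use 4 cm bins with 4 cm Gaussian smoothing of counts and occupancy
separately; coherence is computed on the *unsmoothed* map (smoothing
would inflate it) - both are explicit arguments. Bins are half-open with
0-based indices. Degenerate inputs are flagged, never silently repaired:
constant maps, zero-variance trains, all-flat LFP and zero-spike cycles
all carry explicit undefined flags or errors.

## Reproducing the benchmarks

`recovery_benchmarks(seed)` re-runs every recovery study;
`scripts/acceptance.R --seed 1 --out results/acceptance.json` writes the
flat summary. `run_pipeline(pipeline_config(...))` executes the full
chain on one simulated (or on-disk) session and
`validate_against_truth()` scores it against the generator's truth.
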