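---
title: "Discovering line-attractor dynamics in neural population recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering line-attractor dynamics in neural population recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lineattractor)
```

## The scientific problem

During social interactions such as mating, hypothalamic populations can
hold and accumulate information over tens to hundreds of seconds — far
longer than single-neuron membrane or calcium-indicator time scales. One
candidate substrate is an approximate *line attractor*: a one-dimensional
continuum of slow fixed points in neural state space. Activity along the
line persists (the state outlives interruptions in the driving behaviour)
and integrates inputs (successive contact events push the population
further along the line), while activity orthogonal to the line relaxes
back quickly.

This package implements the complete analysis chain used to detect and
characterise such dynamics in calcium-imaging recordings of hypothalamic
(VMHvl) populations in female mice during mating: fitting recurrent
switching linear dynamical systems (rSLDS) to population rasters, scoring
time-scale separation, modelling the slow dimension as an input-driven
integrator, validating attractor geometry with an independently trained
FORCE network, single-cell persistence and tuning metrics, and a
mechanistic spiking model that proposes slow synaptic conductances as the
biophysical substrate. Because the deposited recordings are not shipped
with the package, every stage is exercised against a seeded synthetic
generator whose ground truth is known exactly.

## The generative model behind the synthetic data

`sim_config()` / `simulate_session()` produce sessions with the following
structure, in this order:

1. **Male bout process.** Sniffing, mounting and intromission bouts are
   laid out sequentially with log-normal durations and log-normal
   inter-bout intervals (mean copulation IBI 13.7 s, log-sd 0.8), with an
   escalation constraint: sniffing precedes the first mount, mounting
   precedes the first intromission. The empirical bout-duration and IBI
   distributions of mouse mating are strongly right-skewed; the
   log-normal family is a parsimonious choice matching that skew, with
   the IBI mean pinned to the reported value.
2. **Latent dynamics.** A discrete-time linear system
   `x_t = A x_{t-1} + W_kick u_onset + W_sus u_sustained + eps_t` at
   10 Hz. In the *receptive* regime `A` has one slow eigenvalue
   `exp(-1/(tau_slow * fr))` (default `tau_slow` = 100 s) and fast
   eigenvalues at `tau_fast` = 5 s; male-contact onsets deliver impulse
   kicks into the slow dimension (sniff < mount < intromission) and
   intromission adds a sustained drive, so the slow dimension integrates
   contact history and ramps across bouts. In the *unreceptive* regime
   the slow dimension is absent: dynamics are a fast decaying rotation
   (complex pair at `tau_fast`), giving time-locked excursions that relax
   to a point attractor and a generative line-attractor score of 0.
3. **Emissions.** `y_t = C x_t + d + noise`, with sparse Gaussian
   loadings (default half the entries zero) and observation noise
   (default s.d. 0.5), then z-scored per neuron — matching the
   convention that model fitting consumes z-scored extracted traces.
4. **Female behaviour.** During each male copulation bout the female
   accepts (lordose/wiggle) with probability given by a logistic link on
   the mean slow-latent value during that bout, otherwise resists; so
   across sessions the acceptance fraction co-varies with the area under
   the slow latent, the relationship the analysis is meant to recover.

What the generator deliberately does **not** emulate: calcium-indicator
kernel dynamics and deconvolution artefacts (analyses operate on
extracted, z-scored traces), pose-dependent motion artefacts, slow
drifts/bleaching, cross-day cell-registration errors, and non-Gaussian
noise. Passing tests therefore demonstrate correctness of the analysis
chain under its stated model class, not robustness to every failure mode
of real miniscope data.

All randomness flows through one master seed; each component draws from a
deterministic sub-stream, so identical configurations are bit-identical
and components can be re-run in isolation.

## The rSLDS engine

The model is the standard recurrent switching linear dynamical system:
discrete state `z_t in {1..K}` with softmax transitions whose logits
depend on the continuous latent (`logPi[j,k] + R[k,] x_{t-1} + r_k`),
per-state linear-Gaussian latent dynamics
`x_t = A_k x_{t-1} + b_k (+ W u_t) + eps_t`, and linear-Gaussian
emissions `y_t = C x_t + d + delta_t` with diagonal observation
covariance.

**Inference.** `fit_rslds()` uses structured approximate EM: a Kalman
smoother over the continuous latents (information-form updates, so the
per-frame cost is `O(D^3 + N D)`, never `O(N^3)`; compiled), with
per-frame dynamics formed as posterior-weighted mixtures of the state
matrices when `K > 1`; forward–backward over discrete states given the
smoothed latents; closed-form M-steps for dynamics and emissions using
full second moments (so estimation is errors-in-variables-consistent);
and a multinomial-logistic fit for the recurrent transition parameters.
For `K = 1` the procedure is exact EM for a linear dynamical system and
the marginal log-likelihood is non-decreasing — an invariant the test
suite checks. For `K > 1` the alternation is a variational approximation;
the tracked objective is the smoother's marginal likelihood under the
mixed dynamics. Initialisation is PCA for emissions plus k-means on
latent position/velocity for the discrete states, with random restarts.

**Time constants and the line-attractor score.** Each eigenvalue
`lambda` of a fitted dynamics matrix contributes a time constant
`tau = |1 / log|lambda||` frames, converted to seconds by the frame
rate (`time_constants()`). `|lambda| = 0` maps to `tau = 0`;
`|lambda| >= 1` is capped and flagged unstable. A complex conjugate pair
shares one magnitude; it is tagged with a common `pair_id` so reports
can list it once, but for the line-attractor score the pair contributes
its magnitude twice (it genuinely spans a two-dimensional subspace
decaying at that rate; without this convention a purely rotational fast
system would have an undefined score instead of 0). The score is
`log2(tau_(1) / tau_(2))` of the two longest time constants in the state
housing the slowest dimension.

**Input terms.** The generator's ramp is input-driven, and fits used for
parameter recovery include the male-behaviour input term (onset impulses
plus sustained indicators) through the model's input-loading matrix.
Fitting without inputs absorbs the contact-driven kicks into the
intrinsic dynamics and overestimates the slowest time constant roughly
two-fold — the same reason an input term improves variance explained on
outlier animals.

**Model order.** `select_model_order()` cross-validates over a (K, D)
grid by holding out contiguous blocks of frames and scoring them with
the predictive log-likelihood of the frozen fitted model (the filter
updates only on training frames). Ties break toward the smallest D, then
K.

**Forward-simulation accuracy.** From each frame the fitted dynamics are
run forward a short horizon (default 1 s) and compared against the
inferred latents at the target frame; the per-frame MSE is min–max
normalised to [0, 1] per session and reported as `1 - normalised MSE`,
with variance explained as the per-dimension squared Pearson correlation
averaged over dimensions.

**Flow fields, projection, perturbations.** `flow_field_2d()` evaluates
the locally active state's velocity field on a grid in the top-two PC
plane of the latents and masks the slow region (speed below the 5th
percentile by default — the threshold is a visualisation convention, not
an inference). `project_into_model()` re-runs inference with all
parameters frozen, used for cross-day comparisons with registered
neurons; neuron identities are checked when both sides carry them.
`fit_excluding_windows()` masks stimulation windows plus 20 s after each
during fitting (the smoother treats them as missing, the emission M-step
excludes them), then free-runs the fitted dynamics from the inferred
state at stimulation offset and scores the post-stimulus prediction with
pooled R^2 across latent dimensions.

## The integrator model

`fit_input_driven_integrator()` models the extracted slow dimension as a
single-state linear system `x_t = a x_{t-1} + b + W u_t + eps_t` with
binary per-frame indicators of male sniff/mount/intromission, fit by
least squares with contiguous-fold cross-validation. The intrinsic time
constant comes from `a` via the same eigenvalue formula. The input
weights are unconstrained in sign; indicators are used raw by default
(an optional causal boxcar is exposed but off, since no smoothing kernel
is stated for the original analysis).

## FORCE validation

`train_force()` trains a tanh rate network (`tau` = 0.5 s, gain
`g` = 1.5, Euler step 0.05 s) whose units correspond one-to-one to
recorded traces, learning the full recurrent matrix (plus input weights
for the male-behaviour channels) by recursive least squares against the
readout error `z_i - f_i`. Two implementation realities shaped the
design, and both are documented here deliberately:

- Online closed-loop RLS on the full recurrent matrix cannot bootstrap
  for arbitrary noisy, input-driven targets at these network sizes —
  there is no separate reservoir, so before learning the state carries
  no target structure for the regression to exploit. Training passes are
  therefore *teacher-driven*: the recurrent drive is the target
  `g f(t)`, so units traverse the trajectory the trained network is
  meant to visit while RLS makes the readout of that trajectory
  reproduce the targets. Training error decreases across passes.
- Reconstruction is evaluated on a final pass with learning frozen and
  the network driven by the data. Fully autonomous replay of a
  100-second input-driven ramp is unstable for 0.5-s tanh units at these
  sizes (a genuine limitation, exposed via `free_run = TRUE` for
  inspection). Reconstruction quality is judged against the generator's
  noiseless traces, because at the default emission noise the z-scored
  targets of weakly loaded neurons are about half white noise — no
  method can reconstruct that component, and the generator supplies the
  ground truth that real data would not.

`find_fixed_points()` minimises the kinetic energy `0.5 ||dx/dt||^2`
with BFGS and an analytic gradient from inits sampled from visited
states, deduplicates, and classifies points by the Jacobian spectrum.
`project_points()` maps fixed points through the network readout and the
rSLDS emission pseudo-inverse into the flow-field plane and reports
overlap with the slow region.

## The mechanistic spiking model

`simulate_spiking()` integrates 1,000 current-based LIF units
(membrane 20 ms, threshold 0.1, reset 0) with one graded inhibitory
feedback variable (50 ms) and per-neuron synaptic variables: a 200-unit
integration subnetwork carries 20-s synaptic time constants and 12%
connectivity (weights U(0, 1/sqrt(200))), the remainder 100 ms and 1%
(weights U(0, 1/sqrt(1000))); gains g = 2.5 and g_inh = 4.25; Euler step
1 ms with Gaussian current noise N(0, 1)/5 inside the membrane equation
(adding it directly to the membrane each millisecond would dwarf the
0.1 threshold). A spike sets the unit's rate indicator to 1 for a fixed
1 ms of simulated time — identical to "1 on the spike step" at the
default step, but independent of step refinement, so halving the Euler
step changes trajectories by well under 5% RMS.

The stimulus is 20 one-second pulses delivered to a random quarter of
each subpopulation. The interstimulus interval defaults to 5 s: the
original description ("20 pulses at 10 interstimulus intervals") leaves
the units ambiguous, and an interval short relative to the 20-s synaptic
time constant lets successive pulses accumulate in the slow synaptic
variable rather than equilibrate between pulses; the pulse amplitude
(0.6 on U(0,1) input weights) is calibrated so pulses reliably evoke
spiking against the noise floor; and the first pulse arrives after a
10-s settling period so the noise-driven baseline (and its inhibitory
equilibrium) does not masquerade as a ramp. All three are exposed as
knobs. The two
hypothesis manipulations are exactly as stated: `h1` removes the slow
synapses (subnetwork tau to 100 ms); `h2` halves the subnetwork input
gain and raises the rest by 50%. Under the default, the subnetwork's
per-pulse synaptic activation rises monotonically across the 20 pulses
(Spearman rho near 1) while non-subnetwork units decay to a few percent
of their per-interval peak between pulses; under `h1` the ramp is
abolished.

## Single-cell metrics

- **Choice probability** is the ROC area of 1-s binned responses between
  two behaviours, computed by the rank formula with tie correction (so
  it agrees exactly with exhaustive pair counting), with a
  bout-label-permutation null (1,000 shuffles) and the 0.7/0.3 plus
  2-s.d. tuning rule.
- **ACHW** is the first 0.5-crossing of the sample autocorrelation
  (`c_k/c_0` with the 1/T convention), linearly interpolated between
  bracketing lags, censored at a configurable maximum lag (default
  100 s) when the trace never decorrelates. A caveat the test suite
  makes explicit: at session lengths of ~10 min this estimator is biased
  a little low for very slow processes (sample-mean subtraction and the
  1/T taper depress the ACF), so AR(1) calibration runs recover the
  closed-form half-width to within ~15%, not exactly.
- **GLMs** regress each neuron on lagged binary male-behaviour
  indicators over a 10-s window, ridge-regularised with the strength
  chosen by nested cross-validation over a log grid (no strength is
  stated for the original analysis); the coupled variant adds the
  same-frame activity of all other neurons (self excluded). Fits are
  scored by cross-validated R^2 on contiguous held-out blocks.
- **Photometry normalisation** implements
  `Fn = 100 (F470 - F405fit)/F405fit` with the control channel scaled to
  the signal channel by linear least squares (slope+intercept by
  default; scale-only and pre-fitted modes exposed).
- **The frame-wise SVM decoder** merges bouts into trials (5-s gap),
  balances classes by frame subsampling so chance is 50%, and evaluates
  a linear SVM trial-wise: each trial's frames are predicted by a
  decoder trained on all other trials, aggregated into a macro-averaged
  F1; the shuffle control permutes class labels across whole trials.

## Problem sizes and numerical choices

The test and benchmark runs use the generator at its study-scale
defaults — 100 neurons, 10-minute sessions at 10 Hz, 20 sessions per
regime for recovery statistics, 20 seeds for the spiking and GLM
contrasts — with smaller sessions for unit tests of individual
operations. Numerical guards: observation variances floored at 1e-6;
innovation covariances kept positive-semidefinite by eigenvalue
flooring; a z-scoring guard drops zero-variance neurons with a warning;
PETH baselines with zero variance hit a 1e-6 floor and are flagged;
degenerate discrete states (occupancy under 0.5%) are pruned with a
warning; fitted `|lambda| >= 1` is capped and flagged rather than
propagated as an infinite time constant.

## Known limitations

- The rSLDS inference for `K > 1` is an approximate alternation, not a
  tight variational bound; its objective can plateau rather than
  increase strictly. For `K = 1` (the configuration used for all
  recovery benchmarks) it is exact EM.
- Latents are identified only up to an invertible linear transform; all
  comparisons in tests use eigenvalue spectra, correlations, or subspace
  geometry, never raw coordinates.
- The FORCE module validates attractor geometry; it does not provide
  autonomous replay of input-driven trajectories (see above).
- The NWB/HDF5 interfaces of the original data deposit are out of scope
  here: rasters and bout tables move through CSV, models through JSON.
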