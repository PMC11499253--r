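# lineattractor

Tools for discovering and characterising **line-attractor dynamics** in
calcium-imaging recordings of hypothalamic neural populations during
social behaviour, together with a seeded synthetic-data generator so the
whole analysis chain can be validated against known ground truth.

## The problem and who this is for

Hypothalamic populations (here, the Esr1+ "alpha cells" of VMHvl in
female mice during mating) can hold and escalate an internal state over
minutes — far longer than single-neuron time scales. A candidate
mechanism is an approximate *line attractor*: a one-dimensional continuum
of slow fixed points in neural state space. Activity along the line
persists through pauses in behaviour and integrates male-contact cues;
activity orthogonal to it relaxes back within seconds. This package is
for systems neuroscientists who want to run that analysis end to end on
population rasters (neurons x frames, z-scored) plus behavioural bout
annotations.

## What is inside

- **rSLDS engine** (`fit_rslds`): recurrent switching linear dynamical
  systems `x_t = A_{z_t} x_{t-1} + b_{z_t} (+ W u_t) + eps_t`,
  `y_t = C x_t + d + delta_t`, with softmax transitions driven by the
  continuous latent. Structured approximate EM (compiled information-form
  Kalman smoother; exact EM at K = 1), cross-validated model-order
  selection, forward-simulation accuracy, flow fields with slow-region
  masks, frozen-model projection for cross-day comparisons, and fitting
  with held-out perturbation windows.
- **Time constants and the line-attractor score**
  (`time_constants`, `line_attractor_score`): per-eigenvalue
  `tau = |1/log|lambda||`, and the `log2` ratio of the two longest time
  constants — large values mean one dominant slow mode.
- **Integrator model** (`fit_input_driven_integrator`): the slow
  dimension as `x_t = a x_{t-1} + b + W u_t + eps_t` over binary male
  sniff/mount/intromission indicators.
- **Single-cell metrics**: ROC choice probability with a shuffle null
  (`choice_probability`), autocorrelation half-width
  (`autocorr_halfwidth`), ridge GLMs with lagged behaviour filters and
  neuronal coupling (`fit_behavior_glm`, `fit_coupled_glm`), photometry
  isosbestic normalisation (`photometry_normalize`), and a frame-wise
  linear-SVM behaviour decoder with trial-label shuffles
  (`framewise_svm_decoder`).
- **FORCE validation** (`train_force`, `find_fixed_points`,
  `project_points`): an RLS-trained rate network fit to the same traces,
  whose fixed/slow points are projected into the rSLDS plane as a
  method-independent check of attractor geometry.
- **Mechanistic spiking model** (`simulate_spiking`): 1,000 LIF neurons
  with feedback inhibition and a 20-s-synapse integration subnetwork that
  ramps across a 20-pulse stimulus; hypothesis manipulations
  (`apply_hypothesis`) remove the slow synapses or redistribute input
  gain.
- **Behaviour analysis** (`bout_table`, `merge_bouts`,
  `behavior_probability`, `bout_ibi_stats`, `initiation_split`,
  `engagement_fractions`, `event_triggered_average`).
- **Synthetic sessions** (`sim_config`, `simulate_session`): male bout
  point process (log-normal durations/IBIs, mean IBI 13.7 s), latent
  line-attractor dynamics with contact-driven input (receptive) or fast
  point-attractor dynamics (unreceptive), sparse linear-Gaussian
  emissions, and a logistic link from the slow latent to female
  acceptance.
- **Pipeline orchestration** (`run_pipeline`) with a JSON manifest,
  CSV raster/bout IO and JSON model serialization.

## Worked example

```r
library(lineattractor)

# a receptive-regime session: 100 neurons, 10 min at 10 Hz
cfg <- sim_config(seed = 5)
ses <- simulate_session(cfg)

# fit a 2-dimensional dynamical system with the male-contact input term
ms <- male_input_series(ses$male_bouts, 6000)
fit <- fit_rslds(ses$raster, K = 1, D = 2,
                 inputs = rbind(ms$onset, ms$indicator), seed = 1)

tcs <- time_constants(fit)
round(tcs$tau_s, 1)
#> [1] 89.1  5.9
line_attractor_score(tcs)
#> [1] 3.914171

idim <- integration_dimension(fit)
cor(idim$raw, ses$latents$x[1, ])
#> [1] 0.9905226

m <- fit_input_driven_integrator(idim$raw, ses$male_bouts)
round(c(tau_s = m$tau_s, cvR2 = m$cvR2), 2)
#> tau_s  cvR2
#> 68.41  0.99
```

The two fitted time constants (89 s versus 6 s) recover the generative
100 s/5 s separation; their log2 ratio — the line-attractor score — is
about 3.9, against ~0 for unreceptive-regime sessions. The extracted
integration dimension tracks the true slow latent almost perfectly, and
the input-driven integrator model on that dimension confirms a long
intrinsic time constant (~70 s; the extraction mixes in a little of the
fast mode) with near-perfect cross-validated accuracy.

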