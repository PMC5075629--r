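---
title: "Time-variant fMRI priors for EEG source imaging: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-variant fMRI priors for EEG source imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stesi)
```

## The problem

EEG measures cortical currents with millisecond resolution but poor spatial
specificity; fMRI localises activity to millimetres but its BOLD contrast is
a static summary of the whole task period. The classical way to combine them
— weight the source covariance of a minimum-norm inverse by the fMRI
activation map, once, for all time points — penalises any source outside
the map for the entire epoch and, conversely, keeps every BOLD-active
region "open" at every instant. When activity sweeps across regions (a
visual response followed hundreds of milliseconds later by a motor one),
this *temporal mismatch* lets transiently silent but BOLD-active regions
absorb noise and bias the reconstruction.

`stesi` implements the time-variant alternative: the fMRI map is split
into submaps, each submap becomes a covariance-component prior, and the
component weights are re-estimated from the EEG of every short analysis
window by empirical Bayes. Regions that are electrically silent in a given
window are switched off *in that window only*.

## Model

For one analysis window the sensor data \(Y \in \mathbb{R}^{m \times d}\)
(µV) follow the two-level Gaussian hierarchy

\[
Y = GJ + \varepsilon,\qquad \varepsilon \sim N(0, C),\qquad
J \sim N(0, R),
\]

with \(G\) the lead field (µV per nA·m), \(J\) the current density and
\(C\) the sensor noise covariance. The source covariance is a weighted sum
of components derived from the thresholded fMRI map,

\[
R = \sum_{i=1}^{N} w_i\, Q_i, \qquad Q_i = q_i q_i^{\mathsf T},
\]

where \(q_i\) is the indicator vector of submap \(i\) (one connected
suprathreshold cluster, or a cluster × region-label piece). The rank-1
form models coherent activity across a submap; because that is a strong
assumption, a `diagonal` encoding \(Q_i = \mathrm{diag}(q_i)\)
(independent within-submap sources) is also available and is used for the
static baseline method. Weights are parameterised on the log scale,
\(w_i = e^{\lambda_i}\), and the sensor-noise level \(\lambda^C\) is
treated as one more hyperparameter of the same kind, so the marginal
sensor covariance is

\[
\Sigma(\lambda) = e^{\lambda^C} C + \sum_i e^{\lambda_i}\, G Q_i G^{\mathsf T}.
\]

### Free energy and ReML

Hyperparameters are estimated by maximising the variational free energy
\(F\), a lower bound on the log model evidence \(\ln p(Y \mid \lambda)\).
With \(S = YY^{\mathsf T}/d\),

\[
F(\lambda) \;=\; -\tfrac{d}{2}\,\mathrm{tr}\!\big(\Sigma^{-1}S\big)
 - \tfrac{d}{2}\ln|\Sigma| - \tfrac{dm}{2}\ln 2\pi
 - \tfrac{1}{2}(\lambda-\eta)^{\mathsf T}\Pi(\lambda-\eta)
 \;+\; \tfrac{1}{2}\ln\big|\Sigma^\lambda \Pi\big| .
\]

Two presentation choices matter here. First, the data terms carry the
sample count \(d\): the window is modelled as \(d\) i.i.d. draws, which is
what makes free energies comparable across window lengths. Second, the
posterior-entropy term \(\tfrac12\ln|\Sigma^\lambda\Pi|\) depends on the
hyperparameter posterior covariance \(\Sigma^\lambda\); during the ascent
the optimiser maximises the data + prior terms (the classical ReML
objective), and the entropy term is added at the optimum to give the
evidence bound reported as `logEvidence`. `freeEnergy()` mirrors this: it
returns the ascent objective unless you pass a `sigmaLambda`.

### The hyperprior

Each log-weight carries an independent Gaussian prior with mean
\(\eta = -32\) and variance \(256\) (`hyperPrior()`). The mean encodes
"off": \(e^{-32} \approx 10^{-14}\) silences a component. The variance is
large (sd 16), so the prior is a weak automatic-relevance device — turning
a needed component fully on (\(\lambda \approx 0\)) costs only about 2
nats, which any informative window repays instantly. A much tighter prior
(precision 256 instead of variance 256, a reading the bare symbols would
also admit) would make the switch-on cost \(\approx 1.3\times10^5\) nats
— beyond what any realistic window can pay — so no component could ever
activate; the package therefore uses the variance reading, which is the
standard one in empirical-Bayes covariance-component estimation.

Two practical consequences are worth knowing. (i) Components and the data
second moment are trace-normalised internally (mean diagonal 1) before the
ascent, so "off" and "on" have the same meaning whatever the physical
units; the returned `weights` undo the normalisation. (ii) Because the
prior is weak, an unsupported component does not ride all the way down to
\(e^{-32}\): it settles where the gentle prior pull balances the sampling
fluctuation of the window, typically three to four orders of magnitude
below the supported components. That equilibrium is a genuine stationary
point of \(F\), not an optimiser failure, and it is plenty for the
inverse solution, where the component's contribution to \(R\) is
negligible.

### Optimiser

`remlEstimate()` uses Fisher scoring on \(\lambda\): gradient
\(g_i = \tfrac{d}{2}\big[\mathrm{tr}(\Sigma^{-1}V_i\Sigma^{-1}S) -
\mathrm{tr}(\Sigma^{-1}V_i)\big] - \Pi(\lambda_i-\eta)\) with
\(V_i = e^{\lambda_i}K_i\), expected information
\(\mathcal I_{ij} = \tfrac{d}{2}\mathrm{tr}(\Sigma^{-1}V_i\Sigma^{-1}V_j)
+ \Pi_{ij}\), and step-halving whenever a proposed step would lower the
objective — which makes the `FTrace` non-decreasing by construction (a
tested invariant). Defaults: tolerance \(10^{-4}\) on \(\Delta F\),
128 iterations, \(\lambda\) clamped to \(\pm 256\) against exponent
overflow. \(\Sigma^\lambda\) is the inverse information at the optimum.
Degenerate windows with \(d < m\) are fine: \(S\) enters only through
traces and \(\Sigma\) stays positive definite through the noise component.
If a factorisation fails inside `inverseSolution()`, a diagonal jitter of
\(10^{-10}\,\mathrm{tr}(M)/m\) is added once, with a message.

### Inversion and the windowed pipeline

Given the fitted weights, the current density of the window is the
weighted minimum-norm estimate

\[
J = R\,G^{\mathsf T}\big(G R G^{\mathsf T} + \lambda^C C\big)^{-1} Y ,
\]

with \(\lambda^C\) the fitted noise weight. `fitSpatiotemporal()` runs
segment → ReML → assemble \(R\) → invert for every window (40 ms by
default, non-overlapping; a 1600 ms epoch gives exactly 40 windows; a
partial final window is dropped with a warning) and concatenates the
blocks. Analysis is single-trial; `averageEstimates()` averages
reconstructions post hoc.

The baseline `fitTimeInvariant()` is the classical static method: one
\(R = \mathrm{diag}(1\ \text{on-map},\ w_\mathrm{off}\ \text{off-map})\)
for the whole epoch, with \(w_\mathrm{off} = 0.1\) by default (the common
"90 % fMRI weighting" convention) and \(\lambda^C\) picked by the
L-curve corner (maximum discrete curvature of the log residual-norm /
log solution-norm curve over a 24-point logarithmic grid). For model
comparison it is additionally *scored* window-by-window under the same
ReML machinery with its single static component, so that
`compareModels()` compares models, not optimisers; whether the original
method would refit per window is left open by its usual description, and
per-window scoring is the like-for-like choice. `compareModels()` reports
the average per-window free energy (higher is better) and refuses fits
whose data/lead-field provenance differs.

## fMRI priors

`glmTmap()` fits the per-vertex GLM by vectorised OLS and returns contrast
t-statistics on \(T-k\) degrees of freedom (`glmDesign()` builds boxcar
regressors convolved with the canonical double-gamma HRF). Degenerate
zero-residual vertices are capped at \(t = 10^6\) with a warning.
`thresholdMap()` removes vertices with two-sided \(p \ge 0.05\) (default),
labels the survivors by connected components under the mesh's shared-edge
adjacency, and drops components smaller than 4 vertices (default;
survival is inclusive, size = 4 survives). This voxel-p + cluster-extent
rule is a deliberate simplification of random-field/permutation FWER
cluster correction, which belongs to the excluded fMRI preprocessing.
`partitionSubmaps()` yields one submap per cluster, or splits clusters by
region labels; submaps are enforced disjoint.

## Forward model

The built-in conductor is the analytic concentric-sphere model
(`sphericalHeadModel()`: radii 0.087/0.092/0.100 m, conductivities
0.33, 0.33/80, 0.33 S/m — the literature-standard skull ratio, not a
fitted value). Per spherical-harmonic order the radial transfer across the
shells is obtained from the interface continuity conditions by a
log-scaled downward recursion that cannot overflow, and the potential is
accumulated with Legendre recursions, vectorised over all
electrode–source pairs. Dipoles are fixed along the mesh normals. The
series is truncated at 100 terms by default and warns if the last term
exceeds \(10^{-10}\) of the field. Tests pin the implementation to the
closed-form homogeneous-sphere solution (summed via Legendre generating
functions) at \(10^{-8}\) relative accuracy. The lead field is
average-referenced by default; `G` and the EEG it is used with must share
a reference, and `averageReferenceProjector()` is provided because the
reference that a given recording implies cannot be guessed from the data.

A user-supplied lead field can be passed through the matrix container
instead; nothing in the pipeline depends on the spherical model.

## Synthetic scenes: what they emulate, and what they do not

`defaultScene()` mimics a visual-stimulus → motor-response trial on the
icosphere cortex (162 vertices at 0.07 m, desk scale): a posterior
"visual" patch bursts at 100–175 ms, a "premotor" patch at 370–460 ms and
a "motor" patch centred on the 600 ms response (560–660 ms); all patches
are 1-ring neighbourhoods (7 vertices) at 20 nA·m with Gaussian-burst
waveforms; sensor SNR is 10 dB over the active span; sampling 1000 Hz over
−400…1200 ms. The fMRI map is the *static union* of all patches at a fixed
suprathreshold t (10 on 100 dof) — the temporal-mismatch structure the
method exists for. An optional spurious patch (fMRI-active, EEG-silent) is
placed inside the sensed electrode cap; placing it on the unsampled
underside of the sphere would make both methods equally blind to it and
the comparison meaningless. Noise is white at the sensors by default, with
an optional random smooth spatial covariance for robustness checks.

What the generator does **not** emulate: realistic cortical folding (and
hence the wildly varying gain of real sulcal sources), correlated
physiological artifacts (EKG, ocular), trial-to-trial latency jitter,
habituation, and BOLD amplitude variation across regions. Passing tests on
these scenes therefore demonstrates the estimator's internal correctness
and its qualitative advantages under temporal mismatch — not clinical
accuracy on real recordings.

Simulation sizes used throughout the tests (162 sources, 32 channels,
1600 samples, 20 seeds for the model-comparison experiment) were chosen as
the smallest configuration at which the patches are clearly separated on
the mesh and the evidence comparison stabilises across seeds.

## Numerical choices

* **Tolerances** — ReML: \(|\Delta F| < 10^{-4}\); series tail warning
  \(10^{-10}\) relative; inverse-solution jitter \(10^{-10}\,\mathrm{tr}/m\).
* **Grid-oracle tests** — ReML is checked against an exhaustive
  free-energy grid search on 2–3 hyperparameter toys with 16 000 samples,
  so the evidence peak is much narrower than a grid step; at small sample
  counts the discrete argmax slides along the correlated
  noise-vs-component ridge even when the optimiser's \(F\) beats every
  grid point.
* **Ties and ordering** — cluster labels are assigned by decreasing
  cluster size, ties broken by smallest vertex index; the last partial
  window is dropped, never padded.
* **Degenerate inputs** — empty prior set falls back to the no-prior
  (identity, minimum-norm) model with a message; an empty fMRI mask in the
  baseline method degenerates to unweighted minimum norm with a warning;
  all-zero component lists are an error.
* **Units** — µV, nA·m, µV/(nA·m), metres, seconds; file formats use
  0-based vertex indices, R code 1-based.
* **Reproducibility** — every stochastic path is seeded; the simulator is
  bit-reproducible given a scene seed.

## Known limitations

The rank-1 submap encoding assumes full coherence within a submap; real
patches are only partially coherent (the diagonal encoding is one lever,
but a principled patch-basis encoding is out of scope). The spherical
head model preserves the mathematical structure of the inverse problem but
not the gain heterogeneity of a BEM on a real head. The L-curve corner for
the baseline method is a heuristic and can be off by an order of magnitude
on flat curves — which is precisely why the Bayesian method estimates its
regularisation by evidence instead. Window lengths well below 40 ms make
the per-window second moment very rank-deficient; estimates remain defined
(the noise component keeps \(\Sigma\) positive definite) but hyperparameter
variance grows.
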