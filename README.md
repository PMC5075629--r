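# stesi — spatiotemporal fMRI-constrained EEG source imaging

`stesi` reconstructs cortical current density from EEG using fMRI spatial
priors that are **re-weighted over time**. It is written for
multimodal-neuroimaging researchers who have (i) epoched EEG, (ii) a lead
field (or a spherical head model to compute one), and (iii) a per-vertex
fMRI statistic map on the cortical source mesh, and who want source
estimates that do not inherit the fMRI map's temporal blindness.

## The model in brief

EEG data `Y` (m channels × d samples) in one analysis window follow

    Y = G J + ε,   ε ~ N(0, C),   J ~ N(0, R),

with lead field `G` and source covariance

    R = Σᵢ exp(λᵢ) Qᵢ,   Qᵢ = qᵢ qᵢᵀ,

where each `qᵢ` indicates one submap (connected cluster) of the
thresholded fMRI activation map. The log-scale weights λ = {λ^C, λ^R}
(including the sensor-noise level) carry the Gaussian shrinkage prior
N(−32, 256) and are estimated per window by ReML, i.e. by maximising the
variational free energy

    F = −(d/2) tr(Σ⁻¹S) − (d/2) ln|Σ| − (dm/2) ln 2π
        − ½(λ−η)ᵀΠ(λ−η) + ½ ln|Σ^λ Π|,     Σ = G R Gᵀ + λ^C C,

a lower bound on the log evidence ln p(Y | λ) that also serves as the
model-comparison score. The window's current density is then the weighted
minimum-norm inverse

    J = R Gᵀ (G R Gᵀ + λ^C C)⁻¹ Y.

Because the weights are re-estimated in every window (40 ms by default),
fMRI-active but momentarily silent regions are switched off where the
classical *time-invariant* method (one static fMRI-weighted `R`, λ^C by
L-curve — also implemented, as `fitTimeInvariant()`) keeps them open.

## Worked example

Simulate the default visual→motor scene on a desk-scale spherical head,
build priors from its (static, union) fMRI map, and compare both methods:

```r
library(stesi)

src   <- makeIcosphereSourceSpace(2, 0.07)            # 162-vertex cortex
head  <- sphericalHeadModel()                         # 3-shell conductor
G     <- computeLeadField(head, electrodeCap(32, 0.1), src)

scene <- defaultScene(src, snrDb = 10, seed = 1)      # bursts at 100-175,
sim   <- simulateScene(scene, src, G)                 # 370-460, 560-660 ms

thr    <- thresholdMap(sim$map, src, p = 0.05, minCluster = 4)
priors <- partitionSubmaps(thr, src)
priors
#> PriorSet: 3 component(s) over 162 sources, encoding 'indicator-rank1'
#>   submap sizes: 7, 7, 7

est  <- fitSpatiotemporal(sim$epochs, G, priors)      # 40 ms windows
est
#> SourceEstimate (spatiotemporal): 162 sources x 1600 samples @ 1000 Hz, 40 window(s)

base <- fitTimeInvariant(sim$epochs, G, thr)
compareModels(spatiotemporal = est, time_invariant = base)
#>           method     meanF nWindows    deltaF
#> 1 spatiotemporal -1656.179       40   0.00000
#> 2 time_invariant -1698.031       40 -41.85214

evaluateEstimate(est, sim$Jtrue, scene, src)
#> EvalReport:
#>   visual       loc. error 0.0000 m, time-course r = 0.997
#>   premotor     loc. error 0.0000 m, time-course r = 0.997
#>   motor        loc. error 0.0000 m, time-course r = 0.998
#>   energy outside true support: 0.000
```

Reading the numbers: `meanF` is the average per-window free energy (log
evidence; higher is better), so the spatiotemporal model is preferred by
ΔF ≈ 42 nats per window on this temporal-mismatch scene. The evaluation
shows every simulated patch recovered at its true peak vertex (zero
localisation error) with regional time courses correlating ≈ 0.997 with
the ground-truth waveforms and essentially no energy leaking outside the
true support.

Real data enter through `readBrainVision()` (epoched EEG),
`readMatrixContainer()` (lead field) and `readStatOverlay()` (per-vertex
fMRI map); see the vignette for unit and reference conventions.

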