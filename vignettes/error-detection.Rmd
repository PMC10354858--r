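---
title: "Unsupervised error detection in VMAT QA: models, simulator and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsupervised error detection in VMAT QA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(vmatqa)
```

## The problem

Patient-specific QA compares the dose a treatment planning system predicts
with the dose a linac actually delivers to a phantom. Gamma analysis, the
routine comparison, blends a dose-difference (DD) tolerance with a
distance-to-agreement (DTA) tolerance; precisely because DTA forgives
spatial mismatch, gamma can wave through random MLC leaf errors, small
gantry-angle errors and similar faults. This package implements a
detection scheme that treats QA as anomaly detection: learn what
*error-free* measured-vs-calculated discrepancy looks like, and flag
anything unusual — no error examples needed at training time.

## The three methods

**Dose-difference maps.** The unit of analysis is a 27 × 27 map of
`measured − calculated` dose (both normalized by the measured isocenter
dose of plane 1) on a 5-mm in-plane lattice covering the central
13 × 13 cm of each detector plane, clipped to ±0.2. Lattice nodes that
carry a diode keep the diode value exactly; nodes in the 10-mm-pitch
peripheral region are filled by separable linear interpolation (along
diode-bearing rows, then along columns) — on this regular layout the
result is identical to barycentric interpolation on a triangulation, with
nearest-value fallback outside the diode hull. Clipping is applied last;
the order is only observable when a raw difference above 0.2 neighbors an
interpolated node. The difference sign is `measured − calculated`, so an
*output +3%* error (an inflated calculated dose) leaves a *negative*
in-field mean.

**VAE + Mahalanobis scoring.** The encoder (three 3 × 3 stride-2
convolution blocks of 16/32/64 filters with batch norm and ReLU) outputs a
30-dimensional latent mean μ and log-variance; the decoder mirrors it with
transposed convolutions and a linear output, since inputs live in
[−0.2, 0.2]. Training minimizes the negative evidence lower bound

&nbsp;&nbsp;&nbsp;&nbsp;loss = Σ(x − x̂)² / (2 σ_rec²) + KL,&nbsp;&nbsp;
KL = −½ Σᵢ (1 + log vᵢ − μᵢ² − vᵢ),

with v the latent variance. Two conventions here deserve a note, because
the common informal presentations of the VAE are ambiguous about both:

* *The reparameterization noise* ε in z = μ + ε·σ is standard normal.
  Descriptions that call ε "a number between 0 and 1" conflate the
  sampled quantile with the sample; the standard-normal draw is what makes
  the KL term above the correct closed form.
* *σ vs σ².* Written with σ as the standard deviation the closed form has
  log σᵢ² and σᵢ² terms; `kl_loss(mu, sigma)` therefore takes the
  *variance* as its second argument, which is also how the log-variance
  head is consumed internally.

The reconstruction term is a Gaussian log-likelihood with decoder noise
scale `recon_sigma = 0.01` — the ~1% residual amplitude of error-free
maps. This matters: with maps whose pixel scale is ~10⁻², an unweighted
"per-pixel MSE + KL" objective is dominated by the KL term and collapses
the posterior (every map encodes to μ ≈ 0, destroying the anomaly score).
Dividing the summed squared error by 2σ_rec² is the principled balance and
keeps the latent informative. Training: Adam at 10⁻³, minibatch 64, 200
epochs by default, no early stopping; validation loss is logged with a
deterministic latent (z = μ) but never used to stop.

After training, the error-free training maps are encoded; their latent
means define the reference mean x̄ and sample covariance Σ (denominator
n − 1). The anomaly score of a test map is

&nbsp;&nbsp;&nbsp;&nbsp;MD(x) = √((x − x̄) Σ⁻¹ (x − x̄)ᵀ),

using all 30 dimensions of μ (σ is not used in scoring). The reference set
is the augmented training encodings (800 maps by default). A ridge of
10⁻⁶ · tr(Σ)/30 is added before inversion — a 30 × 30 covariance from
finitely many correlated encodings can be ill-conditioned — and is
reported in the fitted object. A case's score is the mean MD of its two
plane maps; `md ≤ threshold` classifies as error-free (the boundary goes
to the negative class).

**Supervised CNN.** Three conv blocks (3 × 3 conv, batch norm, ReLU,
2 × 2 max-pool; 16/32/64 filters — deliberately close to the VAE encoder)
feeding dense layers 256 → 32 → 2 with dropout 0.2/0.5 and a softmax. It
trains on error-free maps labeled negative and all nine error conditions
labeled positive; the error-free training maps are expanded 9-fold to
balance the classes. The expansion is the 4 flips, the 4 flips rescaled by
0.95, and the identity rescaled by 1.05 (re-clipped); the rescaling
factors are configurable, since flip-plus-rescale expansion admits several
equally reasonable factor choices. Epochs and learning rate mirror the
VAE, and the best-validation-accuracy checkpoint is kept.

**Gamma analysis.** Global criteria: γ(p) is the minimum over in-plane
offsets r of √((Δd(r)/(dd% · D_norm))² + (‖r‖/DTA)²), with the calculated
distribution interpolated bilinearly on a 2.5-mm plane grid, a search
lattice of step DTA/10 and radius 3·DTA (sorted by radius with the
standard early stop), followed by a three-level local refinement that
removes the residual lattice discretization error. D_norm defaults to the
maximum of the calculated distribution ("global" normalization; the
isocenter dose is a configurable alternative). Diodes below 10% of the
maximum reference dose are excluded; the two planes are pooled, not
averaged. Pass rate above the threshold classifies error-free; the
boundary goes to any-error, mirroring the MD convention.

**Phantom-position optimization.** The measurement-preprocessing step
searches 3D translations (coarse ±3 mm at 0.5 mm, then ±0.5 mm at 0.1 mm)
of the diode positions against the calculated 3D dose. The coarse
objective is the 3%/1 mm pass rate. That objective plateaus at 100% over
a ≥1-mm-wide region — any offset within the DTA tolerance passes — so
maximizing it alone cannot localize the phantom to sub-millimeter
precision, and breaking ties toward the smallest shift would simply
return zero for a genuine 1-mm displacement. Ties and the refinement
stage therefore use the mean absolute dose difference at the shifted
positions, which is sharply minimized at exact alignment; in the
noise-free limit the optimization undoes a pure translation exactly. The
pipeline's synthetic measurements contain no setup offset, so the
correction is exposed as a function (and tested) but not run per beam by
default.

**ROC evaluation.** Negatives are the error-free cases, positives the
cases of one error kind (36 each per ROC under the full protocol). Scores
where lower is more anomalous (gamma pass rates) are negated internally so
one code path serves all methods. AUC is the trapezoidal area, identical
to the Mann–Whitney pair statistic. The ideal threshold is the curve point
closest to (0, 1), ties broken by higher sensitivity and then by the
threshold calling more cases positive. AUC differences between methods on
the same cases use the two-sided paired DeLong test, the standard choice
for correlated ROC curves; a paired bootstrap would be the natural
alternative.

## The synthetic data generator

No measured data ship with the package, so the generator emulates a
clinical QA measurement campaign end to end; its defaults define the
simulated study conditions used throughout the tests and the acceptance
script.

* **Geometry.** Two planes through the isocenter containing the couch
  axis, inclined 50° (clockwise) and 40° (counterclockwise) from vertical.
  Diodes on a square in-plane lattice: 5-mm pitch in the central 6 × 6 cm,
  10-mm pitch outside to ±10 cm — 561 diodes per plane, 1122 total, close
  to the real device's 1069; the exact commercial layout is not public and
  is not a contract here. Axes: x lateral, y longitudinal (= gantry
  rotation axis), z vertical, right-handed, mm, isocenter at origin.
* **Plans.** Full arcs of 20 control points with a roughly elliptical
  aperture (radius ≈ 25 mm) whose radius and centroid drift smoothly over
  the arc, plus smooth per-leaf random modulation — prostate-like scale
  and modulation without any clinical input.
* **Dose engine.** Per control point, beam's-eye-view fluence from the
  leaf openings: the aperture indicator convolved with an algebraic
  sigmoid penumbra (σ = 2.5 mm along leaf travel, 2 mm across rows,
  2% leaf transmission), attenuated as exp(−0.005/mm × depth) from the
  phantom surface toward the source, accumulated with the control-point
  MU weight on a 2.5-mm isotropic grid. The engine is *linear in MU* by
  construction and deliberately ignores scatter, divergence and spectral
  effects: what matters for this package is that each error type perturbs
  the dose with the right geometric/scaling structure, at desk-scale cost.
* **Errors.** MLC errors edit the plan and recompute the dose (as a TPS
  recalculation would): the systematic 2-mm offset shifts both banks in
  the same direction — translating apertures; a per-bank widening is an
  equally plausible convention for a single-direction offset and was not
  chosen. Gantry (±2°), output (±3%) and setup (1 mm) errors edit the
  error-free dose grid — rotation about the couch axis, scaling,
  translation — with trilinear resampling, the conventional way such
  errors are simulated without re-running a dose calculation.
* **Measurement noise.** measured = true × daily factor × (1 + correlated
  field + iid noise): per-diode sd 0.7%, correlated-field sd 0.5% with
  20-mm correlation length (a kernel-normalized Gaussian random field),
  daily output factor sd 0.3% — stored so the daily-calibration correction
  can divide it back out, as the real 10 × 10 cm output check does.
  The amplitudes were chosen once so that error-free DD maps are "almost
  plain" images with ~1% residual structure.

**What the simulator does not emulate** — and hence what passing tests do
and do not show: TPS beam-modeling bias, scatter and heterogeneity
effects, realistic per-leaf error spectra (sub-millimeter, single-leaf),
couch/collimator errors, and the inter-facility variability of residuals.
On this cleaner synthetic distribution the learned detectors separate
errors from error-free cases much more sharply (AUCs near 1) than any
method does on clinical data; the end-to-end checks therefore validate
the *pipeline's correctness and ordering behavior* (e.g. gamma's relative
insensitivity to random MLC errors), not clinical performance, and
reproducing clinically reported AUC tables is out of scope.

## Numerical and design choices

* **Neural networks in base R.** No deep-learning framework is part of
  this package's dependency footprint; conv/transposed-conv/batch-norm/
  max-pool/dense layers with reverse-mode gradients and Adam are
  implemented in vectorized R (im2col gathers + sparse scatter, all heavy
  work in BLAS). Analytic gradients are validated against central
  differences in the test suite at 10⁻⁵ relative tolerance. Batch-norm
  running statistics warm-start from the first batch so short training
  runs are usable in inference mode. Training is bit-reproducible under a
  seed.
* **Map interpolation** is exact at diode nodes (no smoothing) — a test
  asserts value-equality there.
* **Determinism.** One master seed derives per-beam and per-stage seeds
  (all < 2³¹); datasets regenerate bit-identically, and an identical
  pipeline configuration re-run from cache reproduces the report exactly.
* **Problem sizes.** Module tests run on toy configurations (≤ 12 beams,
  ≤ 5 epochs). The end-to-end study used by the acceptance checks and
  `scripts/acceptance.R` uses 40/10/36 beams and three seed replicates
  with the VAE at 50 epochs and the S-CNN at 12 — small enough to run in
  minutes, large enough that medians and AUCs over 36 cases/type are
  stable; the structural-count check runs the full 161-beam protocol.
* **Degenerate inputs** are rejected with messages: non-physical detector
  configs, closed search spaces, singular covariances without a ridge,
  all-excluded gamma point sets, single-class training labels.

## Known limitations

* The dose engine's absolute dose scale is arbitrary; only normalized
  quantities are meaningful.
* Gamma DTA search is in-plane (2D) per detector plane; volumetric 3D
  gamma is out of scope.
* The anomaly score uses μ only; reconstruction-error or likelihood
  scores are not implemented (the quantitative score of record is MD).
* Latent-dimension and architecture searches, multi-class error
  identification, and training with error data included are deliberately
  not implemented.
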