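---
title: "Scan-time reduction in Lu-177 planar scintigraphy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scan-time reduction in Lu-177 planar scintigraphy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Quantitative planar scintigraphy after Lu-177 peptide receptor
radionuclide therapy underpins personalised dosimetry: whole-body
anterior/posterior scans at several time points give organ time-activity
curves, which are integrated into cumulated activities and folded with
S values to yield absorbed organ doses (the MIRD schema).  Shorter scans
improve patient comfort and inter-scan registration, but fewer detected
photons mean more Poisson noise and biased count measurements.
`luscint` studies whether a convolutional denoiser can restore
reduced-count planar images well enough that organ count statistics —
and hence dosimetry — are preserved, using a fully synthetic desk-scale
pipeline: digital phantoms, an analytic camera model, binomial count
thinning, a dense-skip convolutional network, and the fidelity / ROI /
dosimetry analyses that quantify the result.

## Acquisition model

`scanner_model()` encodes the modelled system: a dual-head camera with a
medium-energy general-purpose (MEGP) parallel-hole collimator (hole
diameter 3.0 mm, septal thickness 1.05 mm, hole length 58 mm), 2.2 mm
pixels on a 256 x 256 matrix, system sensitivity 65 cps/MBq, system
resolution 9.4 mm FWHM, and 5-minute acquisitions.

`project_expected()` is an analytic surrogate for photon-by-photon
transport.  For each depth slab along the anteroposterior axis it
attenuates the slab activity by the accumulated `exp(-sum(mu dl))` to
the camera face (attenuation evaluated to the slab centre), blurs it
with a Gaussian point-spread function whose FWHM follows the
parallel-hole model

    R(z) = sqrt(R_int^2 + R_coll(z)^2),   R_coll(z) = d_eff (l_eff + z) / l_eff,

and accumulates, scaling by sensitivity times scan time.  The intrinsic
term `R_int` is calibrated once so that `R(100 mm) = 9.4 mm`; 100 mm is
the conventional specification distance for system resolution and is
configurable.  Blur matrices are column-normalised, so the projector
conserves counts exactly — a point source in air integrates to
`A x 65 cps/MBq x 300 s` at any depth, which the tests exploit.

Deliberate simplifications (all documented limitations): no scatter, no
septal penetration, no energy-window physics, no detector dead time —
their net count contribution is folded into the sensitivity constant.
One practical consequence is that large-phantom images contain fewer
counts than a full Monte-Carlo treatment would give (in-window scatter
in a 340 mm water phantom is a substantial count fraction), which is why
published per-table count values are out of reach and only pattern-level
reproduction is attempted.

Counting statistics are exact rather than approximated:
`sample_counts()` draws independent Poisson pixels, and `thin_counts()`
retains each detected photon with probability `f` (binomial thinning),
which is distributionally identical to scanning for the fraction `f` of
the time.  `simulate_scan()` chains thinned images from the next-larger
fraction, so count sets are nested pixelwise — the list-mode
subsampling interpretation, chosen because the study's published tables
reuse the same images across time points (the 96 h full-count scan
equals 60% of the 24 h scan).

## Phantoms

* `make_shepp_logan()` — the standard 10-ellipsoid head phantom with the
  non-negative ("modified") intensity set as activity; water attenuation
  inside the outer ellipsoid.
* `make_brain_like()` — a parametric stand-in for a licensed brain
  phantom: a head-shaped support with folded high/low compartments
  (grey:white = 4:1 by construction) generated from a seeded
  band-limited cosine field.  It is a surrogate with a matched role
  (anatomical complexity), not a reproduction.
* `make_derenzo()` — a flat 340 mm cylinder, 78 mm tall, imaged face-on,
  with one rod per diameter (10/13/17/22/28/33 mm) on a ring.  Activity
  is booked by nominal volumes (180 cm^3 of rods, 7000 cm^3 total,
  10 MBq/kg, water density), so totals are exactly 15.44 MBq (5:1) and
  5.21 MBq (20:1) regardless of voxelisation.  The rod layout
  (single rod per diameter on a ring) is chosen for non-overlap; the
  source geometry beyond rod diameters and volumes is not specified
  anywhere, so no layout fidelity is claimed.
* `make_anthropomorphic()` — a parametric torso: elliptical-cylinder
  body with ellipsoidal liver, spleen and kidneys, again a documented
  surrogate for a licensed anthropomorphic phantom.  Organ centres are
  placed so the four source organs project onto the anterior view
  without mutual overlap, which manual planar-dosimetry ROIs assume.
  Organ activity is `%IA(t) x injected activity`, uniform in the organ.

`default_tac()` fixes the retention structure 1.0 : 0.6 : 0.4 across
24/96/168 h for every organ — the proportionality implied by the
published tables, where the 96 h full-count row equals the 24 h 60% row
and the 168 h row equals the 24 h 40% row.  The absolute 24 h values
(liver 0.57, spleen 0.18, right kidney 0.27, left kidney 0.25 %IA at
7400 MBq injected) were calibrated once so a 5-minute scan yields organ
ROI means near the published regime (roughly 65–120 counts/pixel) and
are not revisited.

## Training corpus

`make_training_corpus()` emulates the published corpus construction:
axial slices of the two base phantoms, each duplicated 30 times along
the anteroposterior axis to form a slab whose planar projection is the
slice itself; at full scale 2 x 150 sets of 256 x 256 x 30.

Per-set activity assignment deserves its own paragraph because it
changes what the denoiser can learn.  The source study quotes only
per-family total-activity *ranges* (2.88–20.6 and 1.36–31 MBq).  Two
readings are implemented:

* `activity_mode = "concentration"` (default): one fixed activity
  concentration per family, scaled so the brightest slice hits the top
  of the range.  Totals vary with slice content; per-voxel full-count
  brightness is constant across the family.
* `activity_mode = "linear"`: totals spaced evenly over the range,
  decoupling brightness from content.

The concentration reading is the default for a statistical reason that
the package's own experiments make vivid: a thinned Poisson image is
*distributionally identical* to a full-count image of a proportionally
weaker source.  If corpus brightness varies freely (linear mode), the
retained fraction of a reduced-count image is fundamentally
unidentifiable from the image alone, and the risk-minimising denoiser
applies a compromise gain — reduced-count images are then restored with
large, fraction-dependent count biases.  Under constant concentration
the full-count brightness is (approximately) known a priori, the
fraction becomes inferable from brightness, and learned restoration
gains approach the correct `1/f`.  This is also the more natural reading
of "activities ranged from X to Y" for a corpus built by slicing a
single phantom.  The residual ambiguity — within-scene brightness
structure and the gap between corpus and evaluation-scene brightness —
is the package's main known limitation (below).

`training_corpus_spec(reference_matrix =)` optionally rescales totals by
the head-area ratio when a corpus is generated at reduced matrix size,
preserving per-pixel count statistics; the desk profile instead quotes
the ranges at its own 96 x 96 grid.

## The denoiser

`network_spec()` describes the DenseNet-style restoration network: one
low-level convolution, dense blocks whose layers each receive the
concatenation of the block input and all previous in-block outputs
(blocks forward their features, and the 1 x 1 bottleneck sees every
preceding feature map), two reconstruction-stage convolutions run at
stride 1 — in the super-resolution lineage these are upscaling
deconvolutions, but input and output share resolution here — and a
single-channel reconstruction layer.  The full-scale configuration
(8 blocks x 8 convolutions, 69 weighted layers) is provided but
GPU-sized; the desk default is 2 blocks x 4 convolutions, growth 8,
8 low-level filters, 16 bottleneck filters (~27k parameters).

Training follows the published recipe exactly: RMSE loss on counts
normalised to about [0, 1] (constant = 99.9th percentile of label
counts, stored with the model), Adam with learning rate 1e-4, first
moment 0.9, weight decay 1e-4 (weights only), mini-batches of 32
co-located 25 x 25 sub-image pairs, MSRA (He) initialisation, zero
biases, one iteration per batch.  "Randomly cropped with stride 25" is
resolved as a stride-25 grid with a random per-image offset: tiles never
overlap, placement varies.  A pair is discarded when its label tile is
all zero.  One model is trained on all nine fractions 10–90% mixed; the
fraction is *not* an input to the network.  Two optional training
controls are off by default and exist for experimentation:
`corpus_patches(balance_fractions =)` (sampling weights
`1/sqrt(1 - f)`, balancing per-fraction gradient scale) and
`train_config(tail_average =)` (Polyak averaging of the final
iterations).

The compiled engine stores feature maps channel-planar over zero-padded
image planes, which turns every 3 x 3 kernel offset into a constant row
shift and lets both passes run as direct SGEMM calls on shifted views
(no im2col copies).  Forward outputs are validated against a pure-R
double-precision reference and the analytic gradients against central
finite differences in the test suite.
Inference normalises, runs the whole image through the stride-1 network
(any size), un-normalises and clamps negatives to zero; outputs remain
real-valued.

## Quantification

* `rmse()`, `psnr()` (`20 log10(I_max / RMSE)`, `I_max = max(ref)`), and
  `ssim_global()` — the single-window SSIM from whole-image means, SDs
  and covariance, with the conventional stabilisers `(0.01 L)^2`,
  `(0.03 L)^2`.  The global form is deliberate (it is what the source
  equations define); a windowed variant is behind a flag.
* ROI analysis: `rod_rois()` applies a 256-bin Otsu threshold to the
  full-count image within each rod's dilated footprint; masks are
  defined once on the full-count image and reused for every
  reduced-count and denoised image so comparisons stay paired.
  `organ_rois()` replaces manual organ outlines with projected-thickness
  thresholds (pixels above half the organ's maximum projected
  thickness).  `two_sample_ttest()` is the pooled-variance Student test
  on ROI pixel values (Welch behind a flag), with p < 0.01 flagged; this
  treats pixels as independent samples, exactly as the published
  analysis does, and inherits that caveat.
* Dosimetry: `conjugate_view_activity()` implements the geometric-mean
  estimate `A = F sqrt(I_A I_P / T) f / C`;
  `self_attenuation_factor()` is the slab-source correction
  `(mu t / 2) / sinh(mu t / 2)`; `cumulated_activity()` integrates a
  time-activity curve (configurable rise, trapezoid, physical-decay tail
  using the Lu-177 half-life 6.647 d, or a mono-exponential fit);
  `absorbed_dose()` is the S-weighted sum.  S values are user-supplied;
  a small synthetic 4-organ matrix ships for tests and demonstrations.

## Desk-scale profile and problem sizes

Full-scale training (2 x 150 sets of 256 x 256 x 30, 100 000
iterations) is a GPU-class workload.  The package's own experiments run
on one CPU core with these sizes, chosen once as the desk-scale study
conditions:

* training scenes: 30 slab phantoms at 96 x 96 (15 slices per family),
  all nine fractions, ~2 300 sub-image pairs;
* training: 2 000 iterations of the default 2-block network
  (~4 minutes per replicate);
* evaluation: 20 held-out fresh-noise scans of the same slab families
  (the published evaluation protocol also measures image fidelity on
  the training anatomies), fractions {10, 30, 50, 70, 90}%;
* pattern evaluation: full-size Derenzo scenes at both
  target-to-background ratios and the torso at 24/96/168 h, 256 x 256
  at 2.2 mm.

## Known limitations, stated quantitatively

The desk-scale denoiser improves held-out PSNR at 30% retained counts
by ~8–10 dB, and restored images are visually close to the full-count
reference.  Count-scale *calibration*, however, is Bayes-limited by the
fraction-identifiability argument above: measured restoration gains on
held-out scenes are about 0.86–0.95 of truth at 10–50% retained counts
and 1.05–1.16 at 90%.  Three consequences, all reproduced by the test
suite and deliberately not papered over:

1. Mean held-out RMSE usually decreases with retained fraction, but the
   90% point can sit slightly above the 70% point (the ~10% gain
   overshoot outweighs the smaller noise), so strict monotonicity
   across fractions holds only marginally and not for every training
   seed.
2. The published significance pattern (denoised images at >= 30%
   retained counts indistinguishable from full-count in every ROI) is
   *not* reached at desk scale.  ROI t-tests with hundreds of pixels
   resolve 2–3% count biases; the desk model's biases on evaluation
   scenes are several times that, and on the Derenzo scenes — whose
   rods sit well below the corpus brightness anchor, partly because the
   scatter-free projector yields roughly half the published rod counts
   — restoration gains are badly miscalibrated.  Reaching the published
   pattern appears to require the full-scale regime, where a 69-layer
   network trained for 1e5 iterations can resolve the remaining
   brightness-fraction ambiguity by memorising corpus anatomy.
3. At desk count levels the smallest (10 mm) rod ROI has only ~20-60
   pixels, so the t-test is underpowered to flag a 90%-count image as
   different; the "every thinned image significant in every ROI"
   property holds for organs and for large-n ROIs at moderate count
   levels, not universally.

What passing tests do show: exact activity bookkeeping, a calibrated
and count-conserving projector, exact Poisson/binomial counting
statistics, metric and statistical engines that match independent
oracles, a correct convolutional engine, substantial and reproducible
denoising gains, and a conjugate-view dosimetry chain that recovers
slab activities within 5% across 5–20 cm of water.  What they do not
show: transfer of the published significance-equivalence claim to real
acquisitions, or desk-scale reproduction of published count tables.

## Numerical choices

* Attenuation of water at 208 keV: 0.0136 /mm (NIST-interpolated),
  configurable everywhere.
* Water density 1 g/cm^3 for MBq/kg conversions.
* Voxel/pixel convention: axes (x, y, z) with z axial; projection along
  y; the posterior image is mirrored left-right to display convention.
* Degenerate inputs: constant images have no Otsu threshold (error);
  zero-variance equal-mean t-tests return p = 1; identical images give
  PSNR = Inf; thinning beyond the current fraction errors (counts
  cannot be created).
* The Otsu histogram uses exact per-bin value sums, so with up to 256
  distinct values the result coincides with an exhaustive search over
  candidate thresholds.
* Single precision in the network engine (about 1e-7 relative forward
  error); all statistics in double precision.
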