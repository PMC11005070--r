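---
title: "Corneal index engineering and perceptron screening: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Corneal index engineering and perceptron screening: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

kcscreen implements an automated keratoconus screening chain of the kind
shipped with combined Placido-disc / anterior-segment OCT topographers: a
set of scalar indexes engineered from corneal elevation and layer-thickness
maps, a multilayer perceptron that maps the index vector to one of five
diagnostic classes, and the ROC / confusion-matrix machinery used to judge
both. Because clinical device data cannot ship with a package, a synthetic
corneal phenotype simulator generates labelled five-class cohorts with the
geometric structure the indexes assume; everything downstream of the maps is
identical for real and synthetic input.

```{r setup}
library(kcscreen)
```

## The data model

Maps live on a polar grid (default 31 rings x 256 meridians over a 4 mm
radius, plus an apex sample), matching the circular/annular geometry of
every index zone and the ring-like sampling of Placido/OCT devices. The
coordinate convention is right-handed with x nasal-positive for right eyes
and y superior-positive; left-eye scans are exact mirror images, and the
grid's meridian count is kept divisible by 4 so that mirroring is an exact
node permutation. Elevation is in mm, positive toward the instrument, zero
at the vertex; thickness maps are in micrometres, with corneal = epithelial
+ stromal enforced at 1 um (well inside device axial resolution).

A scan is stored on disk as a sectioned UTF-8 text file (`[META]` plus five
CSV blocks at 9 significant digits); `write_scan()`/`read_scan()` round-trip
it losslessly at that precision.

## The nineteen indexes

The index vector (see `INDEX_NAMES`) combines four families:

* **Curvature asymmetry.** Gaussian-curvature maps of both surfaces in
  keratometric diopters (`337.5 * sqrt(k1 k2)`), summarized by hemispheric
  symmetry indexes (`SI_F`, `SI_B`: inferior minus superior zone mean on
  the 81/261 or 99/279 degree axis), center-surrounding indexes (`CSI_F`,
  `CSI_B`), the map maxima (`KMax_F`, `KMax_B`) and the central-3 mm
  average keratometry (`KAvg_F`, `KAvg_B`).
* **Deviation from a physiologic reference.** A best-fit aspho-toric
  surface (conicoid meridians, fixed asphericity Q = -0.2 anterior /
  -0.3 posterior, fitted apical radii and toricity over the 8 mm zone)
  defines `RMS_F`, `RMS_B` (area-weighted RMS deviation) and `DZMax_F`,
  `DZMax_B` (signed maximum deviation).
* **Zernike shape.** The ectatic indexes `EI_F`, `EI_B` are
  linear-plus-quadratic functionals of the order-8 orthonormal Zernike
  coefficients, with weights trained by ridge-regularized logistic
  discrimination of keratoconus versus normal surfaces. The weights are
  not constants of the package: they are learned from the training
  partition of whatever cohort is being analysed and carried in the model
  bundle.
* **Pachymetric structure.** Minimum corneal thickness (`Thk_Min`), the
  thickness symmetry index (`SI_THK`), the percentage thickness-increase
  excesses (`pTI`, `pEpiTI`: maximum excess of the subject's annular
  thickness-increase profile over the normative 95th-percentile profile,
  centered on the thinnest point) and the spread of the seven notable
  points (`NPtsR`): the three layer-thickness minima, the two curvature
  maxima and the two deviation maxima. A true cone draws all seven to one
  spot; noise scatters them.

Left-eye scans are mirrored into right-eye orientation before any index is
computed, which makes the entire vector exactly equivariant under the
laterality flip. The symmetry-zone geometry (1.5 mm radius at 3 mm from the
vertex) grazes the edge of the 8 mm support; the zones are clipped to the
support, and the geometry is configurable.

### Numerical choices

Derivatives for curvature are estimated per node by local least-squares
polynomial fits in a frame rotated to the node's radial/tangential
directions. Two details matter. First, the neighbourhood is chosen with a
ring-adaptive meridian stride so that its tangential extent matches its
radial extent: near the apex, adjacent meridians are a few micrometres
apart, and a second derivative estimated across such a sliver amplifies
measurement noise by orders of magnitude. Second, the basis contains, beyond
the biquadratic terms, the cubic terms, the radial quartic, and (away from
the apex) the quartic cross term and (away from the rim) the radial quintic
— ring arcs couple the radial and tangential offsets (`u ~ -v^2/2r`), and
without these terms that coupling biases the curvature of a perfect sphere
by more than the 0.05 D oracle tolerance. With them, spheres of radius
7.0-8.6 mm reproduce `337.5/R` within 0.05 D at every node, including the
rim.

Axial power for `KAvg` is averaged per meridian in the power domain
(`1/Ra`): atop a decentered cone the surface is locally axis-parallel, the
axial radius diverges, and a radius-domain mean would be dominated by those
patches, while their axial power is simply zero.

The aspho-toric fit is Levenberg-Marquardt (via minpack.lm) on the smooth
parametrization `c(theta) = a0 + ac cos 2theta + as sin 2theta` (flat/steep
curvatures and axis are recovered afterwards), started from the closed-form
paraxial spherical fit; the self-fit recovers exact model surfaces to 1e-3
mm and is idempotent to 1e-9. Extremum locations break ties toward the
smallest radius, then the smallest meridian index (the canonical node
order). Degenerate inputs are errors, not guesses: a plane has no axial
curvature and `k_avg()` says so.

## The classifier

The perceptron is written out in full: bipolar sigmoid activations
`2/(1+exp(-sigma x)) - 1` on every neuron, inputs normalized affinely into
[-1, 1] against per-index cutoffs (1st/99th training percentiles, values
outside clipped), 19 input neurons, one output neuron per class, and
full-batch gradient descent with momentum on the mean squared error against
1/0 class-indicator targets. Classification is winner-take-all with ties
resolved to the first class in the fixed order (Abn, Kcn, MyPO, Normal,
SKcn). Weights start as fan-in-scaled uniform draws from a seeded
generator, so training is bitwise reproducible; analytic gradients agree
with numerical differentiation to 1e-6 relative.

Targets of 1/0 with activations bounded in (-1, 1) mean the loss can never
overflow: outputs approach but never reach the targets, which is harmless
because only the argmax matters. It also means classical "divergence to
NaN" cannot occur — a hopeless learning rate shows up as a high error
plateau instead, and `hyperparameter_search()` discards such configurations
by score (test-set macro-F1, ties broken by the variance of the last decile
of the training error, i.e. by the stability of the descent).

The default single training configuration (one hidden layer of 15, learning
rate 0.05, momentum 0.9, sigma 1, at most 3000 epochs with early stopping
after 200 epochs without improvement) was chosen as a sensible center of
the usual search ranges; `default_run_config()` accepts an arbitrary grid.
Inverse-frequency class weighting is available but off by default.

## The simulator

`generate_cornea()` builds each eye from an aspho-toric optical base
(anterior radius ~7.8 mm, posterior ~0.82 of it, Q near -0.2/-0.3,
physiologic toricity and pachymetry) plus per-class features:

* **Keratoconus:** a Gaussian cone protrusion (height 12-40 um, width
  0.9-1.4 mm, center 0.3-1.5 mm from the vertex around the 270 degree
  meridian) applied to both surfaces with posterior amplification 1.3; a
  coma-like inferior steepening component along the cone meridian (a pure
  Gaussian bump has a negative-curvature annulus exactly where the
  hemispheric zones sit, whereas real ectasia steepens the whole inferior
  cornea — this term is what gives frank disease its I-S of ~1-3 D and
  central K above the 47.2 D criterion); a co-located corneal thinning
  crater (40-100 um); focal epithelial thinning over the cone (8-18 um)
  with a compensatory thickened annulus around it — the epithelial
  remodeling signature that `pEpiTI` and `NPtsR` exploit.
* **Suspect:** the same mechanism with every effect size drawn at
  50% +/- 10% of the keratoconus prior means — attenuated disease, not a
  different one.
* **Myopic post-op:** a Gaussian-profiled central ablation (25-85 um,
  sigma 2.2 mm) removing tissue and flattening the center.
* **Abnormal:** band-limited random irregularity (orders 3-6 Zernike
  modes, RMS 2.5-8 um) on both surfaces and the epithelium.

Measurement noise is Gaussian per node: 1.5 um on pachymetry, half on the
epithelium, and 10% of that on elevations — device elevation maps are
model-reconstructed and far smoother than raw sections. Stroma is defined
as cornea minus epithelium, so layer additivity is exact by construction.
The whole cohort, including per-eye parameter draws and laterality, is a
pure function of one integer seed.

What the simulator does **not** emulate: Placido mire geometry, OCT speckle
and segmentation artifacts, tear-film breakup, decentered acquisitions,
scan-quality failures, or the population correlation structure between
indexes of a real clinic mix. Passing tests on synthetic cohorts therefore
demonstrate that the chain is implemented correctly and that the indexes
separate the *modelled* phenotypes — they are not a claim about clinical
accuracy on device data.

The rule-based labeller (`rule_based_label()`) mirrors the clinical
criteria for established keratoconus — 3 mm I-S difference > 1.4 D, central
K > 47.2 D, focal corneal thinning below the normal 5th percentile with an
off-vertex or cone-co-located thinnest point, and focal epithelial thinning
over the cone apex, with disease called at two or more criteria — and
serves as a ground-truth cross-check of the generator (agreement with the
generator labels exceeds 90% on default normal/keratoconus cohorts). The
topographic pattern criteria of the clinical definition (bow-tie shapes,
skewed radial axes) are not implemented.

## Evaluation

`stratified_split()` divides each class at 70/30 (`round(0.7 n)` per
class). Per-index discrimination is the Mann-Whitney AUC from midranks,
oriented to be at least 0.5 with a direction flag, and graded on the
Hosmer-Lemeshow bands (0.5 / 0.7 / 0.8 / 0.95, boundaries belonging to the
upper band). The confusion matrix is reduced one-versus-rest per class to
TP/FP/FN/TN, accuracy, precision, recall and F1, with zero denominators
yielding flagged zeros. Percentile normality ranges use linear interpolation
between order statistics (quantile type 7): values inside (p5, p95) are
normal, within [p1, p5] or [p95, p99] borderline, outside abnormal. A
one-sample Kolmogorov-Smirnov utility is included because percentile
reporting is motivated by the non-normality of most indexes; it gates
nothing.

## The study pipeline

`run_screening_study()` executes the whole chain with strict
train/test hygiene: the ectatic-index weights, the normative profiles and
percentiles, and the normalization cutoffs are all fitted on the training
partition only, before any test scan is generated; test eyes only ever meet
the frozen model. The manifest records md5 checksums of every stage output
(cohort plan, split, weights, normative model, index tables, model,
confusion matrix); two runs from one seed produce identical manifests.
Wall-clock timings are reported separately, outside the manifest, precisely
so that the manifest can be identical across reruns.

Problem sizes used by the shipped checks: the test suite's end-to-end study
uses 500 eyes per class with the single default training configuration, and
`scripts/acceptance.R` runs 200 eyes per class; both report Normal-vs-Kcn
discrimination accuracy, per-class recalls and per-index AUCs computed on
their held-out test partitions.

## Known limitations

* The device's native grid, interpolation, exact zone geometry of the
  symmetry indexes, keratometric convention for the posterior surface, and
  the published classifier's architecture and training hyperparameters are
  not public; each corresponding choice here is documented above and kept
  configurable where it matters.
* `EI` weights and normative profiles are learned from the cohort at hand,
  so their absolute values are not comparable across studies — only their
  discriminative behaviour is.
* The signed maximum convention for `DZMax` (maximum elevation above the
  reference, not maximum absolute deviation) was chosen because ectasia is
  a forward protrusion; deeply depressed surfaces would be summarized by
  `RMS` instead.
* Indexes are exactly invariant under relabeling of the meridian origin
  only for rotation-invariant quantities; the hemispheric indexes are tied
  to the anatomical axes by design, so a physical rotation of the eye is
  not an invariance of the vector.
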