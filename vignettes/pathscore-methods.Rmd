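---
title: "Scoring pathway activation from translocation-assay images: models and methods"
author: "pathscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring pathway activation from translocation-assay images: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The assay and the quantity being estimated

pathscore quantifies how strongly a gene variant activates a signalling
pathway, read out through a nuclear-translocation reporter assay. Cells
are transfected with a tagged gene construct together with a fluorescent
reporter (a downstream signalling protein such as ERK2 or STAT3) that
moves from the cytoplasm into the nucleus when the pathway is active.
Each well is imaged as one three-channel field of view (FOV): a nuclear
stain marking all nuclei, a transfection marker identifying which cells
express the construct, and the reporter itself. The latent quantity of
interest is the per-image probability that the cells carry a
pathway-activating construct; per-variant biology is obtained by
averaging that score over all images of a variant.

## The multi-scale patch network

The classifier is a compact multi-scale convolutional network. An input
image is resampled to each side length in `scales` (default 1024, 512,
256), every version is tiled into non-overlapping `patch` x `patch`
patches (default 256, giving 16 + 4 + 1 = 21 patches), and each patch
passes through a stack of feature-extraction modules — 3 x 3
convolution with size-preserving padding, ReLU, batch normalisation,
then 2 x 2 max pooling — with filter schedule (4, 8, 16, 32, 64). Five
modules shrink a 256-pixel patch through 128, 64, 32 and 16 to an
8 x 8 x 64 feature block. Global average pooling reduces each block to a
64-vector; the vectors of all patches at all scales are concatenated,
scale-major then row-major, into a 1344-long embedding; three fully
connected layers of 100 units with ReLU and 20% dropout between them
feed either a single sigmoid unit (the activation score) or an
`nGenes`-way softmax (the gene-identity head, default 7). The default
network has 229,681 trainable parameters — deliberately small, because
patching plus global average pooling forces the network to respond to
features that recur across many patches rather than to single-image
idiosyncrasies.

Points on which reasonable architectures differ, and what this package
does:

* **Operation order inside a module** is convolution, ReLU, batch
  normalisation, max pooling — normalisation after the activation. The
  more common order normalises before the nonlinearity; this package
  keeps the order above and verifies in its tests that it trains
  stably.
* **Padding** is size-preserving; without it the 8 x 8 x 64
  block shape is unreachable from a 256-pixel patch.
* **Weight sharing.** One extractor is shared by all patches of a scale,
  and each scale has its own extractor, so the scales form parallel computation paths.
  Flags (`shareWithinScale`, `shareAcrossScales`) expose the
  alternatives; sharing across patches is what makes the parameter count
  independent of image size.
* **The gene head** is implemented as an alternative head trained
  separately, not as a second simultaneous output; multi-task weighting
  is otherwise unspecified and would add a free parameter.
* **Initialisation** is variance-scaling (He) for convolutional and
  fully connected weights, unit scale / zero shift for batch norm, all
  drawn from a seeded stream.

### Numerical choices

The sigmoid output is clipped to [1e-7, 1 - 1e-7], so scores are
strictly inside (0, 1) and cross-entropy losses stay finite. Softmax is
computed with the row-max subtracted. Batch normalisation uses eps =
1e-5 and keeps running statistics with momentum 0.9, except that the
first training batch initialises them outright: the conventional (0, 1)
starting values are arbitrary, and with the small step counts of
desk-scale runs an exponential moving average from them would need many
batches to reach the true activation scale, leaving inference-mode
outputs meaningless early in training (we observed exactly this before
adopting first-batch initialisation). Max-pool ties resolve to the first
element in column-major scan order; argmax ties in the gene head resolve
to the lowest class index. Both tie-breaks are deterministic and part of
the contract. Inference disables dropout and freezes batch-norm
statistics, so scoring is bit-reproducible.

Internally, activations travel through the extractor as (H·W·N) x C
matrices; convolution is im2col plus one BLAS GEMM per chunk, and the
element-wise steps (bias + ReLU, batch norm, pooling, global average
pooling) are fused compiled kernels operating in that single layout.
This is an implementation detail — it changes nothing numerically (the
test suite checks the path against naive direct convolution and
finite-difference gradients) — but it is what makes desk-scale training
runs take minutes rather than hours.

## Training

Training follows the reference recipe: mini-batches of 32
images, Adam with learning rate 1e-4. The stopping rule is this
package's own choice: early stopping on validation
loss (default patience 5 within at most 50 epochs), returning the
weights of the best validation epoch. One behaviour matters at desk
scale: with very few optimisation steps per epoch, the validation
*loss* first rises for a number of epochs while the network's raw
scores drift away from 0.5, before the separating direction dominates
and the loss collapses. Ranking metrics (AUC) improve monotonically
through this transient; the loss catches up once the scores calibrate.
On datasets with hundreds of steps per epoch the transient lasts less
than one epoch and the defaults behave conventionally, but the
scaled-down runs shipped with the package (three gradient steps per
epoch) set patience 12-25 within 40-80 epochs so that early stopping
cannot fire inside the transient and return the epoch-1 weights.

Splits are stratified by plate: all images from one plate belong to one
of train/validation/test, so held-out performance measures
generalisation across experimental batches, not interpolation within
them. Plates are assigned greedily (largest first, seeded shuffle for
ties) to the split with the largest remaining image deficit relative to
the 60/20/20 targets; the tests verify this against exhaustive search
over all 3-way partitions for small plate counts. Splits are stratified
by plate only — class labels are not additionally balanced, so strongly
imbalanced designs should allocate wells accordingly.

## The synthetic translocation assay

Because real imaging data of this kind are typically proprietary, the
package ships a simulator whose defaults emulate the statistics of a
production translocation screen: a
1024 x 1024 FOV containing 3543 +/- 767 nuclei (truncated normal,
minimum 1), of which 12% are transfected (i.i.d. Bernoulli). Geometry
is deliberately minimal — nuclei are filled discs with radius uniform
in 6-12 px, cytoplasm a concentric annulus at twice the nucleus radius
— because nuclear/cytoplasmic partitioning, not morphology, is the
phenotype. Nuclei are placed uniformly with rejection of placements
overlapping an existing nucleus by more than 30% of the smaller disc
(lens-area criterion, at most 40 attempts per cell, then the candidate
is accepted; a hard rejection rule cannot terminate at this density).

Each transfected cell owns a fixed reporter photon budget (lognormal
across cells, log-sd 0.25) split between nucleus and annulus by the
per-cell nuclear fraction `clip(0.15 + 0.7 * alpha + N(0, 0.05), 0, 1)`
where alpha in [0, 1] is the latent activation. Translocation therefore
redistributes signal and never changes a cell's total — the
conservation is tested. The base/gain/jitter values are calibration
choices giving clearly separated but noisy classes; all are parameters.
The mapping is graded per cell rather than all-or-none — whether real
cells translocate gradually or switch-like at intermediate activation
is an open question — and setting the jitter high approximates the
all-or-none regime. The camera model is Poisson shot noise on
expected photon counts plus Gaussian read noise (sd 3 counts) and
16-bit quantisation, the standard sCMOS description. Channel photon
scales (600 per nuclear-stain pixel, 200 per marker pixel, 120,000 per
cell of reporter) sit well inside the 16-bit range so clipping is
negligible.

Dose-response ground truth comes from a four-parameter decreasing Hill
curve, `alpha(c) = floor + (alpha0 - floor) / (1 + (c / ic50)^hill)`,
plus an optional high-dose rebound bump
`reboundAmp / (1 + (reboundConc / c)^hill)` emulating off-target
re-activation at high concentrations; with the bump disabled the curve
is non-increasing and bounded by [floor, alpha0].

Wells are shuffled (seeded) before being grouped into plates, so each
simulated plate mixes conditions the way a real assay plate does;
without this, plate-stratified splits would confound plate with class
and both training and evaluation would be degenerate. Identical
(design, parameters, seed) reproduce bit-identical images.

### What the simulator does not model

Cell morphology beyond discs, cell cycle and confluence effects,
fixation artifacts, uneven illumination, focus drift, channel
bleed-through, and real plate batch effects (simulated plates differ
only by sampling noise). Passing the scaled-down performance checks
therefore shows that the pipeline — rendering, splitting, optimisation,
scoring, evaluation — is correct and that the architecture can extract
a nuclear/cytoplasmic partition signal at realistic cell densities and
noise levels; it does not show that real-microscopy accuracies would
reach the same numbers.

## Scoring, calls and statistics

Per-image scores are averaged per variant, and a variant is called
active when its mean score is strictly above the sigmoid midpoint 0.5
— a mean of exactly 0.5 is inactive, and the tests pin the boundary on
both sides. The aggregation unit is the image (well- or repeat-level
averaging can be had by aggregating the manifest first); SEM bars in
dose series are likewise over images. The comparison of a variant to
wildtype is a two-sample t test on per-image scores, Welch by default
because equal variances between a mutant and a wildtype score
distribution is exactly the assumption under test (`pooled = TRUE`
restores the classical test); two constant groups raise an explicit
degenerate-input error rather than returning NaN. Raw p-values are
reported; multiplicity control across variants is left to the caller.

Variant names are parsed tolerantly for the position profile: the first
integer in the name anchors the residue ("V654A" gives 654,
"W557_558Del" gives 557, ad-hoc forms like "G12_G13_Del_Ins_DC" give
12); names without a residue number are returned in a rejects table
with a reason, never silently dropped.

Dose series are non-parametric: mean score and SEM per concentration,
no Hill fitting — the deliverable is the raw mean-per-dose curve, and a
parametric fit would add assumptions the readout does not need. Potency comparison reports the lowest
concentration at which each series drops below a threshold (default:
halfway between its zero-dose mean and its minimum — an explicit
stand-in for a visual judgement) and which series crosses first.
Rebound detection flags a global minimum followed by a later rise
exceeding twice the combined SEM of the two points, so noise-level
fluctuations are not flagged.

## The classical oracle

`oracleRatio()` is an independent, non-learned readout used to validate
the simulator and as a benchmark: Otsu threshold on the nuclear channel,
hole filling, distance-map watershed to split touching nuclei;
transfected cells gated by a one-dimensional Otsu split of the
nucleus-mean marker intensities (marker-positive nuclei form a
well-separated upper mode, and unlike a pixel-background rule the
split is unaffected by how much of the field the whole-cell marker
discs cover; a separation floor declares wells with no marker signal
empty); the statistic is the median over gated cells of mean
reporter intensity inside the nucleus over mean reporter intensity in
the surrounding annulus (nearest-nucleus territory, nuclei excluded).
A well with no gated cell returns an explicit empty-well result. The
segmentation is deliberately simple; it is a validation instrument, not
a contribution, but it is constructed from entirely different
principles than the network, so agreement between the two readouts on
simulated data is informative.

## Problem sizes used in the checks

The shipped checks run at desk scale, chosen once: simulator
calibration over 50-100 full-size default wells; the scaled-down
binary performance analogue on 160 wells at 512 x 512 with cell density
scaled to FOV area (886 +/- 192 nuclei, i.e. the default density per
unit area), activation 0.05 for wildtype-like wells versus 0.9 for
activating ones, 10 plates of 16 wells, split 60/20/20 by plate;
property checks (score monotonicity in alpha, oracle monotonicity,
dose-series shape) on 128-256 px wells at proportionally reduced cell
counts. Production translocation screens run to tens of thousands of
images; the scaled-down analogue checks the same pipeline end to end
at desk scale, on data where ground truth is known exactly.

## Known limitations

* The simulator's simplifications listed above; in particular simulated
  plates carry no systematic batch effect, so plate-stratified
  validation is necessary but not battle-tested against real batch
  structure.
* The activation head treats every non-wildtype training well as
  positive; training data must be restricted to wildtype plus known
  activating variants (the function refuses other annotation classes).
* Gene-head experiments at desk scale use few genes; the 7-gene default
  matches the architecture description, not a shipped dataset.
* Scores are raw sigmoid outputs; no probability calibration beyond the
  0.5 convention is attempted.
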