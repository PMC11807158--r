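---
title: "Pathology-aware segmentation of layered retinal B-scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathology-aware segmentation of layered retinal B-scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Spectral-domain OCT renders the retina as a stack of reflective bands. In
atrophic macular disease — Stargardt disease being the motivating case —
outer bands (photoreceptor segments, outer nuclear layer, sometimes the
RPE) vanish over growing regions. Asking a pixel-classification model for
five sublayers everywhere forces it to invent boundaries where no layer
exists; asking only for the total retina discards the granularity that
thickness-based progression endpoints need.

`pathaware` takes the middle road. Per B-scan:

1. a detector marks the *severely affected region* — the columns where at
   least one sublayer is undetectable — as one orthogonal box (multiple
   pockets are merged into a single larger box);
2. a two-class model segments the total retina over the whole scan;
3. a six-class model segments IR, ONL, PR-IS, PR-OS and RPE, trained with a
   *masked* loss that excludes the box.

The mask `m` is the box expanded to full image height, 0 inside and 1
outside, so only columns left and right of the box carry loss:

$$L_{pa,ce} = -\tfrac{1}{N}\textstyle\sum_i m_i\, y_i \log \hat y_i,\qquad
L_{pa,dc} = 1 - \frac{2\sum_i m_i y_i \hat y_i}
{\sum_i m_i y_i + \sum_i m_i \hat y_i},\qquad
L_{pa} = L_{pa,ce} + L_{pa,dc}.$$

With `m ≡ 1` these reduce bit-for-bit to the standard combined
cross-entropy + Dice loss, and the gradient with respect to any prediction
inside the box is identically zero — both facts are asserted by the test
suite rather than assumed.

Assumptions worth stating: layers are strictly ordered top-to-bottom in
healthy columns; the severely affected region is contiguous enough that a
single box per scan is acceptable (a multi-box extension is deliberately
out of scope); the total retinal band remains visible inside the box;
ground truth for sublayers is undefined inside the box, so nothing inside
it is ever evaluated for the sublayer task.

## Numerical and design choices

* **`0·log 0` convention.** The literal masked form `log(m ŷ)` is
  undefined at `m = 0`; we restrict the sum to unmasked pixels, which is
  the intended semantics. Probabilities are clamped at `1e-7`.
* **Normalisation of the masked cross-entropy.** The batch denominator `N`
  counts *all* pixels by default (`masked_norm = "literal"`, matching the
  definition of `N` as the pixels of the entire batch);
  `masked_norm = "unmasked"` divides by `Σ m_i` instead, removing the
  dependence of the loss scale on box size. Both are exposed because the
  choice is genuinely underdetermined.
* **Multi-class Dice.** The Dice loss and score are one-vs-rest per class,
  averaged over classes. Background joins the cross-entropy but not the
  Dice average; a class absent from both prediction and ground truth is
  undefined and excluded from averages (not scored 1), also in reports.
* **Report aggregation.** Per-layer Dice is summarised as mean ± sd over
  images; the "Overall" row averages layers within an image first, then
  over images. The report records this (`layer-then-image`) explicitly.
* **Coordinates.** Everything is 0-based with half-open `[start, end)`
  intervals, row 0 at the vitreous side; boxes store columns and rows in
  that convention and export to COCO xywh JSON.
* **Paired comparison.** Methods are compared with a two-sided paired
  t-test on per-image overall Dice; a zero-variance difference vector is
  reported as an explicit degenerate case instead of erroring.

## The segmenter

The default architecture is a compact encoder-decoder with 16 base filters:
3×3 convolution (image plus a normalised row-coordinate plane as input),
2×2 average pooling, a second 3×3 convolution, nearest-neighbour
upsampling, a skip concatenation, a fusing 3×3 convolution and a 1×1
classification head with per-pixel softmax — i.e. a U-Net pattern with one
pooling level. At the phantom sizes used throughout (64–128 px tall), one
level of pooling already gives a receptive field spanning the retinal band;
deeper pyramids would mostly convolve padding. Forward and backward passes
are written as im2col + BLAS products (RcppArmadillo); optimisation is
Adam. Training is fully deterministic given the seed: initialisation and
shuffling draw from R's RNG, the kernels are sequential C++.

Training defaults mirror the full-scale schedule: learning rate 5e-4,
batch size 15, a scheduler halving the rate after 15 epochs without
validation-Dice improvement, checkpointing the best validation Dice
(background excluded), 15 epochs for the total-retina task and 30 for the
six-class task. At the reduced phantom scale the package's own experiments
use `lr = 0.01`, `batch_size = 5` and 10 epochs — roughly 150 Adam steps —
which the convergence logs show is where the small net plateaus on this
task. Ground-truth boxes build the training masks; predicted boxes are
used only at composition time. An image whose box spans the full width
contributes zero loss; it is logged and skipped.

## The detector

The default, tested detector is rule-based: segment the sublayers, flag
columns where a layer is effectively undetectable, merge flags into one
box. On ground-truth label masks "undetectable" is literal zero thickness
(`t_min = 1` px), and that exact rule also generates the phantom's
ground-truth boxes, so the round-trip is closed. On *predicted* maps a
convolutional segmenter always paints ~1 px transition bands across layer
boundaries, so absolute zero thickness never occurs; the detector therefore
uses soft thickness (per-column sums of class probabilities) with an
adaptive per-layer threshold, 0.6× that scan's median column thickness,
and ignores two border columns where zero padding degrades predictions.
The box confidence is the fraction of its columns whose thinnest layer
falls below 0.9× the median — a monotone "how atrophic is this span"
score used by the pipeline's keep-top-1-above-0.5 rule. A learned
alternative (logistic region head over per-column intensity-profile
features) satisfies the same contract and is exercised by overfitting
tests; neither aims to reproduce detection scores obtained with large
pretrained detectors on clinical data.

## What the phantom emulates — and what it does not

Each synthetic B-scan is built from six smooth boundary curves (shared
sinusoidal curvature, optional per-boundary jitter, Gaussian foveal dip
acting on the inner boundaries), rendered as piecewise-constant
reflectivity with unit-mean gamma speckle and additive Gaussian noise.
Disease severity, drawn per patient and increasing linearly across visits,
acts outside lesions by thinning ONL/PR-IS/PR-OS (up to 40 % at severity 1)
and attenuating the photoreceptor bands (PR-IS −0.35, PR-OS −0.25, RPE
−0.10 gray levels at severity 1) — the EZ attenuation and outer-retinal
thinning seen clinically, and the domain shift that makes healthy-only
training fail on diseased scans. Above a severity threshold (0.35) a scan
develops a lesion: within its spans the absent layers collapse to zero
thickness, 35 % of the removed thickness is returned to surviving layers
as debris-thickening while the rest thins the band (atrophy), and
hyper-reflective debris blobs are painted. The ground-truth box covers all
columns with a zero-thickness layer; disjoint spans merge into one box.

The phantom is *not* a physical OCT simulation: no coherent speckle
statistics, no vendor formats, no optic nerve, no shadowing artefacts, and
only per-volume severity sharing rather than true 3-D coherence. Debris
texture parameters are free choices, since no quantitative description
exists. Passing tests on phantoms therefore demonstrates the mechanics of
the pipeline — exact loss masking, correct bookkeeping, and the *ordering*
of pathology-aware over standard training under a controlled domain shift
— not clinical-grade accuracy on real scans.

## Cohort machinery

The sampling pipeline reproduces the study bookkeeping: patients split
8:1:1 within each site (validation and test counts floored with a minimum
of 1 when a site has ≥ 3 patients; smaller sites go to training with a
warning), the middle 11 slices of each volume classified central and the
rest peripheral (floor offset for even remainders), and per-patient
sampling of 30 % central / 70 % peripheral scans with the central count
rounded half-up — 3 scans per training patient, 16 per validation/test
patient. The iterative loop transfers 200 randomly sampled scans per loop
from the unannotated pool into the training set against fixed validation
and test manifests (hash-checked); an optional plateau rule stops when the
validation metric improves by less than 0.5 points (absolute) for two
consecutive loops. Random pool sampling is deliberate — the data contain
informative lesion-free scans that uncertainty-driven selection would
skip — and an uncertainty hook is left as an extension point.

## Problem sizes used by the tests and acceptance script

Bookkeeping runs at full manifest scale (259 patients over nine sites,
126,910 rows) without rendering images. Model-based checks run on 64–128 px
phantoms: the directional comparison trains both arms on ~100 scans for 10
epochs (the pathology-aware arm on a 50/50 healthy:diseased mix, its
standard competitor on healthy scans only, since standard sublayer training
is undefined on scans with unannotated regions) and evaluates out-of-box
sublayer Dice on 16 lesioned and 16 healthy held-out scans. These sizes are
the package's reproducibility contract: large enough for the ordering to be
stable across seeds, small enough to re-run anywhere.

## Known limitations

* The rule-based detector inherits the segmenter's blind spots: very
  narrow lesions that the model inpaints can be missed, and its box rows
  are the predicted band extent, not a learned quantity.
* The masked loss leaves the model free to hallucinate plausible layers
  inside the box; by design those pixels are replaced by the total-retina
  segmentation in the composed output, but the raw sublayer map should not
  be consumed inside boxes.
* Absolute Dice/AP values on phantoms say nothing about clinical data;
  only the relative comparisons are meaningful.
* Single-box-per-scan is a modelling decision; scans with widely separated
  pockets pay for it with one large box that hides recoverable boundaries.
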