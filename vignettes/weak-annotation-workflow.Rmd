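---
title: "Semi-automated weak annotation of benthic megafauna: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-automated weak annotation of benthic megafauna: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(faunadetect)
```

## The problem

Towed-camera surveys of the deep seafloor produce tens of thousands of
photographs per cruise, of which only a small fraction contain visible
megafauna. Training an object detector on such imagery requires bounding-box
annotations, and finding the rare animals to annotate is itself the
bottleneck: an annotator must page through thousands of near-identical
sediment images to find a handful of ophiuroids and sponges.

`faunadetect` implements a semi-automated route around this bottleneck.
The key observation is statistical: on a quasi-homogeneous substrate,
almost every image region looks like sediment or manganese-nodule
speckle, so regions occupied by fauna are *anomalies* of the region
population. The workflow is:

1. over-segment each image into **superpixels** (graph-based
   segmentation after Gaussian smoothing);
2. learn an unsupervised representation of the superpixel patches with a
   small **variational autoencoder** (VAE) and use the posterior mean as a
   feature vector;
3. score every patch with an **isolation forest** and flag a generous
   top fraction (the contamination) as candidate anomalies;
4. remove false positives (laser points, dark water-column patches,
   unusual nodules) with either a score **percentile threshold** or a
   trainable **binary patch classifier**, yielding *weak annotations* —
   imprecise boxes without labels;
5. assign **morphotype labels**, split annotations by scene into
   training/validation sets, and export CSV/COCO files for detector
   training;
6. **evaluate** detections with the standard COCO metric family and
   summarise them ecologically: abundance in individuals per square
   metre, exponential Shannon diversity, and gridded spatial density
   along the georeferenced camera track.

Training the final object detector itself is out of scope; the package
provides a detector-agnostic evaluation suite and a configurable noisy
*oracle detector* so that evaluation and ecology are exercisable without
GPU-scale training.

## The synthetic survey generator

Real deep-sea imagery cannot ship with a package, so `faunadetect`
includes a seeded generator whose output has the statistical structure
the workflow assumes. It is first-class, tested code, not a fixture.

A scene (`scene_config()`, `generate_scene()`) is built from:

* a smooth low-frequency sediment field around RGB (0.45, 0.40, 0.33)
  plus Gaussian pixel noise (`noise_sigma`, default 0.02);
* dark nodule ellipses with radii 3.5–6 px at a Poisson mean of
  `nodule_density = 150` per 256×256 frame — dense enough that nodules
  dominate the superpixel population, sparse enough that over 80 % of
  the frame stays background;
* rare fauna (`fauna_rate = 2` per frame, Poisson) drawn from a
  ten-morphotype palette of parametric shapes (disk-with-arms, fan,
  spiked star, elongated blob, irregular plume) with skewed weights —
  ophiuroids, sponges and xenophyophores dominate, as in abyssal nodule
  provinces. The xenophyophore entry is deliberately low-contrast
  (+0.10 per channel over the sediment) to emulate camouflaged
  morphotypes. Ground-truth boxes are computed from the *actually
  rendered* pixels, so they are tight by construction;
* distractors excluded from ground truth: pairs of saturated red laser
  disks (radius 5 px, 40 px apart) and dark water-column patches — the
  dominant false-positive classes of real surveys.

`generate_survey()` adds a camera tow: images every 10 s (a 0.1 Hz still
camera), a straight track at 0.26 m/s (≈ 0.5 kn), navigation fixes at
least as often as the image cadence, and altitude oscillating smoothly
between 1.5 and 3.5 m. An optional `fauna_density_m2` plants fauna at a
target abundance by scaling each scene's Poisson mean with its visual
footprint, which makes ecological parameter recovery a genuine round
trip.

What the generator does *not* emulate: optical attenuation and lighting
gradients, perspective distortion, substrate transitions, overlapping
animal aggregations, and image-to-image background drift. Passing tests
therefore demonstrate the internal consistency of the workflow under its
own assumptions, not performance on real imagery; segmentation and VAE
hyperparameters must be re-tuned per deployment.

### Ophiuroid arms, deliberately thin

Arms of the disk-with-arms shape are ~3 px wide, which is realistic at
the ~1 cm/px ground resolution the scene geometry implies. After
Gaussian smoothing they often merge into the background, so the fauna
segment covers only the central disk — precisely the kind of imprecision
weak annotations are expected to have (a box covering an ophiuroid's
disk but not its arms). The recall criterion below uses IoU > 0.25, so
disk-only boxes usually still count as covering; a minority do not, and
that loss is retained as a property of the method rather than hidden by
thickening the arms.

## Segmentation

`segment_image()` implements greedy graph-based segmentation: pixels are
nodes of an 8-connected graph weighted by Euclidean RGB distance; edges
are processed in nondecreasing order and two components merge when the
edge weight does not exceed either component's internal difference plus
`scale / |C|`. A post-pass dissolves components smaller than `min_size`.
Edge weights are computed on the 0–255 intensity scale — the convention
of the algorithm's reference implementations — so the customary
`scale = 100` default keeps its meaning. On default synthetic scenes
this yields ~150 superpixels per frame with the sediment as one dominant
segment, which `extract_patches()` excludes via `max_area_fraction`
(default 0.25).

Patches are square crops of side `max(box width, box height)` centred on
the segment box, clipped to the image, replicate-padded back to square
(no new colours introduced) and bilinearly resampled to
`patch_size = 64`.

## Feature learning

The VAE (`train_vae()`, `encode_patches()`) minimises a per-sample sum
of squared pixel errors plus the KL divergence of the diagonal-Gaussian
posterior from the standard normal,
`KL = ½ Σ (μ² + σ² − 1 − log σ²)`. Patches are average-pooled to
16×16×3 before a one-hidden-layer encoder (dense, ReLU) producing μ and
log σ²; the decoder mirrors it with a sigmoid output. This is the
smallest architecture that separates the synthetic patch classes and
trains in seconds on one CPU; colour and coarse morphology — the signals
that distinguish fauna from sediment and nodules — survive the pooling.
The reparameterisation `z = μ + σ ⊙ ε` is used during training only;
inference returns the posterior mean, so features are deterministic.

Two scaling choices matter. First, the reconstruction term is summed
over pixels (not averaged): with a per-pixel mean the KL term dominates
at 768 pixels and the posterior collapses to the prior, destroying the
anomaly structure downstream. Second, `vae_config()` defaults to the
conventional `latent_dim = 100`, but the pipeline's default
configuration uses 32, chosen by a small parameter search over
{8, 16, 32, 100} on default synthetic surveys for the best
isolation-forest separation of fauna patches — larger latents dilute
the informative directions among noise dimensions that the forest then
splits on. The latent dimension should be re-tuned for any new image
source.

## Anomaly scoring

`fit_iforest()` is a from-scratch isolation forest: 100 trees, each
grown on a uniform subsample of ψ = 256 rows, splitting a uniformly
random attribute at a uniformly random value within the node's range,
stopping at height ⌈log₂ ψ⌉ or singleton nodes. Constant attributes are
resampled up to d times before a node becomes a leaf. Scores follow
`s(x) = 2^(−E[h(x)]/c(ψ))` with the truncated-leaf credit `c(n)`
(`avg_path_length()`), `c(1) = 0`. `flag_by_contamination()` flags the
top `⌈contamination·n⌉` scores with ties broken by patch id.

The default contamination of 0.4 is deliberately high: camouflaged
morphotypes score only moderately anomalous, and the workflow prefers to
flag four in ten patches and discard false positives later than to miss
them. The cost is pushed onto the filtering step.

## Filtering weak annotations

Both strategies are implemented and selectable (`filter.method`):

* `threshold_filter()` retains patches with scores strictly above the
  linear-interpolation percentile (default 75th) of the score vector.
  It is simple but has no principled threshold, and saturated laser
  points score very high — so thresholding keeps them.
* `train_patch_classifier()` + `classifier_filter()`: a small dense
  network over pooled patch pixels maps a patch to a fauna probability;
  patches at or above `prob_cutoff` (0.5) become weak annotations with
  the superpixel's own box (boxes are never invented) and the anomaly
  score carried through.

In the orchestrated pipeline the classifier's training labels come from
overlap with the synthetic ground truth — the stand-in for the human
who, in a real deployment, skims the score-sorted review queue
(`review_queue()`) and marks examples. Positives are capped at 512 from
the top of the queue; *all* remaining flagged patches serve as
negatives. The false-positive population is heterogeneous — lasers,
dark patches, oddly shaped nodules — and a capped or subsampled
negative set under-represents parts of it, which shows up directly as
lost precision in the filtered annotations.

Labelled annotations are split by `split_annotations()` with whole
scenes assigned to one side (stricter than a per-record split: two
superpixels of one image are near-duplicates, and letting them straddle
the split would leak), targeting `⌊0.9·n⌋` training records.

## Evaluation

The evaluation suite is detector-agnostic and follows the COCO
conventions the field reports: greedy confidence-ordered matching per
class and scene, 101-point interpolated average precision, AP at IoU 0.5
and averaged over 0.50:0.95 in steps of 0.05, size strata at 32² and 96²
pixels (truths outside a stratum are ignored rather than counted as
errors), and average recall at 1/10/100 detections per scene. Empty
strata report `NA` — never 0 — and means skip them. The confusion matrix
matches class-agnostically and then compares labels, with background
row/column for false positives and negatives.

`oracle_detector()` simulates a trained detector with controllable error
modes (miss rate, per-image Poisson false positives, corner jitter,
label confusion); with all noise at zero it returns the ground truth at
confidence 1, which pins the metric ceiling at exactly 100 %.

## Ecology

Detections inherit the position of their parent image, matched to the
navigation track by nearest timestamp (ties to the earlier fix; images
beyond `max_gap_s` are reported unresolved, never silently dropped). The
visual footprint is `(2a·tan(fov/2))²` for altitude `a` and the default
64°×64° field of view — the video head's printed angle, used for the
stills as well since no still-camera value is available; it is
config-overridable. Abundance divides counts by the footprint of *all*
surveyed images; no overlap correction between consecutive frames is
applied. Diversity is the exponential of Shannon entropy ("effective
number of morphotypes"). For mapping, lon/lat are projected to local
planar metres by an equirectangular projection about the mean latitude
(adequate at km scale) and binned into 200 m blocks, each normalised by
the footprint of the images whose centres fall in it.

## Reproducibility and numerical choices

* One global seed fans out to per-stage seeds via an integer hash of the
  stage name, so any stage is independently reproducible and two runs of
  `run_stage("all", ...)` with the same configuration are bit-identical.
* Configurations are schema-validated before any computation; unknown
  keys are rejected outright.
* All randomness in the generator flows through a per-scene derived
  stream, so scene `k` of a 500-scene survey can be regenerated alone.
* Quantiles use R's default type-7 (linear interpolation) definition;
  the 75th percentile of {1,2,3,4} is 3.25.
* Boxes are 0-based, half-open `[x_min, x_max) × [y_min, y_max)`;
  areas and IoU are exact integer-pixel quantities for integer boxes.
* Degenerate inputs fail fast with named errors: empty score tables,
  rank-0 feature matrices, non-finite training losses (reported with the
  epoch), undersized subsamples (lowered with a warning).

## Problem sizes used by the tests

The test suite and acceptance script size their simulations to run on a
single CPU: the end-to-end recall check uses three 100-image surveys at
256×256 (the package's default scene), the anomaly-power benchmark uses
525 points over five seeds, and the orchestration reproducibility check
uses 12-image surveys at 128×128. These sizes were chosen as the
smallest at which the checked statistics are stable.

## Known limitations

* The synthetic generator's contrast between fauna and background is a
  free parameter, not calibrated against any real survey.
* Weak-annotation boxes inherit superpixel geometry; elongated or
  partially buried morphotypes are systematically under-covered.
* The VAE and classifier are deliberately small; on real imagery both
  would need more capacity and more training data.
* Abundance estimates ignore image overlap along track and assume the
  nominal field of view; both simplifications bias densities when tow
  speed is low or altitude is high.
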