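---
title: "Cyst-wise evaluation of tubule segmentations: models and design choices"
author: "cystwise package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cyst-wise evaluation of tubule segmentations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Autosomal dominant polycystic kidney disease (ADPKD) is studied *in vitro*
with engineered kidney tubules: patient-derived epithelial cells seeded in
3D-printed scaffold channels, treated with candidate compounds, fixed, and
imaged as RGB immunofluorescence z-stacks. The readout of such an assay is
the number and size of the cysts that form along each tubule. Counting and
measuring cysts by hand does not scale, so segmentation models are trained
to label each pixel as cyst or not — and the scientific question shifts to
*how to evaluate* such models in a way that reflects what the assay needs:
not just pixel accuracy (which over-weights large cysts), but whether each
individual cyst was found.

`cystwise` implements that evaluation framework end to end:

* **no-G preprocessing** (green-channel muting) and a joint image/mask
  augmentation pipeline;
* a pluggable **segmentation backend** contract with a compact trainable
  encoder–decoder reference network and the standard training recipe;
* **postprocessing** by flood-fill hole filling and circular-element
  opening/closing;
* **pixel-wise and cyst-wise metrics** with a deterministic resolution of
  overlaps into detected (DT), missed (MS) and wrong (WR) cysts;
* **size zones** and **leave-one-tubule-out (LOTO)** cross-validation
  structure;
* a **synthetic scene generator** and a **mask perturber** so that every
  stage is testable with exact ground truth and known answers.

# Data model

Images are RGB arrays in `[0, 1]`; masks are `CystMask` objects — logical
grids with a declared pixel connectivity. Connectivity controls how cyst
pixels group into components (the objects the cyst-wise metrics count);
8-connectivity is the default because annotated cysts are compact blobs and
a diagonal join should not split one. The hierarchy experiment → treatment
→ tubule → image is carried by a one-CSV catalog; tubule ids repeat across
treatments, so all grouping uses the composite key
`experiment/treatment/tubule`.

Annotations are polygons in the Labelme dialect. Rasterization uses the
pixel-center-inside rule with an even-odd crossing test: pixel `(r, c)`
(0-based) is cyst when its center `(c + 0.5, r + 0.5)` lies inside a
polygon. The half-open form of the crossing test resolves centers exactly
on an edge consistently (a top-left style convention); no rule is imposed
by the annotation format itself, so the choice is documented here and
pinned by tests against an independent point-in-polygon oracle.

# The synthetic scene generator

The generator emulates what a human annotator relies on: a red tissue band
(the tubule wall) crossing the frame, point-like blue nuclei scattered over
the tissue and densified in rings around cyst rims, cyst lumens that are
dark voids in red and blue, and a green channel of pure noise (the real
green channel carries markers irrelevant to the task, which is exactly why
no-G preprocessing exists).

Defaults encode the study conditions: 1024×1024 canvases; per-image cyst
counts Poisson with mean 4 capped at 12 (median 4, range 0–12); cyst areas
log-normal truncated to 30–2000 µm². The log-normal location is calibrated
(`meanlog = log 61`, `sdlog = 0.9`) so that the *truncated* distribution
has median ≈ 78 µm²; with the location at `log 78` the lower truncation at
30 µm² would push the median near 92 µm². The µm-per-pixel scale is a
config value (default 0.5 µm/px, a typical confocal magnification) because
pixel areas are what the code measures and µm² is what the size zones are
defined in. Cysts are mildly rotated ellipses stored as 48-gon polygons;
the ground-truth mask *is* the rasterization of those polygons, and cysts
are kept pairwise disjoint by a center-distance margin, so component
counts are known by construction. `bandFraction` controls the tissue band
half-width; at 0.5 and above the tissue fills the frame, emulating a
close-up of the tubule wall.

What the generator does **not** emulate: point-spread blur, z-bleed,
uneven illumination, touching or nested cysts, annotation error. Passing
tests on synthetic scenes therefore validate the *evaluation machinery*
and the trainability of the reference network, not clinical performance on
microscope data.

The perturber turns a ground-truth mask into a synthetic "prediction"
with a known DT/MS/WR outcome: components are dropped, split in two by a
1–3 px background cut through the centroid, or boundary-jittered, and
small spurious blobs (areas drawn below the smallest size zone, because
wrong predictions are typically very small) are placed disjoint from all
ground truth. Rates drive random behaviour; explicit `dropIds`/`splitIds`
and an exact spurious count exist to pin known-answer fixtures.

# Preprocessing

`removeGreen` zeroes the green channel while keeping three channels
(pretrained encoders expect RGB input); red and blue pass through
bit-identically and the operation is idempotent.

The augmentation pipeline applies, in order: horizontal flip (p 0.5),
random ±90° rotation (p 0.5), random brightness (limit 0.2, p 1.0), random
contrast (limit 0.2, p 1.0), random gamma (80–120, p 0.5), CLAHE (clip
limit 4.0, p 0.5), and normalization to reference channel statistics
(p 1.0). Design choices that the parameter table alone does not fix:

* *rotation* is restricted to the two right angles, which are lossless;
  arbitrary-angle rotation would demand an interpolation and border policy
  nothing in the task pins down;
* *brightness/contrast limits* are read multiplicatively — a factor drawn
  from `[0.8, 1.2]`; the convention is config-visible;
* *CLAHE* operates on the luminance representation with an 8×8 tile grid
  and rescales the channels by the luminance ratio, preserving hue;
* *normalization* is `(x − mean)/std` per channel on the `[0, 1]` scale,
  defaulting to the ImageNet statistics, kept in config rather than
  hard-coded.

Geometric transforms act identically on image and mask; photometric
transforms never touch the mask, which stays strictly logical throughout.
Augmentation applies at training time only; evaluation uses no-G and
normalization alone.

# Segmentation backends and the training recipe

A backend is anything mapping an RGB image to a probability map of the
same height/width in `[0, 1]` (`predictProbabilities`). Two backends ship:

* `thresholdBackend()` — a training-free baseline: high probability for
  dark pixels *enclosed by* bright red tissue (darkness alone cannot work,
  because the background outside the tubule is as dark as a lumen). It
  exercises the whole evaluation pipeline without any training.
* `ReferenceNet` — a miniature of the UNet family: three resolution
  levels, two 3×3 convolutions per level, widths 8/16/32 (~30k
  parameters), each convolution followed by non-learned instance
  normalization (the stabilizer the UNet family usually gets from batch
  norm — it makes activation scales independent of the initialization
  draw, which matters when the step budget is small) and a leaky
  rectifier (slope 0.1 — narrow layers make dead units likely under a
  plain ReLU, and a dead path cannot recover within a short step budget),
  2×2 max pooling, nearest-neighbor upsampling, skip concatenations, and
  a 1×1 sigmoid head that also sees the instance-normalized input (an
  input skip: first-order image contrast — dark lumens against bright
  tissue — reaches the logits from the first update instead of waiting
  for deeper features to form). The size is chosen so the full
  training recipe runs in minutes on one CPU; the five published
  large-scale architectures remain external plug-ins behind the backend
  contract rather than re-implementations.

Training follows the fixed recipe: binary cross-entropy on logits, Adam at
learning rate 1e-4, batches of 8 images (gradients averaged), cosine
annealing with warm restarts (T₀ = 10 epochs, T_mult = 2, so the rate
restarts at the 10- and 30-epoch boundaries), early stopping when
validation IoU has not improved for 10 epochs, at most 100 epochs, and
binarization at 0.5. Further choices the recipe leaves open:

* validation IoU is *accumulated* pixel-wise over the whole validation set
  (summed confusion counts), not averaged per image;
* "improvement" is any strict increase (no minimum delta);
* the returned weights are from the best-validation-IoU epoch;
* binarization uses strict `>` at the threshold, so an exactly-0.5
  probability falls to background;
* the network ends in a fixed **logit gain** (×64) after the 1×1 head,
  with the head zero-initialized and its bias set so the initial logits
  sit at the prior (−2; cyst pixels are a small minority). The gain is an
  architecture constant, not an optimizer change: Adam moves each
  parameter by at most ≈ lr per step, so at the mandated learning rate
  and a short step budget an ungained sigmoid head cannot reach confident
  logits; the gain widens the reachable logit range while the recipe
  stays fixed;
* weights use He-normal initialization; all randomness (init, shuffling)
  flows through the R RNG, making training bit-reproducible under a seed
  on a fixed-thread CPU run.

ImageNet pretraining is out of scope for the reference net; training from
random initialization on synthetic scenes is the testable stand-in.

# Postprocessing

Hole filling converts every background component not connected to the
image border into foreground (cysts do not contain holes). Background is
labeled under the connectivity complementary to the foreground's
(8-connected cysts ⇒ 4-connected background), the standard pairing that
avoids paradoxes at diagonal contacts.

Opening and closing use a circular structuring element of size `k`,
defined as the integer offsets within Euclidean distance `(k − 1)/2` of
the center — `k` is a *diameter*, `k = 1` is the identity, and an even `k`
(half-integer radius) yields the disc nested between its odd neighbors.
Pixels outside the image are background for both erosion and dilation, a
policy that matters for cysts touching the frame edge. Each composite runs
on a background-padded canvas wide enough to retain intermediate dilation
growth; this makes closing extensive, opening anti-extensive, and both
exactly idempotent including at borders (cropping between the two stages
would break extensivity there). The pipeline order is hole filling first,
then the optional morphology. Choosing between opening (removes tiny noisy
detections, costs recall) and closing (merges over-segmented fragments of
one cyst, recovers precision) is deliberately left to the analyst;
per-region adaptive postprocessing is out of scope.

# Metrics

Pixel-wise: IoU = TP/(TP+FN+FP), Pr = TP/(TP+FP), Re = TP/(TP+FN). The
identity IoU = Pr·Re/(Pr+Re−Pr·Re) holds whenever the right side is
defined and is enforced to 1e-12 in the tests.

Cyst-wise: predicted and ground-truth components are overlap candidates
when they share at least one pixel (default) or when their pairwise pixel
IoU exceeds a configurable τ (the two rules coincide at τ = 0). Candidates
are resolved into a one-to-one pairing *greedily in descending pairwise
IoU*, breaking ties by larger intersection, then lower component ids — a
deterministic rule. Matched ground truth is DT, unmatched ground truth MS,
unmatched predictions WR; hence a cyst covered by several predictions
yields one DT plus WRs, and a prediction spanning N cysts yields one DT
plus N−1 MS. The counting rules fix what DT/MS/WR must be in every
star-shaped overlap configuration (the cases that occur in practice), and
the test suite verifies greedy matching attains the exhaustive-search
maximum DT on all such instances; general bipartite graphs could in
principle make greedy sub-optimal, which is why the matching is also
checked for the conservation laws DT+MS = #GT and DT+WR = #pred on random
inputs. Cyst-wise IoU/Pr/Re are DT/(DT+MS+WR), DT/(DT+WR), DT/(DT+MS).

Metrics with zero denominators are *undefined*: they are returned as `NA`
and excluded from aggregation, never coerced to 0 or 1.

Size zones stratify object-level performance: six strata with the default
boundaries 34.7, 53.3, 78.7, 120.9, 207.5 µm² (the equal-cardinality
sextiles of the annotated-cyst area distribution). Zones are
left-closed/right-open — an area equal to a boundary belongs to the zone
starting there — and zone 6 is unbounded above. `computeZoneBoundaries`
recomputes the k/n quantiles from any area sample. Attribution uses the
*actual* (ground-truth) size for DT and MS and the *predicted* size for WR
(a wrong prediction has no true size); per-zone counts always sum to the
global counts.

# Evaluation structure

Images from the same tubule are strongly correlated, so all train/test
separation happens at tubule level. LOTO builds one fold per tubule: that
tubule's images are the test set, and the remaining tubules are split
80/20 into training and validation *tubules* (a seeded draw of at least
one). The 80/20 split is made at tubule level rather than image level —
the conservative reading of the leakage argument.

Aggregation is micro within a group (confusion counts summed, metrics
recomputed from the sums — insensitive to how cysts spread across a
tubule's z-slices) and macro across groups (mean over groups). The "±"
intervals are 95% normal-approximation half-widths of the mean across
groups; this is a convention of this package, stated here because the
interval definition is not implied by the metric definitions themselves.
Per-treatment reports add the spread (max pairwise difference) of each
metric across treatments — the treatment-invariance check.

# Problem sizes

The test suite and the acceptance script run entirely on synthetic data at
sizes chosen for single-CPU runs: mask-level property checks use 24–64 px
grids (1000 random pairs for the conservation/identity laws, 200 masks ×
k ∈ {3,5,7} for the morphology oracle); the learning check trains the
reference network on 64 easy 128×128 close-up scenes (full-frame tissue,
3–4 high-contrast lumens of 120–500 µm² at 1 µm/px) for at most 30 epochs
and requires pixel IoU > 0.5 plus cyst recall > 0.8 on a held-out
synthetic tubule; the acceptance script evaluates a perturbed-prediction
study of 8 tubules × 4 images at 256×256 and trains on 32 scenes for up to
20 epochs. The easy regime exists because distinguishing a lumen interior
from the background *outside* the tubule is a contextual task (both are
dark); with tissue filling the frame, the minority-class contrast is local
and the miniature network converges within the epoch budget.

# Known limitations

* The generator's ellipse model cannot produce concave, touching or
  nested cysts; matching behaviour on such shapes is covered only by the
  abstract mask-level property tests.
* The reference network is a deliberately small stand-in; its scores on
  synthetic scenes say nothing quantitative about published architectures
  on microscope data.
* Greedy matching is provably maximal only on star-shaped overlap graphs;
  pathological chain/cycle overlap patterns could lose one DT relative to
  optimal. No such pattern has been observed in practice, and the
  conservation laws hold regardless.
* The z-stack structure is ignored: slices are independent images, and no
  volumetric fusion is attempted.
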