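---
title: "wheatsyn: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{wheatsyn: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: what each stage
models, which parameters matter and why their defaults are what they are,
what the synthetic generator does and does not emulate, and where genuinely
open design choices were settled.

## 1. Scene synthesis

### The stem model

Wheat stems are grown by a Lindenmayer system: a parallel string-rewriting
grammar whose expansion is read as 3D turtle graphics. The default grammar is

* axiom `F`, rule `F -> FF+F`, 3 iterations → 27 forward segments,
* `step_length = 0.04` world units → stems ≈ 1.1 units tall,
* `base_bend = 0.035` rad per `+`/`-` symbol.

The alphabet is `{F, +, -, [, ]}` (branching symbols are supported by the
interpreter but unused by the default grammar, since a wheat culm is
unbranched). Expansion is *simultaneous*: every symbol is rewritten in the
same pass, which the tests pin against an independently written recursive
oracle.

### Wind

Each scene draws one wind state: speed uniform on [0, 1] (arbitrary units)
and azimuth uniform on [0, 2π). Wind enters the geometry twice, and both
paths scale with speed:

1. a per-segment pitch schedule `base_bend * speed * k/n` for segment `k`
   of `n` — bending grows toward the tip, which is where a real culm is most
   compliant;
2. the `+`/`-` symbols of the grammar itself bend by `base_bend * speed`.

The bend azimuth is the wind direction plus one Gaussian jitter per stem
(σ = 0.15 rad), so a scene leans coherently without being uniform. A
consequence we treat as a model invariant: at speed 0 every stem is exactly
vertical. Making the grammar's own bend symbols wind-scaled (rather than
constant) is what preserves that invariant while keeping the grammar
responsible for *where* along the stem curvature can occur; the wind decides
*how much*.

### Heads, camera, boxes

Each head is an ellipsoid of revolution attached at the stem tip and
continuing its direction (default length 0.14, radius 0.04 world units, with
±15% per-plant size jitter). The camera is a standard pinhole
(`u = u0 + f·x/z` in a right-down-forward camera frame); the default
overhead camera sits at altitude 3 looking straight down with `f = 500` px
at 400×400 — chosen, together with the default 1.6×1.6 field extent, so the
camera frames the plot the way an overhead acquisition rig frames a quadrat.

A head's box is the axis-aligned hull of 64 Fibonacci-spiral samples of its
ellipsoid surface, projected and clipped to the frame. The box is kept when
at least 25% of the sample points are visible; partially visible heads keep
their (clipped) boxes, matching the labelling convention of field datasets.
With these defaults ≈84% of generated heads receive a box, and 5000 scenes
at 30–60 plants each yield ≈180k annotations. When a render is available its
id-buffer can refine visibility with occlusion, but the geometry-only rule
is the default because dataset-scale counting runs without rendering.

### The renderer

The rasteriser is deliberately simple and entirely procedural: seeded value
noise plus foliage blobs for the ground, projected polylines for stems, and
per-pixel ray-cast ellipsoids (exact footprints, painter's order far-to-near
with a depth buffer) for heads, with a Lambertian-ish shade and spikelet
noise. Two palettes ("synthetic" and "field") emulate a two-domain setting.
What it does *not* emulate: photoreal texture, specular lighting, motion
blur, real soil/residue clutter, or genuine inter-plant occlusion patterns
of dense canopies. Passing tests on these renders therefore demonstrate the
pipeline's mechanics — geometry-consistent labels, trainability, metric
correctness — not detector transfer to real fields.

## 2. Heatmap labels

For a box with centre `(cx, cy)` and sides `(w, h)`:
`σx = w/6`, `σy = h/6`, and the bump is the separable Gaussian peaking at 1
at the centre. The σ rule puts ±3σ at the box edges — the common
keypoint-regression convention that keeps essentially all of the bump inside
the box. Overlapping bumps combine by elementwise **maximum**, not sum: the
label must stay in [0, 1] because it is consumed by a binary cross-entropy
loss, and a peak (not integrated mass) is what encodes a head. Heatmaps for
resized images are regenerated from the resized boxes rather than
interpolated, so peaks are never attenuated.

## 3. Heatmap-supported translation

### Objective

The translator is the canonical unpaired two-generator setup: generators
`G_s2r`, `G_r2s` (conv encoder with two stride-2 downsamples, residual
trunk — 6 blocks at ≤128 px, 9 at 400 px — and a nearest-upsample decoder
with tanh output in [-1, 1]); 70×70-receptive-field patch discriminators;
least-squares adversarial objective; cycle-consistency and identity terms as
mean absolute error; 50-image replay pools for the discriminator updates.
On top of this sit two lightweight 3-level skip-connection UNets: `U_r`
reads `G_s2r`'s output and regresses the *source* image's heatmap, `U_s`
symmetrically. Each UNet is trained jointly with its generator through one
shared Adam optimiser (lr 2×10⁻⁴, β = (0.5, 0.999)). The generator
objective is

    L_G = L_adv(s2r) + L_adv(r2s) + λ_cyc (L_cyc,s + L_cyc,r)
          + λ_id L_id + λ_hm (L_BCE,s + L_BCE,r)

with defaults λ_cyc = 10, λ_id = 5, λ_hm = 1. Setting λ_hm = 0 gives the
plain baseline translator (used to build dataset C) while leaving every
other computation bit-for-bit identical — a property the tests assert.
The support networks only ever see the source image's own heatmap as
ground truth; a translation that moves, adds or deletes heads therefore
raises the BCE term, which is the mechanism that preserves head geometry.

Choices the published recipe leaves open, settled here: the adversarial
objective is least-squares (the canonical default the baseline implies);
identity loss is included by default but togglable, with λ_id at half of
λ_cyc; λ_hm = 1 and soft (non-binarised) Gaussian BCE targets — BCE is
well-defined for targets in [0, 1] and is minimised, over a constant
prediction, exactly at the target value; the learning rate is constant (the
training account reports degradation after 100 epochs rather than a decay
schedule); batch size is 1, the canonical unpaired recipe.

### Numerical design

The networks run on the package's own array-based framework: forward passes
return explicit caches so a generator can appear twice in one step (its own
translation and the other direction's cycle), and backpropagation
accumulates parameter gradients with compiled im2col+GEMM convolutions.
Every layer's gradient is verified against central finite differences in the
tests. The UNet's sigmoid is fused with the BCE gradient ((p − t)/N into the
logits), avoiding catastrophic cancellation at saturated pixels. Instance
normalisation uses ε = 10⁻⁵; BCE clamps predictions to [10⁻⁷, 1 − 10⁻⁷];
non-finite losses abort training immediately.

Two profiles bundle the operating points: `"paper"` (400 px, 100 epochs,
9 residual blocks, ngf 32/ndf 64/UNet base 16) and `"test"` (64 px,
2 epochs, 6 blocks, ngf 12/ndf 16/UNet base 8). Channel widths are not part
of the published description; the test profile's widths were chosen so a
300-step CPU smoke run finishes in minutes while leaving the UNets under a
quarter of a generator's parameters ("lightweight" made checkable). Images
below 24 px are rejected: the five-level patch discriminator has no output
left there.

The smoke-training property — on a seeded 64 px two-style fixture of 32
images per domain, 300 steps lower the 10-step moving averages of the total
generator loss, both heatmap BCE terms and both cycle terms — is the
module's key assertable behaviour and runs in the acceptance suite. It
demonstrates that the joint objective trains; it says nothing about
translation *quality* at publication scale, which needs the paper profile
and a real target domain.

## 4. Domain clustering

Appearance features default to a deterministic channel-wise colour histogram
(16 bins × 3 channels, L2-normalised): global colour statistics are exactly
what separates the broad appearance modes (species colour, growth stage,
lighting) that clustering is meant to split, and the extractor is fully
reproducible offline. The contract is pluggable — any
image → feature-vector function, such as pooled activations of a pretrained
CNN, drops in via `extract_features(images, extractor = )`.

K-means is an explicit Lloyd loop: k-means++ seeding, best of `n_init = 10`
restarts by inertia, empty clusters rescued by re-seeding at the point
farthest from its centre (keeping k fixed), and a per-iteration inertia
trace whose monotone decrease the tests assert. Default k = 4 follows the
published compromise between cluster count and per-cluster volume; a
warning fires when a cluster falls below 100 images, the scale below which
adversarial training on that target becomes unreliable. Since visual
cluster inspection is inherently qualitative, the recovery test uses
separable Gaussian blobs instead: four blobs at mutual distance ≥ 10 with
σ = 0.1 must be recovered with adjusted Rand index exactly 1, and base R's
`kmeans` serves as an independent cross-check on the same data.

## 5. Dataset assembly

Bundles carry images, annotations, optional heatmaps and per-image
provenance (origin id + transform chain). Translated bundles inherit their
source boxes verbatim — translated outputs are never re-annotated, which
matches the pipeline being reproduced and knowingly accepts the residual
risk of hallucinated heads in the plain-translator baseline. `build_K`
translates every synthetic image once per cluster model, suffixing ids, so
|K| = k·|S| exactly (quadrupling at k = 4). All resizing flows through one
path that scales boxes per axis and regenerates heatmaps. Bundles serialise
to PNG + CSV + JSON manifest and round-trip losslessly up to 8-bit image
quantisation.

## 6. Detection evaluation

Matching is greedy by descending IoU with one-to-one consumption and
deterministic tie-breaks (lower prediction index, then lower ground-truth
index) — simpler than Hungarian assignment and standard in detection
evaluation. It is a 1/2-approximation of the optimal assignment, not always
optimal; the tests bound it against a brute-force oracle on small instances.
Conventions that the headline numbers cannot themselves disambiguate are
declared and config-switchable:

* per-image IoU = Σ matched IoUs / (matched + missed + spurious) — both
  missed heads and hallucinated detections count as 0
  (`aggregation = "penalize_unmatched"`; `"matched_only"` available);
* centre distances are collected over matched pairs only;
* confidence filtering is inclusive (≥ threshold);
* the reported SD is the population SD over per-image scores;
* an image with no ground truth and no surviving detections scores IoU 1
  (vacuous agreement; test sets genuinely contain near-empty frames).

The reference blob detector (colour saliency `R + G − 2B`, threshold,
connected components, confidence = normalised component saliency) exists so
the generate–translate–detect–evaluate loop closes without a learned
detector; external detectors are scored through the CSV/JSON adapter.

## 7. Problem sizes used by the checks

The test and acceptance runs use desk-scale sizes chosen as the package's
own operating points: 64 px fixtures with 32 images per domain and 300
optimisation steps for the translator smoke run; 5000 geometry-only scenes
for the annotation-count reproduction; 20 rendered 96 px scenes for the
end-to-end loop; 200-point blob sets for cluster recovery. The paper profile
(400 px, 100 epochs, k = 4 cluster models, thousands of images) is fully
expressible in the same configs but is a multi-day CPU computation and is
not exercised by the tests.

## 8. Known limitations

* The renderer is a geometric stand-in; no claim is made that detectors
  trained on its output transfer to real imagery.
* The histogram feature extractor captures colour, not texture; domains
  differing only in texture would need a CNN extractor plugged in.
* Greedy matching can under-match adversarial box configurations (bounded
  above by 2× optimum).
* Batch size is fixed at 1; there is no GPU path, no multi-threading, and
  no learning-rate schedule.
* Translated images inherit source annotations by construction; label noise
  introduced by translation failures is not corrected.
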