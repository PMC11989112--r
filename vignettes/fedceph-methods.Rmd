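---
title: "Methods: federated skeletal classification from cephalograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: federated skeletal classification from cephalograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the labeling rule, the model family, the federated protocol, the evaluation
panel, the synthetic data the tests run on, and every numerical choice that
was genuinely open.

## ANB labeling

The sagittal skeletal classes are defined from the ANB angle at nasion.
`compute_anb_angle()` returns a *signed* angle: the rotation from ray
N→B to ray N→A, counter-clockwise positive in an x-right/y-up frame,
computed as `atan2(cross(NB, NA), dot(NB, NA))`. Image pixel coordinates
have y pointing down, so the default `y_axis = "down"` negates the y
components first. The sign convention assumes a facing-right lateral view:
then a protruded mandible (B anterior to A) gives a negative angle, which
is what Class III thresholds below zero require. An unsigned angle could
never fall below 0, so a signed convention is forced; the 2-D cross product
is the natural way to obtain it.

`classify_skeletal()` is total on finite angles: the Class I band
`[class1_low, class1_high]` is closed at both ends, Class II is strictly
above, Class III strictly below. Both bundled standards follow their
written descriptions — Steiner "3.2–5.7" with Class II "exceeding" and
Class III "falling below" the band leaves the closed band to Class I, and
likewise for the Kim band 0–4. Landmark files are parsed positionally:
the 19-slot layout keeps A, N, B at lines 5, 2, 6; 3-line files are read
as A, N, B. Both comma and whitespace separators are accepted, and lines
past the expected count are ignored, because the two dataset exports the
layout emulates differ in these details.

## Model family

The backbone is a DenseNet-style network: a 7×7 stride-2 stem convolution,
batch norm, ReLU and a 3×3 stride-2 max pool; dense blocks whose layers
(BN–ReLU–1×1 conv to `4·growth` channels, BN–ReLU–3×3 conv to `growth`
channels) concatenate their output onto the running feature map; and
transitions (BN–ReLU–1×1 conv, 2×2 average pool) between blocks. Transition
compression 0.5 and bottleneck factor 4 are not printed in the structure
diagram the backbone follows; we adopt the canonical values, which are the
ones that make the 121-layer layout `[6,12,24,16]` × growth 32 end at a
1024-channel final feature map (the package asserts the 256/512/1024/1024
per-block bookkeeping in its tests). A reduced preset (`tiny_backbone()`:
blocks `[2,2]`, growth 8, grayscale 64×64 input) exists for CPU-scale
experiments; every head attaches to it unchanged.

Six heads consume the final feature map `F` (after the last BN–ReLU; we
keep that BN–ReLU because the appended blocks are defined on the *final
feature map*):

* **plain** — global average pooling, then a fully connected layer to 3
  logits.
* **CA** — channel attention `σ(MLP(avgpool F) + MLP(maxpool F))`, a
  one-hidden-layer MLP with ReLU shared between the two pooled
  descriptors. The hidden width is `C/r`; the reduction ratio `r` is not
  stated in the source description, so we default to `r = 16`, the value of
  the attention blocks' original papers, clamped so the hidden width is at
  least 1, and configurable.
* **SA** — spatial attention `σ(f7×7([meanc F; maxc F]))`. Padding is
  never stated; stride 1 with zero padding 3 is the only choice that
  preserves H×W, which a two-dimensional attention map over the input
  requires.
* **SE** — squeeze (per-channel spatial mean) then excitation
  `σ(FC(ReLU(FC(z))))`.
* **SA_SE** — SA first, then SE on the gated map, following the variant
  name's token order (configurable in principle; the composition order was
  an open choice).
* **SPP** — spatial pyramid pooling over grids `[4, 8, 16]` with adaptive
  average pooling, concatenated to a fixed-length vector of width
  `C · Σ s² = 336·C`; only this head recomputes the fully connected input
  width (`fc_input_size()`).

Attention application is multiplicative — gates scale the feature map,
channel gates broadcasting over positions and the spatial gate over
channels. The source equations produce maps but never write the
application step for CA/SA; multiplication is the established semantics of
these blocks and is what the SE description states explicitly, so we use
it uniformly. Tests pin this down with a saturation identity: gates forced
to 1 reproduce the plain backbone's logits.

Adaptive average pooling uses the half-open floor/ceil bin convention
(bin `b` of `s` over `n` cells spans `⌊bn/s⌋` to `⌈(b+1)n/s⌉`), matching
the dominant framework convention; when the feature map is smaller than
the grid, bins overlap and repeat cells — accepted and covered by tests.

## Implementation numerics

No deep-learning runtime is used: feature tensors are dense matrices
(`N·H·W` rows × `C` columns), convolutions gather rows through precomputed
index plans (im2col) and run as BLAS products, and every primitive returns
a backward closure, so a forward pass accumulates a tape replayed in
reverse. Gradients of every head family are verified against central
finite differences. Initialization is deterministic per tensor: each
parameter's stream is seeded from a hash of (seed, tensor name), so
identical spec + seed builds bit-identical models and tensors shared
between variants (backbone, final classifier) initialize identically
across heads.

Training follows the study recipe: Adam (learning rate 0.001, β = 0.9 /
0.999, ε = 1e-8), cross-entropy, batch size 64. Batch-norm uses momentum
0.1 and ε = 1e-5; running statistics are part of the parameter vector.
The shuffle stream of global epoch `e` is seeded from `(seed, e)`, which
is what makes a federated round sequence exactly replayable by chained
local training.

The standard train-time augmentations (random resized crop, random
horizontal flip, normalization) and eval-time resize + center crop are
provided. A horizontal flip mirrors the facing direction of a lateral
cephalogram and with it the sign convention of the ANB angle; we keep the
flip available for fidelity to the recipe but expose `hflip = FALSE`, and
the synthetic-data experiments run without augmentation, since the
generator's class signal is orientation-dependent.

## Federated protocol

`run_federated()` simulates the client–server loop: each round the global
parameters are broadcast, each client trains `local_epochs` epochs on its
own data, and the server aggregates with sample-count weights
`n_k / Σ n_j`. Sample-count weighting is the canonical federated-averaging
rule and the only sensible choice when the clients differ several-fold in
size. Fault tolerance is exclude-and-renormalize: a client whose local
training raises an error is dropped from the round; a round with no
survivors aborts. Defaults are 50 rounds × 5 local epochs (the study
setting); the desk-scale tests use 10 × 5.

Three choices the protocol description leaves open, and what we did:
optimizer state is client-local and reset every round (only parameters
cross the wire); batch-norm running statistics are averaged like weights
(the simplest faithful reading of exchanging the full model state); and
the global model is evaluated on the shared test pool every round, which
gives the convergence series the round log stores. Clients run
sequentially in-process; aggregation is permutation-invariant in client
order, and the tests check this algebraically.

Two exact identities anchor the implementation: federation with a single
client equals sequential local training with the same seed stream, bit for
bit (both reset Adam at round boundaries); and identical clients with
identical seeds leave the aggregate at either client's update. With
learning rate 0 the trainable parameters are frozen through any number of
rounds — batch-norm running statistics still move, because forward passes
happen; the invariant is therefore stated on the trainable subset.

## Evaluation panel

`compute_metrics()` reports accuracy, support-weighted one-vs-rest
precision/recall/F1, Cohen's kappa `(p_o − p_e)/(1 − p_e)` with chance
agreement from marginal products, and the unweighted mean of per-class
one-vs-rest AUCs computed as the Mann–Whitney ranking probability (ties
counted ½). Support-weighted recall equals accuracy algebraically; the
tests assert it as an internal consistency check, and the AUC agrees with
an all-pairs counting oracle and with an established ROC implementation.
Degenerate panels are flagged rather than crashed: a class absent from the
truth is excluded from the AUC mean with a warning, and `p_e = 1` yields
kappa 1 for perfect agreement and 0 otherwise.

The harness compares three settings on a two-client dataset: LL (each
client trains alone, everyone is tested on the merged pool), CL (merged
training), FL (federated rounds). `contribution_table()` turns the
resulting accuracies into plain differences — FL−LL per client
(federation's contribution to that site) and CL−FL (the sacrifice versus
pooling; negative when federation wins). The bundled benchmark tables of
the full-scale two-clinic study ship as a fixture
(`reported_accuracies()`); recomputing its contribution table recovers the
printed deltas at 1e-4 for 17 of 18 cells — one printed cell (0.002 for
the SE variant's CL-vs-FL column) disagrees with its own source
accuracies, which give 0.0028, and the tests document this rather than
hide it. For cross-validated comparisons, `paired_ttest()` and
`shapiro_wilk()` wrap the standard tests with explicit degenerate-case
handling, and `kfold_split()` produces stratified folds whose class shares
are within one sample of the global proportions.

## Synthetic data: what it emulates and what it does not

`generate_dataset()` emulates the *structure* of the two-clinic scenario:
two clients of different sizes (defaults 856 and 400), different class
mixes (0.46/0.33/0.21 vs 0.2/0.22/0.58) and different labeling standards
(Kim vs Steiner). Generation is angle-first: a class-consistent angle is
drawn uniformly from the class band clipped to ±15° and trimmed 0.1° from
each boundary (so placement jitter can never cross a class), the A/N/B
geometry is solved to realize the angle exactly (round-trip error below
1e-9 degrees), and the image is rendered with a cranial dome, a maxillary
ridge through A, and a mandibular contour through B whose chin point is
displaced anteriorly in proportion to minus the angle — a protruded
mandible for Class III — plus uniform background noise. Class counts are
deterministic largest-remainder apportionments of the configured ratios,
so the generated proportions equal the configured ones exactly at any `n`,
and the 80/20 train/test split is stratified. Landmark files use the full
19-slot layout with meaningless filler points, so the realistic parsing
path is exercised.

The images are stylized line drawings, not radiographs: no anatomy beyond
the three landmarks, no soft tissue, no scanner characteristics, no
demographic structure. Passing the desk-scale experiments therefore shows
that the pipeline is correct and that federation behaves as expected under
size/ratio/standard heterogeneity — it does not certify accuracy on real
cephalograms, whose headline numbers require the original datasets and
full-scale training.

## Desk-scale experiment sizes

The test suite runs the reduced backbone at 64×64: a 300-image
single-client dataset trained centrally for 20 epochs (held-out accuracy
≥ 0.80), and a two-client dataset of 150 images per client compared across
LL (50 epochs) and FL (10 rounds × 5 local epochs), where the federated
model beats both local models on the merged test pool — the qualitative
FL > LL finding at desk scale. Generator seed 123 and training seeds 1 and
7 are fixed study conditions chosen up front; all other checks
(oracle equivalences, federation identities, 10⁴-record label
self-consistency) are deterministic or property-based under fixed seeds.

## Known limitations

* The renderer's class signal is deliberately strong; desk-scale accuracy
  says nothing about class separability on real images, where the
  inter-class angle bands are only a few degrees wide.
* Kept horizontal flip in the default augmentation mirrors the ANB sign
  convention; use `hflip = FALSE` (as the synthetic experiments do) when
  orientation matters.
* Secure aggregation, differential privacy and client subsampling are out
  of scope; both clients participate in every round.
* ImageNet-style pretrained weights are supported only as a checkpoint
  load path (`load_checkpoint()`); all experiments here start from random
  initialization.
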