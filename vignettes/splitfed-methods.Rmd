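---
title: "Split federated learning with conditional GAN rebalancing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Split federated learning with conditional GAN rebalancing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Hospitals hold privacy-sensitive grayscale images (the motivating case is
brain MRI slices graded by dementia severity) that cannot be pooled, and the
class distribution is severely skewed: with class counts 896 / 64 / 3,200 the
imbalance ratios — minority over majority count — are 0.28 and 0.02. A
classifier trained naively on such data collapses onto the majority class;
training it centrally violates data locality. `splitfed` implements the
combination of two remedies:

* **split federated learning (SFL)** — collaborative training in which each
  client runs only the front of the network and a server runs the back, so
  raw images never leave the client and the client's compute burden is small;
* **conditional GAN (cGAN) augmentation** — label-conditioned synthesis of
  minority-class images on the client side, raising the imbalance ratio
  before training.

## The split network

The classifier is a ResNet18-style convolutional network for one-channel
images, cut after its second stage:

* **Client half**: 7x7 stride-2 convolution (64 channels), batch
  normalization, ReLU, 3x3 stride-2 max pooling; then a 3x3 convolution
  (64 channels), batch normalization, ReLU, and dropout (p = 0.5). Its
  output — the *smashed data* — is a `(size/4, size/4, 64)` activation map
  (56x56x64 at the 224x224 input size).
* **Server half**: a conv–BN–ReLU–conv–BN refinement stage at 64 channels,
  three basic residual blocks (two 3x3 convolutions with batch
  normalization plus a projection shortcut; 128, 256, 512 channels, each
  entered at stride 2), global average pooling, and a dense layer to the 3
  class logits trained with categorical cross-entropy.

Design choices in the split that the prose description of the architecture
leaves open, fixed here once:

* the client's second convolution is followed by a ReLU (the alternative —
  batch norm with no activation before the cut — is a one-line change);
* the cut carries the dropout layer, so the transmitted activations are the
  regularized ones during training;
* residual-stage widths follow the standard ResNet18 doubling (128/256/512);
  the composed model is validated as a working 3-class classifier rather
  than as a parameter-count clone of canonical ResNet18, since the client
  front is deliberately simplified;
* both halves are trained with Adam at step size 1e-4 (batch 64), each half
  owning its optimizer state.

### The protocol

Per global round (Algorithm: *split federated learning with label
sharing*): every participating client iterates its shard in mini-batches —
client forward to the cut, transmission of smashed data plus labels,
server-side forward, cross-entropy, server update and gradient-at-the-cut
transmission, client backward from that gradient, client update. The server
half is a single shared model updated sequentially across clients within
the round; after all clients finish, the client halves are aggregated by
**federated averaging** — the unweighted element-wise mean of every
parameter array, batch-norm running statistics included — and the average
is installed as the new global client model. Baselines:

* **FL**: each client trains a full local copy of the composed network for
  one local epoch; all weights are averaged each round.
* **SL**: clients are processed sequentially against the shared server
  half; the single client half (with its optimizer state) is relayed from
  client to client, with no averaging.
* **centralized**: the composed model on pooled data — the reference that
  all three protocols must match exactly when there is one client.

Two details make the single-client equivalence exact rather than
approximate. First, client-side optimizer state is reset only when
aggregation actually replaced the client's weights (more than one
participant); with a single participant the installed weights are the
client's own and stale-momentum concerns do not arise, so Adam state
persists exactly as in centralized training. Second, when every client
participates (`frac = 1`) selection consumes no randomness, so the RNG
streams of a 1-client protocol run and a centralized run coincide
batch-for-batch, dropout mask for dropout mask. The degenerate-equivalence
test then demands equality to 1e-6, and the split-vs-composed gradient test
demands relative agreement to 1e-5; both in fact hold to machine precision
because the two paths execute identical kernel calls in identical order.

## The conditional GAN

The generator maps a 100-dimensional standard-normal latent vector plus a
class label to a tanh-range image: the latent feeds a dense layer of
`(s/4)^2` units (413,696 parameters at s = 256) with leaky-ReLU; the label
feeds a 50-dimensional embedding and a dense layer of the same width
(208,896 parameters); the two maps are concatenated to a 2-channel
`(s/4, s/4)` tensor, upsampled 2x, passed through a stride-2 4x4 transposed
convolution with 64 filters (2,112 parameters) and a final stride-1 4x4
transposed convolution to one channel (1,025 parameters) with tanh output.
The discriminator embeds the label, lifts it to an `(s, s, 1)` map
(3,342,336 parameters at s = 256), concatenates it with the image, and
applies five stride-2 3x3 convolutions of 128 filters (2,432 then 147,584
parameters each), flatten, dropout 0.4 and a sigmoid unit (8,193
parameters). Kernel sizes are not part of the reference layer summaries; they are
recovered uniquely from the parameter counts (3x3 with 2-channel input:
3·3·2·128+128 = 2,432; 4x4 transposed: 4·4·2·64+64 = 2,112), and a
conformance test pins every non-embedding count. The embedding rows are
excluded from conformance: the reference summaries list 200 parameters
(vocabulary 4 x dimension 50) while the build parameterizes by `n_classes`
(3 x 50 = 150); the package follows `n_classes`.

Training follows the standard conditional-GAN loop: per batch the
discriminator takes one Adam step on a real half-batch (target 1) and one
on a generated half-batch (target 0), then the generator takes one step
through the frozen discriminator. The value function is
`E[log D(x)] + E[log(1 - D(G(z)))]`; the generator minimizes the
non-saturating surrogate `-log D(G(z))` (the literal saturating form is
available as an option, and `gan_objective()` exposes the value function
itself). Real images are mapped from [0, 1] to the tanh range [-1, 1] for
training, and synthesized outputs are mapped back — the affine rescaling
`(x + 1) / 2`. Adam uses step size 2e-4 with beta1 = 0.5, the customary
GAN setting; leaky-ReLU slope is 0.2 and discriminator dropout 0.4.

### Augmentation policy

`augment_minority()` raises each client shard's per-class count to
`ceiling(target_ratio x majority count)` with synthesized images, enhanced
by CLAHE and resized to the shard geometry, flagged `provenance =
"synthetic"`. The default `target_ratio = 0.5` deliberately stops short of
full balance: synthesizing too many minority instances risks overfitting
the classifier to GAN artifacts, and some residual imbalance reflects the
real class prior. The test set is never augmented. The GAN is trained once
on the pooled minority classes of the training split by default; training
one GAN per client is the stricter privacy variant and is a deliberate
non-default because the phantom study holds so few minority images per
client.

## Enhancement and augmentation of real images

Contrast limited adaptive histogram equalization (CLAHE: tile-wise
histogram equalization with a clip limit and bilinear blending between
tiles) is applied with clip limit 2.0 on an 8x8 tile grid — the technique's
standard defaults, since only the technique itself is prescribed — followed
by bilinear resizing to 224x224. The order is CLAHE first, then resize.
By default enhancement is applied to synthetic images only, with real
images passing through untouched; a single configuration flag includes the
real images too. Training-time augmentation (random resized crop with
scale [0.8, 1], horizontal/vertical flips, rotation up to ±15°,
brightness/contrast jitter 0.2, random grayscale — an identity on
already-grayscale input, kept as an explicit flag — and final
normalization with mean 0.5 / sd 0.5) is available through
`augmentation_config()` and is off by default in the phantom studies, which
need no extra regularization at their scale.

## The phantom image module

Real MRI data cannot ship with the package, so every end-to-end property is
exercised on *phantom* images: an elliptical bright ring (the "skull")
enclosing mid-intensity tissue textured by random low-frequency sinusoids,
with a dark central cavity whose radius grows with the class index — a
geometric stand-in for the ventricular enlargement that accompanies
atrophy. The signal is geometric rather than textural on purpose: cavity
area survives CLAHE, resizing, and downsampling, so every pipeline stage
preserves the class structure. Per-image nuisance variation (center jitter
±5%, axis jitter ±5%, cavity-size jitter ±8%, additive Gaussian noise with
sd 0.05) keeps the task non-trivial. The cavity radius is
`(0.10 + 0.12 x class x severity_scale)` of the skull radius. The default
`severity_scale = 0.7` was frozen by a two-sided calibration: large enough
that the leave-one-out nearest-class-centroid oracle (on 16x16
area-averaged thumbnails) scores above 0.9 on the default spec, small
enough that a 5-epoch classifier run does not saturate minority-class
recall — without headroom the directional augmentation comparison would
degenerate into noise on a handful of rare-class test images. The default
counts 800/224/16 reproduce the quarter-subsampled study imbalance (ratios
0.28 and 0.02).

What passing on phantoms does *not* show: robustness to scanner bias
fields, registration error, anatomical variability, or any texture-borne
pathology signal. Phantom results validate the protocol machinery and the
direction of the augmentation effect, not clinical performance.

## Numerical choices

* The convolutional kernels (im2col lowering onto single-precision BLAS
  gemm, with specialized plane-accumulation forward kernels for the
  generator's small transposed convolutions) accumulate in float32;
  parameters, optimizer state and everything crossing the R boundary are
  double. Oracle tests against a direct-loop convolution use tolerance
  1e-5 and finite-difference gradient checks 1e-2, the float level.
* Batch-norm uses eps 1e-5 and momentum 0.1 with biased batch variance in
  both normalization and running estimates; running statistics are part of
  the weight collections, so federated averaging and checkpoints cover
  them.
* Argmax ties in prediction break to the lowest class index; per-class
  precision and recall define 0/0 as 0; macro averages are unweighted
  means. The reference results print single precision/recall values for a
  3-class problem without stating the averaging basis, so per-class values
  are always exposed alongside the macro summary — a reported precision of
  1.00 is not recoverable without knowing that basis.
* History CSVs serialize at 17 significant digits, so reloads are exact
  and two same-seed runs produce byte-identical files.
* All randomness flows through R's RNG under per-run seeds; augmentation
  transforms carry a private stream so applying them never perturbs the
  run stream.

## Problem sizes in the shipped checks

The package's own studies (test suite and `scripts/acceptance.R`) run at a
desk scale chosen once: phantoms at 64x64 with the full 800/224/16 counts,
an 80/20 stratified split, two IID client shards, 5 global SFL epochs at
batch 64, and a cGAN pre-trained for 60 epochs (batch 128) on the training
split's 192 minority-class images before augmenting to target ratio 0.5;
the directional recall comparison uses the median over three seeds for the
augmented arm. Smaller unit fixtures (16-32 px, handfuls of images)
exercise individual operations. The equivalence and conformance properties
are scale-free; the accuracy and recall checks are calibrated to this
phantom scale and say nothing quantitative about the MRI-scale setting.

## Known limitations

* In-process simulation only: clients and server are function calls, not
  network endpoints; there is no transport, encryption, or straggler
  handling.
* IID stratified sharding is the only implemented partition; non-IID
  partitions are a configuration hook left unimplemented.
* The label-sharing protocol variant is implemented; the no-label-sharing
  variant (sending only smashed data and returning predictions) is not.
* Single-channel square images only; the compute core is CPU-bound and
  single-threaded apart from BLAS.
* GAN training at the shipped scale produces images good enough to move
  minority recall, not visually convincing anatomy; quality metrics (FID
  and friends) are out of scope.
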