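---
title: "Video synthesis by latent trajectories over a frozen progressive GAN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Video synthesis by latent trajectories over a frozen progressive GAN}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Direct video GANs must synthesise an entire pixel volume at once, which is
what makes high-resolution medical video (for example colonoscopy footage,
where simulators want long, smooth, anonymised sequences) so expensive to
model. `plugingan` implements the memory-efficient alternative: decouple
*appearance* from *motion* and never train a 3-D network at all.

**Stage 1** trains an ordinary 2-D GAN on individual video frames. The
backbone is a progressively grown generator/critic pair: training starts at
4 px and doubles the resolution phase by phase, each new block blended in by
a fade-in coefficient $\alpha$ that ramps from 0 to 1. The objective is the
WGAN-GP critic loss

$$L_C = \mathbb{E}[f(\tilde x)] - \mathbb{E}[f(x)] +
  \lambda\,\mathbb{E}_{\hat x}\big(\lVert\nabla_{\hat x} f(\hat x)\rVert - 1\big)^2
  + \varepsilon_d\,\mathbb{E}[f(x)^2],$$

with interpolates $\hat x = u x + (1-u)\tilde x$, $u \sim U(0,1)$ per
sample, $\lambda = 10$ and a small drift term $\varepsilon_d = 10^{-3}$
(both switchable). Pixel-wise feature normalisation and equalised learning
rates — the usual progressive-GAN stabilisers — are on by default; the
minibatch-standard-deviation channel is **off** by default so that the
critic's penultimate layer remains a *per-sample* feature map (below, that
layer becomes a feature extractor, and cross-sample coupling there would
make a clip's representation depend on its batch neighbours). A flag
restores it.

**Stage 2** freezes the backbone entirely. Two small networks are trained
adversarially:

* the **plugin** $\phi(t, z)$ maps one shared Gaussian noise vector $z$
  plus a per-frame time index $t$ to a latent code. It is four
  concatenate-then-linear layers — at reference scale
  $2047{+}1 \to 1535$, $1535{+}1 \to 1023$, $1023{+}1 \to 511$,
  $511{+}1 \to 512$ — with ReLU after the first three and the output
  normalised onto the unit hypersphere. A clip is the frozen generator
  applied to the trajectory $[\phi(t_1,z), \dots, \phi(t_n,z)]$; because
  every row is computed independently, clips of any length can be decoded
  from the same plugin.
* the **video discriminator** $D$ never sees pixels. Each frame is pushed
  through the frozen frame critic *minus its last layer*, giving one
  512-long feature row per frame; the rows are stacked into an
  $8 \times 512$ single-channel image that a four-layer strided 2-D
  convolution stack (kernel/stride pattern $(3,10)/(1,2)$, $(3,8)/(1,2)$,
  $(3,6)/(1,2)$, $(2,6)/(1,2)$) reduces to 27 values feeding a final
  linear + sigmoid layer.

The stage-2 game is binary cross-entropy: $D$ pushes featurised real clip
windows toward 1 and featurised generated clips toward 0; the plugin is
updated on fresh noise to fool it. Both networks use Adam with learning
rate $2\times 10^{-4}$, $\beta_1 = 0.5$, $\beta_2 = 0.999$, for 50 epochs.
Only plugin and video-critic parameters ever change — the trainer hashes
the backbone before and after and aborts if a single bit moved.

## Design choices where the architecture description was open

* **Three vs four layers.** The plugin is sometimes summarised as three
  fully connected layers, but the detailed layer listing has four `Linear`
  rows; the four-layer form is what the concatenation arithmetic supports,
  and it is what is implemented.
* **Shape of the shared noise.** The concatenation arithmetic
  ($2048 \to 1535$) only works if the time slot is the 2048th component,
  so $z$ has 2047 dimensions and is replicated across the frames of one
  clip.
* **Time encoding.** Frame index $t_i$ is mapped to $t_i/(n_{\rm ref}-1)$
  with $n_{\rm ref} = 8$ by default (`normalized_unit`), keeping the
  appended component on the same scale as the ReLU activations; raw
  integer indices are available by configuration. Nothing in the
  architecture fixes this scale.
* **Hypersphere radius.** Plain L2 normalisation to radius 1 with an
  $\varepsilon = 10^{-8}$ guard so the all-zero vector stays finite. Since
  the generator pixel-normalises its latent input anyway, any radius would
  decode identically when `use_pixelnorm = TRUE` — which is also why
  unit-norm plugin codes and raw Gaussian training noise live on the same
  effective sphere.
* **Critic head.** The frame critic runs convs down to $4\times4$, flattens,
  and applies `Linear -> LReLU -> Linear(F, 1)`. The feature width `F`
  (512 at reference scale) is therefore an explicit configuration knob,
  independent of the convolutional channel schedule, and
  `extract_features()` is literally "the critic without its last layer".
* **Generator loss form.** The printed minimax objective is the saturating
  form, but training uses BCE; the default is the non-saturating variant
  (maximise $\log D(\text{fake})$), with the saturating form selectable.
* **Longer clips vs an 8-frame discriminator.** Generated evaluation clips
  have 16 frames while the video critic's convolution arithmetic fixes an
  8-frame window; longer clips are scored on every contiguous window and
  averaged, and training samples random 8-frame windows from the real
  clips (one $D$ update then one plugin update per step, fresh $z$ per
  fake batch, training timeline fixed to $0..7$).

## Numerical choices

* **All networks, backpropagation and Adam are implemented in the package**
  on base-R arrays, with the convolution inner loop (im2col + BLAS matrix
  product) in compiled code. Every layer's gradient is verified against
  central finite differences in the test suite.
* **Gradient penalty, second derivative.** The penalty's parameter
  gradient needs $\partial_\theta \lVert\nabla_x f\rVert$ — a double
  backward. The input gradient $g = \nabla_x f(\hat x)$ is computed
  exactly by reverse mode; the $\theta$-derivative then uses the
  directional-derivative identity
  $\lVert g\rVert = \partial_e f(\hat x + e\,g/\lVert g\rVert)|_{e=0}$,
  differentiated through a symmetric finite difference with
  $e = 10^{-3}$. The critic is piecewise linear in its input
  (leaky-ReLU stack), so for small $e$ both probe points lie in the same
  linear region and the quotient is exact up to roundoff. The penalty
  *value* is always exact, and the closed forms (constant critic
  $\to \lambda$; linear critic with $\lVert w\rVert = 3$,
  $\lambda = 10 \to 40$) are asserted in the tests.
* **Fréchet distance.** $\lVert\mu_A-\mu_B\rVert^2 +
  \mathrm{Tr}(\Sigma_A+\Sigma_B-2(\Sigma_A\Sigma_B)^{1/2})$, with the
  matrix square root taken by eigendecomposition of the symmetrised
  product $\Sigma_A^{1/2}\Sigma_B\Sigma_A^{1/2}$ (same trace, numerically
  real), negative eigenvalues clipped at zero and the result clamped at
  zero. Covariances use the $N-1$ divisor. The Inception Score uses
  natural logarithms with $0\log 0 := 0$ and is reported as mean ± sd
  over splits.
* **Image convention.** Frames live in $[-1, 1]$ (matching the tanh output
  of the generator); PNG I/O maps linearly to 8-bit with round-half-even,
  so a write/read round trip is exact to one quantisation step (2/255).
  Frame files are zero-padded to five digits and clip folders sorted
  lexicographically, so ordering never depends on the filesystem.
* **Fade-in.** Images from consecutive phases are blended *after* the tanh,
  so at $\alpha = 0$ the grown network reproduces the upsampled previous
  phase exactly (asserted to machine precision) and the output range is
  preserved for every $\alpha$.

## The synthetic data and what it does (not) show

No external video data is downloaded. Two seeded generators provide the
study material:

* `moving_shapes`: two solid shapes translating at `motion_amplitude`
  pixels per frame over a static textured background, **reflecting** off
  the frame edges (wrapping would create the exact frame-to-frame
  discontinuities the coherence property forbids);
* `tunnel`: a fly-through of concentric rings receding toward a dark
  centre with radial wall texture and a slow drift of the tunnel axis —
  the temporal signature (steady forward motion, smoothly deforming
  radial structure) of endoscopic footage.

Both are pure functions of `(spec, n_clips, seed)`. Their defining
property, and the one the plugin is meant to learn, is temporal coherence:
`temporal_coherence_score()` compares adjacent-frame differences with
randomly paired distant frames and is below 1 for every generated clip,
while i.i.d. noise clips score ≈ 1 (identical frames score exactly 1 by
the 0/0 convention).

What passing on these fixtures does **not** show: anything about real
colonoscopy or action-recognition footage. The toy clips have no lighting
changes, occlusion, camera shake, specular highlights or tissue
deformation, and the built-in embedders (frame-critic features, seeded
random projections, and a seeded softmax head for the Inception Score) are
not a pretrained Inception or I3D network — absolute FVD/FID/IS numbers
from this package are on their own scale and only comparisons within one
embedder are meaningful. Features from external pretrained networks can be
brought in through the documented feature-file interface.

## Problem sizes

The test suite and the acceptance script run the full pipeline at a scale
chosen to exercise every phase of both training stages on a single CPU: 64
tunnel clips of 16 frames at 32 px, a backbone with latent width 16 and
channel rule `min(16, 128/resolution)`, feature width 512, 60 steps per
progressive phase, and the full 50-epoch stage 2 with 8 clips per batch.
The reference scale (512-wide latents, 2047-wide noise, 128 px and above)
is reachable through the same configuration surface but is not exercised
by the tests. Unit tests use an 8 px backbone.

## Known limitations

* The generator stays frozen in stage 2 by design; if stage 1 missed a
  mode, the plugin cannot recover it — quality is bounded by the backbone.
* The design motivation for the feature-space discriminator — that it can
  tell a real clip from the same frames in shuffled order — is an emergent
  property of the regime where generated frames are appearance-matched to
  real ones, so temporal order is the only remaining signal. At desk scale
  the briefly trained backbone produces clips that the discriminator can
  reject on per-frame appearance alone; it then saturates (real ≈ 0.98,
  fake ≈ 0.01) and its scores on ordered versus frame-shuffled real clips
  become statistically indistinguishable — and can even invert, because
  plugin trajectories are *smoother* in feature space than real clips, so
  "rougher" shuffled clips do not resemble the fakes either. Mid-training,
  before the discriminator saturates, the expected separation is clearly
  visible (ordered 0.763 vs shuffled 0.747 in a 15-epoch run). A
  GPU-trained, appearance-matched backbone is the precondition for the
  property at convergence.
* The video critic's window is fixed by its convolution arithmetic
  (8 frames at reference scale); longer-range temporal structure is only
  seen through window averaging.
* Training at 1024 px is configuration-reachable but untested here, and
  the CPU implementation is not intended for that scale.
* Checkpoints are R serialisations (RDS) with embedded format/version tags
  and parameter hashes; they are runtime artifacts, not an interchange
  format.
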