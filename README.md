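# plugingan

Memory-efficient video synthesis in R: a small time-conditioned "plugin"
network learns trajectories through the latent space of a frozen,
progressively grown 2-D frame GAN, so that videos are decoded frame by frame
from an image model that never sees a pixel volume. The package is aimed at
researchers prototyping generative video models for settings — such as
endoscopy simulation — where clips are long, resolution matters, and
training a 3-D convolutional video GAN end to end is out of reach.

## The method

Training happens in two stages.

**Stage 1 — frame backbone.** A progressive GAN (generator `G`, critic `f`)
is trained on individual frames with the WGAN-GP objective

    L_C = E[f(x_fake)] − E[f(x_real)] + λ E[(‖∇x f(x̂)‖ − 1)²] + ε_d E[f(x_real)²]

growing from 4 px to the target resolution with fade-in blending, batch size
8 up to 256 px and 4 above, λ = 10. After this stage both networks are
frozen.

**Stage 2 — trajectory plugin.** A plugin network φ maps one shared noise
vector z (2047-dimensional at reference scale) plus a frame index t through
four concatenate-then-linear layers (2048→1535, 1536→1023, 1024→511,
512→512; ReLU on the first three) to a unit-norm latent code. A clip is

    G(φ(T, z)) = [G(φ(t1, z)), …, G(φ(tn, z))].

The video discriminator D never sees pixels: each frame is embedded by the
frozen frame critic *minus its last layer* (512 features), the rows are
stacked into an 8×512 map, and a four-layer strided 2-D conv stack —
Conv(1,16,(3,10),(1,2)), Conv(16,8,(3,8),(1,2)), Conv(8,4,(3,6),(1,2)),
Conv(4,1,(2,6),(1,2)) — flattens to 27 values feeding a linear + sigmoid
layer. φ and D are trained adversarially with binary cross-entropy and Adam
(lr 2e-4, β₁ 0.5, β₂ 0.999) for 50 epochs; the backbone is hash-verified to
stay bit-identical.

Evaluation uses the Gaussian Fréchet distance
`‖μ_R−μ_G‖² + Tr(Σ_R + Σ_G − 2(Σ_R Σ_G)^{1/2})` as FID (on frames) and FVD
(on clips), plus the Inception Score, over pluggable embedders: the
backbone's own critic features, seeded random projections, or precomputed
feature files from external pretrained networks. All networks,
backpropagation (a small reverse-mode tape) and Adam are implemented in the
package, with the convolution inner loop in compiled code; no deep-learning
framework is required.

Synthetic, seeded video generators (moving shapes; a tunnel fly-through
emulating the temporal signature of colonoscopy footage) provide data, so
everything runs offline.

## Worked example

A complete two-stage run at miniature scale (16 px, a few seconds of CPU):

```r
library(plugingan)

spec  <- scene_spec("tunnel", resolution = 16, n_frames = 16, channels = 1)
clips <- generate_tunnel(spec, 16, seed = 1)
temporal_coherence_score(clips[[1]])   # 0.51 — adjacent frames are alike

cfg <- frame_gan_config(latent_dim = 8, max_resolution = 16, img_channels = 1,
                        fmap_base = 64, fmap_max = 8, feature_dim = 128,
                        steps_per_phase = 20)
backbone <- train_frame_gan(as_frame_dataset(clips), cfg, seed = 1)
fit <- train_stage2(clips, backbone,
                    stage2_config(epochs = 5, batch_clips = 4, seed = 1),
                    plugin_cfg = plugin_config(z_dim = 31,
                                               layer_widths = c(15, 15, 7, 8),
                                               out_dim = 8))
fit
#> Latent-trajectory video GAN (frozen backbone + plugin + video critic)
#>   backbone:    16px, latent 8, features 128
#>   plugin:      z_dim 31, widths 15-15-7-8
#>   video critic: flatten 3 -> 1, window 8 frames
#>   trained 5 epochs (20 steps); final D loss 1.062, plugin loss 0.6804

evaluation_protocol(fit, clips, n_clips = 16, clip_len = 16,
                    n_splits = 5, seed = 1)
#> Evaluation report (16 clips x 16 frames, 5 splits, embedder `frame_critic_features`)
#>   FVD:      6.6852
#>   FID:      7.2553 (+/- 0.3810)
#>   IS fake:  1.3720 (+/- 0.0246)
#>   IS real:  1.3682 (+/- 0.0129)
```

The D/plugin losses near `2·log 2 ≈ 1.386` and `log 2 ≈ 0.693` say the
adversarial game is in balance; FVD/FID here are on the scale of the
built-in critic-feature embedder (only comparisons within one embedder are
meaningful). `generate_video(fit$plugin, fit$backbone$generator, z, 0:15)`
decodes a clip of any length from one noise vector, and
`write_frame_dir()` / `read_frame_dir()` round-trip clips as PNG frame
directories with a JSON manifest.

The same pipeline is scriptable from a shell (`exec/plugingan`):

```sh
plugingan make-data    --kind tunnel --resolution 32 --clips 64 --frames 16 --seed 0 --out data
plugingan train-frames --data data --out run1 --seed 0
plugingan train-video  --data data --backbone run1/backbone.rds --out run2 --seed 0
plugingan generate     --checkpoint run2/stage2.rds --clips 8 --frames 16 --seed 1 --out gen
plugingan evaluate     --checkpoint run2/stage2.rds --data data --out report.json
```

Every command writes its resolved YAML configuration and seed next to its
outputs; identical seeds reproduce artifacts bit for bit.

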