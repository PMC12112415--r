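# Shared tiny fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fx <- function(name, build) {
  if (is.null(.fixtures[[name]])) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# an 8 px grayscale backbone config small enough for sub-second training
tiny_gan_cfg <- function(feature_dim = 32L, steps_per_phase = 3L) {
  frame_gan_config(latent_dim = 8L, max_resolution = 8L, img_channels = 1L,
                   feature_dim = feature_dim,
                   channels_schedule = c("4" = 6L, "8" = 4L),
                   steps_per_phase = steps_per_phase)
}

tiny_clips <- function() {
  fx("tiny_clips", function() {
    spec <- scene_spec("tunnel", resolution = 8L, n_frames = 12L,
                       motion_amplitude = 1, channels = 1L)
    generate_tunnel(spec, 6L, seed = 11L)
  })
}

# a briefly trained tiny backbone shared across stage-2/metrics unit tests;
# feature_dim 96 is the narrowest width the reference video-critic conv stack
# accepts
tiny_backbone <- function() {
  fx("tiny_backbone", function() {
    ds <- as_frame_dataset(tiny_clips())
    cfg <- tiny_gan_cfg(feature_dim = 96L, steps_per_phase = 4L)
    train_frame_gan(ds, cfg, seed = 5L)
  })
}

# a small custom video-critic config valid for (n_frames = 4, feature_dim = 32)
tiny_vc_cfg <- function(n_frames = 4L, feature_dim = 32L) {
  video_critic_config(conv_layers = list(
    list(in_ch = 1L, out_ch = 4L, kernel = c(3L, 5L), stride = c(1L, 2L)),
    list(in_ch = 4L, out_ch = 2L, kernel = c(2L, 3L), stride = c(1L, 2L))),
    n_frames = n_frames, feature_dim = feature_dim)
}

# central finite-difference gradient of f with respect to params[[nm]][i]
num_grad <- function(f, params, nm, i, h = 1e-6) {
  p <- params
  p[[nm]][i] <- p[[nm]][i] + h
  fp <- f(p)
  p[[nm]][i] <- p[[nm]][i] - 2 * h
  fm <- f(p)
  (fp - fm) / (2 * h)
}

rel_err <- function(a, b) abs(a - b) / pmax(1e-7, abs(a))
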