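# Stage-2 adversarial training: real-window sampling, BCE step mechanics,
# backbone freezing, and seeded reproducibility.

test_that("real-window sampling covers all offsets and validates lengths", {
  clip16 <- video_clip(array(tanh(rnorm(16 * 8 * 8)), c(16L, 8L, 8L, 1L)), "a")
  # a video of exactly n_frames always yields the full clip
  exact <- video_clip(clip16$frames[1:8, , , , drop = FALSE], "b")
  batch <- sample_real_clip_batch(list(exact), 8L, 5L, rng = 1L)
  for (w in batch) expect_identical(w$frames, exact$frames)
  # reproducible composition
  b1 <- sample_real_clip_batch(list(clip16, exact), 8L, 6L, rng = 3L)
  b2 <- sample_real_clip_batch(list(clip16, exact), 8L, 6L, rng = 3L)
  expect_identical(b1, b2)
  # all 9 start offsets of a 16-frame video occur over many draws
  many <- sample_real_clip_batch(list(clip16), 8L, 400L, rng = 9L)
  starts <- vapply(many, function(w) w$frame_origin, 0L)
  expect_setequal(sort(unique(starts)), 0:8)
  # short videos are named in the error
  short <- video_clip(array(0, c(4L, 8L, 8L, 1L)), "too_short")
  expect_error(sample_real_clip_batch(list(clip16, short), 8L, 2L, 1L),
               "too_short")
})

test_that("a stage-2 step leaves the backbone bit-identical and returns
           finite nonnegative BCE losses", {
  bb <- tiny_backbone()
  gen <- plugingan:::freeze_state(bb$generator)
  fc <- plugingan:::freeze_state(bb$critic)
  gh <- plugingan:::param_hash(gen$params)
  ch <- plugingan:::param_hash(fc$params)
  cfg <- stage2_config(epochs = 1L, batch_clips = 3L, n_frames = 8L)
  pl <- build_plugin(plugingan:::default_plugin_config(8L), seed = 1L)
  vc <- build_video_critic(video_critic_config(n_frames = 8L,
                                               feature_dim = 96L), seed = 2L)
  batch <- sample_real_clip_batch(tiny_clips(), 8L, 3L, rng = 4L)
  st <- stage2_step(pl, vc, gen, fc, batch, cfg, rng = 5L)
  expect_identical(plugingan:::param_hash(gen$params), gh)
  expect_identical(plugingan:::param_hash(fc$params), ch)
  expect_true(is.finite(st$loss_D) && st$loss_D >= 0)
  expect_true(is.finite(st$loss_plugin) && st$loss_plugin >= 0)
  expect_true(st$mean_score_real > 0 && st$mean_score_real < 1)
  # parameters actually moved
  expect_false(identical(st$plugin$params, pl$params))
  expect_false(identical(st$vc$params, vc$params))
  # unfrozen backbone is rejected
  expect_error(stage2_step(pl, vc, bb$generator, fc, batch, cfg, 5L),
               "frozen")
})

test_that("a critic at probability one-half yields loss_D = 2 log 2", {
  bb <- tiny_backbone()
  gen <- plugingan:::freeze_state(bb$generator)
  fc <- plugingan:::freeze_state(bb$critic)
  cfg <- stage2_config(epochs = 1L, batch_clips = 2L, n_frames = 8L)
  pl <- build_plugin(plugingan:::default_plugin_config(8L), seed = 1L)
  vc <- build_video_critic(video_critic_config(n_frames = 8L,
                                               feature_dim = 96L), seed = 2L)
  # zero the final layer: the logit is exactly 0, the probability exactly 1/2
  vc$params[["out.W"]][] <- 0
  vc$params[["out.b"]][] <- 0
  batch <- sample_real_clip_batch(tiny_clips(), 8L, 2L, rng = 6L)
  st <- stage2_step(pl, vc, gen, fc, batch, cfg, rng = 7L)
  expect_equal(st$loss_D, 2 * log(2), tolerance = 1e-12)
  expect_equal(st$mean_score_real, 0.5, tolerance = 1e-12)
  expect_equal(st$mean_score_fake, 0.5, tolerance = 1e-12)
})

test_that("saturating and non-saturating plugin losses move parameters
           in valid directions", {
  bb <- tiny_backbone()
  gen <- plugingan:::freeze_state(bb$generator)
  fc <- plugingan:::freeze_state(bb$critic)
  pl <- build_plugin(plugingan:::default_plugin_config(8L), seed = 1L)
  vc <- build_video_critic(video_critic_config(n_frames = 8L,
                                               feature_dim = 96L), seed = 2L)
  batch <- sample_real_clip_batch(tiny_clips(), 8L, 2L, rng = 6L)
  for (form in c("non_saturating", "saturating")) {
    cfg <- stage2_config(epochs = 1L, batch_clips = 2L, n_frames = 8L,
                         generator_loss_form = form)
    st <- stage2_step(pl, vc, gen, fc, batch, cfg, rng = 7L)
    expect_true(is.finite(st$loss_plugin))
    expect_false(identical(st$plugin$params, pl$params))
  }
})

test_that("full stage-2 training is reproducible and isolates the backbone", {
  bb <- tiny_backbone()
  cfg <- stage2_config(epochs = 2L, batch_clips = 2L, n_frames = 8L, seed = 13L)
  f1 <- train_stage2(tiny_clips(), bb, cfg)
  f2 <- train_stage2(tiny_clips(), bb, cfg)
  expect_identical(f1$plugin$params, f2$plugin$params)
  expect_identical(f1$video_critic$params, f2$video_critic$params)
  expect_identical(f1$backbone_hashes$generator,
                   plugingan:::param_hash(bb$generator$params))
  expect_true(all(is.finite(as.matrix(f1$history[, -(1:2)]))))
  expect_identical(nrow(f1$history),
                   2L * max(1L, length(tiny_clips()) %/% 2L))
  # different seed, different outcome
  f3 <- train_stage2(tiny_clips(), bb,
                     stage2_config(epochs = 2L, batch_clips = 2L,
                                   n_frames = 8L, seed = 14L))
  expect_false(identical(f1$plugin$params, f3$plugin$params))
})

test_that("stage-2 checkpoints round-trip and regenerate identical clips", {
  bb <- tiny_backbone()
  fit <- train_stage2(tiny_clips(), bb,
                      stage2_config(epochs = 1L, batch_clips = 2L,
                                    n_frames = 8L, seed = 21L))
  path <- withr::local_tempfile(fileext = ".rds")
  write_stage2_checkpoint(fit, path)
  back <- read_stage2_checkpoint(path)
  c1 <- generate_clips_from_fit(fit, 2L, clip_len = 10L, seed = 3L)
  c2 <- generate_clips_from_fit(back, 2L, clip_len = 10L, seed = 3L)
  expect_identical(c1, c2)
  expect_identical(dim(c1[[1L]]$frames)[1], 10L)
  expect_error(read_stage2_checkpoint(tempfile()), "not found")
})

test_that("configuration mismatches are caught before training", {
  bb <- tiny_backbone()
  expect_error(
    train_stage2(tiny_clips(), bb,
                 stage2_config(epochs = 1L, n_frames = 8L),
                 plugin_cfg = plugin_config(z_dim = 15L,
                                            layer_widths = c(11L, 9L, 15L, 16L),
                                            out_dim = 16L)),
    "latent_dim")
  expect_error(
    train_stage2(tiny_clips(), bb,
                 stage2_config(epochs = 1L, n_frames = 8L),
                 vc_cfg = video_critic_config(n_frames = 8L,
                                              feature_dim = 512L)),
    "feature_dim")
  expect_error(train_stage2(tiny_clips(), "no/such/checkpoint.rds",
                            stage2_config()), "not found")
})
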