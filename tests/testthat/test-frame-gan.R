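# Progressive frame GAN: builders, fade-in arithmetic, WGAN-GP closed forms,
# feature extraction, and the stage-1 training loop.

test_that("generator and critic honour their shape contracts", {
  cfg <- frame_gan_config(latent_dim = 64L, max_resolution = 32L,
                          img_channels = 3L, feature_dim = 48L,
                          channels_schedule = c("4" = 8L, "8" = 8L,
                                                "16" = 6L, "32" = 4L))
  gen <- build_frame_generator(cfg, seed = 1L)
  img <- generate_frames(gen, matrix(rnorm(5 * 64), 5L),
                         resolution = 32L, alpha = 1)
  expect_identical(dim(img), c(5L, 32L, 32L, 3L))
  expect_true(all(abs(img) <= 1))

  critic <- build_frame_critic(cfg, seed = 2L)
  critic$resolution <- 32L
  s <- critic_scores(critic, img)
  expect_length(s, 5L)
  expect_true(all(is.finite(s)))

  expect_error(frame_gan_config(max_resolution = 48L), "power of two")
  expect_error(gen_forward(gen, matrix(0, 1L, 3L)), "latent")
})

test_that("fade-in with alpha = 0 reproduces the upsampled previous phase", {
  cfg <- tiny_gan_cfg()
  gen <- build_frame_generator(cfg, seed = 3L)
  z <- matrix(rnorm(4L * cfg$latent_dim), 4L)
  lo <- generate_frames(gen, z, resolution = 4L, alpha = 1)
  hi0 <- generate_frames(gen, z, resolution = 8L, alpha = 0)
  up <- lo[, rep(1:4, each = 2L), rep(1:4, each = 2L), , drop = FALSE]
  expect_equal(hi0, up, tolerance = 1e-12)
  # and the blend is continuous: small alpha stays near the upsampled output
  hi_eps <- generate_frames(gen, z, resolution = 8L, alpha = 1e-3)
  expect_lt(max(abs(hi_eps - up)), 0.01)

  critic <- build_frame_critic(cfg, seed = 4L)
  img <- generate_frames(gen, z, resolution = 8L, alpha = 1)
  s8_a0 <- plugingan:::critic_forward(critic, img, resolution = 8L, alpha = 0,
                                      track_params = FALSE)
  down <- (img[, seq(1, 8, 2), seq(1, 8, 2), , drop = FALSE] +
           img[, seq(2, 8, 2), seq(1, 8, 2), , drop = FALSE] +
           img[, seq(1, 8, 2), seq(2, 8, 2), , drop = FALSE] +
           img[, seq(2, 8, 2), seq(2, 8, 2), , drop = FALSE]) / 4
  s4 <- plugingan:::critic_forward(critic, down, resolution = 4L, alpha = 1,
                                   track_params = FALSE)
  expect_equal(plugingan:::tp_value(s8_a0$tape, s8_a0$score),
               plugingan:::tp_value(s4$tape, s4$score), tolerance = 1e-12)
})

test_that("gradient penalty takes its closed-form values", {
  set.seed(10)
  r <- array(rnorm(4 * 8 * 8), c(4L, 8L, 8L, 1L))
  f <- array(rnorm(4 * 8 * 8), c(4L, 8L, 8L, 1L))
  const_critic <- list(value = function(x) rep(2.5, dim(x)[1]),
                       grad = function(x) array(0, dim(x)))
  wl <- wgan_gp_losses(const_critic, r, f, gp_lambda = 10, seed = 1L)
  expect_equal(wl$penalty, 10, tolerance = 1e-10)
  expect_equal(wl$critic_loss, 10, tolerance = 1e-10)  # means cancel
  expect_equal(wl$generator_loss, -2.5, tolerance = 1e-10)

  w <- rnorm(64); w <- 3 * w / sqrt(sum(w^2))
  lin <- list(value = function(x) as.numeric(matrix(x, dim(x)[1], 64L) %*% w),
              grad = function(x) {
                g <- matrix(w, dim(x)[1], 64L, byrow = TRUE)
                dim(g) <- dim(x); g
              })
  expect_equal(wgan_gp_losses(lin, r, f, 10, 1L)$penalty, 10 * (3 - 1)^2,
               tolerance = 1e-10)
  expect_identical(wgan_gp_losses(lin, r, f, 0, 1L)$penalty, 0)

  # finite-difference oracle for the gradient norm of a real critic
  cfg <- tiny_gan_cfg()
  critic <- build_frame_critic(cfg, seed = 6L)
  critic$resolution <- 8L
  xhat <- r[1L, , , , drop = FALSE]
  g <- plugingan:::critic_input_grad_of(critic, xhat)
  h <- 1e-5
  idx <- seq_len(6L)
  gnum <- vapply(idx, function(i) {
    xp <- xhat; xp[i] <- xp[i] + h
    xm <- xhat; xm[i] <- xm[i] - h
    (critic_scores(critic, xp) - critic_scores(critic, xm)) / (2 * h)
  }, 0)
  expect_lt(max(rel_err(gnum, g[idx])), 1e-4)

  expect_error(wgan_gp_losses(lin, r, f[1:2, , , , drop = FALSE], 10, 1L),
               "shape")
})

test_that("stage-1 training is deterministic with finite losses and the
           configured batch schedule", {
  clips <- tiny_clips()
  ds <- as_frame_dataset(clips)
  cfg <- tiny_gan_cfg(steps_per_phase = 4L)
  fit1 <- train_frame_gan(ds, cfg, seed = 3L)
  expect_s3_class(fit1, "frame_gan")
  expect_true(all(is.finite(fit1$history$loss_critic)))
  expect_true(all(is.finite(fit1$history$loss_gen)))
  expect_identical(nrow(fit1$history), 8L)
  # the default schedule trains with batch 8 at resolutions <= 256 px (here
  # capped by the 6-frame x 12 dataset, uncapped batch is 8)
  expect_true(all(fit1$history$batch_size ==
                    pmin(8L, dim(ds$images)[1])))
  expect_identical(unname(cfg$batch_schedule[["8"]]), 8L)

  fit2 <- train_frame_gan(ds, cfg, seed = 3L)
  expect_identical(fit1$generator$params, fit2$generator$params)
  expect_identical(fit1$critic$params, fit2$critic$params)
  expect_false(identical(
    fit1$generator$params,
    train_frame_gan(ds, cfg, seed = 4L)$generator$params))

  expect_error(train_frame_gan(ds, frame_gan_config(max_resolution = 16L),
                               seed = 1L), "max_resolution")
})

test_that("reference batch schedule is 8 up to 256 px and 4 above", {
  cfg <- frame_gan_config(max_resolution = 1024L)
  bs <- cfg$batch_schedule
  expect_true(all(bs[as.integer(names(bs)) <= 256L] == 8L))
  expect_true(all(bs[as.integer(names(bs)) > 256L] == 4L))
})

test_that("extract_features returns the final layer's input activations", {
  cfg <- tiny_gan_cfg(feature_dim = 24L)
  critic <- build_frame_critic(cfg, seed = 8L)
  critic$resolution <- 8L
  imgs <- array(tanh(rnorm(3 * 64)), c(3L, 8L, 8L, 1L))
  fe <- extract_features(critic, imgs)
  expect_identical(dim(fe), c(3L, 24L))
  # introspection oracle: feature width equals the final layer's input width
  expect_identical(ncol(fe), nrow(critic$params[["d4.out.W"]]))
  # and scores are exactly the final linear layer applied to the features
  manual <- fe %*% (critic$params[["d4.out.W"]] * critic$scales[["d4.out"]]) +
    critic$params[["d4.out.b"]]
  expect_equal(as.numeric(manual), critic_scores(critic, imgs),
               tolerance = 1e-12)
  expect_error(extract_features(critic, array(0, c(2L, 4L, 4L, 1L))), "shape")
})

test_that("backbone checkpoints round-trip and detect corruption", {
  fit <- tiny_backbone()
  path <- withr::local_tempfile(fileext = ".rds")
  write_backbone_checkpoint(fit, path)
  back <- read_backbone_checkpoint(path)
  expect_identical(back$generator$params, fit$generator$params)
  obj <- readRDS(path)
  obj$fit$generator$params[[1]][1] <- obj$fit$generator$params[[1]][1] + 1
  saveRDS(obj, path)
  expect_error(read_backbone_checkpoint(path), "integrity")
  expect_error(read_backbone_checkpoint(tempfile()), "not found")
})
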