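# Stage 2: adversarial training of the trajectory plugin and the video
# discriminator against a frozen stage-1 backbone.
#
# Per step: (1) the video discriminator is updated by binary cross-entropy to
# score featurised real clip windows toward 1 and featurised generated clips
# toward 0; (2) with fresh noise, the plugin is updated to fool it (default:
# the non-saturating form, pushing D(fake) toward 1). Gradients for the
# plugin pass through the frozen generator and frame critic, whose
# parameters never change.

#' Stage-2 training configuration
#'
#' Defaults follow the adversarial fine-tuning recipe the architecture was
#' designed around: Adam with learning rate 2e-4, beta1 = 0.5, beta2 = 0.999,
#' binary cross-entropy, 50 epochs, 8-frame training windows.
#'
#' @param learning_rate,beta1,beta2 Adam hyperparameters (both networks).
#' @param epochs number of passes over the real clips (>= 1).
#' @param batch_clips clips per optimisation step.
#' @param n_frames temporal window; must match the video critic.
#' @param generator_loss_form `"non_saturating"` (default; maximise
#'   `log D(fake)`) or `"saturating"` (minimise `log(1 - D(fake))`, the
#'   literal minimax form).
#' @param seed integer seed for the whole stage-2 run.
#' @return an object of class `stage2_config`.
#' @export
stage2_config <- function(learning_rate = 2e-4, beta1 = 0.5, beta2 = 0.999,
                          epochs = 50L, batch_clips = 8L, n_frames = 8L,
                          generator_loss_form = c("non_saturating", "saturating"),
                          seed = 1L) {
  generator_loss_form <- match.arg(generator_loss_form)
  if (learning_rate <= 0) stop_config("learning_rate must be > 0")
  if (epochs < 1) stop_config("epochs must be >= 1")
  if (batch_clips < 1) stop_config("batch_clips must be >= 1")
  if (n_frames < 1) stop_config("n_frames must be >= 1")
  structure(list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 epochs = as.integer(epochs),
                 batch_clips = as.integer(batch_clips),
                 n_frames = as.integer(n_frames),
                 generator_loss_form = generator_loss_form,
                 seed = as.integer(seed)),
            class = "stage2_config")
}

#' Sample a batch of contiguous real clip windows
#'
#' Each sample is an `n_frames`-long contiguous window starting at a
#' uniformly random offset of a uniformly random source video.
#'
#' @param videos list of [video_clip()] objects, each with at least
#'   `n_frames` frames.
#' @param n_frames window length.
#' @param batch_clips number of windows to draw.
#' @param rng integer seed for the draw.
#' @return list of `batch_clips` [video_clip()] windows.
#' @export
sample_real_clip_batch <- function(videos, n_frames, batch_clips, rng) {
  lens <- vapply(videos, function(v) dim(v$frames)[1], 0L)
  short <- which(lens < n_frames)
  if (length(short)) {
    stop_input("videos shorter than n_frames = ", n_frames, ": ",
               paste(vapply(videos[short], function(v) v$clip_id, ""),
                     collapse = ", "))
  }
  with_seed(rng, {
    vi <- sample.int(length(videos), batch_clips, replace = TRUE)
    lapply(seq_len(batch_clips), function(k) {
      v <- videos[[vi[k]]]
      start <- sample.int(lens[vi[k]] - n_frames + 1L, 1L)
      video_clip(v$frames[start:(start + n_frames - 1L), , , , drop = FALSE],
                 clip_id = v$clip_id,
                 frame_origin = v$frame_origin + start - 1L)
    })
  })
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))

# stack clip windows into a (B*n, H, W, C) frame array ordered frame-major
# (row = b + B*(t-1)) so that reshaping feature matrices to (B, n, F) is a
# plain column-major reshape
stack_windows <- function(windows) {
  B <- length(windows)
  d <- dim(windows[[1]]$frames)
  out <- array(0, c(B * d[1], d[2], d[3], d[4]))
  for (b in seq_len(B)) {
    out[b + B * (seq_len(d[1]) - 1L), , , ] <- windows[[b]]$frames
  }
  out
}

# featurise a frame-major (B*n,H,W,C) array into (B, n, F)
featurize_frames_batch <- function(frame_critic, frames, B, n) {
  feats <- extract_features(frame_critic, frames)
  array(feats, c(B, n, ncol(feats)))
}

# build the fake branch on one tape: noise -> plugin -> generator -> frame
# critic features -> video critic logit. Returns list(tape, logit, prob).
fake_branch_tape <- function(plugin, vc, generator, frame_critic, Z, Tn,
                             track_plugin, track_vc) {
  cfg <- plugin$config
  B <- nrow(Z); n <- length(Tn)
  zmat <- Z[rep(seq_len(B), n), , drop = FALSE]      # row = b + B*(t-1)
  tvec <- rep(encode_time(cfg, Tn), each = B)
  pf <- plugin_forward_tape(plugin, zmat, tvec, track_params = track_plugin)
  gf <- gen_forward(generator, pf$out, tape = pf$tape, track_params = FALSE)
  cf <- critic_forward(frame_critic, gf$out, tape = gf$tape,
                       track_params = FALSE)
  F <- ncol(tp_value(cf$tape, cf$features))
  fm <- tp_reshape(cf$tape, cf$features, c(B, n, F))
  video_critic_forward_tape(vc, fm, tape = cf$tape, track_params = track_vc)
}

# value-only fake feature maps (for discriminator updates, where no gradient
# flows back through the frozen backbone)
fake_fmaps_value <- function(plugin, generator, frame_critic, Z, Tn) {
  cfg <- plugin$config
  B <- nrow(Z); n <- length(Tn)
  zmat <- Z[rep(seq_len(B), n), , drop = FALSE]
  tvec <- rep(encode_time(cfg, Tn), each = B)
  pf <- plugin_forward_tape(plugin, zmat, tvec, track_params = FALSE)
  traj <- tp_value(pf$tape, pf$out)
  frames <- generate_frames(generator, traj)
  featurize_frames_batch(frame_critic, frames, B, n)
}

#' One stage-2 adversarial step
#'
#' Performs a discriminator update (BCE: real windows toward 1, generated
#' clips toward 0) followed by a plugin update on fresh noise (default
#' non-saturating BCE toward 1). Only the plugin and video critic change;
#' the backbone must be frozen.
#'
#' @param plugin a `plugin_net`.
#' @param vc a `video_critic`.
#' @param generator frozen, trained `frame_generator`.
#' @param frame_critic frozen `frame_critic`.
#' @param real_batch list of [video_clip()] windows of length
#'   `config$n_frames`.
#' @param config a [stage2_config()].
#' @param rng integer seed for this step's noise.
#' @param opt optimiser bundle from a previous step, or `NULL` to start one.
#' @return list with updated `plugin`, `vc`, `opt`, and scalars `loss_D`,
#'   `loss_plugin`, `mean_score_real`, `mean_score_fake`.
#' @export
stage2_step <- function(plugin, vc, generator, frame_critic, real_batch,
                        config, rng, opt = NULL) {
  if (!isTRUE(generator$frozen) || !isTRUE(frame_critic$frozen)) {
    stop_config("stage 2 requires a frozen backbone (generator and frame critic)")
  }
  B <- length(real_batch)
  n <- config$n_frames
  if (any(vapply(real_batch, function(w) dim(w$frames)[1], 0L) != n)) {
    stop_input("every real window must have exactly n_frames = ", n, " frames")
  }
  if (is.null(opt)) {
    opt <- list(plugin = adam_init(plugin$params), vc = adam_init(vc$params))
  }
  Tn <- seq_len(n) - 1L
  with_seed(rng, {
    # --- discriminator update ---
    real_frames <- stack_windows(real_batch)
    fm_real <- featurize_frames_batch(frame_critic, real_frames, B, n)
    fwr <- video_critic_forward_tape(vc, fm_real, track_params = TRUE)
    sr <- as.numeric(tp_value(fwr$tape, fwr$logit))
    pr <- as.numeric(tp_value(fwr$tape, fwr$prob))
    bwr <- tp_backward(fwr$tape, fwr$logit, matrix((pr - 1) / B, B, 1L))
    Zd <- matrix(stats::rnorm(B * plugin$config$z_dim), B)
    fm_fake <- fake_fmaps_value(plugin, generator, frame_critic, Zd, Tn)
    fwf <- video_critic_forward_tape(vc, fm_fake, track_params = TRUE)
    sf <- as.numeric(tp_value(fwf$tape, fwf$logit))
    pf <- as.numeric(tp_value(fwf$tape, fwf$prob))
    bwf <- tp_backward(fwf$tape, fwf$logit, matrix(pf / B, B, 1L))
    upd <- adam_step(vc$params, grad_add(bwr$params, bwf$params), opt$vc,
                     config$learning_rate, config$beta1, config$beta2)
    vc$params <- upd$params; opt$vc <- upd$state
    loss_D <- mean(softplus(-sr)) + mean(softplus(sf))
    # --- plugin update (fresh fakes) ---
    Zg <- matrix(stats::rnorm(B * plugin$config$z_dim), B)
    fwg <- fake_branch_tape(plugin, vc, generator, frame_critic, Zg, Tn,
                            track_plugin = TRUE, track_vc = FALSE)
    sg <- as.numeric(tp_value(fwg$tape, fwg$logit))
    pg <- as.numeric(tp_value(fwg$tape, fwg$prob))
    if (config$generator_loss_form == "non_saturating") {
      loss_P <- mean(softplus(-sg))
      dlogit <- matrix((pg - 1) / B, B, 1L)
    } else {
      loss_P <- mean(log1p(-pmin(pg, 1 - 1e-12)))
      dlogit <- matrix(-pg / B, B, 1L)
    }
    bwg <- tp_backward(fwg$tape, fwg$logit, dlogit)
    upd <- adam_step(plugin$params, bwg$params, opt$plugin,
                     config$learning_rate, config$beta1, config$beta2)
    plugin$params <- upd$params; opt$plugin <- upd$state
    list(plugin = plugin, vc = vc, opt = opt,
         loss_D = loss_D, loss_plugin = loss_P,
         mean_score_real = mean(pr), mean_score_fake = mean(pf))
  })
}

#' Train the plugin and video discriminator against a frozen backbone
#'
#' Runs `epochs` passes over the real clips (each epoch visits
#' `floor(n_clips / batch_clips)` batches, at least one), verifying before
#' and after that the backbone parameters are bit-identical.
#'
#' @param videos list of [video_clip()] objects at the backbone's resolution,
#'   each at least `n_frames` long.
#' @param backbone a `frame_gan` object or the path of a backbone checkpoint.
#' @param config a [stage2_config()].
#' @param plugin_cfg optional [plugin_config()]; defaults to a four-layer
#'   plugin sized to the backbone's latent width.
#' @param vc_cfg optional [video_critic_config()]; defaults to the reference
#'   conv stack over `(n_frames, feature_dim)`.
#' @return an object of class `plugin_gan_fit` with elements `plugin`,
#'   `video_critic`, `backbone`, `config`, `history`, `backbone_hashes`.
#' @export
train_stage2 <- function(videos, backbone, config = stage2_config(),
                         plugin_cfg = NULL, vc_cfg = NULL) {
  if (is.character(backbone)) backbone <- read_backbone_checkpoint(backbone)
  if (!inherits(backbone, "frame_gan")) {
    stop_config("backbone must be a frame_gan object or checkpoint path")
  }
  if (!isTRUE(backbone$generator$trained)) {
    stop_config("backbone generator is not trained")
  }
  generator <- freeze_state(backbone$generator)
  frame_critic <- freeze_state(backbone$critic)
  hash_before <- list(generator = param_hash(generator$params),
                      critic = param_hash(frame_critic$params))
  if (is.null(plugin_cfg)) {
    plugin_cfg <- default_plugin_config(backbone$config$latent_dim,
                                        n_ref = config$n_frames)
  }
  if (plugin_cfg$out_dim != backbone$config$latent_dim) {
    stop_config("plugin out_dim (", plugin_cfg$out_dim,
                ") must equal backbone latent_dim (",
                backbone$config$latent_dim, ")")
  }
  if (is.null(vc_cfg)) {
    vc_cfg <- video_critic_config(n_frames = config$n_frames,
                                  feature_dim = backbone$config$feature_dim)
  }
  if (vc_cfg$n_frames != config$n_frames) {
    stop_config("video critic n_frames (", vc_cfg$n_frames,
                ") must equal stage-2 n_frames (", config$n_frames, ")")
  }
  if (vc_cfg$feature_dim != backbone$config$feature_dim) {
    stop_config("video critic feature_dim (", vc_cfg$feature_dim,
                ") must equal backbone feature_dim (",
                backbone$config$feature_dim, ")")
  }
  plugin <- build_plugin(plugin_cfg, seed = derive_seed(config$seed, 11L))
  vc <- build_video_critic(vc_cfg, seed = derive_seed(config$seed, 12L))
  opt <- NULL
  steps_per_epoch <- max(1L, length(videos) %/% config$batch_clips)
  hist <- vector("list", config$epochs * steps_per_epoch)
  k <- 0L
  for (epoch in seq_len(config$epochs)) {
    for (step in seq_len(steps_per_epoch)) {
      k <- k + 1L
      batch <- sample_real_clip_batch(videos, config$n_frames,
                                      config$batch_clips,
                                      rng = derive_seed(config$seed, 100L + k))
      st <- stage2_step(plugin, vc, generator, frame_critic, batch, config,
                        rng = derive_seed(config$seed, 100000L + k), opt = opt)
      plugin <- st$plugin; vc <- st$vc; opt <- st$opt
      if (!is.finite(st$loss_D) || !is.finite(st$loss_plugin)) {
        stop("non-finite stage-2 loss at epoch ", epoch, " step ", step,
             ": loss_D=", st$loss_D, " loss_plugin=", st$loss_plugin)
      }
      hist[[k]] <- data.frame(epoch = epoch, step = step,
                              loss_D = st$loss_D,
                              loss_plugin = st$loss_plugin,
                              mean_score_real = st$mean_score_real,
                              mean_score_fake = st$mean_score_fake)
    }
  }
  hash_after <- list(generator = param_hash(generator$params),
                     critic = param_hash(frame_critic$params))
  if (!identical(hash_before, hash_after)) {
    stop("backbone parameters changed during stage-2 training; freezing contract violated")
  }
  plugin$trained <- TRUE
  structure(list(plugin = plugin, video_critic = vc, backbone = backbone,
                 config = config, plugin_config = plugin_cfg,
                 video_critic_config = vc_cfg,
                 history = do.call(rbind, hist),
                 backbone_hashes = hash_before),
            class = "plugin_gan_fit")
}

# plugin sized to a backbone latent width: keeps the reference pattern of
# hidden widths one below a power of two (so width+1 after the time concat is
# a power of two), scaled down with the latent dimension
default_plugin_config <- function(latent_dim, n_ref = 8L) {
  if (latent_dim >= 512L) {
    plugin_config(out_dim = latent_dim,
                  layer_widths = c(3L * latent_dim - 1L, 2L * latent_dim - 1L,
                                   latent_dim - 1L, latent_dim),
                  z_dim = 4L * latent_dim - 1L, n_ref = n_ref)
  } else {
    plugin_config(z_dim = 4L * latent_dim - 1L,
                  layer_widths = c(2L * latent_dim - 1L, latent_dim - 1L,
                                   latent_dim - 1L, latent_dim),
                  out_dim = latent_dim, n_ref = n_ref)
  }
}

#' @export
print.plugin_gan_fit <- function(x, ...) {
  cat("Latent-trajectory video GAN (frozen backbone + plugin + video critic)\n")
  cat("  backbone:    ", x$backbone$config$max_resolution, "px, latent ",
      x$backbone$config$latent_dim, ", features ",
      x$backbone$config$feature_dim, "\n", sep = "")
  cat("  plugin:      z_dim ", x$plugin_config$z_dim, ", widths ",
      paste(x$plugin_config$layer_widths, collapse = "-"), "\n", sep = "")
  cat("  video critic: flatten ", x$video_critic$flatten_dim,
      " -> 1, window ", x$video_critic_config$n_frames, " frames\n", sep = "")
  h <- x$history
  cat("  trained ", max(h$epoch), " epochs (", nrow(h), " steps); final D loss ",
      signif(utils::tail(h$loss_D, 1), 4), ", plugin loss ",
      signif(utils::tail(h$loss_plugin, 1), 4), "\n", sep = "")
  invisible(x)
}

#' @export
summary.plugin_gan_fit <- function(object, ...) {
  h <- object$history
  out <- list(
    epochs = max(h$epoch),
    steps = nrow(h),
    final_loss_D = utils::tail(h$loss_D, 1),
    final_loss_plugin = utils::tail(h$loss_plugin, 1),
    mean_score_real_last_epoch = mean(h$mean_score_real[h$epoch == max(h$epoch)]),
    mean_score_fake_last_epoch = mean(h$mean_score_fake[h$epoch == max(h$epoch)]),
    backbone_hashes = object$backbone_hashes)
  class(out) <- "summary.plugin_gan_fit"
  out
}

#' @export
print.summary.plugin_gan_fit <- function(x, ...) {
  cat("Stage-2 training summary\n")
  cat("  epochs/steps:      ", x$epochs, "/", x$steps, "\n", sep = "")
  cat("  final losses:       D ", signif(x$final_loss_D, 4), ", plugin ",
      signif(x$final_loss_plugin, 4), "\n", sep = "")
  cat("  last-epoch scores:  real ", signif(x$mean_score_real_last_epoch, 4),
      ", fake ", signif(x$mean_score_fake_last_epoch, 4), "\n", sep = "")
  invisible(x)
}

#' Generate clips from a fitted model
#'
#' Draws one shared noise vector per clip and decodes a `clip_len`-frame
#' trajectory through the frozen generator.
#'
#' @param fit a `plugin_gan_fit`.
#' @param n_clips number of clips.
#' @param clip_len frames per clip (any length; the plugin is a per-frame
#'   map).
#' @param seed integer seed.
#' @return list of [video_clip()] objects.
#' @export
generate_clips_from_fit <- function(fit, n_clips, clip_len = 16L, seed = 1L) {
  stopifnot(inherits(fit, "plugin_gan_fit"))
  lapply(seq_len(n_clips), function(i) {
    z <- sample_video_noise(derive_seed(seed, 5000L + i), fit$plugin_config$z_dim)
    generate_video(fit$plugin, fit$backbone$generator, z,
                   T = seq_len(clip_len) - 1L,
                   clip_id = sprintf("gen_%04d", i - 1L))
  })
}

#' Video-critic probability for a clip, averaged over temporal windows
#'
#' Longer clips are scored on every contiguous `n_frames` window and the
#' probabilities averaged.
#'
#' @param fit a `plugin_gan_fit`.
#' @param clip a [video_clip()] at the backbone resolution.
#' @return mean window probability in (0, 1).
#' @export
score_clip <- function(fit, clip) {
  stopifnot(inherits(fit, "plugin_gan_fit"))
  n <- fit$video_critic_config$n_frames
  len <- dim(clip$frames)[1]
  if (len < n) stop_input("clip has ", len, " frames; need at least ", n)
  fc <- freeze_state(fit$backbone$critic)
  starts <- 0:(len - n)
  mean(vapply(starts, function(s) {
    fm <- featurize_clip(fc, clip, s:(s + n - 1L))
    video_critic_forward(fit$video_critic, fm)
  }, 0))
}

# ---- stage-2 checkpoint -----------------------------------------------------

#' Save / load a stage-2 checkpoint
#'
#' Single-file container with the plugin and video-critic parameters, all
#' configs, the training history, and the backbone (with hashes), so a saved
#' fit regenerates identical clips.
#'
#' @param fit a `plugin_gan_fit`.
#' @param path file path.
#' @return `read_stage2_checkpoint` returns the `plugin_gan_fit`.
#' @export
write_stage2_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "plugin_gan_fit"))
  obj <- list(format = "plugingan/stage2", version = 1L, fit = fit,
              plugin_hash = param_hash(fit$plugin$params),
              vc_hash = param_hash(fit$video_critic$params))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname write_stage2_checkpoint
#' @export
read_stage2_checkpoint <- function(path) {
  if (!file.exists(path)) stop_config("stage-2 checkpoint not found: ", path)
  obj <- readRDS(path)
  if (!identical(obj$format, "plugingan/stage2")) {
    stop_config("not a stage-2 checkpoint: ", path)
  }
  if (!identical(obj$plugin_hash, param_hash(obj$fit$plugin$params)) ||
      !identical(obj$vc_hash, param_hash(obj$fit$video_critic$params))) {
    stop_config("stage-2 checkpoint failed its integrity hash: ", path)
  }
  obj$fit
}
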