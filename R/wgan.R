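# WGAN-GP objective and the progressive stage-1 training loop.

# Uniform per-sample interpolates between real and fake batches; vector u
# recycles along the batch (first) dimension of (B,H,W,C) arrays.
interpolate_batch <- function(real, fake, u) u * real + (1 - u) * fake

critic_value_of <- function(critic, x) {
  if (inherits(critic, "frame_critic")) critic_scores(critic, x)
  else if (is.list(critic) && is.function(critic$value)) critic$value(x)
  else stop_input("unsupported critic object")
}

critic_input_grad_of <- function(critic, x) {
  if (inherits(critic, "frame_critic")) {
    fw <- critic_forward(critic, x, track_params = FALSE, track_input = TRUE)
    B <- dim(x)[1]
    bw <- tp_backward(fw$tape, fw$score, matrix(1, B, 1))
    bw$inputs[[as.character(fw$input)]]
  } else if (is.list(critic) && is.function(critic$grad)) {
    critic$grad(x)
  } else {
    stop_input("unsupported critic object")
  }
}

#' WGAN-GP loss components for one batch
#'
#' Computes the Wasserstein critic and generator losses plus the gradient
#' penalty `lambda * mean((||grad_x f(xhat)|| - 1)^2)` evaluated at seeded
#' random interpolates `xhat = u*real + (1-u)*fake`, `u ~ U(0,1)` per sample.
#'
#' @param critic a `frame_critic`, or a list with functions `value(x)` (batch
#'   of images to numeric scores) and `grad(x)` (gradient of the summed score
#'   with respect to `x`), which is convenient for analytically known critics.
#' @param real_batch,fake_batch arrays `(B,H,W,C)` of identical shape.
#' @param gp_lambda penalty weight (>= 0).
#' @param seed seed for the interpolation coefficients.
#' @return list with `critic_loss`, `generator_loss`, `penalty`.
#' @export
wgan_gp_losses <- function(critic, real_batch, fake_batch, gp_lambda = 10,
                           seed = 1L) {
  if (!identical(dim(real_batch), dim(fake_batch))) {
    stop_input("real and fake batches differ in shape: (",
               paste(dim(real_batch), collapse = ","), ") vs (",
               paste(dim(fake_batch), collapse = ","), ")")
  }
  if (gp_lambda < 0) stop_input("gp_lambda must be >= 0")
  B <- dim(real_batch)[1]
  fr <- critic_value_of(critic, real_batch)
  ff <- critic_value_of(critic, fake_batch)
  penalty <- 0
  if (gp_lambda > 0) {
    u <- with_seed(seed, stats::runif(B))
    xhat <- interpolate_batch(real_batch, fake_batch, u)
    g <- critic_input_grad_of(critic, xhat)
    gn <- sqrt(rowSums(matrix(g, B, length(g) / B)^2))
    penalty <- gp_lambda * mean((gn - 1)^2)
  }
  list(critic_loss = mean(ff) - mean(fr) + penalty,
       generator_loss = -mean(ff),
       penalty = penalty)
}

# Parameter gradient of the gradient-penalty term.
#
# The penalty needs d/dtheta of the input-gradient norm — a double backward.
# We compute the input gradient g exactly by backprop, then obtain
# d||g_i||/dtheta through the directional-derivative identity
#   ||g_i|| = g_i . v_i = d/de f(xhat_i + e v_i) |_{e=0},  v_i = g_i/||g_i||,
# differentiated in theta via a symmetric finite difference over e. The
# critic is piecewise linear in its input (leaky-ReLU stack), so for small e
# the two probe points stay in the same linear region and the difference
# quotient is exact up to roundoff.
gp_param_grads <- function(critic, xhat, gp_lambda, resolution, alpha,
                           fd_eps = 1e-3) {
  B <- dim(xhat)[1]
  fw <- critic_forward(critic, xhat, resolution = resolution, alpha = alpha,
                       track_params = FALSE, track_input = TRUE)
  bw <- tp_backward(fw$tape, fw$score, matrix(1, B, 1))
  g <- bw$inputs[[as.character(fw$input)]]
  gn <- sqrt(rowSums(matrix(g, B, length(g) / B)^2))
  vhat <- g / pmax(gn, 1e-12)
  coef <- 2 * gp_lambda * (gn - 1) / B        # dL/d||g_i||
  xp <- xhat + fd_eps * vhat
  xm <- xhat - fd_eps * vhat
  fwp <- critic_forward(critic, xp, resolution = resolution, alpha = alpha,
                        track_params = TRUE)
  bwp <- tp_backward(fwp$tape, fwp$score, matrix(coef / (2 * fd_eps), B, 1))
  fwm <- critic_forward(critic, xm, resolution = resolution, alpha = alpha,
                        track_params = TRUE)
  bwm <- tp_backward(fwm$tape, fwm$score, matrix(-coef / (2 * fd_eps), B, 1))
  list(grads = grad_add(bwp$params, bwm$params),
       penalty = gp_lambda * mean((gn - 1)^2))
}

#' Train the progressive frame GAN (stage 1)
#'
#' Runs the full phase schedule from 4 px to `config$max_resolution`, fading
#' each new resolution block in over the first `fade_fraction` of its phase,
#' with one critic update (WGAN-GP plus drift penalty) and one generator
#' update per step. Dataset frames are average-pooled down to each phase's
#' resolution.
#'
#' @param dataset a `frame_dataset` (see [as_frame_dataset()]) whose images
#'   are at `config$max_resolution`.
#' @param config a [frame_gan_config()].
#' @param seed integer seed controlling initialisation, batch composition and
#'   noise; identical `(dataset, config, seed)` give identical results.
#' @return an object of class `frame_gan` with elements `generator`,
#'   `critic`, `config`, `history` (one row per step with finite losses).
#' @export
train_frame_gan <- function(dataset, config, seed = 1L) {
  stopifnot(inherits(config, "frame_gan_config"))
  if (!inherits(dataset, "frame_dataset") || dim(dataset$images)[1] == 0L) {
    stop_input("dataset must be a non-empty frame_dataset")
  }
  d <- dim(dataset$images)
  if (d[2] != config$max_resolution || d[3] != config$max_resolution) {
    stop_input("dataset frames are ", d[2], "x", d[3],
               " but config$max_resolution is ", config$max_resolution)
  }
  if (d[4] != config$img_channels) {
    stop_input("dataset has ", d[4], " channels, config expects ",
               config$img_channels)
  }
  N <- d[1]
  gen <- build_frame_generator(config, seed = derive_seed(seed, 1L))
  critic <- build_frame_critic(config, seed = derive_seed(seed, 2L))
  opt_g <- adam_init(gen$params)
  opt_c <- adam_init(critic$params)
  hist <- vector("list", length(config$resolutions) * config$steps_per_phase)
  hrow <- 0L
  global_step <- 0L
  with_seed(derive_seed(seed, 3L), {
    for (res in config$resolutions) {
      data_res <- downsample_images(dataset$images, res)
      batch <- unname(config$batch_schedule[[as.character(res)]])
      batch <- min(batch, N)
      fade_steps <- if (res > 4L) ceiling(config$fade_fraction * config$steps_per_phase) else 0L
      for (step in seq_len(config$steps_per_phase)) {
        global_step <- global_step + 1L
        alpha <- if (step <= fade_steps) step / fade_steps else 1
        # --- critic update ---
        idx <- sample.int(N, batch, replace = TRUE)
        real <- data_res[idx, , , , drop = FALSE]
        zc <- matrix(stats::rnorm(batch * config$latent_dim), batch)
        fake <- generate_frames(gen, zc, resolution = res, alpha = alpha)
        fwr <- critic_forward(critic, real, resolution = res, alpha = alpha,
                              track_params = TRUE)
        sr <- tp_value(fwr$tape, fwr$score)
        dr <- matrix(-1 / batch + 2 * config$drift_epsilon * sr / batch, batch, 1)
        bwr <- tp_backward(fwr$tape, fwr$score, dr)
        fwf <- critic_forward(critic, fake, resolution = res, alpha = alpha,
                              track_params = TRUE)
        sf <- tp_value(fwf$tape, fwf$score)
        bwf <- tp_backward(fwf$tape, fwf$score, matrix(1 / batch, batch, 1))
        cg <- grad_add(bwr$params, bwf$params)
        penalty <- 0
        if (config$gp_lambda > 0) {
          u <- stats::runif(batch)
          xhat <- interpolate_batch(real, fake, u)
          gp <- gp_param_grads(critic, xhat, config$gp_lambda, res, alpha)
          cg <- grad_add(cg, gp$grads)
          penalty <- gp$penalty
        }
        upd <- adam_step(critic$params, cg, opt_c, config$learning_rate,
                         config$beta1, config$beta2)
        critic$params <- upd$params; opt_c <- upd$state
        loss_c <- mean(sf) - mean(sr) + penalty +
          config$drift_epsilon * mean(sr^2)
        # --- generator update ---
        zg <- matrix(stats::rnorm(batch * config$latent_dim), batch)
        gfw <- gen_forward(gen, zg, resolution = res, alpha = alpha,
                           track_params = TRUE)
        cfw <- critic_forward(critic, gfw$out, tape = gfw$tape,
                              resolution = res, alpha = alpha,
                              track_params = FALSE)
        sg <- tp_value(cfw$tape, cfw$score)
        bwg <- tp_backward(cfw$tape, cfw$score, matrix(-1 / batch, batch, 1))
        upd <- adam_step(gen$params, bwg$params, opt_g, config$learning_rate,
                         config$beta1, config$beta2)
        gen$params <- upd$params; opt_g <- upd$state
        loss_g <- -mean(sg)
        if (!is.finite(loss_c) || !is.finite(loss_g)) {
          stop("non-finite loss at step ", global_step, " (resolution ", res,
               "): critic=", loss_c, " generator=", loss_g)
        }
        hrow <- hrow + 1L
        hist[[hrow]] <- data.frame(step = global_step, resolution = res,
                                   alpha = alpha, batch_size = batch,
                                   loss_critic = loss_c, loss_gen = loss_g,
                                   penalty = penalty)
      }
    }
  })
  gen$resolution <- config$max_resolution; gen$alpha <- 1; gen$trained <- TRUE
  critic$resolution <- config$max_resolution; critic$alpha <- 1
  critic$trained <- TRUE
  structure(list(generator = gen, critic = critic, config = config,
                 history = do.call(rbind, hist[seq_len(hrow)]), seed = seed),
            class = "frame_gan")
}

#' @export
print.frame_gan <- function(x, ...) {
  cat("Progressive frame GAN backbone\n")
  cat("  resolution:  ", x$config$max_resolution, "px, ",
      x$config$img_channels, " channel(s)\n", sep = "")
  cat("  latent dim:  ", x$config$latent_dim, "\n", sep = "")
  cat("  feature dim: ", x$config$feature_dim, "\n", sep = "")
  cat("  parameters:  ", param_count(x$generator$params), " (generator), ",
      param_count(x$critic$params), " (critic)\n", sep = "")
  cat("  trained for ", nrow(x$history), " steps; final critic loss ",
      signif(utils::tail(x$history$loss_critic, 1), 4), "\n", sep = "")
  invisible(x)
}

# ---- checkpointing ----------------------------------------------------------

#' Save / load a stage-1 backbone checkpoint
#'
#' Single-file container (RDS) holding the config, generator and critic
#' parameters, training history, the RNG seed, and MD5 hashes of both
#' parameter sets for integrity and freeze verification. Format name and
#' version are embedded and checked on read.
#'
#' @param fit a `frame_gan` object.
#' @param path file path to write to / read from.
#' @return `read_backbone_checkpoint` returns the `frame_gan` object.
#' @export
write_backbone_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "frame_gan"))
  obj <- list(format = "plugingan/backbone", version = 1L,
              fit = fit,
              gen_hash = param_hash(fit$generator$params),
              critic_hash = param_hash(fit$critic$params))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname write_backbone_checkpoint
#' @export
read_backbone_checkpoint <- function(path) {
  if (!file.exists(path)) stop_config("backbone checkpoint not found: ", path)
  obj <- readRDS(path)
  if (!identical(obj$format, "plugingan/backbone")) {
    stop_config("not a backbone checkpoint: ", path)
  }
  if (!identical(obj$gen_hash, param_hash(obj$fit$generator$params)) ||
      !identical(obj$critic_hash, param_hash(obj$fit$critic$params))) {
    stop_config("backbone checkpoint failed its integrity hash: ", path)
  }
  obj$fit
}
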