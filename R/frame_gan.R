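# Stage-1 backbone: progressively grown frame generator and critic.

#' Configuration for the progressive frame GAN backbone
#'
#' Describes the stage-1 generator/critic pair trained on individual video
#' frames with the WGAN-GP objective, grown from `start_resolution` (4 px) to
#' `max_resolution` by doubling. The critic minus its last layer doubles as
#' the frame feature extractor consumed by the video discriminator.
#'
#' @param latent_dim width of the generator's latent input (default 512).
#' @param max_resolution final image resolution, a power of two >= 4.
#' @param img_channels 1 (grayscale) or 3 (RGB).
#' @param channels_schedule named integer vector of feature-map widths per
#'   resolution (`"4"`, `"8"`, ...). Defaults to the usual progressive-GAN
#'   rule `min(fmap_max, fmap_base / resolution)`.
#' @param fmap_base,fmap_max parameters of the default channel rule
#'   (reference values 8192 and 512); lower both to scale the whole network
#'   down for toy resolutions.
#' @param feature_dim width of the critic's penultimate layer; this is the
#'   length of extracted frame features (default 512).
#' @param batch_schedule named integer vector of batch sizes per resolution.
#'   Default: 8 for resolutions up to 256 px, 4 above.
#' @param gp_lambda gradient-penalty weight (default 10).
#' @param drift_epsilon weight of the critic drift penalty
#'   `eps * mean(f(real)^2)`; 0 disables (default 1e-3).
#' @param learning_rate,beta1,beta2 Adam hyperparameters for stage 1.
#' @param steps_per_phase optimisation steps spent at each resolution phase.
#' @param fade_fraction fraction of each growth phase spent fading the new
#'   block in (alpha ramping 0 to 1), in (0, 1].
#' @param use_pixelnorm normalise generator feature vectors per pixel (and the
#'   input latent) as in progressive GANs.
#' @param use_eqlr equalised learning rate (He-constant runtime weight
#'   scaling).
#' @param use_mbstd append a minibatch standard-deviation channel in the
#'   critic's 4x4 block. Off by default so frame features are a pure
#'   per-sample map.
#' @return an object of class `frame_gan_config`.
#' @export
frame_gan_config <- function(latent_dim = 512L,
                             max_resolution = 128L,
                             img_channels = 3L,
                             channels_schedule = NULL,
                             fmap_base = 8192L,
                             fmap_max = 512L,
                             feature_dim = 512L,
                             batch_schedule = NULL,
                             gp_lambda = 10,
                             drift_epsilon = 1e-3,
                             learning_rate = 1e-3,
                             beta1 = 0,
                             beta2 = 0.99,
                             steps_per_phase = 600L,
                             fade_fraction = 0.5,
                             use_pixelnorm = TRUE,
                             use_eqlr = TRUE,
                             use_mbstd = FALSE) {
  if (!is_power_of_two(max_resolution) || max_resolution < 4) {
    stop_config("max_resolution must be a power of two >= 4, got ", max_resolution)
  }
  if (!img_channels %in% c(1L, 3L)) {
    stop_config("img_channels must be 1 or 3, got ", img_channels)
  }
  if (latent_dim < 1) stop_config("latent_dim must be >= 1")
  if (gp_lambda < 0) stop_config("gp_lambda must be >= 0")
  if (fade_fraction <= 0 || fade_fraction > 1) {
    stop_config("fade_fraction must be in (0, 1]")
  }
  resolutions <- 2^(2:round(log2(max_resolution)))
  if (is.null(channels_schedule)) {
    channels_schedule <- stats::setNames(
      pmin(as.integer(fmap_max), as.integer(fmap_base / resolutions)),
      as.character(resolutions))
    channels_schedule <- pmax(channels_schedule, 2L)
  }
  if (!all(as.character(resolutions) %in% names(channels_schedule))) {
    stop_config("channels_schedule must name every resolution: ",
                paste(resolutions, collapse = ", "))
  }
  channels_schedule <- channels_schedule[as.character(resolutions)]
  if (any(channels_schedule < 1)) stop_config("channel widths must be >= 1")
  if (is.null(batch_schedule)) {
    batch_schedule <- stats::setNames(
      ifelse(resolutions <= 256L, 8L, 4L), as.character(resolutions))
  }
  batch_schedule <- batch_schedule[as.character(resolutions)]
  if (any(is.na(batch_schedule)) || any(batch_schedule < 1)) {
    stop_config("batch_schedule must map every resolution to a size >= 1")
  }
  structure(list(
    latent_dim = as.integer(latent_dim),
    start_resolution = 4L,
    max_resolution = as.integer(max_resolution),
    resolutions = as.integer(resolutions),
    img_channels = as.integer(img_channels),
    channels_schedule = channels_schedule,
    feature_dim = as.integer(feature_dim),
    batch_schedule = batch_schedule,
    gp_lambda = gp_lambda,
    drift_epsilon = drift_epsilon,
    learning_rate = learning_rate,
    beta1 = beta1,
    beta2 = beta2,
    steps_per_phase = as.integer(steps_per_phase),
    fade_fraction = fade_fraction,
    use_pixelnorm = isTRUE(use_pixelnorm),
    use_eqlr = isTRUE(use_eqlr),
    use_mbstd = isTRUE(use_mbstd)
  ), class = "frame_gan_config")
}

chans <- function(config, res) unname(config$channels_schedule[[as.character(res)]])

# weight init honouring equalised learning rate: raw weights ~ N(0,1) with a
# He runtime scale, or directly He-scaled weights when eqlr is off
init_weight <- function(dims, fan_in, gain, use_eqlr) {
  w <- array(stats::rnorm(prod(dims)), dims)
  scale <- gain / sqrt(fan_in)
  if (use_eqlr) list(W = w, scale = scale) else list(W = w * scale, scale = 1)
}

#' Build a progressive frame generator
#'
#' Initialises all resolution blocks up front (4x4 base block, one
#' upsample+conv block per doubling, and a to-image 1x1 convolution per
#' resolution); the active resolution and fade-in alpha are part of the state,
#' so progressive growth is a matter of advancing them.
#'
#' @param config a [frame_gan_config()].
#' @param seed integer seed for weight initialisation.
#' @return an object of class `frame_generator`.
#' @export
build_frame_generator <- function(config, seed = 1L) {
  stopifnot(inherits(config, "frame_gan_config"))
  with_seed(seed, {
    params <- list()
    scales <- list()
    add <- function(name, dims, fan_in, gain = sqrt(2)) {
      iw <- init_weight(dims, fan_in, gain, config$use_eqlr)
      params[[paste0(name, ".W")]] <<- iw$W
      params[[paste0(name, ".b")]] <<- numeric(dims[length(dims)])
      scales[[name]] <<- iw$scale
    }
    c4 <- chans(config, 4L)
    add("g4.fc", c(config$latent_dim, 16L * c4), config$latent_dim)
    add("g4.conv", c(3L, 3L, c4, c4), 9 * c4)
    for (res in config$resolutions[-1]) {
      cp <- chans(config, res %/% 2L); cr <- chans(config, res)
      add(sprintf("g%d.conv1", res), c(3L, 3L, cp, cr), 9 * cp)
      add(sprintf("g%d.conv2", res), c(3L, 3L, cr, cr), 9 * cr)
    }
    for (res in config$resolutions) {
      cr <- chans(config, res)
      add(sprintf("rgb%d", res), c(1L, 1L, cr, config$img_channels), cr, gain = 1)
    }
    structure(list(params = params, scales = scales, config = config,
                   resolution = 4L, alpha = 1, frozen = FALSE,
                   trained = FALSE),
              class = "frame_generator")
  })
}

#' Build a progressive frame critic
#'
#' Mirror image of the generator: per-resolution from-image 1x1 convolutions
#' and downsampling conv blocks, ending in a 4x4 block that flattens into a
#' linear layer of width `feature_dim` (the frame features) followed by the
#' final scalar layer. `extract_features()` returns the activations feeding
#' that final layer.
#'
#' @inheritParams build_frame_generator
#' @return an object of class `frame_critic`.
#' @export
build_frame_critic <- function(config, seed = 2L) {
  stopifnot(inherits(config, "frame_gan_config"))
  with_seed(seed, {
    params <- list()
    scales <- list()
    add <- function(name, dims, fan_in, gain = sqrt(2)) {
      iw <- init_weight(dims, fan_in, gain, config$use_eqlr)
      params[[paste0(name, ".W")]] <<- iw$W
      params[[paste0(name, ".b")]] <<- numeric(dims[length(dims)])
      scales[[name]] <<- iw$scale
    }
    for (res in config$resolutions) {
      cr <- chans(config, res)
      add(sprintf("from%d", res), c(1L, 1L, config$img_channels, cr),
          config$img_channels, gain = 1)
    }
    for (res in config$resolutions[-1]) {
      cp <- chans(config, res %/% 2L); cr <- chans(config, res)
      add(sprintf("d%d.conv1", res), c(3L, 3L, cr, cr), 9 * cr)
      add(sprintf("d%d.conv2", res), c(3L, 3L, cr, cp), 9 * cr)
    }
    c4 <- chans(config, 4L)
    cin4 <- c4 + if (config$use_mbstd) 1L else 0L
    add("d4.conv", c(3L, 3L, cin4, c4), 9 * cin4)
    add("d4.fc", c(16L * c4, config$feature_dim), 16 * c4)
    add("d4.out", c(config$feature_dim, 1L), config$feature_dim, gain = 1)
    structure(list(params = params, scales = scales, config = config,
                   resolution = 4L, alpha = 1, frozen = FALSE,
                   trained = FALSE),
              class = "frame_critic")
  })
}

# ---- forward passes ---------------------------------------------------------

# Run the generator on a tape. `z` may be a matrix (B, latent_dim) or an
# existing tape node id (for stage-2 chaining). Returns list(tape, out).
gen_forward <- function(gen, z, tape = NULL, resolution = gen$resolution,
                        alpha = gen$alpha, track_params = !gen$frozen) {
  cfg <- gen$config
  if (!resolution %in% cfg$resolutions) {
    stop_config("resolution ", resolution, " is not in the phase schedule")
  }
  tp <- tape %||% tape_new()
  id <- if (is.numeric(z) && length(z) == 1L && z >= 1 && z <= tp$n) z else {
    zm <- z
    if (is.null(dim(zm))) zm <- matrix(zm, 1L)
    if (ncol(zm) != cfg$latent_dim) {
      stop_input("latent input has width ", ncol(zm), ", expected ", cfg$latent_dim)
    }
    tp_input(tp, zm)
  }
  p <- gen$params; sc <- gen$scales
  pn <- function(name) if (track_params) paste0(name, c(".W", ".b")) else NULL
  B <- nrow(tp_value(tp, id))
  if (cfg$use_pixelnorm) {
    # normalise the latent like any other feature vector (scale invariance of
    # the latent input; also what maps unit-norm plugin codes onto the same
    # sphere as training noise)
    id4 <- tp_reshape(tp, id, c(B, 1L, 1L, cfg$latent_dim))
    id4 <- tp_pixelnorm(tp, id4)
    id <- tp_reshape(tp, id4, c(B, cfg$latent_dim))
  }
  c4 <- chans(cfg, 4L)
  x <- tp_linear(tp, id, p[["g4.fc.W"]], p[["g4.fc.b"]], pn("g4.fc"), sc[["g4.fc"]])
  x <- tp_reshape(tp, x, c(B, 4L, 4L, c4))
  x <- tp_lrelu(tp, x)
  if (cfg$use_pixelnorm) x <- tp_pixelnorm(tp, x)
  x <- tp_conv(tp, x, p[["g4.conv.W"]], p[["g4.conv.b"]], pad = c(1L, 1L),
               pnames = pn("g4.conv"), scale = sc[["g4.conv"]])
  x <- tp_lrelu(tp, x)
  if (cfg$use_pixelnorm) x <- tp_pixelnorm(tp, x)
  x_prev <- x
  res_chain <- cfg$resolutions[cfg$resolutions <= resolution]
  for (res in res_chain[-1]) {
    x_prev <- x
    nm1 <- sprintf("g%d.conv1", res); nm2 <- sprintf("g%d.conv2", res)
    x <- tp_up2(tp, x)
    x <- tp_conv(tp, x, p[[paste0(nm1, ".W")]], p[[paste0(nm1, ".b")]],
                 pad = c(1L, 1L), pnames = pn(nm1), scale = sc[[nm1]])
    x <- tp_lrelu(tp, x)
    if (cfg$use_pixelnorm) x <- tp_pixelnorm(tp, x)
    x <- tp_conv(tp, x, p[[paste0(nm2, ".W")]], p[[paste0(nm2, ".b")]],
                 pad = c(1L, 1L), pnames = pn(nm2), scale = sc[[nm2]])
    x <- tp_lrelu(tp, x)
    if (cfg$use_pixelnorm) x <- tp_pixelnorm(tp, x)
  }
  rgb <- sprintf("rgb%d", resolution)
  img <- tp_conv(tp, x, p[[paste0(rgb, ".W")]], p[[paste0(rgb, ".b")]],
                 pnames = pn(rgb), scale = sc[[rgb]])
  img <- tp_tanh(tp, img)
  if (alpha < 1 && resolution > 4L) {
    rgb_lo <- sprintf("rgb%d", resolution %/% 2L)
    lo <- tp_conv(tp, x_prev, p[[paste0(rgb_lo, ".W")]], p[[paste0(rgb_lo, ".b")]],
                  pnames = pn(rgb_lo), scale = sc[[rgb_lo]])
    lo <- tp_tanh(tp, lo)
    lo <- tp_up2(tp, lo)
    img <- tp_blend(tp, lo, img, alpha)
  }
  list(tape = tp, out = img, z = id)
}

# Run the critic. `images` may be an array (B,H,W,C) or a tape node id.
# Returns list(tape, score, features, input) where score is a (B,1) node.
critic_forward <- function(critic, images, tape = NULL,
                           resolution = critic$resolution,
                           alpha = critic$alpha,
                           track_params = !critic$frozen,
                           track_input = FALSE) {
  cfg <- critic$config
  if (!resolution %in% cfg$resolutions) {
    stop_config("resolution ", resolution, " is not in the phase schedule")
  }
  tp <- tape %||% tape_new()
  id <- if (is.numeric(images) && length(images) == 1L && images >= 1 &&
            images <= tp$n) images else {
    d <- dim(images)
    if (length(d) != 4L || d[2] != resolution || d[3] != resolution ||
        d[4] != cfg$img_channels) {
      stop_input("critic expects images of shape (B, ", resolution, ", ",
                 resolution, ", ", cfg$img_channels, "); got (",
                 paste(d, collapse = ", "), ")")
    }
    tp_input(tp, images, track = track_input)
  }
  input_id <- id
  p <- critic$params; sc <- critic$scales
  pn <- function(name) if (track_params) paste0(name, c(".W", ".b")) else NULL
  frm <- sprintf("from%d", resolution)
  x <- tp_conv(tp, id, p[[paste0(frm, ".W")]], p[[paste0(frm, ".b")]],
               pnames = pn(frm), scale = sc[[frm]])
  x <- tp_lrelu(tp, x)
  res_chain <- rev(cfg$resolutions[cfg$resolutions <= resolution])
  first <- TRUE
  for (res in res_chain[res_chain > 4L]) {
    nm1 <- sprintf("d%d.conv1", res); nm2 <- sprintf("d%d.conv2", res)
    x <- tp_conv(tp, x, p[[paste0(nm1, ".W")]], p[[paste0(nm1, ".b")]],
                 pad = c(1L, 1L), pnames = pn(nm1), scale = sc[[nm1]])
    x <- tp_lrelu(tp, x)
    x <- tp_conv(tp, x, p[[paste0(nm2, ".W")]], p[[paste0(nm2, ".b")]],
                 pad = c(1L, 1L), pnames = pn(nm2), scale = sc[[nm2]])
    x <- tp_lrelu(tp, x)
    x <- tp_down2(tp, x)
    if (first && alpha < 1) {
      frm_lo <- sprintf("from%d", res %/% 2L)
      lo <- tp_down2(tp, input_id)
      lo <- tp_conv(tp, lo, p[[paste0(frm_lo, ".W")]], p[[paste0(frm_lo, ".b")]],
                    pnames = pn(frm_lo), scale = sc[[frm_lo]])
      lo <- tp_lrelu(tp, lo)
      x <- tp_blend(tp, lo, x, alpha)
    }
    first <- FALSE
  }
  if (cfg$use_mbstd) x <- tp_mbstd(tp, x)
  x <- tp_conv(tp, x, p[["d4.conv.W"]], p[["d4.conv.b"]], pad = c(1L, 1L),
               pnames = pn("d4.conv"), scale = sc[["d4.conv"]])
  x <- tp_lrelu(tp, x)
  B <- dim(tp_value(tp, x))[1]
  x <- tp_reshape(tp, x, c(B, 16L * chans(cfg, 4L)))
  x <- tp_linear(tp, x, p[["d4.fc.W"]], p[["d4.fc.b"]], pn("d4.fc"), sc[["d4.fc"]])
  feat <- tp_lrelu(tp, x)
  score <- tp_linear(tp, feat, p[["d4.out.W"]], p[["d4.out.b"]], pn("d4.out"),
                     sc[["d4.out"]])
  list(tape = tp, score = score, features = feat, input = input_id)
}

#' Generate frames from latent codes
#'
#' @param gen a `frame_generator`.
#' @param z matrix of latent codes, one row per frame.
#' @param resolution,alpha phase to synthesise at; defaults to the state's.
#' @return array of images `(nrow(z), res, res, channels)` with values in
#'   `[-1, 1]`.
#' @export
generate_frames <- function(gen, z, resolution = gen$resolution,
                            alpha = gen$alpha) {
  fw <- gen_forward(gen, z, resolution = resolution, alpha = alpha,
                    track_params = FALSE)
  tp_value(fw$tape, fw$out)
}

#' Extract frame features from the critic minus its last layer
#'
#' Returns the activations feeding the critic's final scalar layer — the
#' low-dimensional per-frame representation consumed by the video
#' discriminator.
#'
#' @param critic a `frame_critic`.
#' @param images array `(B, res, res, channels)` at the critic's resolution.
#' @return matrix `(B, feature_dim)`.
#' @export
extract_features <- function(critic, images) {
  fw <- critic_forward(critic, images, track_params = FALSE)
  tp_value(fw$tape, fw$features)
}

#' Critic scores for a batch of images
#'
#' @inheritParams extract_features
#' @return numeric vector of length `B` (unbounded Wasserstein scores).
#' @export
critic_scores <- function(critic, images) {
  fw <- critic_forward(critic, images, track_params = FALSE)
  as.numeric(tp_value(fw$tape, fw$score))
}

# mark states as frozen (used by stage 2); parameters become off-limits
freeze_state <- function(state) {
  state$frozen <- TRUE
  state
}

# average-pool images down by repeated factor-2 reduction
downsample_images <- function(x, to_res) {
  while (dim(x)[2] > to_res) {
    d <- dim(x)
    o1 <- seq(1L, d[2], by = 2L); o2 <- seq(1L, d[3], by = 2L)
    x <- (x[, o1, o2, , drop = FALSE] + x[, o1 + 1L, o2, , drop = FALSE] +
          x[, o1, o2 + 1L, , drop = FALSE] + x[, o1 + 1L, o2 + 1L, , drop = FALSE]) / 4
  }
  x
}
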