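# The video discriminator: a strided 2D conv stack over the (frames x
# features) map of frozen frame-critic features, ending in a sigmoid.

#' Configuration of the video discriminator
#'
#' The discriminator sees one clip as a single-channel image of shape
#' `n_frames x feature_dim` whose rows are per-frame features from the frozen
#' frame critic. Four valid (unpadded) convolutions with ReLU reduce it to a
#' small map that is flattened into the final linear + sigmoid layer, whose
#' input width is inferred automatically ([infer_flatten_dim()]); at the
#' reference scale (8 frames x 512 features) that width is 27.
#'
#' @param conv_layers list of `c(in_channels, out_channels, kh, kw, sh, sw)`
#'   rows, or a list of lists `list(in, out, kernel = c(kh, kw),
#'   stride = c(sh, sw))`. Default: the reference stack
#'   (1,16,(3,10),(1,2)), (16,8,(3,8),(1,2)), (8,4,(3,6),(1,2)),
#'   (4,1,(2,6),(1,2)).
#' @param n_frames temporal window height (reference 8).
#' @param feature_dim frame feature width (reference 512).
#' @return an object of class `video_critic_config`.
#' @export
video_critic_config <- function(conv_layers = NULL, n_frames = 8L,
                                feature_dim = 512L) {
  if (is.null(conv_layers)) {
    conv_layers <- list(
      list(in_ch = 1L, out_ch = 16L, kernel = c(3L, 10L), stride = c(1L, 2L)),
      list(in_ch = 16L, out_ch = 8L, kernel = c(3L, 8L), stride = c(1L, 2L)),
      list(in_ch = 8L, out_ch = 4L, kernel = c(3L, 6L), stride = c(1L, 2L)),
      list(in_ch = 4L, out_ch = 1L, kernel = c(2L, 6L), stride = c(1L, 2L)))
  }
  conv_layers <- lapply(conv_layers, function(l) {
    if (is.numeric(l) && length(l) == 6L) {
      l <- list(in_ch = l[1], out_ch = l[2], kernel = l[3:4], stride = l[5:6])
    }
    l[c("in_ch", "out_ch", "kernel", "stride")]
  })
  if (conv_layers[[1]]$in_ch != 1L) {
    stop_config("first conv layer must take 1 input channel (the feature map)")
  }
  for (k in seq_along(conv_layers)) {
    l <- conv_layers[[k]]
    if (any(unlist(l[c("kernel", "stride")]) < 1) || l$in_ch < 1 || l$out_ch < 1) {
      stop_config("conv layer ", k, ": all channel/kernel/stride entries must be >= 1")
    }
    if (k > 1L && conv_layers[[k - 1L]]$out_ch != l$in_ch) {
      stop_config("conv layer ", k, ": in_channels (", l$in_ch,
                  ") does not match previous out_channels (",
                  conv_layers[[k - 1L]]$out_ch, ")")
    }
  }
  cfg <- structure(list(conv_layers = conv_layers,
                        n_frames = as.integer(n_frames),
                        feature_dim = as.integer(feature_dim)),
                   class = "video_critic_config")
  infer_flatten_dim(cfg)  # validates spatial sizes stay >= 1 at every layer
  cfg
}

#' Output length of a valid strided convolution along one axis
#'
#' @param in_size input extent (>= kernel).
#' @param kernel kernel extent (>= 1).
#' @param stride stride (>= 1).
#' @return `floor((in_size - kernel)/stride) + 1`, the number of valid window
#'   positions.
#' @export
conv_output_size <- function(in_size, kernel, stride) {
  if (kernel < 1 || stride < 1) stop_input("kernel and stride must be >= 1")
  if (in_size < kernel) {
    stop_input("input size ", in_size, " is smaller than kernel ", kernel)
  }
  as.integer((in_size - kernel) %/% stride + 1L)
}

#' Flattened width after the conv stack
#'
#' Applies [conv_output_size()] through every layer of the config on an
#' `(n_frames, feature_dim)` input and returns `out_channels * h * w` of the
#' last layer — the input width of the final linear layer. The reference
#' config gives 27 (heights 8->6->4->2->1, widths 512->252->123->59->27).
#'
#' @param config a [video_critic_config()].
#' @return integer flatten width.
#' @export
infer_flatten_dim <- function(config) {
  h <- config$n_frames
  w <- config$feature_dim
  for (k in seq_along(config$conv_layers)) {
    l <- config$conv_layers[[k]]
    h2 <- tryCatch(conv_output_size(h, l$kernel[1], l$stride[1]),
                   plugingan_input_error = function(e) NULL)
    w2 <- tryCatch(conv_output_size(w, l$kernel[2], l$stride[2]),
                   plugingan_input_error = function(e) NULL)
    if (is.null(h2) || is.null(w2)) {
      stop_config("conv layer ", k, ": map of size ", h, "x", w,
                  " is smaller than kernel ", l$kernel[1], "x", l$kernel[2])
    }
    h <- h2; w <- w2
  }
  as.integer(config$conv_layers[[length(config$conv_layers)]]$out_ch * h * w)
}

#' Build a video discriminator
#'
#' @param config a [video_critic_config()].
#' @param seed integer seed; weights are seeded small-variance normal
#'   (He-scaled for the ReLU convs).
#' @return an object of class `video_critic`.
#' @export
build_video_critic <- function(config, seed = 4L) {
  stopifnot(inherits(config, "video_critic_config"))
  flat <- infer_flatten_dim(config)
  with_seed(seed, {
    params <- list()
    for (k in seq_along(config$conv_layers)) {
      l <- config$conv_layers[[k]]
      fan_in <- l$in_ch * l$kernel[1] * l$kernel[2]
      params[[sprintf("conv%d.W", k)]] <-
        array(stats::rnorm(prod(l$kernel) * l$in_ch * l$out_ch,
                           sd = sqrt(2 / fan_in)),
              c(l$kernel, l$in_ch, l$out_ch))
      params[[sprintf("conv%d.b", k)]] <- numeric(l$out_ch)
    }
    params[["out.W"]] <- matrix(stats::rnorm(flat, sd = 1 / sqrt(flat)), flat, 1L)
    params[["out.b"]] <- numeric(1L)
    structure(list(params = params, config = config, flatten_dim = flat,
                   frozen = FALSE),
              class = "video_critic")
  })
}

# Tape-level forward over a batch of feature maps. `fmaps` is an array
# (B, n_frames, feature_dim) or an existing tape node id of that shape (the
# channel axis is added internally). Returns list(tape, logit, prob).
video_critic_forward_tape <- function(vc, fmaps, tape = NULL,
                                      track_params = !vc$frozen) {
  cfg <- vc$config
  tp <- tape %||% tape_new()
  id <- if (is.numeric(fmaps) && length(fmaps) == 1L && fmaps >= 1 &&
            fmaps <= tp$n) fmaps else {
    d <- dim(fmaps)
    if (length(d) != 3L || d[2] != cfg$n_frames || d[3] != cfg$feature_dim) {
      stop_input("video critic expects feature maps of shape (B, ",
                 cfg$n_frames, ", ", cfg$feature_dim, "); got (",
                 paste(d, collapse = ", "), ")")
    }
    tp_input(tp, fmaps)
  }
  d <- dim(tp_value(tp, id))
  B <- d[1]
  pn <- function(name) if (track_params) paste0(name, c(".W", ".b")) else NULL
  x <- tp_reshape(tp, id, c(B, cfg$n_frames, cfg$feature_dim, 1L))
  for (k in seq_along(cfg$conv_layers)) {
    l <- cfg$conv_layers[[k]]
    x <- tp_conv(tp, x, vc$params[[sprintf("conv%d.W", k)]],
                 vc$params[[sprintf("conv%d.b", k)]],
                 stride = l$stride, pnames = pn(sprintf("conv%d", k)))
    x <- tp_relu(tp, x)
  }
  x <- tp_reshape(tp, x, c(B, vc$flatten_dim))
  logit <- tp_linear(tp, x, vc$params[["out.W"]], vc$params[["out.b"]],
                     pnames = pn("out"))
  prob <- tp_sigmoid(tp, logit)
  list(tape = tp, logit = logit, prob = prob)
}

#' Probability that a feature map comes from a real clip
#'
#' @param vc a `video_critic`.
#' @param fmap one feature map: array `(1, n_frames, feature_dim)` or matrix
#'   `(n_frames, feature_dim)`.
#' @return a single probability strictly inside (0, 1).
#' @export
video_critic_forward <- function(vc, fmap) {
  stopifnot(inherits(vc, "video_critic"))
  if (is.matrix(fmap)) dim(fmap) <- c(1L, dim(fmap))
  if (any(!is.finite(fmap))) stop_input("feature map contains non-finite values")
  fw <- video_critic_forward_tape(vc, fmap, track_params = FALSE)
  p <- as.numeric(tp_value(fw$tape, fw$prob))
  # sigmoid of a finite logit; clamp away from exact {0,1} for safety
  min(max(p, .Machine$double.xmin), 1 - .Machine$double.eps)
}

#' Stack frame-critic features of selected frames into a feature map
#'
#' Applies [extract_features()] to the frames of `clip` selected by `window`
#' (0-based indices relative to the clip's own frames) and stacks them in
#' temporal order as a `(1, n_frames, feature_dim)` map.
#'
#' @param frame_critic a trained `frame_critic`.
#' @param clip a [video_clip()] at the critic's resolution.
#' @param window integer vector of 0-based frame indices, length `n_frames`
#'   of the intended video critic.
#' @return array `(1, length(window), feature_dim)`.
#' @export
featurize_clip <- function(frame_critic, clip, window) {
  stopifnot(inherits(frame_critic, "frame_critic"), inherits(clip, "video_clip"))
  n <- dim(clip$frames)[1]
  if (any(window < 0) || any(window >= n)) {
    stop_input("window indices must lie in [0, ", n - 1L, "]")
  }
  frames <- clip$frames[window + 1L, , , , drop = FALSE]
  feats <- extract_features(frame_critic, frames)
  array(feats, c(1L, nrow(feats), ncol(feats)))
}
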