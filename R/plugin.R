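# The trajectory plugin: a small time-conditioned network mapping one shared
# noise vector plus per-frame time indices to unit-norm latent codes for the
# frozen frame generator.

#' Configuration of the trajectory plugin network
#'
#' Four concatenate-then-linear layers: each layer's input is the previous
#' output with the (encoded) frame time appended, so every input width is the
#' previous width + 1. The first three layers use ReLU; the fourth output is
#' normalised onto the unit hypersphere. At reference scale the widths are
#' 2047+1 -> 1535, 1535+1 -> 1023, 1023+1 -> 511, 511+1 -> 512, matching a
#' frame generator with a 512-wide latent space.
#'
#' @param z_dim width of the shared Gaussian noise vector (reference 2047).
#' @param layer_widths output widths of the four linear layers; the last must
#'   equal `out_dim`.
#' @param time_encoding `"normalized_unit"` maps frame index `t` to
#'   `t/(n_ref-1)` in `[0, 1]`; `"raw_index"` uses the integer index.
#' @param n_ref reference clip length for the normalised encoding (default 8).
#' @param norm_epsilon lower bound on the pre-normalisation norm, so the
#'   degenerate all-zero vector stays finite.
#' @param out_dim trajectory row width; must equal the backbone generator's
#'   `latent_dim` (reference 512).
#' @return an object of class `plugin_config`.
#' @export
plugin_config <- function(z_dim = 2047L,
                          layer_widths = c(1535L, 1023L, 511L, 512L),
                          time_encoding = c("normalized_unit", "raw_index"),
                          n_ref = 8L,
                          norm_epsilon = 1e-8,
                          out_dim = 512L) {
  time_encoding <- match.arg(time_encoding)
  if (length(layer_widths) != 4L) {
    stop_config("the plugin has exactly four linear layers; got ",
                length(layer_widths), " widths")
  }
  if (layer_widths[4] != out_dim) {
    stop_config("last layer width (", layer_widths[4],
                ") must equal out_dim (", out_dim, ")")
  }
  if (z_dim < 1 || any(layer_widths < 1)) stop_config("widths must be >= 1")
  if (norm_epsilon <= 0) stop_config("norm_epsilon must be > 0")
  structure(list(z_dim = as.integer(z_dim),
                 layer_widths = as.integer(layer_widths),
                 time_encoding = time_encoding,
                 n_ref = as.integer(n_ref),
                 norm_epsilon = norm_epsilon,
                 out_dim = as.integer(out_dim)),
            class = "plugin_config")
}

# input widths of the four layers (previous width + 1 appended time slot)
plugin_in_widths <- function(config) {
  c(config$z_dim, config$layer_widths[-4L]) + 1L
}

#' Build a plugin network
#'
#' @param config a [plugin_config()].
#' @param seed integer seed for He-scaled normal initialisation.
#' @return an object of class `plugin_net`.
#' @export
build_plugin <- function(config, seed = 3L) {
  stopifnot(inherits(config, "plugin_config"))
  ins <- plugin_in_widths(config)
  outs <- config$layer_widths
  with_seed(seed, {
    params <- list()
    for (l in 1:4) {
      gain <- if (l < 4L) sqrt(2) else 1
      params[[sprintf("fc%d.W", l)]] <-
        matrix(stats::rnorm(ins[l] * outs[l], sd = gain / sqrt(ins[l])),
               ins[l], outs[l])
      params[[sprintf("fc%d.b", l)]] <- numeric(outs[l])
    }
    structure(list(params = params, config = config, frozen = FALSE),
              class = "plugin_net")
  })
}

# encode 0-based frame indices per the config
encode_time <- function(config, T) {
  switch(config$time_encoding,
         normalized_unit = T / max(1L, config$n_ref - 1L),
         raw_index = as.double(T))
}

validate_timeline <- function(T) {
  if (length(T) < 1L || any(!is.finite(T))) {
    stop_input("timeline must contain at least one finite index")
  }
  if (length(T) > 1L && any(diff(T) <= 0)) {
    stop_input("timeline indices must be strictly increasing")
  }
  as.double(T)
}

#' Sample the shared per-clip noise vector
#'
#' One standard-normal vector per clip, shared by all of its frames.
#'
#' @param seed integer seed.
#' @param z_dim noise width (>= 1).
#' @return numeric vector of length `z_dim`.
#' @export
sample_video_noise <- function(seed, z_dim) {
  if (z_dim < 1) stop_input("z_dim must be >= 1")
  with_seed(seed, stats::rnorm(z_dim))
}

# Tape-level forward. `zmat` is an (n_rows, z_dim) matrix (rows may repeat a
# shared z), `tvec` the matching encoded time column. Returns list(tape, out).
plugin_forward_tape <- function(plugin, zmat, tvec, tape = NULL,
                                track_params = !plugin$frozen) {
  cfg <- plugin$config
  if (ncol(zmat) != cfg$z_dim) {
    stop_input("noise width ", ncol(zmat), " does not match z_dim ", cfg$z_dim)
  }
  tp <- tape %||% tape_new()
  p <- plugin$params
  pn <- function(name) if (track_params) paste0(name, c(".W", ".b")) else NULL
  id <- tp_input(tp, zmat)
  tcol <- matrix(tvec, ncol = 1L)
  for (l in 1:4) {
    id <- tp_concat_const(tp, id, tcol)
    id <- tp_linear(tp, id, p[[sprintf("fc%d.W", l)]], p[[sprintf("fc%d.b", l)]],
                    pnames = pn(sprintf("fc%d", l)))
    if (l < 4L) id <- tp_relu(tp, id)
  }
  id <- tp_l2norm_rows(tp, id, eps = cfg$norm_epsilon)
  list(tape = tp, out = id)
}

#' Latent trajectory for one clip
#'
#' Maps the shared noise vector `z` and the timeline `T` through the four
#' concat-then-linear layers; each row is computed independently per frame and
#' normalised onto the unit hypersphere.
#'
#' @param plugin a `plugin_net`.
#' @param z numeric vector of length `z_dim` (shared across frames).
#' @param T strictly increasing 0-based frame indices.
#' @return matrix `(length(T), out_dim)`, rows unit-norm.
#' @export
plugin_forward <- function(plugin, z, T) {
  stopifnot(inherits(plugin, "plugin_net"))
  cfg <- plugin$config
  if (length(z) != cfg$z_dim) {
    stop_input("noise has length ", length(z), ", expected z_dim = ", cfg$z_dim)
  }
  T <- validate_timeline(T)
  n <- length(T)
  zmat <- matrix(rep(as.double(z), each = n), n, cfg$z_dim)
  fw <- plugin_forward_tape(plugin, zmat, encode_time(cfg, T),
                            track_params = FALSE)
  tp_value(fw$tape, fw$out)
}

#' Decode a latent trajectory into a video clip
#'
#' Frame `i` is the frozen generator applied to row `i` of the plugin's
#' trajectory; any clip length is supported since the plugin is a per-frame
#' map.
#'
#' @param plugin a `plugin_net`.
#' @param generator a trained, frozen `frame_generator`.
#' @param z shared noise vector of length `z_dim`.
#' @param T strictly increasing 0-based frame indices.
#' @param clip_id id recorded on the returned clip.
#' @return a [video_clip()] of `length(T)` frames at the generator's
#'   resolution.
#' @export
generate_video <- function(plugin, generator, z, T, clip_id = "generated") {
  stopifnot(inherits(plugin, "plugin_net"), inherits(generator, "frame_generator"))
  if (plugin$config$out_dim != generator$config$latent_dim) {
    stop_config("plugin out_dim (", plugin$config$out_dim,
                ") does not match generator latent_dim (",
                generator$config$latent_dim, ")")
  }
  if (!isTRUE(generator$trained)) {
    stop_config("generator must be trained before decoding trajectories")
  }
  T <- validate_timeline(T)
  traj <- plugin_forward(plugin, z, T)
  frames <- generate_frames(generator, traj)
  video_clip(frames, clip_id, frame_origin = as.integer(T[1]))
}
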