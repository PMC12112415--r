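# Run configuration: nested blocks mirroring the module configs, strict
# schema, YAML round trip, and cross-block consistency checks.

run_config_defaults <- function() {
  list(
    seed = 0L,
    output_dir = "runs",
    data = list(kind = "tunnel", resolution = 128L, n_frames = 16L,
                n_clips = 64L, motion_amplitude = 2, texture_detail = 2L,
                channels = 3L),
    frame_gan = list(latent_dim = 512L, max_resolution = 128L,
                     img_channels = 3L, fmap_base = 8192L, fmap_max = 512L,
                     feature_dim = 512L, gp_lambda = 10,
                     drift_epsilon = 1e-3, learning_rate = 1e-3, beta1 = 0,
                     beta2 = 0.99, steps_per_phase = 600L,
                     fade_fraction = 0.5, use_pixelnorm = TRUE,
                     use_eqlr = TRUE, use_mbstd = FALSE),
    plugin = list(z_dim = 2047L, layer_widths = c(1535L, 1023L, 511L, 512L),
                  time_encoding = "normalized_unit", n_ref = 8L,
                  norm_epsilon = 1e-8, out_dim = 512L),
    video_critic = list(n_frames = 8L, feature_dim = 512L),
    stage2 = list(learning_rate = 2e-4, beta1 = 0.5, beta2 = 0.999,
                  epochs = 50L, batch_clips = 8L, n_frames = 8L,
                  generator_loss_form = "non_saturating"),
    evaluation = list(n_clips = 4092L, clip_len = 16L, n_splits = 5L)
  )
}

# recursive merge with unknown-key rejection; `path` tracks the key path for
# error messages
merge_strict <- function(base, upd, path = character()) {
  if (is.null(upd)) return(base)
  if (!is.list(upd)) {
    stop_config("config block `", paste(path, collapse = "."),
                "` must be a mapping")
  }
  for (nm in names(upd)) {
    here <- c(path, nm)
    if (!nm %in% names(base)) {
      stop_config("unknown config key: ", paste(here, collapse = "."))
    }
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      base[[nm]] <- merge_strict(base[[nm]], upd[[nm]], here)
    } else {
      val <- upd[[nm]]
      if (is.list(val)) val <- unlist(val)
      tmpl <- base[[nm]]
      if (is.numeric(tmpl)) {
        coerced <- suppressWarnings(as.numeric(val))
        if (anyNA(coerced)) {
          stop_config("config key ", paste(here, collapse = "."),
                      " must be numeric, got `", paste(val, collapse = ","), "`")
        }
        val <- coerced
      }
      if (is.logical(tmpl)) {
        val <- as.logical(val)
        if (anyNA(val)) {
          stop_config("config key ", paste(here, collapse = "."),
                      " must be logical")
        }
      }
      if (is.integer(tmpl) && is.numeric(val)) val <- as.integer(val)
      base[[nm]] <- val
    }
  }
  base
}

# apply dotted-path overrides like list("frame_gan.latent_dim" = 64)
apply_overrides <- function(cfg, overrides) {
  for (key in names(overrides)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    upd <- overrides[[key]]
    for (p in rev(parts)) upd <- stats::setNames(list(upd), p)
    cfg <- merge_strict(cfg, upd)
  }
  cfg
}

validate_run_config <- function(cfg) {
  if (cfg$plugin$out_dim != cfg$frame_gan$latent_dim) {
    stop_config("inconsistent config: plugin.out_dim (", cfg$plugin$out_dim,
                ") must equal frame_gan.latent_dim (",
                cfg$frame_gan$latent_dim, ")")
  }
  if (cfg$video_critic$n_frames != cfg$stage2$n_frames) {
    stop_config("inconsistent config: video_critic.n_frames (",
                cfg$video_critic$n_frames, ") must equal stage2.n_frames (",
                cfg$stage2$n_frames, ")")
  }
  if (cfg$video_critic$feature_dim != cfg$frame_gan$feature_dim) {
    stop_config("inconsistent config: video_critic.feature_dim (",
                cfg$video_critic$feature_dim,
                ") must equal frame_gan.feature_dim (",
                cfg$frame_gan$feature_dim, ")")
  }
  if (cfg$data$resolution != cfg$frame_gan$max_resolution) {
    stop_config("inconsistent config: data.resolution (", cfg$data$resolution,
                ") must equal frame_gan.max_resolution (",
                cfg$frame_gan$max_resolution, ")")
  }
  if (cfg$data$channels != cfg$frame_gan$img_channels) {
    stop_config("inconsistent config: data.channels (", cfg$data$channels,
                ") must equal frame_gan.img_channels (",
                cfg$frame_gan$img_channels, ")")
  }
  # constructing the module configs runs their own validation
  block_frame_gan_config(cfg)
  block_plugin_config(cfg)
  block_video_critic_config(cfg)
  block_stage2_config(cfg)
  structure(cfg, class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Missing keys fall back to the reference defaults (the reference
#' architecture at full scale); unknown keys are rejected with their key
#' path. An empty file yields the full defaults.
#'
#' @param path YAML file path.
#' @return an object of class `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: ", path)
  resolve_config(file = path)
}

#' Resolve a run configuration (defaults <- file <- overrides)
#'
#' @param file optional YAML path merged over the defaults.
#' @param overrides named list of dotted-path overrides (e.g.
#'   `list("frame_gan.latent_dim" = 64)`), highest precedence.
#' @return validated `run_config`.
#' @export
resolve_config <- function(file = NULL, overrides = list()) {
  cfg <- run_config_defaults()
  if (!is.null(file)) {
    y <- yaml::read_yaml(file)
    cfg <- merge_strict(cfg, y)
  }
  cfg <- apply_overrides(cfg, overrides)
  validate_run_config(cfg)
}

#' Write a run configuration as YAML
#'
#' @param cfg a `run_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# ---- block -> module-config adapters ---------------------------------------

block_scene_spec <- function(cfg) {
  scene_spec(kind = cfg$data$kind, resolution = cfg$data$resolution,
             n_frames = cfg$data$n_frames,
             motion_amplitude = cfg$data$motion_amplitude,
             texture_detail = cfg$data$texture_detail,
             channels = cfg$data$channels)
}

block_frame_gan_config <- function(cfg) {
  b <- cfg$frame_gan
  frame_gan_config(latent_dim = b$latent_dim, max_resolution = b$max_resolution,
                   img_channels = b$img_channels, fmap_base = b$fmap_base,
                   fmap_max = b$fmap_max, feature_dim = b$feature_dim,
                   gp_lambda = b$gp_lambda, drift_epsilon = b$drift_epsilon,
                   learning_rate = b$learning_rate, beta1 = b$beta1,
                   beta2 = b$beta2, steps_per_phase = b$steps_per_phase,
                   fade_fraction = b$fade_fraction,
                   use_pixelnorm = b$use_pixelnorm, use_eqlr = b$use_eqlr,
                   use_mbstd = b$use_mbstd)
}

block_plugin_config <- function(cfg) {
  b <- cfg$plugin
  plugin_config(z_dim = b$z_dim, layer_widths = b$layer_widths,
                time_encoding = b$time_encoding, n_ref = b$n_ref,
                norm_epsilon = b$norm_epsilon, out_dim = b$out_dim)
}

block_video_critic_config <- function(cfg) {
  b <- cfg$video_critic
  video_critic_config(n_frames = b$n_frames, feature_dim = b$feature_dim)
}

block_stage2_config <- function(cfg) {
  b <- cfg$stage2
  stage2_config(learning_rate = b$learning_rate, beta1 = b$beta1,
                beta2 = b$beta2, epochs = b$epochs,
                batch_clips = b$batch_clips, n_frames = b$n_frames,
                generator_loss_form = b$generator_loss_form,
                seed = cfg$seed)
}

# JSON-lines training log
write_train_log <- function(history, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(history))) {
    writeLines(jsonlite::toJSON(as.list(history[i, ]), auto_unbox = TRUE,
                                digits = NA), con)
  }
  invisible(path)
}
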