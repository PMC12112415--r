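# Seeded synthetic video generators and PNG frame-directory I/O.
#
# These toy datasets emulate the two data regimes the method targets: generic
# object-motion clips (moving shapes over a textured background) and
# endoscopy-like footage (a tunnel fly-through with receding concentric rings,
# radial texture and slow camera drift). Both are deterministic functions of
# (spec, n_clips, seed), and both produce the temporal coherence — adjacent
# frames more alike than distant ones — that the trajectory plugin is meant
# to learn.

#' Scene specification for synthetic clips
#'
#' @param kind `"moving_shapes"` or `"tunnel"`.
#' @param resolution frame side length in pixels, a power of two >= 8.
#' @param n_frames frames per clip (>= 1).
#' @param motion_amplitude motion per frame in pixels (>= 0): shape speed for
#'   `moving_shapes`, forward camera speed for `tunnel`.
#' @param texture_detail non-negative integer; higher adds finer texture.
#' @param channels 1 (grayscale) or 3 (RGB).
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(kind = c("moving_shapes", "tunnel"),
                       resolution = 32L, n_frames = 16L,
                       motion_amplitude = 2, texture_detail = 2L,
                       channels = 3L) {
  kind <- match.arg(kind)
  chk <- function(ok, field, msg) {
    if (!ok) stop_config("invalid scene spec: field `", field, "` ", msg)
  }
  chk(is.numeric(resolution) && length(resolution) == 1L &&
        is.finite(resolution) && is_power_of_two(resolution) && resolution >= 8,
      "resolution", "must be a power of two >= 8")
  chk(is.numeric(n_frames) && length(n_frames) == 1L && is.finite(n_frames) &&
        n_frames >= 1, "n_frames", "must be an integer >= 1")
  chk(is.numeric(motion_amplitude) && length(motion_amplitude) == 1L &&
        is.finite(motion_amplitude) && motion_amplitude >= 0,
      "motion_amplitude", "must be a finite non-negative number")
  chk(is.numeric(texture_detail) && length(texture_detail) == 1L &&
        is.finite(texture_detail) && texture_detail >= 0,
      "texture_detail", "must be a non-negative integer")
  chk(length(channels) == 1L && channels %in% c(1, 3), "channels",
      "must be 1 or 3")
  structure(list(kind = kind, resolution = as.integer(resolution),
                 n_frames = as.integer(n_frames),
                 motion_amplitude = motion_amplitude,
                 texture_detail = as.integer(texture_detail),
                 channels = as.integer(channels)),
            class = "scene_spec")
}

#' Construct a video clip
#'
#' @param frames array `(n_frames, H, W, C)` with values in `[-1, 1]`.
#' @param clip_id character id.
#' @param frame_origin 0-based index of the first frame.
#' @return an object of class `video_clip`.
#' @export
video_clip <- function(frames, clip_id, frame_origin = 0L) {
  d <- dim(frames)
  if (length(d) != 4L) stop_input("frames must be a (n, H, W, C) array")
  if (any(!is.finite(frames))) stop_input("frames contain non-finite values")
  if (max(abs(frames)) > 1 + 1e-9) {
    stop_input("frame values must lie in [-1, 1]; observed range [",
               signif(min(frames), 4), ", ", signif(max(frames), 4), "]")
  }
  structure(list(frames = frames, clip_id = as.character(clip_id),
                 frame_origin = as.integer(frame_origin)),
            class = "video_clip")
}

#' @export
print.video_clip <- function(x, ...) {
  d <- dim(x$frames)
  cat("video clip `", x$clip_id, "`: ", d[1], " frames of ", d[2], "x", d[3],
      "x", d[4], ", values in [", signif(min(x$frames), 3), ", ",
      signif(max(x$frames), 3), "]\n", sep = "")
  invisible(x)
}

# fold a coordinate into [0, L] with reflection (triangle wave) — motion
# bounces off frame edges instead of wrapping, keeping frame-to-frame
# differences continuous
reflect_coord <- function(p, L) {
  m <- p %% (2 * L)
  L - abs(m - L)
}

# smooth per-clip background texture: a low-order sum of 2-D sinusoids with
# `detail` controlling the number (and frequency) of octaves
render_texture <- function(res, detail, rng_pars) {
  g <- seq(0, 1, length.out = res)
  X <- matrix(g, res, res)
  Y <- t(X)
  out <- matrix(0, res, res)
  n_oct <- max(1L, detail)
  for (k in seq_len(n_oct)) {
    p <- rng_pars[[k]]
    out <- out + (0.5^k) * sin(2 * pi * (p[1] * k * X + p[2] * k * Y) + p[3])
  }
  out / max(1, n_oct / 2)
}

texture_pars <- function(detail) {
  lapply(seq_len(max(1L, detail)), function(k) {
    c(stats::runif(1, 0.5, 2.5), stats::runif(1, 0.5, 2.5),
      stats::runif(1, 0, 2 * pi))
  })
}

#' Generate moving-shape clips
#'
#' Each clip shows two solid shapes (a disc and a square) translating at
#' `motion_amplitude` pixels per frame over a static textured background,
#' reflecting off the frame edges. Output is a deterministic function of
#' `(spec, n_clips, seed)`.
#'
#' @param spec a [scene_spec()] with `kind = "moving_shapes"`.
#' @param n_clips number of clips (>= 0).
#' @param seed integer seed.
#' @return list of [video_clip()] objects.
#' @export
generate_moving_shapes <- function(spec, n_clips, seed = 1L) {
  stopifnot(inherits(spec, "scene_spec"))
  if (n_clips < 0) stop_input("n_clips must be >= 0")
  lapply(seq_len(n_clips), function(ci) {
    with_seed(derive_seed(seed, 1000L + ci), {
      res <- spec$resolution
      bg <- 0.35 * render_texture(res, spec$texture_detail,
                                  texture_pars(spec$texture_detail)) - 0.25
      coords <- matrix(seq_len(res), res, res)
      X <- coords; Y <- t(coords)
      n_shapes <- 2L
      p0 <- matrix(stats::runif(n_shapes * 2, 1, res), n_shapes)
      ang <- stats::runif(n_shapes, 0, 2 * pi)
      vel <- spec$motion_amplitude * cbind(cos(ang), sin(ang))
      size <- stats::runif(n_shapes, res / 8, res / 4)
      shade <- stats::runif(n_shapes, 0.4, 0.95) *
        sample(c(-1, 1), n_shapes, replace = TRUE)
      col_w <- matrix(stats::runif(n_shapes * spec$channels, 0.5, 1), n_shapes)
      frames <- array(0, c(spec$n_frames, res, res, spec$channels))
      for (t in seq_len(spec$n_frames)) {
        base <- bg
        masks <- vector("list", n_shapes)
        for (s in seq_len(n_shapes)) {
          cx <- reflect_coord(p0[s, 1] + (t - 1) * vel[s, 1], res)
          cy <- reflect_coord(p0[s, 2] + (t - 1) * vel[s, 2], res)
          masks[[s]] <- if (s %% 2L == 1L) {
            (X - cx)^2 + (Y - cy)^2 <= size[s]^2
          } else {
            abs(X - cx) <= size[s] & abs(Y - cy) <= size[s]
          }
        }
        for (ch in seq_len(spec$channels)) {
          img <- base
          for (s in seq_len(n_shapes)) {
            img[masks[[s]]] <- shade[s] * col_w[s, ch]
          }
          frames[t, , , ch] <- pmax(-1, pmin(1, img))
        }
      }
      video_clip(frames, sprintf("shapes_%04d", ci - 1L))
    })
  })
}

#' Generate tunnel fly-through clips
#'
#' Emulates the temporal structure of endoscopic footage: concentric rings
#' receding toward a dark tunnel centre as the camera advances at
#' `motion_amplitude` per frame, with radial wall texture and a slow sinuous
#' drift of the tunnel axis. Deterministic in `(spec, n_clips, seed)`.
#'
#' @inheritParams generate_moving_shapes
#' @param spec a [scene_spec()] with `kind = "tunnel"`.
#' @return list of [video_clip()] objects.
#' @export
generate_tunnel <- function(spec, n_clips, seed = 1L) {
  stopifnot(inherits(spec, "scene_spec"))
  if (n_clips < 0) stop_input("n_clips must be >= 0")
  lapply(seq_len(n_clips), function(ci) {
    with_seed(derive_seed(seed, 2000L + ci), {
      res <- spec$resolution
      g <- seq(-1, 1, length.out = res)
      X <- matrix(g, res, res); Y <- t(X)
      ring_freq <- 3 + spec$texture_detail
      n_spokes <- 2L * (3L + spec$texture_detail)
      phase0 <- stats::runif(1, 0, 2 * pi)
      spoke_phase <- stats::runif(1, 0, 2 * pi)
      drift_amp <- stats::runif(1, 0.05, 0.2)
      drift_freq <- stats::runif(2, 0.2, 0.6)
      rot_speed <- stats::runif(1, -0.05, 0.05)
      speed <- 2 * pi * spec$motion_amplitude / res
      tint <- if (spec$channels == 3L) c(1, 0.55, 0.45) else 1
      frames <- array(0, c(spec$n_frames, res, res, spec$channels))
      for (t in seq_len(spec$n_frames)) {
        cx <- drift_amp * sin(drift_freq[1] * (t - 1) + phase0)
        cy <- drift_amp * cos(drift_freq[2] * (t - 1) + phase0 / 2)
        dx <- X - cx; dy <- Y - cy
        r <- sqrt(dx^2 + dy^2) + 1e-6
        theta <- atan2(dy, dx)
        rings <- sin(ring_freq * log(r) - speed * (t - 1) + phase0)
        spokes <- sin(n_spokes * (theta + rot_speed * (t - 1)) + spoke_phase)
        depth <- pmin(1, r)^0.7              # darker toward the tunnel centre
        img <- depth * (0.45 + 0.4 * rings + 0.2 * spokes * depth) - 0.55
        for (ch in seq_len(spec$channels)) {
          frames[t, , , ch] <- pmax(-1, pmin(1, (img + 0.35) * tint[ch] - 0.25))
        }
      }
      video_clip(frames, sprintf("tunnel_%04d", ci - 1L))
    })
  })
}

#' Generate clips of either kind according to the spec
#'
#' @param spec a [scene_spec()].
#' @inheritParams generate_moving_shapes
#' @return list of [video_clip()] objects.
#' @export
generate_clips <- function(spec, n_clips, seed = 1L) {
  switch(spec$kind,
         moving_shapes = generate_moving_shapes(spec, n_clips, seed),
         tunnel = generate_tunnel(spec, n_clips, seed))
}

#' Temporal coherence score of a clip
#'
#' Ratio of the mean absolute difference between adjacent frame pairs to the
#' mean absolute difference over an equal number of seeded random
#' non-adjacent pairs (`|i - j| >= 2`). Values below 1 indicate temporal
#' coherence; a clip of identical frames (0/0) scores exactly 1 by
#' convention.
#'
#' @param clip a [video_clip()] with at least 3 frames.
#' @param seed seed for the random pair sample.
#' @return a non-negative ratio.
#' @export
temporal_coherence_score <- function(clip, seed = 1L) {
  stopifnot(inherits(clip, "video_clip"))
  n <- dim(clip$frames)[1]
  if (n < 3L) stop_input("temporal_coherence_score needs >= 3 frames, got ", n)
  f <- clip$frames
  adj <- mean(vapply(seq_len(n - 1L), function(i) {
    mean(abs(f[i + 1L, , , ] - f[i, , , ]))
  }, 0))
  pairs <- which(outer(seq_len(n), seq_len(n),
                       function(i, j) j - i >= 2), arr.ind = TRUE)
  sel <- with_seed(derive_seed(seed, 7L), {
    sample.int(nrow(pairs), n - 1L, replace = nrow(pairs) < n - 1L)
  })
  nonadj <- mean(vapply(sel, function(k) {
    mean(abs(f[pairs[k, 2L], , , ] - f[pairs[k, 1L], , , ]))
  }, 0))
  if (adj == 0 && nonadj == 0) return(1)
  adj / nonadj
}

# ---- frame-directory I/O ----------------------------------------------------

#' Write clips as PNG frame directories
#'
#' Layout: `<path>/<clip_id>/frame_<00000>.png`, indices 0-padded to five
#' digits so lexicographic order equals temporal order. Values are mapped
#' linearly from `[-1, 1]` to 8-bit `[0, 255]` with round-half-even. A
#' `dataset.json` manifest (clip ids, frame counts, resolution, generator
#' spec, seed) is written alongside.
#'
#' @param clips list of [video_clip()] objects.
#' @param path target directory (created if missing).
#' @param spec,seed optional provenance recorded in the manifest.
#' @return `path`, invisibly.
#' @export
write_frame_dir <- function(clips, path, spec = NULL, seed = NULL) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (clip in clips) {
    stopifnot(inherits(clip, "video_clip"))
    cdir <- file.path(path, clip$clip_id)
    dir.create(cdir, showWarnings = FALSE)
    d <- dim(clip$frames)
    for (i in seq_len(d[1])) {
      img <- clip$frames[i, , , ]
      v <- round((img + 1) / 2 * 255) / 255   # round-half-even quantisation
      if (d[4] == 1L) dim(v) <- d[2:3] else dim(v) <- d[2:4]
      png::writePNG(v, file.path(cdir, sprintf("frame_%05d.png",
                                               clip$frame_origin + i - 1L)))
    }
  }
  manifest <- list(
    clips = lapply(clips, function(cl) {
      list(clip_id = cl$clip_id, n_frames = dim(cl$frames)[1],
           frame_origin = cl$frame_origin)
    }),
    resolution = if (length(clips)) dim(clips[[1]]$frames)[2] else NULL,
    channels = if (length(clips)) dim(clips[[1]]$frames)[4] else NULL,
    spec = if (!is.null(spec)) unclass(spec) else NULL,
    seed = seed,
    format = "plugingan/frame-dir",
    version = 1L)
  jsonlite::write_json(manifest, file.path(path, "dataset.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read clips from a PNG frame directory
#'
#' Inverse of [write_frame_dir()]; recovers values up to one 8-bit
#' quantisation step (2/255). Clip folders are taken in lexicographic order;
#' frames in zero-padded filename order.
#'
#' @param path directory containing `<clip_id>/frame_*.png` folders.
#' @return list of [video_clip()] objects (empty for an empty directory).
#' @export
read_frame_dir <- function(path) {
  if (!dir.exists(path)) stop_format("no such frame directory: ", path)
  cdirs <- sort(list.dirs(path, recursive = FALSE, full.names = TRUE))
  clips <- list()
  ref_shape <- NULL
  for (cdir in cdirs) {
    files <- sort(list.files(cdir, full.names = TRUE))
    if (length(files) == 0L) next
    ok <- grepl("^frame_[0-9]{5}\\.png$", basename(files))
    bad <- files[!ok]
    if (length(bad)) {
      stop_format("malformed frame filenames under ", cdir, ": ",
                  paste(basename(bad), collapse = ", "))
    }
    imgs <- lapply(files, function(fp) {
      v <- png::readPNG(fp)
      if (length(dim(v)) == 2L) dim(v) <- c(dim(v), 1L)
      if (dim(v)[3] == 4L) {
        stop_format("alpha channel not supported: ", fp)
      }
      v * 2 - 1
    })
    shapes <- vapply(imgs, function(im) paste(dim(im), collapse = "x"), "")
    if (length(unique(shapes)) != 1L) {
      stop_format("mixed frame shapes under ", cdir, ": ",
                  paste(basename(files)[!duplicated(shapes)], collapse = ", "))
    }
    if (is.null(ref_shape)) ref_shape <- shapes[1]
    if (shapes[1] != ref_shape) {
      stop_format("clip ", basename(cdir), " has frame shape ", shapes[1],
                  " but earlier clips have ", ref_shape)
    }
    d1 <- dim(imgs[[1]])
    frames <- array(0, c(length(imgs), d1))
    for (i in seq_along(imgs)) frames[i, , , ] <- imgs[[i]]
    origin <- as.integer(sub("^frame_([0-9]{5})\\.png$", "\\1",
                             basename(files)[1]))
    clips[[length(clips) + 1L]] <- video_clip(frames, basename(cdir), origin)
  }
  clips
}

#' Flatten clips into a frame dataset
#'
#' @param clips list of [video_clip()] objects with identical frame shapes.
#' @return an object of class `frame_dataset` with elements `images`
#'   (`(N, H, W, C)` array), `clip_id`, `frame_index`.
#' @export
as_frame_dataset <- function(clips) {
  if (length(clips) == 0L) stop_input("no clips supplied")
  shapes <- vapply(clips, function(cl) paste(dim(cl$frames)[-1], collapse = "x"), "")
  if (length(unique(shapes)) != 1L) {
    stop_input("clips have mixed frame shapes: ", paste(unique(shapes), collapse = " vs "))
  }
  ns <- vapply(clips, function(cl) dim(cl$frames)[1], 0L)
  d1 <- dim(clips[[1]]$frames)[-1]
  images <- array(0, c(sum(ns), d1))
  clip_id <- character(sum(ns)); frame_index <- integer(sum(ns))
  at <- 0L
  for (cl in clips) {
    n <- dim(cl$frames)[1]
    images[at + seq_len(n), , , ] <- cl$frames
    clip_id[at + seq_len(n)] <- cl$clip_id
    frame_index[at + seq_len(n)] <- cl$frame_origin + seq_len(n) - 1L
    at <- at + n
  }
  key <- paste(clip_id, frame_index)
  if (anyDuplicated(key)) {
    stop_input("duplicate (clip_id, frame_index) pairs in dataset")
  }
  structure(list(images = images, clip_id = clip_id,
                 frame_index = frame_index),
            class = "frame_dataset")
}
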