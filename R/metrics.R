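# Evaluation stack: Gaussian summaries, Frechet distance, FID/FVD over
# pluggable embedders, Inception Score, and the split evaluation protocol.

#' Fit a Gaussian summary to embedded features
#'
#' @param features numeric matrix `(N, F)`, `N >= 2`.
#' @return object of class `gaussian_summary` with `mean` (length `F`) and
#'   `covariance` (`F x F`, sample covariance with divisor `N - 1`,
#'   symmetric by construction).
#' @export
fit_gaussian <- function(features) {
  features <- as.matrix(features)
  if (nrow(features) < 2L) {
    stop_input("need at least 2 rows to fit a Gaussian summary, got ",
               nrow(features))
  }
  mu <- colMeans(features)
  S <- stats::cov(features)                 # divisor N - 1
  S <- (S + t(S)) / 2
  structure(list(mean = mu, covariance = S), class = "gaussian_summary")
}

# symmetric PSD square root by eigendecomposition with negative eigenvalues
# clipped at zero
sym_sqrtm <- function(S) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Frechet distance between two Gaussian summaries
#'
#' `||mu_A - mu_B||^2 + Tr(S_A + S_B - 2 (S_A S_B)^{1/2})`. The matrix square
#' root is taken via eigendecomposition of the symmetrised product
#' `sqrt(S_A) S_B sqrt(S_A)` (same trace, numerically real), negative
#' eigenvalues are clipped at zero, and the result is clamped at zero.
#'
#' @param A,B `gaussian_summary` objects of matching dimension.
#' @return non-negative real distance.
#' @export
frechet_distance <- function(A, B) {
  stopifnot(inherits(A, "gaussian_summary"), inherits(B, "gaussian_summary"))
  if (length(A$mean) != length(B$mean)) {
    stop_input("dimension mismatch: ", length(A$mean), " vs ", length(B$mean))
  }
  delta <- sum((A$mean - B$mean)^2)
  sA <- sym_sqrtm(A$covariance)
  M <- sA %*% B$covariance %*% sA
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  tr_sqrt <- sum(sqrt(pmax(ev, 0)))
  d <- delta + sum(diag(A$covariance)) + sum(diag(B$covariance)) - 2 * tr_sqrt
  max(d, 0)
}

# ---- embedders --------------------------------------------------------------

#' Construct an embedder
#'
#' An embedder is a deterministic map from frames (mode `"frame"`: array
#' `(N, H, W, C)` to an `(N, F)` matrix) or clips (mode `"clip"`: list of
#' [video_clip()] to an `(N, F)` matrix). External pretrained networks
#' (Inception, I3D) are supported only through precomputed feature files; the
#' built-in embedders keep everything runnable offline.
#'
#' @param name character label.
#' @param mode `"frame"` or `"clip"`.
#' @param dim output feature width.
#' @param embed the mapping function.
#' @param provenance one of `"builtin_critic"`, `"builtin_random_projection"`,
#'   `"external_feature_file"`.
#' @return object of class `embedder`.
#' @export
embedder <- function(name, mode = c("frame", "clip"), dim, embed,
                     provenance = "builtin_random_projection") {
  mode <- match.arg(mode)
  structure(list(name = name, mode = mode, dim = as.integer(dim),
                 embed = embed, provenance = provenance),
            class = "embedder")
}

#' Frame embedder backed by the trained frame critic
#'
#' Embeds frames as the critic's penultimate-layer features — the same
#' representation the video discriminator trains on.
#'
#' @param frame_critic a trained `frame_critic`.
#' @return a frame-mode [embedder()] of width `feature_dim`.
#' @export
make_critic_embedder <- function(frame_critic) {
  stopifnot(inherits(frame_critic, "frame_critic"))
  fc <- freeze_state(frame_critic)
  embedder(name = "frame_critic_features", mode = "frame",
           dim = fc$config$feature_dim,
           embed = function(frames) extract_features(fc, frames),
           provenance = "builtin_critic")
}

#' Seeded random-projection frame embedder
#'
#' Projects flattened frames through a fixed Gaussian matrix; deterministic
#' given `(input_shape, dim, seed)`.
#'
#' @param input_shape `c(H, W, C)` of the frames.
#' @param dim output width.
#' @param seed projection seed.
#' @return a frame-mode [embedder()].
#' @export
make_projection_embedder <- function(input_shape, dim = 64L, seed = 1L) {
  p <- prod(input_shape)
  P <- with_seed(seed, matrix(stats::rnorm(p * dim, sd = 1 / sqrt(p)), p, dim))
  embedder(name = sprintf("random_projection_%d", dim), mode = "frame",
           dim = dim,
           embed = function(frames) {
             d <- dim(frames)
             if (!identical(as.integer(d[-1]), as.integer(input_shape))) {
               stop_input("frames of shape (", paste(d[-1], collapse = ","),
                          ") do not match embedder input (",
                          paste(input_shape, collapse = ","), ")")
             }
             matrix(frames, d[1], p) %*% P
           })
}

#' Lift a frame embedder to clips by temporal pooling
#'
#' Clip embedding = per-frame embeddings mean-pooled over time, optionally
#' concatenated with the mean absolute temporal difference of those
#' embeddings (so frame order information survives the pooling).
#'
#' @param frame_embedder a frame-mode [embedder()].
#' @param temporal_diff include the temporal-difference half (doubles the
#'   output width).
#' @return a clip-mode [embedder()].
#' @export
make_clip_embedder <- function(frame_embedder, temporal_diff = TRUE) {
  stopifnot(inherits(frame_embedder, "embedder"),
            frame_embedder$mode == "frame")
  out_dim <- frame_embedder$dim * (1L + as.integer(temporal_diff))
  embedder(name = paste0(frame_embedder$name, "_clip"), mode = "clip",
           dim = out_dim, provenance = frame_embedder$provenance,
           embed = function(clips) {
             rows <- lapply(clips, function(cl) {
               fe <- frame_embedder$embed(cl$frames)
               pooled <- colMeans(fe)
               if (temporal_diff) {
                 dmat <- if (nrow(fe) > 1L) abs(diff(fe)) else fe * 0
                 c(pooled, colMeans(dmat))
               } else {
                 pooled
               }
             })
             do.call(rbind, rows)
           })
}

embed_set <- function(emb, x, expected_mode) {
  stopifnot(inherits(emb, "embedder"))
  if (emb$mode != expected_mode) {
    stop_config("embedder `", emb$name, "` has mode `", emb$mode,
                "` but a ", expected_mode, "-mode embedder is required")
  }
  if (expected_mode == "frame") {
    if (!is.array(x) || length(dim(x)) != 4L || dim(x)[1] < 1L) {
      stop_input("frame sets must be non-empty (N, H, W, C) arrays")
    }
  } else {
    if (!is.list(x) || length(x) < 1L) {
      stop_input("clip sets must be non-empty lists of video clips")
    }
  }
  emb$embed(x)
}

#' Frechet Inception Distance over a frame embedder
#'
#' Embeds both frame sets, fits Gaussian summaries, and returns their
#' Frechet distance.
#'
#' @param real_frames,fake_frames arrays `(N, H, W, C)`.
#' @param emb a frame-mode [embedder()].
#' @return non-negative real.
#' @export
fid <- function(real_frames, fake_frames, emb) {
  fr <- embed_set(emb, real_frames, "frame")
  ff <- embed_set(emb, fake_frames, "frame")
  frechet_distance(fit_gaussian(fr), fit_gaussian(ff))
}

#' Frechet Video Distance over a clip embedder
#'
#' @param real_clips,fake_clips lists of [video_clip()] objects.
#' @param emb a clip-mode [embedder()].
#' @return non-negative real.
#' @export
fvd <- function(real_clips, fake_clips, emb) {
  fr <- embed_set(emb, real_clips, "clip")
  ff <- embed_set(emb, fake_clips, "clip")
  frechet_distance(fit_gaussian(fr), fit_gaussian(ff))
}

#' Inception Score from class probabilities
#'
#' Splits the rows into `n_splits` contiguous parts; within each part
#' computes `exp(mean_i KL(p(y|x_i) || marginal))` with natural logarithms
#' and the convention `0 log 0 = 0`; returns the mean and standard deviation
#' over parts. Always lies in `[1, K]`.
#'
#' @param probs `(N, K)` matrix of row-stochastic class probabilities.
#' @param n_splits number of parts (`1 <= n_splits <= N`).
#' @return list with `mean` and `sd` (0 when `n_splits = 1`).
#' @export
inception_score <- function(probs, n_splits = 5L) {
  probs <- as.matrix(probs)
  N <- nrow(probs)
  if (n_splits < 1L || n_splits > N) {
    stop_input("n_splits must be between 1 and the number of rows")
  }
  if (any(probs < -1e-12) || any(probs > 1 + 1e-12)) {
    stop_input("class probabilities must lie in [0, 1]")
  }
  if (any(abs(rowSums(probs) - 1) > 1e-8)) {
    stop_input("class probability rows must sum to 1 (tolerance 1e-8)")
  }
  bounds <- floor(seq(0, N, length.out = n_splits + 1L))
  vals <- vapply(seq_len(n_splits), function(s) {
    rows <- (bounds[s] + 1L):bounds[s + 1L]
    p <- probs[rows, , drop = FALSE]
    m <- colMeans(p)
    lt <- p * (log(pmax(p, .Machine$double.xmin)) -
                 rep(log(pmax(m, .Machine$double.xmin)), each = nrow(p)))
    lt[p == 0] <- 0
    exp(mean(rowSums(lt)))
  }, 0)
  list(mean = mean(vals), sd = if (n_splits > 1L) stats::sd(vals) else 0)
}

#' Softmax classification head over an embedder
#'
#' A fixed, seeded linear head mapping embedded features to `K` class
#' probabilities, giving an offline stand-in for a pretrained classifier when
#' computing the Inception Score. Synthetic: its classes carry no semantic
#' labels.
#'
#' @param frame_embedder frame-mode [embedder()].
#' @param n_classes number of classes `K`.
#' @param seed head seed.
#' @return function mapping a frame array to an `(N, K)` probability matrix.
#' @export
make_class_prob_head <- function(frame_embedder, n_classes = 10L, seed = 1L) {
  W <- with_seed(seed, matrix(stats::rnorm(frame_embedder$dim * n_classes),
                              frame_embedder$dim, n_classes))
  function(frames) {
    fe <- embed_set(frame_embedder, frames, "frame")
    fe <- scale(fe)  # decorrelate scales so logits are O(1)
    fe[!is.finite(fe)] <- 0
    logits <- fe %*% (W / sqrt(nrow(W)))
    logits <- logits - apply(logits, 1L, max)
    e <- exp(logits)
    e / rowSums(e)
  }
}

# ---- feature files ----------------------------------------------------------

#' Write / read a precomputed feature matrix with a JSON sidecar
#'
#' Plain TSV matrix plus `<path>.json` naming the embedder (`name`, `mode`,
#' `dim`, `n`), the interchange format for features from external pretrained
#' embedders.
#'
#' @param features `(N, F)` matrix.
#' @param path TSV file path.
#' @param name embedder name recorded in the sidecar.
#' @param mode `"frame"` or `"clip"`.
#' @return `read_feature_file` returns the matrix with attributes `name` and
#'   `mode`.
#' @export
write_feature_file <- function(features, path, name, mode = "frame") {
  utils::write.table(features, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(list(name = name, mode = mode, dim = ncol(features),
                            n = nrow(features), format = "plugingan/features",
                            version = 1L),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_feature_file
#' @export
read_feature_file <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(side)) {
    stop_format("feature file or sidecar missing: ", path)
  }
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (!identical(meta$format, "plugingan/features")) {
    stop_format("not a feature file sidecar: ", side)
  }
  m <- as.matrix(utils::read.table(path, sep = "\t"))
  dimnames(m) <- NULL
  if (!identical(dim(m), as.integer(c(meta$n, meta$dim)))) {
    stop_format("feature file shape does not match its sidecar: ", path)
  }
  attr(m, "name") <- meta$name
  attr(m, "mode") <- meta$mode
  m
}

# ---- evaluation protocol ----------------------------------------------------

#' Full evaluation protocol for a fitted model
#'
#' Generates `n_clips` clips of `clip_len` frames, computes FVD once on
#' clips (real vs generated), then randomly partitions the frames into
#' `n_splits` disjoint parts and reports FID and Inception Scores as
#' mean +/- sd across parts. Embedders default to the backbone's frame
#' critic.
#'
#' @param fit a `plugin_gan_fit`.
#' @param real_clips list of [video_clip()] at the backbone resolution.
#' @param n_clips generated sample size.
#' @param clip_len generated clip length (default 16).
#' @param n_splits FID/IS split count (default 5).
#' @param seed seed for generation and partitioning.
#' @param frame_embedder optional frame-mode [embedder()].
#' @return list of class `evaluation_report` with fields `FVD`, `FID_mean`,
#'   `FID_sd`, `IS_fake_mean`, `IS_fake_sd`, `IS_real_mean`, `IS_real_sd`,
#'   plus the protocol settings.
#' @export
evaluation_protocol <- function(fit, real_clips, n_clips = 64L, clip_len = 16L,
                                n_splits = 5L, seed = 0L,
                                frame_embedder = NULL) {
  stopifnot(inherits(fit, "plugin_gan_fit"))
  if (!isTRUE(fit$plugin$trained %||% FALSE)) {
    stop_config("evaluation requires a trained fit (run train_stage2 first)")
  }
  fake_clips <- generate_clips_from_fit(fit, n_clips, clip_len,
                                        seed = derive_seed(seed, 21L))
  if (is.null(frame_embedder)) {
    frame_embedder <- make_critic_embedder(fit$backbone$critic)
  }
  clip_emb <- make_clip_embedder(frame_embedder)
  FVD <- fvd(real_clips, fake_clips, clip_emb)
  real_frames <- as_frame_dataset(real_clips)$images
  fake_frames <- as_frame_dataset(fake_clips)$images
  head_fn <- make_class_prob_head(frame_embedder, n_classes = 10L,
                                  seed = derive_seed(seed, 22L))
  part_of <- function(n) with_seed(derive_seed(seed, 23L), {
    sample(rep(seq_len(n_splits), length.out = n))
  })
  pr <- part_of(dim(real_frames)[1])
  pf <- part_of(dim(fake_frames)[1])
  fid_s <- is_f <- is_r <- numeric(n_splits)
  for (s in seq_len(n_splits)) {
    rs <- real_frames[pr == s, , , , drop = FALSE]
    fs <- fake_frames[pf == s, , , , drop = FALSE]
    fid_s[s] <- fid(rs, fs, frame_embedder)
    is_f[s] <- inception_score(head_fn(fs), n_splits = 1L)$mean
    is_r[s] <- inception_score(head_fn(rs), n_splits = 1L)$mean
  }
  structure(list(FVD = FVD,
                 FID_mean = mean(fid_s), FID_sd = stats::sd(fid_s),
                 IS_fake_mean = mean(is_f), IS_fake_sd = stats::sd(is_f),
                 IS_real_mean = mean(is_r), IS_real_sd = stats::sd(is_r),
                 n_clips = n_clips, clip_len = clip_len,
                 n_splits = n_splits, seed = seed,
                 embedder = frame_embedder$name),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Evaluation report (", x$n_clips, " clips x ", x$clip_len, " frames, ",
      x$n_splits, " splits, embedder `", x$embedder, "`)\n", sep = "")
  cat(sprintf("  FVD:      %.4f\n", x$FVD))
  cat(sprintf("  FID:      %.4f (+/- %.4f)\n", x$FID_mean, x$FID_sd))
  cat(sprintf("  IS fake:  %.4f (+/- %.4f)\n", x$IS_fake_mean, x$IS_fake_sd))
  cat(sprintf("  IS real:  %.4f (+/- %.4f)\n", x$IS_real_mean, x$IS_real_sd))
  invisible(x)
}

#' Write an evaluation report as JSON (plus optional CSV row)
#'
#' @param report an `evaluation_report`.
#' @param path JSON output path.
#' @param csv optional CSV path receiving the report as a single row.
#' @return `path`, invisibly.
#' @export
write_evaluation_report <- function(report, path, csv = NULL) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  if (!is.null(csv)) {
    utils::write.csv(as.data.frame(unclass(report)), csv, row.names = FALSE)
  }
  invisible(path)
}
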