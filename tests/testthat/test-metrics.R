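# Evaluation stack: Gaussian summaries, Frechet distance closed forms,
# FID/FVD invariances, Inception Score endpoints, and the split protocol.

gsum <- function(mu, S) structure(list(mean = mu, covariance = S),
                                  class = "gaussian_summary")

test_that("fit_gaussian returns the sample mean and N-1 covariance", {
  x <- matrix(c(0, 2), 2L, 1L)
  g <- fit_gaussian(x)
  expect_equal(g$mean, 1)
  expect_equal(g$covariance[1L, 1L], 2)  # ((0-1)^2 + (2-1)^2) / (2-1)
  same <- matrix(rep(c(1, 2, 3), each = 4L), 4L, 3L)
  g2 <- fit_gaussian(same)
  expect_equal(max(abs(g2$covariance)), 0)
  expect_equal(g2$mean, c(1, 2, 3))
  y <- matrix(rnorm(50), 10L, 5L)
  expect_equal(fit_gaussian(y)$mean, colMeans(y))
  expect_lt(max(abs(fit_gaussian(y)$covariance -
                      t(fit_gaussian(y)$covariance))), 1e-15)
  expect_error(fit_gaussian(matrix(1, 1L, 3L)), "2 rows")
})

test_that("frechet_distance matches its closed forms", {
  set.seed(5)
  A <- fit_gaussian(matrix(rnorm(80), 20L, 4L))
  expect_lt(frechet_distance(A, A), 1e-8)

  # 1-D unit variances shifted by 1
  expect_equal(frechet_distance(gsum(0, matrix(1)), gsum(1, matrix(1))), 1,
               tolerance = 1e-10)

  # 2-D diagonal case: 5 + (1-2)^2 + (2-1)^2 = 7
  d <- frechet_distance(gsum(c(0, 0), diag(c(1, 4))),
                        gsum(c(1, 2), diag(c(4, 1))))
  expect_equal(d, 7, tolerance = 1e-8)

  # symmetry
  B <- fit_gaussian(matrix(rnorm(80, sd = 2), 20L, 4L))
  expect_equal(frechet_distance(A, B), frechet_distance(B, A),
               tolerance = 1e-8)

  # commuting (diagonal) case agrees with sum (sqrt(a) - sqrt(b))^2 for
  # random diagonals — the eigendecomposition path against the closed form
  for (k in 1:10) {
    a <- runif(5, 0.1, 4); b <- runif(5, 0.1, 4)
    mu1 <- rnorm(5); mu2 <- rnorm(5)
    expect_equal(frechet_distance(gsum(mu1, diag(a)), gsum(mu2, diag(b))),
                 sum((mu1 - mu2)^2) + sum((sqrt(a) - sqrt(b))^2),
                 tolerance = 1e-8)
  }

  expect_error(frechet_distance(gsum(0, matrix(1)), gsum(c(0, 0), diag(2))),
               "dimension")
})

test_that("frechet_distance is nonnegative and zero only at identity", {
  set.seed(8)
  for (k in 1:10) {
    A <- fit_gaussian(matrix(rnorm(60), 12L, 5L))
    B <- fit_gaussian(matrix(rnorm(60, mean = 0.5), 12L, 5L))
    d <- frechet_distance(A, B)
    expect_gte(d, 0)
    expect_gt(d, 1e-6)  # distinct samples are nonzero apart
  }
})

test_that("fid and fvd are invariant to set order and common rotations", {
  set.seed(9)
  emb <- make_projection_embedder(c(8L, 8L, 1L), dim = 6L, seed = 2L)
  real <- array(tanh(rnorm(30 * 64)), c(30L, 8L, 8L, 1L))
  fake <- array(tanh(rnorm(30 * 64, sd = 0.5)), c(30L, 8L, 8L, 1L))
  d0 <- fid(real, fake, emb)
  expect_gt(d0, 0)
  expect_lt(fid(real, real, emb), 1e-6)
  perm <- sample(30L)
  expect_equal(fid(real[perm, , , , drop = FALSE],
                   fake[rev(perm), , , , drop = FALSE], emb), d0,
               tolerance = 1e-6)

  # rotation invariance of the Frechet distance on embedded features
  fr <- emb$embed(real); ff <- emb$embed(fake)
  Q <- qr.Q(qr(matrix(rnorm(36), 6L)))
  d_rot <- frechet_distance(fit_gaussian(fr %*% Q), fit_gaussian(ff %*% Q))
  expect_equal(d_rot, frechet_distance(fit_gaussian(fr), fit_gaussian(ff)),
               tolerance = 1e-6)

  # clip-level: same-generator sets are closer than cross-generator sets
  mspec <- scene_spec("moving_shapes", resolution = 16L, n_frames = 6L,
                      channels = 1L)
  tspec <- scene_spec("tunnel", resolution = 16L, n_frames = 6L, channels = 1L)
  m1 <- generate_moving_shapes(mspec, 12L, seed = 1L)
  m2 <- generate_moving_shapes(mspec, 12L, seed = 2L)
  t1 <- generate_tunnel(tspec, 12L, seed = 3L)
  cemb <- make_clip_embedder(make_projection_embedder(c(16L, 16L, 1L),
                                                      dim = 6L, seed = 4L))
  expect_identical(cemb$dim, 12L)
  d_same <- fvd(m1, m2, cemb)
  d_diff <- fvd(m1, t1, cemb)
  expect_lt(d_same, d_diff)
  expect_lt(fvd(m1, m1, cemb), 1e-6)

  expect_error(fid(real, fake, cemb), "mode")
  expect_error(fvd(m1, t1, emb), "mode")
})

test_that("inception score hits its analytic endpoints and stays in [1, K]", {
  # identical rows: KL = 0, IS = 1 exactly
  u <- matrix(1 / 4, 20L, 4L)
  expect_equal(inception_score(u, 5L)$mean, 1, tolerance = 1e-12)

  # balanced one-hot rows over K classes: IS = K exactly
  oh <- diag(4L)[rep(1:4, 5L), ]
  is_oh <- inception_score(oh, 1L)
  expect_equal(is_oh$mean, 4, tolerance = 1e-12)
  expect_identical(is_oh$sd, 0)

  # two-row case against a hand-computed oracle
  p <- rbind(c(0.9, 0.1), c(0.1, 0.9))
  m <- c(0.5, 0.5)
  kl <- mean(rowSums(p * log(p / rep(m, each = 2L))))
  expect_equal(inception_score(p, 1L)$mean, exp(kl), tolerance = 1e-10)
  expect_equal(inception_score(p, 1L)$mean, 1.44493, tolerance = 1e-4)

  # random stochastic rows stay within [1, K]
  set.seed(3)
  for (k in 1:10) {
    q <- matrix(rexp(60), 12L, 5L); q <- q / rowSums(q)
    v <- inception_score(q, 3L)$mean
    expect_gte(v, 1); expect_lte(v, 5)
  }

  expect_error(inception_score(matrix(c(0.5, 0.6), 1L, 2L), 1L), "sum to 1")
  expect_error(inception_score(u, 30L), "n_splits")
})

test_that("feature files round-trip with their sidecars", {
  x <- matrix(rnorm(40), 10L, 4L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_file(x, path, name = "ext_inception", mode = "frame")
  y <- read_feature_file(path)
  expect_equal(unclass(y)[seq_along(x)], as.numeric(x), tolerance = 1e-6)
  expect_identical(attr(y, "name"), "ext_inception")
  expect_identical(attr(y, "mode"), "frame")
  expect_error(read_feature_file(tempfile()), "missing")
})

test_that("the evaluation protocol emits the full report schema and is
           near zero on self-comparison", {
  bb <- tiny_backbone()
  fit <- fx("tiny_fit", function() {
    train_stage2(tiny_clips(), bb,
                 stage2_config(epochs = 2L, batch_clips = 2L, n_frames = 8L,
                               seed = 31L))
  })
  rep <- evaluation_protocol(fit, tiny_clips(), n_clips = 10L, clip_len = 10L,
                             n_splits = 3L, seed = 1L)
  need <- c("FVD", "FID_mean", "FID_sd", "IS_fake_mean", "IS_fake_sd",
            "IS_real_mean", "IS_real_sd")
  expect_true(all(need %in% names(rep)))
  expect_true(all(is.finite(unlist(rep[need]))))
  expect_gte(rep$FVD, 0)
  # deterministic
  rep2 <- evaluation_protocol(fit, tiny_clips(), n_clips = 10L,
                              clip_len = 10L, n_splits = 3L, seed = 1L)
  expect_equal(rep[need], rep2[need], tolerance = 1e-12)

  # real-vs-real: embed the real set against itself
  femb <- make_critic_embedder(bb$critic)
  frames <- as_frame_dataset(tiny_clips())$images
  expect_lt(fid(frames, frames, femb), 1e-6)
  cemb <- make_clip_embedder(femb)
  expect_lt(fvd(tiny_clips(), tiny_clips(), cemb), 1e-6)

  path <- withr::local_tempfile(fileext = ".json")
  write_evaluation_report(rep, path)
  got <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(got$FVD, rep$FVD, tolerance = 1e-9)
})
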