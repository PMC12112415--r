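# Synthetic video generators, temporal coherence, and frame-directory I/O.

test_that("generators are seeded, deterministic, and honour n_clips", {
  spec <- scene_spec("moving_shapes", resolution = 16L, n_frames = 6L,
                     motion_amplitude = 2, channels = 3L)
  expect_length(generate_moving_shapes(spec, 0L, seed = 5L), 0L)
  a <- generate_moving_shapes(spec, 4L, seed = 7L)
  b <- generate_moving_shapes(spec, 4L, seed = 7L)
  expect_length(a, 4L)
  expect_identical(a, b)
  expect_false(identical(a, generate_moving_shapes(spec, 4L, seed = 8L)))

  tspec <- scene_spec("tunnel", resolution = 16L, n_frames = 6L, channels = 1L)
  expect_length(generate_tunnel(tspec, 0L, seed = 1L), 0L)
  t1 <- generate_tunnel(tspec, 2L, seed = 3L)
  expect_identical(t1, generate_tunnel(tspec, 2L, seed = 3L))
  for (cl in c(a, t1)) {
    expect_true(all(abs(cl$frames) <= 1))
    expect_identical(dim(cl$frames)[1], 6L)
  }
})

test_that("invalid scene specs name the offending field", {
  expect_error(scene_spec(resolution = 12L), "resolution")
  expect_error(scene_spec(resolution = 4L), "resolution")
  expect_error(scene_spec(n_frames = 0L), "n_frames")
  expect_error(scene_spec(motion_amplitude = -1), "motion_amplitude")
  expect_error(scene_spec(channels = 2L), "channels")
  expect_error(scene_spec(motion_amplitude = Inf), "motion_amplitude")
})

test_that("generated clips of both kinds are temporally coherent", {
  mspec <- scene_spec("moving_shapes", resolution = 32L, n_frames = 8L,
                      motion_amplitude = 2, channels = 3L)
  for (cl in generate_moving_shapes(mspec, 8L, seed = 7L)) {
    expect_lt(temporal_coherence_score(cl, seed = 1L), 1)
  }
  tspec <- scene_spec("tunnel", resolution = 32L, n_frames = 16L, channels = 3L)
  for (cl in generate_tunnel(tspec, 8L, seed = 3L)) {
    expect_lt(temporal_coherence_score(cl, seed = 1L), 1)
  }
})

test_that("coherence score handles degenerate and i.i.d. clips as defined", {
  const <- video_clip(array(0.3, c(6L, 8L, 8L, 1L)), "const")
  expect_identical(temporal_coherence_score(const), 1)

  short <- video_clip(array(0, c(2L, 8L, 8L, 1L)), "short")
  expect_error(temporal_coherence_score(short), "3 frames")

  # i.i.d. noise: adjacent and non-adjacent differences share a distribution,
  # so the ratio concentrates near 1 (averaged over independent clips)
  scores <- vapply(1:20, function(s) {
    f <- withr::with_seed(s, array(stats::runif(10 * 16 * 16, -1, 1),
                                   c(10L, 16L, 16L, 1L)))
    temporal_coherence_score(video_clip(f, "noise"), seed = s)
  }, 0)
  expect_lt(abs(mean(scores) - 1), 0.05)

  # linear drift is coherent
  drift <- array(0, c(8L, 16L, 16L, 1L))
  for (t in 1:8) {
    img <- matrix(-0.5, 16L, 16L)
    img[, pmin(16L, t + 1:4)] <- 0.7
    drift[t, , , 1L] <- img
  }
  expect_lt(temporal_coherence_score(video_clip(drift, "drift")), 1)
})

test_that("frame-directory round trip preserves shapes, order, and values", {
  spec <- scene_spec("moving_shapes", resolution = 16L, n_frames = 5L,
                     channels = 3L)
  clips <- generate_moving_shapes(spec, 2L, seed = 9L)
  dir <- withr::local_tempdir()
  write_frame_dir(clips, dir, spec = spec, seed = 9L)
  expect_true(file.exists(file.path(dir, "dataset.json")))

  back <- read_frame_dir(dir)
  expect_length(back, 2L)
  for (i in 1:2) {
    expect_identical(back[[i]]$clip_id, clips[[i]]$clip_id)
    expect_identical(dim(back[[i]]$frames), dim(clips[[i]]$frames))
    expect_lt(max(abs(back[[i]]$frames - clips[[i]]$frames)), 2 / 255 + 1e-12)
  }

  # extreme values survive within one 8-bit quantisation step
  ext <- video_clip(array(rep(c(-1, 1), each = 32L), c(1L, 8L, 8L, 1L)), "ext")
  write_frame_dir(list(ext), file.path(dir, "ext"))
  got <- read_frame_dir(file.path(dir, "ext"))[[1L]]
  expect_lt(max(abs(got$frames - ext$frames)), 2 / 255 + 1e-12)
  expect_identical(max(got$frames), 1)
  expect_identical(min(got$frames), -1)
})

test_that("reading empty or malformed directories behaves as specified", {
  dir <- withr::local_tempdir()
  expect_length(read_frame_dir(dir), 0L)
  expect_error(read_frame_dir(file.path(dir, "nope")), "no such")

  cdir <- file.path(dir, "clip_a")
  dir.create(cdir)
  png::writePNG(matrix(0.5, 4, 4), file.path(cdir, "frame_00000.png"))
  png::writePNG(matrix(0.5, 4, 4), file.path(cdir, "img1.png"))
  expect_error(read_frame_dir(dir), "img1.png")

  unlink(file.path(cdir, "img1.png"))
  png::writePNG(matrix(0.5, 6, 6), file.path(cdir, "frame_00001.png"))
  expect_error(read_frame_dir(dir), "mixed frame shapes")
})

test_that("frame datasets flatten clips with unique frame keys", {
  clips <- tiny_clips()
  ds <- as_frame_dataset(clips)
  expect_s3_class(ds, "frame_dataset")
  expect_identical(dim(ds$images)[1], sum(vapply(clips, function(cl)
    dim(cl$frames)[1], 0L)))
  expect_false(anyDuplicated(paste(ds$clip_id, ds$frame_index)) > 0)
  expect_error(as_frame_dataset(list()), "no clips")
  mixed <- c(clips[1], list(video_clip(array(0, c(2L, 16L, 16L, 1L)), "x")))
  expect_error(as_frame_dataset(mixed), "mixed")
})

test_that("video clips validate their range and shape", {
  expect_error(video_clip(array(2, c(2L, 4L, 4L, 1L)), "x"), "\\[-1, 1\\]")
  expect_error(video_clip(matrix(0, 2, 2), "x"), "array")
  expect_error(video_clip(array(NaN, c(1L, 4L, 4L, 1L)), "x"), "non-finite")
})
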