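test_that("constant frames interpolate to constant surfaces", {
  surf <- interpolate_frame(matrix(5, 3, 4), n = 50)
  expect_equal(range(surf$m), c(5, 5))
})

test_that("the surface reproduces node values exactly", {
  set.seed(2)
  f <- matrix(rnorm(12), 3, 4)
  fp <- footprint_spec(2, 3)
  xs <- seq(0, fp$width, length.out = 3)
  ys <- seq(0, fp$length, length.out = 4)
  for (i in 1:3) for (j in 1:4)
    expect_equal(interp_frame_at(f, fp, xs[i], ys[j]), f[i, j],
                 tolerance = 1e-14)
})

test_that("interpolation matches the brute-force bilinear oracle", {
  set.seed(3)
  f <- matrix(rnorm(12), 3, 4)
  fp <- footprint_spec(1.4, 2.2)
  x <- runif(100, 0, fp$width)
  y <- runif(100, 0, fp$length)
  got <- interp_frame_at(f, fp, x, y)
  want <- vapply(seq_along(x), function(k)
    oracle_bilinear(f, fp$width, fp$length, x[k], y[k]), numeric(1))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("interpolation agrees with an established implementation", {
  skip_if_not_installed("pracma")
  set.seed(4)
  f <- matrix(rnorm(12), 3, 4)
  fp <- footprint_spec()
  x <- runif(60); y <- runif(60)
  ref <- pracma::interp2(seq(0, 1, length.out = 3),
                         seq(0, 1, length.out = 4), t(f), x, y)
  expect_equal(interp_frame_at(f, fp, x, y), ref, tolerance = 1e-12)
})

test_that("bilinear values stay inside the node range", {
  set.seed(5)
  for (rep in 1:10) {
    f <- matrix(rnorm(12), 3, 4)
    surf <- interpolate_frame(f, n = 40)
    expect_gte(min(surf$m), min(f) - 1e-12)
    expect_lte(max(surf$m), max(f) + 1e-12)
  }
})

test_that("non-finite frames are rejected", {
  f <- matrix(1, 3, 4); f[2, 2] <- NA
  expect_error(interpolate_frame(f, 10), "finite")
  expect_error(interpolate_frame(matrix(1, 3, 4), n = 3), "N must be")
})

test_that("volume of a constant surface is height times area", {
  fp <- footprint_spec(2, 5)
  surf <- interpolate_frame(matrix(3, 3, 4), n = 100, footprint = fp)
  expect_equal(frame_volume(surf), 3 * 10, tolerance = 1e-9)
})

test_that("the volume functional is linear in the frame", {
  set.seed(6)
  f <- matrix(rnorm(12), 3, 4)
  g <- matrix(rnorm(12), 3, 4)
  v <- function(fr) frame_volume(interpolate_frame(fr, n = 80))
  expect_equal(v(2 * f + 3 * g), 2 * v(f) + 3 * v(g), tolerance = 1e-9)
})

test_that("the volume is stable across grid sizes", {
  set.seed(7)
  for (rep in 1:5) {
    # random positive frames, as for physical contact pressures;
    # near-zero-mean frames make the relative bound ill-posed
    f <- matrix(rnorm(12, mean = 5), 3, 4)
    v200 <- frame_volume(interpolate_frame(f, n = 200))
    v500 <- frame_volume(interpolate_frame(f, n = 500))
    v1000 <- frame_volume(interpolate_frame(f, n = 1000))
    expect_lt(abs(v200 - v1000) / max(abs(v1000), 1e-12), 0.01)
    expect_lt(abs(v500 - v1000) / max(abs(v1000), 1e-12), 0.01)
  }
})

test_that("regional weights match explicit surface integration", {
  set.seed(8)
  lay <- channel_layout()
  fp <- footprint_spec(1.3, 0.8)
  n <- 60
  w <- channel_weights(lay, n, fp)
  rec <- array_recording(matrix(rnorm(5 * 12), 5, 12), fs = 100)
  bands <- list(RP = 1:20, IP = 21:40, UP = 41:60)
  for (i in 1:5) {
    f <- array_frame(rec, i)
    m <- interpolate_frame(f, n, fp)$m
    for (g in names(bands)) {
      explicit <- mean(m[bands[[g]], ]) * fp$a_total
      via_w <- fp$a_total * sum(w[g, ] * rec$samples[i, ])
      expect_equal(via_w, explicit, tolerance = 1e-10)
    }
    expect_equal(fp$a_total * sum(w["mean", ] * rec$samples[i, ]),
                 frame_volume(interpolate_frame(f, n, fp)),
                 tolerance = 1e-10)
  }
})

test_that("constant frames give a constant volume series", {
  rec <- array_recording(matrix(2, 50, 12), fs = 100)
  vs <- group_volume_series(rec, "mean", 1:50, n = 30)
  expect_equal(range(vs$values), c(2, 2), tolerance = 1e-12)
  one <- group_volume_series(rec, "RP", 25, n = 30)
  expect_length(one$values, 1)
  expect_equal(one$values, vs$values[25], tolerance = 1e-12)
})

test_that("passage volumes average to the mean volume", {
  set.seed(9)
  rec <- array_recording(matrix(rnorm(20 * 12, mean = 5), 20, 12), fs = 100)
  n <- 200
  v <- lapply(c("RP", "IP", "UP", "mean"), function(g)
    group_volume_series(rec, g, 1:20, n = n)$values)
  avg <- (v[[1]] + v[[2]] + v[[3]]) / 3
  expect_lt(max(abs(avg - v[[4]]) / abs(v[[4]])), 0.01)
})

test_that("empty or out-of-range windows are rejected", {
  rec <- array_recording(matrix(1, 10, 12), fs = 100)
  expect_error(group_volume_series(rec, "RP", integer(0), n = 10), "empty")
  expect_error(group_volume_series(rec, "RP", 5:15, n = 10), "outside")
  expect_error(group_volume_series(rec, "XX", 1:5, n = 10), "unknown group")
})

test_that("the reference channel is the strongest segmentable one", {
  sim <- simulate_recording(clean_sim_config(seed = 4), "ref")
  rec <- sim$recording
  rec$samples[, 5] <- rec$samples[, 5] * 10
  segs <- lapply(1:12, function(ch)
    suppressWarnings(segment_beats(rec$samples[, ch], 100)))
  expect_equal(reference_channel(rec, segs), 5)

  flat <- rec
  flat$samples[, 5] <- 0
  segs2 <- lapply(1:12, function(ch)
    suppressWarnings(segment_beats(flat$samples[, ch], 100)))
  expect_false(reference_channel(flat, segs2) == 5)

  same <- array_recording(matrix(rep(rec$samples[, 1], 12), ncol = 12),
                          fs = 100)
  segs3 <- lapply(1:12, function(ch) segment_beats(same$samples[, ch], 100))
  expect_equal(reference_channel(same, segs3), 1)
})

test_that("separable recordings recover the beat's amplitude ratios", {
  sep <- make_separable_recording()
  feats <- extract_apv_features(sep$recording, sep$window, n = 200)
  fid <- detect_fiducials(sep$beat, 100)
  want_h3 <- fid$h3 / fid$h1
  want_h4 <- fid$h4 / fid$h1
  for (g in c("RP", "IP", "UP", "mean")) {
    got3 <- feats$value[feats$passage == g & feats$parameter == "APV_h3/h1"]
    got4 <- feats$value[feats$passage == g & feats$parameter == "APV_h4/h1"]
    expect_equal(got3, want_h3, tolerance = 1e-6)
    expect_equal(got4, want_h4, tolerance = 1e-6)
  }
})

test_that("rescaling the recording scales volumes and fixes ratios", {
  sep <- make_separable_recording()
  f1 <- extract_apv_features(sep$recording, sep$window, n = 100)
  rec2 <- sep$recording
  rec2$samples <- rec2$samples * 3.7
  f2 <- extract_apv_features(rec2, sep$window, n = 100)
  amps <- grepl("^APV_h[0-9]$", f1$parameter)
  expect_equal(f2$value[amps], 3.7 * f1$value[amps], tolerance = 1e-9)
  expect_equal(f2$value[!amps], f1$value[!amps], tolerance = 1e-9)
})

test_that("time-constant frames give zero APV amplitudes", {
  set.seed(10)
  rec <- array_recording(matrix(rep(rnorm(12, 5), each = 60), 60, 12),
                         fs = 100)
  feats <- extract_apv_features(rec, 1:60, n = 20)
  amps <- grepl("^APV_h[0-9]$", feats$parameter)
  expect_true(all(feats$value[amps] == 0))
  expect_true(all(is.na(feats$value[!amps])))
})

test_that("a beat without a dicrotic wave yields APV_h5 = 0", {
  tt <- (0:79) / 80
  beat <- exp(-((tt - 0.15) / 0.05)^2 / 2)
  beat <- beat - seq(beat[1], beat[1], length.out = 80)
  rec <- array_recording(outer(rep(beat, 3), rep(1, 12)), fs = 100)
  feats <- extract_apv_features(rec, 1:80, n = 50)
  h5 <- feats$value[feats$parameter == "APV_h5"]
  expect_true(all(h5 == 0))
  expect_true(all(feats$value[feats$parameter == "APV_h5/h1"] == 0))
  expect_true(all(is.na(feats$value[feats$parameter == "APV_h3"])))
})
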