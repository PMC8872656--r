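test_that("segmentation finds every beat of a clean constant-rate train", {
  sim <- simulate_recording(clean_sim_config(bpm = 72), "seg")
  ch <- which.max(sim$truth$gains)
  seg <- segment_beats(sim$recording$samples[, ch], 100)
  expect_true(abs(length(seg) - 36) <= 1)
  # detected feet sit on the generated onsets
  near <- vapply(seg, function(o) min(abs(o - sim$truth$onsets)), numeric(1))
  expect_lte(max(near), 2)
})

test_that("degenerate signals give an empty segmentation with a warning", {
  expect_warning(s <- segment_beats(rep(1, 1000), 100), "no beats")
  expect_length(s, 0)
  expect_warning(s2 <- segment_beats(seq(1, 0, length.out = 500), 100),
                 "no beats")
  expect_length(s2, 0)
})

test_that("a single beat is segmented at its foot", {
  beat <- as.numeric(simulate_beat(beat_model(), 0.8, 100))
  x <- c(rep(0, 50), beat, rep(0, 50))
  seg <- segment_beats(x, 100)
  expect_gte(length(seg), 1)
  expect_lte(abs(seg[1] - 51), 2)
})

seg_from_onsets <- function(onsets, fs = 100) {
  structure(as.integer(onsets), fs = fs, class = "beat_segmentation")
}

test_that("the APW of identical beats reproduces the beat", {
  beat <- as.numeric(simulate_beat(beat_model(), 0.8, 100))
  x <- rep(beat, 5)
  seg <- seg_from_onsets(1 + length(beat) * (0:4))
  apw <- compute_apw(x, seg)
  expect_equal(as.numeric(apw), beat, tolerance = 1e-12)
  expect_equal(attr(apw, "n_beats"), 4)
})

test_that("the APW is the pointwise mean of scaled beats", {
  beat <- as.numeric(simulate_beat(beat_model(), 0.8, 100))
  x <- c(beat, 2 * beat, beat)
  seg <- seg_from_onsets(1 + length(beat) * (0:2))
  apw <- compute_apw(x, seg)
  expect_equal(as.numeric(apw), 1.5 * beat, tolerance = 1e-12)
})

test_that("beats of different lengths are averaged at the median length", {
  b80 <- sin(pi * (0:79) / 79)
  b120 <- sin(pi * (0:119) / 119)
  x <- c(b80, b120, rep(0, 10))
  seg <- seg_from_onsets(c(1, 81, 201))
  apw <- compute_apw(x, seg)
  expect_length(apw, 100)
  # oracle: resample both halves to 100 samples and average
  res <- function(v) approx(seq(0, 1, length.out = length(v)), v,
                            xout = seq(0, 1, length.out = 100))$y
  expect_equal(as.numeric(apw), (res(b80) + res(b120)) / 2,
               tolerance = 1e-12)
  expect_error(compute_apw(x, seg_from_onsets(c(1, 81))),
               "insufficient data")
})

test_that("MRPW of identical beats is the first with CC = 1", {
  beat <- as.numeric(simulate_beat(beat_model(), 0.8, 100))
  x <- rep(beat, 5)
  seg <- seg_from_onsets(1 + length(beat) * (0:4))
  apw <- compute_apw(x, seg)
  sel <- select_mrpw(x, seg, apw)
  expect_equal(sel$cc, 1, tolerance = 1e-12)
  expect_equal(sel$beat_index, 1)
  expect_equal(sel$mrpw, beat)
})

test_that("the noise-corrupted beat is never the MRPW", {
  set.seed(5)
  beat <- as.numeric(simulate_beat(beat_model(), 0.8, 100))
  beats <- replicate(6, beat, simplify = FALSE)
  beats[[3]] <- beat + rnorm(length(beat), 0, 0.5)
  x <- unlist(beats)
  seg <- seg_from_onsets(1 + length(beat) * (0:6))
  sel <- select_mrpw(x, seg, compute_apw(x, seg))
  expect_false(sel$beat_index == 3)
  expect_gte(sel$cc, mean(sel$cc_all))
})

test_that("CC is invariant to positive affine rescaling of a beat", {
  beat <- as.numeric(simulate_beat(beat_model(), 0.8, 100))
  x1 <- rep(beat, 3)
  x2 <- c(beat, 2.5 * beat + 7, beat)
  seg <- seg_from_onsets(1 + length(beat) * (0:3))
  apw <- compute_apw(x1, seg)
  cc1 <- select_mrpw(x1, seg, apw)$cc_all
  cc2 <- select_mrpw(x2, seg, apw)$cc_all
  expect_equal(cc1, cc2, tolerance = 1e-9)
})

test_that("the APW of a noiseless periodic recording matches its beats", {
  sim <- simulate_recording(clean_sim_config(bpm = 72, seed = 2), "cc")
  ch <- which.max(sim$truth$gains)
  x <- sim$recording$samples[, ch]
  seg <- segment_beats(x, 100)
  apw <- compute_apw(x, seg)
  sel <- select_mrpw(x, seg, apw)
  expect_gte(sel$cc, 0.999)
})

test_that("h1 is the global maximum relative to the onset", {
  beat <- as.numeric(simulate_beat(beat_model(), 0.9, 100)) + 0.3
  fid <- detect_fiducials(beat, 100)
  expect_equal(fid$h1, max(beat) - beat[1], tolerance = 1e-12)
  expect_equal(fid$t_h1, (which.max(beat) - 1) / 100)
})

test_that("fiducial ordering and sign invariants hold across the model space", {
  set.seed(31)
  for (rep in 1:25) {
    m <- beat_model(
      percussion = list(amp = 1, center = runif(1, 0.10, 0.18),
                        width_l = runif(1, 0.04, 0.07),
                        width_r = runif(1, 0.16, 0.34)),
      tidal = list(amp = runif(1, 0.05, 0.6),
                   center = runif(1, 0.26, 0.36), width_l = 0.07),
      dicrotic = list(amp = runif(1, 0.2, 0.9),
                      center = runif(1, 0.5, 0.66), width_l = 0.10))
    beat <- as.numeric(simulate_beat(m, runif(1, 0.6, 1.0), 100))
    fid <- detect_fiducials(beat, 100)
    expect_gt(fid$h1, 0)
    expect_true(fid$t_h1 < fid$t_h4)
    if (!is.na(fid$t_h3))
      expect_true(fid$t_h1 < fid$t_h3 && fid$t_h3 < fid$t_h4)
    if (fid$h5_present)
      expect_true(fid$t_h4 < fid$t_h5 && fid$t_h5 < fid$t)
    if (!is.na(fid$h3)) {
      expect_lte(fid$h3, fid$h1 + 1e-12)
      expect_lte(fid$h4, fid$h3 + 1e-12)
    }
    expect_equal(fid$t4 + fid$t5, fid$t, tolerance = 1e-12)
    expect_true(fid$w > 0 && fid$w < fid$t)
  }
})

test_that("a single-lobe beat flags the tidal and dicrotic waves absent", {
  tt <- (0:99) / 100
  beat <- exp(-((tt - 0.15) / 0.05)^2 / 2)   # lone Gaussian, monotone decay
  fid <- detect_fiducials(beat, 100)
  expect_identical(fid$h3_mode, "absent")
  expect_false(fid$h5_present)
  expect_identical(fid$h5, 0)
})

test_that("degenerate beats are rejected", {
  expect_error(detect_fiducials(seq(1, 0, length.out = 50), 100),
               "degenerate beat")
  expect_error(detect_fiducials(rep(0, 50), 100), "degenerate beat")
})

test_that("width at 2/3 level matches the analytic triangle value", {
  fs <- 100
  up <- seq(0, 1, length.out = 31)             # rise 0..0.3 s
  down <- seq(1, 0, length.out = 71)[-1]       # fall 0.3..1.0 s
  beat <- c(up, down)
  w <- width_at_fraction(beat, 2 / 3, fs)
  expect_equal(w, 1 / 3, tolerance = 1e-9)     # crossings at 0.2 and 0.5333 s
})

test_that("width of a rectangular pulse is its duration", {
  beat <- c(rep(0, 20), rep(1, 30), rep(0, 50))
  w <- width_at_fraction(beat, 2 / 3, 100)
  expect_lt(abs(w - 0.30), 0.0101)             # within one sample spacing
})

test_that("width is non-increasing in the level fraction", {
  beat <- as.numeric(simulate_beat(beat_model(), 0.8, 100))
  levels <- c(0.1, 0.3, 0.5, 2 / 3, 0.9, 0.999)
  ws <- vapply(levels, function(l) width_at_fraction(beat, l, 100),
               numeric(1))
  expect_true(all(diff(ws) <= 1e-12))
  expect_lt(ws[length(ws)], 0.05)
})
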