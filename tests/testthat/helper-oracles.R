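# Independent oracles and small fixture builders used across the suite.

# Brute-force bilinear interpolation at a single point: explicit cell
# search and the closed-form corner blend, written independently of the
# package's vectorised evaluator.
oracle_bilinear <- function(frame, width, length_, x, y) {
  xs <- seq(0, width, length.out = 3)
  ys <- seq(0, length_, length.out = 4)
  i <- 1
  while (i < 2 && x > xs[i + 1]) i <- i + 1
  j <- 1
  while (j < 3 && y > ys[j + 1]) j <- j + 1
  u <- (x - xs[i]) / (xs[i + 1] - xs[i])
  v <- (y - ys[j]) / (ys[j + 1] - ys[j])
  (1 - u) * (1 - v) * frame[i, j] + u * (1 - v) * frame[i + 1, j] +
    (1 - u) * v * frame[i, j + 1] + u * v * frame[i + 1, j + 1]
}

# Exact two-sided Mann-Whitney p by full enumeration of all
# choose(nx+ny, nx) assignments of ranks to the first sample.
oracle_mw_exact <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(nx + ny, nx)
  u_all <- apply(combs, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  mu <- nx * ny / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu))
}

# A separable noiseless recording: every channel is its spatial gain
# times one repeated beat, no drift/noise. Returns the recording plus
# the single-beat template and the first full beat window.
make_separable_recording <- function(model = beat_model(),
                                     gains = seq(0.4, 1.5, length.out = 12),
                                     period = 60 / 72, fs = 100,
                                     duration = 30) {
  beat <- as.numeric(simulate_beat(model, period, fs))
  n <- round(duration * fs)
  train <- rep(beat, ceiling(n / length(beat)) + 1)[seq_len(n)]
  rec <- array_recording(outer(train, gains), fs = fs,
                         subject_id = "separable", group = "unknown")
  list(recording = rec, beat = beat,
       window = seq_len(length(beat)) + 10 * length(beat))
}

# Noiseless constant-rate simulation config (no drift, powerline, noise).
clean_sim_config <- function(bpm = 72, seed = 1, ...) {
  simulation_config(hr_mean = bpm, hr_sd = 0, noise_sd = 0,
                    drift_amp = 0, powerline_amp = 0, seed = seed, ...)
}
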