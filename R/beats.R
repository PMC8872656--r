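#' Segment a pulse signal into beats
#'
#' Beat onsets (feet) are located as the local minimum immediately
#' preceding each systolic upstroke. Upstrokes are found where the
#' first difference exceeds an adaptive threshold (a fraction of a high
#' quantile of the positive slopes); candidate onsets closer together
#' than the fastest admissible beat are merged, keeping the deeper foot.
#'
#' @param x numeric vector, one filtered channel.
#' @param fs sampling rate, Hz.
#' @param min_hr,max_hr admissible beat rate bounds, bpm.
#' @return Integer vector of onset sample indices (possibly empty, with
#'   a warning when no beats are found), of class `beat_segmentation`
#'   with attribute `fs`.
#' @export
segment_beats <- function(x, fs, min_hr = 40, max_hr = 180) {
  stopifnot(fs > 0, min_hr > 0, min_hr < max_hr)
  empty <- structure(integer(0), fs = fs, class = "beat_segmentation")
  if (length(x) < 2 || stats::sd(x) == 0) {
    warning("no beats found: signal is constant or too short")
    return(empty)
  }
  d <- diff(x)
  pos <- d[d > 0]
  if (!length(pos)) {
    warning("no beats found: signal has no rising segments")
    return(empty)
  }
  thr <- 0.5 * stats::quantile(pos, 0.95, names = FALSE)
  min_gap <- round(60 / max_hr * fs)   # fastest admissible beat, samples
  up <- which(d > thr)
  if (!length(up)) {
    warning("no beats found: no upstroke exceeds the slope threshold")
    return(empty)
  }
  # keep the first sample of each upstroke run separated by >= min_gap
  starts <- up[c(TRUE, diff(up) > min_gap)]
  onsets <- vapply(starts, function(i) {
    j <- i
    while (j > 1 && x[j - 1] < x[j]) j <- j - 1L
    j
  }, integer(1))
  onsets <- unique(onsets)
  # enforce refractory spacing on the feet themselves
  if (length(onsets) > 1) {
    keep <- onsets[1]
    for (o in onsets[-1]) {
      if (o - keep[length(keep)] >= min_gap) keep <- c(keep, o)
      else if (x[o] < x[keep[length(keep)]]) keep[length(keep)] <- o
    }
    onsets <- keep
  }
  structure(as.integer(onsets), fs = fs, class = "beat_segmentation")
}

# Complete beats = consecutive onset pairs whose spacing lies inside the
# admissible beat-period range.
beat_windows <- function(onsets, fs, min_hr = 40, max_hr = 180) {
  if (length(onsets) < 2) return(NULL)
  len <- diff(onsets)
  ok <- len >= 60 / max_hr * fs & len <= 60 / min_hr * fs
  if (!any(ok)) return(NULL)
  cbind(start = onsets[-length(onsets)][ok], end = onsets[-1][ok] - 1L)
}

#' Average pulse wave (APW) of one channel
#'
#' Every complete beat is resampled by linear interpolation to the median
#' beat length and the resampled beats are averaged pointwise. The APW is
#' the per-channel ensemble template against which individual beats are
#' matched.
#'
#' @param x numeric vector, one filtered channel.
#' @param seg a `beat_segmentation` from [segment_beats()].
#' @param min_hr,max_hr admissible beat-period bounds, bpm.
#' @return Numeric vector of length = median beat length, with attribute
#'   `n_beats`.
#' @export
compute_apw <- function(x, seg, min_hr = 40, max_hr = 180) {
  fs <- attr(seg, "fs")
  win <- beat_windows(seg, fs, min_hr, max_hr)
  if (is.null(win) || nrow(win) < 2)
    stop("insufficient data: need at least 2 complete beats for the APW")
  beats <- lapply(seq_len(nrow(win)), function(k) x[win[k, 1]:win[k, 2]])
  m <- round(stats::median(lengths(beats)))
  res <- vapply(beats, resample_to, numeric(m), n_out = m)
  structure(rowMeans(res), n_beats = length(beats), fs = fs)
}

resample_to <- function(v, n_out) {
  if (length(v) == n_out) return(as.numeric(v))
  stats::approx(seq(0, 1, length.out = length(v)), v,
                xout = seq(0, 1, length.out = n_out))$y
}

#' Select the most representative pulse wave (MRPW)
#'
#' Each complete beat is resampled to the APW length and its Pearson
#' correlation coefficient (CC) against the APW is computed; the beat
#' with the highest CC is the MRPW. Ties go to the earliest beat;
#' zero-variance beats are excluded with a warning. The returned beat is
#' the original, un-resampled segment.
#'
#' @param x numeric vector, one filtered channel.
#' @param seg a `beat_segmentation`.
#' @param apw template from [compute_apw()].
#' @param min_hr,max_hr admissible beat-period bounds, bpm.
#' @return A list of class `mrpw_selection`: `beat_index` (among the
#'   complete beats), `mrpw` (numeric vector), `cc`, `cc_all`, and
#'   `window` (start/end sample indices in `x`).
#' @export
select_mrpw <- function(x, seg, apw, min_hr = 40, max_hr = 180) {
  fs <- attr(seg, "fs")
  win <- beat_windows(seg, fs, min_hr, max_hr)
  if (is.null(win) || nrow(win) < 1)
    stop("insufficient data: no complete beats")
  m <- length(apw)
  cc <- vapply(seq_len(nrow(win)), function(k) {
    v <- resample_to(x[win[k, 1]:win[k, 2]], m)
    if (stats::sd(v) == 0) NA_real_ else stats::cor(v, apw)
  }, numeric(1))
  if (anyNA(cc)) warning("zero-variance beat(s) excluded from CC matching")
  if (all(is.na(cc))) stop("no beat has a defined correlation with the APW")
  best <- which.max(cc)   # NA-safe: which.max drops NAs; earliest wins ties
  structure(list(beat_index = best,
                 mrpw = x[win[best, 1]:win[best, 2]],
                 cc = cc[best], cc_all = cc,
                 window = c(start = unname(win[best, 1]),
                            end = unname(win[best, 2]))),
            class = "mrpw_selection")
}

#' @export
print.mrpw_selection <- function(x, ...) {
  cat(sprintf("MRPW: beat %d, CC = %.4f (over %d beats)\n",
              x$beat_index, x$cc, length(x$cc_all)))
  invisible(x)
}

# local extrema on an index subset; idx must exclude the sequence ends
local_minima <- function(s, idx) idx[s[idx] < s[idx - 1] & s[idx] < s[idx + 1]]
local_maxima <- function(s, idx) idx[s[idx] >= s[idx - 1] & s[idx] >= s[idx + 1] &
                                       (s[idx] > s[idx - 1] | s[idx] > s[idx + 1])]

#' Detect fiducial points on a single beat
#'
#' Takes one full pulse period with its onset at the first sample and
#' locates the classical time-domain landmarks:
#' * `h1` - the main (percussion) wave, at the global maximum;
#' * `h4` - the dicrotic notch, the lowest local minimum within 60\% of
#'   the period after the main peak (a physiological bound on systole);
#' * `h3` - the predicrotic (tidal) wave, the largest local maximum
#'   between main peak and notch; when the tidal wave has merged into the
#'   descending limb there is no distinct peak and the detector falls
#'   back to the strongest negative-to-positive zero crossing of the
#'   second derivative (an inflection shoulder), recorded in `h3_mode`;
#'   the fallback is only used when a distinct notch exists, since a
#'   plain monotone descent always carries a spurious inflection;
#' * `h5` - the dicrotic wave, the largest local maximum after the
#'   notch, reported relative to the notch level so that a vanishing
#'   rebound gives `h5 = 0` (and may be slightly negative in noise).
#'
#' All amplitudes except `h5` are relative to the onset amplitude.
#' An optional Savitzky-Golay smoothing (window `smooth_n` samples,
#' cubic) stabilises extremum localisation on noisy beats; with
#' `smooth_n = 0` the raw samples are used and `h1` equals
#' `max(beat) - beat[1]` exactly.
#'
#' @param beat numeric vector, one full period, onset at index 1.
#' @param fs sampling rate, Hz.
#' @param smooth_n odd smoothing window in samples (0 = none).
#' @return A list of class `fiducial_set` with times (s from onset)
#'   `t_h1`, `t_h3`, `t_h4`, `t_h5`, amplitudes `h1`, `h3`, `h4`, `h5`,
#'   the period `t`, durations `t1`, `t4`, `t5`, the main-wave width `w`
#'   at two-thirds of `h1`, and flags `h3_mode`
#'   (`"peak"|"inflection"|"absent"`), `h5_present`, `notch_distinct`.
#' @export
detect_fiducials <- function(beat, fs, smooth_n = 0) {
  n <- length(beat)
  if (n < 10) stop("degenerate beat: too few samples")
  s <- beat
  if (smooth_n >= 3) {
    k <- min(as.integer(smooth_n), n - (1 - n %% 2))
    if (k %% 2 == 0) k <- k - 1L
    if (k >= 5) s <- signal::sgolayfilt(beat, p = 3, n = k)
  }
  base <- s[1]
  i1 <- which.max(s)
  h1 <- s[i1] - base
  if (h1 <= 0) stop("degenerate beat: no maximum above the onset level")
  period <- n / fs

  # dicrotic notch: lowest local minimum in (t_h1, t_h1 + 0.6 t]
  hi <- min(n - 1L, i1 + round(0.6 * n))
  win <- if (i1 + 1 <= hi) seq(i1 + 1L, hi) else integer(0)
  win <- win[win > 1 & win < n]
  mins <- local_minima(s, win)
  notch_distinct <- length(mins) > 0
  i4 <- if (notch_distinct) mins[which.min(s[mins])]
        else if (length(win)) win[which.min(s[win])]
        else n - 1L

  # tidal wave between main peak and notch
  seg <- if (i1 + 1 <= i4 - 1) seq(i1 + 1L, i4 - 1L) else integer(0)
  seg <- seg[seg > 1 & seg < n]
  maxs <- local_maxima(s, seg)
  if (length(maxs)) {
    i3 <- maxs[which.max(s[maxs])]
    h3_mode <- "peak"
  } else if (!notch_distinct) {
    # a plain monotone descent has no tidal shoulder to read: the
    # descending limb of any smooth lobe has an inflection, so the
    # fallback is only meaningful when dicrotic structure exists
    i3 <- NA_integer_
    h3_mode <- "absent"
  } else {
    d2 <- diff(s, differences = 2)        # d2[k] ~ curvature at k + 1
    kk <- seg[seg >= 2 & seg <= n - 2]
    zc <- kk[d2[kk - 1] < 0 & d2[kk] >= 0]
    if (length(zc)) {
      i3 <- zc[which.max(d2[zc] - d2[zc - 1])]
      h3_mode <- "inflection"
    } else {
      i3 <- NA_integer_
      h3_mode <- "absent"
    }
  }

  # dicrotic wave after the notch
  after <- if (i4 + 1 <= n - 1) seq(i4 + 1L, n - 1L) else integer(0)
  after <- after[after > 1]
  m5 <- local_maxima(s, after)
  h5_present <- length(m5) > 0
  i5 <- if (h5_present) m5[which.max(s[m5])] else NA_integer_

  t1 <- (i1 - 1) / fs
  t4 <- (i4 - 1) / fs
  structure(list(
    t = period,
    t_h1 = t1,
    t_h3 = if (is.na(i3)) NA_real_ else (i3 - 1) / fs,
    t_h4 = t4,
    t_h5 = if (is.na(i5)) NA_real_ else (i5 - 1) / fs,
    h1 = h1,
    h3 = if (is.na(i3)) NA_real_ else s[i3] - base,
    h4 = s[i4] - base,
    h5 = if (h5_present) s[i5] - s[i4] else 0,
    t1 = t1, t4 = t4, t5 = period - t4,
    w = width_at_fraction(beat, 2 / 3, fs),
    h3_mode = h3_mode, h5_present = h5_present,
    notch_distinct = notch_distinct),
    class = "fiducial_set")
}

#' @export
print.fiducial_set <- function(x, ...) {
  cat(sprintf(
    "fiducials: t = %.3f s | h1 = %.4g @ %.3f s | h3 = %.4g (%s) | h4 = %.4g @ %.3f s | h5 = %.4g | w = %.3f s\n",
    x$t, x$h1, x$t_h1, x$h3, x$h3_mode, x$h4, x$t_h4, x$h5, x$w))
  invisible(x)
}

#' Width of the main-wave lobe at a fractional level
#'
#' The contiguous interval around the main peak where the amplitude
#' (relative to onset) stays at or above `level_fraction * h1`, with the
#' boundary crossings located by linear interpolation between samples.
#' The conventional pulse-diagram width `w` uses `level_fraction = 2/3`,
#' i.e. one third below the peak.
#'
#' @param beat numeric vector, one full period, onset at index 1.
#' @param level_fraction fraction of `h1` in (0, 1).
#' @param fs sampling rate, Hz.
#' @return Width in seconds.
#' @export
width_at_fraction <- function(beat, level_fraction, fs) {
  stopifnot(level_fraction > 0, level_fraction < 1)
  base <- beat[1]
  i1 <- which.max(beat)
  h1 <- beat[i1] - base
  if (h1 <= 0) stop("no main-wave lobe above the onset level")
  level <- base + level_fraction * h1
  n <- length(beat)
  # walk out from the peak to the first samples below the level
  l <- i1
  while (l > 1 && beat[l - 1] >= level) l <- l - 1L
  r <- i1
  while (r < n && beat[r + 1] >= level) r <- r + 1L
  left <- if (l == 1) l else l - (beat[l] - level) / (beat[l] - beat[l - 1])
  right <- if (r == n) r else r + (beat[r] - level) / (beat[r] - beat[r + 1])
  (right - left) / fs
}
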