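#' Assemble the 3 x 4 array frame at one sample time
#'
#' @param recording an [array_recording()].
#' @param i sample index.
#' @return 3 x 4 numeric matrix `F`; rows are the transverse passages
#'   (outermost first), columns the axial positions.
#' @export
array_frame <- function(recording, i) {
  map <- recording$layout$channel_to_cell
  f <- matrix(NA_real_, 3, 4)
  f[cbind(map[, "row"] + 1L, map[, "col"] + 1L)] <- recording$samples[i, ]
  f
}

# node coordinates of the sensor grid on the footprint: the 3 rows span
# the width, the 4 columns span the length, corners on the boundary
node_coords <- function(footprint) {
  list(x = seq(0, footprint$width, length.out = 3),
       y = seq(0, footprint$length, length.out = 4))
}

#' Bilinear surface interpolation of an array frame
#'
#' The 12 sensor amplitudes are placed on a 3 x 4 node grid spanning the
#' footprint (rows across the width, columns along the length) and
#' interpolated bilinearly onto a uniform N x N grid covering the same
#' rectangle. Bilinear interpolation is bounded by the node values and
#' reproduces them exactly at the node coordinates.
#'
#' @param frame 3 x 4 numeric matrix.
#' @param n grid size N (>= 4); the instrument convention is N = 1000.
#' @param footprint a [footprint_spec()].
#' @return An object of class `interp_surface`: list with the N x N
#'   matrix `m` (rows index the width axis), `n`, and `footprint`.
#' @export
interpolate_frame <- function(frame, n = 1000, footprint = footprint_spec()) {
  frame <- as.matrix(frame)
  if (!all(dim(frame) == c(3, 4)) || !all(is.finite(frame)))
    stop("frame must be a finite 3 x 4 matrix")
  if (n < 4) stop("N must be >= 4")
  gx <- seq(0, footprint$width, length.out = n)
  gy <- seq(0, footprint$length, length.out = n)
  m <- matrix(interp_frame_at(frame, footprint,
                              rep(gx, times = n), rep(gy, each = n)),
              nrow = n)
  structure(list(m = m, n = as.integer(n), footprint = footprint),
            class = "interp_surface")
}

#' Evaluate the bilinear surface of a frame at arbitrary points
#'
#' Vectorised bilinear interpolation on the 3 x 4 node grid: each query
#' point is located in its grid cell and the four corner values are
#' blended with the tensor-product weights
#' `(1-tx)(1-ty), tx(1-ty), (1-tx)ty, tx ty`.
#'
#' @param frame 3 x 4 numeric matrix.
#' @param footprint a [footprint_spec()].
#' @param x,y coordinates (width and length axes) within the footprint.
#' @return Interpolated amplitudes.
#' @export
interp_frame_at <- function(frame, footprint, x, y) {
  frame <- as.matrix(frame)
  nodes <- node_coords(footprint)
  if (any(x < 0 | x > footprint$width | y < 0 | y > footprint$length))
    stop("query point outside the footprint")
  ix <- pmin(pmax(findInterval(x, nodes$x), 1L), 2L)
  iy <- pmin(pmax(findInterval(y, nodes$y), 1L), 3L)
  tx <- (x - nodes$x[ix]) / (nodes$x[ix + 1L] - nodes$x[ix])
  ty <- (y - nodes$y[iy]) / (nodes$y[iy + 1L] - nodes$y[iy])
  frame[cbind(ix, iy)] * (1 - tx) * (1 - ty) +
    frame[cbind(ix + 1L, iy)] * tx * (1 - ty) +
    frame[cbind(ix, iy + 1L)] * (1 - tx) * ty +
    frame[cbind(ix + 1L, iy + 1L)] * tx * ty
}

#' Volume under an interpolated surface
#'
#' The Riemann-sum volume `V = S * sum(M)` where `S` is the per-cell
#' area `a_total / N^2`. For a constant surface of height `c` this is
#' exactly `c * a_total`, and the value is stable in N (the grid only
#' has to resolve the piecewise-bilinear patches).
#'
#' @param surface an `interp_surface` from [interpolate_frame()].
#' @return Volume in amplitude x area units.
#' @export
frame_volume <- function(surface) {
  s <- cell_area(surface$footprint, surface$n)
  s * sum(surface$m)
}

# --- regional channel weights ------------------------------------------
#
# Volumes are linear in the frame, so the regional volume of every frame
# is a fixed weighted sum of the 12 channel amplitudes: the weight of
# channel c in region g is the regional mean of the interpolated unit
# basis frame of c. Weights are computed once per (N, layout, footprint)
# and cached; each band's weights sum to 1.

.weight_cache <- new.env(parent = emptyenv())

# row bands of the N x N grid: the transverse third nearest each sensor
# row (band rounding: RP rows [0, N/3), IP [N/3, 2N/3), UP the rest)
band_rows <- function(n) {
  b1 <- floor(n / 3)
  b2 <- floor(2 * n / 3)
  list(seq_len(b1), seq(b1 + 1L, b2), seq(b2 + 1L, n))
}

#' Regional channel weights of the interpolated surface
#'
#' @param layout a [channel_layout()].
#' @param n grid size N.
#' @param footprint a [footprint_spec()].
#' @return 4 x 12 matrix of weights, rows named after the three passages
#'   plus `"mean"`; `a_total * (weights %*% frame_channels)` gives the
#'   regional volumes.
#' @export
channel_weights <- function(layout, n = 1000, footprint = footprint_spec()) {
  key <- paste(n, footprint$width, footprint$length,
               paste(layout$channel_to_cell, collapse = ","), sep = "|")
  if (!is.null(.weight_cache[[key]])) return(.weight_cache[[key]])
  bands <- band_rows(n)
  w <- matrix(0, 4, 12,
              dimnames = list(c(layout$row_labels, "mean"), NULL))
  map <- layout$channel_to_cell
  for (ch in 1:12) {
    f <- matrix(0, 3, 4)
    f[map[ch, "row"] + 1L, map[ch, "col"] + 1L] <- 1
    m <- interpolate_frame(f, n, footprint)$m
    for (g in 1:3) w[g, ch] <- mean(m[bands[[g]], ])
    w[4, ch] <- mean(m)
  }
  .weight_cache[[key]] <- w
  w
}

#' APV time series of one channel group
#'
#' For each sample in the window the 3 x 4 frame is interpolated and
#' integrated over the group's region: the full footprint for `"mean"`,
#' or the transverse third of the grid nearest the passage's sensor row
#' for `"RP"`, `"IP"`, `"UP"`. Regional volumes are normalised as
#' (regional mean height) x total footprint area, so all four groups
#' share one scale and the mean group is (up to band rounding) the
#' average of the three passages. Linearity of the interpolation reduces
#' the whole computation to cached per-channel weights.
#'
#' @param recording an [array_recording()] (normally filtered).
#' @param group `"RP"`, `"IP"`, `"UP"` or `"mean"` (any passage label of
#'   the recording's layout).
#' @param window integer vector of sample indices (a beat window).
#' @param n grid size N.
#' @param footprint a [footprint_spec()].
#' @return An object of class `volume_series`: list with `values`
#'   (volume per sample), `group`, `window`, `fs`.
#' @export
group_volume_series <- function(recording, group, window, n = 1000,
                                footprint = footprint_spec()) {
  if (length(window) < 1) stop("empty beat window")
  if (any(window < 1 | window > nrow(recording$samples)))
    stop("window outside the recording")
  w <- channel_weights(recording$layout, n, footprint)
  if (!group %in% rownames(w)) stop("unknown group: ", group)
  vals <- footprint$a_total *
    as.vector(recording$samples[window, , drop = FALSE] %*% w[group, ])
  structure(list(values = vals, group = group,
                 window = c(start = window[1], end = window[length(window)]),
                 fs = recording$fs),
            class = "volume_series")
}

#' Pick the reference channel for beat timing
#'
#' The channel with the largest median per-beat amplitude (beat maximum
#' minus beat minimum) among all channels that segmented successfully;
#' ties go to the lowest channel index. Its MRPW window later defines
#' the beat window for feature extraction.
#'
#' @param recording an [array_recording()].
#' @param segs list of 12 `beat_segmentation`s, one per channel.
#' @param min_hr,max_hr admissible beat-period bounds, bpm.
#' @return Integer channel index.
#' @export
reference_channel <- function(recording, segs, min_hr = 40, max_hr = 180) {
  amp <- rep(-Inf, 12)
  for (ch in 1:12) {
    win <- beat_windows(segs[[ch]], recording$fs, min_hr, max_hr)
    if (is.null(win)) next
    a <- vapply(seq_len(nrow(win)), function(k) {
      seg <- recording$samples[win[k, 1]:win[k, 2], ch]
      max(seg) - min(seg)
    }, numeric(1))
    amp[ch] <- stats::median(a)
  }
  if (all(!is.finite(amp)))
    stop("pipeline error: no channel could be segmented into beats")
  which.max(amp)
}

#' Extract the APV feature parameters for one beat
#'
#' For each group (the three passages and the 12-channel mean) the group
#' waveform is the mean of its channels over the beat window; fiducial
#' points are detected on that waveform (so each passage keeps its own
#' timing), and the group's APV series is read at those times. The four
#' absolute features are volume differences from the beat onset,
#' `APV_h5` is measured from the notch level, and the three ratio
#' features divide by `APV_h1`:
#' `APV_h1, APV_h3, APV_h4, APV_h5, APV_h3/h1, APV_h4/h1, APV_h5/h1`.
#'
#' @param recording a filtered [array_recording()].
#' @param window integer vector of sample indices covering one beat.
#' @param n grid size N.
#' @param footprint a [footprint_spec()].
#' @param smooth_n fiducial smoothing window in samples (see
#'   [detect_fiducials()]).
#' @return A data frame of class `apv_features` with columns
#'   `subject_id`, `group` (cohort label), `passage`, `parameter`,
#'   `value`: 4 groups x 7 parameters = 28 rows. Fiducials unavailable
#'   on a group's waveform yield `NA` (absent dicrotic wave yields 0 by
#'   convention). Per-group fiducial sets are attached as attribute
#'   `fiducials`.
#' @export
extract_apv_features <- function(recording, window, n = 1000,
                                 footprint = footprint_spec(),
                                 smooth_n = 0) {
  groups <- c(recording$layout$row_labels, "mean")
  params <- c("APV_h1", "APV_h3", "APV_h4", "APV_h5",
              "APV_h3/h1", "APV_h4/h1", "APV_h5/h1")
  fs <- recording$fs
  fids <- list()
  rows <- list()
  for (g in groups) {
    ch <- if (g == "mean") 1:12 else passage_channels(recording$layout, g)
    wf <- rowMeans(recording$samples[window, ch, drop = FALSE])
    vals <- stats::setNames(rep(NA_real_, 7), params)
    if (stats::sd(wf) == 0) {
      # a time-constant group waveform has identically zero volume
      # differences; amplitudes are 0 by the baseline-relative
      # convention, ratios are undefined
      vals[c("APV_h1", "APV_h3", "APV_h4", "APV_h5")] <- 0
      fids[[g]] <- NULL
      rows[[g]] <- data.frame(subject_id = recording$meta$subject_id,
                              group = recording$meta$group,
                              passage = g, parameter = params,
                              value = unname(vals))
      next
    }
    fid <- tryCatch(detect_fiducials(wf, fs, smooth_n = smooth_n),
                    error = function(e) {
                      warning("group ", g, ": ", conditionMessage(e))
                      NULL
                    })
    fids[[g]] <- fid
    if (!is.null(fid)) {
      v <- group_volume_series(recording, g, window, n, footprint)$values
      at <- function(t_s) v[round(t_s * fs) + 1L]
      v0 <- v[1]
      vals["APV_h1"] <- at(fid$t_h1) - v0
      vals["APV_h4"] <- at(fid$t_h4) - v0
      if (!is.na(fid$t_h3)) vals["APV_h3"] <- at(fid$t_h3) - v0
      vals["APV_h5"] <- if (fid$h5_present) at(fid$t_h5) - at(fid$t_h4) else 0
      vals["APV_h3/h1"] <- vals["APV_h3"] / vals["APV_h1"]
      vals["APV_h4/h1"] <- vals["APV_h4"] / vals["APV_h1"]
      vals["APV_h5/h1"] <- vals["APV_h5"] / vals["APV_h1"]
    }
    rows[[g]] <- data.frame(subject_id = recording$meta$subject_id,
                            group = recording$meta$group,
                            passage = g, parameter = params,
                            value = unname(vals))
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  attr(out, "fiducials") <- fids
  class(out) <- c("apv_features", "data.frame")
  out
}
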