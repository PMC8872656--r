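#' Pipeline configuration
#'
#' Collects every tunable of the analysis pipeline with validated
#' defaults: 100 Hz sampling, a sixth-order Chebyshev type-I band-pass at
#' 1-4 Hz with 0.5 dB passband ripple applied zero-phase, a 1000 x 1000
#' interpolation grid over a unit footprint, beat-rate bounds of
#' 40-180 bpm, and 0.05 alphas for both the normality gate and the group
#' comparison.
#'
#' @param fs sampling rate, Hz.
#' @param filter_low,filter_high band edges, Hz; must satisfy
#'   `0 < low < high < fs/2`.
#' @param filter_order order of the realised band-pass transfer function
#'   (even, >= 2).
#' @param filter_ripple_db passband ripple of the Chebyshev design, dB.
#' @param filter_zero_phase logical; apply the filter forward-backward.
#' @param n_grid interpolation grid size N (>= 4).
#' @param footprint a [footprint_spec()].
#' @param min_hr,max_hr admissible beat rate bounds, bpm.
#' @param fiducial_smooth_ms Savitzky-Golay smoothing window (ms) used by
#'   fiducial detection inside the pipeline; 0 disables smoothing.
#' @param alpha_normality alpha for the Shapiro-Wilk gate.
#' @param alpha_sig significance alpha of the group comparison.
#' @param seed integer seed for any randomised step.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(fs = 100,
                            filter_low = 1, filter_high = 4,
                            filter_order = 6, filter_ripple_db = 0.5,
                            filter_zero_phase = TRUE,
                            n_grid = 1000,
                            footprint = footprint_spec(),
                            min_hr = 40, max_hr = 180,
                            fiducial_smooth_ms = 50,
                            alpha_normality = 0.05, alpha_sig = 0.05,
                            seed = 1L) {
  stopifnot(fs > 0)
  if (!(0 < filter_low && filter_low < filter_high && filter_high < fs / 2))
    stop("config validation error: need 0 < low < high < fs/2")
  if (filter_order < 2 || filter_order %% 2 != 0)
    stop("config validation error: filter_order must be even and >= 2")
  if (filter_ripple_db <= 0)
    stop("config validation error: ripple must be > 0")
  if (n_grid < 4) stop("config validation error: N must be >= 4")
  if (!(min_hr > 0 && min_hr < max_hr))
    stop("config validation error: need 0 < min_hr < max_hr")
  for (a in c(alpha_normality, alpha_sig))
    if (!(a > 0 && a < 1))
      stop("config validation error: alphas must lie in (0, 1)")
  structure(list(fs = fs,
                 filter_low = filter_low, filter_high = filter_high,
                 filter_order = filter_order,
                 filter_ripple_db = filter_ripple_db,
                 filter_zero_phase = isTRUE(filter_zero_phase),
                 n_grid = as.integer(n_grid), footprint = footprint,
                 min_hr = min_hr, max_hr = max_hr,
                 fiducial_smooth_ms = fiducial_smooth_ms,
                 alpha_normality = alpha_normality, alpha_sig = alpha_sig,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Keys absent from the file fall back to the defaults of
#' [pipeline_config()]. Recognised keys: `fs`, `n_grid`, `seed`,
#' `min_hr`, `max_hr`, `fiducial_smooth_ms`, `alpha_normality`,
#' `alpha_sig`, a `filter` block (`low_hz`, `high_hz`, `order`,
#' `ripple_db`, `zero_phase`) and a `footprint` block (`width`,
#' `length`).
#'
#' @param path path to a YAML file, or `NULL` for pure defaults.
#' @return A validated `pipeline_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- if (is.null(path)) list() else {
    if (!file.exists(path)) stop("no such config file: ", path)
    y <- yaml::read_yaml(path)
    if (is.null(y)) list() else y
  }
  flt <- cfg$filter
  fp <- cfg$footprint
  pick <- function(x, default) if (is.null(x)) default else x
  pipeline_config(
    fs = pick(cfg$fs, 100),
    filter_low = pick(flt$low_hz, 1),
    filter_high = pick(flt$high_hz, 4),
    filter_order = pick(flt$order, 6),
    filter_ripple_db = pick(flt$ripple_db, 0.5),
    filter_zero_phase = pick(flt$zero_phase, TRUE),
    n_grid = pick(cfg$n_grid, 1000),
    footprint = footprint_spec(pick(fp$width, 1), pick(fp$length, 1)),
    min_hr = pick(cfg$min_hr, 40),
    max_hr = pick(cfg$max_hr, 180),
    fiducial_smooth_ms = pick(cfg$fiducial_smooth_ms, 50),
    alpha_normality = pick(cfg$alpha_normality, 0.05),
    alpha_sig = pick(cfg$alpha_sig, 0.05),
    seed = pick(cfg$seed, 1L))
}
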