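#' Full single-recording analysis
#'
#' Runs the complete chain on one recording: band-pass denoising, beat
#' segmentation of every channel, reference-channel selection, APW and
#' MRPW computation on the reference channel, and APV feature extraction
#' over the MRPW beat window.
#'
#' @param recording an [array_recording()] of raw samples.
#' @param config a [pipeline_config()].
#' @param filter set `FALSE` to skip denoising (already-filtered or
#'   noiseless input).
#' @return A list of class `pulse_analysis`: `features` (28-row APV
#'   table), `ref_channel`, `mrpw` (an `mrpw_selection`), `apw`,
#'   `window`, `config`.
#' @export
analyze_recording <- function(recording, config = pipeline_config(),
                              filter = TRUE) {
  filt <- recording
  if (filter) {
    spec <- design_bandpass(config$fs, config$filter_low,
                            config$filter_high, config$filter_order,
                            config$filter_ripple_db)
    filt <- apply_filter(recording, spec,
                         zero_phase = config$filter_zero_phase)
  }
  segs <- lapply(1:12, function(ch)
    suppressWarnings(segment_beats(filt$samples[, ch], config$fs,
                                   config$min_hr, config$max_hr)))
  ref <- reference_channel(filt, segs, config$min_hr, config$max_hr)
  x <- filt$samples[, ref]
  apw <- compute_apw(x, segs[[ref]], config$min_hr, config$max_hr)
  mrpw <- select_mrpw(x, segs[[ref]], apw, config$min_hr, config$max_hr)
  window <- seq(mrpw$window["start"], mrpw$window["end"])
  smooth_n <- round(config$fiducial_smooth_ms / 1000 * config$fs)
  feats <- extract_apv_features(filt, window, n = config$n_grid,
                                footprint = config$footprint,
                                smooth_n = smooth_n)
  structure(list(features = feats, ref_channel = ref, mrpw = mrpw,
                 apw = apw, window = window, config = config),
            class = "pulse_analysis")
}

#' @export
print.pulse_analysis <- function(x, ...) {
  cat(sprintf("pulse_analysis: reference channel %d, MRPW CC = %.4f\n",
              x$ref_channel, x$mrpw$cc))
  print(utils::head(x$features, 14))
  cat("...\n")
  invisible(x)
}

#' Analyse a set of recordings
#'
#' @param recordings list of [array_recording()]s.
#' @param config a [pipeline_config()].
#' @return Stacked feature table (one 28-row block per recording).
#'   Recordings that fail to analyse are skipped with a warning.
#' @export
analyze_cohort <- function(recordings, config = pipeline_config()) {
  feats <- lapply(recordings, function(r) {
    tryCatch(analyze_recording(r, config)$features,
             error = function(e) {
               warning("skipping ", r$meta$subject_id, ": ",
                       conditionMessage(e))
               NULL
             })
  })
  out <- do.call(rbind, c(feats[!vapply(feats, is.null, logical(1))],
                          make.row.names = FALSE))
  class(out) <- c("apv_features", "data.frame")
  out
}
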