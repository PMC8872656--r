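Package: arraypulse
Title: Arrayed Radial-Artery Pulse-Wave Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis of multichannel radial-artery pressure recordings
    acquired with a 3 x 4 tactile sensor array. Provides Chebyshev type-I
    band-pass denoising, beat segmentation, ensemble averaging (APW) and
    most-representative-beat (MRPW) selection, automated fiducial-point
    detection (main wave, tidal wave, dicrotic notch, dicrotic wave),
    bilinear surface interpolation of array frames, the array pulse volume
    (APV) statistic with its seven per-passage feature parameters, and a
    normality-gated two-group comparison (Student's t / Mann-Whitney U).
    A synthetic-signal generator with known ground truth emulates the
    acquisition hardware and a two-group clinical cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    jsonlite
Config/testthat/edition: 3
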