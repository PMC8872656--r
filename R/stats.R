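#' Shapiro-Wilk normality check
#'
#' @param x numeric sample, n >= 3 and non-constant.
#' @param alpha significance level of the gate.
#' @return List with `statistic`, `p`, `is_normal` (`p >= alpha`).
#' @export
test_normality <- function(x, alpha = 0.05) {
  if (length(x) < 3) stop("insufficient data: normality test needs n >= 3")
  if (stats::sd(x) == 0) stop("zero variance: normality test undefined")
  sw <- stats::shapiro.test(x)
  list(statistic = unname(sw$statistic), p = sw$p.value,
       is_normal = sw$p.value >= alpha)
}

#' Pooled-variance two-sample Student's t test
#'
#' Two-sided, equal-variance t test with `n_x + n_y - 2` degrees of
#' freedom. Degenerate samples (zero pooled variance) give `t = 0,
#' p = 1` when the means agree and an error otherwise.
#'
#' @param x,y numeric samples, each n >= 2.
#' @return List with `statistic` (t, ordered x vs y), `df`, `p`.
#' @export
student_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("insufficient data: t test needs n >= 2 per group")
  df <- length(x) + length(y) - 2
  pooled <- ((length(x) - 1) * stats::var(x) +
               (length(y) - 1) * stats::var(y)) / df
  if (pooled == 0) {
    if (mean(x) == mean(y)) return(list(statistic = 0, df = df, p = 1))
    stop("degenerate variance: groups are constant with unequal means")
  }
  tt <- stats::t.test(x, y, var.equal = TRUE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. With `n_x + n_y <= 12` and no ties the
#' p-value is exact (enumeration of the rank distribution); otherwise
#' the normal approximation with tie and continuity corrections is used.
#' The reported `U` counts pairs in which `x` precedes `y`, so swapping
#' the samples maps `U` to `n_x * n_y - U` and leaves `p` unchanged.
#'
#' @param x,y numeric samples, each n >= 1.
#' @return List with `U`, `z` (`NA` on the exact path), `p`, `method`.
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) stop("insufficient data: empty sample")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && length(x) + length(y) <= 12
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  u <- unname(wt$statistic)
  z <- NA_real_
  if (!exact) {
    nx <- length(x); ny <- length(y)
    mu <- nx * ny / 2
    r <- rank(c(x, y))
    tie_tab <- table(r)
    sigma2 <- nx * ny / 12 *
      (nx + ny + 1 - sum(tie_tab^3 - tie_tab) / ((nx + ny) * (nx + ny - 1)))
    cc <- sign(u - mu) * 0.5
    z <- if (sigma2 > 0) (u - mu - cc) / sqrt(sigma2) else 0
  }
  list(U = u, z = z, p = wt$p.value,
       method = if (exact) "exact" else "normal-approximation")
}

signif_tier <- function(p) {
  cut(p, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
      labels = c("***", "**", "*", "ns"), right = FALSE)
}

#' Normality-gated two-group comparison of APV features
#'
#' For every (passage, parameter) pair present in both groups the two
#' per-subject samples are compared: with both samples passing the
#' Shapiro-Wilk gate the pooled t test is used, otherwise the
#' Mann-Whitney U test. Constant samples fail the gate and fall to the
#' rank test. No multiple-testing correction is applied (each parameter
#' is reported on its own); `adjust = "BH"` adds a Benjamini-Hochberg
#' column for reuse.
#'
#' @param features_a,features_b feature tables as returned by
#'   [extract_apv_features()] (stacked over subjects): columns
#'   `subject_id`, `passage`, `parameter`, `value`.
#' @param alpha_normality alpha of the normality gate.
#' @param alpha_sig significance alpha for the tier stars.
#' @param labels length-2 character, names of the two groups.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Data frame with one row per (passage, parameter): group
#'   means and SDs, `test_used`, `statistic` (t, or the U-test z),
#'   `p_value`, and `tier` (`***`, `**`, `*`, `ns`).
#' @export
compare_groups <- function(features_a, features_b,
                           alpha_normality = 0.05, alpha_sig = 0.05,
                           labels = c("healthy", "hypertensive"),
                           adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  key_a <- unique(features_a[, c("passage", "parameter")])
  key_b <- unique(features_b[, c("passage", "parameter")])
  keys <- merge(key_a, key_b)
  only <- nrow(key_a) + nrow(key_b) - 2 * nrow(keys)
  if (only > 0)
    warning(only, " parameter(s) present in one group only were skipped")
  # preserve input ordering
  keys <- key_a[paste(key_a$passage, key_a$parameter) %in%
                  paste(keys$passage, keys$parameter), ]
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    ps <- keys$passage[i]; pr <- keys$parameter[i]
    va <- features_a$value[features_a$passage == ps &
                             features_a$parameter == pr]
    vb <- features_b$value[features_b$passage == ps &
                             features_b$parameter == pr]
    va <- va[is.finite(va)]; vb <- vb[is.finite(vb)]
    normal <- length(va) >= 3 && length(vb) >= 3 &&
      stats::sd(va) > 0 && stats::sd(vb) > 0 &&
      test_normality(va, alpha_normality)$is_normal &&
      test_normality(vb, alpha_normality)$is_normal
    res <- if (normal) {
      tt <- student_t(va, vb)
      list(test = "t", stat = tt$statistic, p = tt$p)
    } else {
      mw <- mann_whitney(va, vb)
      list(test = "mann-whitney",
           stat = if (is.na(mw$z)) mw$U else mw$z, p = mw$p)
    }
    data.frame(passage = ps, parameter = pr,
               n_a = length(va), n_b = length(vb),
               mean_a = mean(va), sd_a = stats::sd(va),
               mean_b = mean(vb), sd_b = stats::sd(vb),
               test_used = res$test, statistic = res$stat,
               p_value = res$p)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  if (adjust == "BH") out$p_adj_bh <- stats::p.adjust(out$p_value, "BH")
  out$tier <- as.character(signif_tier(out$p_value))
  attr(out, "labels") <- labels
  out
}
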