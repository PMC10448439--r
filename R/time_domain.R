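#' Construct an extracted ion chromatogram trace
#'
#' A time-indexed intensity profile for one m/z group. Times must be strictly
#' increasing and intensities non-negative.
#'
#' @param mz_center Group centre m/z in Da.
#' @param time Scan times in minutes, strictly increasing.
#' @param intensity Intensities in counts, same length as `time`.
#' @return An object of class `xic_trace`.
#' @export
xic_trace <- function(mz_center, time, intensity) {
  stopifnot(length(time) >= 1, length(time) == length(intensity),
            all(diff(time) > 0), all(intensity >= 0))
  structure(list(mz_center = mz_center, time = as.numeric(time),
                 intensity = as.numeric(intensity)),
            class = "xic_trace")
}

#' @export
print.xic_trace <- function(x, ...) {
  cat(sprintf("<xic_trace> m/z %.4f, %d scans, %.3f-%.3f min\n",
              x$mz_center, length(x$time), min(x$time), max(x$time)))
  invisible(x)
}

#' Chromatographic feature of a precursor ion
#'
#' The precursor's XIC together with its apex retention time and the feature
#' time bounds, as produced by upstream MS1 feature detection.
#'
#' @param mz Precursor m/z in Da.
#' @param apex_time Apex retention time in minutes.
#' @param t_start,t_end Feature start/end times in minutes
#'   (`t_start < apex_time < t_end`).
#' @param trace The precursor [xic_trace()].
#' @return An object of class `precursor_feature`.
#' @export
precursor_feature <- function(mz, apex_time, t_start, t_end, trace) {
  stopifnot(t_start < apex_time, apex_time < t_end,
            inherits(trace, "xic_trace"))
  structure(list(mz = mz, apex_time = apex_time,
                 t_start = t_start, t_end = t_end, trace = trace),
            class = "precursor_feature")
}

#' Group centroided MS2 scans into extracted ion chromatograms
#'
#' Peaks across scans are clustered in the m/z dimension by single-linkage
#' chaining: sorted m/z values whose neighbour gaps are within `mass_window`
#' (0.020 Da, i.e. a 0.010 Da tolerance around the group centre) form one
#' XIC. The group centre is the intensity-weighted mean m/z. Scans with no
#' member peak contribute intensity 0 at their scan time, so every trace is
#' defined on the full scan-time grid.
#'
#' @param scans Data frame in long format with columns `scan_time` (minutes),
#'   `mz` (Da), `intensity` (counts).
#' @param mass_window Grouping window in Da; default 0.020.
#' @return List of [xic_trace()] sorted by centre m/z.
#' @export
group_xics <- function(scans, mass_window = 0.020) {
  scans <- as.data.frame(scans)
  stopifnot(all(c("scan_time", "mz", "intensity") %in% names(scans)))
  times <- sort(unique(scans$scan_time))
  o <- order(scans$mz)
  s <- scans[o, , drop = FALSE]
  grp <- cumsum(c(1, diff(s$mz) > mass_window))
  lapply(split(s, grp), function(g) {
    center <- sum(g$mz * g$intensity) / sum(g$intensity)
    if (!is.finite(center)) center <- mean(g$mz)  # all-zero intensities
    y <- vapply(times, function(t) sum(g$intensity[g$scan_time == t]),
                numeric(1))
    xic_trace(center, times, y)
  })
}

#' Quality control of an MS2 XIC
#'
#' A trace passes when (a) its signal-to-noise ratio exceeds `min_snr` and
#' (b) at least `min_consecutive` consecutive scans each have an intensity
#' strictly above both the forward cumulative intensity mean (mean of
#' intensities up to and including that scan) and the backward cumulative
#' mean (from the end of the trace back to that scan). A flat trace never
#' exceeds its own running mean and fails; a single-scan spike fails the
#' consecutive-scan rule.
#'
#' The noise estimate is the median intensity of the lowest-50% points of
#' the trace; when that is zero and the maximum is positive the S/N is
#' taken as infinite.
#'
#' @param trace An [xic_trace()].
#' @param min_snr Minimum signal-to-noise ratio; default 2.
#' @param min_consecutive Minimum run of mean-exceeding scans; default 3.
#' @return `TRUE` if the trace passes both criteria.
#' @export
qc_filter <- function(trace, min_snr = 2, min_consecutive = 3) {
  stopifnot(inherits(trace, "xic_trace"))
  y <- trace$intensity
  n <- length(y)
  if (n < min_consecutive) return(FALSE)
  noise <- stats::median(sort(y)[seq_len(max(1L, floor(n / 2)))])
  snr <- if (noise > 0) max(y) / noise else if (max(y) > 0) Inf else 0
  if (!(snr > min_snr)) return(FALSE)
  fwd <- cumsum(y) / seq_len(n)
  bwd <- rev(cumsum(rev(y)) / seq_len(n))
  high <- y > fwd & y > bwd
  r <- rle(high)
  any(r$values & r$lengths >= min_consecutive)
}

#' Peak-shape correlation between precursor and candidate fragment
#'
#' Pearson correlation of the two intensity profiles over their shared time
#' range. The fragment trace is resampled onto the precursor scan times by
#' linear interpolation; at least three shared scan times are required. A
#' zero-variance profile yields r = 0 (reject) rather than an undefined
#' value.
#'
#' @param precursor,fragment [xic_trace()] objects.
#' @return Pearson r in `[-1, 1]`.
#' @export
peak_correlation <- function(precursor, fragment) {
  stopifnot(inherits(precursor, "xic_trace"), inherits(fragment, "xic_trace"))
  t0 <- max(min(precursor$time), min(fragment$time))
  t1 <- min(max(precursor$time), max(fragment$time))
  keep <- precursor$time >= t0 & precursor$time <= t1
  if (sum(keep) < 3) stop("peak_correlation: fewer than 3 shared scan times")
  x <- precursor$intensity[keep]
  y <- stats::approx(fragment$time, fragment$intensity,
                     xout = precursor$time[keep])$y
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)
}

#' Apex retention-time difference
#'
#' Absolute difference between the fragment trace's apex time and the
#' precursor feature's apex time. The fragment apex is the scan time of its
#' maximum intensity; ties break to the earliest scan (no peak fitting).
#'
#' @param precursor A [precursor_feature()].
#' @param fragment An [xic_trace()] (should have passed [qc_filter()]).
#' @return Delta t_r in minutes.
#' @export
apex_difference <- function(precursor, fragment) {
  stopifnot(inherits(precursor, "precursor_feature"),
            inherits(fragment, "xic_trace"))
  apex <- fragment$time[which.max(fragment$intensity)]
  abs(apex - precursor$apex_time)
}

#' Record one deconvolution method's verdict on a fragment
#'
#' Each method has its own threshold direction: the CNL score and the
#' correlation must exceed their thresholds, the apex time difference must
#' fall below its.
#'
#' @param method One of `"cnl"`, `"correlation"`, `"tr_diff"`.
#' @param statistic The method's statistic (score, r, or delta t_r in
#'   minutes).
#' @param threshold The method's threshold.
#' @return An object of class `method_decision` with fields `method`,
#'   `statistic`, `threshold`, `accepted`.
#' @export
method_decision <- function(method = c("cnl", "correlation", "tr_diff"),
                            statistic, threshold) {
  method <- match.arg(method)
  accepted <- switch(method,
                     cnl = statistic > threshold,
                     correlation = statistic > threshold,
                     tr_diff = statistic < threshold)
  structure(list(method = method, statistic = statistic,
                 threshold = threshold, accepted = isTRUE(accepted)),
            class = "method_decision")
}

#' Combine per-method verdicts
#'
#' Conjunction: a fragment is kept only if every constituent method accepts
#' it, so stacking methods can only shrink the accepted set (the reduction
#' rate rises and the TP rate falls monotonically as methods are added).
#'
#' @param decisions List of [method_decision()] (at least one).
#' @param mode Combination mode; only `"AND"` is supported.
#' @return `TRUE` if every decision accepted.
#' @export
combine_decisions <- function(decisions, mode = "AND") {
  mode <- match.arg(mode, "AND")
  stopifnot(length(decisions) >= 1)
  all(vapply(decisions, function(d) {
    stopifnot(inherits(d, "method_decision"))
    d$accepted
  }, logical(1)))
}
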