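#' Preprocessing configuration
#'
#' @param neuropil_coefficient fraction of the neuropil trace subtracted from
#'   the raw trace (0.7 in the standard two-photon pipeline).
#' @param baseline_window length of the non-overlapping percentile windows,
#'   seconds (60).
#' @param baseline_percentile percentile taken within each window (50).
#' @param smoothing_sigma Gaussian smoothing sd applied before the percentile
#'   filter, seconds. Long relative to transients, short relative to the
#'   window; default 2 s.
#' @param baseline_mode `"interp"` (linear interpolation between window
#'   centers, constant extrapolation at the ends; default) or `"constant"`
#'   (piecewise-constant per window).
#' @param artifact_z_threshold |z| above which a peri-event trial is treated
#'   as artifact-contaminated (used by [build_tensor()]).
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(neuropil_coefficient = 0.7,
                              baseline_window = 60,
                              baseline_percentile = 50,
                              smoothing_sigma = 2,
                              baseline_mode = c("interp", "constant"),
                              artifact_z_threshold = 10) {
  if (neuropil_coefficient < 0 || neuropil_coefficient >= 1)
    stop("neuropil_coefficient must be in [0, 1)")
  if (baseline_window <= 0) stop("baseline_window must be positive")
  if (baseline_percentile <= 0 || baseline_percentile >= 100)
    stop("baseline_percentile must be in (0, 100)")
  structure(list(neuropil_coefficient = neuropil_coefficient,
                 baseline_window = baseline_window,
                 baseline_percentile = baseline_percentile,
                 smoothing_sigma = smoothing_sigma,
                 baseline_mode = match.arg(baseline_mode),
                 artifact_z_threshold = artifact_z_threshold),
            class = "preprocess_config")
}

#' Neuropil correction
#'
#' Subtracts `r` times the neuropil trace from the raw cellular trace,
#' elementwise.
#'
#' @param f raw fluorescence trace (numeric vector).
#' @param f_neu neuropil trace, same length.
#' @param r correction coefficient (default 0.7).
#' @return corrected trace.
#' @export
neuropil_correct <- function(f, f_neu, r = 0.7) {
  if (length(f) != length(f_neu)) stop("f and f_neu must have equal length")
  f - r * f_neu
}

#' Windowed-percentile baseline estimate
#'
#' The trace is Gaussian-smoothed (`smoothing_sigma`), then the configured
#' percentile (50th by default) is taken within non-overlapping windows of
#' `baseline_window` seconds. A session shorter than one window falls back to
#' a single window; a final partial window gets its own percentile. The
#' per-window values are expanded to full length either by linear
#' interpolation between window centers (default) or piecewise-constant.
#'
#' @param trace numeric vector.
#' @param frame_rate sampling rate, Hz.
#' @param config a [preprocess_config()].
#' @return baseline trace, same length as `trace`.
#' @export
estimate_baseline <- function(trace, frame_rate, config = preprocess_config()) {
  if (config$baseline_window <= 0) stop("non-positive baseline window")
  n <- length(trace)
  sm <- gaussian_smooth(trace, config$smoothing_sigma, frame_rate)
  wlen <- max(1L, round(config$baseline_window * frame_rate))
  starts <- seq(1L, n, by = wlen)
  p <- config$baseline_percentile / 100
  vals <- vapply(starts, function(s) {
    e <- min(n, s + wlen - 1L)
    stats::quantile(sm[s:e], probs = p, names = FALSE, type = 7)
  }, numeric(1))
  if (length(vals) == 1L || config$baseline_mode == "constant") {
    if (length(vals) == 1L) return(rep(vals, n))
    ends <- pmin(n, starts + wlen - 1L)
    return(rep(vals, times = ends - starts + 1L))
  }
  centers <- vapply(starts, function(s) (s + min(n, s + wlen - 1L)) / 2,
                    numeric(1))
  stats::approx(x = centers, y = vals, xout = seq_len(n), rule = 2)$y
}

#' Fractional fluorescence change
#'
#' 100 * (trace - baseline) / baseline, percent. A baseline containing any
#' non-positive value makes the ROI's dF/F undefined; such ROIs are flagged
#' `negative_baseline` and excluded downstream.
#'
#' @param trace corrected fluorescence trace.
#' @param baseline baseline trace, same length.
#' @return list(dff = percent trace (NA if flagged), flagged = logical).
#' @export
compute_dff <- function(trace, baseline) {
  if (length(trace) != length(baseline)) stop("baseline length mismatch")
  if (any(baseline <= 0)) {
    return(list(dff = rep(NA_real_, length(trace)), flagged = TRUE))
  }
  list(dff = 100 * (trace - baseline) / baseline, flagged = FALSE)
}

#' Session-wide z-score
#'
#' (x - mean(x)) / sd(x) over the whole session.
#'
#' @param x numeric trace with nonzero variance.
#' @return z-scored trace.
#' @export
zscore_session <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("zero variance: cannot z-score trace")
  (x - mean(x)) / s
}

#' Preprocess a session recording
#'
#' Per ROI: neuropil correction, windowed-percentile baseline, dF/F (percent),
#' session-wide z-score. ROIs with non-positive baselines or zero-variance
#' dF/F are excluded and recorded in the exclusion report; excluded ROIs never
#' enter downstream tensors.
#'
#' @param rec a `session_recording`.
#' @param config a [preprocess_config()].
#' @return a `trace_matrix`: list(z, dff — kept-ROI x frame matrices,
#'   kept_rois — indices into the recording, exclusion_report — data.frame
#'   (roi, reason in none/negative_baseline/zero_variance), frame_rate,
#'   frame_times, cell_type — for kept ROIs, config).
#' @export
preprocess_session <- function(rec, config = preprocess_config()) {
  stopifnot(inherits(rec, "session_recording"))
  n <- nrow(rec$raw_f)
  reason <- rep("none", n)
  dff <- matrix(NA_real_, n, ncol(rec$raw_f))
  for (i in seq_len(n)) {
    corr <- neuropil_correct(rec$raw_f[i, ], rec$neuropil_f[i, ],
                             config$neuropil_coefficient)
    bl <- estimate_baseline(corr, rec$frame_rate, config)
    d <- compute_dff(corr, bl)
    if (d$flagged) { reason[i] <- "negative_baseline"; next }
    # tolerance absorbs float residue of smoothing a perfectly flat trace
    if (stats::sd(d$dff) < 1e-8) { reason[i] <- "zero_variance"; next }
    dff[i, ] <- d$dff
  }
  kept <- which(reason == "none")
  if (length(kept) == 0L) stop("no ROI survived preprocessing")
  z <- t(apply(dff[kept, , drop = FALSE], 1, zscore_session))
  structure(list(z = z, dff = dff[kept, , drop = FALSE], kept_rois = kept,
                 exclusion_report = data.frame(roi = seq_len(n), reason = reason),
                 frame_rate = rec$frame_rate, frame_times = rec$frame_times,
                 cell_type = rec$cell_type[kept], config = config),
            class = "trace_matrix")
}

#' @export
print.trace_matrix <- function(x, ...) {
  cat("trace_matrix:", nrow(x$z), "kept ROIs x", ncol(x$z), "frames;",
      sum(x$exclusion_report$reason != "none"), "excluded\n")
  invisible(x)
}
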