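#' Build a peri-event tensor
#'
#' Slices the z-scored traces into fixed windows around an alignment event
#' (cue onset or press) for every trial, giving an ROI x trial x sample
#' array. The window spans `window` seconds around the event frame with
#' round(span * rate) + 1 samples, centered at t = 0. Trials are invalid if
#' their window is truncated by the session edge or if any |z| inside it
#' exceeds `artifact_z_threshold` (amplitude-threshold artifact exclusion).
#'
#' @param traces a `trace_matrix` from [preprocess_session()].
#' @param events an `event_log`.
#' @param alignment `"cue_onset"` or `"press"`; presses are restricted to
#'   rewarded (trial) presses.
#' @param window seconds around the event, default c(-5, 5).
#' @param artifact_z_threshold |z| artifact threshold (default from the
#'   preprocessing config, 10).
#' @param conditions restrict to these block types (default both).
#' @return a `peri_event_tensor`: list(data ROI x trial x sample, time,
#'   window, sample_rate, alignment, condition / reaction_time / trial_index /
#'   valid per trial, cell_type, roi_ids).
#' @export
build_tensor <- function(traces, events, alignment = c("press", "cue_onset"),
                         window = c(-5, 5),
                         artifact_z_threshold = NULL,
                         conditions = c("cued", "self_paced")) {
  stopifnot(inherits(traces, "trace_matrix"))
  alignment <- match.arg(alignment)
  thr <- artifact_z_threshold %||% traces$config$artifact_z_threshold %||% 10
  ev <- events$events
  tt <- build_trial_table(events)
  tt <- tt[tt$block_type %in% conditions, ]
  align_time <- if (alignment == "press") tt$press_time else tt$cue_onset
  keep <- !is.na(align_time)
  tt <- tt[keep, ]; align_time <- align_time[keep]
  if (nrow(tt) == 0L) stop("no trials with the requested alignment event")

  rate <- traces$frame_rate
  pre <- round(-window[1] * rate); post <- round(window[2] * rate)
  nsamp <- pre + post + 1L
  nf <- ncol(traces$z)
  frames <- align_events_to_frames(align_time, traces$frame_times)

  n_roi <- nrow(traces$z)
  data <- array(NA_real_, dim = c(n_roi, nrow(tt), nsamp))
  valid <- logical(nrow(tt))
  for (j in seq_len(nrow(tt))) {
    cf <- frames[j]
    if (is.na(cf) || cf - pre < 1L || cf + post > nf) { valid[j] <- FALSE; next }
    sl <- traces$z[, (cf - pre):(cf + post), drop = FALSE]
    data[, j, ] <- sl
    valid[j] <- all(abs(sl) <= thr)
  }
  if (!any(valid)) stop("no valid trials in tensor")
  structure(list(data = data, time = seq(-pre, post) / rate, window = window,
                 sample_rate = rate, alignment = alignment,
                 condition = tt$block_type, reaction_time = tt$reaction_time,
                 trial_index = tt$trial_index, valid = valid,
                 cell_type = traces$cell_type, roi_ids = seq_len(n_roi)),
            class = "peri_event_tensor")
}

#' @export
print.peri_event_tensor <- function(x, ...) {
  cat("peri_event_tensor:", dim(x$data)[1], "ROIs x", dim(x$data)[2],
      "trials x", dim(x$data)[3], "samples;", sum(x$valid), "valid trials;",
      "aligned to", x$alignment, "\n")
  invisible(x)
}

#' Trial-averaged activity
#'
#' Per-ROI mean over valid trials, optionally filtered by condition; returns
#' an ROI x sample matrix. Invalid trials never enter the average.
#'
#' @param tensor a `peri_event_tensor`.
#' @param condition optional block type(s) to keep.
#' @param trials optional explicit trial subset (indices into the tensor's
#'   trial axis), intersected with validity.
#' @return ROI x sample matrix.
#' @export
trial_average <- function(tensor, condition = NULL, trials = NULL) {
  sel <- tensor$valid
  if (!is.null(condition)) sel <- sel & tensor$condition %in% condition
  if (!is.null(trials)) sel <- sel & seq_along(sel) %in% trials
  if (!any(sel)) stop("empty trial selection")
  avg_over_trials(tensor$data[, sel, , drop = FALSE])
}

# mean over the trial axis of an ROI x trial x sample array
avg_over_trials <- function(d) {
  colSums(aperm(d, c(2, 1, 3)), dims = 1) / dim(d)[2]
}

#' Restrict a tensor to an ROI subset
#'
#' Subsets the ROI axis by cluster label, cell type, or explicit indices; all
#' downstream analyses accept the result unchanged.
#'
#' @param tensor a `peri_event_tensor`.
#' @param rois explicit ROI indices (into the tensor's ROI axis), or
#' @param cluster canonical cluster label(s) to keep, with
#' @param clusters the per-ROI canonical labels (from [canonicalize_labels()]),
#'   or
#' @param cell_type cell-type label(s) to keep ("D1"/"D2").
#' @return a `peri_event_tensor` on the ROI subset.
#' @export
restrict_tensor <- function(tensor, rois = NULL, cluster = NULL,
                            clusters = NULL, cell_type = NULL) {
  keep <- rep(TRUE, dim(tensor$data)[1])
  if (!is.null(rois)) keep <- keep & seq_along(keep) %in% rois
  if (!is.null(cluster)) {
    if (is.null(clusters)) stop("cluster filter needs per-ROI labels")
    keep <- keep & clusters %in% cluster
  }
  if (!is.null(cell_type)) keep <- keep & tensor$cell_type %in% cell_type
  if (!any(keep)) stop("empty ROI selection")
  out <- tensor
  out$data <- tensor$data[keep, , , drop = FALSE]
  out$cell_type <- tensor$cell_type[keep]
  out$roi_ids <- tensor$roi_ids[keep]
  out
}
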