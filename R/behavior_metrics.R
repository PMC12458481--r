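#' Detect lever presses from the lever-position trace
#'
#' A press is an upward crossing of `threshold_mm` (below -> at/above),
#' debounced: after a crossing, the lever must return below threshold before
#' another press can be counted. Crossing times are linearly interpolated
#' between the bracketing samples.
#'
#' @param lever data.frame(time_s, position_mm), uniformly sampled.
#' @param threshold_mm displacement threshold (5 mm in the task).
#' @return numeric vector of press times (empty if none).
#' @export
detect_presses <- function(lever, threshold_mm = 5) {
  if (is.null(lever) || nrow(lever) == 0L) return(numeric(0))
  pos <- lever$position_mm
  above <- pos >= threshold_mm
  up <- which(!above[-length(above)] & above[-1]) # crossing between i and i+1
  if (length(up) == 0L) return(numeric(0))
  t0 <- lever$time_s[up]; t1 <- lever$time_s[up + 1L]
  p0 <- pos[up]; p1 <- pos[up + 1L]
  t0 + (threshold_mm - p0) / (p1 - p0) * (t1 - t0)
}

#' Build a per-trial table from an event log
#'
#' Reaction time is press - cue_onset in cued blocks and press - trial_start
#' in self-paced blocks; the rewarded flag comes from reward events. Trials
#' whose press precedes the reference event are flagged invalid.
#'
#' @param events an `event_log` (or its `$events` data.frame).
#' @return a `trial_table` data.frame: trial_index, block_type, block_index,
#'   trial_start, cue_onset (NA in self-paced), press_time, rewarded,
#'   reaction_time, valid.
#' @export
build_trial_table <- function(events) {
  ev <- if (inherits(events, "event_log")) events$events else events
  tidx <- sort(unique(ev$trial_index[!is.na(ev$trial_index) &
                                       ev$kind == "trial_start"]))
  one <- function(ti) {
    rows <- ev[!is.na(ev$trial_index) & ev$trial_index == ti, ]
    ts <- rows$time[rows$kind == "trial_start"][1]
    cue <- if (any(rows$kind == "cue_onset"))
      rows$time[rows$kind == "cue_onset"][1] else NA_real_
    press <- if (any(rows$kind == "press"))
      rows$time[rows$kind == "press"][1] else NA_real_
    btype <- rows$block_type[1]
    ref <- if (btype == "cued") cue else ts
    rt <- if (!is.na(press) && !is.na(ref)) press - ref else NA_real_
    data.frame(trial_index = ti, block_type = btype,
               block_index = rows$block_index[1],
               trial_start = ts, cue_onset = cue, press_time = press,
               rewarded = any(rows$kind == "reward"),
               reaction_time = rt,
               valid = is.na(rt) || rt >= 0)
  }
  out <- do.call(rbind, lapply(tidx, one))
  class(out) <- c("trial_table", "data.frame")
  out
}

#' Per-block behavioral metrics
#'
#' Push rate and reward rate per minute and the rewarded fraction of presses,
#' per block. Counts include unrewarded (ITI) presses. Zero presses in a
#' block yields a missing (NA) rewarded fraction, not 0.
#'
#' @param events an `event_log`.
#' @return data.frame: block_index, block_type, duration_min, n_presses,
#'   n_rewards, push_rate, reward_rate, rewarded_fraction.
#' @export
block_metrics <- function(events) {
  ev <- if (inherits(events, "event_log")) events$events else events
  blocks <- sort(unique(ev$block_index))
  out <- lapply(blocks, function(b) {
    rows <- ev[ev$block_index == b, ]
    t0 <- min(rows$time); t1 <- max(rows$time)
    dur <- (t1 - t0) / 60
    if (dur <= 0) stop("block with non-positive duration")
    np <- sum(rows$kind == "press"); nr <- sum(rows$kind == "reward")
    data.frame(block_index = b, block_type = rows$block_type[1],
               duration_min = dur, n_presses = np, n_rewards = nr,
               push_rate = np / dur, reward_rate = nr / dur,
               rewarded_fraction = if (np > 0) nr / np else NA_real_)
  })
  do.call(rbind, out)
}

#' Lever-trajectory similarity across presses
#'
#' Extracts press-aligned lever segments and computes their pairwise Pearson
#' correlation matrix, the mean trajectory per context, and the correlation
#' between the two context means. Constant segments get NA correlations.
#'
#' @param events an `event_log` with a lever trace.
#' @param window seconds around each press, default c(-0.5, 1).
#' @param rewarded_only use only rewarded (trial) presses; default TRUE.
#' @return list(cross_corr_matrix, segments (press x sample), context (per
#'   segment), time (per sample), mean_trajectory (list cued/self_paced),
#'   context_correlation).
#' @export
trajectory_similarity <- function(events, window = c(-0.5, 1),
                                  rewarded_only = TRUE) {
  ev <- events$events
  lever <- events$lever
  rate <- 1 / stats::median(diff(lever$time_s))
  press <- ev[ev$kind == "press", ]
  if (rewarded_only) press <- press[!is.na(press$trial_index), ]
  half_pre <- round(-window[1] * rate); half_post <- round(window[2] * rate)
  segs <- list(); ctx <- character(0)
  for (j in seq_len(nrow(press))) {
    ci <- which.min(abs(lever$time_s - press$time[j]))
    i0 <- ci - half_pre; i1 <- ci + half_post
    if (i0 < 1L || i1 > nrow(lever)) next
    segs[[length(segs) + 1L]] <- lever$position_mm[i0:i1]
    ctx <- c(ctx, press$block_type[j])
  }
  if (length(segs) < 2L) stop("need at least 2 press-aligned segments")
  m <- do.call(rbind, segs)
  sds <- apply(m, 1, stats::sd)
  cc <- suppressWarnings(stats::cor(t(m)))
  cc[sds == 0, ] <- NA_real_; cc[, sds == 0] <- NA_real_
  diag(cc) <- 1
  mean_traj <- lapply(split(seq_along(ctx), ctx), function(ix)
    colMeans(m[ix, , drop = FALSE]))
  ctx_cor <- if (all(c("cued", "self_paced") %in% names(mean_traj)))
    stats::cor(mean_traj$cued, mean_traj$self_paced) else NA_real_
  list(cross_corr_matrix = cc, segments = m, context = ctx,
       time = seq(-half_pre, half_post) / rate,
       mean_trajectory = mean_traj, context_correlation = ctx_cor)
}

#' Map event times to imaging frames
#'
#' Each event is assigned the nearest preceding frame (causal convention: a
#' neural frame cannot precede its own timestamp). Events outside the imaging
#' span get NA.
#'
#' @param times event times, seconds.
#' @param frame_times strictly increasing frame timestamps.
#' @return integer frame indices (NA outside the span).
#' @export
align_events_to_frames <- function(times, frame_times) {
  if (is.unsorted(frame_times, strictly = TRUE))
    stop("frame_times must be strictly increasing")
  idx <- findInterval(times, frame_times)
  idx[idx == 0L] <- NA_integer_
  idx[times > frame_times[length(frame_times)]] <- NA_integer_
  as.integer(idx)
}
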