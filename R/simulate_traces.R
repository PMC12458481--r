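#' Neural population configuration
#'
#' Parameters of the synthetic fluorescence generator. Each neuron belongs to
#' one of three planted response archetypes mirroring the functional clusters
#' seen in dorsolateral striatum during this task: `action` neurons respond at
#' every lever press in both contexts, `cue` neurons respond only to the go
#' cue, and `post_action` neurons respond after reward with a peak near +1 s.
#' Responses are calcium-transient kernels (difference of exponentials,
#' GCaMP8-like) scaled by a per-neuron amplitude; responses on cued-block
#' events additionally carry a multiplicative context gain. D1-labelled cue
#' neurons are boosted (`d1_cue_boost`, early cue response) and D2-labelled
#' post-action neurons are boosted (`d2_post_boost`, 1--2 s post-event
#' component), matching the direction of the reported D1/D2 differences.
#'
#' @param n_neurons ROI count.
#' @param frame_rate imaging rate, Hz.
#' @param cluster_proportions named numeric over action / cue / post_action,
#'   summing to 1.
#' @param context_gain multiplicative factor on cued-block responses (scalar,
#'   or length `n_neurons` for per-neuron gains).
#' @param d1_fraction fraction of ROIs labelled D1 (the rest D2).
#' @param d1_cue_boost,d2_post_boost cell-type amplitude boosts (see above).
#' @param kernel_rise,kernel_decay transient kernel time constants, seconds.
#' @param amplitude_mean mean transient amplitude, a.u. (per-neuron lognormal).
#' @param noise_sd additive Gaussian noise sd, a.u. (everywhere).
#' @param baseline_drift_amplitude amplitude of the slow sinusoid + linear
#'   trend added to each raw trace, a.u.; exercises the percentile baseline.
#' @param neuropil_gain scaling of the smoothed population-shared signal that
#'   forms the neuropil trace.
#' @param contamination fraction of the noiseless neuropil signal mixed into
#'   each raw trace; matches the 0.7 correction coefficient downstream.
#' @param f0,neuropil_f0 static fluorescence offsets, a.u.
#' @param context_effect optional planted, time-localized context difference:
#'   a list with `window` (seconds relative to the press), `amplitude` (a.u.),
#'   `fraction` (of ROIs carrying it) or `rois` (explicit indices), `mode`
#'   (`"cued_only"`: bump added on cued presses; `"antisymmetric"`: +bump on
#'   cued, -bump on self-paced presses), `mean_zero` (logical; if TRUE the
#'   per-neuron bump signs are balanced +/-1 so the population-mean difference
#'   is ~0) and `pure` (logical; if TRUE the carrier ROIs lose their archetype
#'   response, making the context-axis support disjoint from the action-axis
#'   support). Used to plant divergence windows and context-axis supports.
#' @param seed master seed.
#' @return a `neural_config` list.
#' @export
neural_config <- function(n_neurons = 100L,
                          frame_rate = 30,
                          cluster_proportions = c(action = 0.2, cue = 0.55,
                                                  post_action = 0.25),
                          context_gain = 1.2,
                          d1_fraction = 0.5,
                          d1_cue_boost = 1.8,
                          d2_post_boost = 1.4,
                          kernel_rise = 0.05,
                          kernel_decay = 0.5,
                          amplitude_mean = 30,
                          noise_sd = 5,
                          baseline_drift_amplitude = 5,
                          neuropil_gain = 0.5,
                          contamination = 0.7,
                          f0 = 100,
                          neuropil_f0 = 20,
                          context_effect = NULL,
                          seed = 1L) {
  p <- cluster_proportions
  if (is.null(names(p))) names(p) <- c("action", "cue", "post_action")
  if (abs(sum(p) - 1) > 1e-8) stop("cluster_proportions must sum to 1")
  if (kernel_rise >= kernel_decay) stop("kernel_rise must be < kernel_decay")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (d1_fraction < 0 || d1_fraction > 1) stop("d1_fraction must be in [0,1]")
  if (!is.null(context_effect)) {
    stopifnot(length(context_effect$window) == 2L,
              context_effect$window[1] < context_effect$window[2])
    context_effect$mode <- context_effect$mode %||% "cued_only"
    context_effect$mean_zero <- context_effect$mean_zero %||% TRUE
    stopifnot(context_effect$mode %in% c("cued_only", "antisymmetric"))
  }
  structure(list(n_neurons = as.integer(n_neurons), frame_rate = frame_rate,
                 cluster_proportions = p[c("action", "cue", "post_action")],
                 context_gain = context_gain, d1_fraction = d1_fraction,
                 d1_cue_boost = d1_cue_boost, d2_post_boost = d2_post_boost,
                 kernel_rise = kernel_rise, kernel_decay = kernel_decay,
                 amplitude_mean = amplitude_mean, noise_sd = noise_sd,
                 baseline_drift_amplitude = baseline_drift_amplitude,
                 neuropil_gain = neuropil_gain, contamination = contamination,
                 f0 = f0, neuropil_f0 = neuropil_f0,
                 context_effect = context_effect, seed = as.integer(seed)),
            class = "neural_config")
}

#' Calcium transient kernel
#'
#' Peak-normalized difference of exponentials,
#' k(t) = (exp(-t/decay) - exp(-t/rise)) / peak for t >= 0, zero before.
#'
#' @param t times in seconds (vector).
#' @param rise,decay time constants in seconds, rise < decay.
#' @return kernel values, peak value 1.
#' @export
calcium_kernel <- function(t, rise = 0.05, decay = 0.5) {
  stopifnot(rise < decay)
  tp <- kernel_peak_time(rise, decay)
  peak <- exp(-tp / decay) - exp(-tp / rise)
  k <- ifelse(t >= 0, (exp(-t / decay) - exp(-t / rise)) / peak, 0)
  k[!is.finite(k)] <- 0
  k
}

#' @rdname calcium_kernel
#' @export
kernel_peak_time <- function(rise = 0.05, decay = 0.5) {
  rise * decay / (decay - rise) * log(decay / rise)
}

# Deterministic archetype counts from proportions (largest-remainder rule),
# so planted proportions are exact up to integer rounding.
archetype_counts <- function(n, p) {
  raw <- n * p
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    ord <- order(raw - cnt, decreasing = TRUE)
    cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1L
  }
  as.integer(cnt)
}

# Raised-cosine bump over a window, unit peak.
bump_shape <- function(t, window) {
  span <- window[2] - window[1]
  u <- (t - window[1]) / span
  b <- ifelse(u >= 0 & u <= 1, 0.5 * (1 - cos(2 * pi * u)), 0)
  b
}

#' Simulate raw fluorescence and neuropil traces for a session
#'
#' Builds each neuron's noiseless signal as baseline drift plus a sum of
#' calcium kernels triggered by its archetype's events (action: every press;
#' cue: cue onsets; post_action: rewards, peaking ~1 s later), with
#' context-dependent gain on cued-block responses and cell-type boosts. The
#' neuropil trace is a smoothed population-shared signal; a matching fraction
#' of it contaminates every raw trace so the downstream 0.7-coefficient
#' correction is meaningful. Gaussian noise of sd `noise_sd` is added to raw
#' and neuropil traces independently. Seed sub-streams: behavior (in the event
#' log), cell identities/amplitudes, noise.
#'
#' @param events an `event_log` from [generate_behavior()].
#' @param config a [neural_config()].
#' @return list with `recording` (a `session_recording`: frame_rate,
#'   frame_times, raw_f, neuropil_f — both ROI x frame — and cell_type) and
#'   `truth` (a `ground_truth`: per-ROI `cluster_id`, realized `context_gain`,
#'   `divergence_window`, planted context-effect ROI indices and signs, the
#'   noiseless `signal` matrix, and per-neuron amplitudes).
#' @export
generate_traces <- function(events, config) {
  stopifnot(inherits(events, "event_log"), inherits(config, "neural_config"))
  ev <- events$events
  if (nrow(ev) == 0L || max(ev$time) <= 0) stop("empty EventLog")

  n <- config$n_neurons
  fr <- config$frame_rate
  t_end <- max(ev$time) + 5
  frame_times <- seq(0, t_end, by = 1 / fr)
  nf <- length(frame_times)

  set.seed(sub_seed(config$seed, 2L))
  cnt <- archetype_counts(n, config$cluster_proportions)
  cluster_id <- sample(rep(c("action", "cue", "post_action"), times = cnt))
  n_d1 <- round(n * config$d1_fraction)
  cell_type <- sample(rep(c("D1", "D2"), times = c(n_d1, n - n_d1)))
  amplitude <- stats::rlnorm(n, meanlog = log(config$amplitude_mean), sdlog = 0.2)
  gain <- rep_len(config$context_gain, n)
  phase <- stats::runif(n, 0, 2 * pi)

  ce <- config$context_effect
  ce_rois <- integer(0); ce_sign <- numeric(0)
  if (!is.null(ce)) {
    ce_rois <- if (!is.null(ce$rois)) as.integer(ce$rois) else
      sort(sample.int(n, max(1L, round((ce$fraction %||% 0.5) * n))))
    ce_sign <- if (isTRUE(ce$mean_zero))
      rep_len(c(1, -1), length(ce_rois))[sample.int(length(ce_rois))]
    else rep(1, length(ce_rois))
    if (isTRUE(ce$pure)) amplitude[ce_rois] <- 0
  }

  # trigger events per archetype; post_action kernels are shifted so the
  # transient peaks ~1 s after the reward
  tp <- kernel_peak_time(config$kernel_rise, config$kernel_decay)
  presses   <- ev[ev$kind == "press", c("time", "block_type")]
  cues      <- ev[ev$kind == "cue_onset", c("time", "block_type")]
  rewards   <- ev[ev$kind == "reward", c("time", "block_type")]
  rewards$time <- rewards$time + (1 - tp)
  trig <- list(action = presses, cue = cues, post_action = rewards)

  # kernel support: until the transient decays to <1e-4 of peak
  supp <- ceiling((config$kernel_decay * log(1e4) + tp) * fr)
  kern_of <- function(t0) {
    i0 <- max(1L, floor(t0 * fr) + 1L)
    i1 <- min(nf, i0 + supp)
    idx <- i0:i1
    list(idx = idx, k = calcium_kernel(frame_times[idx] - t0,
                                       config$kernel_rise, config$kernel_decay))
  }

  signal <- matrix(0, nrow = n, ncol = nf)
  for (i in seq_len(n)) {
    tr <- trig[[cluster_id[i]]]
    if (nrow(tr) == 0L) next
    a_base <- amplitude[i]
    if (cell_type[i] == "D1" && cluster_id[i] == "cue")
      a_base <- a_base * config$d1_cue_boost
    if (cell_type[i] == "D2" && cluster_id[i] == "post_action")
      a_base <- a_base * config$d2_post_boost
    for (j in seq_len(nrow(tr))) {
      a <- a_base * if (tr$block_type[j] == "cued") gain[i] else 1
      kk <- kern_of(tr$time[j])
      signal[i, kk$idx] <- signal[i, kk$idx] + a * kk$k
    }
  }

  # planted, time-localized context difference around rewarded presses
  if (!is.null(ce) && length(ce_rois)) {
    tr_press <- ev[ev$kind == "press" & !is.na(ev$trial_index),
                   c("time", "block_type")]
    span <- ce$window
    for (j in seq_len(nrow(tr_press))) {
      ctx_sign <- if (tr_press$block_type[j] == "cued") 1 else
        if (ce$mode == "antisymmetric") -1 else 0
      if (ctx_sign == 0) next
      lo <- tr_press$time[j] + span[1]; hi <- tr_press$time[j] + span[2]
      i0 <- max(1L, floor(lo * fr) + 1L); i1 <- min(nf, ceiling(hi * fr) + 1L)
      if (i1 <= i0) next
      idx <- i0:i1
      b <- bump_shape(frame_times[idx] - tr_press$time[j], span)
      for (m in seq_along(ce_rois))
        signal[ce_rois[m], idx] <- signal[ce_rois[m], idx] +
          ctx_sign * ce_sign[m] * ce$amplitude * b
    }
  }

  # drift, shared neuropil, contamination, noise
  drift <- if (config$baseline_drift_amplitude > 0) {
    tt <- frame_times / t_end
    t(vapply(seq_len(n), function(i)
      config$baseline_drift_amplitude *
        (sin(2 * pi * frame_times / 300 + phase[i]) + (tt - 0.5)),
      numeric(nf)))
  } else matrix(0, n, nf)

  shared <- colMeans(signal)
  neuropil_clean <- config$neuropil_f0 +
    config$neuropil_gain * gaussian_smooth(shared, 0.2, fr)

  set.seed(sub_seed(config$seed, 3L))
  noise_raw <- if (config$noise_sd > 0)
    matrix(stats::rnorm(n * nf, 0, config$noise_sd), n, nf) else matrix(0, n, nf)
  noise_neu <- if (config$noise_sd > 0)
    matrix(stats::rnorm(n * nf, 0, config$noise_sd), n, nf) else matrix(0, n, nf)

  raw_f <- sweep(signal + drift + noise_raw, 2,
                 config$contamination * neuropil_clean, `+`) + config$f0
  neuropil_f <- sweep(noise_neu, 2, neuropil_clean, `+`)

  recording <- structure(list(frame_rate = fr, frame_times = frame_times,
                              raw_f = raw_f, neuropil_f = neuropil_f,
                              cell_type = cell_type),
                         class = "session_recording")
  truth <- structure(list(cluster_id = cluster_id,
                          context_gain = gain,
                          divergence_window = if (!is.null(ce)) ce$window else NULL,
                          context_rois = ce_rois, context_signs = ce_sign,
                          amplitude = amplitude,
                          signal = signal),
                     class = "ground_truth")
  list(recording = recording, truth = truth)
}

#' @export
print.session_recording <- function(x, ...) {
  cat("session_recording:", nrow(x$raw_f), "ROIs x", ncol(x$raw_f), "frames @",
      x$frame_rate, "Hz;", sum(x$cell_type == "D1"), "D1 /",
      sum(x$cell_type == "D2"), "D2\n")
  invisible(x)
}

#' Simulate a full session (behavior + traces)
#'
#' Convenience wrapper chaining [generate_behavior()] and [generate_traces()];
#' the behavior seed is taken from `bcfg`, the neural seed from `ncfg`.
#'
#' @param bcfg a [behavior_config()].
#' @param ncfg a [neural_config()].
#' @return list(events, recording, truth).
#' @export
simulate_session <- function(bcfg = behavior_config(), ncfg = neural_config()) {
  events <- generate_behavior(bcfg)
  tr <- generate_traces(events, ncfg)
  list(events = events, recording = tr$recording, truth = tr$truth)
}
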