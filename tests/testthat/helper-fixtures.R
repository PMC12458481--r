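# Shared synthetic fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# small standard session: 1 block pair, 12 rewards/block, 60 neurons
fix_session <- function() {
  if (is.null(.fixtures$ses)) {
    bc <- behavior_config(n_block_pairs = 1L, rewards_per_block = 12L,
                          seed = 11L)
    nc <- neural_config(n_neurons = 60L, seed = 12L)
    ses <- simulate_session(bc, nc)
    ses$traces <- preprocess_session(ses$recording)
    ses$tensor_press <- build_tensor(ses$traces, ses$events, "press")
    ses$tensor_cue <- build_tensor(ses$traces, ses$events, "cue_onset",
                                   conditions = "cued")
    .fixtures$ses <- ses
  }
  .fixtures$ses
}

# zero-noise, zero-drift session for exactness checks
fix_clean_session <- function() {
  if (is.null(.fixtures$clean)) {
    bc <- behavior_config(n_block_pairs = 1L, rewards_per_block = 8L,
                          unrewarded_presses_per_trial = 0, seed = 21L)
    nc <- neural_config(n_neurons = 30L, noise_sd = 0,
                        baseline_drift_amplitude = 0, seed = 22L)
    .fixtures$clean <- simulate_session(bc, nc)
  }
  .fixtures$clean
}

# wrap a bare z matrix as a trace_matrix
make_trace_matrix <- function(z, rate = 30) {
  structure(list(z = z, dff = z, kept_rois = seq_len(nrow(z)),
                 exclusion_report = data.frame(roi = seq_len(nrow(z)),
                                               reason = "none"),
                 frame_rate = rate,
                 frame_times = seq(0, by = 1 / rate, length.out = ncol(z)),
                 cell_type = rep("D1", nrow(z)),
                 config = preprocess_config()),
            class = "trace_matrix")
}

# minimal event_log with given per-trial times
make_event_log <- function(trial_start, press, cue = NULL,
                           block_type = "self_paced", lever = NULL) {
  n <- length(trial_start)
  rows <- list()
  add <- function(time, kind, ti) data.frame(
    time = time, kind = kind, block_type = block_type,
    block_index = 1L, trial_index = ti)
  rows[[1]] <- add(min(trial_start) - 1, "block_start", NA_integer_)
  for (i in seq_len(n)) {
    rows[[length(rows) + 1]] <- add(trial_start[i], "trial_start", i)
    if (!is.null(cue)) rows[[length(rows) + 1]] <- add(cue[i], "cue_onset", i)
    rows[[length(rows) + 1]] <- add(press[i], "press", i)
    rows[[length(rows) + 1]] <- add(press[i], "reward", i)
  }
  ev <- do.call(rbind, rows)
  ev <- ev[order(ev$time), ]
  structure(list(events = ev, lever = lever, truth = NULL, config = NULL),
            class = "event_log")
}

# wrap an ROI x trial x bin array as a binned_tensor
make_binned <- function(data, labels, centers = NULL) {
  nb <- dim(data)[3]
  structure(list(data = data,
                 bin_centers = centers %||% seq_len(nb),
                 bin_width = 0.066, labels = labels,
                 valid = rep(TRUE, dim(data)[2]),
                 reaction_time = rep(NA_real_, dim(data)[2]),
                 cell_type = rep("D1", dim(data)[1]),
                 roi_ids = seq_len(dim(data)[1]),
                 alignment = "press"),
            class = "binned_tensor")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
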