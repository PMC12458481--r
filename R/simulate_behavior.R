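#' Behavioral task configuration
#'
#' Parameters of the alternating cued / self-paced lever-press session.
#' Defaults reproduce the published task structure: three block pairs, each
#' beginning with a cued block, blocks ending after ~30 rewards; in cued
#' blocks a 4--8 s intertrial interval is followed by a 1.5--2.5 s hold and a
#' go cue, with a reward for presses crossing 5 mm within 2 s of the cue; in
#' self-paced blocks a 2--3 s ITI and a 1--2 s quiet period precede the trial
#' start. Reaction times are exponential with mean 0.30 s (cued, truncated at
#' the response window) and 6.0 s (self-paced).
#'
#' @param n_block_pairs number of cued+self-paced block pairs.
#' @param rewards_per_block rewards collected before a block transition.
#' @param cued_iti_range,self_iti_range ITI ranges, seconds.
#' @param cued_hold_range hold period before the go cue, seconds.
#' @param self_quiet_range quiet period before a self-paced trial start, seconds.
#' @param cue_response_window time after the cue within which a press is
#'   rewarded, seconds.
#' @param press_threshold_mm lever displacement that defines a press, mm.
#' @param cued_rt_mean,self_rt_mean mean reaction times, seconds.
#' @param unrewarded_presses_per_trial expected number of extra (unrewarded)
#'   ITI presses per trial, Poisson. After dead-time and minimum-spacing
#'   losses the default 1.5 places roughly one unrewarded press per rewarded
#'   one, putting the rewarded fraction near 0.5. Set to 0 to disable.
#' @param lever_rate_hz sampling rate of the simulated lever trace.
#' @param seed master seed for the session.
#' @return a `behavior_config` list.
#' @export
behavior_config <- function(n_block_pairs = 3L,
                            rewards_per_block = 30L,
                            cued_iti_range = c(4, 8),
                            self_iti_range = c(2, 3),
                            cued_hold_range = c(1.5, 2.5),
                            self_quiet_range = c(1, 2),
                            cue_response_window = 2,
                            press_threshold_mm = 5,
                            cued_rt_mean = 0.30,
                            self_rt_mean = 6.0,
                            unrewarded_presses_per_trial = 1.5,
                            lever_rate_hz = 100,
                            seed = 1L) {
  cfg <- list(n_block_pairs = as.integer(n_block_pairs),
              rewards_per_block = as.integer(rewards_per_block),
              cued_iti_range = as.numeric(cued_iti_range),
              self_iti_range = as.numeric(self_iti_range),
              cued_hold_range = as.numeric(cued_hold_range),
              self_quiet_range = as.numeric(self_quiet_range),
              cue_response_window = cue_response_window,
              press_threshold_mm = press_threshold_mm,
              cued_rt_mean = cued_rt_mean,
              self_rt_mean = self_rt_mean,
              unrewarded_presses_per_trial = unrewarded_presses_per_trial,
              lever_rate_hz = lever_rate_hz,
              seed = as.integer(seed))
  validate_behavior_config(cfg)
  class(cfg) <- "behavior_config"
  cfg
}

validate_behavior_config <- function(cfg) {
  rng <- function(r) length(r) == 2L && r[1] <= r[2] && all(r > 0)
  if (cfg$rewards_per_block < 1L)
    stop("rewards_per_block must be at least 1")
  if (cfg$n_block_pairs < 1L)
    stop("n_block_pairs must be at least 1")
  if (!rng(cfg$cued_iti_range) || !rng(cfg$self_iti_range) ||
      !rng(cfg$cued_hold_range) || !rng(cfg$self_quiet_range))
    stop("degenerate range: every range needs low <= high, both positive")
  if (cfg$cued_rt_mean < 0 || cfg$self_rt_mean <= 0)
    stop("reaction-time means must be positive")
  if (cfg$cue_response_window <= 0 || cfg$press_threshold_mm <= 0)
    stop("cue_response_window and press_threshold_mm must be positive")
  if (cfg$cued_rt_mean >= cfg$cue_response_window)
    warning("cued_rt_mean >= cue_response_window: hit rate will be degenerate")
  invisible(cfg)
}

# Truncated-exponential RT draw: exponential with the given mean, conditioned
# on being < upper (cued trials always respond within the response window).
rtrunc_exp <- function(n, mean, upper = Inf) {
  if (mean == 0) return(rep(0, n))
  if (is.finite(upper)) {
    u <- stats::runif(n, 0, 1 - exp(-upper / mean))
    -mean * log(1 - u)
  } else {
    stats::rexp(n, rate = 1 / mean)
  }
}

# Lever kinematic template: half-sine push of 8 mm amplitude and 0.4 s
# duration, shared across contexts (so press trajectories are near-identical
# between cued and self-paced blocks by construction). Returns the time from
# movement onset at which the template first crosses `threshold` upward.
lever_template <- function(amplitude = 8, duration = 0.4) {
  list(amplitude = amplitude, duration = duration,
       position = function(t) {
         p <- amplitude * sin(pi * t / duration)
         p[t < 0 | t > duration] <- 0
         p
       },
       cross_time = function(threshold) {
         (duration / pi) * asin(threshold / amplitude)
       })
}

#' Simulate a behavioral session
#'
#' Generates the event log and lever-position trace of one alternating-block
#' session. Blocks alternate cued -> self-paced starting with a cued block;
#' each block runs until `rewards_per_block` rewards. Cued presses occur at
#' cue onset + RT drawn from an exponential of mean `cued_rt_mean` truncated
#' at `cue_response_window`; self-paced presses at trial start + an
#' exponential RT of mean `self_rt_mean`. Unrewarded presses are inserted in
#' intertrial intervals at a configurable Poisson rate. Every press drives the
#' shared half-sine lever template, which crosses `press_threshold_mm` exactly
#' at the press time.
#'
#' @param config a [behavior_config()].
#' @return an `event_log`: list with `events` (data.frame: time, kind,
#'   block_type, block_index, trial_index), `lever` (data.frame: time_s,
#'   position_mm), `config`, and a `truth` data.frame of per-trial drawn
#'   reaction times (generator ground truth for round-trip tests).
#' @export
generate_behavior <- function(config) {
  validate_behavior_config(config)
  set.seed(sub_seed(config$seed, 1L))
  tpl <- lever_template()
  t_cross <- tpl$cross_time(config$press_threshold_mm)

  ev <- list(); truth <- list()
  t <- 0; trial_idx <- 0L
  add <- function(time, kind, btype, bidx, tidx)
    list(time = time, kind = kind, block_type = btype,
         block_index = bidx, trial_index = tidx)

  n_blocks <- 2L * config$n_block_pairs
  for (b in seq_len(n_blocks)) {
    btype <- if (b %% 2L == 1L) "cued" else "self_paced"
    ev[[length(ev) + 1L]] <- add(t, "block_start", btype, b, NA_integer_)
    for (r in seq_len(config$rewards_per_block)) {
      trial_idx <- trial_idx + 1L
      if (btype == "cued") {
        iti <- stats::runif(1, config$cued_iti_range[1], config$cued_iti_range[2])
        hold <- stats::runif(1, config$cued_hold_range[1], config$cued_hold_range[2])
        trial_start <- t + iti
        cue <- trial_start + hold
        rt <- rtrunc_exp(1, config$cued_rt_mean, config$cue_response_window)
        press <- cue + rt
        ev[[length(ev) + 1L]] <- add(trial_start, "trial_start", btype, b, trial_idx)
        ev[[length(ev) + 1L]] <- add(cue, "cue_onset", btype, b, trial_idx)
      } else {
        iti <- stats::runif(1, config$self_iti_range[1], config$self_iti_range[2])
        quiet <- stats::runif(1, config$self_quiet_range[1], config$self_quiet_range[2])
        trial_start <- t + iti + quiet
        cue <- NA_real_
        rt <- rtrunc_exp(1, config$self_rt_mean)
        press <- trial_start + rt
        ev[[length(ev) + 1L]] <- add(trial_start, "trial_start", btype, b, trial_idx)
      }
      # unrewarded presses land in the pre-trial dead time, kept clear of the
      # rewarded press and of the trial reference events
      n_extra <- stats::rpois(1, config$unrewarded_presses_per_trial)
      if (n_extra > 0) {
        lo <- t + 0.5
        hi <- trial_start - 0.5
        if (hi > lo) {
          extras <- sort(stats::runif(n_extra, lo, hi))
          # keep presses >= 0.6 s apart so lever templates never overlap
          keep <- c(TRUE, diff(extras) >= 0.6)
          for (x in extras[keep])
            ev[[length(ev) + 1L]] <- add(x, "press", btype, b, NA_integer_)
        }
      }
      ev[[length(ev) + 1L]] <- add(press, "press", btype, b, trial_idx)
      ev[[length(ev) + 1L]] <- add(press, "reward", btype, b, trial_idx)
      truth[[length(truth) + 1L]] <- list(trial_index = trial_idx,
                                          block_type = btype, block_index = b,
                                          trial_start = trial_start,
                                          cue_onset = cue, press_time = press,
                                          reaction_time = rt)
      t <- press
    }
    t <- t + 2  # post-block pause
  }

  col <- function(lst, f, proto) vapply(lst, function(e) {
    v <- e[[f]]; if (is.null(v)) proto else v
  }, proto)
  events <- data.frame(time = col(ev, "time", numeric(1)),
                       kind = col(ev, "kind", character(1)),
                       block_type = col(ev, "block_type", character(1)),
                       block_index = col(ev, "block_index", integer(1)),
                       trial_index = vapply(ev, function(e)
                         as.integer(e$trial_index), integer(1)))
  events <- events[order(events$time, match(events$kind,
            c("block_start", "trial_start", "cue_onset", "press", "reward"))), ]
  rownames(events) <- NULL
  truth <- data.frame(trial_index = col(truth, "trial_index", integer(1)),
                      block_type = col(truth, "block_type", character(1)),
                      block_index = col(truth, "block_index", integer(1)),
                      trial_start = col(truth, "trial_start", numeric(1)),
                      cue_onset = col(truth, "cue_onset", numeric(1)),
                      press_time = col(truth, "press_time", numeric(1)),
                      reaction_time = col(truth, "reaction_time", numeric(1)))

  # lever trace: template instance at every press; press time = threshold
  # up-crossing, so movement onset precedes it by the template crossing time
  t_end <- max(events$time) + 3
  lt <- seq(0, t_end, by = 1 / config$lever_rate_hz)
  pos <- numeric(length(lt))
  press_times <- events$time[events$kind == "press"]
  for (p in press_times) {
    onset <- p - t_cross
    idx <- which(lt >= onset & lt <= onset + tpl$duration)
    pos[idx] <- pmax(pos[idx], tpl$position(lt[idx] - onset))
  }

  structure(list(events = events,
                 lever = data.frame(time_s = lt, position_mm = pos),
                 truth = truth,
                 config = config),
            class = "event_log")
}

#' @export
print.event_log <- function(x, ...) {
  cat("event_log:", nrow(x$events), "events,",
      sum(x$events$kind == "reward"), "rewards,",
      length(unique(x$events$block_index)), "blocks,",
      sprintf("%.1f s\n", max(x$events$time)))
  invisible(x)
}

#' Write / read an event log as CSV
#'
#' `events.csv` has columns time,kind,block_type,block_index,trial_index;
#' the lever trace is `lever.csv` (time_s, position_mm).
#' @param log an `event_log`.
#' @param dir output directory (created if needed).
#' @export
write_event_log <- function(log, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(log$events, file.path(dir, "events.csv"), row.names = FALSE)
  utils::write.csv(log$lever, file.path(dir, "lever.csv"), row.names = FALSE)
  invisible(file.path(dir, c("events.csv", "lever.csv")))
}

#' @rdname write_event_log
#' @export
read_event_log <- function(dir) {
  events <- utils::read.csv(file.path(dir, "events.csv"),
                            colClasses = c(kind = "character",
                                           block_type = "character"))
  lever <- utils::read.csv(file.path(dir, "lever.csv"))
  structure(list(events = events, lever = lever, truth = NULL, config = NULL),
            class = "event_log")
}
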