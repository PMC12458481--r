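#' Bin a peri-event tensor into decoder time bins
#'
#' Averages consecutive non-overlapping groups of `frames_per_bin` frames
#' (2 frames = 66 ms at 30 Hz) within `window` around the alignment event.
#' The window is half-open; a leftover frame that does not fill a bin is
#' dropped at the window end (reported via message).
#'
#' @param tensor a `peri_event_tensor`.
#' @param frames_per_bin frames per bin (2).
#' @param window seconds around the event, default c(-2, 2) (the 4-s
#'   peri-event decoding window).
#' @return a `binned_tensor`: list(data ROI x trial x bin, bin_centers,
#'   bin_width, labels = per-trial condition, valid, cell_type, roi_ids,
#'   alignment).
#' @export
bin_tensor <- function(tensor, frames_per_bin = 2L, window = c(-2, 2)) {
  m <- window_mask(tensor$time, window)
  if (!any(m)) stop("window outside tensor span")
  idx <- which(m)
  nb <- length(idx) %/% frames_per_bin
  if (nb < 1L) stop("window shorter than one bin")
  drop <- length(idx) - nb * frames_per_bin
  if (drop > 0) message(sprintf("bin_tensor: dropping %d leftover frame(s)", drop))
  idx <- idx[seq_len(nb * frames_per_bin)]
  d <- tensor$data[, , idx, drop = FALSE]
  dims <- dim(d)
  dim(d) <- c(dims[1] * dims[2], frames_per_bin, nb)
  binned <- apply(d, c(1, 3), mean)
  dim(binned) <- c(dims[1], dims[2], nb)
  bt <- matrix(tensor$time[idx], nrow = frames_per_bin)
  structure(list(data = binned, bin_centers = colMeans(bt),
                 bin_width = frames_per_bin / tensor$sample_rate,
                 labels = tensor$condition, valid = tensor$valid,
                 reaction_time = tensor$reaction_time,
                 cell_type = tensor$cell_type, roi_ids = tensor$roi_ids,
                 alignment = tensor$alignment),
            class = "binned_tensor")
}

#' Balanced trial subsampling
#'
#' Random without-replacement subsample so both classes contribute
#' min(class counts) trials each.
#'
#' @param labels per-trial class labels (two classes).
#' @param seed RNG seed.
#' @return sorted integer indices of the selected trials.
#' @export
balance_trials <- function(labels, seed = 1L) {
  cls <- unique(labels)
  if (length(cls) != 2L) stop("balance_trials needs exactly two classes")
  n1 <- sum(labels == cls[1]); n2 <- sum(labels == cls[2])
  if (n1 == 0L || n2 == 0L) stop("a class has zero trials")
  m <- min(n1, n2)
  set.seed(seed)
  sel <- c(sample(which(labels == cls[1]), m),
           sample(which(labels == cls[2]), m))
  sort(sel)
}

# linear-SVM weight vector from an e1071 fit: w = t(coefs) %*% SV, b = -rho.
# Sign convention: decision value > 0 predicts the first factor level.
svm_weights <- function(fit) {
  w <- drop(crossprod(fit$coefs, fit$SV))
  list(w = w, b = -fit$rho)
}

#' Time-resolved linear decoding
#'
#' For each time bin independently: features are the population vector of
#' per-ROI bin means, one feature per neuron; a linear maximum-margin
#' classifier (SVM, cost `cost`) is trained with stratified k-fold
#' cross-validation on class-balanced trials, and accuracy is the mean
#' held-out fraction correct across folds. Weights come from a classifier
#' refit on all balanced trials at that bin.
#'
#' @param binned a `binned_tensor` with two label classes.
#' @param folds CV folds (10). If a class has fewer trials than folds the
#'   fold count is reduced with a warning.
#' @param cost SVM cost parameter (1).
#' @param seed seed for balancing and fold assignment.
#' @param labels optional per-trial labels overriding the tensor's (used by
#'   the shuffled-label null).
#' @param compute_weights refit on all trials per bin for weights (default
#'   TRUE; the null skips it).
#' @param balance subsample to equal class counts first (default TRUE).
#' @return a `decoder_result`: list(accuracy per bin, bin_centers, weights
#'   bin x ROI matrix, intercept per bin, n_per_class, trials_used, folds,
#'   classes, roi_ids, config echo).
#' @export
timebin_decode <- function(binned, folds = 10L, cost = 1, seed = 1L,
                           labels = NULL, compute_weights = TRUE,
                           balance = TRUE) {
  lab <- labels %||% binned$labels
  ok <- binned$valid & !is.na(lab)
  idx <- which(ok)
  lab <- lab[idx]
  cls <- sort(unique(lab))
  if (length(cls) != 2L) stop("decoding needs exactly two classes")
  if (balance) {
    bal <- balance_trials(lab, seed)
    idx <- idx[bal]; lab <- lab[bal]
  }
  n_min <- min(table(lab))
  if (n_min < folds) {
    folds <- max(2L, n_min)
    warning(sprintf("reducing folds to %d (smallest class has %d trials)",
                    folds, n_min))
  }
  y <- factor(lab, levels = cls)
  set.seed(sub_seed(seed, 11L))
  fold_id <- integer(length(y))
  for (cc in cls) {
    w <- which(lab == cc)
    fold_id[w] <- sample(rep_len(seq_len(folds), length(w)))
  }

  nb <- dim(binned$data)[3]
  n_roi <- dim(binned$data)[1]
  accuracy <- numeric(nb)
  weights <- if (compute_weights) matrix(NA_real_, nb, n_roi) else NULL
  intercept <- if (compute_weights) numeric(nb) else NULL
  for (b in seq_len(nb)) {
    x <- t(binned$data[, idx, b, drop = TRUE])
    if (n_roi == 1L) x <- matrix(x, ncol = 1L)
    acc_f <- vapply(seq_len(folds), function(f) {
      tr <- fold_id != f; te <- !tr
      fit <- e1071::svm(x[tr, , drop = FALSE], y[tr], kernel = "linear",
                        cost = cost, scale = FALSE)
      mean(stats::predict(fit, x[te, , drop = FALSE]) == y[te])
    }, numeric(1))
    accuracy[b] <- mean(acc_f)
    if (compute_weights) {
      fit <- e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE)
      sw <- svm_weights(fit)
      weights[b, ] <- sw$w
      intercept[b] <- sw$b
    }
  }
  structure(list(accuracy = accuracy, bin_centers = binned$bin_centers,
                 weights = weights, intercept = intercept,
                 n_per_class = n_min, trials_used = idx, folds = folds,
                 classes = cls, roi_ids = binned$roi_ids,
                 config_echo = list(folds = folds, cost = cost, seed = seed)),
            class = "decoder_result")
}

#' @export
print.decoder_result <- function(x, ...) {
  cat("decoder_result:", x$classes[1], "vs", x$classes[2], "|",
      length(x$accuracy), "bins |", x$n_per_class, "trials/class |",
      sprintf("peak accuracy %.2f at %+.3f s\n", max(x$accuracy),
              x$bin_centers[which.max(x$accuracy)]))
  invisible(x)
}

#' Shuffled-label null for a time-resolved decoder
#'
#' Per repeat, condition labels are permuted once across trials (the same
#' permutation at every bin, preserving temporal structure) and the full
#' cross-validated decoding is rerun on the unchanged activity.
#'
#' @param binned a `binned_tensor`.
#' @param n_repeats null repeats (100).
#' @param seed RNG seed for the whole block.
#' @inheritParams timebin_decode
#' @return matrix n_repeats x bin of null accuracies.
#' @export
shuffled_null <- function(binned, n_repeats = 100L, seed = 1L, folds = 10L,
                          cost = 1) {
  if (n_repeats < 1L) stop("n_repeats must be >= 1")
  lab <- binned$labels
  set.seed(sub_seed(seed, 13L))
  perms <- replicate(n_repeats, sample(lab), simplify = FALSE)
  t(vapply(seq_len(n_repeats), function(r) {
    suppressWarnings(timebin_decode(binned, folds = folds, cost = cost,
                                    seed = sub_seed(seed, 100L + r),
                                    labels = perms[[r]],
                                    compute_weights = FALSE)$accuracy)
  }, numeric(dim(binned$data)[3])))
}

# subset the trial axis of a peri_event_tensor
subset_trials <- function(tensor, keep) {
  out <- tensor
  out$data <- tensor$data[, keep, , drop = FALSE]
  for (f in c("condition", "reaction_time", "trial_index", "valid"))
    out[[f]] <- tensor[[f]][keep]
  out
}

#' SVM1: decode initiation context at the press
#'
#' Cued vs self-paced classification on press-aligned, class-balanced trials
#' with a shuffled-label null.
#'
#' @param tensor press-aligned `peri_event_tensor` with both contexts.
#' @param window decoding window, seconds (c(-2, 2)).
#' @param folds,cost,seed decoder settings.
#' @param n_null shuffled-label repeats (100; 0 skips the null).
#' @return `decoder_result` with `null_accuracy` attached.
#' @export
decode_context_at_press <- function(tensor, window = c(-2, 2), folds = 10L,
                                    cost = 1, seed = 1L, n_null = 100L) {
  binned <- bin_tensor(tensor, window = window)
  res <- timebin_decode(binned, folds = folds, cost = cost, seed = seed)
  if (n_null > 0L)
    res$null_accuracy <- shuffled_null(binned, n_null, seed, folds, cost)
  res$mode <- "context"
  res
}

#' SVM1b: decode context in the cue period on latency-matched trials
#'
#' Cued trials are restricted to a reaction-time bin chosen so the evaluation
#' window precedes movement for every selected trial (default RT 334--666 ms,
#' evaluated -495..-165 ms before the press), then balanced against
#' self-paced trials and decoded. `eval_accuracy` is the mean accuracy over
#' the evaluation-window bins.
#'
#' @param tensor press-aligned `peri_event_tensor`.
#' @param rt_bin cued reaction-time bin, seconds (c(0.334, 0.666); the
#'   0--333 ms bin is the other published choice).
#' @param eval_window evaluation window relative to the press, seconds.
#' @inheritParams decode_context_at_press
#' @return `decoder_result` with `null_accuracy`, `eval_window`,
#'   `eval_bins`, `eval_accuracy`, `eval_null` (per-repeat mean over eval
#'   bins) attached.
#' @export
decode_context_cue_period <- function(tensor, rt_bin = c(0.334, 0.666),
                                      eval_window = c(-0.495, -0.165),
                                      window = c(-2, 2), folds = 10L,
                                      cost = 1, seed = 1L, n_null = 100L) {
  rt <- tensor$reaction_time
  keep <- tensor$condition == "self_paced" |
    (tensor$condition == "cued" & !is.na(rt) & rt >= rt_bin[1] & rt <= rt_bin[2])
  n_cued <- sum(keep & tensor$condition == "cued" & tensor$valid)
  if (n_cued < 2L)
    stop(sprintf("only %d cued trials in RT bin [%.3f, %.3f]",
                 n_cued, rt_bin[1], rt_bin[2]))
  sub <- subset_trials(tensor, keep)
  binned <- bin_tensor(sub, window = window)
  res <- suppressWarnings(
    timebin_decode(binned, folds = folds, cost = cost, seed = seed))
  if (n_null > 0L)
    res$null_accuracy <- suppressWarnings(
      shuffled_null(binned, n_null, seed, res$folds, cost))
  eb <- binned$bin_centers >= eval_window[1] & binned$bin_centers <= eval_window[2]
  res$mode <- "context-cue"
  res$rt_bin <- rt_bin
  res$eval_window <- eval_window
  res$eval_bins <- which(eb)
  res$eval_accuracy <- mean(res$accuracy[eb])
  if (n_null > 0L)
    res$eval_null <- rowMeans(res$null_accuracy[, eb, drop = FALSE])
  res
}

#' SVM2: decode press vs baseline
#'
#' Class A: press-aligned windows from both contexts pooled. Class B:
#' baseline windows sampled from intertrial periods at least `min_gap`
#' seconds away from any press, cue or reward, with the same length and
#' binning, count-matched to the press trials.
#'
#' @param tensor press-aligned `peri_event_tensor` (both contexts pooled).
#' @param traces the `trace_matrix` the tensor was built from.
#' @param events the session `event_log`.
#' @param min_gap minimum distance of a baseline window center from any
#'   event, seconds (2).
#' @inheritParams decode_context_at_press
#' @return `decoder_result` (classes press / baseline) with `null_accuracy`.
#' @export
decode_press_vs_baseline <- function(tensor, traces, events,
                                     window = c(-2, 2), min_gap = 2,
                                     folds = 10L, cost = 1, seed = 1L,
                                     n_null = 100L) {
  ev <- events$events
  ev_times <- ev$time[ev$kind %in% c("press", "cue_onset", "reward")]
  rate <- tensor$sample_rate
  pre <- round(-tensor$window[1] * rate); post <- round(tensor$window[2] * rate)
  nf <- ncol(traces$z)
  cand <- seq(tensor$window[2] + 0.5, max(traces$frame_times) + tensor$window[1] - 0.5,
              by = 0.25)
  gap_ok <- vapply(cand, function(tc) min(abs(ev_times - tc)) >= min_gap,
                   logical(1))
  cand <- cand[gap_ok]
  n_press <- sum(tensor$valid)
  if (length(cand) < n_press)
    stop(sprintf("insufficient clean ITI: %d baseline candidates for %d press trials",
                 length(cand), n_press))
  set.seed(sub_seed(seed, 17L))
  centers <- sort(sample(cand, n_press))
  cf <- align_events_to_frames(centers, traces$frame_times)
  base <- array(NA_real_, dim = c(dim(tensor$data)[1], n_press, pre + post + 1L))
  ok <- logical(n_press)
  for (j in seq_len(n_press)) {
    if (is.na(cf[j]) || cf[j] - pre < 1L || cf[j] + post > nf) next
    base[, j, ] <- traces$z[tensor$roi_ids, (cf[j] - pre):(cf[j] + post)]
    ok[j] <- TRUE
  }
  press_idx <- which(tensor$valid)
  comb <- tensor
  comb$data <- array(NA_real_, dim = c(dim(tensor$data)[1],
                                       length(press_idx) + sum(ok),
                                       pre + post + 1L))
  comb$data[, seq_along(press_idx), ] <- tensor$data[, press_idx, , drop = FALSE]
  comb$data[, length(press_idx) + seq_len(sum(ok)), ] <- base[, ok, , drop = FALSE]
  comb$condition <- c(rep("press", length(press_idx)), rep("baseline", sum(ok)))
  comb$valid <- rep(TRUE, length(comb$condition))
  comb$reaction_time <- rep(NA_real_, length(comb$condition))
  comb$trial_index <- rep(NA_integer_, length(comb$condition))
  binned <- bin_tensor(comb, window = window)
  res <- timebin_decode(binned, folds = folds, cost = cost, seed = seed)
  if (n_null > 0L)
    res$null_accuracy <- shuffled_null(binned, n_null, seed, folds, cost)
  res$mode <- "press-baseline"
  res
}

#' Compare two classifier weight axes
#'
#' Unit-normalized weight vectors at the selected bins, compared by cosine
#' similarity and by Spearman rank correlation of absolute weights, plus the
#' sorted-weight overlay table (sorted by the second result's |weight|, the
#' published overlay convention).
#'
#' @param result_1,result_2 `decoder_result`s over the same ROI set and order.
#' @param bin_1,bin_2 bin indices to compare (default: each decoder's peak-
#'   accuracy bin).
#' @return list(cosine_similarity, rank_correlation, bin_1, bin_2, overlay —
#'   data.frame(roi, w1, w2) sorted by |w2| descending).
#' @export
weight_axis_comparison <- function(result_1, result_2,
                                   bin_1 = NULL, bin_2 = NULL) {
  if (length(result_1$roi_ids) != length(result_2$roi_ids) ||
      any(result_1$roi_ids != result_2$roi_ids))
    stop("decoder results use different ROI sets")
  bin_1 <- bin_1 %||% which.max(result_1$accuracy)
  bin_2 <- bin_2 %||% which.max(result_2$accuracy)
  w1 <- result_1$weights[bin_1, ]; w2 <- result_2$weights[bin_2, ]
  u1 <- w1 / sqrt(sum(w1^2)); u2 <- w2 / sqrt(sum(w2^2))
  overlay <- data.frame(roi = result_1$roi_ids, w1 = u1, w2 = u2)
  overlay <- overlay[order(-abs(overlay$w2)), ]
  list(cosine_similarity = sum(u1 * u2),
       rank_correlation = stats::cor(abs(u1), abs(u2), method = "spearman"),
       bin_1 = bin_1, bin_2 = bin_2, overlay = overlay)
}

#' Project population activity onto a classifier axis
#'
#' Per trial and bin, the inner product of the population vector with the
#' unit-normalized weight vector; summarized as mean +/- SEM per condition.
#'
#' @param binned a `binned_tensor`.
#' @param weights ROI-length weight vector (e.g. one row of a decoder's
#'   weight matrix).
#' @return list(bin_centers, projection trial x bin, condition per trial,
#'   mean / sem — per condition lists over bins).
#' @export
project_onto_axis <- function(binned, weights) {
  if (length(weights) != dim(binned$data)[1])
    stop("weight length must equal ROI count")
  nrm <- sqrt(sum(weights^2))
  if (nrm == 0) stop("zero-norm weight vector")
  u <- weights / nrm
  keep <- binned$valid
  d <- binned$data[, keep, , drop = FALSE]
  proj <- apply(d, c(2, 3), function(v) sum(v * u))
  cond <- binned$labels[keep]
  by_cond <- split(seq_len(nrow(proj)), cond)
  list(bin_centers = binned$bin_centers, projection = proj, condition = cond,
       mean = lapply(by_cond, function(ix) colMeans(proj[ix, , drop = FALSE])),
       sem = lapply(by_cond, function(ix)
         apply(proj[ix, , drop = FALSE], 2, stats::sd) / sqrt(length(ix))))
}
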