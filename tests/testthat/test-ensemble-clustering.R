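test_that("tensor slices use centered index arithmetic and flag artifacts", {
  nf <- 1200L
  z <- matrix(seq_len(nf), nrow = 1)  # z[1, f] = f encodes the frame index
  tr <- make_trace_matrix(z)
  ft <- tr$frame_times
  log <- make_event_log(trial_start = c(ft[600] - 1, 2),
                        press = c(ft[600], 2.5))
  ten <- build_tensor(tr, log, "press", artifact_z_threshold = Inf)
  expect_identical(dim(ten$data), c(1L, 2L, 301L))
  # event at frame 600, window -5..+5 s at 30 Hz -> frames 450..750
  expect_equal(ten$data[1, 1, ], as.numeric(450:750))
  # event 2.5 s after session start: truncated window -> invalid
  expect_false(ten$valid[2])
  expect_true(ten$valid[1])

  # amplitude-threshold artifact exclusion
  z2 <- matrix(rnorm(2 * nf), nrow = 2)
  z2[2, 590] <- 50
  log2 <- make_event_log(c(ft[600] - 1, ft[900] - 1), c(ft[600], ft[900]))
  ten2 <- build_tensor(make_trace_matrix(z2), log2,
                       "press", artifact_z_threshold = 10)
  expect_identical(ten2$valid, c(FALSE, TRUE))
  expect_error(build_tensor(make_trace_matrix(z2), log, "press",
                            artifact_z_threshold = 1e-9), "no valid trials")
})

test_that("trial averages equal the loop-and-sum oracle", {
  set.seed(51)
  ten <- fix_session()$tensor_press
  avg <- trial_average(ten, "cued")
  sel <- which(ten$valid & ten$condition == "cued")
  oracle <- matrix(0, dim(ten$data)[1], dim(ten$data)[3])
  for (r in seq_len(nrow(oracle))) for (s in seq_len(ncol(oracle))) {
    acc <- 0
    for (t in sel) acc <- acc + ten$data[r, t, s]
    oracle[r, s] <- acc / length(sel)
  }
  expect_equal(avg, oracle, tolerance = 1e-12)

  # two identical trials -> average equals either trial
  d <- array(rnorm(4 * 1 * 10), c(4, 2, 10))
  d[, 2, ] <- d[, 1, ]
  tiny <- ten
  tiny$data <- d; tiny$valid <- c(TRUE, TRUE)
  tiny$condition <- c("cued", "cued")
  expect_equal(trial_average(tiny, "cued"), d[, 1, ])
  expect_error(trial_average(tiny, "self_paced"), "empty")
})

test_that("zero-noise cue-aligned average reproduces the planted kernel shape", {
  ses <- fix_clean_session()
  tr <- preprocess_session(ses$recording)
  ten <- build_tensor(tr, ses$events, "cue_onset", conditions = "cued")
  avg <- trial_average(ten, "cued")
  cue_rois <- which(ses$truth$cluster_id[tr$kept_rois] == "cue")
  kern <- calcium_kernel(ten$time)
  rho <- vapply(cue_rois, function(i)
    stats::cor(avg[i, ten$time >= 0], kern[ten$time >= 0]), numeric(1))
  # frame-phase jitter of the fast rise caps the match just below 1
  expect_true(all(rho > 0.98))
})

test_that("Ward clustering separates exact template groups and matches the oracle", {
  skip_if_not_installed("mclust")
  set.seed(52)
  time <- seq(-2, 2, by = 1 / 30)
  tmpl <- rbind(calcium_kernel(time),
                calcium_kernel(time - 1),
                -calcium_kernel(time + 1))
  x <- tmpl[rep(1:3, each = 10), ] + matrix(rnorm(30 * length(time), 0, 1e-6),
                                            30)
  cl <- cluster_neurons(x, time, window = c(-2, 2), k = 3)
  ari <- mclust::adjustedRandIndex(cl$raw_label, rep(1:3, each = 10))
  expect_equal(ari, 1)
  expect_error(cluster_neurons(x[1:2, ], time, k = 3), "fewer neurons")

  # n = 6 merge sequence equals the exhaustive ESS-minimizing Ward oracle
  set.seed(53)
  y <- matrix(rnorm(6 * 8), 6)
  hc <- cluster_neurons(y, seq_len(8) / 30, window = c(0, 1), k = 3)$hclust
  got <- hclust_merges(hc)
  want <- ward_oracle_merges(y)
  expect_length(got, 5L)
  for (s in seq_along(got)) expect_true(same_merge(got[[s]], want[[s]]))
})

test_that("clustering is invariant to neuron order and global translation", {
  set.seed(54)
  time <- seq(-2, 2, by = 1 / 30)
  x <- rbind(matrix(rnorm(10 * 121, 0), 10),
             matrix(rnorm(10 * 121, 3), 10)) +
    tcrossprod(rep(1, 20), calcium_kernel(time))
  base <- cluster_neurons(x, time)$raw_label
  perm <- sample(20)
  permuted <- cluster_neurons(x[perm, ], time)$raw_label
  agree <- table(base[perm], permuted)
  expect_true(all(rowSums(agree > 0) == 1))  # same partition, relabelled
  shifted <- cluster_neurons(x + 7.3, time)$raw_label
  agree2 <- table(base, shifted)
  expect_true(all(rowSums(agree2 > 0) == 1))
})

test_that("canonical labels recover the planted archetypes", {
  ses <- fix_session()
  avg <- trial_average(ses$tensor_cue, "cued")
  cl <- cluster_neurons(avg, ses$tensor_cue$time)
  cl <- canonicalize_labels(cl, ses$tensor_cue, ses$tensor_press)
  truth <- ses$truth$cluster_id[ses$traces$kept_rois]
  mapping <- c(action = 1L, cue = 2L, post_action = 3L)
  expect_equal(mean(cl$canonical_label == mapping[truth]), 1)
  expect_true(all(sort(unique(cl$label_map)) == 1:3))  # bijection

  # permutation invariance of the canonical assignment
  perm <- sample(nrow(avg))
  permute_tensor <- function(ten) {
    ten$data <- ten$data[perm, , , drop = FALSE]
    ten$cell_type <- ten$cell_type[perm]
    ten$roi_ids <- ten$roi_ids[perm]
    ten
  }
  cl2 <- cluster_neurons(avg[perm, ], ses$tensor_cue$time)
  cl2 <- canonicalize_labels(cl2, permute_tensor(ses$tensor_cue),
                             permute_tensor(ses$tensor_press))
  expect_identical(cl2$canonical_label, cl$canonical_label[perm])
})

test_that("window statistics follow their definitions and ordering", {
  time <- seq(-2, 2, by = 1 / 30)
  const <- matrix(2.5, 3, length(time))
  expect_equal(window_mean(const, time, c(0, 0.2)), rep(2.5, 3))
  expect_equal(peak_response(const, time, c(0, 2)), rep(2.5, 3))
  flat0 <- matrix(0, 1, length(time))
  expect_equal(peak_response(flat0, time, c(-0.5, 1.5)), 0)

  set.seed(55)
  x <- matrix(rnorm(20 * length(time)), 20)
  w <- c(-0.5, 1.5)
  expect_true(all(peak_response(x, time, w) >= window_mean(x, time, w)))
  expect_error(window_mean(x, time, c(5, 6)), "window")
})

test_that("planted cell-type boosts appear in the published windows", {
  ses <- fix_session()
  truth_arch <- ses$truth$cluster_id[ses$traces$kept_rois]
  ct <- ses$tensor_cue$cell_type
  avg_cue <- trial_average(ses$tensor_cue, "cued")
  m200 <- window_mean(avg_cue, ses$tensor_cue$time, c(0, 0.2))
  # d1_cue_boost > 1: D1 population mean exceeds D2 in the 0-200 ms window
  expect_gt(mean(m200[ct == "D1"]), mean(m200[ct == "D2"]))
  # d2_post_boost > 1: D2 exceeds D1 at 1-2 s (post-action component)
  m12 <- window_mean(avg_cue, ses$tensor_cue$time, c(1, 2))
  expect_gt(mean(m12[ct == "D2"]), mean(m12[ct == "D1"]))
})

test_that("group_compare dispatches tests with an explicit zero policy", {
  x <- c(1, 2, 3, 4)
  res <- group_compare(x, x, paired = TRUE)
  expect_equal(res$p_value, 1)
  expect_identical(res$test_name, "Wilcoxon signed-rank")

  set.seed(56)
  res2 <- group_compare(rnorm(30), rnorm(30, 2))
  expect_lt(res2$p_value, 1e-4)
  expect_identical(res2$test_name, "Student's t")

  res3 <- group_compare(list(rnorm(20), rnorm(20, 3), rnorm(20)))
  expect_identical(res3$test_name, "one-way ANOVA")
  expect_true(is.matrix(res3$posthoc))
  expect_error(group_compare(list(1:5, 2:6)), ">= 3 groups")
  expect_error(group_compare(1, 1:3), ">= 2 values")
})
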