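test_that("binning averages non-overlapping 2-frame groups", {
  ses <- fix_session()
  ten <- ses$tensor_press
  b <- bin_tensor(ten, window = c(-2, 2))
  expect_identical(dim(b$data)[3], 60L)  # 120 frames over 4 s -> 60 bins
  expect_equal(b$bin_width, 2 / 30)

  # reshape-and-mean oracle
  idx <- which(ten$time >= -2 & ten$time < 2)
  for (bin in c(1, 17, 60)) {
    fr <- idx[(2 * bin - 1):(2 * bin)]
    expect_equal(b$data[, , bin],
                 (ten$data[, , fr[1]] + ten$data[, , fr[2]]) / 2,
                 tolerance = 1e-12)
  }
  # frames (1, 3) in a bin -> 2
  d <- array(0, c(1, 1, 4)); d[1, 1, ] <- c(1, 3, 5, 9)
  tiny <- ten
  tiny$data <- d; tiny$time <- c(0, 1, 2, 3) / 30
  tiny$condition <- "cued"; tiny$valid <- TRUE
  tiny$reaction_time <- NA_real_; tiny$trial_index <- 1L
  tiny$cell_type <- "D1"; tiny$roi_ids <- 1L
  bb <- bin_tensor(tiny, window = c(0, 4 / 30))
  expect_equal(as.numeric(bb$data), c(2, 7))
})

test_that("balanced subsampling equalizes class counts deterministically", {
  labels <- rep(c("cued", "self_paced"), c(40, 25))
  sel <- balance_trials(labels, seed = 3)
  expect_equal(as.integer(table(labels[sel])), c(25L, 25L))
  expect_identical(sel, balance_trials(labels, seed = 3))
  eq <- rep(c("a", "b"), each = 10)
  expect_identical(balance_trials(eq, 1), 1:20)
  expect_error(balance_trials(rep("a", 5), 1), "two classes")
})

test_that("separable classes decode perfectly; chance data does not", {
  set.seed(81)
  d <- array(rnorm(6 * 40 * 3), c(6, 40, 3))
  lab <- rep(c("cued", "self_paced"), each = 20)
  d[1:3, lab == "cued", 2] <- d[1:3, lab == "cued", 2] + 10
  res <- timebin_decode(make_binned(d, lab), folds = 10, seed = 1)
  expect_equal(res$accuracy[2], 1)
  expect_lt(max(res$accuracy[c(1, 3)]), 0.8)
  expect_equal(res$n_per_class, 20)
  expect_identical(dim(res$weights), c(3L, 6L))
  # weights at the separable bin point along the planted contrast
  expect_gt(sum(abs(res$weights[2, 1:3])), sum(abs(res$weights[2, 4:6])))
})

test_that("full-fit weights match the hard-margin closest-hull oracle", {
  set.seed(82)
  xa <- matrix(rnorm(4 * 2, mean = 0, sd = 0.5), 4) + 3    # class a
  xb <- matrix(rnorm(4 * 2, mean = 0, sd = 0.5), 4)        # class b
  d <- array(0, c(2, 8, 1))
  d[, , 1] <- t(rbind(xa, xb))
  lab <- rep(c("a", "b"), each = 4)
  res <- timebin_decode(make_binned(d, lab), folds = 2, cost = 1e5, seed = 1)
  oracle <- svm_oracle_2d(xa, xb)
  u_got <- res$weights[1, ] / sqrt(sum(res$weights[1, ]^2))
  u_want <- oracle$w / sqrt(sum(oracle$w^2))
  expect_equal(abs(sum(u_got * u_want)), 1, tolerance = 1e-3)
  # decision agreement on all training points
  sgn_got <- sign(d[1, , 1] * res$weights[1, 1] +
                    d[2, , 1] * res$weights[1, 2] + res$intercept[1])
  sgn_want <- sign(rbind(xa, xb) %*% oracle$w + oracle$b)
  expect_true(all(sgn_got == drop(sgn_want)) ||
                all(sgn_got == -drop(sgn_want)))
  expect_equal(res$accuracy[1], 1)
})

test_that("accuracy is invariant to ROI permutation", {
  set.seed(83)
  d <- array(rnorm(8 * 30 * 4), c(8, 30, 4))
  lab <- rep(c("cued", "self_paced"), 15)
  d[5, lab == "cued", ] <- d[5, lab == "cued", ] + 2
  b1 <- make_binned(d, lab)
  perm <- sample(8)
  b2 <- make_binned(d[perm, , , drop = FALSE], lab)
  r1 <- timebin_decode(b1, folds = 5, seed = 7, compute_weights = FALSE)
  r2 <- timebin_decode(b2, folds = 5, seed = 7, compute_weights = FALSE)
  expect_equal(r1$accuracy, r2$accuracy, tolerance = 1e-10)
})

test_that("shuffled-label null is reproducible with the right shape", {
  set.seed(84)
  d <- array(rnorm(5 * 24 * 3), c(5, 24, 3))
  b <- make_binned(d, rep(c("cued", "self_paced"), 12))
  n1 <- shuffled_null(b, n_repeats = 4, seed = 2, folds = 4)
  n2 <- shuffled_null(b, n_repeats = 4, seed = 2, folds = 4)
  expect_identical(n1, n2)
  expect_identical(dim(n1), c(4L, 3L))
  expect_true(all(n1 >= 0 & n1 <= 1))
  expect_error(shuffled_null(b, 0, 1), "n_repeats")
})

test_that("cue-period decoder selects latency-matched trials correctly", {
  ses <- fix_session()
  ten <- ses$tensor_press
  res <- decode_context_cue_period(ten, rt_bin = c(0, 2), n_null = 0,
                                   window = c(-1, 1), folds = 3, seed = 2)
  # every selected cued trial has its cue onset before the evaluation window
  rt_bin <- c(0.334, 0.666)
  keep <- ten$condition == "cued" & !is.na(ten$reaction_time) &
    ten$reaction_time >= rt_bin[1] & ten$reaction_time <= rt_bin[2]
  expect_true(all(-ten$reaction_time[keep] <= -0.334))
  expect_true(all(res$eval_window == c(-0.495, -0.165)))
  expect_error(decode_context_cue_period(ten, rt_bin = c(5, 6)), "cued trials")
})

test_that("press-vs-baseline decoding uses count-matched clean ITI epochs", {
  ses <- fix_session()
  res <- decode_press_vs_baseline(ses$tensor_press, ses$traces, ses$events,
                                  window = c(-1, 1), folds = 5, seed = 3,
                                  n_null = 0)
  expect_identical(res$classes, c("baseline", "press"))
  # action-archetype responses make the press class separable near the press
  expect_gt(max(res$accuracy[res$bin_centers > -0.5]), 0.85)
  expect_error(decode_press_vs_baseline(ses$tensor_press, ses$traces,
                                        ses$events, min_gap = 500),
               "insufficient clean ITI")
})

test_that("ROI restriction is a faithful partition", {
  ses <- fix_session()
  ten <- ses$tensor_press
  all_rois <- restrict_tensor(ten)
  expect_identical(all_rois$data, ten$data)
  d1 <- restrict_tensor(ten, cell_type = "D1")
  d2 <- restrict_tensor(ten, cell_type = "D2")
  expect_identical(sort(c(d1$roi_ids, d2$roi_ids)), ten$roi_ids)
  expect_identical(dim(d1$data)[1] + dim(d2$data)[1], dim(ten$data)[1])
  expect_error(restrict_tensor(ten, cell_type = "astrocyte"), "empty")
  expect_error(restrict_tensor(ten, cluster = 1), "labels")
})

test_that("axis projections and weight comparisons behave geometrically", {
  set.seed(85)
  d <- array(rnorm(6 * 10 * 5), c(6, 10, 5))
  b <- make_binned(d, rep(c("cued", "self_paced"), 5))
  w <- c(0, 0, 1, 0, 0, 0)
  pr <- project_onto_axis(b, w)
  expect_equal(pr$projection, d[3, , ], tolerance = 1e-12)
  expect_error(project_onto_axis(b, rep(0, 6)), "zero-norm")
  expect_error(project_onto_axis(b, w[1:3]), "length")

  mk <- function(wmat) structure(list(accuracy = rep(0.9, nrow(wmat)),
                                      weights = wmat,
                                      roi_ids = seq_len(ncol(wmat))),
                                 class = "decoder_result")
  w1 <- matrix(rnorm(6), 1)
  cmp <- weight_axis_comparison(mk(w1), mk(w1))
  expect_equal(cmp$cosine_similarity, 1, tolerance = 1e-12)
  cmp2 <- weight_axis_comparison(mk(w1), mk(-w1))
  expect_equal(cmp2$cosine_similarity, -1, tolerance = 1e-12)
  expect_equal(cmp2$rank_correlation, 1)
  expect_identical(order(-abs(cmp$overlay$w2)), seq_len(6))
  expect_error(weight_axis_comparison(mk(w1), mk(matrix(rnorm(5), 1))),
               "ROI")
})
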