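# builds a tensor directly from an ROI x trial x sample array
array_tensor <- function(d, condition, time = NULL) {
  structure(list(data = d,
                 time = time %||% seq_len(dim(d)[3]) / 30,
                 window = c(0, dim(d)[3] / 30), sample_rate = 30,
                 alignment = "press", condition = condition,
                 reaction_time = rep(NA_real_, dim(d)[2]),
                 trial_index = seq_len(dim(d)[2]),
                 valid = rep(TRUE, dim(d)[2]),
                 cell_type = rep("D1", dim(d)[1]),
                 roi_ids = seq_len(dim(d)[1])),
            class = "peri_event_tensor")
}

test_that("data in an exact 3-dim subspace is reconstructed perfectly", {
  set.seed(61)
  n_roi <- 12; ns <- 40
  u <- qr.Q(qr(matrix(rnorm(n_roi * 3), n_roi)))
  lat <- array(rnorm(3 * 8 * ns), c(3, 8, ns))
  d <- array(0, c(n_roi, 8, ns))
  for (t in 1:8) d[, t, ] <- u %*% lat[, t, ]
  ten <- array_tensor(d, rep(c("cued", "self_paced"), each = 4))
  fit <- fit_trajectories(ten)
  for (cc in c("cued", "self_paced")) {
    avg <- trial_average(ten, cc)
    recon <- fit$basis %*% t(fit$trajectory[[cc]]) + fit$center
    expect_equal(recon, avg, tolerance = 1e-8)
  }
  expect_equal(unname(crossprod(fit$basis)), diag(3),
               tolerance = 1e-10)  # orthonormal
})

test_that("identical condition averages give coincident trajectories", {
  set.seed(62)
  d <- array(rnorm(6 * 4 * 20), c(6, 4, 20))
  d[, 3:4, ] <- d[, 1:2, ]
  ten <- array_tensor(d, c("cued", "cued", "self_paced", "self_paced"))
  fit <- fit_trajectories(ten)
  expect_equal(fit$trajectory$cued, fit$trajectory$self_paced,
               tolerance = 1e-10)
  dist <- trajectory_distance(fit$trajectory$cued, fit$trajectory$self_paced)
  expect_true(all(dist < 1e-10))
})

test_that("projections match the eigendecomposition-of-covariance oracle", {
  set.seed(63)
  d <- array(rnorm(10 * 12 * 25), c(10, 12, 25))
  ten <- array_tensor(d, rep(c("cued", "self_paced"), 6))
  fit <- fit_trajectories(ten)
  x <- cbind(trial_average(ten, "cued"), trial_average(ten, "self_paced"))
  xc <- x - rowMeans(x)
  ev <- eigen(tcrossprod(xc) / (ncol(x) - 1), symmetric = TRUE)
  for (j in 1:3) {
    got <- fit$trajectory$cued[, j]
    want <- drop(crossprod(xc[, 1:25], ev$vectors[, j]))
    expect_equal(abs(stats::cor(got, want)), 1, tolerance = 1e-8)
    expect_equal(abs(got), abs(want), tolerance = 1e-6)  # up to sign
  }
  expect_error(fit_trajectories(array_tensor(d[1:2, , ],
                                             rep(c("cued", "self_paced"), 6))),
               "ROIs")
})

test_that("trajectory distance is the per-sample Euclidean norm", {
  a <- matrix(rnorm(30), 10)
  expect_true(all(trajectory_distance(a, a) == 0))
  b <- a; b[4, 1] <- a[4, 1] + 3
  expect_equal(trajectory_distance(a, b)[4], 3)
  expect_error(trajectory_distance(a, b[1:5, ]), "mismatch")

  set.seed(64)
  b2 <- matrix(rnorm(30), 10)
  oracle <- vapply(1:10, function(s) sqrt(sum((a[s, ] - b2[s, ])^2)),
                   numeric(1))
  expect_equal(trajectory_distance(a, b2), oracle, tolerance = 1e-12)

  # invariant under any rotation of the PC basis
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  expect_equal(trajectory_distance(a %*% q, b2 %*% q),
               trajectory_distance(a, b2), tolerance = 1e-10)
})

test_that("label-shuffle null is reproducible and always n_shuffles rows", {
  set.seed(65)
  d <- array(rnorm(8 * 10 * 15), c(8, 10, 15))
  ten <- array_tensor(d, rep(c("cued", "self_paced"), 5))
  n1 <- shuffle_null(ten, n_shuffles = 7, seed = 99)
  n2 <- shuffle_null(ten, n_shuffles = 7, seed = 99)
  expect_identical(n1$null_distances, n2$null_distances)
  expect_identical(dim(n1$null_distances), c(7L, 15L))
  expect_error(shuffle_null(ten, n_shuffles = 0), "n_shuffles")
  # fixed-basis mode also reproducible and same shape
  n3 <- shuffle_null(ten, n_shuffles = 5, seed = 1, refit_basis = FALSE)
  expect_identical(dim(n3$null_distances), c(5L, 15L))
})

test_that("mean-difference control dissociates from trajectory divergence", {
  expect_equal(mean_difference_control(rep(1, 5), rep(1, 5)), rep(0, 5))
  x <- rnorm(6)
  expect_equal(mean_difference_control(x + 3, x), rep(3, 6))

  # planted mean-zero context effect: population-mean control stays near
  # zero while the population-state trajectories diverge
  bc <- behavior_config(n_block_pairs = 1L, rewards_per_block = 10L,
                        unrewarded_presses_per_trial = 0, seed = 71L)
  nc <- neural_config(n_neurons = 40L, cluster_proportions = c(1, 0, 0),
                      context_gain = 1, noise_sd = 3,
                      baseline_drift_amplitude = 0,
                      context_effect = list(window = c(-0.8, -0.2),
                                            amplitude = 25, fraction = 1,
                                            mode = "cued_only",
                                            mean_zero = TRUE),
                      seed = 72L)
  ses <- simulate_session(bc, nc)
  tr <- preprocess_session(ses$recording)
  ten <- build_tensor(tr, ses$events, "press", window = c(-2, 2))
  ta <- trajectory_analysis(ten, n_shuffles = 30, seed = 5)
  inside <- ten$time >= -0.8 & ten$time <= -0.2
  expect_gt(mean(ta$distance[inside]),
            mean(ta$null_mean[inside] + 2 * ta$null_sd[inside]))
  # the grand-average control misses the (mean-zero) effect entirely
  expect_lt(max(ta$mean_diff_control[inside]), 0.5 * max(ta$distance[inside]))
})
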