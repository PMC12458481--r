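#' Fit condition trajectories in PC space
#'
#' Fits a single PCA basis on the two condition trial-averaged population
#' matrices concatenated over time (a shared basis is required for a
#' meaningful distance), ROI-wise centered, no standardization (traces are
#' already session z-scored). Each condition average is then projected onto
#' the first `n_components` PCs.
#'
#' @param tensor a `peri_event_tensor` containing both conditions.
#' @param conditions the two condition labels, default cued / self_paced.
#' @param n_components number of PCs (3).
#' @param labels optional per-trial condition labels overriding the tensor's
#'   (used by the label-shuffle null).
#' @param basis optional basis (ROI x n_components matrix) to project onto
#'   instead of refitting (fixed-basis mode), with its `center` attribute.
#' @return a `trajectory_result` (partial): list(basis ROI x n_components,
#'   center per ROI, trajectory — list per condition of sample x
#'   n_components, time, explained — variance fractions, conditions).
#' @export
fit_trajectories <- function(tensor, conditions = c("cued", "self_paced"),
                             n_components = 3L, labels = NULL,
                             basis = NULL) {
  lab <- labels %||% tensor$condition
  if (!all(conditions %in% lab)) stop("both conditions must be present")
  if (dim(tensor$data)[1] < n_components)
    stop("need at least n_components ROIs")
  avg <- lapply(conditions, function(cc)
    trial_average_lab(tensor, lab, cc))
  x <- do.call(cbind, avg) # ROI x (2 * samples)
  if (is.null(basis)) {
    pc <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
    nz <- sum(pc$sdev > max(pc$sdev) * 1e-8)
    if (nz < n_components)
      stop(sprintf("data rank %d < %d components", nz, n_components))
    rot <- pc$rotation[, seq_len(n_components), drop = FALSE]
    ctr <- pc$center
    explained <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(n_components)]
  } else {
    rot <- basis
    ctr <- attr(basis, "center") %||% rowMeans(x)
    explained <- NA_real_
  }
  traj <- lapply(avg, function(m) t(m - ctr) %*% rot)
  names(traj) <- conditions
  attr(rot, "center") <- ctr
  structure(list(basis = rot, center = ctr, trajectory = traj,
                 time = tensor$time, explained = explained,
                 conditions = conditions),
            class = "trajectory_result")
}

# trial average with an explicit label vector (shuffle support)
trial_average_lab <- function(tensor, lab, condition) {
  sel <- tensor$valid & lab == condition
  if (!any(sel)) stop("empty trial selection")
  avg_over_trials(tensor$data[, sel, , drop = FALSE])
}

#' Pointwise Euclidean distance between two trajectories
#'
#' @param traj_a,traj_b sample x component matrices of equal shape.
#' @return numeric vector, one distance per sample (PC units).
#' @export
trajectory_distance <- function(traj_a, traj_b) {
  if (!all(dim(traj_a) == dim(traj_b))) stop("trajectory shape mismatch")
  sqrt(rowSums((traj_a - traj_b)^2))
}

#' Label-shuffle null for the trajectory divergence
#'
#' Repeats the full fit-and-distance pipeline `n_shuffles` times with
#' condition labels permuted across trials (group sizes preserved; an
#' identity permutation is kept, not redrawn). By default the PCA basis is
#' refit per shuffle (conservative); `refit_basis = FALSE` holds the observed
#' basis fixed.
#'
#' @param tensor a `peri_event_tensor`.
#' @param n_shuffles number of permutations (100).
#' @param seed RNG seed for the whole permutation block.
#' @param conditions the two condition labels.
#' @param refit_basis refit PCA per shuffle (default TRUE).
#' @param observed optional observed `trajectory_result` (needed for
#'   fixed-basis mode; otherwise fit internally).
#' @return list(null_distances n_shuffles x sample, null_mean, null_sd,
#'   null_sem per sample).
#' @export
shuffle_null <- function(tensor, n_shuffles = 100L, seed = 1L,
                         conditions = c("cued", "self_paced"),
                         refit_basis = TRUE, observed = NULL) {
  if (n_shuffles < 1L) stop("n_shuffles must be >= 1")
  lab <- tensor$condition
  if (sum(tensor$valid & lab == conditions[1]) < 2L ||
      sum(tensor$valid & lab == conditions[2]) < 2L)
    stop("both conditions need >= 2 valid trials")
  basis <- if (!refit_basis) {
    obs <- observed %||% fit_trajectories(tensor, conditions)
    b <- obs$basis; attr(b, "center") <- obs$center; b
  } else NULL
  set.seed(seed)
  nd <- t(vapply(seq_len(n_shuffles), function(r) {
    perm <- sample(lab)
    fit <- fit_trajectories(tensor, conditions, labels = perm, basis = basis)
    trajectory_distance(fit$trajectory[[1]], fit$trajectory[[2]])
  }, numeric(length(tensor$time))))
  list(null_distances = nd,
       null_mean = colMeans(nd),
       null_sd = apply(nd, 2, stats::sd),
       null_sem = apply(nd, 2, stats::sd) / sqrt(n_shuffles))
}

#' Grand-average subtraction control
#'
#' Absolute difference of the two grand-average (over ROIs) population
#' traces; near-zero when a context effect is mean-zero across neurons even
#' though the PC-space trajectories diverge — the dissociation between mean
#' activity and population-state differences.
#'
#' @param grand_avg_a,grand_avg_b per-sample population means (equal length).
#' @return per-sample absolute difference (z units).
#' @export
mean_difference_control <- function(grand_avg_a, grand_avg_b) {
  if (length(grand_avg_a) != length(grand_avg_b)) stop("length mismatch")
  abs(grand_avg_a - grand_avg_b)
}

#' Full trajectory-divergence analysis
#'
#' Observed 3-PC trajectories and distance, the label-shuffle null, and the
#' grand-average subtraction control, in one call.
#'
#' @inheritParams shuffle_null
#' @param n_components PCs to keep (3).
#' @return a `trajectory_result` with distance, null summaries and
#'   mean-difference control attached.
#' @export
trajectory_analysis <- function(tensor, conditions = c("cued", "self_paced"),
                                n_components = 3L, n_shuffles = 100L,
                                seed = 1L, refit_basis = TRUE) {
  fit <- fit_trajectories(tensor, conditions, n_components)
  fit$distance <- trajectory_distance(fit$trajectory[[1]], fit$trajectory[[2]])
  nul <- shuffle_null(tensor, n_shuffles, seed, conditions, refit_basis,
                      observed = fit)
  fit[names(nul)] <- nul
  ga <- lapply(conditions, function(cc) colMeans(trial_average(tensor, cc)))
  fit$mean_diff_control <- mean_difference_control(ga[[1]], ga[[2]])
  fit$n_shuffles <- n_shuffles
  fit
}
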