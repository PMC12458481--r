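#' Hierarchical ensemble clustering of trial-averaged responses
#'
#' Ward's agglomerative clustering on pairwise Euclidean distances between
#' per-neuron trial-averaged traces, cut at a fixed k. The normative input is
#' the cue-aligned cued-trial average restricted to -2..+2 s around the cue;
#' pass a press-aligned average to reproduce the figure-caption ordering
#' variant instead.
#'
#' @param trial_avg ROI x sample matrix of trial-averaged z-scored activity.
#' @param time per-sample times (seconds) matching `trial_avg` columns.
#' @param window seconds kept around the alignment event, default c(-2, 2)
#'   (half-open).
#' @param k number of clusters (3).
#' @return a `cluster_result`: list(raw_label per ROI, hclust object, k,
#'   templates — k x sample matrix of cluster means over the clustering
#'   window, window, time — clustering-window times).
#' @export
cluster_neurons <- function(trial_avg, time, window = c(-2, 2), k = 3L) {
  if (nrow(trial_avg) < k) stop("fewer neurons than clusters")
  keep <- window_mask(time, window)
  x <- trial_avg[, keep, drop = FALSE]
  hc <- stats::hclust(stats::dist(x, method = "euclidean"), method = "ward.D2")
  raw <- stats::cutree(hc, k = k)
  templates <- do.call(rbind, lapply(seq_len(k), function(g)
    colMeans(x[raw == g, , drop = FALSE])))
  structure(list(raw_label = raw, hclust = hc, k = k, templates = templates,
                 window = window, time = time[keep]),
            class = "cluster_result")
}

#' Canonicalize cluster labels by response phenotype
#'
#' Maps raw dendrogram labels onto the field's phenotype numbering:
#' cluster 2 = cue-locked (largest cue-aligned vs press-aligned peak ratio,
#' earliest cue-aligned peak on ties), cluster 1 = action-timed (of the
#' remaining clusters, the one whose press-aligned template peaks are most
#' similar between cued and self-paced trials), cluster 3 = post-action (the
#' remainder). Ties are broken deterministically by cluster size (larger
#' first) and recorded in the result.
#'
#' @param result a `cluster_result`.
#' @param tensor_cue cue-aligned `peri_event_tensor` (cued trials).
#' @param tensor_press press-aligned `peri_event_tensor` (both contexts).
#' @param peak_window_cue,peak_window_press peak-search windows, seconds.
#' @return the `cluster_result` with `canonical_label` (per ROI, 1/2/3),
#'   `label_map` (raw -> canonical), and `tie_break` flag added.
#' @export
canonicalize_labels <- function(result, tensor_cue, tensor_press,
                                peak_window_cue = c(0, 2),
                                peak_window_press = c(-0.5, 1.5)) {
  k <- result$k
  raw <- result$raw_label
  avg_cue <- trial_average(tensor_cue, condition = "cued")
  avg_press_cued <- trial_average(tensor_press, condition = "cued")
  avg_press_self <- trial_average(tensor_press, condition = "self_paced")

  cue_mask <- window_mask(tensor_cue$time, peak_window_cue)
  press_mask <- window_mask(tensor_press$time, peak_window_press)
  grp <- function(m, g) colMeans(m[raw == g, , drop = FALSE])

  stats_g <- lapply(seq_len(k), function(g) {
    tc <- grp(avg_cue, g); tpc <- grp(avg_press_cued, g)
    tps <- grp(avg_press_self, g)
    cue_peak <- max(tc[cue_mask])
    press_peak_c <- max(tpc[press_mask]); press_peak_s <- max(tps[press_mask])
    list(cue_ratio = cue_peak / max(press_peak_c, 1e-12),
         cue_peak_time = tensor_cue$time[cue_mask][which.max(tc[cue_mask])],
         press_sim = -abs(press_peak_c - press_peak_s),
         size = sum(raw == g))
  })
  cue_ratio <- vapply(stats_g, `[[`, numeric(1), "cue_ratio")
  cue_ptime <- vapply(stats_g, `[[`, numeric(1), "cue_peak_time")
  press_sim <- vapply(stats_g, `[[`, numeric(1), "press_sim")
  sizes <- vapply(stats_g, `[[`, numeric(1), "size")

  tie <- FALSE
  ord2 <- order(-cue_ratio, cue_ptime, -sizes)
  if (k > 1L && cue_ratio[ord2[1]] == cue_ratio[ord2[2]]) tie <- TRUE
  lab2 <- ord2[1]
  rest <- setdiff(seq_len(k), lab2)
  ord1 <- rest[order(-press_sim[rest], -sizes[rest])]
  if (length(rest) > 1L && press_sim[ord1[1]] == press_sim[ord1[2]]) tie <- TRUE
  lab1 <- ord1[1]
  lab3 <- setdiff(rest, lab1)

  map <- integer(k)
  map[lab1] <- 1L; map[lab2] <- 2L
  if (length(lab3)) map[lab3] <- seq(3L, length.out = length(lab3))
  result$canonical_label <- map[raw]
  result$label_map <- map
  result$tie_break <- tie
  if (tie) message("canonicalize_labels: tie broken by cluster size")
  result
}

#' Peak response within a window
#'
#' Maximum of each ROI's trial-averaged trace within `peak_window`
#' (half-open).
#'
#' @param trial_avg ROI x sample matrix.
#' @param time per-sample times.
#' @param peak_window seconds.
#' @return numeric vector, one peak per ROI (z units).
#' @export
peak_response <- function(trial_avg, time, peak_window) {
  m <- window_mask(time, peak_window)
  if (!any(m)) stop("peak_window outside tensor span")
  apply(trial_avg[, m, drop = FALSE], 1, max)
}

#' Mean response within a window
#'
#' Time-mean of each ROI's trial-averaged trace over the half-open window
#' [t0, t1) — the sample at t = 0 belongs to the post side, making short
#' bins such as 0--200 ms reproducible.
#'
#' @inheritParams peak_response
#' @param window seconds, half-open.
#' @return numeric vector, one mean per ROI (z units).
#' @export
window_mean <- function(trial_avg, time, window) {
  m <- window_mask(time, window)
  if (!any(m)) stop("window outside tensor span")
  rowMeans(trial_avg[, m, drop = FALSE])
}

#' Two-group (or k-group) comparison
#'
#' Standard test dispatch used for the window/peak quantifications: unpaired
#' two-sample t-test, paired Wilcoxon signed-rank (with an explicit
#' zero-policy: if every paired difference is zero the groups are identical
#' and p = 1), or one-way ANOVA with Tukey-Kramer post hoc for >= 3 groups
#' (pass a list of groups).
#'
#' @param a,b numeric vectors (or `a` a list of >= 3 groups, `b` missing).
#' @param paired use the Wilcoxon signed-rank test on paired values.
#' @return list(statistic, p_value, test_name[, posthoc]).
#' @export
group_compare <- function(a, b = NULL, paired = FALSE) {
  if (is.list(a) && is.null(b)) {
    if (length(a) < 3L) stop("ANOVA path needs >= 3 groups")
    if (any(vapply(a, length, 1L) < 2L)) stop("degenerate group")
    g <- factor(rep(seq_along(a), vapply(a, length, 1L)))
    x <- unlist(a)
    fit <- stats::aov(x ~ g)
    an <- summary(fit)[[1]]
    return(list(statistic = an$`F value`[1], p_value = an$`Pr(>F)`[1],
                test_name = "one-way ANOVA",
                posthoc = stats::TukeyHSD(fit)$g))
  }
  if (length(a) < 2L || length(b) < 2L) stop("need >= 2 values per group")
  if (paired) {
    if (length(a) != length(b)) stop("paired groups must have equal length")
    d <- a - b
    if (all(d == 0))
      return(list(statistic = 0, p_value = 1,
                  test_name = "Wilcoxon signed-rank"))
    wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE))
    list(statistic = unname(wt$statistic), p_value = wt$p.value,
         test_name = "Wilcoxon signed-rank")
  } else {
    tt <- stats::t.test(a, b)
    list(statistic = unname(tt$statistic), p_value = tt$p.value,
         test_name = "Student's t")
  }
}
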