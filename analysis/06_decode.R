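#!/usr/bin/env Rscript
# Time-resolved linear decoding: SVM1 (context at press), SVM1b (context in
# the cue period, latency-matched), SVM2 (press vs baseline), their
# shuffled-label nulls, the weight-axis comparison, axis projections, and
# cluster-1-restricted variants.

source(file.path("analysis", "00_config.R"))

ses <- make_study_session()
tr <- preprocess_session(ses$recording)
ten <- build_tensor(tr, ses$events, "press")

n_null <- 20L
svm1 <- decode_context_at_press(ten, seed = study_seed + 20L, n_null = n_null)
svm1b <- decode_context_cue_period(ten, seed = study_seed + 21L,
                                   n_null = n_null)
svm2 <- decode_press_vs_baseline(ten, tr, ses$events,
                                 seed = study_seed + 22L, n_null = n_null)

acc <- data.frame(bin_center_s = svm1$bin_centers,
                  svm1_accuracy = svm1$accuracy,
                  svm1_null = colMeans(svm1$null_accuracy),
                  svm1b_accuracy = svm1b$accuracy,
                  svm2_accuracy = svm2$accuracy,
                  svm2_null = colMeans(svm2$null_accuracy))
write.csv(acc, file.path(results_dir, "decoder_accuracy.csv"),
          row.names = FALSE)

report <- function(name, res) {
  cat(sprintf("%s: peak accuracy %.2f at %+.2f s (%d trials/class, null mean %.2f)\n",
              name, max(res$accuracy),
              res$bin_centers[which.max(res$accuracy)], res$n_per_class,
              if (!is.null(res$null_accuracy)) mean(res$null_accuracy) else NA))
}
report("SVM1  (cued vs self-paced at press)", svm1)
report("SVM2  (press vs baseline)", svm2)
cat(sprintf("SVM1b (cue period, RT %.0f-%.0f ms): accuracy %.2f in [%.3f, %.3f] s (null %.2f)\n",
            1000 * svm1b$rt_bin[1], 1000 * svm1b$rt_bin[2],
            svm1b$eval_accuracy, svm1b$eval_window[1], svm1b$eval_window[2],
            mean(svm1b$eval_null)))

cmp <- weight_axis_comparison(svm1, svm2)
cat(sprintf("Context axis vs action axis: cosine = %.3f, |w| rank corr = %.3f\n",
            cmp$cosine_similarity, cmp$rank_correlation))
write.csv(cmp$overlay, file.path(results_dir, "weight_overlay.csv"),
          row.names = FALSE)

binned <- bin_tensor(ten)
pr1 <- project_onto_axis(binned, svm1$weights[cmp$bin_1, ])
pr2 <- project_onto_axis(binned, svm2$weights[cmp$bin_2, ])
proj <- data.frame(bin_center_s = pr1$bin_centers,
                   context_axis_cued = pr1$mean$cued,
                   context_axis_self = pr1$mean$self_paced,
                   action_axis_cued = pr2$mean$cued,
                   action_axis_self = pr2$mean$self_paced)
write.csv(proj, file.path(results_dir, "axis_projections.csv"),
          row.names = FALSE)

# cluster-1 (action-timed) restricted decoding
ten_cue <- build_tensor(tr, ses$events, "cue_onset", conditions = "cued")
cl <- canonicalize_labels(cluster_neurons(trial_average(ten_cue, "cued"),
                                          ten_cue$time),
                          ten_cue, ten)
ten_c1 <- restrict_tensor(ten, cluster = 1L, clusters = cl$canonical_label)
svm1_c1 <- decode_context_at_press(ten_c1, seed = study_seed + 23L,
                                   n_null = 0L)
svm2_c1 <- decode_press_vs_baseline(ten_c1, tr, ses$events,
                                    seed = study_seed + 24L, n_null = 0L)
cat(sprintf("Cluster-1-only (n = %d): SVM1 peak %.2f, SVM2 peak %.2f\n",
            dim(ten_c1$data)[1], max(svm1_c1$accuracy),
            max(svm2_c1$accuracy)))
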