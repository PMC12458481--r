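#!/usr/bin/env Rscript
# Ensemble structure: peri-event tensors, Ward (k = 3) clustering of
# cue-aligned trial averages, canonical phenotype labels, per-cluster peak
# responses across alignments, and D1/D2 window comparisons.

source(file.path("analysis", "00_config.R"))

ses <- make_study_session()
tr <- preprocess_session(ses$recording)
ten_press <- build_tensor(tr, ses$events, "press")
ten_cue <- build_tensor(tr, ses$events, "cue_onset", conditions = "cued")

avg_cue <- trial_average(ten_cue, "cued")
cl <- cluster_neurons(avg_cue, ten_cue$time, window = c(-2, 2), k = 3)
cl <- canonicalize_labels(cl, ten_cue, ten_press)

truth <- ses$truth$cluster_id[tr$kept_rois]
assign <- data.frame(roi = tr$kept_rois, raw_label = cl$raw_label,
                     canonical_label = cl$canonical_label,
                     cell_type = ten_cue$cell_type,
                     planted_archetype = truth)
write.csv(assign, file.path(results_dir, "cluster_assignments.csv"),
          row.names = FALSE)

cat("Cluster sizes (canonical 1 = action-timed, 2 = cue-locked, 3 = post-action):\n")
print(table(assign$canonical_label))
cat("Agreement with planted archetypes:\n")
print(table(canonical = assign$canonical_label, planted = assign$planted_archetype))

# per-cluster peak responses across the three alignments
avg_press_cued <- trial_average(ten_press, "cued")
avg_press_self <- trial_average(ten_press, "self_paced")
peaks <- data.frame(
  cluster = rep(1:3, 3),
  alignment = rep(c("cue", "press_cued", "press_self"), each = 3),
  peak_z = c(
    tapply(peak_response(avg_cue, ten_cue$time, c(0, 2)),
           cl$canonical_label, mean),
    tapply(peak_response(avg_press_cued, ten_press$time, c(-0.5, 1.5)),
           cl$canonical_label, mean),
    tapply(peak_response(avg_press_self, ten_press$time, c(-0.5, 1.5)),
           cl$canonical_label, mean)))
write.csv(peaks, file.path(results_dir, "cluster_peaks.csv"),
          row.names = FALSE)
cat("\nMean peak z per cluster and alignment:\n")
print(reshape(peaks, idvar = "cluster", timevar = "alignment",
              direction = "wide"))

# one-way ANOVA across alignments for each cluster (Tukey-Kramer post hoc)
for (k in 1:3) {
  in_k <- cl$canonical_label == k
  an <- group_compare(list(
    cue = peak_response(avg_cue, ten_cue$time, c(0, 2))[in_k],
    press_cued = peak_response(avg_press_cued, ten_press$time,
                               c(-0.5, 1.5))[in_k],
    press_self = peak_response(avg_press_self, ten_press$time,
                               c(-0.5, 1.5))[in_k]))
  cat(sprintf("Cluster %d peak across alignments: ANOVA p = %.2g\n",
              k, an$p_value))
}

# D1/D2 window means in the published windows
ct <- ten_cue$cell_type
windows <- list(cue_0_200ms = list(avg_cue, ten_cue$time, c(0, 0.2)),
                cue_1_2s = list(avg_cue, ten_cue$time, c(1, 2)),
                prepress_750ms = list(avg_press_self, ten_press$time,
                                      c(-0.75, 0)))
cat("\nD1 vs D2 window means (z):\n")
rows <- lapply(names(windows), function(w) {
  v <- do.call(window_mean, windows[[w]])
  cmp <- group_compare(v[ct == "D1"], v[ct == "D2"])
  cat(sprintf("  %-15s D1 = %.3f, D2 = %.3f, %s p = %.2g\n", w,
              mean(v[ct == "D1"]), mean(v[ct == "D2"]),
              cmp$test_name, cmp$p_value))
  data.frame(window = w, d1_mean = mean(v[ct == "D1"]),
             d2_mean = mean(v[ct == "D2"]), p_value = cmp$p_value)
})
write.csv(do.call(rbind, rows), file.path(results_dir, "d1_d2_windows.csv"),
          row.names = FALSE)
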