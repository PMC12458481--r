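#!/usr/bin/env Rscript
# Generate the synthetic study session: behavioral event log, lever trace and
# planted neural ground truth. Writes the behavioral files and ground truth;
# the fluorescence matrices are regenerated on demand by later scripts (the
# generator is deterministic in the seed).

source(file.path("analysis", "00_config.R"))

ses <- make_study_session()

write_event_log(ses$events, file.path(results_dir, "session"))
if (requireNamespace("jsonlite", quietly = TRUE))
  write_ground_truth(ses$truth, file.path(results_dir, "session",
                                          "ground_truth.json"))

ev <- ses$events$events
cat("Session:", sprintf("%.1f min,", max(ev$time) / 60),
    sum(ev$kind == "reward"), "rewards,",
    sum(ev$kind == "press"), "presses\n")
cat("Blocks:\n")
print(table(block = ev$block_index[ev$kind == "reward"],
            type = ev$block_type[ev$kind == "reward"]))
cat("Planted archetypes:\n")
print(table(ses$truth$cluster_id))
cat("Cell types:\n")
print(table(ses$recording$cell_type))
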