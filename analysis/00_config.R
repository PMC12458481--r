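# Shared configuration for the analysis chain.
#
# One synthetic "study session" stands in for a recorded mouse: three
# cued/self-paced block pairs, 20 rewards per block (a scaled-down version of
# the ~30-reward blocks of the task), 120 ROIs. Every numbered script
# regenerates the session deterministically from this seed, so intermediate
# recordings never need to be stored.

library(leverctx)

study_seed <- 42L

make_study_session <- function(seed = study_seed) {
  bcfg <- behavior_config(n_block_pairs = 3L, rewards_per_block = 20L,
                          seed = seed)
  ncfg <- neural_config(n_neurons = 120L, seed = seed + 1L)
  simulate_session(bcfg, ncfg)
}

results_dir <- file.path("results")
dir.create(results_dir, showWarnings = FALSE, recursive = TRUE)
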