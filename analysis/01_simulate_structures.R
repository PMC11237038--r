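#!/usr/bin/env Rscript

# Builds the synthetic structure panel used by the downstream analyses: a
# 93-item "perceptual" reference structure with coarse category geometry,
# plus emulated observers of it --
#   group_average : discrete 0-7 ratings from a simulated rater panel,
#                   averaged (the way a human group-average matrix is built)
#   agent_close   : trial-averaged continuous ratings of a lightly distorted
#                   copy (an artificial rater that tracks the reference well)
#   agent_coarse  : trial-averaged ratings of a copy whose within-category
#                   fine structure was resampled (same coarse geometry only)
# Everything is seeded; outputs land in results/structures/.

suppressPackageStartupMessages(library(gwotalign))

out_dir <- file.path("results", "structures")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
seed <- 20260922

# reference structure: 3 coarse categories x 31 items (93 items), category
# centers placed randomly so the coarse geometry is asymmetric
ref_pair <- make_category_pair(resample_fine = FALSE, seed = seed,
                               permute = FALSE)
reference <- normalize_dissim(ref_pair$source)

# human-like group average: 60 raters, 0-7 integer scale, rater noise 0.8
panel <- simulate_rater_panel(reference, n_raters = 60,
                              rater_noise_sd = 0.8, seed = seed + 1)
group_average <- dissim_from_ratings(panel, labels = dissim_labels(reference))

# close artificial agent: small metric distortion, 5 trials averaged
close_base <- make_pair(reference, noise_sd = 0.02, seed = seed + 2,
                        permute = FALSE)$target
agent_close <- simulate_llm_trials(normalize_dissim(close_base),
                                   n_trials = 5, trial_noise_sd = 0.4,
                                   seed = seed + 3)

# coarse-only agent: same category geometry, fine structure resampled
coarse_pair <- make_category_pair(resample_fine = TRUE, seed = seed,
                                  permute = FALSE)
agent_coarse <- simulate_llm_trials(normalize_dissim(coarse_pair$target),
                                    n_trials = 5, trial_noise_sd = 0.4,
                                    seed = seed + 4)

structures <- list(reference = reference, group_average = group_average,
                   agent_close = agent_close, agent_coarse = agent_coarse)
for (nm in names(structures)) {
  write_dissim_csv(normalize_dissim(structures[[nm]]),
                   file.path(out_dir, paste0(nm, ".csv")))
}

cat("Structure panel (93 items each) written to", out_dir, "\n")
for (nm in names(structures)) {
  d <- normalize_dissim(structures[[nm]])
  cat(sprintf("  %-14s mean off-diagonal %.3f\n", nm,
              mean(d[upper.tri(d)])))
}
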