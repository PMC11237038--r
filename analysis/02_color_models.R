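#!/usr/bin/env Rscript

# Color-space baseline models: draws a 93-color stimulus set from the sRGB
# cube and builds the two model dissimilarity matrices -- Euclidean distance
# in RGB, and CIEDE2000 on CIELAB. These are the "simple model" baselines
# against which richer similarity structures are compared.

suppressPackageStartupMessages(library(gwotalign))

out_dir <- file.path("results", "structures")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

colors <- random_colors(93, seed = 424242)
writeLines(colors$labels, file.path("results", "color_list.txt"))

rgb_model <- normalize_dissim(rgb_dissimilarity(colors))
lab_model <- normalize_dissim(lab_dissimilarity(colors))
write_dissim_csv(rgb_model, file.path(out_dir, "model_rgb.csv"))
write_dissim_csv(lab_model, file.path(out_dir, "model_lab.csv"))

cat("93-color stimulus set and model matrices written\n")
cat(sprintf("  RGB vs LAB upper-triangle Spearman rho: %.3f\n",
            rsa_spearman(rgb_model, lab_model)))
cat(sprintf("  max RGB distance before normalization: %.1f (black-white %.1f)\n",
            max(rgb_dissimilarity(colors)),
            sqrt(3 * 255^2)))
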