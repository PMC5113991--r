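#!/usr/bin/env Rscript
# Generate the synthetic electrophysiology campaign: four replicate runs of
# each monolayer preset (wild-type iso/hypo, knockout, rescue) on a 5-min
# grid over 2 h, plus the reversibility protocol extended to 130 min.
# Raw (uncorrected) sample and blank readings go to results/raw/, the
# latent ground truth alongside for later comparison.

library(paraperm)

out_raw <- "results/raw"
dir.create(out_raw, showWarnings = FALSE, recursive = TRUE)

presets <- preset_library()
n_rep <- 4
base_seed <- 20260101

for (nm in names(presets)) {
  grid <- if (nm == "wt_reversibility") seq(0, 130, 5) else seq(0, 120, 5)
  for (rep in seq_len(n_rep)) {
    seed <- base_seed + 100 * match(nm, names(presets)) + rep
    sim <- simulate_run(presets[[nm]], noise_model(seed = seed), grid)
    path <- file.path(out_raw, sprintf("%s_rep%d.csv", nm, rep))
    write_measurements(sim$sample, path, filter_id = "epithelium",
                       role = "sample")
    write_measurements(sim$blank, path, filter_id = "blank",
                       role = "blank", append = TRUE)
    write.csv(sim$truth,
              file.path(out_raw, sprintf("%s_rep%d_truth.csv", nm, rep)),
              row.names = FALSE)
  }
  cat(sprintf("%-18s %d replicates, %d time points each\n",
              nm, n_rep, length(grid)))
}
cat("raw series written to", out_raw, "\n")
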