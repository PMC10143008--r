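#!/usr/bin/env Rscript
# Step 1: generate the synthetic three-cultivation fermentation study.
#
# Emulates the study design: three batch cultivations with initial
# (glucose, biomass) of (1.21, 0.02), (1.21, 0.002) and (0.76, 0.02),
# 15 h horizon, 2D fluorescence spectra every 15 min on the 120-channel
# scatter-filtered grid (2% multiplicative noise), and hourly offline
# references (5% noise). Writes one spectra CSV and one offline CSV per
# cultivation plus a study manifest.

suppressPackageStartupMessages(library(fermcal))

seed <- as.integer(Sys.getenv("STUDY_SEED", "1"))
out_dir <- file.path("results", "study")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

config <- study_config(seed = seed)
study <- generate_study(config)

manifest <- list(seed = seed,
                 true_params = unclass(config$true_params),
                 cultivations = list())
for (cv in study) {
  sp <- file.path(out_dir, paste0(cv$id, "_spectra.csv"))
  off <- file.path(out_dir, paste0(cv$id, "_offline.csv"))
  truth <- file.path(out_dir, paste0(cv$id, "_truth.csv"))
  write_spectra_csv(cv$spectra, sp)
  write_offline_csv(cv$offline, off)
  write_trajectory_csv(cv$truth$trajectory, truth)
  manifest$cultivations[[cv$id]] <- list(
    id = cv$id, x0 = cv$init$x0, g0 = cv$init$g0, l0 = cv$init$l0,
    spectra = sp, offline = off, truth = truth)
  cat(sprintf("%s: %d spectra x %d channels, %d offline samples (x0=%.3g, g0=%.3g)\n",
              cv$id, length(cv$spectra$times), nrow(cv$spectra$channels),
              nrow(cv$offline), cv$init$x0, cv$init$g0))
}
jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat(sprintf("study written under %s (seed %d, true mu = %.2f 1/h)\n",
            out_dir, seed, config$true_params$mu))
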