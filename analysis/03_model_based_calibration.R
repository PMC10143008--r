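#!/usr/bin/env Rscript
# Step 3: model-based calibration — no offline data involved.
#
# For each leave-one-cultivation-out fold, the specific growth rate is
# optimized so that PLS models calibrated against SIMULATED state
# variables (yields fixed at 3.4 and 2.5) predict the held-out
# cultivation's simulated states best from its SNV-normalized spectra.
# The offline CSVs are deliberately not read here.

suppressPackageStartupMessages(library(fermcal))

manifest <- jsonlite::read_json(file.path("results", "study", "manifest.json"),
                                simplifyVector = FALSE)
cultivations <- lapply(manifest$cultivations, function(m)
  cultivation(m$id, initial_state(m$x0, m$g0, m$l0),
              read_spectra_csv(m$spectra, m$id)))

res <- fit_mbc(cultivations, mbc_config(pso = pso_settings(
  swarm_size = 15, max_iterations = 40, stall_iterations = 10,
  seed = manifest$seed + 2L)))

print(res)

out_dir <- file.path("results", "mbc")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
jsonlite::write_json(
  list(mu_opt = res$mu_opt, fold_mu = as.list(res$fold_mu),
       fold_assignments = res$fold_assignments,
       y_gx_fixed = res$config$y_gx_fixed, y_gl_fixed = res$config$y_gl_fixed,
       se_breakdown = res$se_breakdown),
  file.path(out_dir, "mbc_fit.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
for (id in res$fold_assignments) {
  for (v in names(res$fold_models[[id]]))
    write_pls_model(res$fold_models[[id]][[v]],
                    file.path(out_dir, sprintf("pls_%s_%s.json", id, v)))
  utils::write.csv(
    data.frame(iteration = seq_along(res$se_trace[[id]]),
               best_value = res$se_trace[[id]]),
    file.path(out_dir, sprintf("trace_%s.csv", id)), row.names = FALSE)
}
cat("wrote results/mbc/mbc_fit.json, per-fold PLS models and PSO traces\n")
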