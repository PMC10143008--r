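#!/usr/bin/env Rscript
# Step 4: validate both calibrations against the offline references.
#
# Rebuilds the leave-one-cultivation-out validation: the process-model
# table compares simulated trajectories of each held-out cultivation with
# its offline measurements; the chemometric table compares the fold's PLS
# predictions from spectra with the same measurements. Writes both tables
# as CSV and an overlay plot per cultivation.

suppressPackageStartupMessages(library(fermcal))

manifest <- jsonlite::read_json(file.path("results", "study", "manifest.json"),
                                simplifyVector = FALSE)
cultivations <- lapply(manifest$cultivations, function(m)
  cultivation(m$id, initial_state(m$x0, m$g0, m$l0),
              read_spectra_csv(m$spectra, m$id),
              offline = read_offline_csv(m$offline, m$id)))

cl <- jsonlite::read_json(file.path("results", "classical_fit.json"),
                          simplifyVector = TRUE)
classical_params <- process_params(cl$params$mu, cl$params$y_gx, cl$params$y_gl)

# refit MBC (fast) so fold models and assignments are consistent in-session
res <- fit_mbc(cultivations, mbc_config(pso = pso_settings(
  swarm_size = 15, max_iterations = 40, stall_iterations = 10,
  seed = manifest$seed + 2L)))

val <- validate_study(cultivations, classical_params, res)
cat("process-model simulation vs offline (fold-averaged):\n")
print(val$simulation, digits = 3)
cat("chemometric prediction vs offline (fold-averaged):\n")
print(val$prediction, digits = 3)

write_validation_csv(val$simulation, file.path("results", "table_simulation.csv"))
write_validation_csv(val$prediction, file.path("results", "table_prediction.csv"))

# overlay plots: offline points, classical simulation, fold predictions
for (f in seq_along(res$fold_assignments)) {
  id <- res$fold_assignments[f]
  cv <- cultivations[[match(id, vapply(cultivations, `[[`, "", "id"))]]
  pred <- predict_online(res$fold_models[[id]], cv$spectra)
  sim <- simulate_batch(classical_params, cv$init, cv$spectra$times)
  png(file.path("results", sprintf("overlay_%s.png", id)),
      width = 900, height = 360)
  op <- par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  for (v in c("biomass", "glucose", "lactate")) {
    unit <- if (v == "biomass") "1e8 CFU/mL" else "g/L"
    plot(cv$offline$time, cv$offline[[v]], pch = 19,
         xlab = "time (h)", ylab = sprintf("%s (%s)", v, unit), main = id,
         ylim = range(c(cv$offline[[v]], pred[[v]], sim[[v]]), na.rm = TRUE))
    lines(sim$time, sim[[v]], lty = 2)
    lines(pred$time, pred[[v]], col = "steelblue")
  }
  par(op)
  dev.off()
}
cat("wrote results/table_simulation.csv, results/table_prediction.csv and overlay plots\n")
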