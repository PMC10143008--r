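#!/usr/bin/env Rscript
# Step 2: classical calibration of the process model.
#
# Fits the kinetic triple (mu, Y_GX, Y_GL) to the offline reference tables
# of all three cultivations jointly, by particle swarm optimization of the
# range-normalized sum of per-variable RMSEs; search box 0.2-0.9 1/h for
# mu and 2.0-4.0 for both yields.

suppressPackageStartupMessages(library(fermcal))

manifest <- jsonlite::read_json(file.path("results", "study", "manifest.json"),
                                simplifyVector = FALSE)
datasets <- lapply(manifest$cultivations, function(m)
  list(init = initial_state(m$x0, m$g0, m$l0),
       offline = read_offline_csv(m$offline, m$id)))

fit <- fit_classical(datasets, settings = pso_settings(
  swarm_size = 30, max_iterations = 150, stall_iterations = 30,
  seed = manifest$seed + 1L))

print(fit$params)
cat(sprintf("normalized fitness SE = %.4g (G %.4g + L %.4g + X %.4g)\n",
            fit$fitness$se, fit$fitness$normalized_g, fit$fitness$normalized_l,
            fit$fitness$normalized_x))
cat(sprintf("raw RMSEs: glucose %.4g g/L, lactate %.4g g/L, biomass %.4g 1e8 CFU/mL\n",
            fit$fitness$grmse, fit$fitness$lrmse, fit$fitness$xrmse))

dir.create("results", showWarnings = FALSE)
jsonlite::write_json(
  list(params = unclass(fit$params),
       fitness = fit$fitness[c("grmse", "lrmse", "xrmse", "normalized_g",
                               "normalized_l", "normalized_x", "se")]),
  file.path("results", "classical_fit.json"),
  auto_unbox = TRUE, digits = NA, pretty = TRUE)
write_pso_trace_csv(fit$pso, file.path("results", "classical_trace.csv"))
cat("wrote results/classical_fit.json and results/classical_trace.csv\n")
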