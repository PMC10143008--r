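#' Root mean squared error
#'
#' @param reference,estimate Aligned numeric vectors of equal length.
#' @return `sqrt(mean((reference - estimate)^2))`, in the native units.
#' @examples
#' rmse(c(0, 0), c(3, 4))  # sqrt(25/2)
#' @export
rmse <- function(reference, estimate) {
  if (length(reference) != length(estimate))
    stop("'reference' and 'estimate' must have equal length", call. = FALSE)
  if (length(reference) == 0L) stop("empty vectors", call. = FALSE)
  sqrt(mean((reference - estimate)^2))
}

#' RMSE as a percentage of the reference range
#'
#' @param rmse_value RMSE in native units.
#' @param reference_values The reference series whose span (max - min)
#'   defines the denominator.
#' @return `100 * rmse_value / diff(range(reference_values))`, percent.
#' @examples
#' percent_range(0.15, c(0, 1.9))  # ~7.9
#' @export
percent_range <- function(rmse_value, reference_values) {
  rng <- diff(range(reference_values))
  if (rng <= 0) stop("reference range is zero", call. = FALSE)
  100 * rmse_value / rng
}

# nearest-neighbour matching of offline sampling times to spectra times
.match_times <- function(offline_times, spectra_times, window) {
  idx <- vapply(offline_times, function(t0) {
    j <- which.min(abs(spectra_times - t0))
    if (abs(spectra_times[j] - t0) <= window) j else NA_integer_
  }, 0L)
  if (anyNA(idx))
    warning(sprintf("%d offline point(s) without a spectrum within %.3g h; skipped",
                    sum(is.na(idx)), window))
  idx
}

#' Validate calibrations against offline reference data
#'
#' Builds the two standard validation tables of a leave-one-cultivation-out
#' study: the process-model table compares simulated trajectories of each
#' held-out cultivation with its offline measurements, and the chemometric
#' table compares the held-out fold's PLS predictions from spectra with the
#' same offline measurements. Both are produced for the classical
#' calibration (its fitted kinetic triple, with fold PLS models trained on
#' states simulated under those parameters) and for the model-based
#' calibration (each fold's optimized growth rate with the fixed yields,
#' and that fold's PLS models). Offline timestamps drive the comparison;
#' for the chemometric table each offline point is matched to the nearest
#' spectrum within `window` hours. RMSEs are averaged over folds; the
#' percent-of-range denominator is the pooled offline range across the
#' folds' validation cultivations.
#'
#' @param cultivations List of [cultivation()] objects, each with offline
#'   data.
#' @param classical_params The classical [process_params()] fit.
#' @param mbc_result An `mbc_result` from [fit_mbc()].
#' @param window Offline-to-spectrum matching window, hours.
#' @return A list with data.frames `simulation` and `prediction` (columns
#'   `approach`, `variable`, `rmse`, `pct_range`, `n_points`) and
#'   `per_fold`, the per-fold RMSE detail.
#' @export
validate_study <- function(cultivations, classical_params, mbc_result,
                           window = 0.15) {
  stopifnot(inherits(classical_params, "process_params"),
            inherits(mbc_result, "mbc_result"))
  if (any(vapply(cultivations, function(cv) is.null(cv$offline), TRUE)))
    stop("every cultivation needs offline data for validation", call. = FALSE)
  ids <- vapply(cultivations, `[[`, "", "id")
  stopifnot(identical(sort(ids), sort(mbc_result$fold_assignments)))
  config <- mbc_result$config

  # classical-arm chemometric models: per fold, PLS trained on states
  # simulated under the classical parameter fit
  classical_cfg <- config
  classical_cfg$y_gx_fixed <- classical_params$y_gx
  classical_cfg$y_gl_fixed <- classical_params$y_gl
  cultivations <- lapply(cultivations, function(cv) {
    cv$spectra <- .ensure_snv(cv$spectra)
    cv
  })

  pooled_obs <- list(biomass = numeric(0), glucose = numeric(0),
                     lactate = numeric(0))
  detail <- list()
  for (f in seq_along(ids)) {
    hold_id <- mbc_result$fold_assignments[f]
    cv <- cultivations[[match(hold_id, ids)]]
    off <- cv$offline
    for (v in .state_vars)
      pooled_obs[[v]] <- c(pooled_obs[[v]], off[[v]][!is.na(off[[v]])])

    sims <- list(
      classical = simulate_batch(classical_params, cv$init, off$time),
      mbc = simulate_batch(
        process_params(mbc_result$fold_mu[[f]], config$y_gx_fixed,
                       config$y_gl_fixed),
        cv$init, off$time)
    )
    match_idx <- .match_times(off$time, cv$spectra$times, window)
    preds <- list(
      classical = predict_online(
        .mbc_fold(classical_params$mu, cultivations, hold_id, classical_cfg,
                  want_models = TRUE)$models,
        cv$spectra),
      mbc = predict_online(mbc_result$fold_models[[hold_id]], cv$spectra)
    )
    for (approach in c("classical", "mbc")) {
      for (v in .state_vars) {
        ok <- !is.na(off[[v]])
        detail[[length(detail) + 1L]] <- data.frame(
          fold = hold_id, approach = approach, variable = v,
          table = "simulation",
          rmse = rmse(off[[v]][ok], sims[[approach]][[v]][ok]),
          n_points = sum(ok))
        ok_p <- ok & !is.na(match_idx)
        detail[[length(detail) + 1L]] <- data.frame(
          fold = hold_id, approach = approach, variable = v,
          table = "prediction",
          rmse = rmse(off[[v]][ok_p],
                      preds[[approach]][[v]][match_idx[ok_p]]),
          n_points = sum(ok_p))
      }
    }
  }
  per_fold <- do.call(rbind, detail)

  summarize <- function(tbl) {
    sub <- per_fold[per_fold$table == tbl, ]
    agg <- stats::aggregate(rmse ~ approach + variable, data = sub, FUN = mean)
    agg$pct_range <- mapply(function(r, v) percent_range(r, pooled_obs[[v]]),
                            agg$rmse, agg$variable)
    npt <- stats::aggregate(n_points ~ approach + variable, data = sub, FUN = sum)
    merge(agg, npt, by = c("approach", "variable"))
  }
  list(simulation = summarize("simulation"),
       prediction = summarize("prediction"),
       per_fold = per_fold)
}

#' Write a validation report as CSV
#'
#' @param report One of the data.frames returned by [validate_study()].
#' @param path File path.
#' @export
write_validation_csv <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
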