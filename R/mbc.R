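#' A cultivation: spectra, initial state, optional offline references
#'
#' @param id Unique label within a study.
#' @param init The cultivation's [initial_state()].
#' @param spectra A `spectrum_series` (see [spectrum_series()]).
#' @param offline Optional `offline_dataset`, used only for validation —
#'   never for model-based calibration.
#' @param truth Optional ground-truth record (generating parameters and
#'   noise-free trajectory) attached by the synthetic-study generator.
#' @return An object of class `cultivation`.
#' @export
cultivation <- function(id, init, spectra, offline = NULL, truth = NULL) {
  stopifnot(inherits(init, "initial_state"), inherits(spectra, "spectrum_series"))
  if (!is.null(offline)) stopifnot(inherits(offline, "offline_dataset"))
  structure(list(id = as.character(id), init = init, spectra = spectra,
                 offline = offline, truth = truth),
            class = "cultivation")
}

#' Model-based calibration configuration
#'
#' The growth rate is searched over `[mu_lower, mu_upper]` while both
#' yields are held fixed (they are assumed known from prior cultivations);
#' defaults are a 0.2-0.9 1/h search range and fixed yields 3.4 and
#' 2.5 (1e8 CFU/g). PLS component counts default to 3 for biomass and 5
#' for glucose and lactate. The PSO defaults here are leaner than
#' [pso_settings()]'s generic defaults because the search is
#' one-dimensional and smooth.
#'
#' @param mu_lower,mu_upper Growth-rate search bounds, 1/h.
#' @param y_gx_fixed,y_gl_fixed Fixed yield coefficients, 1e8 CFU/g.
#' @param n_components Named integer vector of PLS component counts per
#'   state variable.
#' @param pso A [pso_settings()] object.
#' @return An object of class `mbc_config`.
#' @export
mbc_config <- function(mu_lower = 0.2, mu_upper = 0.9,
                       y_gx_fixed = 3.4, y_gl_fixed = 2.5,
                       n_components = c(biomass = 3, glucose = 5, lactate = 5),
                       pso = pso_settings(swarm_size = 15, max_iterations = 40,
                                          stall_iterations = 10)) {
  if (y_gx_fixed <= 0 || y_gl_fixed <= 0)
    stop("fixed yields must be positive", call. = FALSE)
  if (!all(.state_vars %in% names(n_components)))
    stop("'n_components' must name biomass, glucose and lactate", call. = FALSE)
  space <- search_space(mu_lower, mu_upper, "mu")
  structure(list(mu_space = space, y_gx_fixed = y_gx_fixed,
                 y_gl_fixed = y_gl_fixed, n_components = n_components,
                 pso = pso),
            class = "mbc_config")
}

# SNV exactly once: normalize unless the series is already marked
.ensure_snv <- function(series) {
  if (isTRUE(series$snv)) series else snv_normalize(series)
}

# Fit one fold at a given growth rate: PLS per variable on the pooled
# calibration cultivations, predictions and squared-error breakdown on the
# holdout. Shared by the PSO objective and the final refit.
.mbc_fold <- function(mu, cultivations, holdout_id, config, want_models = FALSE) {
  ids <- vapply(cultivations, `[[`, "", "id")
  hold <- match(holdout_id, ids)
  if (is.na(hold)) stop("unknown holdout id '", holdout_id, "'", call. = FALSE)
  if (length(cultivations) - 1L < 2L)
    stop("model-based calibration needs at least 2 calibration cultivations ",
         "besides the holdout", call. = FALSE)
  params <- process_params(mu, config$y_gx_fixed, config$y_gl_fixed)

  sims <- lapply(cultivations, function(cv)
    simulate_batch(params, cv$init, cv$spectra$times))
  mats <- lapply(cultivations, function(cv) .ensure_snv(cv$spectra)$intensities)

  cal <- setdiff(seq_along(cultivations), hold)
  X_cal <- do.call(rbind, mats[cal])
  X_test <- mats[[hold]]

  se <- 0
  breakdown <- numeric(0)
  models <- list()
  for (v in .state_vars) {
    y_cal <- unlist(lapply(sims[cal], `[[`, v), use.names = FALSE)
    m <- fit_pls(X_cal, y_cal, config$n_components[[v]], target_name = v)
    pred <- predict_pls(m, X_test)
    sim_test <- sims[[hold]][[v]]
    rng <- diff(range(sim_test))
    if (rng <= 0) {
      warning(sprintf("simulated '%s' has zero range on holdout '%s'; excluded",
                      v, holdout_id))
      next
    }
    term <- sum((pred - sim_test)^2) / rng^2
    breakdown[[v]] <- term
    se <- se + term
    if (want_models) models[[v]] <- m
  }
  list(se = se, breakdown = breakdown, models = models)
}

#' Model-based calibration objective for one fold
#'
#' Sum of squared differences between chemometric predictions and simulated
#' state variables on the held-out cultivation. All cultivations are
#' simulated with the candidate growth rate (yields fixed) from their own
#' initial states and aligned to their spectra; one PLS model per state
#' variable is fitted on the pooled calibration cultivations and applied to
#' the holdout spectra; each variable's sum of squared prediction-vs-
#' simulation differences is divided by the squared simulated range of that
#' variable on the holdout, making the objective dimensionless.
#'
#' Spectra are SNV-normalized exactly once: series already marked as
#' normalized are used as-is.
#'
#' @param mu Candidate specific growth rate, 1/h.
#' @param cultivations List of [cultivation()] objects (>= 3).
#' @param holdout_id Id of the cultivation used as test set.
#' @param config An [mbc_config()].
#' @return Scalar objective value (dimensionless).
#' @export
mbc_objective <- function(mu, cultivations, holdout_id, config = mbc_config()) {
  .mbc_fold(mu, cultivations, holdout_id, config)$se
}

#' Model-based calibration: joint growth-rate and chemometric optimization
#'
#' The core procedure: for each leave-one-cultivation-out fold, the
#' specific growth rate is optimized by PSO against [mbc_objective()] —
#' simultaneously selecting the growth rate and the PLS models calibrated
#' on simulated state variables — with no offline data involved. Each
#' cultivation is held out exactly once. The reported `mu_opt` is the mean
#' of the per-fold optima; per-fold models are refit at each fold's
#' optimal growth rate.
#'
#' @param cultivations List of [cultivation()] objects; at least 3, with
#'   unique ids, so every fold retains >= 2 calibration cultivations.
#' @param config An [mbc_config()].
#' @return An object of class `mbc_result`: `mu_opt`, `fold_mu` (named
#'   per-fold optima), `fold_assignments` (holdout id per fold),
#'   `fold_models` (per fold, one `pls_model` per state variable),
#'   `se_trace` (per-fold PSO traces), `se_breakdown` (per fold, the
#'   per-variable normalized test error at the optimum), `config`.
#' @export
fit_mbc <- function(cultivations, config = mbc_config()) {
  if (length(cultivations) < 3L)
    stop("model-based calibration needs at least 3 cultivations", call. = FALSE)
  ids <- vapply(cultivations, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("cultivation ids must be unique", call. = FALSE)
  # SNV once, before splitting
  cultivations <- lapply(cultivations, function(cv) {
    cv$spectra <- .ensure_snv(cv$spectra)
    cv
  })
  fold_mu <- numeric(length(ids))
  fold_models <- vector("list", length(ids))
  fold_breakdown <- vector("list", length(ids))
  traces <- vector("list", length(ids))
  base_seed <- config$pso$seed
  for (f in seq_along(ids)) {
    settings <- config$pso
    if (!is.null(base_seed)) settings$seed <- (base_seed + 7919L * f) %% 2147483647L
    res <- tryCatch(
      pso_minimize(function(x) mbc_objective(x[1L], cultivations, ids[f], config),
                   config$mu_space, settings),
      error = function(e) stop("fold '", ids[f], "' failed: ",
                               conditionMessage(e), call. = FALSE))
    fold_mu[f] <- res$best_position[[1L]]
    traces[[f]] <- res$trace
    refit <- .mbc_fold(fold_mu[f], cultivations, ids[f], config,
                       want_models = TRUE)
    fold_models[[f]] <- refit$models
    fold_breakdown[[f]] <- refit$breakdown
  }
  names(fold_mu) <- ids
  names(fold_models) <- ids
  names(fold_breakdown) <- ids
  names(traces) <- ids
  structure(
    list(mu_opt = mean(fold_mu), fold_mu = fold_mu, fold_assignments = ids,
         fold_models = fold_models, se_trace = traces,
         se_breakdown = fold_breakdown, config = config),
    class = "mbc_result"
  )
}

#' @export
print.mbc_result <- function(x, ...) {
  cat(sprintf("Model-based calibration: mu_opt = %.4f 1/h (folds: %s)\n",
              x$mu_opt, paste(sprintf("%.4f", x$fold_mu), collapse = ", ")))
  cat(sprintf("Fixed yields: Y_GX = %.3g, Y_GL = %.3g (1e8 CFU/g)\n",
              x$config$y_gx_fixed, x$config$y_gl_fixed))
  invisible(x)
}

#' Online prediction of state variables from spectra
#'
#' Applies per-variable chemometric models to a spectrum series to predict
#' biomass, glucose and lactate at every timestamp. Output is the raw
#' chemometric estimate — no clamping — but rows with negative
#' concentration estimates are flagged.
#'
#' @param models Named list with one `pls_model` per state variable
#'   (`biomass`, `glucose`, `lactate`), e.g. one element of
#'   `fit_mbc(...)$fold_models`.
#' @param spectra A `spectrum_series` on the training channel grid; SNV
#'   is applied if not already done.
#' @return A data.frame (`time`, `biomass`, `glucose`, `lactate`) with an
#'   attribute `negative_flags`, a logical matrix marking negative
#'   estimates.
#' @export
predict_online <- function(models, spectra) {
  stopifnot(inherits(spectra, "spectrum_series"))
  if (!all(.state_vars %in% names(models)))
    stop("'models' must name biomass, glucose and lactate", call. = FALSE)
  X <- .ensure_snv(spectra)$intensities
  out <- data.frame(time = spectra$times)
  for (v in .state_vars) out[[v]] <- predict_pls(models[[v]], X)
  flags <- as.matrix(out[, .state_vars]) < 0
  attr(out, "negative_flags") <- flags
  out
}
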