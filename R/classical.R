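#' Offline reference measurements for one cultivation
#'
#' Laboratory reference data: plate-count biomass and HPLC glucose/lactate
#' at discrete sampling times. Any series may contain `NA` for samples
#' where that variable was not measured.
#'
#' @param cultivation_id Label.
#' @param times Sampling times, hours, sorted ascending.
#' @param biomass Biomass, 1e8 CFU/mL (`NA` allowed).
#' @param glucose Glucose, g/L (`NA` allowed).
#' @param lactate Lactic acid, g/L (`NA` allowed).
#' @return An object of class `offline_dataset` (a data.frame).
#' @export
offline_dataset <- function(cultivation_id, times, biomass, glucose, lactate) {
  if (is.unsorted(times)) stop("'times' must be sorted ascending", call. = FALSE)
  n <- length(times)
  if (any(lengths(list(biomass, glucose, lactate)) != n))
    stop("all series must have the same length as 'times'", call. = FALSE)
  structure(
    data.frame(time = times, biomass = biomass, glucose = glucose,
               lactate = lactate),
    class = c("offline_dataset", "data.frame"),
    cultivation_id = as.character(cultivation_id)
  )
}

#' Read / write offline reference CSVs
#'
#' Same dialect as trajectories (`time_h,biomass_1e8cfu_ml,glucose_g_l,
#' lactate_g_l`); empty cells are missing measurements.
#'
#' @param path File path.
#' @param cultivation_id Label to attach.
#' @return An `offline_dataset`.
#' @export
read_offline_csv <- function(path, cultivation_id = basename(path)) {
  df <- read_trajectory_csv(path)
  offline_dataset(cultivation_id, df$time, df$biomass, df$glucose, df$lactate)
}

#' @rdname read_offline_csv
#' @param dataset An `offline_dataset`.
#' @export
write_offline_csv <- function(dataset, path) {
  write_trajectory_csv(dataset, path)
}

.state_vars <- c("biomass", "glucose", "lactate")

#' Fitness of process parameters against offline data
#'
#' The classical calibration objective. Each cultivation is simulated at
#' its offline sampling times from its own initial state; residuals are
#' pooled across cultivations per variable; per-variable root mean squared
#' errors (glucose, lactate, biomass) are computed over the non-missing
#' points; each RMSE is then normalized by the pooled observed range
#' (max - min) of that variable's offline values so that the three terms
#' are dimensionless and carry equal leverage; the fitness is their sum.
#' A variable with zero observed range is excluded with a warning.
#'
#' @param params A [process_params()] candidate.
#' @param datasets A list of `list(init = initial_state, offline =
#'   offline_dataset)` pairs, one per cultivation.
#' @return An object of class `fitness_breakdown`: raw RMSEs (`grmse`,
#'   `lrmse`, `xrmse`, native units), normalized components and their sum
#'   `se`.
#' @export
fitness_classical <- function(params, datasets) {
  stopifnot(inherits(params, "process_params"), length(datasets) >= 1L)
  resid <- list(biomass = numeric(0), glucose = numeric(0), lactate = numeric(0))
  obs <- resid
  for (ds in datasets) {
    stopifnot(inherits(ds$init, "initial_state"),
              inherits(ds$offline, "offline_dataset"))
    sim <- simulate_batch(params, ds$init, ds$offline$time)
    for (v in .state_vars) {
      ok <- !is.na(ds$offline[[v]])
      resid[[v]] <- c(resid[[v]], ds$offline[[v]][ok] - sim[[v]][ok])
      obs[[v]] <- c(obs[[v]], ds$offline[[v]][ok])
    }
  }
  rmse_v <- vapply(resid, function(r) sqrt(mean(r^2)), 0)
  range_v <- vapply(obs, function(o) diff(range(o)), 0)
  norm_v <- rep(NA_real_, 3L); names(norm_v) <- .state_vars
  for (v in .state_vars) {
    if (range_v[[v]] <= 0) {
      warning(sprintf("offline '%s' has zero observed range; excluded from fitness", v))
    } else {
      norm_v[[v]] <- rmse_v[[v]] / range_v[[v]]
    }
  }
  structure(
    list(grmse = rmse_v[["glucose"]], lrmse = rmse_v[["lactate"]],
         xrmse = rmse_v[["biomass"]],
         normalized_g = norm_v[["glucose"]], normalized_l = norm_v[["lactate"]],
         normalized_x = norm_v[["biomass"]],
         se = sum(norm_v, na.rm = TRUE),
         n = vapply(resid, length, 0L)),
    class = "fitness_breakdown"
  )
}

#' Default process-parameter search space
#'
#' Growth rate in 0.2-0.9 1/h, both yields in 2.0-4.0 (1e8 CFU/g).
#'
#' @return A [search_space()] with dimensions `mu`, `y_gx`, `y_gl`.
#' @export
classical_search_space <- function() {
  search_space(c(0.2, 2.0, 2.0), c(0.9, 4.0, 4.0), c("mu", "y_gx", "y_gl"))
}

#' Classical calibration of the process model against offline data
#'
#' Fits the kinetic triple (mu, Y_GX, Y_GL) by minimizing
#' [fitness_classical()] over a box search space with particle swarm
#' optimization. One parameter set is fitted jointly to all cultivations.
#'
#' @param datasets As in [fitness_classical()].
#' @param space A 3-dimensional [search_space()]; default
#'   [classical_search_space()].
#' @param settings A [pso_settings()] object.
#' @return A list: `params` ([process_params()] at the optimum), `fitness`
#'   (`fitness_breakdown` at the optimum), `trace`, `pso` (full optimizer
#'   result).
#' @export
fit_classical <- function(datasets, space = classical_search_space(),
                          settings = pso_settings()) {
  if (length(space$lower) != 3L)
    stop("'space' must have the 3 dimensions (mu, y_gx, y_gl)", call. = FALSE)
  obj <- function(x) {
    fitness_classical(process_params(x[1L], x[2L], x[3L]), datasets)$se
  }
  res <- pso_minimize(obj, space, settings)
  params <- process_params(res$best_position[[1L]], res$best_position[[2L]],
                           res$best_position[[3L]])
  list(params = params,
       fitness = fitness_classical(params, datasets),
       trace = res$trace, pso = res)
}
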