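#' Kinetic parameters of the batch fermentation model
#'
#' Bundles the kinetic triple of the closed-form batch model: the specific
#' growth rate and the two yield-type coefficients that couple glucose
#' consumption and lactic-acid production to biomass increase.
#'
#' @param mu Specific growth rate, 1/h.
#' @param y_gx Biomass-on-glucose yield, 1e8 CFU per g: biomass increase
#'   (1e8 CFU/mL) produced per g/L glucose consumed.
#' @param y_gl Biomass-to-lactate coupling, 1e8 CFU per g: biomass increase
#'   (1e8 CFU/mL) per g/L lactic acid produced.
#' @return An object of class `process_params`.
#' @examples
#' process_params(0.53, 3.33, 2.68)
#' @export
process_params <- function(mu, y_gx, y_gl) {
  for (nm in c("mu", "y_gx", "y_gl")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("'%s' must be a single finite positive number", nm),
           call. = FALSE)
    }
  }
  structure(list(mu = mu, y_gx = y_gx, y_gl = y_gl), class = "process_params")
}

#' @export
print.process_params <- function(x, ...) {
  cat(sprintf("Process parameters: mu = %.4g 1/h, Y_GX = %.4g, Y_GL = %.4g (1e8 CFU/g)\n",
              x$mu, x$y_gx, x$y_gl))
  invisible(x)
}

#' Initial state of a batch cultivation
#'
#' @param x0 Inoculated biomass, 1e8 CFU/mL (> 0).
#' @param g0 Initial glucose, g/L (>= 0).
#' @param l0 Initial lactic acid, g/L (>= 0); an uninoculated substrate
#'   carries none, so the default is 0.
#' @return An object of class `initial_state`.
#' @examples
#' initial_state(x0 = 0.02, g0 = 1.21)
#' @export
initial_state <- function(x0, g0, l0 = 0) {
  if (!is.numeric(x0) || length(x0) != 1L || !is.finite(x0) || x0 <= 0)
    stop("'x0' must be a single finite positive number", call. = FALSE)
  for (nm in c("g0", "l0")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop(sprintf("'%s' must be a single finite non-negative number", nm),
           call. = FALSE)
  }
  structure(list(x0 = x0, g0 = g0, l0 = l0), class = "initial_state")
}

#' Glucose depletion time
#'
#' Time at which batch glucose reaches zero under exponential growth:
#' `t* = log(1 + g0 * y_gx / x0) / mu`. Biomass and lactate are frozen
#' beyond `t*`.
#'
#' @param params A [process_params()] object.
#' @param init An [initial_state()] object.
#' @return Depletion time in hours; 0 when `g0 = 0`.
#' @examples
#' depletion_time(process_params(0.53, 3.33, 2.68),
#'                initial_state(0.02, 1.21))  # ~10.02 h
#' @export
depletion_time <- function(params, init) {
  stopifnot(inherits(params, "process_params"), inherits(init, "initial_state"))
  if (init$g0 == 0) return(0)
  log1p(init$g0 * params$y_gx / init$x0) / params$mu
}

#' Simulate a batch cultivation trajectory
#'
#' Closed-form batch model: biomass grows exponentially,
#' `x(t) = x0 * exp(mu * t)`, glucose is consumed as
#' `g(t) = g0 - (x(t) - x0) / y_gx`, and lactic acid is produced as
#' `l(t) = l0 + (x(t) - x0) / y_gl`, until the glucose depletion time `t*`
#' (see [depletion_time()]); for `t >= t*` glucose is exactly 0 and biomass
#' and lactate are held at their depletion-time values. Because `t*` is
#' handled analytically, trajectories are exact at arbitrary timestamps.
#'
#' @param params A [process_params()] object.
#' @param init An [initial_state()] object.
#' @param times Sampling times in hours, non-negative and sorted ascending.
#' @return A `state_trajectory`: a data.frame with columns `time` (h),
#'   `biomass` (1e8 CFU/mL), `glucose` (g/L), `lactate` (g/L).
#' @examples
#' p <- process_params(0.53, 3.33, 2.68)
#' s <- initial_state(0.02, 1.21)
#' simulate_batch(p, s, times = 0:15)
#' @export
simulate_batch <- function(params, init, times) {
  stopifnot(inherits(params, "process_params"), inherits(init, "initial_state"))
  if (!is.numeric(times) || length(times) == 0L || anyNA(times))
    stop("'times' must be a non-empty numeric vector", call. = FALSE)
  if (any(times < 0)) stop("'times' must be non-negative", call. = FALSE)
  if (is.unsorted(times)) stop("'times' must be sorted ascending", call. = FALSE)

  tstar <- depletion_time(params, init)
  # evaluating at min(t, t*) makes the post-depletion freeze exact
  growth <- exp(params$mu * pmin(times, tstar))
  x <- init$x0 * growth
  g <- init$g0 - init$x0 * (growth - 1) / params$y_gx
  g[times >= tstar] <- 0
  g <- pmax(g, 0)
  l <- init$l0 + init$x0 * (growth - 1) / params$y_gl

  structure(
    data.frame(time = times, biomass = x, glucose = g, lactate = l),
    class = c("state_trajectory", "data.frame"),
    params = params, init = init, depletion_time = tstar
  )
}

# column mapping between internal names and the on-disk CSV dialect
.trajectory_csv_cols <- c(
  time = "time_h", biomass = "biomass_1e8cfu_ml",
  glucose = "glucose_g_l", lactate = "lactate_g_l"
)

#' Write / read a state trajectory as CSV
#'
#' CSV dialect: header `time_h,biomass_1e8cfu_ml,glucose_g_l,lactate_g_l`,
#' one row per timestamp; empty cells are missing values (used by offline
#' reference tables).
#'
#' @param trajectory A data.frame with columns `time`, `biomass`, `glucose`,
#'   `lactate` (e.g. from [simulate_batch()]).
#' @param path File path.
#' @return `read_trajectory_csv()` returns a data.frame with the internal
#'   column names.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  stopifnot(all(names(.trajectory_csv_cols) %in% names(trajectory)))
  out <- trajectory[, names(.trajectory_csv_cols)]
  names(out) <- unname(.trajectory_csv_cols)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE)
  missing_cols <- setdiff(unname(.trajectory_csv_cols), names(raw))
  if (length(missing_cols))
    stop("trajectory CSV is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  out <- raw[, unname(.trajectory_csv_cols)]
  names(out) <- names(.trajectory_csv_cols)
  out
}
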