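#' Box-constrained search space
#'
#' @param lower,upper Per-dimension bounds, `lower < upper` elementwise.
#' @param names Optional per-dimension labels.
#' @return An object of class `search_space`.
#' @examples
#' search_space(c(0.2, 2, 2), c(0.9, 4, 4), c("mu", "y_gx", "y_gl"))
#' @export
search_space <- function(lower, upper, names = NULL) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (length(lower) != length(upper))
    stop("'lower' and 'upper' must have the same length", call. = FALSE)
  if (!all(is.finite(lower)) || !all(is.finite(upper)) || !all(lower < upper))
    stop("bounds must be finite with lower < upper elementwise", call. = FALSE)
  if (is.null(names)) names <- paste0("x", seq_along(lower))
  if (length(names) != length(lower))
    stop("'names' length must match the bounds", call. = FALSE)
  structure(list(lower = lower, upper = upper, names = as.character(names)),
            class = "search_space")
}

#' Particle swarm optimizer settings
#'
#' Defaults are the widely used constriction-equivalent coefficients:
#' inertia 0.729 with cognitive = social = 1.49445, a swarm of 30, at most
#' 100 iterations, and an early stop after 20 consecutive iterations whose
#' total improvement of the global best falls below `stall_tolerance`.
#'
#' @param swarm_size Number of particles (>= 2).
#' @param inertia,cognitive,social Velocity-update coefficients (> 0).
#' @param max_iterations Iteration cap (>= 1).
#' @param stall_tolerance Objective improvement below which an iteration
#'   counts as stalled.
#' @param stall_iterations Consecutive stalled iterations triggering stop;
#'   `Inf` disables the early stop.
#' @param seed RNG seed for reproducible runs, or `NULL` to use the current
#'   RNG state.
#' @return An object of class `pso_settings`.
#' @export
pso_settings <- function(swarm_size = 30, inertia = 0.729,
                         cognitive = 1.49445, social = 1.49445,
                         max_iterations = 100, stall_tolerance = 1e-8,
                         stall_iterations = 20, seed = NULL) {
  if (swarm_size < 2) stop("'swarm_size' must be >= 2", call. = FALSE)
  if (max_iterations < 1) stop("'max_iterations' must be >= 1", call. = FALSE)
  if (inertia <= 0 || cognitive <= 0 || social <= 0)
    stop("PSO coefficients must be positive", call. = FALSE)
  structure(list(swarm_size = as.integer(swarm_size), inertia = inertia,
                 cognitive = cognitive, social = social,
                 max_iterations = as.integer(max_iterations),
                 stall_tolerance = stall_tolerance,
                 stall_iterations = stall_iterations, seed = seed),
            class = "pso_settings")
}

#' Minimize an objective by global-best particle swarm optimization
#'
#' Standard inertia-weight PSO: particles are initialized uniformly over
#' the box; each velocity is updated with a cognitive pull toward the
#' particle's personal best and a social pull toward the global best;
#' positions leaving the box are clamped to the violated bound and the
#' offending velocity component is zeroed. Objective values that are
#' non-finite (or raise an error) are treated as `+Inf`. The best value
#' trace is monotone non-increasing and the whole run is reproducible for
#' a given seed.
#'
#' @param objective Function mapping a position vector to a scalar.
#' @param space A [search_space()].
#' @param settings A [pso_settings()] object.
#' @return A list: `best_position` (named), `best_value`, `trace`
#'   (global-best value per iteration), `iterations`, `evaluations`.
#' @examples
#' sp <- search_space(rep(-5, 3), rep(5, 3))
#' pso_minimize(function(x) sum(x^2), sp, pso_settings(seed = 1))$best_value
#' @export
pso_minimize <- function(objective, space, settings = pso_settings()) {
  stopifnot(inherits(space, "search_space"), inherits(settings, "pso_settings"))
  if (!is.null(settings$seed)) set.seed(settings$seed)
  d <- length(space$lower)
  S <- settings$swarm_size
  lower <- space$lower; upper <- space$upper
  span <- upper - lower

  last_error <- NULL
  n_eval <- 0L
  eval_one <- function(x) {
    n_eval <<- n_eval + 1L
    v <- tryCatch(objective(x), error = function(e) { last_error <<- e; Inf })
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) Inf else v
  }

  pos <- matrix(stats::runif(S * d), S, d)
  pos <- sweep(sweep(pos, 2L, span, `*`), 2L, lower, `+`)
  vel <- matrix(stats::runif(S * d, -1, 1), S, d)
  vel <- sweep(vel, 2L, span, `*`)

  fit <- apply(pos, 1L, eval_one)
  if (all(!is.finite(fit)) && !is.null(last_error))
    stop("objective failed on every evaluation; last error: ",
         conditionMessage(last_error), call. = FALSE)
  pbest_pos <- pos
  pbest_val <- fit
  g <- which.min(pbest_val)
  gbest_pos <- pbest_pos[g, ]
  gbest_val <- pbest_val[g]

  trace <- numeric(settings$max_iterations)
  stalled <- 0L
  iters <- 0L
  for (it in seq_len(settings$max_iterations)) {
    r1 <- matrix(stats::runif(S * d), S, d)
    r2 <- matrix(stats::runif(S * d), S, d)
    vel <- settings$inertia * vel +
      settings$cognitive * r1 * (pbest_pos - pos) +
      settings$social * r2 * sweep(-pos, 2L, gbest_pos, `+`)
    pos <- pos + vel
    for (j in seq_len(d)) {
      low <- pos[, j] < lower[j]
      high <- pos[, j] > upper[j]
      pos[low, j] <- lower[j]; pos[high, j] <- upper[j]
      vel[low | high, j] <- 0
    }
    fit <- apply(pos, 1L, eval_one)
    better <- fit < pbest_val
    pbest_val[better] <- fit[better]
    pbest_pos[better, ] <- pos[better, , drop = FALSE]
    g <- which.min(pbest_val)
    improvement <- gbest_val - pbest_val[g]
    if (pbest_val[g] < gbest_val) {
      gbest_val <- pbest_val[g]
      gbest_pos <- pbest_pos[g, ]
    }
    trace[it] <- gbest_val
    iters <- it
    stalled <- if (is.finite(improvement) && improvement < settings$stall_tolerance)
      stalled + 1L else 0L
    if (stalled >= settings$stall_iterations) break
  }
  if (all(!is.finite(trace[seq_len(iters)])) && !is.null(last_error))
    stop("objective failed on every evaluation; last error: ",
         conditionMessage(last_error), call. = FALSE)
  names(gbest_pos) <- space$names
  list(best_position = gbest_pos, best_value = gbest_val,
       trace = trace[seq_len(iters)], iterations = iters, evaluations = n_eval)
}

#' Export a PSO best-value trace as CSV
#'
#' @param result A result from [pso_minimize()].
#' @param path File path; header `iteration,best_value`.
#' @export
write_pso_trace_csv <- function(result, path) {
  utils::write.csv(
    data.frame(iteration = seq_along(result$trace), best_value = result$trace),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
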