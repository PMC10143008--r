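# Independent oracles and fixture builders used across the suite.

# Forward-Euler integration of the batch ODE system with stop-at-depletion;
# deliberately ignorant of the closed-form solution.
euler_state <- function(params, init, t_end, h = 1e-4) {
  x <- init$x0; g <- init$g0; l <- init$l0
  n <- ceiling(t_end / h - 1e-12)
  for (k in seq_len(n)) {
    if (g <= 0) break
    step <- min(h, t_end - (k - 1) * h)
    dx <- params$mu * x
    x <- x + step * dx
    g <- g - step * dx / params$y_gx
    l <- l + step * dx / params$y_gl
    if (g < 0) g <- 0
  }
  c(biomass = x, glucose = g, lactate = l)
}

# High-accuracy ODE oracle: lsodar with a glucose-zero root that terminates
# growth; post-depletion values are the frozen root-time state.
ode_trajectory <- function(params, init, times, rtol = 1e-10, atol = 1e-12) {
  rhs <- function(t, y, p) {
    dx <- params$mu * y[1L]
    list(c(dx, -dx / params$y_gx, dx / params$y_gl))
  }
  rootf <- function(t, y, p) y[2L]
  tt <- sort(unique(c(0, times)))
  out <- as.data.frame(deSolve::lsodar(
    c(x = init$x0, g = init$g0, l = init$l0), tt, rhs, parms = NULL,
    rtol = rtol, atol = atol, rootfunc = rootf))
  last <- out[nrow(out), ]
  idx <- vapply(times, function(t0) {
    j <- which(abs(out$time - t0) < 1e-9)
    if (length(j)) j[1L] else NA_integer_
  }, 0L)
  x <- out$x[idx]; g <- out$g[idx]; l <- out$l[idx]
  after <- is.na(idx)  # times beyond the depletion root
  x[after] <- last$x; g[after] <- 0; l[after] <- last$l
  data.frame(time = times, biomass = x, glucose = pmax(g, 0), lactate = l)
}

# Ordinary least squares prediction via the normal equations (with a
# pseudoinverse for safety); brute-force oracle for full-rank PLS.
ols_predict <- function(X_train, y_train, X_new) {
  A <- cbind(1, X_train)
  coef <- qr.solve(A, y_train)
  drop(cbind(1, X_new) %*% coef)
}

# Random kinetic parameters inside the study's search bounds.
random_params <- function() {
  process_params(runif(1, 0.2, 0.9), runif(1, 2, 4), runif(1, 2, 4))
}

# Synthetic study with an analytically linear sensor: spectrum rows are
# exact affine functions of the state variables and the series is marked
# as already normalized, so the calibration pipeline consumes them as-is.
# All cultivations share g0, so every holdout's states lie in the affine
# hull of the calibration cultivations and linear prediction is exact.
linear_sensor_study <- function(true_params = process_params(0.54, 3.4, 2.5),
                                inits = list(initial_state(0.02, 1.21),
                                             initial_state(0.002, 1.21),
                                             initial_state(0.01, 1.21)),
                                times = seq(0, 15, by = 0.5),
                                n_channels = 40, seed = 99) {
  set.seed(seed)
  channels <- channel_grid()[seq_len(n_channels), ]
  load_x <- rnorm(n_channels); load_g <- rnorm(n_channels)
  load_l <- rnorm(n_channels); load_0 <- rnorm(n_channels)
  lapply(seq_along(inits), function(i) {
    traj <- simulate_batch(true_params, inits[[i]], times)
    intens <- outer(traj$biomass, load_x) + outer(traj$glucose, load_g) +
      outer(traj$lactate, load_l) + matrix(load_0, nrow(traj), n_channels,
                                           byrow = TRUE)
    series <- spectrum_series(sprintf("lin_%d", i), times, channels, intens)
    series$snv <- TRUE  # analytically normalized sensor
    cultivation(sprintf("lin_%d", i), inits[[i]], series,
                truth = list(params = true_params, trajectory = traj))
  })
}

# Leaner PSO settings for repeated-fit experiments.
lean_pso <- function(seed) {
  pso_settings(swarm_size = 20, max_iterations = 60, stall_iterations = 15,
               seed = seed)
}

mbc_test_config <- function(seed, ...) {
  mbc_config(pso = pso_settings(swarm_size = 15, max_iterations = 40,
                                stall_iterations = 10, seed = seed), ...)
}
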