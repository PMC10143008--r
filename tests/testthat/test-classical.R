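truth <- process_params(0.53, 3.33, 2.68)
inits <- list(initial_state(0.02, 1.21), initial_state(0.002, 1.21),
              initial_state(0.02, 0.76))

noise_free_datasets <- function(times = 0:15) {
  lapply(seq_along(inits), function(i) {
    tr <- simulate_batch(truth, inits[[i]], times)
    list(init = inits[[i]],
         offline = offline_dataset(paste0("c", i), tr$time, tr$biomass,
                                   tr$glucose, tr$lactate))
  })
}

test_that("fitness is zero at the generating parameters and positive elsewhere", {
  ds <- noise_free_datasets()
  fb <- fitness_classical(truth, ds)
  expect_equal(fb$se, 0, tolerance = 1e-12)
  expect_equal(fb$se, fb$normalized_g + fb$normalized_l + fb$normalized_x,
               tolerance = 1e-12)
  off <- fitness_classical(process_params(0.6, 3.33, 2.68), ds)
  expect_gt(off$se, 0)
})

test_that("glucose RMSE matches hand arithmetic", {
  # offline [1.21, 0.5, 0] vs simulated [1.21, 0.6, 0] -> sqrt(0.01/3)
  init <- initial_state(0.02, 1.21)
  times <- c(0, 5, 12)
  sim <- simulate_batch(truth, init, times)
  off_g <- sim$glucose + (c(1.21, 0.5, 0) - c(1.21, 0.6, 0))
  ds <- list(list(init = init,
                  offline = offline_dataset("c", times, sim$biomass, off_g,
                                            sim$lactate)))
  fb <- fitness_classical(truth, ds)
  expect_equal(fb$grmse, sqrt(0.01 / 3), tolerance = 1e-12)
  expect_equal(fb$lrmse, 0)
  expect_equal(fb$xrmse, 0)
})

test_that("the fitness is invariant to rescaling one variable's units", {
  set.seed(21)
  ds <- noise_free_datasets()
  # perturb so residuals are non-zero
  pert <- process_params(0.5, 3.1, 2.9)
  base <- fitness_classical(pert, ds)
  # express glucose in mg/L instead of g/L: offline values, initial glucose
  # and the biomass-on-glucose yield all change together
  ds_scaled <- lapply(ds, function(d) {
    d$offline$glucose <- d$offline$glucose * 1000
    d$init <- initial_state(d$init$x0, d$init$g0 * 1000, d$init$l0)
    d
  })
  pert_scaled <- process_params(pert$mu, pert$y_gx / 1000, pert$y_gl)
  scaled <- fitness_classical(pert_scaled, ds_scaled)
  expect_equal(scaled$se, base$se, tolerance = 1e-9)
})

test_that("missing offline entries are skipped and counted out", {
  ds <- noise_free_datasets()
  ds[[1]]$offline$glucose[c(2, 5)] <- NA
  fb <- fitness_classical(truth, ds)
  expect_equal(fb$se, 0, tolerance = 1e-12)
  expect_identical(unname(fb$n[["glucose"]]), 46L)
  expect_identical(unname(fb$n[["biomass"]]), 48L)
})

test_that("a variable with zero observed range is excluded with a warning", {
  init <- initial_state(0.02, 1.21)
  times <- c(0, 2, 4)
  sim <- simulate_batch(truth, init, times)
  ds <- list(list(init = init,
                  offline = offline_dataset("c", times, sim$biomass,
                                            sim$glucose, rep(0.5, 3))))
  expect_warning(fb <- fitness_classical(truth, ds), "zero observed range")
  expect_true(is.na(fb$normalized_l))
  expect_identical(fb$se, fb$normalized_g + fb$normalized_x)
})

test_that("noise-free offline data identify the generating parameters", {
  ds <- noise_free_datasets()
  fit <- fit_classical(ds, settings = pso_settings(swarm_size = 30,
                                                   max_iterations = 200,
                                                   stall_iterations = 40,
                                                   stall_tolerance = 1e-12,
                                                   seed = 5))
  expect_equal(fit$params$mu, truth$mu, tolerance = 1e-2)
  expect_equal(fit$params$y_gx, truth$y_gx, tolerance = 1e-2)
  expect_equal(fit$params$y_gl, truth$y_gl, tolerance = 1e-2)
})

test_that("bounds that exclude the truth pin the fit to the boundary", {
  ds <- noise_free_datasets()
  sp <- search_space(c(0.2, 2, 2), c(0.4, 4, 4), c("mu", "y_gx", "y_gl"))
  fit <- fit_classical(ds, space = sp, settings = lean_pso(6))
  expect_equal(fit$params$mu, 0.4, tolerance = 1e-6)
})

test_that("parameter recovery degrades monotonically with offline noise", {
  traj <- lapply(inits, function(init) simulate_batch(truth, init, 0:15))
  mu_err <- vapply(c(0, 0.02, 0.10), function(cv) {
    errs <- vapply(1:8, function(r) {
      ds <- lapply(seq_along(inits), function(i) {
        off <- generate_offline(traj[[i]], 0:15, noise_cv = cv,
                                seed = 5000 + 97 * r + i)
        list(init = inits[[i]], offline = off)
      })
      fit <- fit_classical(ds, settings = pso_settings(
        swarm_size = 15, max_iterations = 50, stall_iterations = 12,
        seed = 80 + r))
      abs(fit$params$mu - truth$mu)
    }, 0)
    median(errs)
  }, 0)
  expect_true(all(diff(mu_err) >= -1e-3))
})

test_that("fit_classical requires a 3-dimensional search space", {
  ds <- noise_free_datasets()
  expect_error(fit_classical(ds, space = search_space(0.2, 0.9)),
               "3 dimensions")
})

test_that("offline CSVs round-trip with missing cells", {
  off <- offline_dataset("c1", c(0, 1, 2), c(0.02, NA, 0.05),
                         c(1.21, 1.15, NA), c(0, 0.02, 0.05))
  path <- withr::local_tempfile(fileext = ".csv")
  write_offline_csv(off, path)
  back <- read_offline_csv(path, "c1")
  expect_identical(is.na(back$biomass), c(FALSE, TRUE, FALSE))
  expect_equal(back$glucose[1:2], c(1.21, 1.15))
})
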