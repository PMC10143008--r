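mu_true <- 0.54

test_that("the objective vanishes at the true growth rate for a linear sensor", {
  study <- linear_sensor_study()
  cfg <- mbc_test_config(seed = 1,
                         n_components = c(biomass = 2, glucose = 2, lactate = 2))
  se_true <- mbc_objective(mu_true, study, "lin_1", cfg)
  expect_lt(se_true, 1e-6)
  # and is strictly larger at any probed wrong growth rate
  mus <- seq(0.2, 0.9, length.out = 50)
  se_grid <- vapply(mus, mbc_objective, 0, cultivations = study,
                    holdout_id = "lin_1", config = cfg)
  expect_true(all(se_grid[abs(mus - mu_true) > 0.02] > se_true))
  expect_lt(abs(mus[which.min(se_grid)] - mu_true), diff(mus[1:2]) + 1e-9)
})

test_that("uninformative spectra score far worse than informative ones", {
  study <- linear_sensor_study()
  cfg <- mbc_test_config(seed = 1,
                         n_components = c(biomass = 2, glucose = 2, lactate = 2))
  mus <- seq(0.3, 0.8, length.out = 6)
  se_lin <- vapply(mus, mbc_objective, 0, cultivations = study,
                   holdout_id = "lin_2", config = cfg)
  se_lin_best <- min(vapply(c(mus, 0.54), mbc_objective, 0,
                            cultivations = study, holdout_id = "lin_2",
                            config = cfg))
  for (s in 1:10) {
    noise_study <- lapply(study, function(cv) {
      set.seed(s * 1000 + match(cv$id, vapply(study, `[[`, "", "id")))
      cv$spectra$intensities <- matrix(
        rnorm(length(cv$spectra$intensities)),
        nrow(cv$spectra$intensities))
      colnames(cv$spectra$intensities) <- cv$spectra$channels$name
      cv
    })
    se_noise <- vapply(mus, mbc_objective, 0, cultivations = noise_study,
                       holdout_id = "lin_2", config = cfg)
    # uninformative spectra never approach the informative optimum: at every
    # probed growth rate the noise SE exceeds 10x the best linear-case SE,
    # and no spurious near-zero optimum appears anywhere
    expect_true(all(se_noise > 10 * se_lin_best))
    expect_gt(min(se_noise), 1)
  }
})

test_that("a linear sensor closes the loop exactly: growth rate and predictions", {
  study <- linear_sensor_study()
  cfg <- mbc_test_config(seed = 2,
                         n_components = c(biomass = 2, glucose = 2, lactate = 2))
  res <- fit_mbc(study, cfg)
  expect_equal(unname(res$fold_mu), rep(mu_true, 3), tolerance = 5e-3)
  # models calibrated at the true growth rate reproduce the holdout states
  # exactly: the sensor is linear and the holdout lies in the calibration
  # states' affine hull
  params_true <- process_params(mu_true, cfg$y_gx_fixed, cfg$y_gl_fixed)
  hold <- study[[1]]
  X_cal <- rbind(study[[2]]$spectra$intensities, study[[3]]$spectra$intensities)
  sims <- lapply(study[2:3], function(cv)
    simulate_batch(params_true, cv$init, cv$spectra$times))
  models <- sapply(c("biomass", "glucose", "lactate"), function(v)
    fit_pls(X_cal, c(sims[[1]][[v]], sims[[2]][[v]]), 2, target_name = v),
    simplify = FALSE)
  pred <- predict_online(models, hold$spectra)
  sim_true <- simulate_batch(params_true, hold$init, hold$spectra$times)
  expect_identical(nrow(pred), length(hold$spectra$times))
  expect_equal(pred$biomass, sim_true$biomass, tolerance = 1e-6)
  expect_equal(pred$glucose, sim_true$glucose, tolerance = 1e-6)
  expect_equal(pred$lactate, sim_true$lactate, tolerance = 1e-6)
  # fold-refit models track the fold's own simulation closely
  for (f in seq_along(study)) {
    cv <- study[[f]]
    pred_f <- predict_online(res$fold_models[[cv$id]], cv$spectra)
    sim_f <- simulate_batch(process_params(res$fold_mu[[f]], cfg$y_gx_fixed,
                                           cfg$y_gl_fixed),
                            cv$init, cv$spectra$times)
    expect_equal(pred_f$biomass, sim_f$biomass, tolerance = 0.02)
  }
})

test_that("cross-validation accounting holds: each cultivation held out once", {
  study <- linear_sensor_study()
  cfg <- mbc_test_config(seed = 3,
                         n_components = c(biomass = 2, glucose = 2, lactate = 2))
  res <- fit_mbc(study, cfg)
  ids <- vapply(study, `[[`, "", "id")
  expect_identical(sort(res$fold_assignments), sort(ids))
  expect_identical(anyDuplicated(res$fold_assignments), 0L)
  # the holdout never contributes to its own calibration set: its fold's
  # models are trained on exactly the other cultivations' rows
  n_per <- vapply(study, function(cv) length(cv$spectra$times), 0L)
  for (f in seq_along(ids)) {
    m <- res$fold_models[[f]]$biomass
    expect_identical(nrow(m$scores), as.integer(sum(n_per) - n_per[f]))
  }
})

test_that("the reported optimum is consistent with its own trace and the fold mean", {
  study <- linear_sensor_study()
  cfg <- mbc_test_config(seed = 4,
                         n_components = c(biomass = 2, glucose = 2, lactate = 2))
  res <- fit_mbc(study, cfg)
  expect_equal(res$mu_opt, mean(res$fold_mu))
  for (f in seq_along(res$fold_assignments)) {
    se_at_opt <- mbc_objective(res$fold_mu[[f]], study,
                               res$fold_assignments[f], cfg)
    expect_lte(se_at_opt, min(res$se_trace[[f]]) + 1e-12)
  }
})

test_that("fewer than 3 cultivations is a precondition error", {
  study <- linear_sensor_study()[1:2]
  expect_error(fit_mbc(study, mbc_test_config(seed = 1)), "at least 3")
  expect_error(mbc_objective(0.5, study, "lin_1", mbc_test_config(seed = 1)),
               "at least 2 calibration")
})

test_that("model-based and classical calibrations agree on the same study", {
  study <- generate_study(study_config(seed = 31))
  res <- fit_mbc(study, mbc_test_config(seed = 31))
  ds <- lapply(study, function(cv) list(init = cv$init, offline = cv$offline))
  cl <- fit_classical(ds, settings = lean_pso(31))
  expect_lt(abs(cl$params$mu - res$mu_opt), 0.05)
})

test_that("online predictions flag negative concentration estimates", {
  set.seed(41)
  ch <- channel_grid()[1:10, ]
  X <- matrix(rnorm(30 * 10), 30, 10)
  models <- lapply(c(biomass = "biomass", glucose = "glucose",
                     lactate = "lactate"), function(v)
    fit_pls(X[1:20, ], rnorm(20, mean = 0.1), 2, target_name = v))
  series <- spectrum_series("c", seq(0.1, 3, by = 0.1), ch, X)
  series$snv <- TRUE
  pred <- predict_online(models, series)
  flags <- attr(pred, "negative_flags")
  expect_identical(dim(flags), c(30L, 3L))
  expect_identical(unname(flags[, 1]), unname(pred$biomass < 0))
  expect_true(any(flags))  # random models do stray negative
})
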