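#' Gaussian fluorophore specification for synthetic spectra
#'
#' A fluorophore contributes a 2D Gaussian peak on the excitation/emission
#' plane whose amplitude tracks one state variable (or stays constant),
#' plus an optional flat baseline.
#'
#' @param name Label.
#' @param ex_center,em_center Peak position, nm.
#' @param ex_width,em_width Gaussian widths, nm (> 0).
#' @param linked_state One of `"biomass"`, `"glucose"`, `"lactate"`,
#'   `"constant"`.
#' @param gain Intensity units per state unit (per 1 for `"constant"`).
#' @param baseline Flat intensity offset added to every channel.
#' @return An object of class `fluorophore`.
#' @export
fluorophore <- function(name, ex_center, em_center, ex_width, em_width,
                        linked_state, gain, baseline = 0) {
  linked_state <- match.arg(linked_state,
                            c("biomass", "glucose", "lactate", "constant"))
  if (ex_width <= 0 || em_width <= 0)
    stop("fluorophore widths must be positive", call. = FALSE)
  if (!is.finite(gain)) stop("'gain' must be finite", call. = FALSE)
  structure(list(name = name, ex_center = ex_center, em_center = em_center,
                 ex_width = ex_width, em_width = em_width,
                 linked_state = linked_state, gain = gain,
                 baseline = baseline),
            class = "fluorophore")
}

#' Default fluorophore set of the synthetic sensor
#'
#' Emulates the dominant signals a multi-wavelength fluorescence probe sees
#' in a cereal-substrate lactic-acid fermentation. The substrate itself
#' fluoresces strongly and constantly: a protein tryptophan-like peak
#' (ex 290 / em 350) and a broad background dominate every spectrum, so the
#' state-linked signals ride on a large structured baseline — which keeps
#' the SNV-normalized spectra close to affine in the state variables, as a
#' linear chemometric model assumes. On top of that: an NADH-like peak
#' (ex 340 / em 440) tracks biomass, and a riboflavin-like peak
#' (ex 450 / em 530) tracks glucose — flavins in the cereal substrate are
#' taken up by the bacteria alongside the sugar, so this signal decays
#' with the substrate. Lactate has no fluorophore of its own: like in the
#' real process it is inferred indirectly through its coupling with
#' biomass.
#'
#' @return A list of [fluorophore()] objects.
#' @export
default_fluorophores <- function() {
  list(
    fluorophore("trp_substrate", 290, 350, 25, 30, "constant", gain = 100),
    fluorophore("background", 370, 470, 80, 90, "constant", gain = 50,
                baseline = 2),
    fluorophore("nadh", 340, 440, 40, 40, "biomass", gain = 15),
    fluorophore("riboflavin", 450, 530, 30, 35, "glucose", gain = 25)
  )
}

#' Synthetic fluorescence spectra from a state trajectory
#'
#' Noise-free channel intensity at time t is
#' `sum_f gain_f * state_f(t) * exp(-(ex - ex_c)^2 / (2 ex_w^2))
#'  * exp(-(em - em_c)^2 / (2 em_w^2)) + sum_f baseline_f`,
#' where `state_f` is the linked state variable (1 for constant
#' fluorophores). Detector noise is multiplicative:
#' every intensity is scaled by `1 + e`, `e ~ N(0, noise_cv)`.
#'
#' @param trajectory A `state_trajectory` from [simulate_batch()].
#' @param channels A channel grid from [channel_grid()].
#' @param fluorophores List of [fluorophore()] objects.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param seed RNG seed; runs repeat bitwise for the same seed.
#' @param cultivation_id Label for the resulting series.
#' @return A `spectrum_series`.
#' @export
generate_spectra <- function(trajectory, channels,
                             fluorophores = default_fluorophores(),
                             noise_cv = 0.02, seed = 1,
                             cultivation_id = "synthetic") {
  if (nrow(channels) == 0L) stop("'channels' must be non-empty", call. = FALSE)
  if (noise_cv < 0) stop("'noise_cv' must be >= 0", call. = FALSE)
  n_t <- nrow(trajectory)
  intensities <- matrix(0, n_t, nrow(channels))
  for (fl in fluorophores) {
    shape <- exp(-(channels$ex_nm - fl$ex_center)^2 / (2 * fl$ex_width^2)) *
             exp(-(channels$em_nm - fl$em_center)^2 / (2 * fl$em_width^2))
    state <- if (fl$linked_state == "constant") rep(1, n_t)
             else trajectory[[fl$linked_state]]
    intensities <- intensities + fl$gain * outer(state, shape) + fl$baseline
  }
  if (noise_cv > 0) {
    set.seed(seed)
    intensities <- intensities *
      (1 + matrix(stats::rnorm(length(intensities), 0, noise_cv),
                  n_t, nrow(channels)))
  }
  spectrum_series(cultivation_id, trajectory$time, channels, intensities)
}

#' Synthetic offline reference measurements
#'
#' Draws noisy offline samples (plate counts, HPLC) from a trajectory:
#' each present value is perturbed multiplicatively by `1 + e`,
#' `e ~ N(0, noise_cv)`, then floored at 0.
#'
#' @param trajectory A `state_trajectory` containing all `sample_times`.
#' @param sample_times Offline sampling times, hours; must occur in
#'   `trajectory$time`.
#' @param noise_cv Coefficient of variation per variable per timepoint.
#' @param seed RNG seed.
#' @param cultivation_id Label.
#' @return An `offline_dataset`.
#' @export
generate_offline <- function(trajectory, sample_times, noise_cv = 0.05,
                             seed = 1, cultivation_id = "synthetic") {
  idx <- match(round(sample_times, 9), round(trajectory$time, 9))
  if (anyNA(idx))
    stop("every sample time must occur in the trajectory", call. = FALSE)
  if (noise_cv < 0) stop("'noise_cv' must be >= 0", call. = FALSE)
  set.seed(seed)
  vals <- lapply(.state_vars, function(v) {
    x <- trajectory[[v]][idx]
    if (noise_cv > 0) x <- x * (1 + stats::rnorm(length(x), 0, noise_cv))
    pmax(x, 0)
  })
  names(vals) <- .state_vars
  offline_dataset(cultivation_id, sample_times, vals$biomass, vals$glucose,
                  vals$lactate)
}

#' Configuration of a synthetic fermentation study
#'
#' Defaults emulate the study conditions the analysis assumes: three batch
#' cultivations with initial glucose/biomass of (1.21, 0.02), (1.21, 0.002)
#' and (0.76, 0.02), a 15 h horizon at 37 C, spectra every 0.25 h (61 per
#' run), offline samples every 1 h (16 per run), 2% spectral and 5% offline
#' multiplicative noise, and generating kinetics mu = 0.54 1/h with yields
#' 3.4 and 2.5 (1e8 CFU/g).
#'
#' @param true_params Generating [process_params()].
#' @param initial_states List of [initial_state()] objects (3 by default).
#' @param horizon Cultivation length, hours.
#' @param spectra_interval,offline_interval Sampling intervals, hours.
#' @param spectral_noise_cv,offline_noise_cv Noise levels (fractions).
#' @param fluorophores Fluorophore set for the synthetic sensor.
#' @param channels Channel grid.
#' @param seed Base RNG seed; all per-cultivation streams derive from it.
#' @return An object of class `study_config`.
#' @export
study_config <- function(true_params = process_params(0.54, 3.4, 2.5),
                         initial_states = list(
                           initial_state(0.02, 1.21),
                           initial_state(0.002, 1.21),
                           initial_state(0.02, 0.76)),
                         horizon = 15, spectra_interval = 0.25,
                         offline_interval = 1.0,
                         spectral_noise_cv = 0.02, offline_noise_cv = 0.05,
                         fluorophores = default_fluorophores(),
                         channels = channel_grid(), seed = 1) {
  stopifnot(inherits(true_params, "process_params"))
  if (horizon <= 0 || spectra_interval <= 0 || offline_interval <= 0)
    stop("horizon and intervals must be positive", call. = FALSE)
  if (spectral_noise_cv < 0 || offline_noise_cv < 0)
    stop("noise fractions must be >= 0", call. = FALSE)
  for (s in initial_states) stopifnot(inherits(s, "initial_state"))
  structure(list(true_params = true_params, initial_states = initial_states,
                 horizon = horizon, spectra_interval = spectra_interval,
                 offline_interval = offline_interval,
                 spectral_noise_cv = spectral_noise_cv,
                 offline_noise_cv = offline_noise_cv,
                 fluorophores = fluorophores, channels = channels,
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Generate a complete synthetic fermentation study
#'
#' One [cultivation()] per initial state, each carrying a spectrum series,
#' an offline dataset and the ground-truth record (generating parameters
#' and noise-free trajectory) for recovery experiments.
#'
#' @param config A [study_config()].
#' @return A list of [cultivation()] objects.
#' @examples
#' study <- generate_study(study_config(seed = 7))
#' length(study)                    # 3
#' length(study[[1]]$spectra$times) # 61
#' @export
generate_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  spectra_times <- seq(0, config$horizon, by = config$spectra_interval)
  offline_times <- seq(0, config$horizon, by = config$offline_interval)
  lapply(seq_along(config$initial_states), function(i) {
    id <- sprintf("cultivation_%d", i)
    init <- config$initial_states[[i]]
    traj <- simulate_batch(config$true_params, init,
                           sort(unique(c(spectra_times, offline_times))))
    traj_spec <- traj[match(round(spectra_times, 9), round(traj$time, 9)), ]
    spectra <- generate_spectra(
      traj_spec, config$channels, config$fluorophores,
      noise_cv = config$spectral_noise_cv,
      seed = (config$seed + 1009L * i) %% 2147483647L, cultivation_id = id)
    offline <- generate_offline(
      traj, offline_times, noise_cv = config$offline_noise_cv,
      seed = (config$seed + 2003L * i) %% 2147483647L, cultivation_id = id)
    cultivation(id, init, spectra, offline,
                truth = list(params = config$true_params,
                             trajectory = traj_spec))
  })
}
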