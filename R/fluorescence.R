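#' Excitation/emission channel grid with scattered-light removal
#'
#' Builds the ordered list of excitation/emission wavelength pairs of a
#' BioView-style 2D fluorescence sensor: excitation 270-550 nm, emission
#' 310-590 nm, both in 20 nm steps. Channels whose emission lies too close
#' to (or below) the excitation wavelength are dominated by scattered light
#' and are removed via a minimum Stokes offset `em - ex >= min_stokes`; the
#' default 40 nm offset retains exactly 120 of the 225 grid pairs.
#'
#' @param ex_min,ex_max Excitation range, nm.
#' @param em_min,em_max Emission range, nm.
#' @param step Grid step, nm; must divide both ranges.
#' @param min_stokes Minimum emission-minus-excitation offset in nm, or
#'   `NULL` for no scatter filter.
#' @return A data.frame with columns `ex_nm`, `em_nm` and `name`
#'   (`"ex{ex}em{em}"`), ordered excitation-major then emission ascending.
#' @examples
#' nrow(channel_grid())                    # 120
#' nrow(channel_grid(min_stokes = NULL))   # 225
#' @export
channel_grid <- function(ex_min = 270, ex_max = 550, em_min = 310,
                         em_max = 590, step = 20, min_stokes = 40) {
  if (step <= 0 || (ex_max - ex_min) %% step != 0 || (em_max - em_min) %% step != 0)
    stop("'step' must divide both the excitation and emission ranges",
         call. = FALSE)
  ex <- seq(ex_min, ex_max, by = step)
  em <- seq(em_min, em_max, by = step)
  grid <- expand.grid(em_nm = em, ex_nm = ex)[, c("ex_nm", "em_nm")]
  if (!is.null(min_stokes)) {
    if (min_stokes < 0) stop("'min_stokes' must be >= 0 or NULL", call. = FALSE)
    grid <- grid[grid$em_nm - grid$ex_nm >= min_stokes, , drop = FALSE]
  }
  grid$name <- sprintf("ex%dem%d", grid$ex_nm, grid$em_nm)
  rownames(grid) <- NULL
  grid
}

#' Time series of 2D fluorescence spectra for one cultivation
#'
#' @param cultivation_id Label of the cultivation.
#' @param times Timestamps in hours, strictly increasing.
#' @param channels A channel grid from [channel_grid()].
#' @param intensities Numeric matrix, rows = timestamps, columns = channels,
#'   arbitrary fluorescence units; finite values only.
#' @return An object of class `spectrum_series`.
#' @export
spectrum_series <- function(cultivation_id, times, channels, intensities) {
  intensities <- as.matrix(intensities)
  if (!is.numeric(times) || is.unsorted(times, strictly = TRUE))
    stop("'times' must be strictly increasing", call. = FALSE)
  if (nrow(intensities) != length(times) || ncol(intensities) != nrow(channels))
    stop(sprintf("intensity matrix must be %d x %d (times x channels), got %d x %d",
                 length(times), nrow(channels),
                 nrow(intensities), ncol(intensities)), call. = FALSE)
  if (!all(is.finite(intensities)))
    stop("intensities must be finite", call. = FALSE)
  colnames(intensities) <- channels$name
  structure(
    list(cultivation_id = as.character(cultivation_id), times = times,
         channels = channels, intensities = intensities, snv = FALSE),
    class = "spectrum_series"
  )
}

#' @export
print.spectrum_series <- function(x, ...) {
  cat(sprintf("Spectrum series '%s': %d spectra x %d channels, %.2f-%.2f h%s\n",
              x$cultivation_id, length(x$times), nrow(x$channels),
              min(x$times), max(x$times),
              if (isTRUE(x$snv)) " (SNV-normalized)" else ""))
  invisible(x)
}

#' Standard normal variate (SNV) normalization
#'
#' Row-wise normalization of spectra: each spectrum (row) is centered to
#' mean 0 and scaled to sample standard deviation 1 (denominator n-1).
#' SNV removes multiplicative gain and additive offset differences between
#' spectra and is idempotent. A spectrally flat row has no information and
#' zero spread; it raises an error naming the offending timestamp.
#'
#' @param x A `spectrum_series` or a numeric matrix (rows = spectra).
#' @return Same type as the input, normalized; a `spectrum_series` is marked
#'   so a second application is skipped by downstream code.
#' @examples
#' snv_normalize(matrix(c(1, 2, 3), nrow = 1))  # -1 0 1
#' @export
snv_normalize <- function(x) {
  if (inherits(x, "spectrum_series")) {
    x$intensities <- .snv_matrix(x$intensities, x$times)
    x$snv <- TRUE
    return(x)
  }
  .snv_matrix(as.matrix(x), times = NULL)
}

.snv_matrix <- function(m, times = NULL) {
  if (ncol(m) < 2L) stop("SNV needs at least 2 channels per spectrum", call. = FALSE)
  mu <- rowMeans(m)
  s <- sqrt(rowSums((m - mu)^2) / (ncol(m) - 1L))
  bad <- which(s <= .Machine$double.eps * pmax(abs(mu), 1))
  if (length(bad)) {
    where <- if (is.null(times)) sprintf("row %d", bad[1L])
             else sprintf("t = %g h", times[bad[1L]])
    stop("degenerate spectrum with zero spread at ", where, call. = FALSE)
  }
  out <- (m - mu) / s
  dimnames(out) <- dimnames(m)
  out
}

#' Align spectra with simulated state variables
#'
#' Pairs every spectrum of a cultivation with the model state (biomass,
#' glucose, lactate) at exactly the same timestamp. The process model is
#' closed-form, so no interpolation is involved: states are evaluated
#' directly at the spectral timestamps.
#'
#' @param series A `spectrum_series`.
#' @param params A [process_params()] object.
#' @param init The cultivation's [initial_state()].
#' @return A list with elements `times`, `intensities` (unchanged spectra)
#'   and `states` (a `state_trajectory` at the spectral timestamps); one
#'   state row per spectrum.
#' @export
align_to_model <- function(series, params, init) {
  stopifnot(inherits(series, "spectrum_series"))
  states <- simulate_batch(params, init, series$times)
  list(times = series$times, intensities = series$intensities, states = states)
}

#' Write / read a spectrum series as CSV
#'
#' Dialect: header `time_h,ex270em310,...` with one channel column per
#' grid pair, one row per timestamp; one file per cultivation.
#'
#' @param series A `spectrum_series`.
#' @param path File path.
#' @param cultivation_id Label to attach on read.
#' @return `read_spectra_csv()` returns a `spectrum_series`.
#' @export
write_spectra_csv <- function(series, path) {
  stopifnot(inherits(series, "spectrum_series"))
  out <- data.frame(time_h = series$times, series$intensities,
                    check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path, cultivation_id = basename(path)) {
  raw <- utils::read.csv(path, check.names = FALSE)
  if (names(raw)[1L] != "time_h")
    stop("spectra CSV must start with a 'time_h' column", call. = FALSE)
  chan_names <- names(raw)[-1L]
  m <- regmatches(chan_names, regexec("^ex([0-9]+)em([0-9]+)$", chan_names))
  if (any(lengths(m) != 3L))
    stop("channel columns must be named 'ex{ex}em{em}'", call. = FALSE)
  channels <- data.frame(
    ex_nm = as.integer(vapply(m, `[`, "", 2L)),
    em_nm = as.integer(vapply(m, `[`, "", 3L)),
    name = chan_names
  )
  spectrum_series(cultivation_id, raw$time_h, channels,
                  as.matrix(raw[, -1L, drop = FALSE]))
}
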