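#' Fit a single-response PLS regression model (NIPALS)
#'
#' Partial least squares regression of one state variable on a spectrum
#' matrix, by the NIPALS algorithm with deflation of the predictor matrix
#' only. Predictors and response are centered; neither is variance-scaled
#' (SNV already row-normalizes the spectra, and the response is univariate).
#' The extracted weights, loadings and y-loadings are composed into a single
#' regression vector so that prediction is a linear map plus intercept.
#'
#' With a univariate response the NIPALS inner loop converges in a single
#' pass per component; the loop is still run to the stated tolerance
#' (1e-10, at most 500 iterations) for form's sake. If the response
#' residual becomes numerically orthogonal to the deflated predictors
#' before the requested number of components is reached, the component
#' count is reduced with a warning.
#'
#' @param predictors Numeric matrix, samples x channels; no missing values.
#' @param response Numeric vector, one value per sample.
#' @param n_components Number of latent components, between 1 and
#'   `min(n_samples - 1, n_channels)`.
#' @param target_name Which state variable the model predicts
#'   (free-form label; `"biomass"`, `"glucose"` or `"lactate"` in this
#'   package's pipelines).
#' @return An object of class `pls_model` with fields `coefficients`,
#'   `intercept`, `predictor_center`, `response_center`, `response_scale`,
#'   `weights`, `x_loadings`, `y_loadings`, `scores` (training scores),
#'   `n_components`, `channel_names`, `target_name`.
#' @examples
#' X <- matrix(rnorm(60), 10, 6)
#' y <- X %*% rnorm(6) + 1
#' m <- fit_pls(X, y, n_components = 3)
#' predict_pls(m, X)
#' @export
fit_pls <- function(predictors, response, n_components,
                    target_name = "response") {
  X <- as.matrix(predictors)
  y <- as.numeric(response)
  n <- nrow(X); p <- ncol(X)
  if (n < 2L) stop("PLS needs at least 2 samples", call. = FALSE)
  if (length(y) != n) stop("response length must match rows of predictors",
                           call. = FALSE)
  if (anyNA(X) || anyNA(y)) stop("missing values are not allowed", call. = FALSE)
  max_comp <- min(n - 1L, p)
  if (n_components < 1L || n_components > max_comp)
    stop(sprintf("'n_components' must be in [1, %d]", max_comp), call. = FALSE)

  x_center <- colMeans(X)
  y_center <- mean(y)
  E <- sweep(X, 2L, x_center)
  f <- y - y_center
  yscale <- sqrt(sum(f^2))

  W <- matrix(0, p, n_components)
  P <- matrix(0, p, n_components)
  Tm <- matrix(0, n, n_components)
  q <- numeric(n_components)
  used <- 0L
  for (a in seq_len(n_components)) {
    w <- drop(crossprod(E, f))
    for (iter in seq_len(500L)) {
      wn <- sqrt(sum(w^2))
      if (wn <= 1e-12 * max(yscale, 1)) break
      w <- w / wn
      tvec <- drop(E %*% w)
      # univariate response: the updated weight is colinear with the old one
      w_new <- drop(crossprod(E, f))
      if (sqrt(sum((w_new / sqrt(sum(w_new^2)) - w)^2)) < 1e-10 ||
          sqrt(sum(w_new^2)) <= 1e-12 * max(yscale, 1)) break
      w <- w_new
    }
    wn <- sqrt(sum(w^2))
    if (wn <= 1e-12 * max(yscale, 1)) break
    w <- w / wn
    tvec <- drop(E %*% w)
    tt <- sum(tvec^2)
    if (tt <= .Machine$double.eps * n) break
    pvec <- drop(crossprod(E, tvec)) / tt
    qa <- sum(f * tvec) / tt
    E <- E - tcrossprod(tvec, pvec)
    f <- f - qa * tvec
    used <- a
    W[, a] <- w; P[, a] <- pvec; Tm[, a] <- tvec; q[a] <- qa
  }
  if (used < n_components) {
    warning(sprintf("response exhausted after %d component(s); reducing from %d",
                    used, n_components))
  }
  if (used == 0L) {
    coefs <- numeric(p)
  } else {
    W <- W[, seq_len(used), drop = FALSE]
    P <- P[, seq_len(used), drop = FALSE]
    Tm <- Tm[, seq_len(used), drop = FALSE]
    q <- q[seq_len(used)]
    coefs <- drop(W %*% solve(crossprod(P, W), q))
  }
  structure(
    list(coefficients = coefs,
         intercept = y_center - sum(x_center * coefs),
         predictor_center = x_center,
         response_center = y_center,
         response_scale = 1,
         weights = if (used) W else matrix(0, p, 0L),
         x_loadings = if (used) P else matrix(0, p, 0L),
         y_loadings = if (used) q else numeric(0),
         scores = if (used) Tm else matrix(0, n, 0L),
         n_components = used,
         channel_names = colnames(X),
         target_name = target_name),
    class = "pls_model"
  )
}

#' Predict from a fitted PLS model
#'
#' @param model A `pls_model` from [fit_pls()].
#' @param predictors Matrix with the same channels (columns) as training.
#' @return Numeric vector of predictions, one per row.
#' @export
predict_pls <- function(model, predictors) {
  stopifnot(inherits(model, "pls_model"))
  X <- as.matrix(predictors)
  if (ncol(X) != length(model$coefficients))
    stop(sprintf("channel mismatch: model trained on %d channels, given %d",
                 length(model$coefficients), ncol(X)), call. = FALSE)
  if (!is.null(model$channel_names) && !is.null(colnames(X)) &&
      !identical(colnames(X), model$channel_names))
    stop("channel mismatch: prediction grid [", colnames(X)[1L], "...] differs ",
         "from training grid [", model$channel_names[1L], "...]", call. = FALSE)
  drop(X %*% model$coefficients) * model$response_scale + model$intercept
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("PLS model for %s: %d component(s), %d channels\n",
              x$target_name, x$n_components, length(x$coefficients)))
  invisible(x)
}

#' Serialize / restore a PLS model as JSON
#'
#' Flat, human-inspectable JSON document holding the channel names, centers,
#' component count and coefficient vector.
#'
#' @param model A `pls_model`.
#' @param path File path.
#' @return `read_pls_model()` returns the restored `pls_model`.
#' @export
write_pls_model <- function(model, path) {
  stopifnot(inherits(model, "pls_model"))
  doc <- list(
    target_name = model$target_name,
    n_components = model$n_components,
    channel_names = model$channel_names,
    predictor_center = unname(model$predictor_center),
    response_center = model$response_center,
    response_scale = model$response_scale,
    intercept = model$intercept,
    coefficients = unname(model$coefficients),
    weights = model$weights,
    x_loadings = model$x_loadings,
    y_loadings = model$y_loadings
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pls_model
#' @export
read_pls_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  coefs <- as.numeric(doc$coefficients)
  structure(
    list(coefficients = coefs,
         intercept = doc$intercept,
         predictor_center = as.numeric(doc$predictor_center),
         response_center = doc$response_center,
         response_scale = doc$response_scale,
         weights = as.matrix(doc$weights),
         x_loadings = as.matrix(doc$x_loadings),
         y_loadings = as.numeric(doc$y_loadings),
         scores = NULL,
         n_components = doc$n_components,
         channel_names = doc$channel_names,
         target_name = doc$target_name),
    class = "pls_model"
  )
}
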