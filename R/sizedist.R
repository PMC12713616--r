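#' Evaluate a composite multimodal density
#'
#' Sum of K unimodal component curves on the microplastic size domain
#' \[0, 5\] mm. Gaussian components are amplitude-parameterized,
#' `A exp(-(x - mu)^2 / (2 s^2))`; lognormal components use
#' `A exp(-(log x - mu)^2 / (2 s^2))` for x > 0.
#'
#' @param x sizes in mm.
#' @param locations,scales,amplitudes per-component parameter vectors.
#' @param family `"gaussian"` or `"lognormal"`.
#' @return density values at `x`.
#' @export
mixture_density <- function(x, locations, scales, amplitudes,
                            family = c("gaussian", "lognormal")) {
  family <- match.arg(family)
  out <- numeric(length(x))
  for (k in seq_along(locations)) {
    out <- out + component_density(x, locations[k], scales[k], amplitudes[k], family)
  }
  out
}

component_density <- function(x, mu, s, A, family) {
  if (family == "gaussian") A * exp(-(x - mu)^2 / (2 * s^2))
  else ifelse(x > 0, A * exp(-(log(pmax(x, .Machine$double.xmin)) - mu)^2 / (2 * s^2)), 0)
}

# local maxima of a sampled curve (boundary points included)
pick_peaks <- function(x, y, k) {
  n <- length(y)
  is_max <- c(y[1] > y[2], y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n],
              y[n] > y[n - 1])
  idx <- which(is_max)
  idx <- idx[order(-y[idx])]
  x[utils::head(idx, k)]
}

#' Fit a K-curve composite size-distribution envelope
#'
#' Nonlinear least squares (Levenberg-Marquardt through minpack.lm) of a
#' K-component composite envelope to a sampled particle-size density on
#' \[0, 5\] mm. The objective is multimodal, so the fit is multi-start: one
#' start seeded from the data's own local maxima plus `n_starts` random
#' initializations; the lowest-WSSR converged solution wins.
#'
#' @param samples data frame (or 2-column matrix) with sizes (mm) and
#'   densities.
#' @param K number of components (default 4).
#' @param family `"gaussian"` (default) or `"lognormal"`.
#' @param seed integer seed for the random starts.
#' @param n_starts random initializations (default 20).
#' @param weights per-point weights of the weighted sum of squared residuals
#'   (default 1).
#' @return object of class `hs_sizemix`: list with `K`, `family`,
#'   `components` (data frame `location`, `scale`, `amplitude`, `peak`,
#'   `fraction`), `WSSR`, `R2`, `df`, and `n_points`. Fractions are each
#'   component's integrated share over \[0, 5\] mm and sum to 1.
#' @export
fit_mixture <- function(samples, K = 4, family = c("gaussian", "lognormal"),
                        seed = 1L, n_starts = 20, weights = NULL) {
  family <- match.arg(family)
  samples <- as.data.frame(samples)
  names(samples)[1:2] <- c("size_mm", "density")
  x <- samples$size_mm; y <- samples$density
  if (any(x < 0) || any(x > 5)) hs_validation_error("sizes must lie in [0, 5] mm")
  if (any(y < 0)) hs_validation_error("densities must be nonnegative")
  if (length(x) < 3 * K + 1)
    hs_validation_error(sprintf("need at least %d points for K = %d", 3 * K + 1, K))
  w <- if (is.null(weights)) rep(1, length(x)) else weights
  sw <- sqrt(w)

  resid_fn <- function(par) {
    mu <- par[1:K]; s <- par[K + 1:K]; A <- par[2 * K + 1:K]
    sw * (y - mixture_density(x, mu, s, A, family))
  }
  lower <- c(rep(if (family == "gaussian") 0 else -10, K), rep(1e-4, K), rep(0, K))
  upper <- c(rep(if (family == "gaussian") 5 else log(5), K), rep(10, K), rep(Inf, K))

  set.seed(seed)
  ymax <- max(y)
  starts <- list()
  pk <- pick_peaks(x, y, K)
  if (length(pk) < K) pk <- c(pk, runif(K - length(pk), 0, 5))
  mu0 <- if (family == "gaussian") pk else log(pmax(pk, 1e-3))
  starts[[1]] <- c(mu0, rep(diff(range(x)) / (4 * K), K), rep(ymax / 2, K))
  for (i in seq_len(n_starts)) {
    mu <- if (family == "gaussian") sort(runif(K, 0, 5)) else sort(runif(K, -4, log(5)))
    starts[[i + 1]] <- c(mu, runif(K, 0.02, 1), runif(K, 0.05, 1) * ymax)
  }

  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = lower, upper = upper, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 500,
                                                              ftol = 1e-14,
                                                              ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit) || fit$info %in% c(0, 5, 9)) next
    wssr <- sum(resid_fn(fit$par)^2)
    if (is.null(best) || wssr < best$wssr) best <- list(par = fit$par, wssr = wssr)
  }
  if (is.null(best)) hs_compute_error("mixture fit failed to converge from any start")

  mu <- best$par[1:K]; s <- best$par[K + 1:K]; A <- best$par[2 * K + 1:K]
  ord <- order(mu)
  mu <- mu[ord]; s <- s[ord]; A <- A[ord]
  peaks <- if (family == "gaussian") mu else pmin(pmax(exp(mu - s^2), 0), 5)
  model <- structure(list(K = K, family = family,
                          components = data.frame(location = mu, scale = s,
                                                  amplitude = A, peak = peaks),
                          n_points = length(x)),
                     class = "hs_sizemix")
  model$components$fraction <- integrated_fractions(model)
  gof <- goodness(model, samples, weights = w)
  model$WSSR <- gof[["WSSR"]]; model$R2 <- gof[["R2"]]; model$df <- gof[["df"]]
  model
}

#' @export
predict.hs_sizemix <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) newdata[[1]] else newdata
  mixture_density(x, object$components$location, object$components$scale,
                  object$components$amplitude, object$family)
}

#' Integrated modal fractions
#'
#' Each component's quadrature over \[0, 5\] mm divided by the total mass;
#' the fractions sum to 1.
#'
#' @param model an `hs_sizemix` fit.
#' @return numeric vector of per-component fractions.
#' @export
integrated_fractions <- function(model) {
  cm <- model$components
  ints <- vapply(seq_len(nrow(cm)), function(k) {
    stats::integrate(component_density, 0, 5, mu = cm$location[k],
                     s = cm$scale[k], A = cm$amplitude[k],
                     family = model$family,
                     rel.tol = 1e-10, subdivisions = 500L)$value
  }, numeric(1))
  tot <- sum(ints)
  if (tot <= 0) hs_compute_error("zero total integrated mass")
  ints / tot
}

#' Goodness of fit of a size mixture
#'
#' @param model an `hs_sizemix` fit.
#' @param samples the data the model was fitted to.
#' @param weights WSSR weights (default 1).
#' @return named vector `WSSR` (weighted sum of squared residuals), `R2`
#'   (1 - SSR/SST), `df` (points minus free parameters, 3 per component).
#' @export
goodness <- function(model, samples, weights = NULL) {
  samples <- as.data.frame(samples)
  names(samples)[1:2] <- c("size_mm", "density")
  n <- nrow(samples)
  p <- 3 * model$K
  if (n <= p) hs_validation_error("more free parameters than data points")
  w <- if (is.null(weights)) rep(1, n) else weights
  pred <- predict(model, samples$size_mm)
  res <- samples$density - pred
  ssr <- sum(res^2)
  sst <- sum((samples$density - mean(samples$density))^2)
  c(WSSR = sum(w * res^2), R2 = 1 - ssr / sst, df = n - p)
}

#' Write a fitted size mixture as a JSON report
#'
#' @param model an `hs_sizemix` fit.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sizemix <- function(model, path) {
  jsonlite::write_json(list(K = model$K, family = model$family,
                            components = model$components,
                            WSSR = model$WSSR, R2 = model$R2, df = model$df),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
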