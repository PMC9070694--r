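#' Scattering dataset
#'
#' A one-dimensional curve: abscissa (wave-vector transfer in 1/Angstrom,
#' exit angle in degrees, or detector pixel index), observed intensity, and an
#' optional per-point error. The observation scale declares whether residuals
#' are formed on the measured intensity or on its natural logarithm (the usual
#' choice for scattering curves spanning decades).
#'
#' @param abscissa Numeric vector; sorted ascending (a warning is issued if
#'   sorting was needed; duplicate abscissa values are averaged).
#' @param observed Observed intensities, same length.
#' @param error Optional per-point standard deviations.
#' @param scale `"log"` or `"linear"`.
#' @return A tibble of class `scattering_data` with columns `abscissa`,
#'   `observed` (and `error`), and an `obs_scale` attribute.
#' @export
scattering_data <- function(abscissa, observed, error = NULL,
                            scale = c("log", "linear")) {
  scale <- match.arg(scale)
  if (length(abscissa) != length(observed))
    stop("abscissa and observed must have equal length")
  df <- tibble::tibble(abscissa = as.numeric(abscissa),
                       observed = as.numeric(observed))
  if (!is.null(error)) df$error <- rep_len(as.numeric(error), nrow(df))
  if (is.unsorted(df$abscissa)) {
    warning("abscissa was not increasing; rows sorted")
    df <- dplyr::arrange(df, .data$abscissa)
  }
  if (anyDuplicated(df$abscissa)) {
    warning("duplicate abscissa values averaged")
    df <- dplyr::summarise(dplyr::group_by(df, .data$abscissa),
                           dplyr::across(dplyr::everything(), mean),
                           .groups = "drop")
  }
  if (scale == "log" && any(df$observed <= 0))
    stop("log observation scale requires positive observations")
  attr(df, "obs_scale") <- scale
  class(df) <- c("scattering_data", class(df))
  df
}

obs_scale <- function(data) attr(data, "obs_scale") %||% "log"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Gaussian residual log-likelihood
#'
#' Independent, identically distributed Gaussian residuals between the data
#' and the forward-model prediction, on the dataset's observation scale:
#' `sum_j [ -(y_j - f_j)^2 / (2 sigma2) - log(2 pi sigma2) / 2 ]`. The
#' residual variance is an unknown parameter (`sigma2` element of `params`).
#' A non-finite model prediction yields `-Inf` (certain rejection).
#'
#' @param params Named physical-scale parameter vector including `sigma2`.
#' @param model A forward model (see [saxs_model()], [refl_model()],
#'   [xwfh_model()]), i.e. anything with a `predict` closure.
#' @param data A [scattering_data()].
#' @param weights Optional per-point standard deviations (relative weights);
#'   defaults to the identical-error treatment (or the data's `error` column
#'   if present and `weights = "data"`).
#' @export
log_likelihood <- function(params, model, data, weights = NULL) {
  sigma2 <- params[["sigma2"]]
  if (!is.finite(sigma2) || sigma2 <= 0) return(-Inf)
  f <- model$predict(params, data$abscissa)
  if (any(!is.finite(f))) return(-Inf)
  y <- data$observed
  if (obs_scale(data) == "log") {
    if (any(f <= 0)) return(-Inf)
    y <- log(y); f <- log(f)
  }
  w2 <- if (identical(weights, "data") && !is.null(data$error)) data$error^2
        else if (is.numeric(weights)) rep_len(weights, length(y))^2
        else rep(1, length(y))
  r2 <- (y - f)^2 / w2
  -sum(r2) / (2 * sigma2) - 0.5 * sum(log(2 * pi * sigma2 * w2))
}

#' Central-difference gradient
#'
#' Component-wise central differences `(U(z + h e_i) - U(z - h e_i)) / (2 h)`
#' with step `h_i = max(1e-5, 1e-5 |z_i|)` by default. If one probe is
#' non-finite a one-sided difference is used; if both are, an error is
#' raised.
#'
#' @param U Scalar function of a numeric vector.
#' @param z Evaluation point.
#' @param h Step size(s); recycled.
#' @param U_z Optional precomputed `U(z)` (used by the one-sided fallback).
#' @export
numerical_gradient <- function(U, z, h = NULL, U_z = NULL) {
  n <- length(z)
  if (is.null(h)) h <- pmax(1e-5, 1e-5 * abs(z)) else h <- rep_len(h, n)
  g <- numeric(n)
  for (i in seq_len(n)) {
    zp <- z; zp[i] <- z[i] + h[i]
    zm <- z; zm[i] <- z[i] - h[i]
    up <- U(zp); um <- U(zm)
    if (is.finite(up) && is.finite(um)) {
      g[i] <- (up - um) / (2 * h[i])
    } else {
      u0 <- if (is.null(U_z)) U(z) else U_z
      if (is.finite(up)) g[i] <- (up - u0) / h[i]
      else if (is.finite(um)) g[i] <- (u0 - um) / h[i]
      else stop("gradient probes non-finite on both sides of coordinate ", i)
    }
  }
  g
}

#' Generic target density
#'
#' The contract consumed by every sampling kernel: a potential `U(z)` on the
#' unconstrained sampling scale and its gradient. If no gradient is supplied,
#' central differences are used.
#'
#' @param U Potential function (negative log density, sampling scale).
#' @param grad Gradient function; `NULL` for numerical differentiation.
#' @param n_params Dimension.
#' @param param_names Parameter names (defaults to `x1..xN`).
#' @param transform Optional [param_transform()] used when back-transforming
#'   draws.
#' @export
target_density <- function(U, grad = NULL, n_params,
                           param_names = paste0("x", seq_len(n_params)),
                           transform = NULL) {
  if (is.null(grad)) grad <- function(z) numerical_gradient(U, z)
  structure(list(U = U, grad = grad, n_params = n_params,
                 param_names = param_names, transform = transform),
            class = "target_density")
}

#' Potential energy with change-of-variables correction
#'
#' `U(z) = -logL(untransform(z)) - log|Jacobian|`: the potential of the
#' Hamiltonian system is the negative log probability density, expressed on
#' the unconstrained sampling scale. The Jacobian term makes the density of
#' the transformed variable integrate correctly, so the implied prior is flat
#' on the physical scale and the sampled posterior is proportional to the
#' likelihood there.
#'
#' @param z Sampling-scale parameter vector.
#' @param model,data As in [log_likelihood()].
#' @param transform A [param_transform()] covering all entries of `z`.
#' @export
potential_energy <- function(z, model, data, transform) {
  phys <- to_physical(z, transform)
  names(phys) <- transform$name
  ll <- log_likelihood(phys, model, data)
  if (!is.finite(ll)) return(Inf)
  -ll - transform_log_jacobian(z, transform)
}

#' Build the target density for a forward model and dataset
#'
#' Ties a forward model and a dataset into the potential sampled by
#' [run_chain()]: Gaussian residual likelihood with unknown variance,
#' parameter transforms to the unconstrained scale, and gradients by central
#' differences. The residual-variance coordinate is differentiated
#' analytically when (as by default) it is log-transformed; curve parameters
#' are differentiated by finite differences on the potential, re-evaluating
#' the forward model per probe.
#'
#' @param model A forward model object.
#' @param data A [scattering_data()].
#' @param transform A [param_transform()] for the free parameters (model
#'   defaults when `NULL`); must contain a `sigma2` row.
#' @param fixed Named vector of parameters held fixed at the given physical
#'   values (excluded from sampling).
#' @return A [target_density()] whose `curve(z)` element evaluates the model
#'   prediction, used for credible bands.
#' @export
scattering_target <- function(model, data, transform = NULL, fixed = NULL) {
  if (is.null(transform)) transform <- model_transforms(model)
  if (!is.null(fixed))
    transform <- transform[!(transform$name %in% names(fixed)), ]
  if (!"sigma2" %in% transform$name)
    stop("transform must include a sigma2 row (residual variance)")
  free <- transform$name
  n <- length(free)
  y <- data$observed
  if (obs_scale(data) == "log") y <- log(y)
  npt <- length(y)

  assemble <- function(z) {
    phys <- to_physical(z, transform)
    names(phys) <- free
    if (!is.null(fixed)) phys <- c(phys, fixed)
    phys
  }
  curve_fun <- function(z) model$predict(assemble(z), data$abscissa)
  resid_of <- function(z) {
    f <- curve_fun(z)
    if (any(!is.finite(f))) return(NULL)
    if (obs_scale(data) == "log") {
      if (any(f <= 0)) return(NULL)
      f <- log(f)
    }
    f - y
  }
  ssr_of <- function(z) {
    r <- resid_of(z)
    if (is.null(r)) Inf else sum(r^2)
  }
  U <- function(z) {
    phys <- assemble(z)
    s2 <- phys[["sigma2"]]
    ssr <- ssr_of(z)
    if (!is.finite(ssr) || s2 <= 0) return(Inf)
    0.5 * npt * log(2 * pi * s2) + ssr / (2 * s2) -
      transform_log_jacobian(z, transform)
  }
  i_s2 <- match("sigma2", free)
  s2_is_log <- transform$kind[i_s2] == "log"
  # a purely multiplicative intensity scale sampled on the log scale shifts
  # the log curve uniformly, so its gradient is available in closed form
  i_I0 <- match("I0", free)
  I0_analytic <- isTRUE(model$multiplicative_scale) &&
    obs_scale(data) == "log" && !is.na(i_I0) &&
    transform$kind[i_I0] == "log"
  grad <- function(z) {
    g <- numeric(n)
    r0 <- resid_of(z)
    ssr0 <- if (is.null(r0)) Inf else sum(r0^2)
    s2 <- to_physical(z, transform)[i_s2]
    for (i in seq_len(n)) {
      if (i == i_s2 && s2_is_log) {
        # d/dz [ n/2 log(2 pi e^z) + SSR e^-z / 2 - z ]
        g[i] <- npt / 2 - ssr0 / (2 * s2) - 1
      } else if (I0_analytic && i == i_I0 && !is.null(r0)) {
        g[i] <- sum(r0) / s2 - 1
      } else {
        h <- max(1e-5, 1e-5 * abs(z[i]))
        zp <- z; zp[i] <- z[i] + h
        zm <- z; zm[i] <- z[i] - h
        up <- U(zp); um <- U(zm)
        if (is.finite(up) && is.finite(um)) g[i] <- (up - um) / (2 * h)
        else if (is.finite(up)) g[i] <- (up - U(z)) / h
        else if (is.finite(um)) g[i] <- (U(z) - um) / h
        else g[i] <- NaN
      }
    }
    g
  }
  out <- target_density(U, grad, n, free, transform)
  out$curve <- curve_fun
  out$assemble <- assemble
  out$model <- model
  out$data <- data
  out$fixed <- fixed
  out
}

# default transforms for a model's parameters + sigma2 (all models here have
# positive parameters unless the model declares otherwise)
#' @rdname scattering_target
#' @export
model_transforms <- function(model) {
  kinds <- model$transform_kinds %||%
    setNames(rep("log", length(model$param_names)), model$param_names)
  param_transform(c(unname(kinds), "log"),
                  names = c(names(kinds), "sigma2"),
                  lower = c(model$lower %||% rep(-Inf, length(kinds)), -Inf),
                  upper = c(model$upper %||% rep(Inf, length(kinds)), Inf))
}
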