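#' Fit a scattering model by Hamiltonian Monte Carlo
#'
#' The main user entry point: ties a forward model to a dataset through the
#' Gaussian residual likelihood, transforms parameters to the unconstrained
#' scale, preconditions the mass matrix, and runs the requested kernel.
#'
#' Mass-matrix preconditioning follows the configured strategy.
#' `"gradient_scaled_diag"` starts from a diagonal scaled to the mean
#' potential-gradient magnitudes probed around the initial point (snapped to
#' magnitude levels); `"inverse_variance_diag"` starts from the identity.
#' Either way, when the burn-in is long enough (>= 60 iterations) the warm-up
#' proceeds in windows: two short bounded-cost segments whose sample
#' variances successively refine the diagonal mass to the inverse posterior
#' variances (the restart-with-inverse-covariance practice), followed by the
#' main run with a final dual-averaging burn-in segment. `"identity"` skips
#' preconditioning entirely.
#'
#' @param data A [scattering_data()].
#' @param model A forward model ([saxs_model()], [refl_model()],
#'   [xwfh_model()]).
#' @param init Named physical-scale initial values for all free parameters
#'   (must include `sigma2`).
#' @param fixed Named physical values held fixed.
#' @param kernel `"nuts"`, `"hmc"` or `"random_walk"`.
#' @param config A [sampler_config()]. `n_burn_in` counts the total warm-up,
#'   including the preconditioning windows.
#' @return An object of class `hmc_fit` with elements `chain`, `pre_chains`,
#'   `target`, `model`, `data`, `config`. Use [tidy()] for the summary
#'   table, [glance()] for run-level diagnostics, [credible_band()] and
#'   [autoplot()] for curves.
#' @export
fit_hmc <- function(data, model, init, fixed = NULL,
                    kernel = c("nuts", "hmc", "random_walk"),
                    config = sampler_config()) {
  kernel <- match.arg(kernel)
  target <- scattering_target(model, data, fixed = fixed)
  miss <- setdiff(target$param_names, names(init))
  if (length(miss) > 0)
    stop("init is missing parameters: ", paste(miss, collapse = ", "))
  z0 <- to_sampling(init[target$param_names], target$transform)

  grad_probe_mass <- function(z) {
    set.seed(config$seed)
    probes <- rbind(z, t(replicate(7, z + rnorm(length(z), 0, 0.01))))
    grads <- t(apply(probes, 1, target$grad))
    adapt_mass_matrix(strategy = "gradient_scaled_diag", grad_probe = grads)
  }
  inv_var_mass <- function(draws) {
    v <- pmax(apply(draws, 2, var), 1e-6)
    mass_matrix(1 / v)
  }

  pre_chains <- list()
  B <- config$n_burn_in
  staged <- kernel != "random_walk" &&
    config$mass_strategy != "identity" && B >= 60L
  if (staged) {
    # windowed warm-up: two short exposure segments (bounded-cost
    # fixed-length HMC) whose sample variances successively refine the
    # diagonal mass -- the restart-with-inverse-variance practice -- then
    # the main run with its own dual-averaging burn-in segment
    s1 <- ceiling(0.3 * B)
    s2 <- ceiling(0.3 * B)
    s3 <- B - s1 - s2
    mass <- if (config$mass_strategy == "gradient_scaled_diag")
      grad_probe_mass(z0) else NULL
    eps <- config$step_size
    z <- z0
    for (k in 1:2) {
      seg <- if (k == 1) s1 else s2
      cfg_k <- config
      cfg_k$seed <- config$seed + (k - 1L)
      cfg_k$n_iterations <- as.integer(seg)
      cfg_k$n_burn_in <- as.integer(seg - 1L)
      cfg_k$step_size <- eps
      ch_k <- run_chain(z, target, cfg_k, kernel = "hmc", mass = mass)
      pre_chains[[k]] <- ch_k
      keep <- max(1L, floor(seg / 2)):seg
      mass <- inv_var_mass(ch_k$draws[keep, , drop = FALSE])
      eps <- ch_k$final_step_size
      z <- ch_k$draws[seg, ]
    }
    main_cfg <- config
    main_cfg$seed <- config$seed + 2L
    main_cfg$n_iterations <- config$n_iterations - as.integer(s1 + s2)
    main_cfg$n_burn_in <- as.integer(s3)
    main_cfg$step_size <- eps
    chain <- run_chain(z, target, main_cfg, kernel = kernel, mass = mass)
  } else {
    mass <- if (config$mass_strategy == "gradient_scaled_diag" &&
                kernel != "random_walk") grad_probe_mass(z0) else NULL
    chain <- run_chain(z0, target, config, kernel = kernel, mass = mass)
  }
  structure(list(chain = chain, pre_chains = pre_chains, target = target,
                 model = model, data = data, config = config,
                 kernel = kernel, init = init, mass = chain$mass),
            class = "hmc_fit")
}

#' @export
print.hmc_fit <- function(x, ...) {
  cat("<hmc_fit>", x$model$name, "|", x$kernel, "kernel\n")
  print(x$chain)
  s <- tidy(x)
  cat("\nPosterior summary (physical scale):\n")
  print(as.data.frame(s), digits = 4)
  invisible(x)
}

#' Tidy a fitted chain into the summary table
#'
#' One row per parameter: posterior mean, s.d., t-statistic and p-value on
#' the physical scale, plus effective sample size.
#'
#' @param x An `hmc_fit` or `hmc_chain`.
#' @param ... Unused.
#' @export
tidy.hmc_fit <- function(x, ...) summarize_chain(x$chain)

#' @rdname tidy.hmc_fit
#' @export
tidy.hmc_chain <- function(x, ...) summarize_chain(x)

#' One-row chain-level diagnostics
#'
#' @param x An `hmc_fit` or `hmc_chain`.
#' @param ... Unused.
#' @export
glance.hmc_fit <- function(x, ...) glance(x$chain)

#' @rdname glance.hmc_fit
#' @export
glance.hmc_chain <- function(x, ...) {
  n <- nrow(x$draws)
  post <- (x$burn_in + 1):n
  s <- summarize_chain(x)
  tibble::tibble(kernel = x$kernel, n_iterations = n, n_burn_in = x$burn_in,
                 acceptance_rate = mean(x$accepted[post]),
                 n_divergent = sum(x$divergent),
                 step_size = x$final_step_size,
                 min_ess = suppressWarnings(min(s$ess, na.rm = TRUE)),
                 seed = x$seed)
}

#' Data with fitted curve and credible band
#'
#' @param fit An `hmc_fit`.
#' @param n_draws Draws used for the band.
#' @export
fitted_curve <- function(fit, n_draws = 200) {
  band <- credible_band(fit, n_draws = n_draws)
  dplyr::bind_cols(tibble::as_tibble(fit$data)[, c("abscissa", "observed")],
                   band[, c("lower", "median", "upper")])
}

#' Diagnostic and result plots
#'
#' `type = "trace"` draws per-parameter traces (burn-in shaded),
#' `"acf"` the post-burn-in autocorrelation with significance bounds,
#' `"band"` the data with the posterior median curve and 95% band,
#' `"histogram"` marginal posterior histograms.
#'
#' @param object An `hmc_fit` (all types) or `hmc_chain` (`trace`, `acf`,
#'   `histogram`).
#' @param type Plot type.
#' @param ... Unused.
#' @export
autoplot.hmc_fit <- function(object, type = c("trace", "acf", "band",
                                              "histogram"), ...) {
  type <- match.arg(type)
  if (type == "band") {
    fc <- fitted_curve(object)
    return(
      ggplot2::ggplot(fc, ggplot2::aes(x = .data$abscissa)) +
        ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                          ymax = .data$upper),
                             fill = "steelblue", alpha = 0.4) +
        ggplot2::geom_line(ggplot2::aes(y = .data$median),
                           colour = "steelblue") +
        ggplot2::geom_point(ggplot2::aes(y = .data$observed), size = 0.6) +
        ggplot2::scale_y_log10() +
        ggplot2::labs(x = "abscissa", y = "intensity",
                      title = "posterior median and 95% band")
    )
  }
  autoplot(object$chain, type = type, ...)
}

#' @rdname autoplot.hmc_fit
#' @export
autoplot.hmc_chain <- function(object, type = c("trace", "acf",
                                                "histogram"), ...) {
  type <- match.arg(type)
  if (type == "acf") {
    d <- chain_draws(object, scale = "physical")
    long <- purrr::map_dfr(setdiff(names(d), ".iteration"), function(nm) {
      a <- autocorrelation(d[[nm]])
      a$term <- nm
      a
    })
    return(
      ggplot2::ggplot(long, ggplot2::aes(x = .data$lag, y = .data$acf)) +
        ggplot2::geom_col(width = 0.3) +
        ggplot2::geom_hline(ggplot2::aes(yintercept = .data$upper),
                            linetype = 2, colour = "red") +
        ggplot2::geom_hline(ggplot2::aes(yintercept = .data$lower),
                            linetype = 2, colour = "red") +
        ggplot2::facet_wrap(~term, scales = "free_y")
    )
  }
  d <- chain_draws(object, scale = "physical", include_burn_in = TRUE)
  long <- tidyr::pivot_longer(d, -".iteration", names_to = "term")
  if (type == "trace") {
    ggplot2::ggplot(long, ggplot2::aes(x = .data$.iteration,
                                       y = .data$value)) +
      ggplot2::geom_line(linewidth = 0.3) +
      ggplot2::geom_vline(xintercept = object$burn_in, linetype = 3) +
      ggplot2::facet_wrap(~term, scales = "free_y") +
      ggplot2::labs(x = "iteration", y = NULL)
  } else {
    post <- dplyr::filter(long, .data$.iteration > object$burn_in)
    ggplot2::ggplot(post, ggplot2::aes(x = .data$value)) +
      ggplot2::geom_histogram(bins = 40) +
      ggplot2::facet_wrap(~term, scales = "free")
  }
}
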