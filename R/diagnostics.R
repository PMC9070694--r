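#' Normalised autocorrelation of a chain
#'
#' Biased (divide-by-n) normalised autocorrelation function with the
#' `+-1.96 / sqrt(n)` significance bounds for the zero-autocorrelation
#' hypothesis. `ACF(0) = 1` by construction.
#'
#' @param x Scalar draw series (at least 10 points, non-constant).
#' @param max_lag Largest lag (default `min(n - 1, 10 log10(n))`).
#' @return Tibble with columns `lag`, `acf`, `lower`, `upper`.
#' @export
autocorrelation <- function(x, max_lag = NULL) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 10) stop("need at least 10 samples")
  if (sd(x) == 0) stop("zero-variance series has no autocorrelation")
  if (is.null(max_lag)) max_lag <- min(n - 1L, floor(10 * log10(n)))
  a <- drop(acf(x, lag.max = max_lag, plot = FALSE, demean = TRUE)$acf)
  bound <- 1.96 / sqrt(n)
  tibble::tibble(lag = 0:max_lag, acf = a, lower = -bound, upper = bound)
}

#' Effective sample size
#'
#' `ESS = n / (1 + 2 sum rho_k)` with the autocorrelation sum truncated by
#' Geyer's initial positive sequence (pairwise sums of autocorrelations are
#' kept while positive). The fraction `ESS / n` is the per-draw efficiency
#' reported alongside.
#'
#' @param x Scalar draw series (post-burn-in segment).
#' @return Tibble with `ess` and `fraction`.
#' @export
effective_sample_size <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 10) stop("need at least 10 samples")
  if (sd(x) == 0) stop("constant series has undefined effective sample size")
  rho <- drop(acf(x, lag.max = n - 1L, plot = FALSE)$acf)[-1]
  m <- floor(length(rho) / 2)
  ssum <- 0
  for (k in seq_len(m)) {
    gam <- rho[2 * k - 1] + rho[2 * k]
    if (gam <= 0) break
    ssum <- ssum + gam
  }
  ess <- n / (1 + 2 * ssum)
  ess <- min(ess, n)
  tibble::tibble(ess = ess, fraction = ess / n)
}

#' Summary table of a chain
#'
#' Per-parameter posterior mean, standard deviation, t-statistic
#' (`mean / sd`) and two-sided p-value against zero, computed from
#' post-burn-in draws on the physical scale (after back-transform). The
#' p-value is the empirical two-sided tail fraction
#' `2 min(P(x <= 0), P(x >= 0))`; when no draw crosses zero it falls back to
#' the normal approximation `2 pnorm(-|t|)`. A parameter whose draws are all
#' identical is reported with `sd = 0`, `p = 0` and flagged `degenerate`.
#'
#' @param chain An `hmc_chain` (or a draw matrix/tibble on the physical
#'   scale).
#' @param burn_in Override of the chain's stored burn-in index.
#' @return A tibble: `term`, `mean`, `sd`, `t_stat`, `p_value`, `ess`,
#'   `ess_fraction`, `degenerate`.
#' @export
summarize_chain <- function(chain, burn_in = NULL) {
  if (inherits(chain, "hmc_chain")) {
    if (!is.null(burn_in)) chain$burn_in <- burn_in
    d <- chain_draws(chain, scale = "physical")
    d$.iteration <- NULL
  } else {
    d <- tibble::as_tibble(chain)
    if (!is.null(burn_in) && burn_in > 0) d <- d[-seq_len(burn_in), ]
  }
  purrr::map_dfr(names(d), function(nm) {
    x <- d[[nm]]
    m <- mean(x); s <- sd(x)
    if (s == 0) {
      return(tibble::tibble(term = nm, mean = m, sd = 0, t_stat = Inf,
                            p_value = 0, ess = NA_real_,
                            ess_fraction = NA_real_, degenerate = TRUE))
    }
    t_stat <- m / s
    p_emp <- 2 * min(mean(x <= 0), mean(x >= 0))
    p <- if (p_emp == 0) 2 * pnorm(-abs(t_stat)) else p_emp
    es <- effective_sample_size(x)
    tibble::tibble(term = nm, mean = m, sd = s, t_stat = t_stat,
                   p_value = min(p, 1), ess = es$ess,
                   ess_fraction = es$fraction, degenerate = FALSE)
  })
}

#' Posterior correlation matrix
#'
#' Pearson correlations of the post-burn-in draws on the physical scale.
#' Derived parameters can be added as expressions of the draw columns
#' (e.g. `total = d_ps + d_ptba`), the device used to inspect strongly
#' anti-correlated thickness pairs during model selection.
#'
#' @param chain An `hmc_chain`.
#' @param ... Optional named expressions defining derived columns.
#' @param burn_in Optional burn-in override.
#' @export
correlation_matrix <- function(chain, ..., burn_in = NULL) {
  if (inherits(chain, "hmc_chain")) {
    if (!is.null(burn_in)) chain$burn_in <- burn_in
    d <- chain_draws(chain, scale = "physical")
    d$.iteration <- NULL
  } else d <- tibble::as_tibble(chain)
  dots <- rlang::enquos(...)
  if (length(dots) > 0) d <- dplyr::mutate(d, !!!dots)
  stats::cor(as.matrix(d))
}

#' Pointwise credible band of the model prediction
#'
#' Evaluates the forward model at (a thinned subset of) the post-burn-in
#' draws and returns the pointwise 2.5%, 50% and 97.5% percentiles — the 95%
#' confidence band of the predicted curve.
#'
#' @param chain An `hmc_chain` produced with a [scattering_target()] (or a
#'   fitted object from [fit_hmc()]).
#' @param target The [scattering_target()] (taken from a fit object when
#'   omitted).
#' @param abscissa Evaluation abscissa (the data grid when `NULL`).
#' @param n_draws Maximum number of draws to evaluate (evenly thinned).
#' @param probs Percentiles (lower, median, upper).
#' @export
credible_band <- function(chain, target = NULL, abscissa = NULL,
                          n_draws = 200, probs = c(0.025, 0.5, 0.975)) {
  if (inherits(chain, "hmc_fit")) {
    target <- chain$target
    chain <- chain$chain
  }
  if (is.null(target)) stop("target required")
  if (is.null(abscissa)) abscissa <- target$data$abscissa
  idx <- (chain$burn_in + 1):nrow(chain$draws)
  if (length(idx) > n_draws)
    idx <- idx[unique(round(seq(1, length(idx), length.out = n_draws)))]
  model <- target$model
  curves <- vapply(idx, function(i) {
    phys <- target$assemble(chain$draws[i, ])
    model$predict(phys, abscissa)
  }, numeric(length(abscissa)))
  qs <- apply(curves, 1, quantile, probs = probs, names = FALSE)
  tibble::tibble(abscissa = abscissa, lower = qs[1, ], median = qs[2, ],
                 upper = qs[3, ])
}
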