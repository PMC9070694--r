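test_that("autocorrelation is exact at lag zero and matches a direct sum", {
  set.seed(21)
  x <- rnorm(500)
  a <- autocorrelation(x, max_lag = 20)
  expect_equal(a$acf[1], 1)
  # direct biased estimator, computed independently
  xc <- x - mean(x)
  direct <- vapply(0:20, function(k)
    sum(xc[1:(500 - k)] * xc[(1 + k):500]) / sum(xc^2), numeric(1))
  expect_equal(a$acf, direct, tolerance = 1e-10)
  expect_equal(a$upper[1], 1.96 / sqrt(500))
  expect_error(autocorrelation(rep(1, 100)), "variance")
  expect_error(autocorrelation(rnorm(5)), "at least 10")
})

test_that("white noise and AR(1) autocorrelations behave as theory says", {
  set.seed(22)
  x <- rnorm(1e4)
  a <- autocorrelation(x, max_lag = 30)
  expect_gt(mean(abs(a$acf[-1]) < 3 / sqrt(1e4)), 0.9)
  y <- ar1_series(2e4, 0.9, seed = 23)
  ay <- autocorrelation(y, max_lag = 5)
  expect_equal(ay$acf[-1], 0.9^(1:5), tolerance = 0.05)
})

test_that("effective sample size matches iid and AR(1) closed forms", {
  set.seed(24)
  es <- effective_sample_size(rnorm(5000))
  expect_gt(es$fraction, 0.8)
  expect_lte(es$fraction, 1.2)
  y <- ar1_series(5e4, 0.9, seed = 25)
  es_y <- effective_sample_size(y)
  want <- (1 - 0.9) / (1 + 0.9)
  expect_equal(es_y$fraction, want, tolerance = 0.35 * want)
  expect_error(effective_sample_size(rep(3, 100)), "constant")
})

test_that("summary table computes moments, t-stats and p-values", {
  set.seed(26)
  d <- tibble::tibble(null = rnorm(4000), strong = rnorm(4000, 10, 1),
                      const = rep(2.5, 4000))
  s <- summarize_chain(d)
  null_row <- s[s$term == "null", ]
  expect_lt(abs(null_row$t_stat), 0.1)
  expect_gt(null_row$p_value, 0.5)
  strong <- s[s$term == "strong", ]
  expect_equal(strong$t_stat, 10, tolerance = 0.1)
  expect_lt(strong$p_value, 1e-20)
  cr <- s[s$term == "const", ]
  expect_true(cr$degenerate)
  expect_equal(cr$p_value, 0)
  expect_equal(cr$mean, 2.5)
})

test_that("summaries are computed on the physical scale of a chain", {
  # log-normal draws: the physical mean must be exp(mu + s^2/2), not exp(mu)
  tr <- param_transform("log", "theta")
  set.seed(27)
  z <- matrix(rnorm(6000, 1, 0.5), ncol = 1)
  colnames(z) <- "theta"
  ch <- structure(list(draws = z, accepted = rep(TRUE, 6000),
                       dH = numeric(6000), step_size = numeric(6000),
                       divergent = logical(6000),
                       accept_stat = numeric(6000), burn_in = 1000L,
                       kernel = "hmc", param_names = "theta",
                       transform = tr, seed = 1L, final_step_size = 0.1,
                       mass = NULL, config = NULL), class = "hmc_chain")
  s <- summarize_chain(ch)
  expect_equal(s$mean, exp(1 + 0.125), tolerance = 0.05)
})

test_that("correlation matrix handles identities and derived columns", {
  set.seed(28)
  d <- tibble::tibble(a = rnorm(1e4), b = rnorm(1e4))
  cm <- correlation_matrix(d)
  expect_equal(diag(cm), c(a = 1, b = 1))
  expect_lt(abs(cm["a", "b"]), 0.05)
  cm2 <- correlation_matrix(dplyr::mutate(d, neg = -a))
  expect_equal(cm2["a", "neg"], -1)
  cm3 <- correlation_matrix(d, total = a + b)
  expect_equal(cm3["a", "total"], cor(d$a, d$a + d$b), tolerance = 1e-12)
})

test_that("credible bands match conjugate-normal predictive quantiles", {
  # linear model f = theta * x with theta ~ N(2, 0.25); analytic pointwise
  # quantiles are (2 +- 1.96 * 0.5) x
  lin_model <- structure(list(
    name = "line", param_names = "theta",
    transform_kinds = c(theta = "identity"),
    predict = function(params, abscissa) params[["theta"]] * abscissa),
    class = "scatter_model")
  x <- seq(0.5, 3, length.out = 6)
  d <- scattering_data(x, 2 * x, scale = "linear")
  tgt <- scattering_target(lin_model, d)
  set.seed(29)
  n <- 4000
  draws <- cbind(theta = rnorm(n, 2, 0.5), sigma2 = rep(0, n))
  ch <- structure(list(draws = cbind(draws[, 1], log(1e-4)),
                       accepted = rep(TRUE, n), dH = numeric(n),
                       step_size = numeric(n), divergent = logical(n),
                       accept_stat = numeric(n), burn_in = 0L,
                       kernel = "hmc",
                       param_names = c("theta", "sigma2"),
                       transform = tgt$transform, seed = 1L,
                       final_step_size = 0.1, mass = NULL, config = NULL),
                  class = "hmc_chain")
  band <- credible_band(ch, tgt, abscissa = x, n_draws = 4000)
  expect_true(all(band$lower <= band$median & band$median <= band$upper))
  expect_equal(band$median, 2 * x, tolerance = 0.03)
  expect_equal(band$upper, (2 + 1.96 * 0.5) * x, tolerance = 0.05)
  expect_equal(band$lower, (2 - 1.96 * 0.5) * x, tolerance = 0.05)

  # single draw: degenerate band
  ch1 <- ch
  ch1$draws <- ch$draws[1, , drop = FALSE]
  ch1$accepted <- TRUE; ch1$divergent <- FALSE
  b1 <- credible_band(ch1, tgt, abscissa = x)
  expect_equal(b1$lower, b1$upper)
})

test_that("the 95% band covers the true curve in a cheap recovery run", {
  dec_model <- structure(list(
    name = "toy", param_names = c("amp", "rate"),
    transform_kinds = c(amp = "log", rate = "log"),
    predict = function(params, abscissa)
      params[["amp"]] * exp(-params[["rate"]] * abscissa)),
    class = "scatter_model")
  x <- seq(0.05, 3, length.out = 40)
  truth <- c(amp = 2, rate = 1.1, sigma2 = 0.02)
  spec <- synthetic_spec(dec_model, truth, x, seed = 61)
  ds <- simulate_dataset(spec)
  tgt <- scattering_target(dec_model, ds)
  z0 <- to_sampling(c(1.5, 1.5, 0.05), tgt$transform)
  cfg <- sampler_config(n_iterations = 2500, n_burn_in = 500, seed = 62,
                        step_size = 0.1)
  ch <- run_chain(z0, tgt, cfg, kernel = "hmc")
  band <- credible_band(ch, tgt, n_draws = 300)
  f_true <- dec_model$predict(truth, x)
  expect_gte(mean(f_true >= band$lower & f_true <= band$upper), 0.9)
})
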