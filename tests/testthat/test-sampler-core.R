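test_that("momentum draws have the mass-matrix covariance", {
  set.seed(1)
  m1 <- mass_matrix(c(1, 1))
  draws <- t(replicate(1e5, sample_momentum(m1)))
  # identity mass: iid standard normal components, var within 3 s.e. of 1
  se_var <- sqrt(2 / 1e5)
  expect_lt(abs(var(draws[, 1]) - 1), 3 * se_var)
  expect_lt(abs(mean(draws[, 2])), 3 / sqrt(1e5))

  m4 <- mass_matrix(4)
  d4 <- replicate(1e5, sample_momentum(m4))
  expect_lt(abs(var(d4) - 4), 3 * 4 * se_var)

  # full mass with correlation
  S <- matrix(c(2, 1.2, 1.2, 1), 2)
  mf <- mass_matrix(S)
  df <- t(replicate(2e4, sample_momentum(mf)))
  expect_equal(cov(df), S, tolerance = 0.1)

  expect_length(sample_momentum(mass_matrix(numeric(0))), 0)
})

test_that("mass matrix construction rejects invalid inputs", {
  expect_error(mass_matrix(c(1, -2)), "positive")
  expect_error(mass_matrix(matrix(c(1, 2, 2, 1), 2)), "positive definite")
  expect_error(mass_matrix(matrix(c(1, 2, 3, 4), 2)), "symmetric")
})

test_that("kinetic energy is p' M^-1 p / 2", {
  expect_equal(kinetic_energy(0, mass_matrix(1)), 0)
  expect_equal(kinetic_energy(3, mass_matrix(1)), 4.5)
  # p = 2, M = diag(4): 0.5 * 2 * (1/4) * 2 = 0.5 (hand matrix-solve)
  expect_equal(kinetic_energy(2, mass_matrix(4)), 0.5)
  S <- matrix(c(2, 0.5, 0.5, 1), 2)
  p <- c(0.3, -1.1)
  expect_equal(kinetic_energy(p, mass_matrix(S)),
               0.5 * drop(p %*% solve(S) %*% p))
  expect_error(kinetic_energy(c(1, 2), mass_matrix(1)), "length")
})

harmonic <- target_density(function(z) sum(z^2) / 2, function(z) z, 1)

test_that("one leapfrog step matches the closed-form harmonic update", {
  # U = x^2/2, x = 1, p = 0, eps = 0.1:
  # x' = 1 - eps^2/2 = 0.995, p' = -eps (1 - eps^2/4) = -0.09975
  st <- leapfrog_step(1, 0, 0.1, harmonic, mass_matrix(1))
  expect_equal(st$z, 0.995, tolerance = 1e-14)
  expect_equal(st$p, -0.09975, tolerance = 1e-14)
})

test_that("leapfrog is exactly time-reversible and eps = 0 is a no-op", {
  tg <- target_density(function(z) sum(z^4) / 4 + sum(z^2) / 2,
                       function(z) z^3 + z, 3)
  mass <- mass_matrix(c(1, 2, 0.5))
  set.seed(42)
  for (rep in 1:5) {
    z0 <- rnorm(3); p0 <- rnorm(3)
    fw <- leapfrog_step(z0, p0, 0.05, tg, mass, n_steps = 25)
    bk <- leapfrog_step(fw$z, -fw$p, 0.05, tg, mass, n_steps = 25)
    expect_lt(max(abs(bk$z - z0)), 1e-10)
    expect_lt(max(abs(-bk$p - p0)), 1e-10)
  }
  st <- leapfrog_step(c(1, 1, 1), c(0.3, 0, -1), 0, tg, mass)
  expect_equal(st$z, c(1, 1, 1))
})

test_that("energy error scales as a second-order integrator", {
  # on the harmonic target max|dH| over a fixed trajectory drops ~4x when
  # eps is halved
  mass <- mass_matrix(1)
  H <- function(z, p) z^2 / 2 + kinetic_energy(p, mass)
  max_dH <- function(eps, L) {
    z <- 1; p <- 0.5; H0 <- H(z, p)
    worst <- 0
    for (l in seq_len(L)) {
      st <- leapfrog_step(z, p, eps, harmonic, mass)
      z <- st$z; p <- st$p
      worst <- max(worst, abs(H(z, p) - H0))
    }
    worst
  }
  e1 <- max_dH(0.2, 50)
  e2 <- max_dH(0.1, 100)
  expect_gt(e1 / e2, 3)
  expect_lt(e1 / e2, 5)
})

test_that("momentum reflection mirrors about the constraint surface", {
  expect_equal(reflect_momentum(c(1, 2), c(1, 0)), c(-1, 2))
  # Householder oracle: p' = (I - 2 n n') p
  n <- c(1, 1) / sqrt(2)
  p <- c(1, 0)
  expect_equal(reflect_momentum(p, n),
               drop((diag(2) - 2 * n %o% n) %*% p))
  expect_equal(reflect_momentum(p, n), c(0, -1), tolerance = 1e-14)
  # momentum parallel to the surface is unchanged, kinetic energy conserved
  expect_equal(reflect_momentum(c(0, 3), c(1, 0)), c(0, 3))
  pr <- reflect_momentum(c(0.7, -1.1), c(0.3, 2))
  expect_equal(sum(pr^2), sum(c(0.7, -1.1)^2), tolerance = 1e-12)
  expect_error(reflect_momentum(c(1, 1), c(0, 0)), "non-zero")
})

test_that("hmc accepts with probability one at zero energy error", {
  # eps -> 0 keeps dH ~ 0; every draw must be accepted
  set.seed(3)
  z <- 0.5; U <- harmonic$U(z)
  for (i in 1:50) {
    st <- hmc_draw(z, U, harmonic, 1e-5, 3, mass_matrix(1))
    expect_true(st$accepted)
    expect_equal(st$accept_stat, 1, tolerance = 1e-6)
    z <- st$z; U <- st$U
  }
})

test_that("dual averaging moves the step size in the right direction", {
  st <- dual_averaging_init(0.1, target_accept = 0.8)
  eps_hist <- numeric(20)
  for (i in 1:20) {
    st <- dual_averaging_update(st, 1)
    eps_hist[i] <- st$eps
  }
  expect_true(all(diff(eps_hist) > 0))
  st <- dual_averaging_init(0.1, target_accept = 0.8)
  for (i in 1:20) st <- dual_averaging_update(st, 0)
  expect_lt(st$eps, 0.1)
})

test_that("dual averaging reaches the target acceptance on a unit normal", {
  cfg <- sampler_config(step_size = 1, n_leapfrog = 5, n_iterations = 3000,
                        n_burn_in = 1000, seed = 11, target_accept = 0.8)
  ch <- run_chain(0.3, harmonic, cfg, kernel = "hmc")
  post_acc <- mean(ch$accept_stat[(ch$burn_in + 1):3000])
  expect_lt(abs(post_acc - 0.8), 0.1)
})

test_that("mass adaptation recovers inverse variances and handles degeneracy", {
  set.seed(5)
  draws <- cbind(rnorm(4000, 0, 1), rnorm(4000, 0, 10))
  m <- adapt_mass_matrix(draws, "inverse_variance_diag")
  expect_equal(m$M, c(1, 0.01), tolerance = 0.15)

  const <- matrix(2, 20, 2)
  mf <- adapt_mass_matrix(const, "inverse_variance_diag", floor = 1e-6)
  expect_true(all(is.finite(mf$M)))
  expect_equal(mf$M, rep(1e6, 2))

  expect_error(adapt_mass_matrix(draws[1:5, ], "inverse_variance_diag"),
               "at least 10")
})

test_that("gradient-scaled mass splits coordinates into magnitude levels", {
  # six high-gradient coordinates against a low-gradient remainder produce
  # a two-level diagonal (400 vs 1)
  set.seed(6)
  g <- cbind(matrix(rnorm(8 * 6, 0, 300), 8), matrix(rnorm(8 * 4, 0, 1), 8))
  m <- adapt_mass_matrix(strategy = "gradient_scaled_diag", grad_probe = g)
  expect_setequal(unique(m$M), c(400, 1))
  expect_true(all(m$M[1:6] == 400))
  expect_error(adapt_mass_matrix(strategy = "gradient_scaled_diag"),
               "probe")
})

test_that("kernels reproduce Gaussian target moments (light version)", {
  tg2 <- gauss_target(c(0, 0), matrix(c(1, 0.9, 0.9, 1), 2))
  cfg <- sampler_config(step_size = 0.2, n_leapfrog = 10,
                        n_iterations = 4000, n_burn_in = 500, seed = 7)
  ch <- run_chain(c(1, -1), tg2, cfg, kernel = "hmc")
  d <- as.matrix(chain_draws(ch, scale = "sampling")[, -1])
  for (j in 1:2)
    expect_lt(abs(mean(d[, j])), 4 * batch_se(d[, j]))
  expect_equal(cor(d[, 1], d[, 2]), 0.9, tolerance = 0.05)
})

test_that("nuts is deterministic given a seed and robust to huge steps", {
  cfg <- sampler_config(step_size = 0.5, n_iterations = 200, n_burn_in = 50,
                        seed = 9, adaptation = "none")
  ch1 <- run_chain(0.1, harmonic, cfg, kernel = "nuts")
  ch2 <- run_chain(0.1, harmonic, cfg, kernel = "nuts")
  expect_identical(ch1$draws, ch2$draws)

  # pathologically large step: high flag rate but finite draws
  cfg$step_size <- 10
  ch3 <- run_chain(0.1, harmonic, cfg, kernel = "nuts")
  expect_true(all(is.finite(ch3$draws)))
})

test_that("chain honours the rejection-retention invariant and burn-in", {
  steep <- target_density(function(z) sum(z^2) * 50,
                          function(z) 100 * z, 1)
  cfg <- sampler_config(step_size = 0.4, n_leapfrog = 20,
                        n_iterations = 300, n_burn_in = 0,
                        adaptation = "none", seed = 12)
  ch <- run_chain(0.5, steep, cfg, kernel = "hmc")
  rej <- which(!ch$accepted)
  rej <- rej[rej > 1]
  expect_gt(length(rej), 0)
  for (t in rej) expect_identical(ch$draws[t, ], ch$draws[t - 1, ])
  # n_burn_in = 0: no adaptation ever applied
  expect_true(all(ch$step_size == 0.4))
})

test_that("random-walk kernel matches textbook Metropolis behaviour", {
  cfg <- sampler_config(n_iterations = 8000, n_burn_in = 500, seed = 13,
                        rw_sd = 2.4)
  ch <- run_chain(0, harmonic, cfg, kernel = "random_walk")
  x <- chain_draws(ch, scale = "sampling")$x1
  expect_lt(abs(mean(x)), 4 * batch_se(x))
  expect_equal(var(x), 1, tolerance = 0.15)
  acc <- mean(ch$accepted[501:8000])
  expect_gt(acc, 0.3); expect_lt(acc, 0.65)
})

test_that("multi-start runs return one chain per initial value", {
  cfg <- sampler_config(n_iterations = 60, n_burn_in = 10, seed = 20,
                        adaptation = "none", step_size = 0.5)
  chains <- run_chain(list(0.1, -2), harmonic, cfg, kernel = "hmc")
  expect_length(chains, 2)
  expect_equal(chains[[2]]$seed, 21L)
  expect_false(identical(chains[[1]]$draws, chains[[2]]$draws))
})

test_that("a burn-in made entirely of divergences aborts with a message", {
  stiff <- target_density(function(z) 5e5 * sum(z^2),
                          function(z) 1e6 * z, 1)
  cfg <- sampler_config(step_size = 5, n_leapfrog = 10, n_iterations = 40,
                        n_burn_in = 20, adaptation = "none", seed = 77)
  expect_error(run_chain(0.5, stiff, cfg, kernel = "hmc"), "diverged")
})
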