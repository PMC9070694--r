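# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths.

# closed-form Fresnel |r|^2 of a single sharp interface, q referenced to the
# ambient
fresnel_r2 <- function(q, delta_amb, delta_sub, lambda) {
  k0 <- 2 * pi / lambda
  kz0 <- q / 2
  kz1 <- sqrt(as.complex(kz0^2 - 2 * k0^2 * (delta_sub - delta_amb)))
  Mod((kz0 - kz1) / (kz0 + kz1))^2
}

# Nevot-Croce damped box-model reflectivity for ambient / one layer /
# substrate with sharp-interface Parratt recursion and Gaussian roughness
# damping factors exp(-2 kz_j kz_j+1 sigma^2)
nc_box_reflectivity <- function(q, delta_layer, h, sigma_top, sigma_bot,
                                delta_amb, delta_sub, lambda) {
  k0 <- 2 * pi / lambda
  vapply(q, function(qi) {
    kz <- c(complex(real = qi / 2),
            sqrt(as.complex((qi / 2)^2 - 2 * k0^2 * (delta_layer - delta_amb))),
            sqrt(as.complex((qi / 2)^2 - 2 * k0^2 * (delta_sub - delta_amb))))
    r01 <- (kz[1] - kz[2]) / (kz[1] + kz[2]) *
      exp(-2 * kz[1] * kz[2] * sigma_top^2)
    r12 <- (kz[2] - kz[3]) / (kz[2] + kz[3]) *
      exp(-2 * kz[2] * kz[3] * sigma_bot^2)
    ph <- exp(2i * kz[2] * h)
    Mod((r01 + r12 * ph) / (1 + r01 * r12 * ph))^2
  }, numeric(1))
}

# brute-force double Riemann sum for the polydisperse smeared sphere
# intensity (dense midpoint rules, independent of the package quadrature)
saxs_brute_force <- function(q, I0, Ib, R, sigR, sigq,
                             nR = 1200, nq = 241, trunc_R = 5, trunc_q = 4) {
  Rg <- seq(max(R - trunc_R * sigR, 1e-6), R + trunc_R * sigR,
            length.out = nR)
  wR <- dnorm(Rg, R, sigR)
  V <- 4 * pi * Rg^3 / 3
  Fq <- function(qv) {
    x <- outer(qv, Rg)
    3 * rep(1, length(qv)) %o% V * (sin(x) - x * cos(x)) / x^3
  }
  denom <- sum(wR * V^2)
  vapply(q, function(qi) {
    if (sigq > 0) {
      qg <- qi + sigq * seq(-trunc_q, trunc_q, length.out = nq)
      wq <- dnorm(qg, qi, sigq)
      keep <- qg > 0
      qg <- qg[keep]; wq <- wq[keep]
    } else {
      qg <- qi; wq <- 1
    }
    F2 <- Fq(qg)^2
    num <- sum(wq * drop(F2 %*% wR)) / sum(wq)
    I0 * num / denom + Ib
  }, numeric(1))
}

# AR(1) series with known autocorrelation rho^k
ar1_series <- function(n, phi, seed) {
  set.seed(seed)
  x <- numeric(n)
  x[1] <- rnorm(1) / sqrt(1 - phi^2)
  for (i in 2:n) x[i] <- phi * x[i - 1] + rnorm(1)
  x
}

# Monte-Carlo standard error of a mean estimated from a possibly correlated
# chain, via the package-independent batch-means method
batch_se <- function(x, n_batch = 25) {
  n <- length(x)
  bs <- floor(n / n_batch)
  bm <- vapply(seq_len(n_batch),
               function(b) mean(x[((b - 1) * bs + 1):(b * bs)]), numeric(1))
  sd(bm) / sqrt(n_batch)
}

# standard multivariate normal target densities for the known-target suite
gauss_target <- function(mean, cov) {
  P <- solve(cov)
  target_density(
    U = function(z) 0.5 * drop(t(z - mean) %*% P %*% (z - mean)),
    grad = function(z) drop(P %*% (z - mean)),
    n_params = length(mean))
}

table1_truth <- c(I0 = 1.34, Ib = 2.00e-5, R = 757.7, sigR = 59.5,
                  sigq = 1.44e-5, sigma2 = 1.78e-3)
table2_truth <- c(I0 = 1.06, sigma_Si = 2.6, h_o = 12.2, h_t = 22.7,
                  h_i = 11.2, delta_o = 6.59e-7, delta_t = 4.19e-7,
                  delta_i = 9.30e-7, sigma_o = 4.9, sigma_t = 4.2,
                  sigma_i = 8.5, sigma2 = 5.7e-4)
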