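#' Mass matrix for the auxiliary momentum
#'
#' The momentum of the Hamiltonian system is drawn from a zero-mean
#' multivariate normal whose covariance is the mass matrix `M`. A diagonal
#' (vector) form or a full symmetric positive-definite matrix are accepted.
#' Preconditioning with a non-trivial `M` (typically the inverse of the
#' posterior variances) is what makes the dynamics efficient on badly scaled
#' problems.
#'
#' @param x Positive numeric vector (diagonal mass) or symmetric
#'   positive-definite matrix.
#' @return An object of class `mass_matrix`.
#' @examples
#' mass_matrix(c(1, 4))
#' @export
mass_matrix <- function(x) {
  if (is.matrix(x)) {
    if (!isSymmetric(unname(x))) stop("full mass matrix must be symmetric")
    ch <- tryCatch(chol(x), error = function(e) NULL)
    if (is.null(ch) || any(diag(ch) <= 0))
      stop("full mass matrix must be positive definite")
    out <- list(type = "full", M = x, chol = ch, Minv = chol2inv(ch),
                n = nrow(x))
  } else {
    x <- as.numeric(x)
    if (any(!is.finite(x)) || any(x <= 0))
      stop("diagonal mass entries must be positive and finite")
    out <- list(type = "diag", M = x, sd = sqrt(x), Minv = 1 / x,
                n = length(x))
  }
  structure(out, class = "mass_matrix")
}

#' Draw a momentum vector
#'
#' Samples `p ~ N(0, M)` for a valid [mass_matrix()].
#'
#' @param mass A [mass_matrix()].
#' @return Numeric vector of length `mass$n` (length 0 for an empty mass).
#' @export
sample_momentum <- function(mass) {
  stopifnot(inherits(mass, "mass_matrix"))
  if (mass$n == 0L) return(numeric(0))
  if (mass$type == "diag") rnorm(mass$n, 0, mass$sd)
  else drop(crossprod(mass$chol, rnorm(mass$n)))
}

#' Kinetic energy of a momentum
#'
#' Returns `p' M^-1 p / 2`. The normalisation constant of the momentum
#' density is dropped throughout: for a fixed mass matrix it cancels in the
#' Metropolis acceptance ratio.
#'
#' @param p Momentum vector.
#' @inheritParams sample_momentum
#' @export
kinetic_energy <- function(p, mass) {
  stopifnot(inherits(mass, "mass_matrix"))
  if (length(p) != mass$n) stop("momentum length does not match mass matrix")
  if (mass$n == 0L) return(0)
  if (mass$type == "diag") 0.5 * sum(p * p * mass$Minv)
  else 0.5 * drop(p %*% mass$Minv %*% p)
}

mass_velocity <- function(p, mass) {
  if (mass$type == "diag") mass$Minv * p else drop(mass$Minv %*% p)
}

#' Leapfrog integration of the Hamiltonian dynamics
#'
#' Advances `(z, p)` by `n_steps` leapfrog steps of size `eps`:
#' half momentum kick, full position drift with velocity `M^-1 p`, half kick.
#' The integrator is symplectic and exactly time-reversible, which is what
#' guarantees detailed balance of the resulting Markov chain.
#'
#' @param z Position (sampling scale).
#' @param p Momentum.
#' @param eps Step size (may be negative to integrate backwards).
#' @param target A [target_density()] (its `grad` is used).
#' @param mass A [mass_matrix()].
#' @param n_steps Number of leapfrog steps.
#' @param grad_z Optional gradient at `z` (saves one evaluation).
#' @return List with `z`, `p`, `grad` (gradient at the final position) and
#'   `divergent` (`TRUE` if a non-finite gradient was met; integration stops).
#' @export
leapfrog_step <- function(z, p, eps, target, mass, n_steps = 1L,
                          grad_z = NULL) {
  g <- if (is.null(grad_z)) target$grad(z) else grad_z
  if (any(!is.finite(g)))
    return(list(z = z, p = p, grad = g, divergent = TRUE))
  for (l in seq_len(n_steps)) {
    p_half <- p - (eps / 2) * g
    z <- z + eps * mass_velocity(p_half, mass)
    g <- target$grad(z)
    if (any(!is.finite(g)))
      return(list(z = z, p = p_half, grad = g, divergent = TRUE))
    p <- p_half - (eps / 2) * g
  }
  list(z = z, p = p, grad = g, divergent = FALSE)
}

#' Reflect a momentum at a constraint surface
#'
#' Mirrors the momentum about the constraint surface with outward normal `n`:
#' `p' = p - 2 (p . n) n / |n|^2`. Kinetic energy is conserved exactly (for an
#' isotropic mass), so the trajectory bounces off the boundary without energy
#' loss instead of being wasted on a rejected state.
#'
#' @param p Momentum vector.
#' @param normal Non-zero normal vector of the constraint surface.
#' @export
reflect_momentum <- function(p, normal) {
  nn <- sum(normal^2)
  if (nn == 0) stop("constraint normal must be non-zero")
  p - 2 * sum(p * normal) / nn * normal
}

#' One Hamiltonian Monte Carlo draw
#'
#' Draws a fresh momentum, integrates `L` leapfrog steps of size `eps`, and
#' accepts the endpoint with probability `min(1, exp(H_old - H_new))`. On
#' rejection the current position is retained. Trajectories with non-finite
#' energies or `|dH|` above `div_threshold` are rejected and flagged
#' divergent.
#'
#' @param z Current position (sampling scale).
#' @param U_z Potential at `z`.
#' @param target A [target_density()].
#' @param eps Step size.
#' @param L Number of leapfrog steps.
#' @param mass A [mass_matrix()].
#' @param div_threshold Energy-error threshold flagging a divergence.
#' @param grad_z Optional gradient at `z`.
#' @return List with `z`, `U`, `grad`, `accepted`, `dH`, `accept_stat`,
#'   `divergent`.
#' @export
hmc_draw <- function(z, U_z, target, eps, L, mass, div_threshold = 1000,
                     grad_z = NULL) {
  p0 <- sample_momentum(mass)
  H0 <- U_z + kinetic_energy(p0, mass)
  lf <- leapfrog_step(z, p0, eps, target, mass, n_steps = L, grad_z = grad_z)
  if (lf$divergent) {
    return(list(z = z, U = U_z, grad = grad_z, accepted = FALSE, dH = Inf,
                accept_stat = 0, divergent = TRUE))
  }
  U1 <- target$U(lf$z)
  H1 <- U1 + kinetic_energy(lf$p, mass)
  dH <- H1 - H0
  if (!is.finite(dH) || abs(dH) > div_threshold) {
    return(list(z = z, U = U_z, grad = grad_z, accepted = FALSE, dH = dH,
                accept_stat = 0, divergent = TRUE))
  }
  a <- min(1, exp(-dH))
  if (runif(1) < a) {
    list(z = lf$z, U = U1, grad = lf$grad, accepted = TRUE, dH = dH,
         accept_stat = a, divergent = FALSE)
  } else {
    list(z = z, U = U_z, grad = grad_z, accepted = FALSE, dH = dH,
         accept_stat = a, divergent = FALSE)
  }
}

# one leapfrog step carrying (z, p, grad, U); used by the NUTS tree
leapfrog1 <- function(z, p, g, eps, target, mass) {
  p_half <- p - (eps / 2) * g
  z1 <- z + eps * mass_velocity(p_half, mass)
  g1 <- target$grad(z1)
  if (any(!is.finite(g1)))
    return(list(z = z1, p = p_half, g = g1, U = Inf, ok = FALSE))
  p1 <- p_half - (eps / 2) * g1
  U1 <- target$U(z1)
  list(z = z1, p = p1, g = g1, U = U1, ok = is.finite(U1))
}

nuts_uturn <- function(z_minus, z_plus, p_minus, p_plus, mass) {
  dz <- z_plus - z_minus
  (sum(dz * mass_velocity(p_minus, mass)) >= 0) &&
    (sum(dz * mass_velocity(p_plus, mass)) >= 0)
}

# recursive doubling of the trajectory (slice-sampling tree)
nuts_build_tree <- function(zpg, logu, v, j, eps, target, mass, H0,
                            div_threshold) {
  if (j == 0L) {
    st <- leapfrog1(zpg$z, zpg$p, zpg$g, v * eps, target, mass)
    H1 <- if (st$ok) st$U + kinetic_energy(st$p, mass) else Inf
    n1 <- as.integer(is.finite(H1) && logu <= -H1)
    s1 <- is.finite(H1) && (logu - div_threshold) < -H1
    alpha <- if (is.finite(H1)) min(1, exp(H0 - H1)) else 0
    return(list(minus = st, plus = st, prop = st, n = n1, s = s1,
                alpha = alpha, n_alpha = 1L, divergent = !s1))
  }
  t1 <- nuts_build_tree(zpg, logu, v, j - 1L, eps, target, mass, H0,
                        div_threshold)
  if (!t1$s) return(t1)
  outer <- if (v == -1) t1$minus else t1$plus
  t2 <- nuts_build_tree(outer, logu, v, j - 1L, eps, target, mass, H0,
                        div_threshold)
  if (v == -1) t1$minus <- t2$minus else t1$plus <- t2$plus
  ntot <- t1$n + t2$n
  if (t2$n > 0L && runif(1) < t2$n / ntot) t1$prop <- t2$prop
  t1$s <- t2$s &&
    nuts_uturn(t1$minus$z, t1$plus$z, t1$minus$p, t1$plus$p, mass)
  t1$n <- ntot
  t1$alpha <- t1$alpha + t2$alpha
  t1$n_alpha <- t1$n_alpha + t2$n_alpha
  t1$divergent <- t1$divergent || t2$divergent
  t1
}

#' One No-U-Turn sampler draw
#'
#' Builds a leapfrog trajectory by binary-tree doubling in randomly chosen
#' directions, stopping when the path starts to retrace (U-turn criterion) or
#' diverges, and returns a draw selected by slice sampling over the candidate
#' set. This automates the choice of total integration length `L * eps`.
#'
#' @inheritParams hmc_draw
#' @param max_depth Maximum tree depth (trajectory length `2^max_depth`).
#' @return List with `z`, `U`, `grad`, `accepted` (position changed),
#'   `accept_stat` (mean Metropolis statistic over the trajectory), `dH`,
#'   `depth`, `divergent`.
#' @export
nuts_draw <- function(z, U_z, target, eps, mass, max_depth = 10L,
                      div_threshold = 1000, grad_z = NULL) {
  g <- if (is.null(grad_z)) target$grad(z) else grad_z
  p0 <- sample_momentum(mass)
  H0 <- U_z + kinetic_energy(p0, mass)
  logu <- -H0 - rexp(1)       # log u, u ~ Unif(0, exp(-H0))
  state0 <- list(z = z, p = p0, g = g, U = U_z, ok = TRUE)
  minus <- plus <- state0
  prop <- state0
  j <- 0L; n <- 1L; s <- TRUE
  alpha <- 0; n_alpha <- 0L; divergent <- FALSE
  while (s && j < max_depth) {
    v <- if (runif(1) < 0.5) -1 else 1
    tr <- nuts_build_tree(if (v == -1) minus else plus, logu, v, j, eps,
                          target, mass, H0, div_threshold)
    if (v == -1) minus <- tr$minus else plus <- tr$plus
    if (tr$s && tr$n > 0L && runif(1) < tr$n / n) prop <- tr$prop
    n <- n + tr$n
    s <- tr$s && nuts_uturn(minus$z, plus$z, minus$p, plus$p, mass)
    alpha <- alpha + tr$alpha
    n_alpha <- n_alpha + tr$n_alpha
    divergent <- divergent || tr$divergent
    j <- j + 1L
  }
  H1 <- prop$U + kinetic_energy(prop$p, mass)
  list(z = prop$z, U = prop$U, grad = prop$g,
       accepted = !isTRUE(all.equal(prop$z, z)),
       accept_stat = if (n_alpha > 0L) alpha / n_alpha else 0,
       dH = H1 - H0, depth = j, divergent = divergent)
}

#' Dual-averaging step-size adaptation
#'
#' Nesterov dual averaging drives the running mean Metropolis acceptance
#' statistic towards `target_accept` during burn-in. After burn-in the step
#' size is frozen at the averaged value `exp(log_eps_bar)`. Constants
#' `gamma = 0.05`, `t0 = 10`, `kappa = 0.75` are the standard recommendations.
#'
#' @param eps0 Initial step size.
#' @param target_accept Desired mean acceptance statistic, in (0, 1).
#' @param gamma,t0,kappa Adaptation constants.
#' @return `dual_averaging_init()` returns an adaptation state;
#'   `dual_averaging_update()` returns the updated state whose `eps` element
#'   is the step size for the next iteration.
#' @export
dual_averaging_init <- function(eps0, target_accept = 0.8, gamma = 0.05,
                                t0 = 10, kappa = 0.75) {
  list(mu = log(10 * eps0), log_eps = log(eps0), log_eps_bar = 0,
       H_bar = 0, iter = 0L, gamma = gamma, t0 = t0, kappa = kappa,
       target_accept = target_accept, eps = eps0)
}

#' @rdname dual_averaging_init
#' @param state Adaptation state from a previous call.
#' @param accept_stat Realised acceptance statistic in `[0, 1]`.
#' @export
dual_averaging_update <- function(state, accept_stat) {
  m <- state$iter + 1L
  w <- 1 / (m + state$t0)
  state$H_bar <- (1 - w) * state$H_bar +
    w * (state$target_accept - accept_stat)
  state$log_eps <- state$mu - sqrt(m) / state$gamma * state$H_bar
  eta <- m^(-state$kappa)
  state$log_eps_bar <- eta * state$log_eps + (1 - eta) * state$log_eps_bar
  state$iter <- m
  state$eps <- exp(state$log_eps)
  state
}

#' Estimate a preconditioning mass matrix
#'
#' Three strategies mirror common practice. `"inverse_variance_diag"` sets the
#' diagonal mass to the reciprocal sample variances of warm-up draws, i.e. the
#' momentum scale matches the inverse posterior scale per coordinate.
#' `"gradient_scaled_diag"` coarsely scales the diagonal proportionally to the
#' mean absolute potential gradient per coordinate at probe points, snapped to
#' a small set of magnitude levels (powers of 20) so fast and slow coordinates
#' get clearly separated step scales. `"identity"` returns the unit mass.
#'
#' @param draws Matrix of warm-up draws (iterations x parameters), required by
#'   the variance strategy (at least 10 rows).
#' @param strategy One of `"identity"`, `"inverse_variance_diag"`,
#'   `"gradient_scaled_diag"`.
#' @param grad_probe Matrix of gradient vectors at probe points (rows), used
#'   by the gradient strategy.
#' @param floor Lower bound applied to variances before inversion, guarding
#'   against degenerate (constant) coordinates.
#' @return A [mass_matrix()].
#' @export
adapt_mass_matrix <- function(draws = NULL,
                              strategy = c("inverse_variance_diag",
                                           "gradient_scaled_diag",
                                           "identity"),
                              grad_probe = NULL, floor = 1e-8) {
  strategy <- match.arg(strategy)
  if (strategy == "identity") {
    n <- if (!is.null(draws)) ncol(draws) else nrow(grad_probe)
    return(mass_matrix(rep(1, n)))
  }
  if (strategy == "inverse_variance_diag") {
    if (is.null(draws) || nrow(draws) < 10)
      stop("inverse_variance_diag needs at least 10 warm-up draws")
    v <- pmax(apply(draws, 2, var), floor)
    return(mass_matrix(1 / v))
  }
  # gradient_scaled_diag
  if (is.null(grad_probe))
    stop("gradient_scaled_diag needs a matrix of probe gradients")
  g <- colMeans(abs(grad_probe))
  g <- pmax(g, floor)
  rel <- g / min(g)
  lev <- 20^round(log(rel, base = 20))   # snap to 1, 20, 400, ...
  mass_matrix(lev)
}

#' Sampler configuration
#'
#' Collects the tunables of [run_chain()]: step size, leapfrog count (or
#' maximum tree depth for NUTS), iteration and burn-in counts, adaptation and
#' mass-matrix strategy, RNG seed.
#'
#' @param step_size Leapfrog step size (initial value when adapting).
#' @param n_leapfrog Leapfrog steps per iteration (fixed-length HMC).
#' @param n_iterations Total iterations including burn-in.
#' @param n_burn_in Burn-in iterations (must be < `n_iterations`).
#' @param seed Integer RNG seed; the run owns a single seeded generator.
#' @param adaptation `"dual_averaging"` (during burn-in only) or `"none"`.
#' @param target_accept Dual-averaging target acceptance.
#' @param mass_strategy Mass-matrix strategy used by [fit_hmc()] warm-up.
#' @param max_tree_depth NUTS maximum tree depth.
#' @param div_threshold Divergence threshold on the energy error.
#' @param rw_sd Proposal standard deviations for the random-walk kernel
#'   (vector, recycled). If `NULL`, derived from the mass matrix as
#'   `sqrt(2.4^2 / N)` times the implied position scales.
#' @export
sampler_config <- function(step_size = 0.1, n_leapfrog = 10L,
                           n_iterations = 2000L, n_burn_in = 500L,
                           seed = 1L,
                           adaptation = c("dual_averaging", "none"),
                           target_accept = 0.8,
                           mass_strategy = c("inverse_variance_diag",
                                             "gradient_scaled_diag",
                                             "identity"),
                           max_tree_depth = 10L, div_threshold = 1000,
                           rw_sd = NULL) {
  adaptation <- match.arg(adaptation)
  mass_strategy <- match.arg(mass_strategy)
  stopifnot(step_size > 0, n_leapfrog >= 1, n_iterations >= 1,
            n_burn_in >= 0, n_burn_in < n_iterations,
            target_accept > 0, target_accept < 1)
  structure(list(step_size = step_size, n_leapfrog = as.integer(n_leapfrog),
                 n_iterations = as.integer(n_iterations),
                 n_burn_in = as.integer(n_burn_in), seed = as.integer(seed),
                 adaptation = adaptation, target_accept = target_accept,
                 mass_strategy = mass_strategy,
                 max_tree_depth = as.integer(max_tree_depth),
                 div_threshold = div_threshold, rw_sd = rw_sd),
            class = "sampler_config")
}

#' Run a Markov chain
#'
#' The main sampling loop: HMC, NUTS or random-walk Metropolis kernels over a
#' [target_density()]. Step-size adaptation (dual averaging) runs during
#' burn-in only; afterwards the step size is frozen at its averaged value.
#' All randomness flows from the single seeded generator owned by the run, so
#' equal seeds give bit-identical chains. Multiple initial values (a list)
#' run a multi-start set of chains with consecutive seeds.
#'
#' @param init Initial position on the sampling scale (numeric vector), or a
#'   list of such vectors for multi-start runs.
#' @param target A [target_density()].
#' @param config A [sampler_config()].
#' @param kernel `"hmc"`, `"nuts"` or `"random_walk"`.
#' @param mass A [mass_matrix()]; identity if `NULL`.
#' @return An object of class `hmc_chain` (or a list of them for
#'   multi-start): draw matrix on the sampling scale, acceptance flags,
#'   per-iteration energy errors and step sizes, divergence flags, burn-in
#'   index and configuration.
#' @export
run_chain <- function(init, target, config = sampler_config(),
                      kernel = c("nuts", "hmc", "random_walk"),
                      mass = NULL) {
  kernel <- match.arg(kernel)
  if (is.list(init) && !is.numeric(init)) {
    chains <- vector("list", length(init))
    for (k in seq_along(init)) {
      cfg_k <- config
      cfg_k$seed <- config$seed + (k - 1L)
      chains[[k]] <- run_chain(init[[k]], target, cfg_k, kernel, mass)
    }
    return(chains)
  }
  set.seed(config$seed)
  N <- length(init)
  if (is.null(mass)) mass <- mass_matrix(rep(1, N))
  n_it <- config$n_iterations
  draws <- matrix(NA_real_, n_it, N)
  colnames(draws) <- target$param_names
  accepted <- logical(n_it)
  dH <- numeric(n_it)
  eps_trace <- numeric(n_it)
  divergent <- logical(n_it)
  accept_stat <- numeric(n_it)

  z <- as.numeric(init)
  U_z <- target$U(z)
  if (!is.finite(U_z)) stop("potential is not finite at the initial position")
  g_z <- target$grad(z)

  adapting <- config$adaptation == "dual_averaging" && config$n_burn_in > 0 &&
    kernel != "random_walk"
  eps <- config$step_size
  da <- if (adapting) dual_averaging_init(eps, config$target_accept) else NULL

  rw_sd <- config$rw_sd
  if (kernel == "random_walk" && is.null(rw_sd)) {
    scales <- if (mass$type == "diag") sqrt(1 / mass$M)
              else sqrt(diag(mass$Minv))
    rw_sd <- sqrt(2.4^2 / N) * scales
  }
  if (!is.null(rw_sd)) rw_sd <- rep_len(rw_sd, N)

  n_div_burn <- 0L
  for (it in seq_len(n_it)) {
    if (kernel == "hmc") {
      st <- hmc_draw(z, U_z, target, eps, config$n_leapfrog, mass,
                     config$div_threshold, grad_z = g_z)
    } else if (kernel == "nuts") {
      st <- nuts_draw(z, U_z, target, eps, mass, config$max_tree_depth,
                      config$div_threshold, grad_z = g_z)
    } else {
      zp <- z + rnorm(N, 0, rw_sd)
      Up <- target$U(zp)
      a <- if (is.finite(Up)) min(1, exp(U_z - Up)) else 0
      if (runif(1) < a) {
        st <- list(z = zp, U = Up, grad = NULL, accepted = TRUE,
                   dH = Up - U_z, accept_stat = a, divergent = FALSE)
      } else {
        st <- list(z = z, U = U_z, grad = NULL, accepted = FALSE,
                   dH = Up - U_z, accept_stat = a, divergent = FALSE)
      }
    }
    z <- st$z; U_z <- st$U
    if (!is.null(st$grad)) g_z <- st$grad
    draws[it, ] <- z
    accepted[it] <- st$accepted
    dH[it] <- st$dH
    divergent[it] <- st$divergent
    accept_stat[it] <- st$accept_stat
    eps_trace[it] <- eps
    if (adapting && it <= config$n_burn_in) {
      da <- dual_averaging_update(da, st$accept_stat)
      eps <- da$eps
      if (it == config$n_burn_in) eps <- exp(da$log_eps_bar)
    }
    if (it <= config$n_burn_in && st$divergent) {
      n_div_burn <- n_div_burn + 1L
      if (n_div_burn >= config$n_burn_in && config$n_burn_in > 0)
        stop("all burn-in iterations diverged; reduce the step size ",
             "or check the gradients")
    }
  }
  structure(list(draws = draws, accepted = accepted, dH = dH,
                 step_size = eps_trace, divergent = divergent,
                 accept_stat = accept_stat,
                 burn_in = config$n_burn_in, kernel = kernel,
                 param_names = target$param_names,
                 transform = target$transform, seed = config$seed,
                 final_step_size = eps, mass = mass, config = config),
            class = "hmc_chain")
}

#' @export
print.hmc_chain <- function(x, ...) {
  n <- nrow(x$draws)
  cat("<hmc_chain> kernel =", x$kernel, "|", n, "iterations (burn-in",
      x$burn_in, ") |", ncol(x$draws), "parameters\n")
  cat("  acceptance rate:",
      round(mean(x$accepted[(x$burn_in + 1):n]), 3),
      "| divergences:", sum(x$divergent), "\n")
  invisible(x)
}

#' Post-burn-in draws of a chain as a tibble
#'
#' @param chain An `hmc_chain`.
#' @param scale `"physical"` back-transforms the draws through the chain's
#'   parameter transform (when one is attached); `"sampling"` returns the raw
#'   unconstrained draws.
#' @param include_burn_in Keep the burn-in segment?
#' @return A tibble with an `.iteration` column and one column per parameter.
#' @export
chain_draws <- function(chain, scale = c("physical", "sampling"),
                        include_burn_in = FALSE) {
  scale <- match.arg(scale)
  idx <- if (include_burn_in) seq_len(nrow(chain$draws))
         else (chain$burn_in + 1):nrow(chain$draws)
  d <- chain$draws[idx, , drop = FALSE]
  if (scale == "physical" && !is.null(chain$transform)) {
    ph <- apply(d, 1, to_physical, transform = chain$transform)
    d <- if (is.matrix(ph)) t(ph) else matrix(ph, ncol = 1)
    colnames(d) <- chain$param_names
  }
  out <- tibble::as_tibble(as.data.frame(d))
  tibble::add_column(out, .iteration = idx, .before = 1)
}
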