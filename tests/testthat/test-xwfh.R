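test_that("cubic B-spline basis is a partition of unity with the right size", {
  b <- cbs_basis(30, 831)
  z <- seq(0, 831, length.out = 200)
  B <- b$eval(z)
  expect_equal(dim(B), c(200, 30))
  expect_true(all(B >= 0))
  expect_equal(rowSums(B), rep(1, 200), tolerance = 1e-12)
})

test_that("spline density is flat for equal coefficients and linear in them", {
  b <- cbs_basis(20, 500)
  z <- seq(50, 450, length.out = 50)
  phi_flat <- cbs_density(rep(0.02, 20), b, d_au = 7)
  v <- phi_flat(z)
  expect_lt(diff(range(v)) / mean(v), 1e-10)

  a <- rep(0, 20); a[9] <- 0.01
  phi1 <- cbs_density(a, b, d_au = 7)
  phi2 <- cbs_density(2 * a, b, d_au = 7)
  expect_equal(phi2(z), 2 * phi1(z))
  # single coefficient -> single localised bump near its knot centre
  zf <- seq(0, 500, length.out = 1000)
  prof <- phi1(zf)
  expect_equal(sum(diff(sign(diff(prof))) == -2), 1)

  # doubling d_au doubles the integrated density
  phi_d <- cbs_density(a, b, d_au = 14)
  expect_equal(sum(phi_d(zf)), 2 * sum(phi1(zf)), tolerance = 1e-12)
})

test_that("standing-wave field has the free-space and evanescent limits", {
  # vacuum everywhere: |E|^2 = 1 at any angle (no reflection)
  vac <- list(z = seq(0.5, 99.5), rho = rep(0, 100), dz = 1,
              ambient_rho = 0, substrate_rho = 0)
  f <- field_intensity_depth(vac, c(0.1, 0.5), 12.1)
  expect_equal(max(abs(f$e2 - 1)), 0, tolerance = 1e-10)
  expect_equal(f$r2, c(0, 0), tolerance = 1e-12)

  # below the substrate critical angle: evanescent decay with depth
  si <- list(z = seq(0.5, 199.5), rho = rep(0.6987, 200), dz = 1,
             ambient_rho = 0, substrate_rho = 0.6987)
  qc_ang <- sqrt(2 * xray_dispersion(0.6987, xray_wavelength(12.1)))
  fs <- field_intensity_depth(si, 0.5 * qc_ang * 180 / pi, 12.1)
  prof <- fs$e2[, 1]
  expect_true(all(diff(prof) < 0))
  expect_lt(prof[200] / prof[1], 1e-2)
  expect_equal(fs$r2, 1, tolerance = 1e-9)
})

test_that("energy flux is conserved through a non-absorbing stack", {
  slabs <- list(z = NULL, rho = c(rep(0.33, 150), rep(0.32, 150)), dz = 2,
                ambient_rho = 0, substrate_rho = 0.6987)
  ang <- seq(0.35, 1.2, length.out = 15)   # above the Si critical angle
  f <- field_intensity_depth(slabs, ang, 12.1)
  expect_equal(f$r2 + f$tflux, rep(1, 15), tolerance = 1e-8)
})

test_that("hologram endpoints, non-negativity and linearity in the profile", {
  geom <- xwfh_geometry()
  nb <- 12
  a <- setNames(rep(0, nb), paste0("a_", seq_len(nb)))
  a["a_5"] <- 0.01
  base <- c(I0 = 0.1, z_offset = 15.7, sigma_air_ps = 30, d_ps = 222,
            sigma_ps_ptba = 20, d_ptba = 609, d_au = 7, f_elastic = 0, a)
  pix <- seq(30, 160, by = 4)
  I_f <- hologram_intensity(base, geom, pix, n_basis = nb, dz = 4)
  expect_true(all(I_f >= 0))

  # doubling the coefficients doubles the pure-fluorescence signal in the
  # perturbative regime (a thin emitter barely alters the waveguide field;
  # a thick gold layer feeds back on it through the density profile)
  thin <- base; thin["d_au"] <- 0.05
  I_thin <- hologram_intensity(thin, geom, pix, n_basis = nb, dz = 4)
  p2 <- thin
  p2[paste0("a_", seq_len(nb))] <- 2 * a
  expect_equal(hologram_intensity(p2, geom, pix, n_basis = nb, dz = 4),
               2 * I_thin, tolerance = 2e-3)

  # f_elastic = 1: pure elastic background, independent of the coefficients
  # beyond the integrated-density normalisation
  p_el <- base; p_el["f_elastic"] <- 1
  I_el <- hologram_intensity(p_el, geom, pix, n_basis = nb, dz = 4)
  expect_true(all(I_el >= 0))
  expect_gt(max(abs(I_el / max(I_el) - I_f / max(I_f))), 1e-3)

  # pixels at or below z_offset have no exit path
  expect_equal(hologram_intensity(base, geom, c(10, 15), n_basis = nb,
                                  dz = 4), c(0, 0))
})

test_that("a monolayer at an exit-field antinode outshines one at a node", {
  geom <- xwfh_geometry()
  nb <- 40  # fine spline spacing so the layer is thin against the
            # standing-wave period
  base <- c(I0 = 1, z_offset = 0, sigma_air_ps = 5, d_ps = 222,
            sigma_ps_ptba = 5, d_ptba = 609, d_au = 0.5, f_elastic = 0,
            setNames(rep(0, nb), paste0("a_", seq_len(nb))))
  # pick one exit angle and locate the antinode/node of the exit field
  # with a direct field evaluation (the quadrature oracle)
  af <- 0.30
  slabs <- hmcscatter:::xwfh_rho_slabs(base, geom, dz = 2)
  film <- slabs$z > 50 & slabs$z < 780
  e_exit <- field_intensity_depth(slabs, af, geom$lines$energy_keV[1])$e2[, 1]
  e_inc <- field_intensity_depth(slabs, geom$alpha_i_deg,
                                 geom$energy_keV)$e2[, 1]
  prod_field <- e_inc * e_exit
  z_anti <- slabs$z[film][which.max(prod_field[film])]
  z_node <- slabs$z[film][which.min(prod_field[film])]
  pix <- af / geom$pixel_scale_deg   # z_offset = 0
  b <- cbs_basis(nb, 831)
  mk <- function(z0) {
    # coefficients approximating a delta layer at depth z0
    a <- drop(b$eval(z0))
    p <- base
    p[paste0("a_", seq_len(nb))] <- a
    p
  }
  I_anti <- hologram_intensity(mk(z_anti), geom, pix, n_basis = nb, dz = 2)
  I_node <- hologram_intensity(mk(z_node), geom, pix, n_basis = nb, dz = 2)
  expect_gt(I_anti, I_node * 1.5)
})

test_that("xwfh model predicts finite positive holograms at the truth", {
  spec <- xwfh_table3_spec(seed = 2)
  f <- spec$model$predict(spec$truth, spec$abscissa)
  expect_true(all(is.finite(f)))
  expect_true(all(f > 0))
  # angle-dependent fringes: multiple local maxima across the exit angles
  expect_gt(sum(diff(sign(diff(f))) == -2), 2)
})

test_that("scaled hologram recovery pins the gold depth and the total
           thickness more tightly than the individual layers", {
  # small instance of the monolayer regime: 12 splines, coarse slabs, only
  # the two polymer thicknesses and the residual variance free; basic HMC
  # with fixed step size 0.05 and ten leaps per iteration
  geom <- xwfh_geometry()
  m <- xwfh_model(geom, n_basis = 12, dz = 4)
  a <- setNames(rep(0, 12), paste0("a_", 1:12))
  a["a_4"] <- 0.01
  truth <- c(I0 = 0.12, z_offset = 15.7, sigma_air_ps = 30, d_ps = 222,
             sigma_ps_ptba = 20, d_ptba = 609, d_au = 7,
             f_elastic = 1e-9, a, sigma2 = 6e-4)
  spec <- synthetic_spec(m, truth, seq(26, 170, by = 4), seed = 71)
  ds <- simulate_dataset(spec)
  fixed <- truth[setdiff(names(truth), c("d_ps", "d_ptba", "sigma2"))]
  init <- c(d_ps = 230, d_ptba = 600, sigma2 = 2e-3)
  r0 <- log(ds$observed) -
    log(m$predict(c(init, fixed), ds$abscissa))
  init["sigma2"] <- mean(r0^2)
  # ten leaps per iteration as in the full-scale analysis; the step size
  # starts at 0.05 and is dual-averaged, which this stiffer scaled-down
  # posterior needs for stability
  cfg <- sampler_config(n_iterations = 200, n_burn_in = 80, seed = 72,
                        step_size = 0.05, n_leapfrog = 10,
                        mass_strategy = "gradient_scaled_diag")
  fit <- fit_hmc(ds, m, init, fixed = fixed, kernel = "hmc", config = cfg)
  s <- tidy(fit)
  tr <- attr(ds, "truth")
  for (par in c("d_ps", "d_ptba")) {
    row <- s[s$term == par, ]
    expect_lt(abs(row$mean - tr[[par]]), 4 * row$sd)
  }
  # the film total is better determined than either layer alone
  d <- chain_draws(fit$chain)
  rel <- function(x) sd(x) / mean(x)
  expect_lt(rel(d$d_ps + d$d_ptba), rel(d$d_ps))
  expect_lt(rel(d$d_ps + d$d_ptba), rel(d$d_ptba))
  expect_lt(cor(d$d_ps, d$d_ptba), 0)
})
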