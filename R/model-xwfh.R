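#' Cubic B-spline basis on uniform knots
#'
#' `n_basis` cubic B-splines on uniform knots spanning `[0, depth]`, the
#' flexible nonparametric representation used for the buried-emitter number
#' density. Interior splines form a partition of unity and the basis is
#' twice continuously differentiable.
#'
#' @param n_basis Number of basis functions (>= 4).
#' @param depth Film depth spanned (Angstrom).
#' @return List with `knots`, `n_basis`, `depth`, `spacing` and an
#'   `eval(z)` closure returning the `length(z) x n_basis` design matrix.
#' @export
cbs_basis <- function(n_basis = 30L, depth) {
  stopifnot(n_basis >= 4, depth > 0)
  h <- depth / (n_basis - 3)
  knots <- h * seq(-3, n_basis)
  ev <- function(z) splines::splineDesign(knots, z, ord = 4, outer.ok = TRUE)
  list(knots = knots, n_basis = as.integer(n_basis), depth = depth,
       spacing = h, eval = ev)
}

# bulk gold atomic number density (atoms / Angstrom^3)
.rho_au_atoms <- 0.05901

#' Gold number-density depth profile from spline coefficients
#'
#' `phi_au(z) = N_au sum_k a_k B_k(z)` with the normalisation `N_au` set so
#' that a unit coefficient sum corresponds to a nominal pure-gold layer of
#' thickness `d_au`: `integral(phi) = d_au * rho_bulk * sum(a)` (with the
#' bulk gold atom density 0.059 atoms/Angstrom^3). The profile is linear in
#' the coefficients, and doubling `d_au` doubles the integrated density.
#'
#' @param a Coefficient vector of length `basis$n_basis` (may be negative;
#'   non-negativity can be enforced during sampling by momentum reflection).
#' @param basis A [cbs_basis()].
#' @param d_au Nominal pure-gold thickness (Angstrom).
#' @return Function `phi(z)` returning atoms/Angstrom^3.
#' @export
cbs_density <- function(a, basis, d_au) {
  stopifnot(length(a) == basis$n_basis, d_au >= 0)
  scale <- d_au * .rho_au_atoms / basis$spacing
  function(z) scale * drop(basis$eval(z) %*% a)
}

#' Standing-wave intensity versus depth
#'
#' Depth-resolved field intensity `|E(z)|^2` in a sliced multilayer at the
#' given grazing angle(s) and photon energy, computed by the dynamical
#' (transfer) theory with unit incident amplitude. Shares the slab machinery
#' of the reflectivity model; the electron-density slabs are converted to
#' dispersions at the requested wavelength.
#'
#' @param rho_slabs List with slab electron densities `rho` (top to bottom),
#'   midpoints `z`, slab thickness `dz`, and `ambient_rho` / `substrate_rho`.
#' @param angle_deg Grazing angle(s) in degrees.
#' @param energy_keV Photon energy.
#' @return List: `e2` (`n_slab x n_angle` matrix of `|E|^2`), `r2`
#'   (reflectivity), `tflux` (substrate-transmitted flux fraction), `z`.
#' @export
field_intensity_depth <- function(rho_slabs, angle_deg, energy_keV) {
  lambda <- xray_wavelength(energy_keV)
  res <- cpp_efield(as.numeric(angle_deg) * pi / 180, lambda,
                    xray_dispersion(rho_slabs$rho, lambda),
                    rep(0, length(rho_slabs$rho)), rho_slabs$dz,
                    xray_dispersion(rho_slabs$ambient_rho, lambda), 0,
                    xray_dispersion(rho_slabs$substrate_rho, lambda), 0)
  res$z <- rho_slabs$z
  res
}

#' Waveguide geometry for fluorescence holography
#'
#' Fixed experiment-side quantities of the thin-film waveguide: grazing
#' incidence angle, incident energy, fluorescence line groups (representative
#' energy and relative emission weight, overridable), the buried-stack
#' composition beneath the polymer film (Pd/Cr on Si, nominal values held
#' fixed), and the linear pixel-to-exit-angle mapping.
#'
#' @param alpha_i_deg Grazing incidence angle (degrees).
#' @param energy_keV Incident (elastic) energy.
#' @param lines Tibble with `name`, `energy_keV`, `weight` of the
#'   fluorescence line groups (weights renormalised to unit sum).
#' @param d_pd,d_cr Pd and Cr layer thicknesses (Angstrom).
#' @param pixel_scale_deg Exit-angle increment per detector pixel.
#' @export
xwfh_geometry <- function(alpha_i_deg = 0.125, energy_keV = 12.1,
                          lines = tibble::tibble(
                            name = c("La12", "Lb215"),
                            energy_keV = c(9.671, 11.576),
                            weight = c(0.84, 0.16)),
                          d_pd = 200, d_cr = 50,
                          pixel_scale_deg = 0.00986) {
  lines$weight <- lines$weight / sum(lines$weight)
  list(alpha_i_deg = alpha_i_deg, energy_keV = energy_keV, lines = lines,
       d_pd = d_pd, d_cr = d_cr, pixel_scale_deg = pixel_scale_deg,
       rho_ps = .rho_e[["ps"]], rho_ptba = .rho_e[["ptba"]],
       rho_pd = .rho_e[["pd"]], rho_cr = .rho_e[["cr"]],
       rho_si = .rho_e[["silicon"]], sigma_deep = 5)
}

# electron-density slabs of the full waveguide (air / PS / PtBA / Pd / Cr /
# Si) including the gold contribution; phi_fun may be NULL
xwfh_rho_slabs <- function(p, geom, dz, phi_fun = NULL) {
  sig <- c(p[["sigma_air_ps"]], p[["sigma_ps_ptba"]],
           rep(geom$sigma_deep, 3))
  prof <- slab_profile_fast(
    h = c(p[["d_ps"]], p[["d_ptba"]], geom$d_pd, geom$d_cr),
    amp_layers = c(geom$rho_ps, geom$rho_ptba, geom$rho_pd, geom$rho_cr),
    sig = sig[1:4], sig_sub = sig[5], amb = 0, sub = geom$rho_si, dz = dz)
  if (is.null(prof)) return(NULL)
  rho <- prof$amp                       # amplitudes here are densities
  if (!is.null(phi_fun)) rho <- rho + 79 * phi_fun(prof$z)
  list(z = prof$z, rho = rho, dz = dz, ambient_rho = 0,
       substrate_rho = geom$rho_si)
}

#' Exit-angle-resolved fluorescence hologram
#'
#' Simplified reciprocity form of the hologram intensity: the fluorescence
#' yield at exit angle `alpha_f` is the depth integral of the product of the
#' incident standing-wave intensity (at the fixed grazing angle and elastic
#' energy) and the exit standing-wave intensity (at `alpha_f` and the line
#' energy), weighted by the gold number density, summed incoherently over
#' the line groups; plus an elastic background term of the same form with
#' the total electron density in place of the gold density, normalised to a
#' comparable integrated weight. `f_elastic` mixes the two contributions:
#'
#' `I(af) = I0 [ (1 - f) sum_l w_l int |E_i(z)|^2 |E_l(z; af)|^2 phi(z) dz
#'             + f B(af) ]`
#'
#' @param params Named physical parameter vector: `I0`, `z_offset` (pixels),
#'   `sigma_air_ps`, `d_ps`, `sigma_ps_ptba`, `d_ptba`, `d_au`, `f_elastic`
#'   and spline coefficients `a_1..a_n`.
#' @param geometry An [xwfh_geometry()].
#' @param pixels Detector pixel indices (mapped to exit angles through
#'   `z_offset` and the pixel scale).
#' @param n_basis Number of spline coefficients expected in `params`.
#' @param dz Slab thickness (Angstrom).
#' @export
hologram_intensity <- function(params, geometry, pixels, n_basis = 30L,
                               dz = 2) {
  p <- params
  D <- p[["d_ps"]] + p[["d_ptba"]]
  if (!is.finite(D) || D <= 0) return(rep(NaN, length(pixels)))
  a <- unname(p[paste0("a_", seq_len(n_basis))])
  basis <- cbs_basis(n_basis, D)
  phi <- cbs_density(a, basis, p[["d_au"]])
  slabs <- xwfh_rho_slabs(p, geometry, dz, phi)
  if (is.null(slabs)) return(rep(NaN, length(pixels)))
  phi_z <- pmax(phi(slabs$z), 0)

  alpha_f <- (pixels - p[["z_offset"]]) * geometry$pixel_scale_deg
  ok <- alpha_f > 1e-4
  out <- numeric(length(pixels))
  if (!any(ok)) return(out)
  af <- alpha_f[ok]

  e_inc <- field_intensity_depth(slabs, geometry$alpha_i_deg,
                                 geometry$energy_keV)$e2[, 1]
  fluor <- 0
  for (l in seq_len(nrow(geometry$lines))) {
    e_out <- field_intensity_depth(slabs, af,
                                   geometry$lines$energy_keV[l])$e2
    fluor <- fluor + geometry$lines$weight[l] *
      drop(crossprod(e_out, e_inc * phi_z)) * slabs$dz
  }
  f_el <- p[["f_elastic"]]
  elastic <- 0
  if (f_el > 0) {
    e_el <- field_intensity_depth(slabs, af, geometry$energy_keV)$e2
    b <- drop(crossprod(e_el, e_inc * slabs$rho)) * slabs$dz
    # normalise the all-atoms term to the gold-integrated weight so the
    # mixture fraction compares like with like
    b <- b * sum(phi_z) / max(sum(slabs$rho), 1e-12)
    elastic <- b
  }
  out[ok] <- p[["I0"]] * ((1 - f_el) * fluor + f_el * elastic)
  out
}

#' XWFH forward model
#'
#' Forward model of the one-dimensional fluorescence hologram from a buried
#' gold layer inside a polymer waveguide (PS cap / gold / PtBA on Pd/Cr/Si),
#' with the gold depth profile parameterised by cubic B-spline coefficients.
#' Free parameters: `I0`, `z_offset` (pixels, identity transform),
#' `sigma_air_ps`, `d_ps`, `sigma_ps_ptba`, `d_ptba`, `d_au` (positive, log
#' transform), `f_elastic` (logit on `[0, 1]`), and unconstrained spline
#' coefficients `a_1..a_n`.
#'
#' @param geometry An [xwfh_geometry()].
#' @param n_basis Number of spline coefficients.
#' @param dz Slab thickness (Angstrom).
#' @export
xwfh_model <- function(geometry = xwfh_geometry(), n_basis = 30L, dz = 2) {
  an <- paste0("a_", seq_len(n_basis))
  pn <- c("I0", "z_offset", "sigma_air_ps", "d_ps", "sigma_ps_ptba",
          "d_ptba", "d_au", "f_elastic", an)
  kinds <- c(I0 = "log", z_offset = "identity", sigma_air_ps = "log",
             d_ps = "log", sigma_ps_ptba = "log", d_ptba = "log",
             d_au = "log", f_elastic = "logit",
             setNames(rep("identity", n_basis), an))
  lower <- ifelse(kinds == "logit", 0, -Inf)
  upper <- ifelse(kinds == "logit", 1, Inf)
  predict_fun <- function(params, abscissa) {
    hologram_intensity(params, geometry, abscissa, n_basis, dz)
  }
  structure(list(name = "xwfh_gold_monolayer", param_names = pn,
                 transform_kinds = kinds, lower = unname(lower),
                 upper = unname(upper), predict = predict_fun,
                 geometry = geometry, n_basis = as.integer(n_basis),
                 dz = dz, multiplicative_scale = TRUE),
            class = c("xwfh_model", "scatter_model"))
}
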