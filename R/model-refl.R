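#' X-ray dispersion of a medium
#'
#' Real decrement `delta` of the refractive index `n = 1 - delta + i beta`,
#' from the electron density: `delta = r_e lambda^2 rho_e / (2 pi)` with the
#' classical electron radius `r_e = 2.81794e-5` Angstrom.
#'
#' @param rho_e Electron density (electrons / Angstrom^3).
#' @param lambda X-ray wavelength (Angstrom).
#' @export
xray_dispersion <- function(rho_e, lambda) {
  2.81794e-5 * lambda^2 * rho_e / (2 * pi)
}

#' Wavelength from photon energy
#' @param energy_keV Photon energy in keV.
#' @return Wavelength in Angstrom.
#' @export
xray_wavelength <- function(energy_keV) 12.39842 / energy_keV

# electron densities (e / Angstrom^3) of common media at their bulk density
.rho_e <- c(water = 0.3344, silicon = 0.6987, ps = 0.3386, ptba = 0.3220,
            pd = 3.1313, cr = 2.0055, gold_atoms = 79)

# smeared step: 0 far above the interface, 1 far below (z increasing into
# the film); sharp step in the sigma -> 0 limit. pnorm((z-z0)/sigma) is the
# erf-smeared interface, 0.5 * (1 + erf((z - z0) / (sigma sqrt(2)))).
smooth_step <- function(z, z0, sigma) {
  if (sigma < 1e-12) return(as.numeric(z > z0) + 0.5 * (z == z0))
  pnorm((z - z0) / sigma)
}

# slab dispersion profile without container overhead: the hot path used by
# model predictions inside the sampler
slab_profile_fast <- function(h, amp_layers, sig, sig_sub, amb, sub, dz,
                              ext = 4) {
  zi <- c(0, cumsum(h))
  sigs <- c(sig, sig_sub)
  sig_max <- max(sigs, 1e-3)
  z_top <- -ext * sig_max
  z_bot <- zi[length(zi)] + ext * sig_max
  n <- max(1L, ceiling((z_bot - z_top) / dz))
  # absurd geometries (runaway thickness/roughness proposals) are signalled
  # to the likelihood as non-finite rather than allocated
  if (!is.finite(n) || n > 2e5) return(NULL)
  z <- z_top + (seq_len(n) - 0.5) * dz
  steps <- vapply(seq_along(zi),
                  function(i) smooth_step(z, zi[i], sigs[i]), numeric(n))
  w <- cbind(1 - steps[, 1],
             steps[, -ncol(steps), drop = FALSE] -
               steps[, -1, drop = FALSE],
             steps[, ncol(steps)])
  w[w < 0] <- 0
  amp <- c(amb, amp_layers, sub)
  list(z = z, amp = drop((w / rowSums(w)) %*% amp))
}

#' Multilayer stack for specular reflectivity
#'
#' Ordered ambient -> layers (top to bottom) -> substrate. Each layer carries
#' a thickness, a dispersion, and the roughness of its upper interface; the
#' substrate roughness applies to the lowest interface.
#'
#' @param layers Tibble/data frame with columns `thickness`, `dispersion`,
#'   `roughness` (Angstrom, dimensionless, Angstrom), top to bottom.
#' @param ambient,substrate Ambient and substrate dispersions.
#' @param substrate_roughness Roughness of the layer/substrate interface
#'   (Angstrom).
#' @export
layer_stack <- function(layers, ambient, substrate, substrate_roughness) {
  layers <- tibble::as_tibble(layers)
  stopifnot(nrow(layers) >= 1,
            all(c("thickness", "dispersion", "roughness") %in% names(layers)),
            all(layers$thickness >= 0), all(layers$roughness >= 0),
            substrate_roughness >= 0)
  structure(list(layers = layers, ambient = ambient, substrate = substrate,
                 substrate_roughness = substrate_roughness),
            class = "layer_stack")
}

# weights of each medium (ambient, layers..., substrate) at depths z;
# columns sum to one at every z by construction (telescoping erf steps)
stack_weights <- function(stack, z) {
  h <- stack$layers$thickness
  zi <- c(0, cumsum(h))                          # interface depths
  sig <- c(stack$layers$roughness, stack$substrate_roughness)
  n_med <- length(h) + 2L
  w <- matrix(0, length(z), n_med)
  steps <- vapply(seq_along(zi),
                  function(i) smooth_step(z, zi[i], sig[i]),
                  numeric(length(z)))
  w[, 1] <- 1 - steps[, 1]
  for (j in seq_along(h)) w[, j + 1] <- steps[, j] - steps[, j + 1]
  w[, n_med] <- steps[, length(zi)]
  # guard against slightly negative weights when roughness ~ thickness
  w[w < 0] <- 0
  w / rowSums(w)
}

#' Effective-density dispersion profile
#'
#' Builds the continuous smeared profile `delta(z)` induced by box layer
#' parameters: each interface is smeared by an error function with that
#' interface's roughness, and the per-medium weights are renormalised to sum
#' to one at every depth. Unlike a Debye-Waller-type damping factor, this
#' construction stays valid when the roughness is comparable to the layer
#' thickness, letting a layer's material penetrate deep into its neighbours.
#'
#' @param stack A [layer_stack()].
#' @param z Depth grid (Angstrom, increasing into the film; 0 at the
#'   ambient-side interface).
#' @return Tibble with columns `z` and `delta`.
#' @export
effective_density_profile <- function(stack, z) {
  amp <- c(stack$ambient, stack$layers$dispersion, stack$substrate)
  w <- stack_weights(stack, z)
  tibble::tibble(z = z, delta = drop(w %*% amp))
}

#' Slice a stack into uniform slabs
#'
#' Discretises the effective-density profile into slabs of thickness `dz`
#' over a window extending `ext` times the largest roughness beyond the
#' outermost interfaces.
#'
#' @inheritParams effective_density_profile
#' @param dz Slab thickness (Angstrom).
#' @param ext Window extension in multiples of the maximum roughness.
#' @return List with slab midpoints `z`, slab dispersions `delta`, `dz`, and
#'   the ambient/substrate dispersions.
#' @export
slice_stack <- function(stack, dz = 0.5, ext = 4) {
  sig_max <- max(stack$layers$roughness, stack$substrate_roughness, 1e-3)
  z_top <- -ext * sig_max
  z_bot <- sum(stack$layers$thickness) + ext * sig_max
  n <- max(1L, ceiling((z_bot - z_top) / dz))
  z_mid <- z_top + (seq_len(n) - 0.5) * dz
  prof <- effective_density_profile(stack, z_mid)
  list(z = z_mid, delta = prof$delta, dz = dz,
       ambient = stack$ambient, substrate = stack$substrate)
}

#' Dynamical reflectivity of a sliced profile
#'
#' Recursive Fresnel-coefficient (Parratt) reflectivity computed from the
#' substrate upward over the uniform slabs, returning `|r|^2`. `q` is the
#' wave-vector transfer in the ambient, `q = 4 pi sin(theta) / lambda`.
#'
#' @param slabs A slab list from [slice_stack()] (or a hand-built one with
#'   elements `delta`, `dz`, `ambient`, `substrate`).
#' @param q Wave-vector transfer values (1/Angstrom, positive).
#' @param lambda Wavelength (Angstrom).
#' @param beta,beta_ambient,beta_substrate Optional absorption indices
#'   (imaginary part of the refractive index), zero by default.
#' @export
parratt_reflectivity <- function(slabs, q, lambda, beta = NULL,
                                 beta_ambient = 0, beta_substrate = 0) {
  stopifnot(all(q > 0))
  nb <- length(slabs$delta)
  if (is.null(beta)) beta <- rep(0, nb)
  cpp_parratt(as.numeric(q), as.numeric(slabs$delta), rep_len(beta, nb),
              slabs$dz, slabs$ambient, beta_ambient,
              slabs$substrate, beta_substrate, lambda)
}

#' Reflectivity curve of a layer stack
#'
#' Composition of [effective_density_profile()], [slice_stack()] and
#' [parratt_reflectivity()], scaled by the intensity factor `I0`.
#'
#' @inheritParams parratt_reflectivity
#' @param stack A [layer_stack()].
#' @param I0 Intensity scale.
#' @param dz Slab thickness (a warning is issued if `dz` exceeds the
#'   smallest layer thickness).
#' @export
reflectivity_curve <- function(stack, q, lambda, I0 = 1, dz = 0.5) {
  h_min <- min(stack$layers$thickness[stack$layers$thickness > 0], Inf)
  if (dz > h_min)
    warning("slab thickness dz exceeds the thinnest layer; refine dz")
  I0 * parratt_reflectivity(slice_stack(stack, dz), q, lambda)
}

#' Reflectivity forward model: supported lipid bilayer in water
#'
#' Effective-density multilayer reflectivity for a silicon-supported bilayer
#' under water, in the cell geometry (beam through water; profile ordered
#' water -> layers -> Si). The three-layer preset has outer head (`o`),
#' hydrocarbon tail (`t`) and inner head (`i`) layers; the four-layer preset
#' adds a water cushion (`w`) between inner head and substrate. Parameters
#' per layer `x`: thickness `h_x` (Angstrom), dispersion `delta_x`, upper
#' interface roughness `sigma_x`; plus the substrate roughness `sigma_Si`
#' and intensity scale `I0`. All parameters are positive and sampled on the
#' log scale.
#'
#' @param n_layers 3 or 4.
#' @param energy_keV Photon energy (default 20 keV).
#' @param dz Slab thickness for the dynamical calculation (Angstrom).
#' @param ambient_rho_e,substrate_rho_e Electron densities of ambient water
#'   and Si substrate.
#' @export
refl_model <- function(n_layers = 3L, energy_keV = 20, dz = 0.5,
                       ambient_rho_e = .rho_e[["water"]],
                       substrate_rho_e = .rho_e[["silicon"]]) {
  stopifnot(n_layers %in% c(3L, 4L))
  lambda <- xray_wavelength(energy_keV)
  amb <- xray_dispersion(ambient_rho_e, lambda)
  sub <- xray_dispersion(substrate_rho_e, lambda)
  tags <- if (n_layers == 3L) c("o", "t", "i") else c("o", "t", "i", "w")
  pn <- c("I0", "sigma_Si",
          paste0("h_", tags), paste0("delta_", tags), paste0("sigma_", tags))
  predict_fun <- function(params, abscissa) {
    p <- params[pn]
    if (any(!is.finite(p)) || any(p <= 0)) return(rep(NaN, length(abscissa)))
    prof <- slab_profile_fast(unname(p[paste0("h_", tags)]),
                              unname(p[paste0("delta_", tags)]),
                              unname(p[paste0("sigma_", tags)]),
                              unname(p[["sigma_Si"]]), amb, sub, dz)
    if (is.null(prof)) return(rep(NaN, length(abscissa)))
    p[["I0"]] * cpp_parratt(abscissa, prof$amp, rep(0, length(prof$amp)),
                            dz, amb, 0, sub, 0, lambda)
  }
  structure(list(name = paste0("refl_bilayer_", n_layers, "layer"),
                 param_names = pn,
                 transform_kinds = setNames(rep("log", length(pn)), pn),
                 predict = predict_fun, lambda = lambda, dz = dz,
                 ambient = amb, substrate = sub, tags = tags,
                 multiplicative_scale = TRUE),
            class = c("refl_model", "scatter_model"))
}

#' Default reflectivity synthetic q grid
#'
#' 200 linear points in `[0.02, 0.60]` 1/Angstrom (20 keV regime).
#' @param n Number of points.
#' @param q_min,q_max Range in 1/Angstrom.
#' @export
refl_q_grid <- function(n = 200L, q_min = 0.02, q_max = 0.60) {
  seq(q_min, q_max, length.out = n)
}
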