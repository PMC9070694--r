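# hmcscatter

Hamiltonian Monte Carlo parameter estimation for X-ray scattering models.

Model-based analysis of X-ray scattering data is an inverse problem:
a physical forward model — scattering from polydisperse nanoparticles,
specular reflectivity of a layered film, an exit-angle-resolved
fluorescence hologram from a buried emitter — is fit to a measured
one-dimensional curve, and the experimenter needs not just the best-fit
parameters but their uncertainties, their correlations, and the confidence
of the predicted curve. Random-walk Markov chain Monte Carlo gives all of
that in principle but stalls as the parameter count grows. `hmcscatter`
implements the gradient-based alternative for this setting: Hamiltonian
Monte Carlo with leapfrog integration, the No-U-Turn sampler, dual-averaging
step-size adaptation and mass-matrix preconditioning, wired to Gaussian
residual likelihoods (with the residual variance as an unknown), parameter
transforms, and the chain diagnostics the workflow needs (autocorrelation,
effective sample size, significance tables, credible bands, correlation
matrices). It is aimed at scattering practitioners who want posterior-based
uncertainty and model assessment without leaving R.

## The method in brief

Parameters `x` are augmented with a momentum `p ~ N(0, M)` and the pair is
evolved by the frictionless Hamiltonian dynamics of

    H(x, p) = U(x) + p' M^-1 p / 2,      U(x) = -log L(x),

integrated numerically with the time-reversible leapfrog scheme and
corrected by a Metropolis accept/reject with probability
`min{1, exp(H_old − H_new)}`. Energy conservation keeps acceptance high
while the momentum carries the chain to distant parts of parameter space,
so serial correlation is far lower than for random-walk proposals. The
No-U-Turn sampler removes the trajectory-length tuning by doubling the
trajectory until it starts to retrace. The likelihood is Gaussian in the
(log-)intensity residuals with a single unknown variance σ²; bounded
parameters are log- or logit-transformed, with the Jacobian included in the
potential so the implied prior is flat on the physical scale.

Three forward models ship with the package:

* `saxs_model()` — dilute polydisperse spheres: Gaussian size
  distribution, Gaussian q-resolution smearing, scattering-volume
  normalisation, scale and flat background;
* `refl_model()` — specular reflectivity of a silicon-supported lipid
  bilayer in water via the effective-density model (erf-smeared,
  renormalised layer profile, valid when roughness ≈ thickness) and exact
  Parratt recursion on the sliced profile;
* `xwfh_model()` — the fluorescence hologram of a buried gold layer in a
  polymer waveguide, with a cubic-B-spline depth profile and standing-wave
  fields from dynamical theory.

Heavy kernels (form-factor quadrature, Parratt recursion, depth-resolved
fields) are compiled (Rcpp); everything user-facing takes and returns
tibbles, and fitted objects support `tidy()`, `glance()` and `autoplot()`.

## Worked example

Recover the sphere parameters from a synthetic small-angle curve generated
in the published silica-sphere regime (100 log-spaced q points in
0.002–0.05 1/Å, log-normal noise), starting from a deliberately poor guess
(R = 500 Å, σR = 20 Å):

```r
library(hmcscatter)

spec <- saxs_table1_spec(seed = 7)        # truth: R = 757.7 Å, sigR = 59.5 Å
data <- simulate_dataset(spec)
fit  <- fit_hmc(data, spec$model, preset_init(spec, data),
                kernel = "nuts",
                config = sampler_config(n_iterations = 2000,
                                        n_burn_in = 500, seed = 3,
                                        step_size = 0.05))
tidy(fit)
#>     term      mean        sd  t_stat   p_value   ess ess_fraction
#> 1     I0 1.354e+00 8.272e-03 163.645 0.000e+00 541.0       0.3607
#> 2     Ib 1.981e-05 2.852e-07  69.455 0.000e+00 823.3       0.5488
#> 3      R 7.584e+02 8.843e-01 857.617 0.000e+00 337.8       0.2252
#> 4   sigR 5.896e+01 6.782e-01  86.936 0.000e+00 486.4       0.3243
#> 5   sigq 5.180e-05 3.257e-05   1.591 1.117e-01 186.6       0.1244
#> 6 sigma2 1.734e-03 2.665e-04   6.504 7.804e-11 531.1       0.3540
```

Every generating parameter is recovered within two posterior standard
deviations. The q-resolution width `sigq` comes out non-significant
(p = 0.11): the synthetic data cannot resolve it, so the model tells you it
can be dropped — the same model-assessment logic applies to redundant
layers in reflectivity fits, where a near ±1 thickness correlation in
`correlation_matrix(fit$chain)` flags an unresolvable pair. The
effective-sample-size fraction of 0.23 for `R` may be contrasted with a
matched-length random-walk chain (`kernel = "random_walk"`), which manages
about 0.002 on the same posterior.

`autoplot(fit, "trace")`, `autoplot(fit, "acf")` and
`autoplot(fit, "band")` draw the trace, autocorrelation and 95%
credible-band plots; `credible_band()` returns the band as a tibble.

A small command line (installed under `exec/`, or
`cli_main()` from R) covers simulation, fitting, diagnostics and the
HMC-versus-random-walk comparison:

```sh
hmcscatter simulate --preset saxs_table1 --seed 5 --out curve.tsv
hmcscatter fit --preset refl_table2 --seed 5 --out-dir results/
```

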