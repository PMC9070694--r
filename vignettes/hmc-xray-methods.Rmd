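---
title: "Hamiltonian Monte Carlo for X-ray scattering models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hamiltonian Monte Carlo for X-ray scattering models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmcscatter)
```

## The estimation problem

X-ray scattering curves — small-angle scattering intensities, specular
reflectivities, exit-angle-resolved fluorescence holograms — are fit by
physical forward models whose parameters (particle sizes, layer thicknesses,
roughnesses, dispersions) are what the experimenter actually wants.
`hmcscatter` treats this inverse problem by sampling the parameter posterior
with gradient-based Markov chain Monte Carlo, so that parameter
uncertainties, correlations and pointwise confidence bands of the model
curve all come out of one chain instead of a quadratic approximation around
a least-squares optimum.

The likelihood is Gaussian in the residuals between data and model on the
declared observation scale, with a single unknown residual variance
$\sigma^2$ treated as one more parameter:

$$\log L = \sum_j \left[ -\frac{(y_j - f_j(x))^2}{2\sigma^2}
  - \tfrac12 \log(2\pi\sigma^2) \right].$$

For intensity curves spanning several decades the residuals are formed on
the natural logarithm of the intensity (`obs_scale = "log"`), which is what
makes a single homoscedastic $\sigma^2$ a reasonable error model; any other
fixed logarithm base would only rescale $\sigma^2$. Per-point error columns
are supported as relative weights but default to the identical-error
treatment.

## Sampling scale, transforms and the implied prior

Bounded parameters are mapped to an unconstrained sampling scale: positive
parameters by $\log$, interval-bounded ones (the elastic fraction) by a
logit, and free ones (detector offset, spline coefficients) by the
identity. The potential energy sampled by the Hamiltonian dynamics is

$$U(z) = -\log L(\theta(z)) - \log\left|\frac{d\theta}{dz}\right|,$$

i.e. the change-of-variables Jacobian is included. The implied prior is
therefore flat on the *physical* scale, which keeps the procedure an
MLE-style analysis: the posterior density of $\sigma^2$ peaks exactly at
$\mathrm{SSR}/n$, and a positive parameter that the data cannot resolve
(such as the q-resolution width below the instrument's sensitivity) gets a
proper posterior that decays with the Jacobian instead of drifting to
$-\infty$ on the log scale. This choice is deliberate: a flat prior on the
transformed scale would drop the Jacobian term and make such posteriors
improper. MAP-style informative priors can be added through the target
density contract but are off by default.

## The sampler

The engine implements standard Hamiltonian Monte Carlo with the leapfrog
integrator (half momentum kick, position drift by $M^{-1}p$, half kick),
Metropolis correction $\min\{1, e^{H_\text{old} - H_\text{new}}\}$, and
three kernels:

* **`hmc`** — fixed number of leapfrog steps per iteration;
* **`nuts`** — the No-U-Turn sampler with binary trajectory doubling,
  slice-sampling candidate selection, and the U-turn stopping criterion,
  removing the choice of trajectory length (the original slice variant is
  implemented; maximum tree depth 10, divergence threshold
  $\Delta H > 1000$);
* **`random_walk`** — multivariate normal Metropolis, used as the
  efficiency baseline; its proposal covariance defaults to the mass-implied
  position scales times $2.4^2/N$.

The normalisation constant of the momentum density is dropped everywhere;
for a fixed mass matrix it cancels in the acceptance ratio. Divergent
trajectories (non-finite gradients or energy errors beyond the threshold)
are rejected with the state retained and counted, never fatal, except that
a burn-in consisting entirely of divergences aborts with a diagnostic.
Every run owns a single seeded generator, so chains are bit-reproducible
from the seed; multi-start exploration is a list of initial values with
consecutive seeds.

Step sizes adapt during burn-in only, by Nesterov dual averaging driving
the mean acceptance statistic to 0.8 (configurable), with the standard
constants $\gamma = 0.05$, $t_0 = 10$, $\kappa = 0.75$; after burn-in the
step is frozen at its averaged value. Burn-in length is user-specified —
the package deliberately includes no automatic convergence test, and trace
plots (`autoplot(fit, "trace")`) are the intended check.

### Preconditioning

A diagonal mass matrix sets the momentum scale per coordinate. Two
estimation strategies are provided: inverse sample variances of warm-up
draws, and a coarse scaling proportional to mean absolute potential
gradients at probe points, snapped to powers of 20 so that fast and slow
blocks of coordinates (e.g. the six high-gradient parameters of the
hologram model against its spline coefficients, 400 vs 1) get clearly
separated scales. Because a one-shot estimate from an unconverged chain is
unreliable, `fit_hmc()` refines the mass in windows: two short fixed-length
HMC segments whose second-half sample variances successively replace the
diagonal, then the main run with a final dual-averaging burn-in segment.
The windowed restart is what lets the badly scaled twelve-parameter
reflectivity posterior converge within a few hundred iterations; with a
single gradient-scaled estimate the same chain stalls. Variances are
floored at $10^{-6}$ (sampling scale) so a coordinate that has not yet
moved cannot freeze the next window.

Hard constraints can also be handled during integration by mirroring the
momentum about a constraint surface without energy loss
(`reflect_momentum()`), e.g. to enforce non-negative spline coefficients;
by default the coefficients are sampled unconstrained, since near-zero
coefficients with two-sided uncertainty are themselves informative.

### Gradients

Gradients of the potential are central finite differences per coordinate
with step $h_i = \max(10^{-5}, 10^{-5}|z_i|)$ and one-sided fallback at a
non-finite probe. Two coordinates short-circuit to closed forms: the
log-variance coordinate ($\partial U/\partial z = n/2 -
\mathrm{SSR}/2\sigma^2 - 1$) and, for purely multiplicative models on log
scale, the intensity-scale coordinate. Each leapfrog step therefore costs
about $2N_\text{curve}+1$ forward-model evaluations, which is why the
forward models are implemented in compiled code.

## Forward models

**Polydisperse spheres (SAXS).** Scattering from dilute spheres with a
normal size distribution (mean $R$, s.d. $\sigma_R$) convolved with a
normal q-resolution of width $\sigma_q$, normalised by
$\int P V^2\,dR'$ so the bracketed fraction tends to 1 as $q \to 0$, plus
a flat background. The size integral is Gauss–Legendre on
$R \pm 5\sigma_R$ truncated at $R' > 0$; the resolution integral is an
11-node normal-weighted kernel on $\pm 4\sigma_q$ (renormalised if nodes
are truncated at $q' \le 0$). The default 31 size nodes reproduce a
ten-fold denser rule to better than $10^{-4}$ relative over the default
grid (100 log-spaced points in $[0.002, 0.05]\,\mathrm{Å^{-1}}$, chosen to
cover several form-factor oscillations of $\sim$760 Å particles); both
counts are configurable and should be raised for substantially larger
particles. The $q \to 0$ limit of the form amplitude is handled by series
expansion.

**Effective-density reflectivity.** For layered films whose roughnesses
are comparable to the layer thicknesses, a Debye–Waller/Névot–Croce
damping factor on sharp boxes is no longer valid. Instead each interface
is smeared by an error function with its own roughness, per-layer weights
are renormalised to sum to one at every depth, and the resulting
continuous dispersion profile $\delta(z)$ is sliced into uniform slabs fed
to the dynamical (Parratt) recursion. The suite verifies the two regimes
explicitly: agreement with Névot–Croce boxes within 2% when $d \gg
\sigma$, material disagreement when $d \approx \sigma$. Slabs default to
$dz = 0.5$ Å over a window extending four maximal roughnesses beyond the
outer interfaces. Slicing error is second order in $dz$; at the default
the worst-case deviation from a converged curve is a few $10^{-3}$
relative, located at high-$q$ reflectivities below $10^{-7}$ — far below
the counting noise of any measured curve — while $dz \le 0.2$ Å reaches
$10^{-3}$ everywhere and is what the convergence test uses. Absorption is
omitted by default (layers are parameterised by dispersions only); the
slab interface accepts imaginary parts through a hook. The bilayer preset
(ambient water on top, then outer head, tail, inner head, silicon; a
four-layer variant adds a water cushion) works at 20 keV with dispersions
derived from bulk electron densities.

**Waveguide fluorescence hologram.** The gold number density buried in a
PS/PtBA film on Pd/Cr/Si is parameterised by 30 cubic B-spline
coefficients on uniform knots spanning the polymer film, normalised so a
unit coefficient sum corresponds to a nominal pure-gold thickness
$d_\text{au}$ at bulk atom density; the profile is linear in the
coefficients. The measured hologram intensity is reconstructed in
reciprocity form: the depth integral of incident standing-wave intensity
(fixed grazing angle, elastic energy) times exit standing-wave intensity
(exit angle, fluorescence line energy) times the gold density, summed
incoherently over the two L-line groups with tabulated relative emission
weights (0.84 : 0.16, overridable), plus an elastic term of the same form
with the total electron density, normalised to the gold-integrated weight
and mixed by `f_elastic`. The original publication presents the
fluorescence and elastic integrals only as display equations that are not
recoverable from the available text; this reciprocity form is a
reconstruction and is flagged as such — its qualitative behaviour
(standing-wave contrast, monolayer localisation, insensitivity to the
elastic fraction at right-angle detection) is what the tests pin down, not
equation-level equivalence. Fields are computed by the same dynamical
transfer machinery as the reflectivity model, including the gold's own
contribution to the density profile; consequently the hologram is exactly
linear in the coefficients only in the thin-emitter limit, which is how
the linearity test is phrased. The pixel-to-exit-angle map is linear with
a configurable scale (default 0.00986°/pixel) and a fitted offset, since
the true detector calibration behind the offset parameter is not
published.

## Synthetic data

`simulate_dataset()` draws $y_j = f_j(\theta^\ast)\,e^{\varepsilon_j}$,
$\varepsilon_j \sim N(0, \sigma^2)$, for log-scale models (additive
otherwise), reproducibly from a seed, and stores the generating truth with
the dataset. The presets carry the published posterior means as ground
truth: the SAXS sphere regime ($R = 757.7$ Å, $\sigma_R = 59.5$ Å,
$\sigma^2 = 1.78\times10^{-3}$, …), the three-layer bilayer regime at
20 keV (200 linear points in $[0.02, 0.6]\,\mathrm{Å^{-1}}$,
$\sigma^2 = 5.7\times10^{-4}$), and the 7 Å gold monolayer hologram. The
four-layer model-selection preset adds a thin water cushion
($h_w = 3.2$ Å at the water dispersion, smeared with $\sigma_w = 6$ Å —
a Gauss–Newton analysis of this generator gives a local
thickness-pair correlation of $-0.99$, the degeneracy the model-selection
test must detect). What the generator deliberately does not emulate:
counting statistics (noise is homoscedastic on log intensity, not
Poisson), instrument backgrounds beyond a flat term, beam damage or
misalignment drifts, and detector nonlinearity. Recovery tests on these
data therefore demonstrate correctness of the inference machinery under
the stated error model, not robustness to real-beamline systematics.

Initial values follow the practice of starting from sensible
prior-knowledge values rather than the truth: a deliberately poor sphere
guess ($R = 500$ Å, $\sigma_R = 20$ Å), nominal literature-style bilayer
values, a flat spline profile for the hologram; $\sigma^2$ starts at its
conditional MLE given those guesses (`preset_init()`).

## Problem sizes and numerical choices

The shipped end-to-end runs use 2000 NUTS iterations (500 warm-up) for the
six-parameter SAXS recovery and 1200 HMC iterations (400 warm-up, ten
leaps) for the twelve-parameter reflectivity recovery — enough for
effective sample sizes of order $10^2$ on every parameter, which is what
the 4-posterior-s.d. recovery checks and the tabled means need. The
scaled-down hologram recovery in the test suite frees only the two polymer
thicknesses and the variance on a coarser grid (37 pixels, $dz = 4$ Å, 12
splines) so that it runs in about a minute; unlike the full-size analysis,
its much stiffer reduced posterior needs the dual-averaged step size
rather than a fixed 0.05. The model-selection check of the four-layer
degenerate ridge likewise runs scaled down: the well-determined parameters
are held at their generating values, the degenerate block (cushion and
inner-head thicknesses, their roughnesses and dispersions, the variance)
is sampled, and a second stage is preconditioned with the full inverse
sample covariance of the first — the full-covariance restart is what lets
a chain traverse a ridge with correlation beyond 0.95, where any diagonal
mass mixes too slowly. Degenerate inputs are handled conservatively:
runaway geometry proposals (kilometre-thick layers) are mapped to infinite
potential rather than allocated; zero-variance warm-up coordinates are
floored; quadrature nodes pushed below $R' > 0$ or $q' > 0$ are dropped
with weight renormalisation; ties in the p-value definition fall back to
the normal approximation $2\Phi(-|t|)$ when no draw crosses zero —
matching how a strictly positive parameter's significance is reported in
the tables.

## Diagnostics

Autocorrelation uses the biased (divide-by-$n$) estimator with
$\pm 1.96/\sqrt{n}$ bounds; the effective sample size truncates the
autocorrelation sum by Geyer's initial positive sequence. Summary tables
report physical-scale means and standard deviations (never sampling-scale
moments), $t = \text{mean}/\text{s.d.}$, and the empirical two-sided tail
probability against zero. Credible bands are pointwise 2.5/50/97.5
percentiles of the model curve over (thinned) post-burn-in draws.
Correlation matrices accept derived columns (e.g. a total film thickness)
because sums of anti-correlated thicknesses are often far better
determined than the addends — the package's model-assessment workflow
rests on exactly this: a redundant layer shows up as a near $\pm 1$
thickness correlation and a non-significant roughness, and the reduced
model restores all-significant parameters.

## Known limitations

* Gradients are finite differences; an analytic or autodifferentiated
  forward model would cut the per-step cost by $2N$ and is the natural
  extension point.
* The mass matrix is diagonal; strongly correlated posteriors (the
  four-layer degenerate ridge) mix slowly along the correlated direction,
  which is detectable in the ESS but not removed. Dense or quasi-Newton
  mass adaptation is out of scope.
* The hologram model fixes the buried Pd/Cr stack at nominal values, omits
  self-absorption, and models only the already-integrated one-dimensional
  exit-angle profile.
* No automatic convergence diagnostics (R-hat across multi-start chains is
  left to the user's inspection of the returned chain list).
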