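---
title: "The coupled-deformation model behind twistcouple"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The coupled-deformation model behind twistcouple}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twistcouple)
```

## The model

Double-stranded RNA and DNA respond to very different stimuli — lowered
salt, raised temperature, stretching force, protein binding — with twist
changes that travel through one shared elastic pathway.  For RNA the twist
couples to the major groove width; for DNA, to the helix diameter.
`twistcouple` implements this picture as a per-base-pair harmonic energy in
units of $k_BT$,

$$P^{bp} = \tfrac12 k_\omega (\Delta\omega)^2
         + \tfrac12 k_X (\Delta X)^2
         + k_{\omega X}\, \Delta\omega\, \Delta X ,$$

where $\Delta\omega$ is the twist deviation in degrees per base-pair step
and $\Delta X$ the deviation of the conjugate coordinate in nm (groove
width $G$ for RNA, diameter $D$ for DNA).  The stiffness matrix
$K = [[k_\omega, k_{\omega X}], [k_{\omega X}, k_X]]$ must be positive
definite.  A stimulus enters as a generalized force $\Delta f$ conjugate to
$X$, adding $-\Delta f\,\Delta X$ to the energy; minimisation gives the
closed-form linear response implemented by `equilibrium_shift()`:

$$\Delta\omega = \frac{-k_{\omega X}\,\Delta f}{k_\omega k_X - k_{\omega X}^2},
\qquad
\Delta X = \frac{k_\omega\,\Delta f}{k_\omega k_X - k_{\omega X}^2}.$$

Positive $\Delta f$ widens $X$; with $k_{\omega X} > 0$ it undertwists the
duplex.  Every response the package predicts — salt, temperature, or a
user-supplied force — is this single formula fed by a different driver, which
is exactly why the three pathways collapse onto one line in the
$(X, \omega)$ plane (`collapse_metric()` quantifies this).

Two drivers are built in:

* **Salt** (`pp_force()`, `delta_force_salt()`): the screened
  phosphate–phosphate repulsion across the major groove,
  $f = \frac{e^2}{4\pi\epsilon_r\epsilon_0} e^{-r/\lambda_D}
  (1/r^2 + 1/(r\lambda_D))$, with $\lambda_D = 0.3034/\sqrt{c}$ nm for
  monovalent salt, P–P distance $r = 0.6$ nm held fixed, and
  $\epsilon_r = 78.4$.  The force change relative to the 1 M reference is
  multiplied by a rescale factor $\alpha = 1.8$ (one pair of phosphates
  stands in for many) in `salt_twist_curve()`, never inside the force
  itself.
* **Temperature** (`decompose_U_S()`, `thermal_force()`): free-energy
  profiles $F(G;T)$ at two or more temperatures are split per grid point
  into $F = U - T\,S$ by least squares, under the approximation that $U$
  and $S$ are temperature-insensitive.  The entropy slope
  $k_{SG} = \partial S/\partial G \approx 0.024$ kJ/(mol·K·nm) turns a
  temperature offset into a groove-widening force
  $\Delta f_G^T = k_{SG}\,\Delta T$.  A degree Celsius and a kelvin are the
  same increment, so the slope per °C equals the slope per K.

A purely geometric relation (`groove_from_twist()`) closes the physical
picture: the two phosphates flanking the major groove sit a fixed backbone
azimuth $\beta \approx 140^\circ$ apart, so
$G \approx h\beta/\omega - D\sin\theta$ — fewer degrees of twist per step
means more steps across the groove and hence a wider groove.  The helical
rise $h$ is not printed alongside the other geometry values, so by default
it is calibrated so the curve passes through the reference equilibrium
point $(32.15^\circ, 0.52\ \mathrm{nm})$, giving $h \approx 0.247$ nm; pass
an explicit `rise` to override.

## What the synthetic generator emulates — and what it does not

`sample_pair_ensemble()` stands in for a molecular-dynamics trajectory
analysed into helical parameters.  It draws per-bp $(\Delta\omega, \Delta X)$
pairs from the bivariate Gaussian with precision matrix $K$ (independently
across base pairs, since the per-bp energy carries no inter-bp coupling),
averages over `n_bp` base pairs, and offsets by the reference point.  Chain
averaging multiplies the effective stiffness of the averaged coordinates by
`n_bp`; the sample covariance converges to $K^{-1}/n_{bp}$.

Defaults are the study conditions of the reference analysis: the
`rna-eq3` preset ($k_\omega = 0.18$ k$_B$T/deg², $k_G = 3.61$ k$_B$T/nm²,
$k_{\omega G} = 0.43$ k$_B$T/(deg·nm), reference point
$32.15^\circ$/$0.52$ nm), `n_bp = 19` (the central window that avoids duplex
end effects), $T = 295$ K, and $5\times10^4$ snapshots — a count chosen to
hold the standard error of recovered constants below about 3%, comparable to
the information content of a few hundred nanoseconds of trajectory.  The
DNA preset `dna-prev` carries $(0.18, 263, 4.5)$ with a canonical B-DNA
reference point $(34.3^\circ, 2.0\ \mathrm{nm})$; only deviations from the
reference enter any computed quantity.

The generator reproduces the harmonic model's equilibrium statistics
exactly and nothing else: no anharmonic tails, no sequence dependence, no
time correlation between snapshots, no ion-specific effects.  Passing tests
therefore demonstrate that the estimators are faithful to the model, not
that the model exhausts real trajectories; with real data the 3 k$_B$T
cutoff is what shields the quadratic fit from anharmonicity.

A second generator, `synth_rotation_extension()`, emulates magnetic-tweezers
rotation–extension curves: linear plectoneme branches, a quadratic cap
blending the two slopes over the flat peak region, Gaussian extension noise.
The cap is built so the extrapolated branches always cross at the true
torsion-relaxed point, which makes the crossing estimator's target exact by
construction; its precise shape is irrelevant because the fit windows
exclude the peak region.

## Estimator choices

**PMF binning.** `build_pmf2d()` defaults to 0.1 deg × 0.01 nm bins for
19-bp-averaged RNA coordinates — roughly 25 bins across ±2 SD of each
coordinate.  For the much stiffer DNA diameter (SD ≈ 0.019 nm) pass
`conj_bin = 0.002`.  Empty bins are `NA`, never zero energy.

**Quadratic surface fit.** `fit_harmonic2d()` fits all six quadratic
coefficients by unweighted least squares to occupied bins within 3 k$_B$T of
the minimum, then divides curvatures by the explicit `n_bp` (never inferred
from the data).  Two numerical refinements matter at histogram noise
levels:

1. *Iterated cutoff.* Selecting bins by their noisy observed values
   preferentially admits rim bins that fluctuated low and deflates every
   curvature by ~10%.  The fit therefore re-selects bins by the fitted
   surface value and repeats until the selection stabilises (a couple of
   iterations in practice).
2. *Log-occupancy bias.* $\mathrm{E}[\ln \hat n] \approx \ln n - 1/(2n)$,
   so each bin value is corrected by $-1/(2n)$ (`bias_correct = TRUE`).
   Without it the rim sits ~0.1 k$_B$T too high and curvatures inflate by
   a few percent.

With both refinements the reference ensemble returns its generating
constants within the quoted uncertainties (±0.01, ±0.28, ±0.05); the tests
also cross-check against the moment estimator `solve(cov(records))/n_bp`,
which is the exact maximum-likelihood route for Gaussian data and would be
preferred in production use when raw snapshots (rather than only a PMF) are
available.

**Conditional profiles.** `conditional_profile()` plus `fit_quadratic1d()`
reproduce the 1-D analysis: within a narrow groove-width window the twist
PMF is a parabola of curvature $\approx n_{bp} k_\omega/2 \approx 1.7$
k$_B$T/deg², with its centre drifting to smaller twist as the window moves
to wider grooves.  `conditional_mean_slope()` regresses bin-mean twist on
groove width; for the Gaussian model the population slope is
$-k_{\omega G}/k_\omega \approx -2.39$ deg/nm, independent of the averaging
length.

**Entropy window.** The entropy-slope fit window defaults to the full
common grid of the supplied profiles: the decomposition sees only curves,
not the ensemble SD, so it cannot place a ±2 SD window itself.  Callers who
want a window pass `fit_window`.

**Grid oracle.** `minimize_tilted_oracle()` verifies the closed-form
response by brute-force lattice search.  Because the energy valley is
tilted relative to the lattice axes, a single lattice's arg-min can sit a
couple of steps off along the soft direction; two 10× refinement passes
(still pure grid search) bring the discretisation error well below one
initial step, which is the agreement the tests assert for 100 random
positive-definite stiffness sets.

**Tweezers windows.** `fit_torsion_relaxed()` auto-selects fit windows
`[apex − 20, apex − 5]` and `[apex + 5, apex + 20]` turns around the raw
arg-max extension; the ±20 reflects the measurement protocol and the ±5
exclusion half-width is this package's (configurable) choice, because the
peak region is flat and uninformative.  The estimator is exactly invariant
to rescaling all extensions (a refractive-index change moves peak heights,
not peak locations) and equivariant under shifts of the turns axis.

**Protein-deformation direction.** The "direction of coupling" that
complex-induced deformations are compared against is operationalised as the
soft eigenmode of the SD-normalised stiffness matrix
$\mathrm{diag}(\delta\omega, \delta X)\,K\,\mathrm{diag}(\delta\omega, \delta X)$,
oriented with a non-negative twist component; the conditional-mean slope
$-k_{\omega X}/k_\omega$ is an equally defensible alternative and the choice
is recorded in the output (`direction` field).  With $k_{\omega X} > 0$ the
soft mode pairs overtwist with groove compression, so deformations in that
quadrant score positive cosines.

## Degenerate inputs and failure modes

Fits refuse, rather than repair, pathological input: non-positive-definite
fitted surfaces are an error (no clamping), as are non-convex 1-D profiles,
parallel plectoneme lines, isotropic normalised stiffness (no soft mode),
ensembles collapsing into one histogram bin, and entropy decompositions
with fewer than two distinct temperatures.  Series files must declare units
(`# units: twist=deg, groove_width=nm`); nothing is guessed.

## Temperature coefficient: a known numerical tension

Evaluating the temperature coefficient
$-k_{\omega X} k_{SG}/(k_\omega k_X - k_{\omega X}^2)$ with the rounded
headline inputs gives $\approx -0.0091$ °/(°C·bp), whereas the quantity is
usually quoted as $\approx -0.012$ (presumably computed from unrounded
fitted constants).  The package asserts the sign and the window
$|\mathrm{coeff}| \in [0.008, 0.016]$ rather than a point value, and makes
no claim about the experimentally measured $-0.014$.

## Problem sizes

The shipped tests and the acceptance script use $5\times10^4$-snapshot
ensembles (the generator's default study condition) for constant recovery,
$2\times10^4$ snapshots per point for pathway-collapse curves, 100 random
stiffness sets for the oracle property, and 200 synthetic tweezers curves
for the recovery property; the full suite runs in well under a minute on
one CPU.

## A worked example

```{r example, eval = FALSE}
library(twistcouple)

rna <- coupling_preset("rna-eq3")
ens <- sample_pair_ensemble(ensemble_spec(rna, n_snapshots = 5e4, seed = 1))
fit <- fit_coupling(ens)
coef(fit)

# salt response with the default electrostatic driver
salt_twist_curve(rna, electrostatic_params(), c(1, 0.5, 0.2, 0.1, 0.05))

# temperature coefficient from the default entropy slope
temp_twist_coefficient(rna, load_config()$entropy$k_SG)
```
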