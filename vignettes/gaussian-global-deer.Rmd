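---
title: "Global Gaussian-mixture analysis of DEER decays: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Global Gaussian-mixture analysis of DEER decays: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deerfit)
```

## The measurement and the model

Four-pulse DEER (double electron-electron resonance, also PELDOR) measures
the dipolar coupling between pairs of unpaired electrons — in protein work,
nitroxide spin labels attached to engineered cysteines. The coupling
frequency scales as $r^{-3}$, so the time-domain echo decay $V(t)$ encodes
the distribution $P(r)$ of inter-label distances, and with it the mixture of
protein conformations present in the sample.

`deerfit` models one decay as

$$V(t) = \bigl[(1 - \lambda) + \lambda F(t)\bigr]\, B(t),$$

with modulation depth $\lambda$ (the fraction of the echo modulated by the
intramolecular coupling, set by labelling and inversion efficiency), form
factor

$$F(t) = \int P(r)\, K(t, r)\, \mathrm{d}r, \qquad
K(t,r) = \int_0^1 \cos\bigl[(1 - 3x^2)\,\omega_{dd}(r)\, t\bigr]\,
\mathrm{d}x,$$

and an intermolecular background $B(t) = e^{-kt}$ from couplings to labels
on *other* molecules. $\omega_{dd}(r) = 2\pi D / r^3$ with
$D = 52.04\ \mathrm{MHz\,nm^3}$ for a nitroxide pair ($g \approx 2$). The
kernel is evaluated in closed form through Fresnel integrals, with a
Gauss-Legendre quadrature of the angular integral available as an internal
cross-check (`dipolar_kernel(..., method = "quadrature")`); the two agree to
about $10^{-14}$.

Where the composite convention is concerned (whether $\lambda$ multiplies
inside the bracket, as here, or the variants $V = F \cdot B$), published
analyses differ; the bracketed form above is the common choice for
global-analysis software and is what every routine in this package assumes.

$P(r)$ is a **sum of Gaussians**, each component carrying a center (nm),
width (standard deviation, nm) and population weight; weights are
normalized to sum to one. This parametric choice — as opposed to model-free
Tikhonov inversion — is what lets several conditions be fit *globally* and
lets populations be compared across conditions without a user-chosen
baseline correction.

The background is fixed to the homogeneous three-dimensional form (pure
exponential). Detergent micelles and nanodiscs approximate a homogeneous
spin bath at the concentrations used in practice; excluded-volume and
fractal-dimension backgrounds are out of scope, and the dimension is not a
fit parameter.

## Global fitting

Decays recorded for the *same* spin-label pair under different biochemical
conditions (apo, nucleotide-trapped, turnover time points, ...) share one
background rate $k$ — the sample concentrations are matched, so the
intermolecular contribution is common — while every trace keeps its own
distribution, and its own modulation depth (labelling efficiency varies
between preparations; a `share_depth` switch exists for samples where
sharing is appropriate, off by default). The weighted residual

$$r_i(t) = \frac{V^{\mathrm{data}}_i(t) - V^{\mathrm{model}}_i(t)}
{\hat\sigma_i}$$

concatenated over traces is minimized under box constraints with the
Levenberg-Marquardt implementation in `minpack.lm`, with per-trace noise
$\hat\sigma_i$ estimated from second differences of the tail of each trace
(variance of the second difference of white noise is $6\sigma^2$), so
traces of different length and quality contribute comparably.

Component weights are fit as *raw* weights in $[0,1]$ and normalized at
evaluation time, which keeps the optimizer inside simple box bounds at the
cost of one redundant degree of freedom per trace; identifiable parameter
counts (used in F tests and covariance estimates) subtract it.

### Multi-start policy

Nonlinear DEER fits have well-known degenerate optima (a single broad
Gaussian plus a slow background can imitate a structured $P(r)$). The fit
is therefore multi-started deterministically — given the data, the
specification, and the seed, the result is bit-reproducible:

1. bound midpoints (always start 1);
2. Latin-hypercube draws within the bounds (`n_starts - 1` of them, seeded);
3. *tail starts* for one-component fits: $k$ and $\lambda$ read off the
   tail of each decay, where $V \approx (1-\lambda)e^{-kt}$, combined with
   a short scan of candidate centers (2-6 nm);
4. a *hierarchical* start for multi-trace groups, assembled from
   single-trace fits (the objective is separable except for shared
   parameters, so per-trace basins are best found per trace);
5. *component-ladder* starts for $k$-component fits: the $(k-1)$-component
   solution with its dominant component split, either as a shoulder
   ($\pm 0.15$ nm) or as a variance split (children at $\pm \tfrac12\sigma$
   and $\pm\sigma$ with halved widths);
6. a final *recombination* polish taking, for each trace, the best
   per-trace parameter block found in any start.

Steps 3-6 each cost a handful of extra optimizer runs and remove
essentially all of the start-dependence we observed in development;
step 5 also makes the best $k$-component RSS structurally no worse than the
best $(k-1)$-component RSS, which the F-test ladder relies on.

Traces are ordered canonically by condition label before packing, so the
result is exactly invariant to the order in which traces are supplied.

### Uncertainties

Standard errors come from the linearized covariance
$\hat\sigma^2 (J^\top J)^{-1}$ with a rank-revealing SVD; parameters pinned
at a bound, or lying in a null direction of $J$ (the redundant raw weight),
are flagged `NA` rather than reported. A Monte-Carlo check in the test
suite verifies the reported errors track replicate scatter within a factor
of two at SNR 30.

## Choosing the number of components

Components are added one at a time and accepted by a nested F test on the
pooled (group-level) weighted RSS:

$$F = \frac{(\mathrm{RSS}_1 - \mathrm{RSS}_2)/(p_2 - p_1)}
{\mathrm{RSS}_2 / (n - p_2)},$$

accepted when the upper-tail $p$ of $F(p_2 - p_1,\ n - p_2)$ falls below
$\alpha$ (default 0.05 — configurable; the threshold is a study-design
choice, not an estimate). The pooled test matches the global character of
the fit; in multi-trace groups an accepted component is granted to the
trace whose own RSS improved most, so component counts may differ between
conditions. Selection stops at the first rejection or at `max_components`
(default 4; experimental distance distributions in this distance range
rarely support more resolvable Gaussians).

Because the alternative's extra parameters (a center, width and weight that
vanish under the null) are only partially identifiable, the test is
*conservative* on this problem: the measured type-I rate in the calibration
experiment runs below the nominal $\alpha$. That errs on the side of fewer
components, which is the right failure mode for population comparisons.

AIC/BIC are deliberately not used for the decision; the F test on nested
least-squares fits is the selection criterion this analysis style is built
around.

## Condition summaries

For reporting, distances move to angstroms (the unit conventional for
spin-label work). Populations are the normalized component weights; the
mean distance is computed on the evaluated grid, so truncation at the grid
edges is reflected honestly. `compare_conditions()` assigns components to
named reference states by nearest center within 3 Å (components further
from every state land in an `unassigned` bucket) and tabulates population
shifts against the first condition — the quantity of interest under
turnover conditions, where the balance between, say, a high-energy
post-hydrolysis state and a nucleotide-bound state shifts with time.

## Numerical choices

* **Distance grid**: 1-10 nm in 0.02 nm steps. Mixtures are truncated to
  the grid and renormalized by their trapezoidal integral. For smooth
  mixtures the trapezoid rule on this grid is accurate to ~$10^{-12}$
  (checked against adaptive double quadrature); fitted mean distances move
  by well under 0.005 nm when the grid is halved.
* **Fit width floor**: fitted component widths are bounded below at
  0.05 nm (2.5 grid steps). Narrower components cannot be represented
  faithfully on the grid, do not occur physically for spin-label pairs,
  and — if allowed — act as tunable-frequency basis functions the
  optimizer can park on noise, which at high SNR inflates the F test's
  apparent improvement and causes overfitting. Distributions themselves
  may carry widths down to 0.02 nm for simulation purposes.
* **Kernel caching**: the $(t, r)$ kernel matrix is cached per grid pair
  and the cache stores exact matrices, so results are bit-identical with
  and without it.
* **Tolerances**: optimizer gradient tolerance $10^{-9}$, step tolerance
  $10^{-10}$, at most $5 \times 10^4$ residual evaluations — below the
  noise scale of any realistic trace, above double-precision dust.
* **Degenerate weights**: if all raw weights of a trace vanish, evaluation
  falls back to equal populations; component lists are reported sorted by
  center with ties broken by width.
* **Zero-time location** maximizes echo symmetry around the (lightly
  smoothed) maximum with a parabolic sub-sample refinement; monotone traces
  fall back to the maximum with a warning.

## The synthetic generator, and what passing tests mean

`synthetic_scenario()` fixes ground truth per condition, the acquisition
grid, the SNR and the seed. Noise is additive white Gaussian on the real
channel — the right model for averaged echo-detected DEER — with
$\sigma = V(0)/\mathrm{SNR}$; optional phase rotation and zero-time delay
exercise the raw-data pipeline. The canonical three-state fixture
(`scenario_three_state()`) uses three conditions of one pair sharing
$k = 0.08\,\mu s^{-1}$: a unimodal 4.5 nm state, a unimodal 3.0 nm state,
and their 0.65/0.35 mixture, at SNR 30, 250 points to 3 µs — a realistic
Q-band acquisition for this distance range.

The generator does **not** emulate orientation selection, nuclear
modulation artifacts, multispin (more than two label) effects, instrument
drift, or heteroscedastic noise. Recovery tests therefore demonstrate the
estimator and selection machinery under the stated noise model, not
robustness to every artifact of real spectrometer data. Homodimer samples
carrying four labels are analysed as superpositions of pair distributions,
without ghost-peak correction.

Study sizes in the test suite and acceptance script (150-300 points per
trace, 2-20 starts, 50-200 replicates) are the package's chosen experiment
sizes; they were fixed alongside the experiments themselves.

## Known limitations

* The long-distance tail of the window matters: with a 3 µs trace, a minor
  component at 4.5 nm (1.7 oscillation periods) carries limited
  information, and its maximum-likelihood center can sit ~0.2 nm from
  truth at SNR 30 even when the optimizer provably reaches the global
  optimum (the fit's RSS falls below the RSS at truth). Population
  fractions are much more robust (within 0.03-0.05). Measuring longer
  windows, not changing the fit, is the remedy.
* Population precision has a hard information limit set by
  $\lambda \times \mathrm{SNR} \times \sqrt{n}$. For a balanced
  3.0/4.5 nm pair at $\lambda = 0.3$, SNR 50, 250 points, the
  maximum-likelihood population estimate scatters with a standard
  deviation of about 0.035-0.04 — verified to be the global optimum, not
  an optimizer artifact — so individual runs land outside $\pm 0.05$
  roughly a quarter of the time. Sharper populations need deeper
  modulation, more averaging, or longer traces, not different software.
* The F-test calibration is conservative (see above) on traces whose
  noise model is exact. Traces that pass through the raw-data pipeline
  additionally carry a multiplicative scale error from the three-point
  V(0) normalization (of order 1/SNR — the estimate interpolates noisy
  samples). The signal model fixes V(0) = 1 and cannot absorb a scale, so
  this error biases the fitted depth by roughly 1/SNR and, for long
  high-SNR traces, can surface as an extra small component in selection.
  Averaging more scans (raising SNR) or recording denser points around
  zero time reduces it at the source.
* Background model misspecification (non-3D samples) will bias $k$ and
  $\lambda$; no diagnostic for background dimensionality is provided.
* `read_bes3t` handles one-dimensional real or complex BES3T data only —
  no 2D nuclear-modulation-averaged sets, no vendor formats beyond BES3T.
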