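# deerfit

Global Gaussian-mixture analysis of four-pulse DEER (double
electron–electron resonance / PELDOR) dipolar decays.

DEER measures the distance distribution P(r) between pairs of nitroxide
spin labels on a protein, and with it the mixture of conformations present
under each biochemical condition — apo, nucleotide-trapped, or ATP
turnover time points. `deerfit` is for spectroscopists who want to
*compare populations across conditions* without a hand-tuned baseline:
decays recorded for the same label pair are fit simultaneously, sharing
one intermolecular background, so population shifts between conditions are
not artifacts of per-trace background choices.

## The model

Each decay is modelled as

    V(t) = [(1 − λ) + λ F(t)] · exp(−k t)

with modulation depth λ, form factor `F(t) = ∫ P(r) K(t,r) dr` over the
dipolar kernel

    K(t,r) = ∫₀¹ cos[(1 − 3x²) ω_dd(r) t] dx,   ω_dd = 2π·D/r³,
    D = 52.04 MHz·nm³,

evaluated in closed form via Fresnel integrals, and an exponential
background from inter-molecular couplings (homogeneous 3D spin bath).
P(r) is a sum of Gaussians; traces of one spin-label pair share k across
conditions while each keeps its own distribution and depth. Bounded
weighted least squares (Levenberg–Marquardt, deterministic multi-start)
minimizes the pooled residuals, and the number of Gaussian components is
chosen by nested F tests on the pooled RSS:

    F = [(RSS₁ − RSS₂)/(p₂ − p₁)] / [RSS₂/(n − p₂)]

accepted at p < α (default 0.05). A seeded synthetic-data generator with
known ground truth backs every stage with recovery and calibration tests —
no spectrometer data required.

## Worked example

Simulate a two-state pair under three conditions and analyse it end to
end:

```r
library(deerfit)

rr <- run_recovery(scenario_three_state(), n_starts = 10, seed = 0)
rr
#> <recovery_report> seed 101; components true/estimated: apo=1/1, amp_pnp=1/1, adp_vi=2/2
#>          parameter truth estimate abs_error rel_error
#>    background_rate  0.08 0.080856  0.000856   0.01070
#>         depth[apo]  0.30 0.299460  0.000536   0.00179
#>      center[apo.1]  4.50 4.479100  0.020900   0.00464
#>       width[apo.1]  0.35 0.403950  0.054000   0.15400
#>      weight[apo.1]  1.00 1.000000  0.000000   0.00000
#>     depth[amp_pnp]  0.35 0.353330  0.003330   0.00952
#>  center[amp_pnp.1]  3.00 3.019800  0.019800   0.00660
#>   width[amp_pnp.1]  0.30 0.270710  0.029300   0.09760
#>  weight[amp_pnp.1]  1.00 1.000000  0.000000   0.00000
#>      depth[adp_vi]  0.28 0.281490  0.001490   0.00531
#>   center[adp_vi.1]  3.00 3.038700  0.038700   0.01290
#>    width[adp_vi.1]  0.30 0.385780  0.085800   0.28600
#>   weight[adp_vi.1]  0.65 0.680060  0.030100   0.04630
#>   center[adp_vi.2]  4.50 4.687900  0.188000   0.04180
#>    width[adp_vi.2]  0.35 0.207550  0.142000   0.40700
#>   weight[adp_vi.2]  0.35 0.319940  0.030100   0.08590
```

Reading this: the selection ladder found one Gaussian for the two
unimodal conditions and two for the mixed one; the shared background rate
0.0809 µs⁻¹ recovers the true 0.08; centers of the unimodal states land
within 0.02 nm of truth (30.2 and 44.8 Å); the bimodal condition's
populations come back 0.68/0.32 against a true 0.65/0.35. The minor
long-distance component's center (46.9 vs 45 Å) illustrates the window
limit discussed in the vignette.

The same analysis, from files on disk:

```r
cmd_simulate(system.file("extdata", "three_state.yaml", package = "deerfit"),
             "sim")                    # traces + truth manifest + run config
cmd_fit(file.path("sim", "run_config.yaml"), outdir = "results")
cmd_report("results", reference = c(nucleotide_bound = 30, HES_like = 45))
```

`cmd_fit` writes, per group: `selection.json` (the F-test ladder),
`fit.json` (all parameters in nm/µs and Å), `pr_<condition>.csv`
(P(r) in Å), `fit_<condition>.csv` (data, fit, residuals), `summary.csv`,
and a top-level `manifest.json` (config hash, version, seeds) from which
any run can be reproduced exactly. A thin shell wrapper lives at
`inst/cli/deerfit` (`deerfit simulate|fit|report`).

Raw Bruker data enter through `read_bes3t()` (BES3T .DTA/.DSC) or
`read_ascii()`, followed by `phase_correct()`, `locate_zero_time()` and
`finalize_trace()` — or automatically through the run configuration.

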