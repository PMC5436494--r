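# flowramp

Transient flow-ramp kinetics for automated flow reactors.

## The problem

Collecting a full concentration–time profile of a multistep reaction in a
flow reactor normally means one steady-state experiment per residence time:
slow, and wasteful of material. A **linear flow ramp** avoids this: the total
flow rate through a coil reactor is decelerated at a constant rate while the
inlet composition is held fixed, so a single transient experiment sweeps a
whole range of residence times, sampled by periodic HPLC injections. Repeating
the ramp over a small factorial of reagent equivalents and temperatures yields
a dataset rich enough to fit every rate constant and activation energy of a
multistep kinetic motif in a few hours of instrument time.

`flowramp` implements the complete workflow around that idea for
process-development kineticists:

* **Virtual rig** — simulate full ramp campaigns for a kinetic scheme (the
  SNAr reaction of 2,4-difluoronitrobenzene with pyrrolidine in ethanol ships
  as the built-in network: parallel *ortho*/*para* substitution followed by
  over-reaction to the bis-adduct), with configurable HPLC noise.
* **Residence-time transform** — map each injection's clock time *t* to the
  residence time of the fluid element leaving the coil. With velocity
  `u(t) = β(T)(u₀ − αt)` (β the thermal-expansion correction of the solvent),
  τ_res solves the swept-volume integral `L = ∫_{t−τ}^{t} u(t′) dt′`, a
  quadratic whose physical root reduces to `V/Q` at constant flow.
* **Global Arrhenius fitting** — all profiles are fitted simultaneously by
  Levenberg–Marquardt least squares. Each step's rate constant is
  parameterized as its value `k_ref` at a reference temperature (default
  90 °C), `k(T) = k_ref·exp[−(E_a/R)(1/T − 1/T_ref)]`, which decorrelates
  `k_ref` and `E_a`; rate constants are optimized in log space. Standard
  errors, 95 % confidence intervals, R², and rate-order model discrimination
  (corrected AIC) are provided.
* **Dispersion diagnostics** — Taylor–Aris dispersion in coiled tubes
  (`D_s = D_m + κ d_t² u² / 192 D_m`, with the coil dispersion ratio κ ≤ 1
  from Dean-vortex mixing), the closed-vessel (Wehner–Wilhelm) conversion of
  a first-order reaction, the resulting systematic underestimation
  ε = (k_obs − k)/k of fitted rate constants, and estimation of κ from a
  measured step-response F-curve.

## Worked example

Simulate the default campaign — 12 ramps (pyrrolidine equivalents
1.5/4/7 × 30/60/90/120 °C), total flow 10 → 1.5 mL min⁻¹ at 0.836 mL min⁻²,
one injection every 2 min in a 5 mL, 0.79 mm ID coil — with 2 % HPLC noise,
then refit the kinetic parameters globally:

```r
library(flowramp)

table <- run_campaign(campaign_design(), snar_scheme(),
                      noise = noise_model(), seed = 1)
fit <- fit_kinetics(table)
print(fit)
#> <kinetic_fit>: 8 parameters, 288 observations, R^2 = 0.99927
#>   Rate constants at T_ref = 363.15 K:
#>   step1    k =  57.962 +/-  0.607 (1e-2 M^-1 s^-1 at 363 K)   Ea = 33.38 +/-  0.19 kJ/mol
#>   step2    k =   2.624 +/-  0.112 (1e-2 M^-1 s^-1 at 363 K)   Ea = 35.00 +/-  1.03 kJ/mol
#>   step3    k =   0.852 +/-  0.011 (1e-2 M^-1 s^-1 at 363 K)   Ea = 39.66 +/-  0.52 kJ/mol
#>   step4    k =   1.784 +/-  0.302 (1e-2 M^-1 s^-1 at 363 K)   Ea = 38.35 +/-  7.08 kJ/mol
```

The generating values (k = 57.9, 2.70, 0.865, 1.63 × 10⁻² M⁻¹ s⁻¹; E_a =
33.3, 35.3, 38.9, 44.8 kJ mol⁻¹) are recovered within the reported
uncertainties from one noisy virtual campaign; `tidy(fit)`, `glance(fit)` and
`autoplot(fit)` give the tidy parameter table, the one-row fit summary and
the data-vs-model profile plot. With `noise = NULL` the recovery is exact to
machine precision.

How much does coil dispersion bias these constants? Lump each profile's
substrate consumption into a pseudo-first-order constant
`k = (k₁ + k₂)·C₂,₀` and apply the small-dispersion bias at a conservative
κ = 0.15:

```r
campaign_dispersion_report(table, fit, kappa = 0.15)
#>   equivalents temp_C k12_s1 epsilon_12_pct masked_12
#>           1.5     30 0.0101         -0.475 FALSE
#>           1.5    120 0.212          -9.91  FALSE
#>           4      120 0.564         -26.4   TRUE
#>           7      120 0.988         -46.2   TRUE
```

Masked rows are profiles whose substrate concentration barely changes (fully
converted), so they carry no information about `k₁ + k₂` and no meaningful
bias estimate. The coil dispersion ratio itself can be estimated from a
measured step response with `estimate_kappa_from_f_curve()`.

A YAML-configured end-to-end run (simulate → fit → dispersion report, with
deterministic artifacts) is available as `run_pipeline(load_campaign_config())`
or from the shell via `inst/cli/flowramp.R`.

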