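---
title: "Transient flow-ramp kinetics: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transient flow-ramp kinetics: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flowramp)
```

This vignette is the package's own account of the science it implements: the
models, the approximations behind them, the tunable parameters, and the design
decisions taken where more than one reasonable choice existed.

## 1. The flow-ramp experiment and the batch-element model

A coil reactor of volume $V$ (default 5 mL) and tube internal diameter $d_t$
(default 0.79 mm) is fed by three pumps: substrate stock (P1), solvent
make-up (P2) and nucleophile stock (P3). Within one *ramp* the pump flow
ratios — hence the inlet composition — are constant, while the total flow
decelerates linearly, $Q(t) = Q_0 - \alpha t$. Because the coil is heated,
the fluid expands and the velocity carries the correction
$\beta(T) = 1 + \alpha_v (T_1 - T_0)$:

$$u(t) = \beta(T)\,(u_0 - \alpha_u t), \qquad u_0 = \frac{Q_0}{\pi d_t^2/4}.$$

A fluid element leaving the coil at clock time $t$ has swept the whole tube
length $L = V/(\pi d_t^2/4)$, so its residence time $\tau_{res}$ solves

$$L = \int_{t-\tau_{res}}^{t} u(t')\,dt',$$

a quadratic in $\tau_{res}$ for linear ramps. `residence_time()` takes the
*smaller positive root*: the larger root corresponds to an unphysical sweep
through zero flow. Elements that entered before ramp onset are handled by
extending $u(t') = \beta u_0$ into the pre-ramp hold; the hold must be long
enough for the reactor to be fully swept (a `hold_min` shorter than the
initial residence time raises a schedule error). At constant flow the root
degenerates to $\tau = V/(\beta Q)$ — 0.5 min at 10 mL min$^{-1}$ in the 5 mL
coil — and the closed form is continuously checked against direct bisection
on the sweep integral (`method = "numeric"`).

**The quasi-static batch-element assumption.** Each exiting element is
modelled as a tiny batch reactor that reacted for $\tau_{res}$ at the ramp's
temperature and inlet composition. Within a ramp both the temperature and the
inlet composition of every element's history are constant, so the element's
chemistry depends *only* on its transit time — the batch model evaluated at
the correct $\tau_{res}$ is exact under these conditions, not an
approximation. For this reason the package does not carry a separate
"integrate along the velocity history" mode; the numeric inversion of the
sweep integral is the validation route for the transform itself. What the
batch-element picture does neglect is axial dispersion, which is treated
separately (section 5) as a quantified bias rather than folded into the
forward model.

## 2. The reaction network and its ODEs

The built-in scheme (`snar_scheme()`) is the SNAr reaction of
2,4-difluoronitrobenzene (**1**) with pyrrolidine (**2**) in ethanol: two
parallel substitutions to the *ortho* (**3**) and *para* (**4**) products and
two consecutive substitutions of those to the bis-adduct (**5**). In the
default motif every step is first order in its aromatic reactant and first
order in pyrrolidine:

$$r_j = k_j(T)\, C_{\mathrm{aromatic}} C_2, \qquad
  k_j(T) = k_{j,ref}\exp\!\left[-\frac{E_{a,j}}{R}\Big(\frac 1T - \frac 1{T_{ref}}\Big)\right].$$

The reference-temperature parameterization (rather than a pre-exponential
factor) is used because (i) rate constants for this system are reported at
$T_{ref}$ = 90 °C, and (ii) it nearly decorrelates $k_{ref}$ and $E_a$ during
fitting when the data bracket $T_{ref}$. Default parameters are the reference
estimates for this system: $k = 0.579, 0.0270, 0.00865, 0.0163$
M$^{-1}$s$^{-1}$ and $E_a = 33.3, 35.3, 38.9, 44.8$ kJ mol$^{-1}$.

Two linear invariants hold along any trajectory and are asserted in the test
suite to $10^{-9}$ M: the aromatic core
$C_1 + C_3 + C_4 + C_5$ and the nucleophile balance
$C_2 + \nu(C_3 + C_4 + 2C_5)$. The stoichiometric factor $\nu$ is 1 by
default (one amine consumed per substitution event); whether a second
equivalent is consumed as an HF scavenger is chemically plausible but not
established for this system, so $\nu = 2$ is available as a configuration
switch rather than a default.

**Integration.** The ODEs are integrated with `deSolve::lsoda` at relative
tolerance $10^{-8}$ and absolute tolerance $10^{-10}$ M. Concentrations are
never clipped inside the right-hand side (integer-order rate laws are well
defined for the sub-tolerance negative excursions an adaptive solver may
take); they are clipped at zero for reporting only. The adaptive path is
cross-checked against a fixed-step classical Runge–Kutta integration at
$\Delta\tau = 10^{-3}$ s, and against the pseudo-first-order closed form
$C_1(\tau) = C_{1,0}e^{-(k_1+k_2)C_{2,0}\tau}$ at 100-fold nucleophile
excess.

## 3. The virtual rig: what the generator emulates, and what it does not

`run_campaign()` reproduces the reference campaign design by default:
equivalents $\{1.5, 4, 7\}$ × temperatures $\{30, 60, 90, 120\}$ °C, flow
10 → 1.5 mL min$^{-1}$ at $\alpha$ = 0.836 mL min$^{-2}$, injections every
2 min from ramp onset — 6 injections per ramp, 72 records in total, spanning
residence times from 0.5 min (shorter at high temperature, where thermal
expansion speeds the coil velocity) to about 2 min.

Parameters the design leaves open were fixed once, as follows:

* *Ramp-rate unit.* The deceleration is interpreted as 0.836 mL min$^{-2}$:
  per-minute units give a 10.2 min ramp consistent with 2-min injections,
  6 points per ramp and a sub-3-hour campaign; per-second units would imply a
  0.17 s ramp, physically impossible. Configs may state either unit
  explicitly (`alpha_mL_min2` / `alpha_mL_s2`).
* *Substrate inlet concentration.* $C_{1,0}$ = 0.1 M, a typical
  process-development screening concentration; it is a required config input
  with this documented default.
* *Stocks.* 0.5 M substrate and 2.0 M pyrrolidine stocks keep all three pump
  fractions strictly positive up to 7 equivalents.
* *Thermal expansion.* $\alpha_v = 1.1\times10^{-3}$ K$^{-1}$ (ethanol near
  ambient), $T_0$ = 25 °C; both configurable, since only the form of
  $\beta(T)$ is fixed by the method.
* *First injection.* Taken at ramp onset (configurable to the pre-ramp steady
  state; composition and residence time are identical, only labelling
  differs).
* *Noise.* Gaussian, sd $= \max(0.02\,C, 10^{-4}\ \mathrm{M})$, truncated at
  zero — a conventional HPLC repeatability surrogate (2 % relative with a
  small absolute floor). Reproducible from a single integer seed.

What the generator does **not** emulate: pump pulsation and controller
transients (the reason real campaigns discard points below 0.5 min residence
time), detector calibration error and drift, carry-over between injections,
axial dispersion of the profile, and pressure effects. Passing
parameter-recovery tests on this generator therefore demonstrates the
correctness of the transform and the estimator — not that every real-world
error source is survivable.

## 4. Global fitting, uncertainty and model discrimination

`fit_kinetics()` minimizes the unweighted sum of squared concentration
residuals over all records and all *aromatic* species (the HPLC-visible
ones; pyrrolidine is excluded from the default residual, and relative
weighting is available as an option). The model for each record is the batch
ODE solution at that record's temperature, inlet composition and residence
time; all condition groups are stacked into one block-diagonal ODE system and
integrated in a single adaptive solve per residual evaluation.

Optimization is Levenberg–Marquardt (`minpack.lm::nls.lm`) in
$(\log k_{ref}, E_a)$ space — log-parameterization enforces positivity and
evens out the five-hundred-fold spread between $k_1$ and $k_3$. Default
bounds are $k_{ref} \in [10^{-6}, 10^{3}]$ M$^{-1}$s$^{-1}$ and
$E_a \in [0, 200]$ kJ mol$^{-1}$; convergence tolerances are $10^{-12}$
(relative SSE and step) with at most 500 iterations.

**Why a pre-screen and a two-stage default.** The SSE landscape of
saturating kinetics has plateaus: once a rate constant is large enough to
convert its reactant completely within the shortest residence time, the
residual no longer responds to it, and a local optimizer started far away can
park a parameter at a bound. The default protocol therefore (i) fits the four
rate constants on the isothermal records at $T_{ref}$ first with activation
energies held fixed, then releases all eight parameters (`init =
"two_stage"`), and (ii) before each LM run evaluates a deterministic
latin-hypercube pre-screen of the plausible window ($k_{ref}$ from $10^{-4}$
to 10 M$^{-1}$s$^{-1}$, $E_a$ from 5 to 150 kJ mol$^{-1}$, plus
activation-energy-only candidates around the stage-one rate constants) and
polishes the best candidates, keeping the lowest final SSE. The test suite
verifies that ten random starting points across that window all reach the
same optimum on the noise-free campaign. Estimates that end on a bound raise
a warning.

**Uncertainty.** At the optimum the covariance is the linearized
$s^2 (J^\top J)^{-1}$ with $s^2 = SSE/(n-p)$, mapped to the natural scale by
the delta method ($\mathrm{SE}_k = k\,\mathrm{SE}_{\log k}$); 95 % intervals
use the $t$ quantile at $n-p$ degrees of freedom. Both the SEs and the 95 %
half-widths are reported, since "SE at the 95 % confidence level" is
ambiguous in common usage. Directions in which $J^\top J$ is singular (e.g.
activation energies fitted to a single temperature level) are reported with
infinite SE and a warning rather than a spuriously tight zero. Monte-Carlo
calibration over 25 replicate noisy campaigns (in the test suite) confirms
the linearized SE of $k_1$ tracks the empirical sampling spread within a
factor of 1.5, and that SEs scale linearly with the noise level.

$R^2 = 1 - SSE/SS_{tot}$ is computed with $SS_{tot}$ about the grand mean of
all measured concentrations entering the residual — the convention matters
and is fixed here; it makes $R^2$ invariant to record order and comparable
across refits.

**Discrimination.** `rank_rate_orders()` refits candidate motifs (orders
0–2 in the aromatic component and the nucleophile; the exact historical
candidate set for this chemistry is not published, so the shipped default is
a superset of plausible motifs) and ranks them by SSE and by the small-sample
corrected AIC, $n\log(SSE/n) + 2p + 2p(p+1)/(n-p-1)$, chosen because it is
computable from least-squares output alone. Failed candidate fits are kept in
the report, flagged, and ranked last.

## 5. Dispersion in the coil and the bias it leaves in rate constants

Axial dispersion in laminar pipe flow follows Taylor–Aris,
$D_s = D_m + \kappa\, d_t^2 u^2 / (192 D_m)$, where the dispersion ratio
$\kappa \le 1$ accounts for the Dean-vortex radial mixing of a coiled tube
($\kappa = 1$ recovers the straight tube; the molecular term $D_m$ is
negligible in liquids). $\kappa$ correlates with $\mathrm{De}\sqrt{\mathrm{Sc}}$,
with $\mathrm{De} = \mathrm{Re}\sqrt{d_t/d_c}$. The shipped
`kappa_correlation()` is a *synthetic* log-log table in the spirit of the
published coiled-tube data — anchored at $\kappa = 0.31$ for
$\mathrm{De}\sqrt{\mathrm{Sc}} = 65$ and decaying to $\approx 0.04$ at
$2\times10^3$ — clearly labelled approximate and intended to be replaced by
user measurements; no quantitative claim in the package depends on its exact
values except through self-consistent round trips.

Conversion of a first-order solute in a dispersed closed vessel follows the
Wehner–Wilhelm solution, parameterized here by the **dispersion number**
$\mathrm{Pe} \equiv D/(uL)$ — note this is the *reciprocal* of the
conventional Péclet number; the naming follows the flow-chemistry literature
this package serves, and the mapping is stated wherever the symbol appears.
`conversion_with_dispersion()` evaluates the full closed form (stabilized by
factoring the dominant exponential; it aborts with advice to use the series
branch if $k\tau$ is so large the exponentials overflow), together with the
small-dispersion expansion $a \approx 1 + 2k\tau \mathrm{Pe} -
2(k\tau\mathrm{Pe})^2$, flagged valid for $\mathrm{Pe} < 0.05$. Its limits —
plug flow $X = 1 - e^{-k\tau}$ as $\mathrm{Pe}\to 0$, perfectly mixed
$X = k\tau/(1+k\tau)$ as $\mathrm{Pe}\to\infty$ — are pinned in tests.

Fitting a plug-flow model to dispersed data *underestimates* rate constants.
In the small-dispersion regime the fractional bias is proportional to
$\kappa$ and to the radial-diffusion Damköhler number
$\mathrm{Da}_r = k d_t^2/D_m$:

$$\varepsilon = \frac{k_{obs}-k}{k} = -\frac{\kappa\,\mathrm{Da}_r}{c}.$$

Two values of the constant $c$ are provided. The default, `"printed"`
($c = 250$), matches the published evaluation for this workflow
($\varepsilon \approx -500\,\%\,\kappa k$ for a 1 mm tube with
$D_m = 0.8\times10^{-9}$ m$^2$s$^{-1}$). Carrying the Taylor–Aris coefficient
through the Wehner–Wilhelm expansion analytically gives $c = 192$
($\varepsilon = -k\tau\mathrm{Pe} = -\kappa k d_t^2/(192 D_m)$, about 30 %
larger bias), available as `coefficient = "taylor_aris"`. Both give
$\varepsilon \le 0$, monotone in $\kappa$, $k$ and $d_t^2/D_m$, and an
$|\varepsilon| > 50\,\%$ evaluation warns that the expansion itself is out of
its validity range. `campaign_dispersion_report()` applies this per profile
after lumping the fitted second-order constants at each profile's nucleophile
excess, $k \approx (k_1+k_2)C_{2,0}$ (and $(k_3+k_4)C_{2,0}$ for the
over-reaction steps), and masks profiles whose reacting-component
concentration range is below a threshold (default 5 % of $C_{1,0}$) — a
fully-converted profile carries no information about the constant, so no
bias estimate is meaningful there.

**F-curve estimation of $\kappa$.** The normalized step response of the coil
is fitted with the closed-vessel axial-dispersion model over the dispersion
number; the fitted $D_s$ is then referenced to the straight-tube Taylor–Aris
value at the same operating point, $\kappa = (D_s - D_m)/(d_t^2u^2/192D_m)$.
For $\mathrm{Pe} < 0.02$ — which covers every coil operating point of
practical interest here, including the 6-min reference measurement — the
closed-vessel response is evaluated as its Gaussian small-dispersion limit
with the exact closed-vessel variance
$\sigma^2 = 2\mathrm{Pe} - 2\mathrm{Pe}^2(1-e^{-1/\mathrm{Pe}})$; for larger
$\mathrm{Pe}$ the Danckwerts closed-closed PDE is solved by method of lines
(central differencing, 300 cells; the cell Péclet number is checked). The two
branches agree to better than 0.03 in $F$ at the crossover, the residual
difference being the genuine skewness the Gaussian limit discards. Round
trips recover $\kappa \in \{0.05, 0.15, 0.31, 1.0\}$ to well under 3 %; an
ideally sharp front is reported as $\kappa \approx 0$ with an
under-resolution warning rather than a confident estimate.

A caveat inherited from the source system: the coil *winding* diameter of the
reference rig is not credibly documented (the printed value repeats the tube
ID), so Dean numbers for that rig cannot be reproduced independently;
$d_c$ is therefore a required input for Dean-number work, without a default.

## 6. Numerical choices, degenerate inputs, problem sizes

* ODE tolerances $10^{-8}$/$10^{-10}$ M; conservation asserted to
  $10^{-9}$ M; closed-form vs numeric residence time to $10^{-6}$ s over
  1000 random draws.
* Quadratic root selection and pre-ramp-hold extension as in section 1;
  ramp overrun ($Q \le 0$) and unswept reactors raise schedule errors.
* Residuals and R² on absolute concentrations; optimizer tolerances
  $10^{-12}$, max 500 iterations; pre-screen sizes 24 (global) / 48
  (isothermal stage), 2–4 polished starts — all adjustable in `fit_spec()`.
* Degenerate fits: fewer informative points than parameters, or zero total
  variance, raise errors; single-temperature campaigns warn and report
  unbounded activation-energy uncertainty.
* Test problem sizes were chosen to exercise the full default campaign while
  keeping the suite quick: the 72-record campaign everywhere, 25 replicate
  campaigns for Monte-Carlo calibration, 10 random restarts for the
  multi-start check, 1000 draws for the flow-transform property, $10^4$
  replicate perturbations for the noise calibration.

## 7. Known limitations

* The batch-element model ignores axial dispersion in the *forward*
  simulation; dispersion enters only as the bias diagnostic of section 5.
  For the default geometry and flows this is a percent-level effect.
* The shipped $\kappa$ correlation is an approximate digitisation, not a
  measured calibration.
* The small-dispersion bias is a first-order expansion; at
  $|\varepsilon| \gtrsim 50\,\%$ it is a qualitative flag, not a correction.
* Real transient artefacts at very short residence times (the reason for the
  0.5 min floor in practice) have no physical model here; the default
  schedule simply does not produce such points.
* Rate-law orders are restricted to $\{0, 1, 2\}$ per reactant and shared
  across steps in the shipped candidate set; fully heterogeneous per-step
  orders can be built with `kinetic_scheme()` directly.
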