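---
title: "A two-state thermodynamic model of solvent-assisted lipid bilayer formation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-state thermodynamic model of solvent-assisted lipid bilayer formation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(salb)
```

## The model and its assumptions

The solvent-assisted lipid bilayer (SALB) method forms supported lipid
bilayers (SLBs) by exchanging a water-miscible organic solvent containing
dissolved lipids for aqueous buffer inside a flow chamber. This package
treats the chamber as a closed thermodynamic system at equilibrium: buffer
infusion is slow compared with lipid self-assembly, so the endpoint state
minimizes free energy rather than reflecting kinetics. The kinetic effect
of solvent exchange enters only through a scalar discount, the scaling
factor $\xi$, defined as the time-averaged relative lipid concentration
over the exchange window: of the $N_0$ lipids initially present, $\xi N_0$
are available for adsorption.

Each available lipid occupies one of two states: the supported layer
(chemical potential $\mu_s$) or suspended micelles/vesicles ($\mu_{mv}$).
With $N_s$ lipids in the supported layer, the free energy in units of $RT$
is

$$G = N_s\mu_s + (\xi N_0 - N_s)\mu_{mv}
  - RT\left[\xi N_0 \ln\frac{\xi N_0}{N_s}
  + (\xi N_0 - N_s)\ln\frac{N_s}{\xi N_0 - N_s}\right],$$

implemented exactly in this two-logarithm form by `free_energy()`.
Differentiating the bracket with respect to $N_s$ gives
$-\ln\!\big(N_s/(\xi N_0 - N_s)\big)$, so the stationary point is the
logistic equilibrium

$$N_s = \frac{\xi N_0}{1 + e^{-(\mu_{mv}-\mu_s)/RT}},$$

returned by `equilibrium_adsorbed_number()`. We verified this equivalence
analytically and enforce it numerically in the test suite (brute-force grid
minimization against the closed form over random parameters), rather than
substituting a differently-grouped mixing-entropy expression.

Two conventions are fixed once, in one constants table (`salb_constants`):

* chemical potentials are per mole, so the thermal scale is $RT$ with
  $R = 8.314462618$ J/(mol K). A difference of 0.585 kJ/mol at 297 K is
  about $0.24\,RT$ — weak preference for the supported state.
* only the difference $\mu_{mv}-\mu_s$ is modeled; $\mu_s$ is pinned to
  zero. Constant offsets shift $G$ but not its argmin, and coverage data
  identify only the difference.

The substrate enters as a discrete switch: hydrophilic surfaces template a
bilayer (leaflet multiplicity $b = 2$), hydrophobic ones a monolayer
($b = 1$). No numeric chemical potentials are assigned to the two substrate
classes; only the resulting layer multiplicity is modeled.

## From lipid counts to QCM-D observables

QCM-D reports a resonance frequency shift $\Delta f$; for thin rigid films
the Sauerbrey relation $\Delta m = -C\,\Delta f$ converts it to areal mass.
Dividing the equilibrium adsorbed mass by the mass of a complete layer
gives coverage linear in the initial concentration $c_0$:

$$\frac{\Delta f}{\Delta f_c} =
  \frac{V \xi}{C A |\Delta f_c|}
  \cdot \frac{1}{1 + e^{-(\mu_{mv}-\mu_s)/RT}} \cdot c_0,$$

with all unit conversions (mm³→cm³, mm²→cm², mg/mL→ng/cm³, Å²→cm²)
centralized in one internal prefactor function so they round-trip exactly.

The complete-layer shift itself depends on lipid packing:
$\Delta f_c = -bM/(N_A C a_0)$, with the area per lipid $a_0(T)$ piecewise
linear in temperature within each membrane phase and discontinuous at the
main transition $T_m$. Two choices here were genuinely open:

* the general coverage expression contains a layer-multiplicity symbol that
  algebraic substitution of $\Delta f_c(T)$ into the coverage equation
  forces to equal the leaflet factor $b$; we implement it as the substrate
  multiplicity (2 for bilayers), which keeps the general expression exactly
  equal to the composition of its two ingredients (`coverage_general()`
  agrees with the composed pipeline to $10^{-12}$ relative, by test).
* $T = T_m$ is assigned to the fluid branch, matching the branch
  inequality as printed ($T \ge T_m$ fluid). The discontinuity magnitude is
  then the APL ratio $a_m^f/a_m^g$ (1.2905 for DPPC).

$\Delta f_c$ is stored as measured — negative — and every ratio uses
magnitudes, so coverage is positive. Raw (uncapped) coverage is always
reported next to a value clipped to $[0,1]$; regime classification uses the
raw value, since coverage above 1 is the supersaturation signal.

Setting coverage to 1 gives the minimum concentration for a complete layer,

$$c_{\min}(T) = \frac{bMA}{N_A V \xi}
  \cdot \frac{1 + e^{-(\mu_{mv}-\mu_s)/RT}}{a_0(T)},$$

and the tests require `coverage_general(min_concentration(...)) = 1` to
$10^{-9}$ over randomized lipids, chambers and temperatures.

## Parameters that matter

| parameter | units | default | rationale |
|---|---|---|---|
| $\mu_{mv}-\mu_s$ | J/mol | none (user/fit) | 585 J/mol for DOPC from the calibration fit; ~1 kJ/mol for DPPC |
| $V$ | mm³ | 58 | reference flow-cell volume |
| $A$ | mm² | 97 | active crystal area |
| $C$ | ng cm⁻² Hz⁻¹ | 17.7 | sensor constant |
| $\xi$ | — | 0.05 | reference solvent-exchange discount |
| $\Delta f_c$ (DOPC) | Hz | −25 | measured complete-bilayer shift |
| DPPC $M$, $T_m$ | g/mol, K | 734.039, 314 | literature values |
| DPPC APL | Å², Å²/K | 47.5/61.3, 0.06/0.2 | gel/fluid APL at $T_m$ and slopes |
| regime band | — | ±0.02 | see below |

$\xi$ is primarily a supplied constant. The derivation behind the reference
value is not part of this package; instead we provide a documented optional
model, exponential washout $c(t) = c_0 e^{-kt}$ (a continuously stirred
tank with flow $Q$ and $k = Q/V$), for which the time average is analytic:
$\xi = (1 - e^{-k\tau})/(k\tau)$, computed with `expm1` so the
$k\tau \to 0$ limit is exact. The tests pin this against trapezoid
quadrature of a generated washout trace to $10^{-8}$.

## Inference

`fit_mu_difference()` inverts the coverage line for the chemical-potential
difference. Design choices:

* **Through-origin ordinary least squares.** The model line has zero
  intercept by construction, and no error model is given for the endpoint
  measurements, so unweighted OLS on coverage with replicates as individual
  rows is the default. A free-intercept diagnostic fit is reported (not
  used) so users can spot baseline offsets.
* **Delta-method uncertainty.** With slope $s$ and prefactor $K$, the
  implied fraction is $f = s/K$ and
  $\mu = RT\ln\big(s/(K-s)\big)$, so
  $\mathrm{d}\mu/\mathrm{d}s = RT\,K/\big(s(K-s)\big)$ maps the slope SE to
  a $\mu$ SE. A seeded residual bootstrap is available as a cross-check; on
  the default synthetic design the two agree within a few tens of percent.
* **Typed failures.** $s \le 0$ or $s \ge K$ (implied fraction at or above
  1) raise an identifiability error — no finite $\mu$ exists; fewer than
  two distinct positive concentrations raise an insufficient-data error;
  fits with $f > 0.999$ are flagged near-saturated because the logistic
  link is nearly flat there and $\mu$ is numerically unstable.

## What the synthetic generator does and does not emulate

`generate_endpoint_dataset()` reproduces the statistical structure the fit
assumes: endpoint shifts on the model line with i.i.d. Gaussian noise added
in the measurement domain (Hz on $\Delta f$, not on coverage), eight
concentrations spanning 0.025–0.25 mg/mL, five replicates, and
$\sigma = 1$ Hz by default — a plausible QCM-D endpoint resolution; the
true replicate count and noise level of the original calibration are not
stated, so these defaults are declared assumptions, configurable but not
tuned. Seeds are mandatory for any stochastic output and generators are
deterministic functions of (spec, seed).

Passing recovery tests on these data shows the estimator is consistent and
its reported uncertainty is calibrated *under the model's own assumptions*.
Real QCM-D endpoint data additionally carry coupled-solvent mass (measured
complete-layer shifts exceed the bare-lipid Sauerbrey estimate),
viscoelastic deviations from the Sauerbrey relation, drift, and possibly
concentration-dependent variance — none of which the generator simulates,
so agreement here does not validate those aspects against real data.

## Numerical choices

* The "complete" regime is a band around coverage 1 (default ±2%), since
  an exact-equality contour has measure zero on a grid; raw coverage is
  exported so users can re-threshold. The band half-width must lie in
  (0, 0.5).
* Phase-diagram grids default to 290–330 K in 0.5 K steps and 0–1 mg/mL in
  0.01 steps, spanning the DPPC transition with the complete band
  resolvable; grid exports write 17 significant digits so read-back is
  bit-exact, and the file-level commands serialize results at 9 significant
  digits for reproducible diffs.
* `free_energy()` rejects boundary states ($N_s \in \{0, \xi N_0\}$),
  where the entropy logarithms are undefined; the gel-branch APL
  linearization errors out if extrapolated to where it would go
  nonpositive.
* Test problem sizes: grid minimization uses $10^5$-point grids over 100
  random parameter draws (with a refinement pass where $10^{-6}$ relative
  agreement is asserted); recovery checks run 200 simulated experiments
  per true $\mu$; quadrature checks use $2\times10^4$–$10^5$ trapezoid
  steps. These sizes make the full suite run in seconds while leaving
  discretization error an order of magnitude below each asserted
  tolerance.

## Known limitations

* Equilibrium only: no kinetics of micelle rupture, vesicle fusion or
  adsorption, and no free-energy barriers along the exchange path.
* The Sauerbrey relation is the only transducer model; dissipation and
  viscoelastic corrections are out of scope, which is why measured
  complete-layer shifts can exceed the model's bare-lipid values.
* The supersaturated regime is classified, not resolved: the model flags
  coverage above 1 but says nothing about aggregate morphology.
* Substrate chemistry is a binary hydrophilic/hydrophobic switch; partial
  wettability and material-specific interactions are not modeled.
* The chemical-potential difference is assumed temperature-independent
  when evaluating temperature scans, on the argument that suspended and
  supported states respond similarly to temperature.
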