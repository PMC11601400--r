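# facdis

Kinetic and structural-mechanical analysis of protein complexes engineered
for **effector-facilitated dissociation** — systems in which a host protein
(A) binds a partner (B) tightly, yet releases it within seconds when an
effector (C) binds the partner–host complex and drives it into a
mechanically strained ternary intermediate (BAC). The package is aimed at
protein designers and biophysicists who measure these systems by surface
plasmon resonance (SPR) and fluorescence polarization (FP) and who want to
relate predicted structural deformations to the observed off-rate
enhancements.

## What it computes

**Chip-occupancy kinetics.** During a dissociation window at constant
effector concentration `[C]`, occupancies on the SPR chip follow

    d[BAC]/dt = -k_off,B:AC [BAC] + k_on,BA:C [BA][C] - k_off,BA:C [BAC]
    d[BA]/dt  = -k_off,B:A  [BA]  - k_on,BA:C [BA][C] + k_off,BA:C [BAC]
    d[BAn]/dt = -k_off,B:An [BAn]

with BAn an effector-unresponsive host population that accumulates across
cycles through the re-loading recursion (a fraction `f_responsive` of
refilled sites is responsive). The package solves this system in closed
form, fits it globally to all dissociation cycles at once
(`fit_global()`), and summarises the process by the effective rate
`k_eff = ln 2 / t_half`, which runs from `k_off,B:A` at zero effector to
`k_off,B:AC` at saturation.

**Mechanism discrimination.** Effector association rates versus
concentration distinguish induced fit (linear,
`k_app = k_on,BA:C [C] + k_off,BA:C`) from conformational selection
(hyperbolic, `k_app = (k_switch - k_base)[C]/(K_1/2 + [C]) + k_base`);
`discriminate_mechanism()` fits both laws and selects by AIC.

**Equilibrium binding.** FP titrations are fit with the exact quadratic
binding isotherm `P = P0 + P1 f_bound`, with censored reporting
(`K_D < [C]`) when the affinity is too strong for the titration to
resolve.

**Strain mechanics.** From a clashing design model and a strained
ternary-complex model, `pivot_decomposition()` extracts the screw-axis
pivot angle `θ − θ0` and its angle `φ` to the interface binder helix. The
strain energy inferred from kinetics,
`ΔΔG = RT ln(k_off,B:AC / min(k_base, k_off,B:A))`, is linked to geometry
through a Hooke's-law spring model with perpendicularity-dependent
stiffness, `ΔΔG_pred = (m sin φ + b)(θ − θ0)²`, fitted across a design
cohort by `fit_spring_model()`.

Seeded generators (`generate_spr_dataset()`, `generate_kapp_profile()`,
`generate_fp_titration()`, `generate_structure_pair()`,
`generate_strain_cohort()`) emulate each experiment with known ground
truth, so every estimator is validated by parameter recovery.

## Worked example

```r
library(facdis)

ds  <- generate_spr_dataset(noise = noise_spec(sd = 0.01, seed = 1))
fit <- fit_global(ds, n_starts = 2)
fit
#> Global fit of multi-cycle SPR dissociation data
#> Facilitated-dissociation rate constants:
#>   k_off,B:A   0.001937     s^-1      (partner off binary)
#>   k_on,BA:C   3.043e+04    M^-1 s^-1 (effector on)
#>   k_off,BA:C  0.0008958    s^-1      (effector off ternary)
#>   k_off,B:AC  0.04983      s^-1      (partner off ternary)
#>   k_off,B:An  1.215e-05    s^-1      (partner off unresponsive)
#>   f_responsive = 0.8961
#>   residual SSE = 3876.33 RU^2 over 6 cycles
#>   note: k_on,BA:C and k_off,BA:C tightly covary at these concentrations;
#>   only partner off-rates are well determined

fold_change(fit)
#> [1] 25.72417

effective_rate(fit$rates, c(0, 5e-6))
#> [1] 0.00194 0.03330
```

The simulated experiment was generated with a 25-fold effector-induced
acceleration (`k_off,B:A = 2e-3`, `k_off,B:AC = 0.05` s^-1) and
`f_responsive = 0.9`; from six noisy cycles the fit recovers the base
off-rate to ~3%, the accelerated off-rate to ~0.3%, the responsive
fraction to 0.004, and the headline fold change as 25.7. The `k_eff`
values show dissociation accelerating from the base rate toward the
ternary off-rate as effector rises to 5 µM. The covariance note is
expected: only the balance of the effector on/off pair affects the
observable kinetics in this regime.

On the mechanics side:

```r
cohort <- generate_strain_cohort(seed = 1)   # 30 designs, 10% ddG noise
fit_spring_model(cohort)
#> perpendicularity-linear spring model:
#>   k(phi) = m sin(phi) + b,  m = 30.1084, b = 5.44891 kcal/mol/rad^2
#>   R^2 (predicted vs experimental ddG) = 0.9931 over 30 designs
#> unstrained off-rate floor 0.0002 s^-1, T = 298.15 K
```

recovering the generating coefficients (m = 30, b = 5) within a few
percent.

A thin command-line dispatcher over the same functions is installed at
`inst/cli/facdis.R` (`simulate` / `fit` / `strain` subcommands); its
outputs are byte-identical to direct library calls with the same seed.

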