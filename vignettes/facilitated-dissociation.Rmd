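---
title: "Modelling effector-facilitated dissociation: kinetics, global fitting, and the strain-energy spring model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling effector-facilitated dissociation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facdis)
```

## The system

`facdis` analyses engineered protein systems built around *facilitated
dissociation*: a host protein (A) binds a partner (B) tightly, and an
effector (C) can bind the partner–host complex to form a mechanically
strained ternary intermediate (BAC) from which the partner leaves orders of
magnitude faster than from the binary complex. Two measurements anchor the
analysis:

* **Kinetics.** Multi-cycle SPR experiments in which chip-bound
  partner–host complexes are exposed to an effector dilution series, and
  the dissociation of every cycle is fit jointly by a small reaction
  network.
* **Structural mechanics.** The geometry of the deformation that resolves
  the designed steric clash in the ternary complex, summarised by a pivot
  angle and its orientation relative to the interface binder helix, and
  linked to the kinetically inferred strain energy through a Hooke's-law
  spring model.

## The chip-occupancy model

During a dissociation window at constant effector concentration $[C]$ the
occupancies obey

$$
\begin{aligned}
\frac{d[BAC]}{dt} &= -k_{off,B:AC}[BAC] + k_{on,BA:C}[BA][C]
                     - k_{off,BA:C}[BAC]\\
\frac{d[BA]}{dt}  &= -k_{off,B:A}[BA] - k_{on,BA:C}[BA][C]
                     + k_{off,BA:C}[BAC]\\
\frac{d[BAn]}{dt} &= -k_{off,B:An}[BAn]
\end{aligned}
$$

where BAn is a host population unresponsive to the effector. With $[C]$
fixed this is a linear constant-coefficient system: the BA/BAC pair is
$2\times 2$ and is solved exactly through its spectral decomposition, with
a series-limit branch when the eigenvalue gap falls below
$10^{-12}\,\max|\lambda|$; BAn is an independent exponential. The closed
form is bit-stable inside optimisation loops and is verified in the test
suite against an independent adaptive Runge–Kutta integration to
$10^{-8}$ absolute occupancy. Occupancies are dimensionless fractions of
chip capacity; concentrations are strictly molar. Free effector is assumed
non-depleting (flow conditions), and no mass-transport or rebinding
corrections are applied.

Between cycles the chip is re-loaded: free capture sites refill, a
fraction $f_{responsive}$ into the responsive BA pool and the rest into
BAn, which therefore accumulates across cycles. Each cycle starts with
$[BAC]=0$; any ternary complex left at the end of a window is folded into
the BA pool, since the effector washes out between cycles. (For designs
with very slow effector release this assumption, inherited from the model
itself, becomes inaccurate.) The response map is
$S = f_n\,(a_{BA}[BA] + a_{BAC}[BAC] + a_{BAn}[BAn])$ with $f_1 \equiv 1$:
without that gauge the amplitudes and per-cycle factors are jointly
unidentifiable.

The effective rate of the full process is defined through the half-time of
total partner-bound occupancy starting from $[BA]=1$, $[BAC]=0$:
$k_{eff} = \ln 2 / t_{1/2}$. It interpolates monotonically between
$k_{off,B:A}$ (no effector) and $k_{off,B:AC}$ (saturating effector); the
half-time is found by bracketed root-finding (relative tolerance
$10^{-10}$) on the closed-form solution, which is safe because total bound
occupancy is strictly decreasing.

## Global fitting

`fit_global()` minimises the unweighted sum of squared residuals over all
cycles jointly, varying the five rates (log-parameterised, box-bounded to
physically plausible decades), the three amplitudes (log), the per-cycle
scale factors for cycles $\ge 2$ (log), and $f_{responsive}$ (logit).
Optimisation uses Levenberg–Marquardt. Two practical features matter:

* **Initialisation.** Each cycle is first fit with a double exponential;
  the resulting empirical rate-versus-concentration profile supplies
  starting values (fast end $\to k_{off,B:AC}$, slow end
  $\to k_{off,B:A}$, half-maximal concentration $\to$ the $k_{on}$ scale).
  Because most of a cycle's signal can decay within seconds, generic
  starting points let the optimiser fall onto a "predict zero" plateau or
  role-swapped local minima in which the unresponsive pool absorbs the
  signal; the data-driven start avoids these.
* **Multi-start and staging.** Each start is run twice — directly with all
  parameters free, and staged (rates plus $f_{responsive}$ first with the
  response map pinned, then everything) — and jittered copies of both the
  user-supplied and data-driven starts are tried. A final sequence of
  restarts polishes the best solution, since restarting resets the
  Levenberg–Marquardt trust region.

The effector on/off pair $(k_{on,BA:C}, k_{off,BA:C})$ covaries tightly
whenever $k_{on,BA:C}[C]$ dominates the partner off-rates: only their
balance affects the observable kinetics. The fit reports this as a
covariance flag rather than an error, and the dissociation-rate estimates
are unaffected (scaling the pair jointly by tenfold changes $k_{eff}$ by
under a few percent in the flagged regime). Point estimates only are
reported; residuals are unweighted across cycles, which is recorded in the
result.

## Curve fits and mechanism discrimination

The closed-form fits used around the network model are implemented with
the same conventions:

* Single/double exponential decays and rises, with the reporting rule for
  heterogeneous host populations: the rate of the faster **and**
  higher-amplitude component is reported. When the faster component has
  the lower amplitude it is still reported provided it carries at least
  25% of the total amplitude, otherwise the higher-amplitude rate is
  reported — and the conflict is always flagged, since the choice is a
  judgement call that should be visible. Near-equal rates
  ($k_1/k_2 < 1.5$) or a vanishing amplitude ($<1\%$) collapse the model
  to a single exponential.
* Apparent effector association rates versus concentration:
  $k_{app} = k_{on,BA:C}[C] + k_{off,BA:C}$ for an induced-fit effector
  (binds the partner-blocked state directly), versus
  $k_{app} = (k_{switch}-k_{base})[C]/(K_{1/2}+[C]) + k_{base}$ for
  conformational selection (a concentration-independent conformational
  step rate-limits binding). `discriminate_mechanism()` fits both and
  selects by AIC under a Gaussian residual likelihood with the noise
  variance profiled out. AIC is preferred over an F-test because the
  linear law is not nested in the hyperbola's interior parameterisation;
  the AIC difference depends only on the residual sum-of-squares ratio, so
  the selection is invariant to affine rescaling of the rate units.
* The fluorescence-polarization isotherm uses the exact quadratic solution
  of the equilibrium mass balance, evaluated in the product form
  $f = 2[A]/(s + \sqrt{s^2 - 4[A][C]})$, $s = [A]+[C]+K_D$, which avoids
  the catastrophic cancellation the textbook form suffers when
  $[A][C] \ll s^2$. When the fitted $K_D$ falls below the labelled probe
  concentration the affinity is too strong to measure by titration; the
  result is censored and reported as the upper bound $K_D < [C]$ exactly.
* The sigmoid baseline-drift model
  $S = S_1/(1+e^{-k(t-t_{1/2})}) + S_0$ and its subtraction helper support
  long time courses whose slow instrument drift would otherwise bias rate
  estimates.

## Deformation geometry and the spring model

The strained ternary complex resolves a designed clash by a global,
nearly rigid pivot of the partner. `pivot_decomposition()` makes the
pictorial construction precise:

1. superpose the strained model onto the reference via the switch
   coordinates (Kabsch, SVD, reflections excluded);
2. compute the rigid transform carrying the clashing partner onto the
   switch-aligned strained partner;
3. decompose it in screw (Chasles) form — rotation angle
   $\theta-\theta_0$, located axis (the axis point is chosen perpendicular
   to the axis, minimising the screw translation), and the residual
   translation along the axis, which is reported rather than discarded;
4. fit the interface binder helix axis by a principal-component line
   through its Cα trace (robust for near-ideal designed helices, and
   fully specified, unlike ideal-helix fitting);
5. report $\varphi$, the angle between pivot and helix axes folded to
   $[0, \pi/2]$ (perpendicularity is sign-free), and $\sin\varphi$.

Whether the deformation angle should be measured between centroid lines in
the plane normal to the axis or as the full 3D rotation angle is a genuine
ambiguity; the screw rotation angle is used because it is well defined for
any rigid displacement, and the residual translation quantifies how far
the motion departs from a pure pivot. Rotations below $10^{-6}$ rad are
reported as degenerate (no meaningful axis). The helix range is indexed
into the reference host coordinates because the binder helix is part of
the host fusion and is structurally identical across design variants.
Angles and $\sin\varphi$ are invariant under any common rigid transform of
all inputs (verified to $10^{-9}$).

The strain energy favouring partner dissociation is estimated from
kinetics as
$\Delta\Delta G = RT\,\ln(k_{off,B:AC}/k_{off,B:A,unstrained})$, taking
the effector-bound and effector-free on-rates as equal. Because a fusion
can form extra stabilising contacts that persist in the ternary complex,
the unstrained off-rate is floored:
$k_{off,B:A,unstrained} = \min(k_{base}, k_{off,B:A})$ with
$k_{base} = 2\times10^{-4}\,\mathrm{s}^{-1}$ by default (close to the
off-rate from an unhindered binder fusion, $9\times10^{-5}$ s$^{-1}$).
Hooke's law gives the per-design spring constant
$k = \Delta\Delta G/(\theta-\theta_0)^2$, and across a cohort the spring
constant is modelled as linear in the deformation's perpendicularity to
the secondary structure:
$\Delta\Delta G_{pred} = (m\sin\varphi + b)(\theta-\theta_0)^2$.
`fit_spring_model()` fits $m, b$ by least squares **on the strain
energies** (not on the $k$-versus-$\sin\varphi$ line, which remains a
diagnostic view); being linear in $m$ and $b$, this reduces to ordinary
least squares on the regressors $\sin\varphi\,\theta^2$ and $\theta^2$.
Exclusion of outlying designs is left to the caller rather than automated.
Energies are in kcal/mol at 298.15 K (experiments at 25 °C); both the
temperature and the floor are configurable.

## Synthetic data: what it emulates and what it does not

Every input the analyses consume can be generated with a known ground
truth, attached as a `truth` attribute so recovery tests never reach into
generator internals. Defaults mirror the experimental designs the models
were built for:

* SPR: 6 cycles, effector two-fold diluted from 5 µM, 600 s dissociation
  windows sampled at 1 s, Gaussian noise at 1% of the maximum response (a
  typical SPR noise floor). The default ground-truth rates
  ($k_{off,B:A}=2\times10^{-3}$, $k_{on,BA:C}=3\times10^4$,
  $k_{off,BA:C}=10^{-3}$, $k_{off,B:AC}=0.05$,
  $k_{off,B:An}=10^{-5}$; a 25-fold acceleration) were chosen, once, so
  that the $k_{eff}$ transition lies inside the 32-fold dilution window —
  the situation a well-designed dilution series creates, and the only one
  in which both partner off-rates are structurally identifiable from six
  cycles. Designs with very large fold changes need wider dilution series
  before their base off-rate is recoverable; that is a property of the
  experiment, not of the fitting code.
* FP titrations: 24 wells, two-fold host dilution, noise at 2% of the
  polarization range.
* $k_{app}$ profiles: 8-point two-fold concentration grids spanning
  $K_{1/2}$, 5% noise.
* Structures: a random globular host carrying an ideal α-helix over the
  declared range, a partner rotated by a known angle about a known located
  axis, the whole strained complex placed in a random rigid frame, and
  optional isotropic coordinate noise.
* Strain cohorts: 30 designs with uniformly drawn $\theta$ and $\varphi$,
  strain energies from the spring model with 10% multiplicative noise,
  converted back to self-consistent off-rates.

The generators reproduce the statistical structure the estimators assume
— independent Gaussian noise, constant effector, rigid-body deformation.
They deliberately omit instrument physics (within-cycle drift, bulk
refractive-index jumps, spike artifacts) and model mismatch (non-rigid
deformation, slow effector washout). Passing recovery tests therefore
demonstrates correctness of the estimators under their own assumptions,
not robustness to every artifact of real sensorgrams.

## Numerical choices, in brief

* Rates optimised in log space; responsive fraction via logit; box bounds
  at physically plausible decades.
* Half-time root-finding: bracketed, geometric bracket expansion, relative
  tolerance $10^{-10}$.
* Eigenvalue degeneracy threshold $10^{-12}\max|\lambda|$ with a
  limit-correct series branch.
* Nonlinear fits use tight Levenberg–Marquardt tolerances
  (`ftol = 1e-15`) with multiple deterministic starting heuristics so
  noiseless inputs are recovered essentially to machine precision.
* Problem sizes in the test-suite simulation studies (6-cycle fits, 100
  discrimination profiles, 20-seed recovery medians, 100 frame-invariance
  transforms) were chosen to keep the whole suite comfortably fast while
  leaving the acceptance margins wide.

## Known limitations

* The cycle model assumes complete effector washout between cycles and
  constant effector during a window; neither holds for very slow effector
  release or strong depletion.
* The covarying effector on/off pair is reported, not resolved; resolving
  it requires a direct effector-association experiment (the $k_{app}$
  module fits exactly that).
* The spring model is deliberately coarse: a single global mode with
  stiffness linear in $\sin\varphi$. It does not attempt per-region
  stiffness or anything like a normal-mode analysis, and uncertainty in
  the fitted $m, b$ is left to resampling by the caller.
* Identifiability of the base off-rate depends on the dilution window, as
  discussed above.

## A worked example

```{r example}
ds <- generate_spr_dataset(noise = noise_spec(sd = 0.01, seed = 1))
fit <- fit_global(ds, n_starts = 2)
fit
fold_change(fit)
effective_rate(fit$rates, c(0, 5e-6))
```
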