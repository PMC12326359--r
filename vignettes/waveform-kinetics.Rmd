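---
title: "Modeling steady-state catalytic voltammetry of H+/H2 interconversion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling steady-state catalytic voltammetry of H+/H2 interconversion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfewave)
```

## The problem

In protein film electrochemistry (PFE) a redox enzyme adsorbed on a
rotating electrode exchanges electrons directly with it, and catalysis is
read out as current. For hydrogenases, which interconvert H⁺ and H₂ in
both directions, a slow-scan cyclic voltammogram is a steady-state
activity-versus-driving-force curve. A single voltammogram carries little
mechanistic information, but how its shape changes with pH and H₂
concentration is rich: it encodes the pKa's and reduction potentials of
catalytic intermediates and the kinetics of the chemical steps. This
package implements that inference chain — from raw two-column CV files to
a parameter table — together with the reverse (generative) direction used
to validate it.

## The waveform and its interpretation

Any *ordered* two-electron bidirectional catalytic cycle produces a
steady-state voltammetric response of the form

$$i(E) = \frac{i_{lim}^{ox}\,e^{f(E-E_{cat}^{ox})}\,e^{f(E-E_{cat}^{red})}
  - i_{lim}^{red}}{\left(1+e^{f(E-E_{cat}^{red})}\right)
  \left(1+e^{f(E-E_{cat}^{ox})}\right)}, \qquad f = F/RT,$$

with oxidative and reductive plateau currents and two "catalytic
potentials" at the inflections (`steady_state_current()`). Because the
response is steady state, the ratio of the plateaus is pinned to the
equilibrium potential of the H⁺/H₂ couple,

$$\frac{i_{lim}^{ox}}{|i_{lim}^{red}|} =
  \exp\!\left[\frac{2F}{RT}\left(\frac{E_{cat}^{ox}+E_{cat}^{red}}{2}
  - E_{eq}\right)\right],$$

which `eq2_implied_eeq()` inverts and `fit_wave(constrain_eeq = )` can
impose. The waveform fits *any* ordered cycle; mechanism enters through
how the four parameters move with conditions.

The interpretive model is an EECC cycle: two electron transfers with
effective potentials $E_1^{0\prime}$, $E_2^{0\prime}$ (pH dependent
because the first reduction is coupled to a fast protonation with
equilibrium constant $K$), then two reversible chemical steps. In the
default step assignment, step 1 is protonation through the terminal
proton relay (rates saturating around $pK_{relay}$, because the proton
comes from the relay rather than from bulk), and step 2 is H₂
release/binding (unimolecular release $k_2$, bimolecular binding
$k_{-2}'[H_2]$). `wave_from_rates()` maps instantaneous step rates onto
the waveshape; `apparent_ph_params()` carries out the substitution that
turns a pH series into the six identifiable apparent parameters
($\alpha$, $\beta$, $E_1^{0app}$, $pK_1$, $pK_2$, $pK_3$) plus the
thermodynamic pair ($E_2^0$, $pK$); `km_from_micro()` gives
$K_M = (k_2 + k_{-1})/k_{-2}'$ for the H₂ series. The catalytic pKa's are
kinetic quantities — combinations of the relay acidity and rate
constants — and always satisfy $pK_2 \le \min(pK_1, pK_3)$, which the
package enforces both algebraically and as a hard fitting constraint.

`variant_wave()` re-routes the two condition laws onto the other
chemical step. These variants matter because they are *testable*: with
H₂ binding in step 1, $E_{cat}^{ox}$ must increase with [H₂] for any
positive rate set — the opposite of what the default assignment predicts
(and of what is observed) — so the variant is rejected on sign alone.
The property suite checks this over random rate sets.

## Identifiability and conventions

* **Sign convention.** The reductive limiting current is negative in the
  rate expressions; everywhere in the package it is stored as a
  magnitude (`ilim_red_mag`) and the sign is applied only inside the
  waveform. This keeps the equilibrium-relation ratio well defined. The
  printed form of the waveform's numerator is written accordingly.
* **Exchange symmetry.** The waveform is exactly invariant under
  exchanging $E_{cat}^{ox} \leftrightarrow E_{cat}^{red}$, so a single
  trace determines only the unordered pair. `fit_wave()` canonicalizes
  to $E_{cat}^{ox} \ge E_{cat}^{red}$. For strongly "reversible"
  catalysts with crossed potentials the labels would genuinely be
  ambiguous from one trace; the series models resolve them through their
  condition dependence.
* **Lumped scale.** The prefactor $2FA\Gamma$ multiplying all currents is
  one `scale` parameter; electrode area and electroactive coverage are
  never separated because coverage is unknowable in PFE. Consequently
  limiting currents are treated relative (the series fits normalize by
  the oxidative plateau at the anchor condition, pH 7 for pH series and
  the highest concentration for H₂ series).
* **Acidity on the log scale.** All acid constants are handled as pK;
  mixing $10^{pK-pH}$ terms through `log1p` avoids under/overflow at pH
  extremes. Potentials are volts vs SHE and temperatures kelvin
  internally; mV and the SCE reference appear only at I/O boundaries
  (`to_she()` applies the +241 mV shift).

## Numerical choices

* **Overflow-safe waveform.** The rational expression is evaluated as
  $i = i_{lim}^{ox}\sigma(a)\sigma(b) - i_{lim}^{red}\sigma(-a)\sigma(-b)$
  with logistic factors, which is exact and bounded for any argument.
* **Broadening.** Slow, dispersed interfacial electron transfer broadens
  real waves. The full dispersed-rate Butler–Volmer treatment is out of
  scope here; `broadened_current()` instead averages the ideal waveform
  over a uniform potential-offset window (midpoint rule, 64 nodes),
  which preserves plateaus exactly, reduces to the ideal waveform at
  width 0, and moves the zero crossing by well under 1 mV for widths up
  to 100 mV. It is off by default and is a phenomenological shape
  control, not a physical ET model.
* **Optimizer.** All fits are Levenberg–Marquardt (`minpack.lm::nls.lm`)
  on explicit residual vectors with tight tolerances (`ftol`, `ptol`
  1e-14) and box bounds (currents ≥ 0, potentials within the data window
  ± 0.2 V). Order constraints are imposed by reparameterization:
  $pK_2 = pK_3 - \delta$ (or $pK_1 - \delta$) with $\delta \ge 0$.
  Standard errors come from the usual covariance approximation
  $\hat\sigma^2 (J^\top J)^{-1}$.
* **Multi-start.** The reductive-potential step of the pH protocol has
  local minima when pK and pK₂ are both free (a shallow trade-off
  between them and $E_2^0$); it is started from a small grid over both
  and the best deviance kept. The titration fit uses three starts to
  guard against its shallow $E_2^0$ direction.
* **Initial guesses.** Plateaus are top/bottom 5%-of-window medians
  (robust to noise); catalytic potentials come from peaks of a smoothed
  numerical dI/dE, with a single merged peak duplicated (reversible
  waves) and a missing branch seeded 0.1 V inside the other (monotone
  waves). A trace whose amplitude is below ~6× its point-to-point noise
  is rejected as "no catalytic wave".

## The sequential series protocol

`fit_ph_series()` follows the stepwise, constraint-aware order in which
such data are analyzed in practice:

1. oxidative limiting current → $\alpha$, $pK_1$ (often only an upper
   bound: a pH-independent plateau just means $pK_1$ is below the
   window);
2. reductive limiting current → $\beta$, $pK_3$;
3. reductive catalytic potential, with $pK_3$ fixed and $pK_2 \le pK_3$
   → $E_2^0$, $pK$, $pK_2$;
4. oxidative catalytic potential, with $pK$ fixed and $pK_2 \le pK_1$ →
   $E_1^{0app}$.

$pK_1$ and $pK_2$ are reported from their measuring steps (1 and 3);
step 4 refits them only as nuisance parameters. A pK whose fitted value
falls outside the condition window ± 0.3 log units is flagged as a bound
and rendered `<value` — the data constrain it only one-sidedly, and
refitting with the bound moved a unit lower changes the quotable
parameters by less than 1 mV / 0.01 pK (this insensitivity is tested).
The fits are inverse-variance weighted by stage-1 standard errors when
those are available and well conditioned, else uniform.

`global_fit()` fits all four observables simultaneously with shared
constants (potential residuals scaled by RT/F, currents by the largest
plateau); it is a cross-check and agrees with the sequential protocol on
noiseless data. `fit_h2_series()` fits the saturating oxidative current
and the logarithmic $E_{cat}^{ox}$ decrease jointly with a shared $K_M$
by default, and the H₂-independent reductive pair as constants.

One known flat direction deserves mention: in step 3 the pK of the
one-electron-reduced state trades off against $E_2^0$ over a range of
roughly half a pK unit with only a slight degradation of fit (moving pK
by −0.5 shifts $E_1^{0app}$ by a few tens of mV). The per-parameter
standard errors reported by the fit reflect this; no separate profile
likelihood is computed.

## The equilibrium titration model

At fixed H₂ pressure the solution potential experienced by the enzyme is
the Nernst potential of H⁺/H₂, so a pH titration sweeps potential and pH
together. Four states are observable by their CO-stretch marker bands
(defaults 1939, 1933, 1891, 1881 cm⁻¹ for Hox, Hred, HredH⁺, HsredH⁺);
their equilibrium fractions follow from Boltzmann weights built from two
reduction potentials and one protonation (`equilibrium_fractions()`,
computed with a log-sum-exp guard). Band amplitudes are converted to
fractions assuming equal extinction coefficients — supported by the
observed conservation of the summed band intensity, and checked by
`band_sum_varies()`, which flags series whose total drifts by more than
20%. Per-state extinction weights are available for sensitivity
analysis. The weak hydride-state band near 1850 cm⁻¹ is excluded as too
small to quantify. Residuals are unweighted across all four fractions
and all pH points; the exact weighting used in prior analyses of such
data is not documented, and on clean data the choice is immaterial
(recovery is exact to optimizer tolerance).

## What the generator emulates — and what it does not

`synthesize_series()` produces triangular sweeps (shared potential grid
in both directions), the model current (optionally broadened) scaled by
exponential film loss $e^{-\lambda\,(\text{scan index}-1)}$, plus a
quadratic background with a sweep-direction-antisymmetric offset
(capacitive current reverses sign with scan direction) and homoscedastic
Gaussian current noise; matching enzyme-free blanks and interleaved
reference scans at the anchor condition are emitted, and a YAML manifest
records every generator parameter for automatic recovery scoring. All
randomness flows from one integer seed.

Preprocessing mirrors standard practice: forward/backward averaging
(which cancels the antisymmetric offset except at the sweep vertex,
sampled only once), blank subtraction (removing the symmetric
background), and film-loss normalization using the top-5%-of-window
median oxidative plateau of the bracketing reference scans, interpolated
*linearly in log scale* against scan index — exact when the loss is
exponential, which is both the generator's model and the usual
first-order desorption picture. The plateau statistic itself is a
documented choice; any robust plateau summary would do.

The generator deliberately omits: electrode hydrodynamics and mass
transport (experiments rotate fast enough to make it negligible), ohmic
drop, instrument drift other than film loss, non-steady-state (scan-rate
dependent) responses, and the true dispersed-ET broadening shape.
Passing closed-loop tests therefore demonstrates that the inference
chain is self-consistent and unbiased under these nuisances — not that
real electrodes contain no others.

## Study conditions and defaults

The built-in benchmark conditions mirror the experimental design the
package is modeled on: pH series at 1 atm H₂ (grids 4.5–10 at 30 °C and
4.5–9 at 40 °C, step 0.5), H₂ series at constant pH (0.04–0.89 mM at
5 °C, pH 7.7; 0.06–0.64 mM at 40 °C, pH 6.5, using solubilities
0.89 mM/atm at 5 °C and 0.64 mM/atm at 40 °C), and a titration under 2%
H₂ over pH 5–10 (step 0.25). Parameter-table entries only known as upper
bounds are instantiated in the generators at pK₁/pK₂ = 4.5/4.0 (first
row) and 3.0/2.5 (second row), respecting pK₂ ≤ pK₁; the recovered
values then come back flagged as bounds whenever they fall below the pH
window, as they should. Sweeps use 400 points per half-sweep over a
window that extends ≳300 mV past both catalytic potentials, so both
plateaus are defined. These sizes keep a full closed loop under a couple
of seconds while leaving interpolation error far below the 1 mV / 0.02
pK recovery tolerances; the noisy Monte-Carlo checks use 50–100
replicates.

## Limitations

* The waveform applies to steady-state, ordered cycles only;
  chronoamperometry and non-steady-state voltammetry are out of scope.
* $E_1^{0app}$ is offset from $E_1^0$ by a rate-dependent term and
  cannot be interpreted as a thermodynamic potential; likewise
  $E_2^{0app}$ from an H₂ series. Only ($E_2^0$, pK) from a pH series,
  $E_1^{0\prime}$ from an H₂ series, and the titration parameters are
  thermodynamically meaningful.
* Intramolecular relay-cluster electron transfer and the ECEC/ECECC
  extensions are intentionally not modeled: they add parameters that
  this kind of data cannot determine.
* Equal extinction across marker bands is an approximation; the
  sensitivity path (`extinction` arguments) quantifies, but does not
  remove, the resulting bias.
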