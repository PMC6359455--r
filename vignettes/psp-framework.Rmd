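---
title: "The partial-solvation-parameter framework: model, numerics, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The partial-solvation-parameter framework: model, numerics, design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psptherm)
library(dplyr)
```

This vignette is the package's own account of the science it implements:
the model and its assumptions, the parameters that matter and their
defaults, the numerical choices, and what the tests do and do not
establish.

## 1. From LSER descriptors to solvation parameters

A compound is characterised by five Abraham-type LSER descriptors:
McGowan characteristic volume $V_x$ (in (cm$^3$/mol)/100), excess molar
refraction $E$, dipolarity/polarizability $S$, hydrogen-bond acidity $A$
and basicity $B$. The partial solvation parameters are

$$\sigma_d = 100\sqrt{\frac{3.1V_x + E}{V_m}},\quad
  \sigma_p = 100\sqrt{\frac{S}{V_m}},\quad
  \sigma_{Ga} = 100\sqrt{\frac{A}{V_m}},\quad
  \sigma_{Gb} = 100\sqrt{\frac{B}{V_m}},$$

all in MPa$^{0.5}$ with the molar volume $V_m$ in cm$^3$/mol. The acidity
and basicity parameters are Gibbs-level: the free energy of forming an
acid–base contact at 298 K is $-G_{HB,298} = 2V_m\sigma_{Ga}\sigma_{Gb}
= 20000\sqrt{AB}$ J/mol. Throughout the package the product "$AB$" in the
hydrogen-bonding working equations is read as $\sqrt{AB}$; only that
reading makes the free-energy identity algebraically consistent with the
definitions above, and it reproduces the reference surface- and
cohesive-energy tables cell by cell (the package tests assert both).

Drug molar volumes are rarely tabulated. `add_psp()` therefore resolves
$V_m$ with a fixed precedence: an explicit `Vm` column wins; otherwise
$V_m$ is recovered by inverting the $\sigma_d$ definition,
$V_m = 10^4(3.1V_x+E)/\sigma_d^2$, from a supplied dispersion parameter;
otherwise the compound is rejected with an error. The inversion route is
self-consistent: the recomputed $\sigma_p$, $\sigma_{Ga}$, $\sigma_{Gb}$
of all six bundled drugs then agree with the reference values to
$\pm0.01$ MPa$^{0.5}$.

Segment numbers for the lattice bookkeeping use the simple proportional
rule $r = V_x/0.213$ rather than a group-contribution scheme; 0.213 is
the McGowan volume of one lattice segment. All model constants (gas
constant 8.314 J/(mol K), the hydrogen-bond energy and entropy scales
30450 J/mol and 35.1 J/(K mol) per $\sqrt{AB}$, the lower-alkanol
reference pair $-23000$ J/mol and $-26.5$ J/(K mol) they interpolate, the
dispersion slope 3.1) live in one registry, `psp_constants()`.

## 2. Hydrogen-bond association equilibria

Each species carries at most one donor type (active when $A>0$) and one
acceptor type (active when $B>0$). Bond formation between donor $i$ and
acceptor $j$ has $G_{HB,ij} = -(30450 - 35.1\,T)\sqrt{A_iB_j}$ J/mol.
Pairs with $A_iB_j = 0$ are treated as *nonexistent* — their bond numbers
are pinned at zero and their terms dropped from every product and
logarithm — because a zero free energy would otherwise assert spurious
association between inert species.

With $\nu_{ij}$ the number of $i$–$j$ bonds per lattice segment
($r = \sum_k x_k r_k$ segments per mole of mixture), equilibrium is the
minimum of the Veytsman association free energy, with stationarity
conditions

$$\nu_{ij} = \nu_{i0}\,\nu_{0j}\,e^{-G_{HB,ij}/RT},\qquad
  \nu_{i0} = \frac{x_i}{r} - \sum_j \nu_{ij},\qquad
  \nu_{0j} = \frac{x_j}{r} - \sum_i \nu_{ij}.$$

For a pure self-associating fluid this collapses to a quadratic with the
closed form $r\nu_{11} = \bigl(A_{11} + 2 - \sqrt{A_{11}(A_{11}+4)}\bigr)/2$,
$A_{11} = r\,e^{G_{HB}/RT}$ — ethanol at 298.15 K gives a bonded fraction
of 0.767 — and the hydrogen-bonding cohesive energy density is
$ced_{HB} = -r\nu_{11}E_{HB}/V_m$, whose square root is $\sigma_{hb}$.

**Solver.** `solve_hbond()` sweeps the existing pairs Gauss–Seidel style:
holding the other bonds fixed, each $\nu_{ij}$ satisfies a scalar
quadratic that is solved exactly, so every sweep is a feasible descent
step on a strictly convex function. Plain damped successive substitution
on the stationarity conditions was rejected: for strongly associating
species the association constant can exceed $10^4$ and the substitution
map explodes from a cold start, whereas the coordinate-exact sweep is
unconditionally stable. Two numerical details matter:

* the smaller quadratic root is evaluated in its conjugate form
  $2K d a/(b + \sqrt{b^2 - 4K^2da})$, which avoids catastrophic
  cancellation when bonds are strong and one species is nearly absent
  (exactly the infinite-dilution regime IGC works in);
* after meeting the residual tolerance ($10^{-12}$ on the stationarity
  defect, 10,000-sweep cap) the solver runs cheap polish sweeps until the
  relative per-bond change falls below $10^{-14}$, so bond numbers of
  order $10^{-9}$ are still resolved to near machine relative precision.

The test suite checks the solver against an *independent* brute-force
minimiser of the same free energy (barrier-method `constrOptim` on the
bond variables) on random two-species systems: agreement to $10^{-8}$ on
every bond number, balances to $10^{-10}$.

## 3. Activity coefficients

$\ln\gamma_1$ of a solute in a binary mixture is combinatorial plus
residual. The combinatorial part is Flory–Huggins,
$\ln(\phi_1/x_1) + (1 - r_1/r_2)\phi_2$ (with its analytic
infinite-dilution limit $\ln(r_1/r_2)+1-r_1/r_2$ used at $x_1 = 0$); the
surface-fraction (Guggenheim–Staverman) alternative is deliberately not
implemented, so no $\theta$/$q$ bookkeeping exists anywhere. The residual
part has three contributions: two always-nonnegative quadratic terms,

$$\ln\gamma_1^{VE} = \frac{10^4V_{x,1}\phi_2^2}{RT}
  \Bigl(\sqrt{3.1 + E_1/V_{x,1}} - \sqrt{3.1 + E_2/V_{x,2}}\Bigr)^2,\qquad
  \ln\gamma_1^{S} = \frac{10^4V_{x,1}\phi_2^2}{RT}
  \Bigl(\sqrt{S_1/V_{x,1}} - \sqrt{S_2/V_{x,2}}\Bigr)^2,$$

and the hydrogen-bonding term from the association state of the mixture
referenced to the pure solute — the only contribution that can be
negative (cross-association pulls $\gamma$ below 1; self-association of
the solvent pushes it above). `activity_coefficients()` reports the split
plus $\chi_{12} = \ln\gamma_1^{res}/(r_1\phi_2^2)$.

**Infinite dilution.** IGC measures $\ln\gamma^\infty$, so the limit
$x_1\to0$, $\phi_2\to1$ is implemented twice: numerically (the full model
at $x_1 = 10^{-8}$) and analytically, with the solvent self-association
fraction $r_2\nu_{22}$ and cross-association constants
$A_{ij} = r_2e^{G_{HB,ij}/RT}$:

$$\ln\gamma_1^{res,\infty} = \{VE + S\}_{\phi_2=1} + r_1\nu_{22}
 - \ln\frac{1 + A_{12} - r_2\nu_{22}}{A_{12}}
 - \ln\frac{1 + A_{21} - r_2\nu_{22}}{A_{21}}
 - \bigl\{r_1\nu_{11} + 2\ln(1 - r_1\nu_{11})\bigr\}.$$

The grouping of the logarithmic terms is fixed by requiring agreement
with the numerical limit, not by typography: the suite verifies
$|{\rm analytic} - {\rm numerical}(x_1{=}10^{-8})| < 10^{-5}$ over 100
random descriptor draws (the residual difference is genuine $O(x_1)$
truncation of the numerical route, about $10^{-7}$–$10^{-6}$ here). The
numerical limit is the fallback authority wherever the two could
disagree.

Temperatures are explicit everywhere; defaults are 298.15 K for bulk
properties and 303.15 K (the 30 °C column) for IGC-related quantities.

## 4. Solubility

The solid–liquid equilibrium estimate is

$$y_1 = \frac{1}{\gamma_1^C\gamma_1^{res}}
  \exp\Bigl\{\frac{\Delta H_1^m}{RT}\Bigl(\frac{T}{T_1^m}-1\Bigr)\Bigr\},$$

with both activity coefficients evaluated at the *saturated* composition
(not at infinite dilution): that is the standard reading of the
expression, and `solve_solubility()` makes it concrete as a fixed-point
iteration $y \leftarrow y^{id}/(\gamma^C(y)\gamma^{res}(y))$ started at
the ideal value, damped by 0.5, capped at $y = 1$ and stopped when
successive iterates agree to $10^{-10}$. No $\Delta C_p$ correction, no
solid-state activity correction, no solvate/polymorph thermodynamics: a
drug that changes solid form in a solvent is outside the model, and the
evaluation utility (`evaluate_predictions()`) accepts an exclusion list
for such cases instead of pretending to model them. Compounds without
fusion data (the amorphous cyclosporine A) fail loudly by design.

## 5. Surface energy

With $D = 3.1V_x + E + S$, a measured dispersive surface energy
$\gamma_d$ (Dorris–Gray from alkane IGC; always an *input* here, never
computed) is identified with the non-hydrogen-bonding component
$\gamma_{VES}$ and split by the proportionality
$\gamma_a/A = \gamma_b/B = \gamma_{VES}/D$, giving
$\gamma_{hb} = 2\sqrt{\gamma_a\gamma_b}$ and
$\gamma_{tot} = \gamma_d\,(D + 2\sqrt{AB})/D$. The proportionality
constant $\gamma_{VES}/D$ is a deliberate design choice: the printed form
of the defining relation is typographically ambiguous, and this is the
unique reading that reproduces every acid/base cell of the reference
drug table to $\pm0.01$ mJ/m$^2$ (tested for all six drugs). The inverse
map from a *total* surface energy, and the geometric-mean contact-angle
relation (with $\cos\theta$ clamped to $[-1,1]$ so complete wetting and
dewetting are handled without errors), complete the module. The PSP
polarity descriptor $S$ is used in $D$ — the in-silico alternative does
not reproduce the reference cells.

## 6. IGC reduction

The chain is net retention volume
$V_N = (j/m)F(t_R - t_0)\,T/273.15$ (James–Martin correction $j$
computed from inlet/outlet pressures when not given), mass activity
coefficient
$\ln\Omega^\infty = \ln\bigl(273.15R/(p_0M_1V_N)\bigr) - p_0(B_{11}-V_1)/RT$,
and the mole-fraction conversion that strips exactly the Flory–Huggins
combinatorial dilution limit, leaving the residual
$\ln\gamma_1^{res,\infty} = r_1\chi_{12}$. Internally everything is SI —
that is the convention under which the logarithm's argument is
dimensionless — while `reduce_igc()` accepts the lab-unit run sheet
(seconds, sccm, mg) and converts. Probe saturation pressures, second
virial coefficients and molar volumes at 303.15 K are not part of the
measured record; the bundled `probes_physical.csv` carries compiled
reference estimates, is documented as such, and is meant to be edited —
fitted descriptors inherit whatever uncertainty these properties carry.

## 7. Descriptor fitting

`fit_descriptors()` estimates a stationary phase's $E, S, A, B$ (with
$V_x$ known from structure) from a panel of probe
$\ln\gamma^\infty$ values via the analytic infinite-dilution model. The
staging follows the physics: stage 1 fits $(E,S)$ with $(A,B)$ held
fixed, stage 2 fits $(A,B)$ with $(E,S)$ fixed, alternating to
convergence ($10^{-8}$ on descriptor changes, 50-round cap). Both stages
minimise the *same* full-panel least-squares objective over complementary
coordinate blocks, so the alternation is exact block coordinate descent
and the objective decreases monotonically (a tested invariant). Stage 1
is *not* restricted to hydrocarbon probes: the measured panel contains no
aromatics, and alkanes alone constrain only the sum of the dispersion and
polarity brackets (both scale identically with probe $V_{x,1}$), leaving
$E$ and $S$ unidentifiable in isolation; the polar probes' brackets break
the degeneracy. Each stage uses bounded Levenberg–Marquardt
(`minpack.lm`) with five deterministic starts including zero, ties broken
by lowest rms then smallest parameter sum; because the alternation can
still park a coordinate on the nonnegativity bound in a shallow local
minimum, a joint four-parameter polish from the alternation result plus
five deterministic starts finishes the fit. Noise-free synthetic panels
are recovered to better than $10^{-4}$ in every coordinate over random
drug-like truths (tested over 20 draws).

**Identifiability.** A drug's acidity $A$ is sensed through
cross-association with *basic* probes ($B_1 > 0$), its basicity $B$
through *acidic* probes ($A_1 > 0$: chloroform, dichloromethane), and
both through its own self-association term $r_1\nu_{22}$, which shifts
every probe. One-sided panels trigger explicit identifiability warnings.

**Uncertainty.** The `psp_fit` object carries Wald standard errors from
the numeric Jacobian at the solution. These are local: the model is
strongly curved in $E$ over the width of its own confidence interval
(the $E$ sensitivity of every probe enters through
$\sqrt{3.1 + E/V_{x,2}}$ with drug-sized $V_{x,2}$ in the denominator, so
$E$ is weakly identified at realistic noise), and $\pm3$ Wald-SE
intervals undercover in simulation. Recovery studies therefore use the
Monte-Carlo formulation packaged as `descriptor_recovery_study()`: draw a
truth, simulate replicate noisy panels, refit each, and take the
*empirical* sampling standard deviation per coordinate as the standard
error. Under the study conditions — the ten-probe measured panel,
Gaussian noise of 0.05 on $\ln\gamma$, truths drawn across the drug
descriptor ranges but away from the nonnegativity bounds
($A \in [0.2, 0.8]$, $B \in [0.6, 2.5]$), where sampling theory for a
bounded estimator applies — at least 95% of replicates land within three
such standard errors of the truth in every coordinate. The suites run
this at 4 truths × 25 replicates (tests) and 8 × 25 (studies); sizes
chosen as the smallest that estimate a per-truth SD stably.

**What the generator emulates — and does not.** `generate_synthetic_igc()`
produces model-exact $\ln\gamma^\infty$ values plus i.i.d. Gaussian
noise, bit-reproducible per seed. Real IGC data additionally carry
probe-specific systematic error: gas-phase association of alkanols,
finite surface coverage, probe-property (Antoine/virial) bias — effects
that are *not* independent noise and will not shrink with replication.
Passing recovery tests therefore establishes the correctness and
stability of the estimation machinery, not that four descriptors can be
extracted from any real ten-probe experiment at this accuracy; with real
data the reported drug descriptors remain initial estimates whose
per-probe residual diagnostics (`autoplot()`, `jackknife_descriptors()`)
deserve inspection.

## 8. Known limitations and documented discrepancies

* One donor type and one acceptor type per molecule; multi-site typing is
  out of scope.
* Binary mixtures only in the activity and solubility layers (the
  association solver itself is n-species).
* The reference table of drug cohesive-energy components is *partially*
  reproducible from the printed descriptors: $\sigma_p$, $\sigma_{Ga}$,
  $\sigma_{Gb}$ match to $\pm0.01$ MPa$^{0.5}$, but $\sigma_{hb}$ for the
  three self-associating drugs does not (recomputed 8.39/3.57/9.09
  against published 8.14/2.89/9.01 MPa$^{0.5}$; carvedilol, simvastatin,
  zafirlukast). The implied self-association constants differ by a
  near-constant factor, suggesting the published values used unrounded
  descriptors or a different segment/temperature convention. The package
  does not force-match: it documents the recomputed values and the test
  suite asserts agreement only to the 25% band the discrepancy supports.
* Drug descriptors themselves are not numerically reproducible from the
  published record (raw retention data unpublished); the fitting module
  is validated by synthetic recovery instead.

## 9. Problem sizes used by the shipped suites

Oracle comparisons run 50 random two-species association systems and 100
random infinite-dilution draws; descriptor recovery runs 20 noise-free
truths and 100–200 noisy replicate fits; the solubility and surface
checks are desk-scale (six drugs, thirty solvents). These sizes are the
package's own validation choices: large enough to exercise every branch
(zero-descriptor species, strong association, boundary compositions),
small enough that the whole suite runs in a couple of minutes on one
core.
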