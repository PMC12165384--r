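---
title: "Modeling locally administered CAR T-cell therapy in solid tumors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling locally administered CAR T-cell therapy in solid tumors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cartloco)
```

## The model

`cartloco` simulates a radially symmetric solid tumor interacting with
chimeric antigen receptor (CAR) T cells delivered locally — either injected
into the tumor center (intratumoral) or layered onto its surface
(intracavitary). Two density fields live on a radial grid: the tumor cell
density $u(r,t)$ and the effector CAR T-cell density $v(r,t)$
(cells/cm$^3$), plus a scalar count $V_E(t)$ of exhausted CAR T cells.

The tumor follows logistic growth with density-thresholded diffusion
("go-or-grow"):

$$\partial_t u = \frac{1}{r^2}\partial_r\!\left(D_T(u)\, r^2 \partial_r u\right)
  + a\,u\,(1 - b\,u) - D(u,v), \qquad
  D_T(u) = \begin{cases} 0 & u \le u^* \\ D_T^* & u > u^* \end{cases}$$

Below the critical density $u^*$ cells proliferate in place; above it they
also migrate at rate $D_T^*$. The local lysis rate is the ratio-dependent
saturating form

$$D(u,v) = d\,\frac{(v/u)^l}{s + (v/u)^l}\,u,$$

so killing saturates at $d$ per tumor cell per day as the CAR T : tumor
ratio grows, with cooperativity $l$. Effector CAR T cells diffuse at a
constant $D_C$, proliferate in response to ongoing lysis, die at rate $m$,
and convert to the exhausted state upon repeated engagement:

$$\partial_t v = \frac{D_C}{r^2}\partial_r\!\left(r^2 \partial_r v\right)
  + j\,\frac{D^2}{k + D^2}\,v - m\,v - q\,u\,v.$$

Exhausted cells are inert and tracked as a whole-tumor count so simulated
totals can be compared with imaging measurements that do not distinguish
phenotypes:

$$\frac{dV_E}{dt} = -m\,V_E + 4\pi q \int_0^{r_{max}} u\,v\,r^2\,dr.$$

The boundary conditions are symmetry at the origin, a far-field Dirichlet
condition $u = 0$ at $r_{max}$ (free tumor expansion; the threshold keeps
the tumor away from the boundary), and zero flux for $v$ (CAR T cells may
accumulate at the domain edge without artificial leakage).

## Parameters

Four tumor archetypes ship as presets (`tumor_preset()`), spanning
proliferation rates $a$ of 0.025–0.25/day and diffusivities $D_T^*$ of
1e-5–1e-4 cm$^2$/day, with thresholds at 50%, 10%, 1% and 1% of the
carrying capacity $1/b = 2.39\times10^8$ cells/cm$^3$ (a 10 µm cell
radius). The imaging detection threshold defaults to $10^8$ cells/cm$^3$;
tumor tissue below it is invisible, which is what makes the diffuse
type III/IV archetypes clinically deceptive — their growth front advances
undetected.

The CAR T-cell diffusion constant defaults to $D_C = 0.0138$
cm$^2$/day, derived from intratumoral CAR T-cell velocities in murine
imaging; a value 100-fold larger also circulates for the same measurement
and is best read as a unit slip. The remaining CAR T kinetic parameters
(`cart_preset()`) are **synthetic reconstructions**: the published
supplementary tables they would come from are not redistributable here, so
the package ships parameter vectors inside the biologically reported
ranges, calibrated once so that the shipped scenarios reproduce the
reported treatment phenomenology — eradication of a 2 cm type III tumor
around four weeks after a 10$^9$-cell intratumoral dose, a complete-to-
progressive flip near 20% ex vivo exhaustion for type IV at $3\times10^8$
cells, no intracavitary eradication of 2 cm tumors, and the mouse-scale
timing described below. They are calibration products, not measurements,
and every value is overridable through `cart_params()` or a YAML/JSON
config (`write_params()`).

Two defaults are package choices where the source material is qualitative:
the intratumoral injection ball radius (`r_inj = 0.5` cm for a 2 cm tumor;
"a high concentration at the center" fixes neither the volume nor the
concentration, and the wider bolus is required for the top dose to clear
the dense type I tumor) and the intracavitary shell thickness (two grid
cells). Both are recorded in every run manifest and exposed in
`scenario()`.

## Numerics

The solver (`simulate()`, compiled core) uses node-centered finite volumes
on a uniform radial grid with face areas $\propto r^2$: the origin has a
zero-area face, so the $1/r^2$ coordinate singularity never appears and
zero-flux mass conservation is exact to round-off. Time stepping is
Crank–Nicolson for both diffusion operators with the thresholded tumor
diffusivity evaluated once per step from the beginning-of-step state
(lagged mask, preserving tridiagonality), and a Heun (trapezoidal)
predictor–corrector for the reaction terms. A single-evaluation explicit
reaction variant is available (`reaction_order = 1`); the default keeps
the scheme second-order on smooth problems, which the verification study
below confirms. The exhausted-cell count advances by a matched
exponential/trapezoidal update. Negative densities (possible for
Crank–Nicolson at under-resolved fronts) are clamped to zero and the
clamped mass is accumulated and reported; at the shipped resolutions it is
zero in all shipped scenarios.

The default grid spacing is $\Delta r = 0.015$ cm and the default step is
the empirical recipe $\Delta t = \min(a\,\Delta r / D_C,\ \Delta r/5)$
days, offered verbatim despite its unusual dimensional form; any explicit
`dt` overrides it. Mouse-scale runs use $\Delta r = 0.005$ cm and $\Delta
t = 0.002$ d — at coarser steps the eradication fronts in the
fast-killing mouse fits are under-resolved and measurable clamping
appears, which is the diagnostic the `clamped_mass` field exists for.

The **threshold mask on faces** deserves a note. The continuous model
does not determine how the step diffusivity should be evaluated at a cell
face. Applying
the threshold to the face-averaged density deadlocks any tumor with $u^*
\ge (1/b)/2$ — the face between a saturated and an empty cell averages to
below threshold, so the type I archetype could never spread. The package
default (`mask_rule = "node"`) averages the two node diffusivities, so an
above-threshold node always sheds mass at $D_T^*/2$; `"either"` (full
diffusivity if either node is above threshold) and a smooth-`"ramp"`
regularization are provided for comparison. All three produce detectable
front speeds within ~10% of each other and are grid- and step-converged;
the choice is not what limits accuracy.

**Doubling times.** With the four preset archetypes, the volume doubling
times from a 2-cm detectable baseline computed by the reproduction script
are roughly 194, 136, 103 and 32 days (types I–IV). These are the model's
own converged values: the implied detectable-front speeds respect the
rigorous comparison bound that a thresholded front cannot outrun the
constant-diffusivity Fisher speed $2\sqrt{a D_T^*}$, and the day-56
refinement test confirms grid/step stability. Published doubling times
for parameter sets of this kind are substantially shorter, which would
require front speeds above that bound; reproducing them would require
either different parameters or numerically under-resolved front handling,
and the package deliberately reports its converged values instead.

## Verification

`mms_convergence()` runs a method-of-manufactured-solutions study. The
smooth control problem (Gaussian fields, no threshold, midpoint source)
shows the classical second-order Crank–Nicolson behavior in both
$\Delta t$ and $\Delta r$. For the thresholded operator a naive
manufactured pair is *inconsistent*: the flux jump at the moving threshold
interface is not representable by a pointwise source, and the measured
error saturates rather than converges. The package therefore uses a
threshold-compatible design (`mms_solution_threshold()`): the active
region carries a bump whose gradient vanishes at the interface, so the
composite solves the discontinuous-coefficient equation exactly and any
degradation is attributable to the discrete mask. With a static interface
the spatial order for $u$ at $r = 0.5$ drops to about 1.1; with a moving
interface the temporal error is dominated by irregular mask-crossing
events and the fitted temporal order is unstable between about 1 and 2.5
depending on the interface speed — the package reports the fit diagnostics
(`r_squared`, monotonicity) alongside every order estimate for this
reason.

## Scenarios, outcomes, calibration

`grow_to_size()` integrates a 1 mm seed at carrying capacity until the
detectable radius reaches a target (memoized per session; the domain
auto-extends if the tumor nears its edge). `init_intratumoral()` /
`init_intracavitary()` place the effector fraction of a dose as a central
ball or a surface shell, with the exhausted fraction going directly into
$V_E$; both conserve the dose to relative 1e-6 and never touch $u$.

Outcomes are computed from the recorded scalar series: detectable radius
(outermost interpolated crossing of the detection threshold), total and
detectable burden, volume doubling time and time to progression (linear
interpolation between samples), and response labels. RECIST uses
diameter-only rules (CR disappearance, PR at −30%, PD at +20%, with
progression treated as irreversible once reached, following clinical
practice); Choi additionally accepts a 15% drop in average detectable
density (fold change ≤ 0.85) or a 10% diameter decrease as partial
response. Eradication is defined as fewer than one whole tumor cell — a
grid-independent count, chosen because "eradicates" needs an unambiguous
computational meaning. The default evaluation time is 56 days (8 weeks),
overridable since the classification is known to be timing-sensitive.

Calibration fits follow a staged procedure: `fit_growth()` does bounded
two-parameter least squares for $(a, D_T^*)$ on pre-treatment burden
series; `fit_killing_rate()` does a bracketed one-dimensional search over
$d$ on treated series; `lhs_refine()` iterates latin-hypercube sampling
with re-centering on the best three runs and box shrinkage (factor 0.5 per
round), stopping on a concrete version of "satisfactory fit": under 1%
round-over-round improvement. Bioluminescence series can be marked
proportional, in which case the photons-to-cells scale factor is profiled
out analytically rather than invented. `generate_synthetic_series()`
produces fixture data for recovery tests: model totals sampled at given
times under unit-mean multiplicative lognormal noise. The generator
emulates the two mouse-study designs (pre-treatment growth points plus
post-injection decline; joint short-horizon tumor and CAR T series); it
does not emulate measurement censoring, inter-animal variability beyond a
single noise level, or BLI saturation, so passing recovery tests show
identifiability under the model's own assumptions, not robustness to real
assay artifacts.

## Problem sizes used in tests and reproduction runs

Shipped tests and the reproduction script run the human-scale scenarios at
$\Delta r = 0.015$ cm (grids of 200–400 nodes, steps of 0.003 d) and the
mouse-scale scenarios at $\Delta r = 0.005$ cm, $\Delta t = 0.002$ d;
refinement by a factor 2 in both changes day-56 burdens by under 2%.
Outcome maps in examples use coarse dose/exhaustion grids (the full
10-point-per-axis maps are a straightforward but longer `outcome_map()`
call).

## Known limitations

* The CAR T kinetic preset is a calibrated reconstruction, not a fitted
  published set; conclusions that depend on its exact values (e.g. the
  precise minimum-dose boundaries) should be treated as illustrative.
* At the shipped resolution the intracavitary response of the dense
  archetypes classifies as stable disease rather than partial response:
  burden falls substantially but the diameter does not shrink past the
  RECIST −30% bound.
* Progression is single-lesion by construction; multi-lesion RECIST
  clauses (new lesions) have no counterpart in a radially symmetric model.
* The model omits necrosis, angiogenesis, chemotaxis, antigen
  heterogeneity and endogenous immunity; it is a deliberately minimal
  spatial extension of well-mixed CAR T ODE models.
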