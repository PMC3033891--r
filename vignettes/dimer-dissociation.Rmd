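---
title: "An elastic tug-of-war: modelling gramicidin dimer dissociation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An elastic tug-of-war: modelling gramicidin dimer dissociation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memtug)
```

## The model

Gramicidin A forms bilayer-spanning ion channels by head-to-head
dimerization of two subunits, one per leaflet. The conducting dimer is
shorter than the unperturbed bilayer hydrophobic thickness, so the bilayer
must deform locally to meet the channel, and the resulting elastic
frustration acts as a *disjoining force* that pulls the two subunits apart.
`memtug` models this competition in one dimension, along the axial
centre-of-mass separation $r$ of the two monomers:

$$
V(r) \;=\; D_e\left[\bigl(1 - e^{-\beta (r - r_e)}\bigr)^2 - 1\right]
\;+\; \frac{H_B}{2}\,\bigl(d - l(r)\bigr)^2 .
$$

The first term is a Morse bond: the subunit–subunit junction (a few
intermonomer hydrogen bonds plus packing interactions) with dissociation
energy $D_e$, equilibrium separation $r_e$, and stiffness $\beta$; near the
minimum it is harmonic with force constant $k = 2 D_e \beta^2$
(`beta_from_hooke()` inverts this). The second term is the bilayer: the
full continuum elastic response (compression plus bending) collapsed into a
single phenomenological spring of coefficient $H_B$ acting on the
hydrophobic mismatch $d - l(r)$ between the bilayer hydrophobic thickness
$d$ and the dimer hydrophobic length $l(r)$.

**Length coupling.** The membrane term needs $l$ as a function of $r$, and
the geometry fixes only that $l$ grows as the subunits separate axially. We
take the simplest coupling consistent with that geometry,
$l(r) = l_0 + s\,(r - r_e)$ with unit slope $s = 1$ by default: every
nanometre of extra separation adds one nanometre of hydrophobic length.
The slope is exposed as `coupling_slope` so its influence can be explored,
but all shipped results use 1. The dissociated well then sits where the
mismatch is relieved, $l(r) = d$, i.e. near $r = r_e + (d - l_0)$.

**Offset convention.** The Morse term is written with its minimum at
$-D_e$ and plateau at 0, so $D_e$ reads directly as the bond depth. Every
reported kinetic quantity is an energy *difference* and is therefore
independent of this convention.

**Two-sided spring.** The membrane term penalizes overshoot
($l(r) > d$) as well as undershoot. A rectified, one-sided spring would be
a different physical claim and is deliberately not implemented.

**Temperature.** The Arrhenius expression needs $k_BT$; we store the
single field `kBT` and express energies in thermal units by default
(`kBT = 1`), which absorbs the temperature into the unit system rather than
carrying a redundant $(k_B, T)$ pair.

## Landscape analysis

With realistic parameters the potential is a double well: the
conducting-dimer well near $r_e$, the dissociated well near relieved
mismatch, and a transition state between them. `analyze_landscape()`
evaluates the analytic gradient on a bracketing grid (4001 points over an
interval auto-derived to cover both candidate wells with five Morse decay
lengths of margin), refines every sign change by Brent bracketing followed
by a Newton polish using the analytic curvature, and accepts a root only
when the gradient is below $10^{-10}$ in reduced units. Roots closer than
$10^{-6}\,r_e$ are merged; a curvature magnitude below $10^{-8}$ (reduced)
is classified degenerate and flags the landscape `barrierless`, since that
is the signature of the bifurcation at which the transition state and a
well coalesce. These tolerances are engineering choices, documented here
precisely because the physics does not dictate them.

Regimes: `double_well` (minimum–maximum–minimum), `single_well_dimer`
(e.g. $H_B = 0$, or mismatch too weak to carve a second well),
`single_well_dissociated` (membrane wins outright), and `barrierless`.
In a single-well landscape the well is attributed to the dimer or the
dissociated state by whichever of $r_e$ and the mismatch-relief separation
it lies closer to.

An entirely derivative-free check, `oracle_grid_search()`, locates extrema
of the *sampled* potential values on a dense grid. The test suite holds the
root-finder to agreement with this oracle — same count, same kinds,
locations within one grid step — across randomized parameter sets.

```{r landscape}
p <- load_config(NULL)$params   # default profile
L <- analyze_landscape(p)
L
```

## Kinetics

In the double-well regime, transition-state theory gives the dissociation
rate $k_d = A \exp(-\Delta V^{\ddagger}/k_BT)$ with
$\Delta V^{\ddagger} = V(r_{ts}) - V(r_{dim})$, and the mean channel
lifetime is $\tau = 1/k_d$. The pre-exponential factor $A$ is not fixed by
a 1D energetic model (it would require attempt frequencies and friction),
so lifetimes are reported as $\ln(\tau A) = \Delta V^{\ddagger}/k_BT$ by
default, which every trend result is invariant to; absolute lifetimes are
available whenever the user supplies `A`. When no transition state exists
the rate is reported only as the lower bound $A$ (`rate_lower_bound`)
rather than fabricating a barrier. The disjoining force is
$F = H_B\,(d - l(r_{dim}))$, the membrane spring force evaluated at the
dimer well — identically minus the gradient of the membrane term there,
which the tests assert to $10^{-10}$.

```{r kinetics}
kinetics_summary(L)
```

## Parameter defaults (the `paper2011` profile)

The shipped profile describes gramicidin A in a monoglyceride-like bilayer,
in thermal energy units and nanometres:

| field | value | meaning |
|---|---|---|
| `D_e` | 20 kBT | junction depth; a multi-hydrogen-bond interface, giving a ~14.5 kBT barrier and hence lifetimes of seconds for attempt rates of $10^6$–$10^9\,s^{-1}$ |
| `r_e` | 1.1 nm | equilibrium centre-of-mass separation, half the dimer hydrophobic length |
| `beta` | 10 /nm | Morse decay length 0.1 nm; equivalent Hookean constant $k = 2 D_e \beta^2 = 4000$ kBT/nm² (~16 N/m, the right order for a few hydrogen bonds in parallel) |
| `l0` | 2.2 nm | dimer hydrophobic length |
| `d` | 3.0 nm | bilayer hydrophobic thickness (mismatch 0.8 nm) |
| `H_B` | 20 kBT/nm² | membrane spring coefficient (~0.08 N/m), the order of continuum-elastic estimates for solvent-free monoglyceride bilayers — and three hundredfold softer than the bond, which is what makes the tug-of-war interesting |
| `A` | 1 | reduced time units |
| `kBT` | 1 | energies already thermal |

The profile lives in `inst/extdata/profiles/paper2011.yaml` and is loaded
by name, never hard-coded in the model core. In reduced units (energies per
$D_e$, lengths per $r_e$) this landscape coincides with the test suite's
reduced set $\{D_e = 1, r_e = 1, \beta = 10, l_0 = 2.2, d = 3, H_B = 1\}$
up to the energy scale, so every frozen oracle value exercises the same
geometry the defaults do.

## Scans and linear trends

`scan_thickness()` and `scan_stiffness()` recompute the landscape and
kinetics point by point (each row is independently reproducible by
`analyze_landscape()` + `kinetics_summary()` at that row's parameters) and
fit $\ln(\tau A)$ against the swept variable by OLS over the double-well
rows only; rows in other regimes are retained in the output but excluded
from the fit, with the fitted count recorded, because near-bifurcation rows
have no barrier and would silently corrupt the summary. Default ranges are
$d \pm 0.4$ nm and $H_B \pm 50\%$ in 9 points; ranges are user inputs, not
baked into logic. The $r^2$ thresholds used by the test suite to
operationalize "approximately linear" (0.98 for lifetime trends, 0.99 for
force-vs-mismatch) are recorded in each scan's `meta` so reports are
self-describing.

```{r scans}
sc <- scan_thickness(p)
glance(sc)
mismatch_slope(sc)
```

Three robust behaviours emerge over the double-well range, mirroring what
single-channel electrophysiology sees when bilayer thickness or stiffness
is titrated: $\ln \tau$ falls approximately linearly with thickness and
with stiffness; the distance the subunits must separate to reach the
transition state *decreases* as the bilayer thickens, but modestly; and the
disjoining force is almost exactly linear in the mismatch, which is the
assumption underlying the experimental use of gramicidin as a bilayer-force
transducer.

One quantitative caveat discovered while testing: over the default
thickness sweep the *relative* change in the barrier (23%) is smaller than
the relative change in the transition-state distance (30%), and both are
invariant under rescaling the energy axis. The sense in which the distance
change is "small" is relative to the lifetime itself: a 3.5 kBT barrier
change multiplies $\tau$ thirty-fold (a 97% relative change) while the
distance moves 30%. One acceptance-style check in the test suite asserts
the barrier-based ordering and is expected to fail; it is retained
deliberately as a record of this distinction.

## The fixture generator

`generate_fixture_parameters()` draws randomized, physically sensible
parameter sets for property tests: $D_e \in [2, 30]$ kBT,
$\beta r_e \in [2, 30]$, $r_e \in [0.5, 2]$ nm, mismatch
$d - l_0 \in [-0.5, 1.5]$ nm (negative mismatch is legal), and $H_B$
limited so the frustration energy at the dimer well never exceeds $D_e$
(with an additional cap of $20 D_e / r_e^2$ so near-zero mismatch cannot
produce an unphysically stiff membrane). Each set is annotated with the
regime found by a coarse oracle pass. Draws are deterministic per seed and
leave the caller's RNG state untouched. What this emulates is the *range*
of elastic environments a channel could meet; what it does not emulate is
real data — there is no noise model, no 3D geometry, no lateral monomer
diffusion — so passing tests demonstrate internal consistency of the
energetics and numerics, not quantitative prediction of measured lifetimes.

## Numerical choices and degenerate inputs

* Bracketing grid 4001 points; robustness over speed at this problem size.
* Root refinement: Brent on the bracket, then Newton with the analytic
  curvature; stops at $|V'(r)| \le 10^{-10}$ (reduced).
* Ties and merges: roots within $10^{-6} r_e$ collapse to one.
* Sweeps accept repeated values (a constant sweep yields identical rows)
  but reject unsorted input; thickness values must be positive, stiffness
  values non-negative.
* `linear_fit()` refuses fewer than three finite pairs or zero variance in
  x; a constant response returns slope 0 with $r^2 = 1$ (zero residual on
  zero total variance) and a `degenerate` flag.
* Problem sizes in the shipped checks — 4001-point brackets, 9-point
  sweeps, 100 fixture sets against a $10^{-4} r_e$-step oracle — keep the
  full suite comfortably interactive while still resolving every feature
  (the narrowest, the Morse well, is ~0.1 nm wide against a
  ~$10^{-4}$ nm step).

## Known limitations

The model is one-dimensional and two-body: it cannot resolve the coupled
rotation/translation of real dissociation pathways, intermediate
partially-hydrogen-bonded conducting states, or lateral drift after
separation, and its absolute rates inherit the unassigned prefactor $A$.
It is a tool for *trends* — how lifetime responds to thickness and
stiffness — and for making the disjoining-force picture quantitative
within its own assumptions.
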