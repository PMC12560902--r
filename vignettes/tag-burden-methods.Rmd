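---
title: "Methods: from drag coefficients to tag burden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from drag coefficients to tag burden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tagburden)
```

## What the package models

An externally attached tag changes the drag a swimming shark must overcome.
CFD sweeps summarise that change as drag coefficients
$C_D = 2 F_D / (\rho A U_\infty^2)$ on a grid of swim speeds and body sizes,
for an untagged baseline and one or more tag configurations. Everything in
this package is downstream of such a grid: forces, daily energetics,
equal-power speed compensation and the assessment tables built from them.
The packaged grid covers a lamnid body plan at fork lengths 1–2.95 m and
speeds 0.5–9.1 m/s, with an archival tag on the dorsal musculature
(all sizes) and a fin-mounted transmitter (full size only).

The underlying flow assumptions are inherited from the sweeps themselves: a
rigid body in steady rectilinear flow, a fully turbulent boundary layer,
gravity and buoyancy neglected (shark tissue is close to neutrally buoyant
in seawater), and no body undulation or fin propulsion. Drag on the rigid
body then stands in for the thrust the animal must produce, which is why
drag power is used as the energetic currency.

## Physical parameters and defaults

| parameter | default | units | why |
|---|---|---|---|
| density $\rho$ | 1025 | kg/m³ | seawater at 20 °C, typical of the habitat |
| dynamic viscosity $\mu$ | 0.00109 | Pa·s | same |
| fork length $L$ | user | m | characteristic length; snout to caudal fork |
| frontal area $A$ | $c_A L^2$, $c_A = 0.12/2.95^2$ | m² | see below |
| cruise speed | 1 | m/s | sustained swimming in tracking records |
| glide fraction | 0.07 | — | regular unpowered glide phases |
| burst speeds | 3.6, 5, 7.8, 9.1 | m/s | recorded burst range; sub-adult grids conventionally use 3.6 only |
| burst fractions | 0–0.20 step 0.01 | — | range reported for the behaviour; the 1% step is this package's resolution choice |
| day length | 86 400 | s | "daily" taken literally |
| turbulence intensity Ti | 0.02 | — | the value used in the sweep calibration; an assumption for production speeds, overridable |

Frontal area is never printed alongside published coefficient tables, so it
is a configurable geometry field with a slender-body default calibrated to
give $A \approx 0.12\,\mathrm{m}^2$ at $L = 2.95$ m. Every headline metric
is a ratio in which $A$, $\rho$ and day length cancel; absolute forces and
energies are reported with that caveat, and `energy_increase()` computes the
ratio from dimensionless $\sum_b f_b\, C_D(v_b)\, v_b^3$ sums so the
cancellation is structural (bit-exact), not a numerical accident.

The length–mass model is isometric, $m = 17\,(L/1\,\mathrm{m})^3$ kg,
anchored at the 17 kg mass of a 1 m animal; the anchor and exponent are
overridable because published length–weight fits vary by region and species.
Uniform geometric scaling ($L \to sL$, $A \to s^2 A$, $m \to s^3 m$)
mirrors how smaller age classes are represented in the sweeps; ontogenetic
shape change is not modelled.

## Interpolation and numerical choices

`lookup_cd()` is linear in $\log C_D$ vs $\log U$ between speed knots —
turbulent drag coefficients decay approximately as a power law in Reynolds
number, so the log–log interpolant is smooth, exact at knots, and preserves
monotone decay — and linear in fork length between tabulated sizes. Queries
outside the grid are clamped to its edge with a warning by default; a strict
mode raises a range error instead, because the sweeps say nothing beyond
their own span. Each (size, speed) pair is treated independently; no
Reynolds-similarity matching across sizes is attempted, since the packaged
coefficients are themselves size-specific.

Equal-power burst-speed compensation is deliberately offered in two
variants, because "same power output" is ambiguous about whether drag is
re-evaluated at the reduced speed:

* `fixed_force` holds the drag force at its burst-speed value, giving the
  closed form $v' = v_b/(1+\delta)$, reduction $\delta/(1+\delta)$. Reported
  speed reductions in the tag-burden literature (≈22% for a ≈27–31% drag
  increase) are consistent with this arithmetic, so it is the default.
* `cd_interpolated` solves $C_{D,\mathrm{tag}}(v')\,v'^3 =
  C_{D,\mathrm{untag}}(v_b)\,v_b^3$ by bisection on $[0.5, v_b]$ m/s to
  $10^{-6}$ m/s. For a constant coefficient this reduces to
  $1-(1+\delta)^{-1/3}$ (≈8% for the same $\delta$), and on decaying tables
  it is always the smaller reduction — slowing down also lowers the
  coefficient. Neither variant is asserted as the "true" reading.

Degenerate inputs are rejected rather than patched: zero speed has no
coefficient (zero dynamic pressure), an all-glide budget has no defined
energy ratio, zero turbulence intensity is not a valid inlet, and weight
rules require a positive body mass. Weight-rule comparisons are inclusive at
the boundary (3.0% passes a 3% rule) and use the tag's mass in air — the
quantity vendors publish — with the explicit caveat that mass ratios are a
poor proxy for hydrodynamic burden.

## Fidelity to the source coefficients

The packaged table retains the printed three-decimal coefficients verbatim,
including cells where the archival configuration sits *below* the untagged
baseline at high speed; these are within printing precision and are
annotated, not floored. Placement sites 1–4 of the archival tag share the
single published coefficient series — per-site differences live in force
components that were never tabulated.

Three-decimal rounding has visible consequences that the tests acknowledge
rather than hide. The cruise-only fin-mount energy increase computed from
the table is 20.41% against a published 20.5% from unrounded forces. And the
ordering of fin-mount energy increases across burst speeds is genuinely
blurred: the tagged/untagged coefficient ratio at burst speed *decreases*
from 29.7% at 3.6 m/s to 27.3% at 9.1 m/s in the rounded table, so the
faster-burst scenarios dominate only while burst time is modest. The
qualitative-structure test therefore checks the speed ordering at burst
allocations up to 5% (faster-burst scenarios above the slowest), where it
holds cleanly, together with the saturation property (the marginal increase
per 1% of burst time at 20% is far below a quarter of that at 1%) and the
order-of-magnitude gap between fin-mount and archival burden.

## What the synthetic generator emulates — and what it does not

`generate_table()` produces coefficient sweeps from a friction-line
surrogate,
$C_D = c_p + k_f\,\cdot\,0.074\,Re^{-1/5}\,\cdot\,S_w/A + \Delta_{tag}$,
i.e. a turbulent flat-plate friction line scaled by a form factor and the
wetted-to-frontal area ratio, plus a speed-independent pressure term and an
additive tag drag area. Defaults (form factor 1.15, $S_w/A = 25$) were
chosen once so the noiseless curve passes through the observed coefficient
range (≈0.13 at $Re = 1.4\times10^6$ down to ≈0.07 at $2.5\times10^7$).
Per-cell Gaussian noise (sd 0.002, the order of the printing precision,
truncated at zero) emulates solver convergence scatter; each table draws
from a private RNG stream seeded in its parameter record, so identical
parameters give bit-identical tables and no global random state is touched.

This reproduces the two statistical features the pipeline relies on — a
monotone power-law decay in Reynolds number and a near-constant additive tag
delta — and nothing else. It does not emulate transitional boundary layers
at the lowest speeds, the slight size dependence of the real coefficients at
fixed Reynolds number, speed-dependent tag interference (which the real
fin-mount series shows), or lift/side/moment components. Passing tests on
surrogate data therefore demonstrate that the plumbing and estimators are
correct, not that real sweeps satisfy the surrogate's assumptions.

`fit_surrogate()` inverts the generator by ordinary least squares on the
$0.074\,Re^{-1/5}$ basis. In a single-configuration fit only the combined
friction scale (form factor × $S_w/A$) and the intercept are identifiable;
with a baseline plus tagged configurations the additive tag delta separates
from the intercept through the shared baseline. A constant table (or fewer
than four speed knots) is a fit failure, not a silent zero-slope answer. The
test suite exercises recovery at grid sizes matching the packaged sweep
(8 speeds, 1–5 sizes) and 30–50 Monte-Carlo replicates per noise level —
sizes chosen to match the data the package actually handles, at which the
whole suite runs in seconds.

## Known limitations

Everything rests on rigid-body steady-flow drag: undulatory propulsion,
dermal-denticle microstructure, behavioural compensation and tag-induced
instability (side forces, pitching moments — only the scalar drag series is
packaged) are outside the model, and comparisons against in-vivo
measurements elsewhere suggest static drag estimates tend to underestimate
real tag effects. Absolute energies inherit the frontal-area assumption.
The packaged table is one body plan and two tag shapes; other species,
DIY tag packages, or attachment angles require new sweeps, which
`read_drag_table()` accepts in the same four-column CSV dialect.
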