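---
title: "Steady-state kinetics of pH-based enzymatic biosensors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Steady-state kinetics of pH-based enzymatic biosensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ureakin)
```

## The model

A pH-sensitive field-effect transducer carries a thin immobilized enzyme
layer. Substrate at bulk concentration $S_B$ exchanges with the layer at a
first-order transport rate $k_S$, is converted by Michaelis–Menten kinetics
$V = V_{max} S/(K_M + S)$, and the protolytic products shift the proton
balance at the surface, which the transducer reads as a pH change. Replacing
diffusion gradients by concentration-proportional transport (rate constants
$k_X$ for each species $X$) turns the reaction–transport ODE system into
algebraic balances at steady state. This is appropriate for thin
(sub-micrometre) homogeneous layers where gradients across the film are
negligible and enzymatic kinetics, not diffusion, limits the response; it is
*not* a model of thick membranes, where a diffusion profile must be resolved.

The assumptions in force:

* steady state — all layer concentrations time-invariant (the package does
  not integrate the dynamic equations);
* Michaelis–Menten kinetics for the enzymatic conversion;
* dissociation constants identical in the layer and the bulk;
* bidirectional, protonation-independent transport with equal rate constants
  for all species, which makes the normalized constants
  $\bar k_W = \bar k_H = 1$ (both remain configurable for sensitivity
  studies).

At steady state the substrate balance has the closed form

$$S = \tfrac12\!\left[S_B - \bar k_V - K_M +
  \sqrt{(K_M + \bar k_V - S_B)^2 + 4 K_M S_B}\right],$$

and summing the product, buffer and proton balances gives one implicit
equation for the surface proton concentration $H$:

$$\bar k_H (H_B - H)
  + \bar k_W c_{WB}\!\left[\frac{1}{1 + K_{aW}/H_B} -
                            \frac{1}{1 + K_{aW}/H}\right]
  + \bar k_V \frac{S}{K_M + S}\!\left[\frac{n_A}{1 + H/K_{aA}} -
                                       \frac{n_B}{1 + K_{aB}/H}\right] = 0.$$

For urea/urease the product stoichiometry is read off the hydrolysis
reaction: one carbonic-acid/bicarbonate equivalent ($n_A = 1$) and two
ammonium/ammonia equivalents ($n_B = 2$) per urea. Near pH 7.4 the base
term dominates, so the reaction consumes protons and the surface
alkalinizes; hydroxide produced by the hydrolysis is not a separate term —
it is equivalent to proton consumption in this single balance, and water
autoionization is not modelled. The carbonate system is treated with a
single dissociation step (CO$_3^{2-}$ neglected, a good approximation below
pH ~9).

Two parameters are fitted: $K_M$ and the *normalized maximum rate*
$\bar k_V = V_{max}/k_S$, which has concentration units. With layer
geometry, $k_S = D/(l\,t)$ converts $\bar k_V$ back to an absolute
$V_{max}$.

## Parameters, units, defaults

All internal concentrations are mol/L; file interfaces use mM and convert on
ingest, and reports carry units in their key names (`K_M_mM`, `kbar_V_M`) to
avoid ambiguity.

| quantity | default | why |
|---|---|---|
| $pK_{aA}$ (H$_2$CO$_3$/HCO$_3^-$) | 6.35 | standard 25 °C value; the framework only requires constants be the same in both layers |
| $pK_{aB}$ (NH$_4^+$/NH$_3$) | 9.25 | standard 25 °C value |
| $pK_{aW}$ (H$_2$PO$_4^-$/HPO$_4^{2-}$) | 7.21 | standard 25 °C value |
| $\bar k_H$, $\bar k_W$ | 1 | equal-transport assumption above |
| parameter box | $[10^{-14}, 1]$ mol/L | wide bounds spanning every physically plausible value |
| $D$, $l$, $t$ | $9.3\times10^{-5}$ cm²/s, 1 cm, $10^{-7}$ cm | urea diffusion constant and the active-layer geometry of the EISCAP presets, giving $k_S = 930$ s$^{-1}$ |
| sensitivity $S_{pH}$ | 0.033 V/pH | midpoint of the 30–35 mV/decade range typical of Ta$_2$O$_5$ gates |

The `pbs_urea` preset is 0.33 mM phosphate at bulk pH 7.4. The `au_urea`
preset represents an artificial-urine-like matrix as an *effective*
single-buffer medium (2 mM effective phosphate-like buffering at pH 7.4,
roughly the phosphate content of ten-fold-diluted artificial urine): the
matrix is not resolved into its constituent couples, and the matrix effect on
the enzyme is carried entirely by the fitted $\bar k_V$, which drops by three
orders of magnitude in such media.

## Numerical choices

**Root solving.** The balance residual is strictly decreasing in $H$ — the
transport term strictly, the buffer and reaction brackets monotonically — so
the physical root is unique. `solve_surface_H()` brackets it on a 200-point
logarithmic grid over $H \in [10^{-14}, 1]$ mol/L and refines by bisection in
$\log_{10} H$ to about $2\times10^{-13}$ relative. Zero or multiple sign
changes on the grid abort with the endpoint residuals: multiple sign changes
cannot occur for a valid chemistry, so silently picking one would only mask a
misconfiguration. Computation uses the normalized variable $Ha = H/K_{aA}$.

**Independent oracle.** Clearing the three speciation denominators turns the
balance into a quartic polynomial in $Ha$. `quartic_root_oracle()` expands it
exactly, takes companion-matrix roots, and keeps only real positive roots
whose *unexpanded* residual is below $10^{-8}$ of the largest additive term —
multiplying through by denominators can manufacture roots at the poles. The
bracketed solver and the validated quartic roots agree to $10^{-8}$ relative
across randomized chemistries in the test suite.

**Stable quadratic branch.** The closed-form layer substrate concentration is
evaluated as $2 K_M S_B / (b + \sqrt{b^2 + 4 K_M S_B})$ when
$b = K_M + \bar k_V - S_B > 0$: the textbook $(\!-b + \sqrt{\cdot})/2$ branch
cancels catastrophically there and loses about six digits, which shows up
directly as a nonzero steady-state balance residual.

**Optimization in log space.** The box spans 14 decades while fitted values
sit at $10^{-7}$–$10^{-2}$ mol/L, so both optimizers work on
$(\log_{10} K_M, \log_{10} \bar k_V)$; bounds are enforced by clamping with a
quadratic penalty. Nelder–Mead runs from a deterministic $5\times5$ log-grid
of starts (it is a local method and no canonical start exists); differential
evolution (rand/1/bin, population 24, $F = 0.8$, $CR = 0.9$, 60 generations)
is seeded and finished by a local simplex polish, standard practice for DE on
smooth objectives. On noise-free data the two agree to well under 1%.
Zero-concentration points are computed exactly ($S_B = 0$ is a regular input;
plotting conventions that substitute a tiny concentration are presentation
devices only) and excluded from linearization transforms, which divide by
$S$ and $v$.

**Goodness of fit.** The objective $\Phi$ is the sum of squared
$\log_{10}$-proton ratios, identically the sum of squared pH residuals (the
$K_{aA}$ normalization cancels). The $\chi^2$ reported alongside it is the
Pearson form on pH values, $\sum_i (pH_{obs,i} - pH_{mod,i})^2 / pH_{mod,i}$,
with the upper-tail probability on $n-2$ degrees of freedom. That definition
is this package's documented convention — reasonable for magnitudes of
squared-pH sums scaled by pH — and results should not be compared against
$\chi^2$ values computed under other conventions; $\Phi$ is always reported
so no information is lost.

## The synthetic-data generator

No public measurements exist for this sensor class, so `generator_spec()` /
`generate_dataset()` / `generate_voltage_traces()` emulate the calibration
design: bulk urea on the grid {0, 0.1, 0.3, 1, 3, 10, 30, 50} mM (the
experimental 0.1–50 mM series plus the zero anchor), model surface pH from
the implicit balance, additive Gaussian pH noise with $\sigma = 0.02$, and —
for the raw-trace path — CONCAP-style voltage traces
$V(t) = V_\infty + (V_0 - V_\infty)e^{-t/\tau} + \eta(t)$ at 5 Hz for 300 s
with $\tau = 20$ s (so the record is 15 settling times long), 0.5 mV Gaussian
noise, and the 33 mV/pH linear map. Everything is seeded and byte-stable.

What the generator does *not* emulate: sensor drift and aging, reference
electrode artifacts, temperature excursions, mechanistic inhibition of
urease by matrix constituents, or non-Nernstian response. Passing recovery
tests therefore demonstrates that the estimation machinery is correct and
well-conditioned under the model's own assumptions — not that a physical
sensor meets any accuracy figure.

**Identifiability in weakly responding media.** With the AU-like preset and
$\bar k_V = 8.6\times10^{-7}$ M the model's whole-grid pH response is only
about $5\times10^{-4}$ pH units — far below 0.02 pH noise. The fit then finds
a genuinely lower residual away from the generating truth: the parameters are
simply not identifiable at that signal-to-noise, and `analysis/04_report.R`
quantifies this rather than hiding it. Recovery criteria are therefore
carried by the PBS-like condition; the AU-like end-to-end round trip is
exercised at zero trace noise, where the preprocessing and fitting path must
return the truth essentially exactly (and does, to ~$10^{-6}$ relative).

## Preprocessing conventions

The pseudo-steady-state plateau of a CONCAP trace is operationalized as the
arithmetic mean of the last 100 samples — no drift modelling beyond an
optional slope warning. The linear calibration `pH = pH0 + (V0 − Vx)/S_pH`
stores $S_{pH}$ in V/pH with the sign convention that alkalinization lowers
the tracked voltage; generator and reader share it. When no explicit
calibration is supplied, the zero-concentration trace anchors $V_0$ and the
chemistry's bulk pH anchors $pH_0$; both a dedicated urea-free measurement
and a first-trace anchor are thereby supported.

## Problem sizes

The shipped analyses and tests use 8–12-point calibration grids, 20-seed
recovery studies, ~100-chemistry randomized solver/oracle comparisons and
1000-draw steady-state consistency checks — sizes at which every stage is
exact or Monte-Carlo-stable while the full suite runs in a couple of minutes
on one core.

## Limitations

* Steady state only: transients, response times and the dynamic layer
  equations are out of scope.
* No electrostatics: the Ta$_2$O$_5$ site-binding/double-layer physics behind
  the voltage response is collapsed into the linear $S_{pH}$ map.
* Single-step speciation per product; no temperature dependence of any
  constant.
* No uncertainty quantification beyond cross-method agreement; the
  linearization estimators are consistency checks, not standalone methods.
* The AU preset is an effective medium; it does not claim the true buffer
  composition of artificial urine.
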