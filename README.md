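# ureakin

Steady-state kinetic modelling and calibration analysis for pH-based
potentiometric enzyme biosensors, with the urea/urease reaction on a
capacitive field-effect (EISCAP) pH transducer as the worked system.

## The problem

An enzyme layer immobilized on a pH-sensitive gate converts its substrate
into protolytic products; for urease,

    CO(NH2)2 + 3 H2O  ->  2 NH4+ + HCO3- + OH-

so urea hydrolysis consumes protons and raises the local pH at the sensor
surface. The sensor reads that surface pH. Quantitative analysis needs the
inverse map: given a measured pH-vs-concentration calibration curve, what are
the apparent Michaelis–Menten constant `K_M` and the maximum reaction rate of
the immobilized enzyme?

`ureakin` implements a simplified kinetic framework in which species exchange
between bulk and enzyme layer is first-order in concentration (rate constants
`k_X`) instead of being resolved by diffusion PDEs — appropriate for thin
(< 10 µm) homogeneous layers where kinetics, not transport, limits the
response. At steady state the layer substrate concentration has the closed
form

    S = [ S_B − k̄_V − K_M + sqrt((K_M + k̄_V − S_B)² + 4 K_M S_B) ] / 2

and the surface proton concentration H solves the implicit balance

    k̄_H (H_B − H)
      + k̄_W c_WB [ 1/(1 + Ka_W/H_B) − 1/(1 + Ka_W/H) ]
      + k̄_V S/(K_M + S) [ n_A/(1 + H/Ka_A) − n_B/(1 + Ka_B/H) ] = 0

where `c_WB`, `Ka_W` describe the bulk buffer, `Ka_A`, `Ka_B` the acid and
base products (carbonic acid / ammonium for urea), `H_B = 10^−pH_B`, and
`k̄_V = V_max / k_S` is the normalized maximum rate, a concentration. Fitting
minimizes

    Φ(K_M, k̄_V) = Σ_i [ log10( Ha(S_B,i) / Ha_exp,i ) ]²

(the squared pH residual, written in normalized proton concentrations
`Ha = H/Ka_A`) over the box [1e-14, 1]² mol/L with multi-start Nelder–Mead
and differential evolution, solving the implicit balance at every objective
evaluation.

Around this core the package provides: reduction of raw constant-capacitance
(CONCAP) voltage traces to calibration points (trailing 100-sample mean, then
the linear map `pH = pH0 + (V0 − Vx)/S_pH`); conversion of `k̄_V` to an
absolute `V_max` via `k_S = D/(l·t)`; Lineweaver–Burk, Eadie–Hofstee and
Hanes–Woolf linearization cross-checks; and a seeded synthetic-data generator
(noisy calibration curves and CONCAP-style traces) so the whole pipeline is
testable without measured data.

## Worked example

```r
library(ureakin)

chem  <- chem_preset("pbs_urea")   # 0.33 mM phosphate, pH 7.4, urea products
truth <- kinetic_parameters(K_M = 10.88e-3, kbar_V = 2.2e-4)

# synthesize a noisy calibration experiment and fit it
spec <- generator_spec(chem, truth, noise_sd_pH = 0.02, seed = 11)
d    <- generate_dataset(spec)
run_pipeline(d, chem, method = "DE", seed = 11)
```

```
<pipeline_report>
  K_M    = 11.87 mM
  kbar_V = 0.0002292 M
  V_max  = 0.2132 M/(L s)
  phi = 0.00291, chi2 = 0.0003812, p = 1 (DE, seed 11)
  8 calibration points
```

The fit recovers the generating `K_M = 10.88 mM` and `k̄_V = 2.2e-4 M` to
within the scatter implied by 0.02 pH noise on 8 points; `V_max` is
`k̄_V · k_S` with `k_S = 9.3e-5 / (1 × 1e-7) = 930 1/s`, and a noise-free run
returns the truth to optimizer precision. `phi` is the summed squared pH
residual, `chi2` the Pearson statistic on pH values with its upper-tail
probability `p` on n − 2 degrees of freedom.

The numbered scripts under `analysis/` run the full study — synthetic PBS and
artificial-urine experiments, raw-trace preprocessing, NM and DE fits,
linearization cross-checks, and a 20-seed recovery summary — writing tables
under `results/`.

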