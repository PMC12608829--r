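#!/usr/bin/env Rscript
# Stage 1: synthesize the calibration experiments.
#
# No deposited measurements exist for this sensor, so the study conditions are
# emulated: urea/urease response curves at bulk pH 7.4 in a PBS-like medium
# (0.33 mM phosphate) and an artificial-urine-like matrix, over 0.1-50 mM urea
# plus a zero point, with 0.02 pH Gaussian noise and raw CONCAP-style voltage
# traces (33 mV/pH sensitivity, 0.5 mV trace noise, 20 s settling).
# The generating parameters are the fitted values the sensors produced:
# PBS K_M = 10.88 mM, kbar_V = 2.2e-4 M; AU K_M = 32.45 mM, kbar_V = 8.6e-7 M.

suppressPackageStartupMessages(library(ureakin))
dir.create("results/sim", showWarnings = FALSE, recursive = TRUE)

conditions <- list(
  pbs = list(chem = chem_preset("pbs_urea"),
             truth = kinetic_parameters(10.88e-3, 2.2e-4)),
  au  = list(chem = chem_preset("au_urea"),
             truth = kinetic_parameters(32.45e-3, 8.6e-7))
)

for (name in names(conditions)) {
  cond <- conditions[[name]]
  spec <- generator_spec(cond$chem, cond$truth, noise_sd_pH = 0.02,
                         seed = 20260925L)
  d <- generate_dataset(spec)
  write_calibration_csv(d, sprintf("results/sim/%s_calibration.csv", name))
  traces <- generate_voltage_traces(spec)
  write_traces(traces, sprintf("results/sim/%s_traces", name))
  jsonlite::write_json(
    list(K_M_mM = cond$truth$K_M * 1e3, kbar_V_M = cond$truth$kbar_V,
         noise_sd_pH = spec$noise_sd_pH, seed = spec$seed),
    sprintf("results/sim/%s_truth.json", name), auto_unbox = TRUE,
    digits = NA)
  curve <- response_curve(spec$s_b_grid, cond$chem, cond$truth)
  write_response_curve(curve, sprintf("results/sim/%s_model_curve.csv", name))
  cat(sprintf("%s: %d calibration points, pH %.3f-%.3f; %d traces written\n",
              name, nrow(d), min(d$pH), max(d$pH), length(traces)))
}
cat("Stage 1 done: synthetic datasets, traces, and truth files under results/sim/\n")
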