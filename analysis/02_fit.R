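#!/usr/bin/env Rscript
# Stage 2: recover (K_M, kbar_V) from the synthetic calibration data.
#
# Both retained optimizers run on each medium: multi-start Nelder-Mead and
# seeded differential evolution, minimizing the squared log10 proton-ratio
# residual inside the box [1e-14, 1]^2 mol/L. Raw traces are reduced first
# (trailing 100-sample mean, linear voltage-to-pH map) so the whole data path
# is exercised, and the fits are compared with the generating truth.

suppressPackageStartupMessages(library(ureakin))
dir.create("results", showWarnings = FALSE)

rows <- list()
for (name in c("pbs", "au")) {
  chem <- chem_preset(sprintf("%s_urea", name))
  truth <- jsonlite::read_json(sprintf("results/sim/%s_truth.json", name),
                               simplifyVector = TRUE)
  traces <- read_traces(sprintf("results/sim/%s_traces", name))
  cal <- sensor_calibration(pH0 = chem$buffer$pH_B, V0 = 0.5, S_pH = 0.033)
  d <- build_dataset(traces, chem, cal = cal, medium = name)

  for (m in c("NM", "DE")) {
    fit <- fit_parameters(d, method = m, seed = 20260925L)
    rows[[length(rows) + 1L]] <- data.frame(
      medium = name, method = m,
      K_M_mM = fit$params$K_M * 1e3, kbar_V_M = fit$params$kbar_V,
      K_M_true_mM = truth$K_M_mM, kbar_V_true_M = truth$kbar_V_M,
      phi = fit$phi, chi2 = fit$chi2, p_value = fit$p_value,
      n_evals = fit$n_evals)
    cat(sprintf(
      "%s/%s: K_M = %.3f mM (true %.2f), kbar_V = %.3e M (true %.2e), chi2 = %.2e\n",
      name, m, fit$params$K_M * 1e3, truth$K_M_mM,
      fit$params$kbar_V, truth$kbar_V_M, fit$chi2))
  }
}
fits <- do.call(rbind, rows)
write.csv(fits, "results/fits.csv", row.names = FALSE)
cat("Stage 2 done: results/fits.csv\n")
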