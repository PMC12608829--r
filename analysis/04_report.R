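#!/usr/bin/env Rscript
# Stage 4: recovery study and final report.
#
# Repeats the noisy-calibration experiment over 20 seeds per medium and
# summarizes how well the fit recovers the generating parameters, then writes
# one pipeline report per medium (fit + goodness of fit + linearization
# cross-check) as JSON.

suppressPackageStartupMessages(library(ureakin))
dir.create("results", showWarnings = FALSE)

summary_rows <- list()
for (name in c("pbs", "au")) {
  chem <- chem_preset(sprintf("%s_urea", name))
  truth <- jsonlite::read_json(sprintf("results/sim/%s_truth.json", name),
                               simplifyVector = TRUE)
  tp <- kinetic_parameters(truth$K_M_mM * 1e-3, truth$kbar_V_M)
  errs <- vapply(1:20, function(s) {
    d <- generate_dataset(generator_spec(chem, tp, noise_sd_pH = 0.02,
                                         seed = s))
    fit <- fit_parameters(d, method = "DE", seed = s)
    c(abs(fit$params$K_M - tp$K_M) / tp$K_M,
      abs(fit$params$kbar_V - tp$kbar_V) / tp$kbar_V)
  }, numeric(2))
  summary_rows[[name]] <- data.frame(
    medium = name,
    median_rel_err_K_M = median(errs[1, ]),
    median_rel_err_kbar_V = median(errs[2, ]),
    max_rel_err_K_M = max(errs[1, ]), max_rel_err_kbar_V = max(errs[2, ]))
  cat(sprintf("%s recovery (20 seeds, sigma 0.02 pH): median |dK_M|/K_M = %.3f, median |dkv|/kv = %.3f\n",
              name, median(errs[1, ]), median(errs[2, ])))
  if (name == "au") {
    cat("  note: the AU-like response spans ~5e-4 pH over the whole grid,",
        "far below the 0.02 pH noise,\n",
        " so (K_M, kbar_V) are not identifiable at this noise level;",
        "the large errors above quantify that,\n",
        " not an optimizer failure (the fit reaches a lower residual than",
        "the truth does).\n")
  }

  d <- read_calibration_csv(sprintf("results/sim/%s_calibration.csv", name),
                            chem, medium = name)
  run_pipeline(d, chem, method = "DE", seed = 20260925L,
               out_path = sprintf("results/%s_report.json", name))
}
write.csv(do.call(rbind, summary_rows), "results/recovery_summary.csv",
          row.names = FALSE)
cat("Stage 4 done: results/recovery_summary.csv and per-medium report JSONs\n")
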