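# Shared fixtures: the urea/urease presets and randomized chemistries for
# property-style tests. All randomized helpers draw from the caller's RNG
# stream; tests seed explicitly.

pbs_chem <- function() chem_preset("pbs_urea")

pbs_truth <- function() kinetic_parameters(K_M = 10.88e-3, kbar_V = 2.2e-4)

au_truth <- function() kinetic_parameters(K_M = 32.45e-3, kbar_V = 8.6e-7)

# 12-point log grid spanning the 0.1-50 mM calibration range
grid12 <- function() 10^seq(log10(1e-4), log10(5e-2), length.out = 12)

runif_log <- function(n, lo, hi) 10^stats::runif(n, log10(lo), log10(hi))

random_chemistry <- function() {
  n_A <- sample(0:2, 1L)
  n_B <- if (n_A == 0) sample(1:2, 1L) else sample(0:2, 1L)
  biosensor_chemistry(
    buffer = buffer_system(c_WB = runif_log(1, 1e-5, 1e-1),
                           pKa_W = stats::runif(1, 4, 10),
                           pH_B = stats::runif(1, 5, 9),
                           kbar_W = stats::runif(1, 0.5, 2)),
    products = product_system(n_A = n_A, pKa_A = stats::runif(1, 4, 8),
                              n_B = n_B, pKa_B = stats::runif(1, 7, 11)),
    transport = transport_model(kbar_H = stats::runif(1, 0.5, 2))
  )
}

random_params <- function() {
  kinetic_parameters(K_M = runif_log(1, 1e-6, 1e-1),
                     kbar_V = runif_log(1, 1e-10, 1e-2))
}

noise_free_dataset <- function(chem = pbs_chem(), truth = pbs_truth(),
                               grid = grid12()) {
  d <- calibration_dataset(grid, response_curve(grid, chem, truth)$pH_surface,
                           chem, medium = "noise-free")
  attr(d, "truth") <- truth
  d
}
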