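test_that("calibration dataset validates, sorts, and rejects duplicates", {
  chem <- pbs_chem()
  d <- calibration_dataset(c(1e-2, 0, 1e-3), c(8, 7.4, 7.6), chem)
  expect_equal(d$s_b, c(0, 1e-3, 1e-2))
  expect_equal(d$pH, c(7.4, 7.6, 8))

  expect_error(calibration_dataset(c(1e-3, 1e-3), c(7.5, 7.6), chem),
               "duplicated")
  expect_error(calibration_dataset(1e-3, 15, chem), "pH")
  expect_error(calibration_dataset(-1e-3, 7.5, chem), "non-negative")
})

test_that("phi is zero at the generating parameters and positive away from them", {
  d <- noise_free_dataset()
  truth <- attr(d, "truth")
  expect_lt(residual_phi(truth, d), 1e-18)

  doubled <- kinetic_parameters(truth$K_M * 2, truth$kbar_V)
  expect_gt(residual_phi(doubled, d), 1e-6)
})

test_that("phi equals the sum of squared pH deviations (Ka_A cancels)", {
  chem <- pbs_chem()
  truth <- pbs_truth()
  grid <- c(1e-3, 1e-2)
  pH_model <- response_curve(grid, chem, truth)$pH_surface

  # exact +0.1 / -0.1 pH offsets: phi = 0.01 + 0.01
  d <- calibration_dataset(grid, pH_model + c(0.1, -0.1), chem)
  expect_equal(residual_phi(truth, d), 0.02, tolerance = 1e-10)

  # same offsets, different acid-product Ka in the normalization: the pH
  # residual is unchanged only through the model, and phi always equals the
  # squared pH deviation sum for the dataset's own chemistry
  d3 <- noise_free_dataset()
  p_off <- kinetic_parameters(5e-3, 1e-4)
  pH_m <- response_curve(d3$s_b, pbs_chem(), p_off)$pH_surface
  expect_equal(residual_phi(p_off, d3), sum((d3$pH - pH_m)^2),
               tolerance = 1e-10)
})

test_that("objective at the truth is the minimum over random perturbations", {
  set.seed(11)
  d <- noise_free_dataset(grid = 10^seq(log10(1e-4), log10(5e-2),
                                        length.out = 8))
  truth <- attr(d, "truth")
  phi0 <- residual_phi(truth, d)
  for (i in 1:100) {
    pert <- kinetic_parameters(
      truth$K_M * 10^stats::runif(1, -2, 2),
      truth$kbar_V * 10^stats::runif(1, -2, 2))
    expect_gte(residual_phi(pert, d), phi0)
  }
})

test_that("fit rejects degenerate designs", {
  chem <- pbs_chem()
  d2 <- calibration_dataset(c(1e-3, 1e-2), c(7.5, 8.0), chem)
  expect_error(fit_parameters(d2), "at least 3")
  expect_error(goodness_of_fit(d2, pbs_truth()), "more than 2")
})

test_that("a reduced-budget DE fit lands near the generating parameters", {
  d <- noise_free_dataset(grid = 10^seq(log10(1e-4), log10(5e-2),
                                        length.out = 8))
  truth <- attr(d, "truth")
  fit <- fit_parameters(d, method = "DE", seed = 3,
                        control = list(np = 12, maxiter = 25))
  expect_true(fit$converged)
  expect_lt(abs(fit$params$K_M - truth$K_M) / truth$K_M, 0.05)
  expect_lt(abs(fit$params$kbar_V - truth$kbar_V) / truth$kbar_V, 0.05)
  expect_true(fit$params$K_M >= fit$bounds_used["lower"] &&
                fit$params$K_M <= fit$bounds_used["upper"])
  expect_gt(fit$n_evals, 0)
})

test_that("chi-square on pH values follows its definition", {
  d <- noise_free_dataset()
  truth <- attr(d, "truth")

  gof0 <- goodness_of_fit(d, truth)
  expect_lt(gof0$chi2, 1e-20)
  expect_equal(gof0$p_value, 1)

  # one point off by delta at model pH m: chi2 = delta^2 / m
  delta <- 0.05
  pH_m <- response_curve(d$s_b, pbs_chem(), truth)$pH_surface
  pH_obs <- pH_m
  pH_obs[7] <- pH_obs[7] + delta
  d1 <- calibration_dataset(d$s_b, pH_obs, pbs_chem())
  gof1 <- goodness_of_fit(d1, truth)
  expect_equal(gof1$chi2, delta^2 / pH_m[7], tolerance = 1e-8)
  expect_gt(gof1$p_value, 0.9)  # tiny chi2 on 10 df: tail prob near 1
  expect_lte(gof1$p_value, 1)

  # chi2 grows with the deviations
  d2 <- calibration_dataset(d$s_b, pH_m + 0.1, pbs_chem())
  d3 <- calibration_dataset(d$s_b, pH_m + 0.2, pbs_chem())
  expect_gt(goodness_of_fit(d3, truth)$chi2,
            goodness_of_fit(d2, truth)$chi2)
})

test_that("calibration CSV round-trips in mM units", {
  d <- noise_free_dataset()
  path <- withr::local_tempfile(fileext = ".csv")
  write_calibration_csv(d, path)
  d2 <- read_calibration_csv(path, pbs_chem(), medium = "roundtrip")
  expect_equal(d2$s_b, d$s_b, tolerance = 1e-12)
  expect_equal(d2$pH, d$pH, tolerance = 1e-12)
})
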