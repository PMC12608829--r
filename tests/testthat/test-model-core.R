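test_that("steady-state substrate concentration matches its closed form and limits", {
  p <- kinetic_parameters(K_M = 10e-3, kbar_V = 1e-3)

  expect_identical(steady_state_substrate(0, p), 0)

  # no-reaction limit: the discriminant collapses to (K_M + S_B)^2
  p0 <- kinetic_parameters(K_M = 10e-3, kbar_V = 1e-300)
  expect_equal(steady_state_substrate(10e-3, p0), 10e-3, tolerance = 1e-12)

  # K_M = 10 mM, kbar_V = 1 mM, S_B = 10 mM -> S = (-1 + sqrt(401))/2 mM
  expect_equal(steady_state_substrate(10e-3, p),
               (-1 + sqrt(401)) / 2 * 1e-3, tolerance = 1e-14)

  expect_error(steady_state_substrate(-1e-3, p), "non-negative")
  expect_error(steady_state_substrate(NaN, p), "finite")
})

test_that("steady-state output zeroes the normalized substrate balance on random draws", {
  set.seed(42)
  for (i in 1:200) {
    p <- random_params()
    S_B <- runif_log(1, 1e-6, 5e-2)
    S <- steady_state_substrate(S_B, p)
    expect_true(S >= 0 && S <= S_B)
    bal <- S_B - S - p$kbar_V * S / (p$K_M + S)
    expect_lt(abs(bal), 1e-10 * max(S_B, p$K_M))
  }
})

test_that("surface balance residual has the stated fixed points and error paths", {
  chem <- pbs_chem()
  p <- pbs_truth()
  Ha_B <- chem$buffer$H_B / chem$products$Ka_A

  # zero substrate at bulk pH: every bracketed difference vanishes
  expect_equal(surface_balance_residual(Ha_B, 0, chem, p), 0,
               tolerance = 1e-18)

  # no buffer, vanishing reaction: only the proton-transport term survives
  chem0 <- biosensor_chemistry(buffer_system(0, pH_B = 7.4),
                               product_system(), transport_model())
  p0 <- kinetic_parameters(1e-2, 1e-300)
  Ha <- 2 * Ha_B
  expect_equal(surface_balance_residual(Ha, 1e-2, chem0, p0),
               chem0$buffer$H_B - Ha * chem0$products$Ka_A,
               tolerance = 1e-20)

  expect_error(surface_balance_residual(0, 1e-3, chem, p), "positive")
  expect_error(surface_balance_residual(-1, 1e-3, chem, p), "positive")
})

test_that("solve_surface_H finds the physical root of the balance", {
  chem <- pbs_chem()
  p <- pbs_truth()

  # zero-substrate fixed point
  s0 <- solve_surface_H(0, chem, p)
  expect_equal(s0$pH_surface, 7.4, tolerance = 1e-9)

  # urea stoichiometry consumes protons net: alkaline shift
  s <- solve_surface_H(10e-3, chem, p)
  expect_gt(s$pH_surface, 7.4)
  expect_equal(s$Ha, s$H / chem$products$Ka_A)
  expect_equal(s$pH_surface, -log10(s$H))
  expect_lt(abs(surface_balance_residual(s$Ha, 10e-3, chem, p)), 1e-12)

  # vanishing-reaction limit pins the surface at the bulk pH
  p_tiny <- kinetic_parameters(K_M = 10e-3, kbar_V = 1e-14)
  for (sb in c(1e-4, 1e-2, 5e-2)) {
    expect_lt(abs(solve_surface_H(sb, chem, p_tiny)$pH_surface - 7.4), 1e-6)
  }
})

test_that("quartic expansion recovers the bracketed root and rejects spurious ones", {
  chem <- pbs_chem()
  p <- pbs_truth()

  # zero substrate: single root at the bulk proton concentration
  q0 <- quartic_root_oracle(0, chem, p)
  Ha_B <- chem$buffer$H_B / chem$products$Ka_A
  expect_equal(length(q0), 1L)
  expect_equal(q0, Ha_B, tolerance = 1e-10)

  # PBS preset at 1 mM: the solver root appears in the validated set
  s <- solve_surface_H(1e-3, chem, p)
  q <- quartic_root_oracle(1e-3, chem, p)
  expect_lt(min(abs(q - s$Ha)) / s$Ha, 1e-8)

  # degenerate chemistry: no buffer, no reaction
  chem0 <- biosensor_chemistry(buffer_system(0, pH_B = 7.4),
                               product_system(), transport_model())
  pd <- kinetic_parameters(1e-2, 1e-300)
  qd <- quartic_root_oracle(0, chem0, pd)
  expect_equal(length(qd), 1L)
  expect_equal(qd, chem0$buffer$H_B / chem0$products$Ka_A, tolerance = 1e-10)
})

test_that("bracketed solver and quartic oracle agree on randomized chemistries", {
  set.seed(7)
  n_ok <- 0L
  for (i in 1:120) {
    chem <- random_chemistry()
    p <- random_params()
    S_B <- runif_log(1, 1e-5, 5e-2)
    s <- solve_surface_H(S_B, chem, p)
    q <- quartic_root_oracle(S_B, chem, p)
    expect_gt(length(q), 0L)
    expect_lt(min(abs(q - s$Ha)) / s$Ha, 1e-8)
    n_ok <- n_ok + 1L
  }
  expect_gte(n_ok, 100L)
})

test_that("response curve is ordered, monotone for urea chemistry, and deterministic", {
  chem <- pbs_chem()
  p <- pbs_truth()

  rc0 <- response_curve(0, chem, p)
  expect_equal(nrow(rc0), 1L)
  expect_equal(rc0$pH_surface, 7.4, tolerance = 1e-9)

  grid <- grid12()
  rc <- response_curve(grid, chem, p)
  expect_equal(rc$s_b, grid)
  expect_true(all(diff(rc$pH_surface) >= 0))

  # duplicated grid values give duplicated identical outputs
  rc2 <- response_curve(c(1e-3, 1e-3), chem, p)
  expect_identical(rc2[1, ], rc2[2, ], ignore_attr = TRUE)

  expect_error(response_curve(c(1e-3, -1e-3), chem, p), "non-negative")
})

test_that("stronger buffering suppresses the pH shift; infinite buffer pins bulk pH", {
  p <- pbs_truth()
  cwbs <- c(0.1e-3, 0.33e-3, 1e-3, 5e-3, 50e-3, 1)
  pHs <- vapply(cwbs, function(cwb) {
    chem <- biosensor_chemistry(
      buffer_system(cwb, pKa_W = 7.21, pH_B = 7.4),
      product_system(), transport_model())
    solve_surface_H(10e-3, chem, p)$pH_surface
  }, numeric(1))
  expect_true(all(diff(pHs) <= 1e-12))
  expect_lt(abs(pHs[length(pHs)] - 7.4), 1e-3)

  # kbar_V -> 0 limit approaches bulk pH uniformly over the grid
  kvs <- 10^seq(-4, -12, by = -2)
  chem <- pbs_chem()
  dev <- vapply(kvs, function(kv) {
    rc <- response_curve(grid12(), chem, kinetic_parameters(10.88e-3, kv))
    max(abs(rc$pH_surface - 7.4))
  }, numeric(1))
  expect_true(all(diff(dev) <= 0))
  expect_lt(dev[length(dev)], 1e-6)
})

test_that("solver reports useless brackets instead of guessing", {
  # pH_B at the edge of the physical window with a huge alkalinizing rate:
  # the root would sit above pH 14, outside the physical bracket
  chem <- biosensor_chemistry(
    buffer_system(0, pH_B = 13.9),
    product_system(n_A = 0, n_B = 2), transport_model())
  p <- kinetic_parameters(1e-6, 1)
  expect_error(solve_surface_H(5e-2, chem, p), "no sign change")
})

test_that("chemistry YAML round-trips through read/write and presets load", {
  chem <- chem_preset("au_urea")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_chemistry(chem, path)
  chem2 <- read_chemistry(path)
  expect_equal(chem2$buffer$c_WB, chem$buffer$c_WB)
  expect_equal(chem2$products$Ka_B, chem$products$Ka_B)
  expect_equal(chem2$transport$k_S, chem$transport$k_S)

  shipped <- system.file("extdata", "chemistry", "pbs_urea.yaml",
                         package = "ureakin")
  chem3 <- read_chemistry(shipped)
  expect_equal(chem3$buffer$c_WB, 0.33e-3)
  expect_equal(chem3$transport$k_S, 930)
})
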