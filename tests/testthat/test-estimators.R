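test_that("normalized-to-absolute rate conversion follows k_S = D/(l t)", {
  tr <- transport_model(D = 9.3e-5, l = 1, t = 1e-7)
  expect_equal(tr$k_S, 930)
  expect_equal(vmax_from_normalized(2.2e-4, tr), 2.2e-4 * 930)
  expect_equal(round(vmax_from_normalized(2.2e-4, tr), 2), 0.20)

  expect_equal(vmax_from_normalized(0, tr), 0)
  expect_equal(vmax_from_normalized(1, transport_model(k_S = 1)), 1)

  expect_error(transport_model(D = 9.3e-5, l = 1, t = 0), "positive")
  expect_error(vmax_from_normalized(1e-4, transport_model()), "no k_S")

  # linear in kbar_V and in 1/t
  expect_equal(vmax_from_normalized(4.4e-4, tr),
               2 * vmax_from_normalized(2.2e-4, tr))
  tr2 <- transport_model(D = 9.3e-5, l = 1, t = 2e-7)
  expect_equal(vmax_from_normalized(2.2e-4, tr2),
               vmax_from_normalized(2.2e-4, tr) / 2)
})

test_that("all three linearizations are exact on noise-free rate-law data", {
  V_max <- 1e-3; K_M <- 5e-3
  S <- c(0.5, 1, 2, 5, 10, 20, 50) * 1e-3
  v <- V_max * S / (K_M + S)
  for (f in list(lineweaver_burk, eadie_hofstee, hanes_woolf)) {
    est <- f(S, v)
    expect_equal(est$V_max, V_max, tolerance = 1e-10)
    expect_equal(est$K_M, K_M, tolerance = 1e-10)
  }

  # two points: exact interpolation
  S2 <- c(2e-3, 20e-3); v2 <- V_max * S2 / (K_M + S2)
  est2 <- lineweaver_burk(S2, v2)
  expect_equal(est2$V_max, V_max, tolerance = 1e-10)
  expect_equal(est2$K_M, K_M, tolerance = 1e-10)

  expect_error(lineweaver_burk(c(0, 1e-3), c(1e-4, 2e-4)), "positive")
  expect_error(eadie_hofstee(c(1e-3, 1e-3), c(1e-4, 1e-4)), "distinct")
})

test_that("noisy linearization estimates track a grid-search least-squares oracle", {
  set.seed(19)
  V_max <- 1e-3; K_M <- 5e-3
  S <- 10^seq(log10(5e-4), log10(5e-2), length.out = 15)
  v <- V_max * S / (K_M + S) * exp(stats::rnorm(15, 0, 0.02))

  # brute-force nonlinear least squares of the rate law on a fine log grid
  vg <- 10^seq(log10(V_max) - 0.5, log10(V_max) + 0.5, length.out = 201)
  kg <- 10^seq(log10(K_M) - 0.5, log10(K_M) + 0.5, length.out = 201)
  sse <- outer(vg, kg, function(vm, km) {
    vapply(seq_along(vm), function(i) {
      sum((v - vm[i] * S / (km[i] + S))^2)
    }, numeric(1))
  })
  idx <- arrayInd(which.min(sse), dim(sse))
  oracle <- c(V_max = vg[idx[1]], K_M = kg[idx[2]])

  for (f in list(lineweaver_burk, eadie_hofstee, hanes_woolf)) {
    est <- f(S, v)
    expect_lt(abs(est$V_max - oracle["V_max"]) / oracle["V_max"], 0.15)
    expect_lt(abs(est$K_M - oracle["K_M"]) / oracle["K_M"], 0.25)
  }
})

test_that("model-generated rates close the loop through every linearization", {
  p <- pbs_truth()
  tr <- transport_model(D = 9.3e-5, l = 1, t = 1e-7)
  V_max <- vmax_from_normalized(p$kbar_V, tr)

  suppressMessages({
    rates <- rates_from_fit(p, tr, c(0, grid12()))
  })
  expect_equal(nrow(rates), 12L)  # zero point dropped

  # saturation and half-saturation
  sat <- rates_from_fit(p, tr, 1e4 * p$K_M)
  expect_equal(sat$v, V_max, tolerance = 1e-3)
  half <- rates_from_fit(p, tr, p$K_M + p$kbar_V / 2)  # layer S = K_M exactly
  expect_equal(half$v, V_max / 2, tolerance = 1e-12)

  # closed loop: the mechanism behind identical rows across methods
  for (f in list(lineweaver_burk, eadie_hofstee, hanes_woolf)) {
    est <- f(rates$S, rates$v)
    expect_equal(est$V_max, V_max, tolerance = 1e-10)
    expect_equal(est$K_M, p$K_M, tolerance = 1e-10)
  }
})
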