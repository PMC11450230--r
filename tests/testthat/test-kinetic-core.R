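test_that("microscopic reversibility holds for every constructed parameter set", {
  for (seed in 1:20) {
    p <- random_params(seed)
    expect_lt(abs(reversibility_gap(p)), 1e-10)
  }
  # any single constant can be designated as derived
  base <- random_params(1)
  for (nm in c("k12_0", "k21", "k23_0", "k32", "k34", "k43_0", "k14_0",
               "k41_0")) {
    p <- kinetic_params(k12_0 = base$k12_0, k21 = base$k21,
                        k23_0 = base$k23_0, k32 = base$k32, k34 = base$k34,
                        k43_0 = base$k43_0, k14_0 = base$k14_0,
                        k41_0 = base$k41_0, N = base$N,
                        derived_constant = nm)
    expect_lt(abs(reversibility_gap(p)), 1e-10)
  }
  expect_error(kinetic_params(k12_0 = -1, k21 = 1, k23_0 = 1, k32 = 1,
                              k34 = 1, k14_0 = 1, k41_0 = 1),
               "strictly positive")
})

test_that("voltage and concentration resolution of the elementary rates", {
  p <- random_params(2)
  # at 0 mV the Eyring factors are 1
  r0 <- resolve_rates(p, conditions(V = 0))
  expect_equal(r0$k14, p$k14_0)
  expect_equal(r0$k41, p$k41_0)
  # bilinear internal product: doubling both internal concentrations
  # quadruples k43
  c1 <- conditions(K_in = 0.05, H_in = 1e-7)
  c2 <- conditions(K_in = 0.10, H_in = 2e-7)
  expect_equal(resolve_rates(p, c2)$k43, 4 * resolve_rates(p, c1)$k43)
  # symmetric barrier: k14 * k41 is voltage independent
  prods <- sapply(seq(-180, 60, by = 20), function(v)
    with(resolve_rates(p, conditions(V = v)), k14 * k41))
  expect_equal(max(prods), min(prods), tolerance = 1e-12)
  expect_error(conditions(K_out = -1), "concentrations")
  expect_error(conditions(T_K = 0), "temperature")
})

test_that("closed-form occupancies normalise and match the null-space oracle", {
  for (seed in 1:50) {
    r <- random_rates(seed)
    ka <- king_altman_occupancies(r)
    expect_lt(abs(sum(ka$occupancy) - 1), 1e-12)
    expect_true(all(ka$occupancy >= 0 & ka$occupancy <= 1))
    oracle <- numeric_occupancy_oracle(r)
    expect_equal(unname(ka$occupancy), unname(oracle), tolerance = 1e-9)
  }
})

test_that("uniform rates on the cycle give equal occupancies", {
  r <- as.list(stats::setNames(rep(3.7, 8),
                               c("k12", "k21", "k23", "k32", "k34", "k43",
                                 "k14", "k41")))
  expect_equal(unname(numeric_occupancy_oracle(r)), rep(0.25, 4),
               tolerance = 1e-12)
})

test_that("state C3 is unreachable without external K+ and internal return flux", {
  r <- random_rates(3)
  r$k23 <- 0
  r$k43 <- 0
  ka <- king_altman_occupancies(r)
  expect_identical(unname(ka$occupancy["C3"]), 0)
  r0 <- lapply(r, function(x) 0)
  expect_error(king_altman_occupancies(r0), "degenerate")
})

test_that("factored closed-form current equals the occupancy form", {
  for (seed in 1:20) {
    p <- random_params(seed)
    cond <- random_conditions(seed + 100)
    s <- steady_state_current(p, cond)
    expect_equal(s$I, s$I_occupancy_form, tolerance = 1e-9)
    expect_identical(s$I, s$I_plus + s$I_minus)
    expect_gte(s$I_plus, 0)
    expect_lte(s$I_minus, 0)
  }
})

test_that("current vanishes at the reversal potential and changes sign across it", {
  for (seed in 1:10) {
    p <- random_params(seed)
    cond <- random_conditions(seed + 200)
    vr <- reversal_potential(cond)
    at <- function(v) steady_state_current(p, conditions(
      V = v, T_K = cond$T_K, K_out = cond$K_out, H_out = cond$H_out,
      K_in = cond$K_in, H_in = cond$H_in))
    s <- at(vr)
    expect_lt(abs(s$I), 1e-12 * abs(s$I_plus))
    expect_lt(at(vr - 5)$I, 0)
    expect_gt(at(vr + 5)$I, 0)
  }
})

test_that("reversal potential formula agrees with a numeric root of the current", {
  expect_equal(reversal_potential(conditions(K_out = 1e-3, K_in = 1e-3,
                                             H_out = 1e-6, H_in = 1e-6)), 0)
  p <- random_params(4)
  cond <- conditions(K_out = 5e-4, H_out = 10^-5, K_in = 0.08,
                     H_in = 10^-7.2)
  vr <- reversal_potential(cond)
  f <- function(v) steady_state_current(p, conditions(
    V = v, K_out = cond$K_out, H_out = cond$H_out, K_in = cond$K_in,
    H_in = cond$H_in))$I
  root <- stats::uniroot(f, c(vr - 30, vr + 30), tol = 1e-9)$root
  expect_equal(root, vr, tolerance = 1e-6)
  expect_error(reversal_potential(conditions(K_out = 0)), "undefined")
})

test_that("detailed balance holds at the reversal potential", {
  p <- random_params(5)
  cond <- random_conditions(205)
  vr <- reversal_potential(cond)
  r <- resolve_rates(p, conditions(V = vr, T_K = cond$T_K,
                                   K_out = cond$K_out, H_out = cond$H_out,
                                   K_in = cond$K_in, H_in = cond$H_in))
  fwd <- r$k12 * r$k23 * r$k34 * r$k41
  rev <- r$k21 * r$k32 * r$k43 * r$k14
  expect_equal(fwd, rev, tolerance = 1e-9)
})

test_that("calibrated defaults give inward current at physiological uptake conditions", {
  p <- default_params_cached()
  s <- steady_state_current(p, conditions(V = -120, pH_out = 4.5,
                                          K_out = 20e-6))
  expect_lt(s$I, 0)
})
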