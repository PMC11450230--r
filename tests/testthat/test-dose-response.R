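mm_curve <- function(conc, I_max, K_m) I_max * conc / (conc + K_m)
hill_curve <- function(conc, I_max, K_m, h)
  I_max * conc^h / (conc^h + K_m^h)
bell_curve <- function(conc, I_max, I_s, K_m)
  I_max * conc * K_m / (conc + K_m)^2 + I_s

test_that("Michaelis-Menten fit recovers noiseless truth at the standard concentrations", {
  d <- dose_response_dataset(paper_concs,
                             mm_curve(paper_concs, 1.0, 23.56e-6))
  fit <- fit_michaelis_menten(d)
  expect_equal(fit$estimate$K_m, 23.56e-6, tolerance = 1e-6)
  expect_equal(fit$estimate$I_max, 1.0, tolerance = 1e-6)
  # half-saturation on the fitted curve
  expect_equal(fit$fitted(fit$estimate$K_m), fit$estimate$I_max / 2)
  expect_true(fit$converged)
})

test_that("dose-response constructors and fit preconditions reject bad input", {
  expect_error(dose_response_dataset(c(1e-6, 1e-6), c(1, 2)), "distinct")
  expect_error(dose_response_dataset(c(1e-6, 2e-6), c(1, -2)), ">= 0")
  expect_error(fit_michaelis_menten(
    dose_response_dataset(c(1e-6, 2e-6), c(1, 2))), "3 points")
  expect_error(fit_michaelis_menten(
    dose_response_dataset(c(1e-6, 2e-6, 5e-6), c(1, 2, 3))), "factor 10")
  expect_error(fit_hill(
    dose_response_dataset(c(1e-6, 2e-6, 5e-6), c(1, 2, 3))), "4 points")
})

test_that("Hill fit nests the Michaelis-Menten fit and recovers cooperative truths", {
  d1 <- dose_response_dataset(paper_concs,
                              mm_curve(paper_concs, 1.0, 23.56e-6))
  hf <- fit_hill(d1)
  mf <- fit_michaelis_menten(d1)
  expect_equal(hf$estimate$h, 1, tolerance = 1e-4)
  expect_equal(hf$estimate$K_m, mf$estimate$K_m, tolerance = 1e-6)
  # proton-activation style truths with the reported Hill exponents
  concs_h <- 10^seq(-8, -4, length.out = 10)
  for (h_true in c(1.67, 2.17)) {
    d <- dose_response_dataset(concs_h,
                               hill_curve(concs_h, 1.0, 4.81e-6, h_true),
                               substrate = "H")
    fit <- fit_hill(d)
    expect_equal(fit$estimate$h, h_true, tolerance = 1e-4)
    expect_equal(fit$estimate$K_m, 4.81e-6, tolerance = 1e-4)
  }
})

test_that("bell-shaped steady-state fit recovers the printed wild-type parameters", {
  concs <- paper_concs
  d <- dose_response_dataset(concs,
                             bell_curve(concs, 1.01e-6, 124e-9, 28.3e-6))
  fit <- fit_steady_state_bell(d, K_m_fixed = 28.3e-6)
  expect_equal(fit$estimate$I_max, 1.01e-6, tolerance = 1e-6)
  expect_equal(fit$estimate$I_s, 124e-9, tolerance = 1e-6)
  # the fitted curve tends to the offset in both concentration limits
  expect_equal(fit$fitted(1e-12), 124e-9, tolerance = 1e-4)
  expect_equal(fit$fitted(10), 124e-9, tolerance = 1e-4)
  # and its maximum sits exactly at the fixed K_m
  grid <- 10^seq(-9, -1, length.out = 10001)
  expect_equal(grid[which.max(fit$fitted(grid))], 28.3e-6,
               tolerance = 2e-3)
})

test_that("bell argmax equals K_m and ignores scale and offset", {
  expect_equal(bell_argmax(28.3e-6), 28.3e-6)
  for (km in c(1e-6, 28.3e-6, 5e-3)) {
    grid <- 10^seq(log10(km) - 3, log10(km) + 3, length.out = 10000)
    vals <- bell_curve(grid, 2.5, 0.3, km)
    expect_equal(grid[which.max(vals)], bell_argmax(km),
                 tolerance = 2e-3)
  }
  expect_error(bell_argmax(-1), "> 0")
})

test_that("percent inactivation is bounded, scale invariant, and guarded", {
  expect_equal(percent_inactivation(1, 1), 0)
  expect_equal(percent_inactivation(1, 0), 100)
  expect_equal(percent_inactivation(2e-7, 0.5e-7),
               percent_inactivation(2, 0.5))
  expect_error(percent_inactivation(0, 0), "dI_peak")
})

test_that("trace features round-trip the generator truth", {
  # flat zero trace
  proto <- step_protocol()
  n <- sum(proto$segments$duration_s) * proto$sampling_Hz
  flat <- structure(list(time_s = seq(0, by = 0.1, length.out = n),
                         current_A = rep(0, n)), class = "tevc_trace")
  f0 <- extract_trace_features(flat, proto)
  expect_equal(f0$dI_peak_A, 0)
  expect_equal(f0$dI_ss_A, 0)
  # noiseless synthetic trace: extracted features equal recorded truth
  nm0 <- noise_model(cv = 0, additive_sd = 0, leak_sd = 0, seed = 5)
  tr <- simulate_tevc_trace(hak5_trace_preset(), proto, noise = nm0)
  f <- extract_trace_features(tr)
  truth <- attr(tr, "truth")$segments
  expect_equal(f$dI_peak_A, truth$dI_peak_A[2], tolerance = 0.01)
  expect_equal(f$dI_ss_A, truth$dI_ss_A[2], tolerance = 0.01)
  # missing baseline segment is an error
  bad <- step_protocol(segments = data.frame(
    duration_s = 120, substrate = "K", conc_M = 2e-3, pH = 4.5))
  expect_error(extract_trace_features(tr, bad), "baseline")
})

test_that("K_m estimation is nearly unbiased under multiplicative noise", {
  truth <- list(I_max = 1, K_m = 23.56e-6)
  kms <- sapply(1:50, function(seed) {
    d <- generate_dose_response(truth, paper_concs,
                                noise_model(cv = 0.05, seed = seed),
                                n_replicates = 5)
    fit_michaelis_menten(d)$estimate$K_m
  })
  expect_lt(abs(stats::median(kms) / truth$K_m - 1), 0.10)
})
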