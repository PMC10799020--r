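test_that("recovery series matches the bleach-depth relation at t = 0", {
  for (K in c(0.5, 1, 3, 6)) {
    expect_equal(frap_recovery_fraction(0, K, tau_D = 5),
                 (1 - exp(-K)) / K, tolerance = 1e-9)
  }
})

test_that("recovery series reaches full recovery and handles the no-bleach limit", {
  tau <- 5
  expect_equal(frap_recovery_fraction(1e6 * tau, K = 3, tau_D = tau), 1,
               tolerance = 1e-5)
  expect_equal(frap_recovery_fraction(12, K = 1e-8, tau_D = tau), 1,
               tolerance = 1e-6)
})

test_that("recovery is monotone, bounded, and depends on t only through t/tau_D", {
  t <- seq(0, 200, length.out = 400)
  for (K in c(1, 3, 6)) {
    for (tau in c(1, 4.94, 20)) {
      f <- frap_recovery_fraction(t, K, tau)
      f0 <- (1 - exp(-K)) / K
      # slack at the level of the series truncation tolerance (1e-9)
      expect_true(all(diff(f) >= -1e-8))
      expect_true(all(f >= f0 - 1e-8 & f <= 1 + 1e-8))
    }
    # halving D (doubling tau_D) and doubling t leaves f unchanged
    expect_equal(frap_recovery_fraction(t, K, 5),
                 frap_recovery_fraction(2 * t, K, 10), tolerance = 1e-12)
  }
})

test_that("series agrees with the finite-difference diffusion oracle", {
  # light check on a coarse grid; the acceptance suite covers K in {1,3,6}
  tau <- 0.25 # w = 1, D = 1
  tt <- seq(0.05, 20 * tau, length.out = 15)
  pde <- pde_recovery_oracle(tt, K = 3)
  ser <- frap_recovery_fraction(tt, K = 3, tau_D = tau)
  expect_lt(max(abs(pde - ser)), 5e-3)
})

test_that("argument validation names the offending parameter", {
  expect_error(frap_recovery_fraction(-1, 3, 5), "`t`")
  expect_error(frap_recovery_fraction(1, -3, 5), "`K`")
  expect_error(frap_recovery_fraction(1, 3, 0), "`tau_D`")
  expect_error(frap_recovery_fraction(1, 3, 5, tol = 0), "`tol`")
  expect_error(frap_recovery_fraction(1, 500, 5, max_terms = 50L),
               "did not converge")
})

test_that("model curve composes immobile-fraction bookkeeping correctly", {
  beam <- std_beam(t_max = 400)
  # F(0) is independent of R_f
  t0 <- 1e-9
  f_lo <- frap_model_curve(beam, D = 0.03, R_f = 0.2, t = t0)$F
  f_hi <- frap_model_curve(beam, D = 0.03, R_f = 0.9, t = t0)$F
  expect_equal(f_lo, f_hi, tolerance = 1e-6)

  # fully mobile: complete recovery to F_pre
  expect_equal(frap_model_curve(beam, D = 0.03, R_f = 1, F_pre = 2.5,
                                t = 1e7)$F, 2.5, tolerance = 1e-4)

  # fully immobile: flat at F_pre * f(0)
  flat <- frap_model_curve(beam, D = 0.03, R_f = 0)
  f0 <- (1 - exp(-beam$K)) / beam$K
  expect_equal(flat$F, rep(f0, nrow(flat)), tolerance = 1e-12)

  # normalized recovery equals R_f exactly
  for (Rf in c(0.25, 0.65, 0.9)) {
    F0 <- frap_model_curve(beam, D = 0.03, R_f = Rf, t = 0)$F
    Finf <- frap_model_curve(beam, D = 0.03, R_f = Rf, t = 1e8)$F
    expect_equal((Finf - F0) / (1 - F0), Rf, tolerance = 1e-5)
  }
})

test_that("beam protocol and bleach-depth helpers validate and invert", {
  expect_error(beam_protocol(w = -1), "`w`")
  expect_error(beam_protocol(K = 0), "`K`")
  expect_error(beam_protocol(t_grid = c(3, 2, 1)), "strictly increasing")
  expect_error(beam_protocol(n_pre = 0), "`n_pre`")

  # K = 3 sits inside the 60-75% bleach operating range
  expect_gt(bleach_depth(3), 0.60)
  expect_lt(bleach_depth(3), 0.75)
  for (K in c(0.5, 2, 3, 5)) {
    expect_equal(bleach_depth_to_K(1 - bleach_depth(K)), K, tolerance = 1e-8)
  }
  expect_equal(tau_diffusion(0.77, 0.03), 0.77^2 / (4 * 0.03))
  expect_identical(tau_diffusion(0.77, 0), Inf)
})
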