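test_that("normalization fixes the pre-bleach baseline at one and is idempotent", {
  beam <- std_beam(t_max = 30)
  cur <- simulate_frap_curve(beam, 0.03, 0.65, seed = 1, F_pre = 500)
  norm <- normalize_frap(cur)
  expect_equal(mean(norm$F_au[norm$phase == "pre"]), 1, tolerance = 1e-12)
  expect_equal(normalize_frap(norm)$F_au, norm$F_au, tolerance = 1e-12)

  # noiseless curve at any gain normalizes onto the unit-baseline model
  cur0 <- simulate_frap_curve(beam, 0.03, 0.65, noise = noise_model(0),
                              seed = 1, F_pre = 3.7)
  model <- frap_model_curve(beam, D = 0.03, R_f = 0.65, F_pre = 1)
  norm0 <- normalize_frap(cur0)
  expect_equal(norm0$F_au[norm0$phase == "post"], model$F, tolerance = 1e-12)

  bad <- cur
  bad$F_au[bad$phase == "pre"] <- 0
  expect_error(normalize_frap(bad), "pre-bleach mean")
})

test_that("noiseless curves are recovered to at least four significant figures", {
  beam <- std_beam(t_max = 150)
  for (truth in list(c(D = 0.03, Rf = 0.65), c(D = 0.01, Rf = 0.4))) {
    cur <- simulate_frap_curve(beam, truth["D"], truth["Rf"],
                               noise = noise_model(0), seed = 1)
    for (K in list(NULL, 3)) {
      f <- fit_frap(cur, w = beam$w, K = K)
      expect_lt(abs(f$Rf_hat - truth["Rf"]) / truth["Rf"], 1e-4)
      expect_lt(abs(f$D_hat - truth["D"]) / truth["D"], 1e-4)
      expect_true(f$converged)
    }
  }
})

test_that("estimates are invariant to detector gain and coherent under time rescaling", {
  beam <- std_beam(t_max = 120)
  cur <- simulate_frap_curve(beam, 0.025, 0.6, seed = 8)
  f1 <- fit_frap(cur, w = beam$w)
  scaled <- dplyr::mutate(cur, F_au = F_au * 7.3)
  f2 <- fit_frap(scaled, w = beam$w)
  expect_equal(f1$Rf_hat, f2$Rf_hat, tolerance = 1e-6)
  expect_equal(f1$D_hat, f2$D_hat, tolerance = 1e-6)

  # doubling all times halves the fitted D exactly
  slowed <- dplyr::mutate(cur, t_s = t_s * 2)
  f3 <- fit_frap(slowed, w = beam$w)
  expect_equal(f3$D_hat, f1$D_hat / 2, tolerance = 1e-6)
  expect_equal(f3$Rf_hat, f1$Rf_hat, tolerance = 1e-6)
})

test_that("low-recovery curves keep R_f but flag D as unreliable", {
  beam <- std_beam(t_max = 120)
  cur <- simulate_frap_curve(beam, 0.025, 0.15, seed = 5)
  f <- fit_frap(cur, w = beam$w, K = 3)
  expect_lt(f$recovery_pct, 20)
  expect_false(f$d_reliable)
  expect_true(is.finite(f$Rf_hat))
  expect_equal(f$Rf_hat, 0.15, tolerance = 0.05)
})

test_that("estimator bias vanishes as measurement noise shrinks", {
  beam <- std_beam(t_max = 120)
  med_err <- vapply(c(0.05, 0.02, 0.005), function(s0) {
    errs <- vapply(1:30, function(s) {
      cur <- simulate_frap_curve(beam, 0.025, 0.65,
                                 noise = noise_model(s0), seed = 1000 + s)
      f <- fit_frap(cur, w = beam$w, K = 3)
      c(abs(f$D_hat - 0.025) / 0.025, abs(f$Rf_hat - 0.65))
    }, numeric(2))
    apply(errs, 1, median)
  }, numeric(2))
  expect_true(all(diff(med_err[1, ]) < 0))  # relative D error decreases
  expect_true(all(diff(med_err[2, ]) < 0))  # absolute Rf error decreases
  expect_lt(med_err[1, 3], 0.01)
  expect_lt(med_err[2, 3], 0.005)
})

test_that("cohort fitting returns one flagged row per cell, never dropping failures", {
  beam <- std_beam(t_max = 60)
  design <- tibble::tibble(condition = c("a", "b"), crosslinked = c(FALSE, TRUE),
                           D = 0.025, R_f = c(0.6, 0.4), n_cells = 3)
  coh <- simulate_frap_cohort(design, beam, seed = 2)
  # corrupt one cell so its fit cannot proceed
  broken <- coh
  broken$F_au[broken$cell_id == "a_c1" & broken$phase == "pre"] <- 0
  res <- fit_frap_cohort(broken, w = beam$w)
  expect_equal(nrow(res), 6)
  expect_false(res$converged[res$cell_id == "a_c1"])
  expect_true(all(res$converged[res$cell_id != "a_c1"]))
})
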