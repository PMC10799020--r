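test_that("binding parameters enforce time-step and geometry stability", {
  expect_error(binding_sim_params(k_on = 3, k_off = 3, dt = 0.02),
               "k_on \\+ k_off")
  expect_error(binding_sim_params(D_free = 0.5, box_size = 8, dt = 0.05),
               "diffusion")
  beam <- std_beam(t_max = 10)
  p <- binding_sim_params(box_size = 5, n_particles = 100, dt = 0.001)
  expect_error(simulate_binding_frap(p, beam, seed = 1), "10 \\* w")
})

test_that("binding simulation is reproducible and conserves particles", {
  beam <- beam_protocol(K = 3, t_grid = seq(0.3, 20, by = 0.3),
                        n_pre = 5, monitor_interval = 0.3)
  p <- binding_sim_params(D_free = 0.03, k_on = 0.5, k_off = 0.5,
                          box_size = 8, n_particles = 4000, dt = 0.02)
  a <- simulate_binding_frap(p, beam, seed = 9)
  b <- simulate_binding_frap(p, beam, seed = 9)
  expect_identical(a$F_au, b$F_au)
  expect_identical(attr(a, "diagnostics")$n_particles, 4000L)
  expect_true(all(a$F_au >= 0))
})

test_that("bound fraction at bleach time sits at the kinetic steady state", {
  beam <- beam_protocol(K = 3, t_grid = seq(0.3, 5, by = 0.3),
                        n_pre = 3, monitor_interval = 0.3)
  for (frac in c(0.25, 0.6)) {
    k_off <- 1; k_on <- k_off * frac / (1 - frac)
    p <- binding_sim_params(D_free = 0.03, k_on = k_on, k_off = k_off,
                            box_size = 8, n_particles = 20000, dt = 0.02)
    d <- attr(simulate_binding_frap(p, beam, seed = 5), "diagnostics")
    se <- sqrt(frac * (1 - frac) / 20000)
    expect_lt(abs(d$bound_frac_at_bleach - frac), 5 * se)
  }
})

test_that("with binding switched off the fit recovers pure-diffusion truth", {
  beam <- beam_protocol(K = 3, t_grid = seq(0.2, 30, by = 0.3),
                        n_pre = 5, monitor_interval = 0.3)
  p0 <- binding_sim_params(D_free = 0.03, k_on = 0, k_off = 0,
                           box_size = 16, n_particles = 120000, dt = 0.028)
  ests <- t(vapply(1:3, function(s) {
    f <- fit_frap(simulate_binding_frap(p0, beam, seed = s), w = beam$w, K = 3)
    c(f$Rf_hat, f$D_hat)
  }, numeric(2)))
  expect_gt(mean(ests[, 1]), 0.9)            # no immobile population
  expect_lt(abs(mean(ests[, 2]) - 0.03), 0.012) # D within Monte Carlo error
})

test_that("slow and fast exchange produce the stable and transient signatures", {
  # one seeded replicate per regime; the acceptance suite sweeps 10 each
  beam <- beam_protocol(K = 3, t_grid = seq(0.2, 30, by = 0.3),
                        n_pre = 5, monitor_interval = 0.3)
  tauD <- tau_diffusion(0.77, 0.03)
  run_arm <- function(k_on, k_off, dt, seeds, cond, cl) {
    prm <- binding_sim_params(D_free = 0.03, k_on = k_on, k_off = k_off,
                              box_size = 16, n_particles = 120000, dt = dt)
    fit_frap_cohort(dplyr::bind_rows(lapply(seeds, function(s)
      suppressWarnings(simulate_binding_frap(
        prm, beam, seed = s, cell_id = paste0(cond, s),
        condition = cond, crosslinked = cl)))), K = 3)
  }
  control <- run_arm(0, 0, 0.028, 101:106, "free", FALSE)

  k_off_s <- 0.01 / tauD
  stable_arm <- run_arm(k_off_s * 2/3, k_off_s, 0.028, 1:6, "CL", TRUE)
  expect_identical(classify_interaction(control, stable_arm)$classification,
                   "stable")

  k_off_t <- 100 / tauD
  transient_arm <- run_arm(k_off_t * 2/3, k_off_t,
                           0.09 / (k_off_t * 5/3), 1:6, "CL", TRUE)
  expect_identical(classify_interaction(control, transient_arm)$classification,
                   "transient")
})
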