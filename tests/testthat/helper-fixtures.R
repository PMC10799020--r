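# Shared fixtures and the independent finite-difference diffusion oracle.

std_beam <- function(t_max = 120, dt = 0.4, K = 3, w = 0.77, n_pre = 10) {
  beam_protocol(w = w, K = K, t_grid = seq(dt, t_max, by = dt),
                n_pre = n_pre, monitor_interval = dt)
}

# Independent oracle for Gaussian-spot recovery: numerically evolve the 2-D
# axisymmetric diffusion equation dc/dt = D (c_rr + c_r / r) from the
# post-bleach profile c(r, 0) = exp(-K exp(-2 r^2 / w^2)) (Dirichlet c = 1
# at the far boundary, reflective at r = 0) and integrate against the
# monitoring Gaussian. Flux-conservative finite volumes in r; stiff ODE
# integration in t. Works in units w = 1, D = 1 (the recovery depends on
# t / tau_D only).
pde_recovery_oracle <- function(t_eval, K, R_max = 14, nr = 700) {
  dr <- R_max / nr
  r <- (seq_len(nr) - 0.5) * dr
  c0 <- exp(-K * exp(-2 * r^2))
  mon <- exp(-2 * r^2) * r
  rhs <- function(t, c, p) {
    r_edge <- seq_len(nr - 1) * dr
    flux <- r_edge * (c[-1] - c[-nr]) / dr
    outer_flux <- R_max * (1 - c[nr]) / (dr / 2)
    div <- c(flux, outer_flux) - c(0, flux)
    list(div / (r * dr))
  }
  sol <- deSolve::ode(y = c0, times = c(0, t_eval), func = rhs, parms = NULL,
                      method = "lsoda", rtol = 1e-8, atol = 1e-8)
  vapply(seq_along(t_eval),
         function(i) sum(sol[i + 1, -1] * mon) / sum(mon), numeric(1))
}

# per-cell mobile fractions under the cohort generator's between-cell
# variability model (logit-normal with delta-method CV mapping)
draw_cell_Rf <- function(n, Rf, cv = 0.15) {
  stats::plogis(stats::rnorm(n, stats::qlogis(Rf), cv / (1 - Rf)))
}

# assemble a minimal per-cell fits tibble for inference-layer tests
fits_tbl <- function(condition, Rf, D = NULL, d_reliable = TRUE) {
  tibble::tibble(
    cell_id = paste0(condition, "_", seq_along(Rf)),
    condition = condition,
    Rf_hat = Rf,
    D_hat_um2_per_s = if (is.null(D)) rep(NA_real_, length(Rf)) else D,
    recovery_pct = 60, d_reliable = d_reliable, converged = TRUE
  )
}
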