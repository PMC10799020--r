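#' Measurement-noise model for simulated FRAP curves
#'
#' Photon-counting detection gives shot noise whose standard deviation grows
#' with the square root of the signal; the default scheme applies Gaussian
#' noise with SD `sigma0 * sqrt(F)` (the Gaussian limit of Poisson noise).
#' A `constant` scheme with SD `sigma0` is available for detectors dominated
#' by read noise.
#'
#' @param sigma0 Noise scale at unit fluorescence (>= 0), dimensionless.
#' @param scheme `"signal-scaled"` (default) or `"constant"`.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma0 = 0.02, scheme = c("signal-scaled", "constant")) {
  check_scalar(sigma0, "sigma0", lower = 0)
  scheme <- match.arg(scheme)
  structure(list(sigma0 = sigma0, scheme = scheme), class = "noise_model")
}

noise_sd <- function(noise, F) {
  switch(noise$scheme,
         "signal-scaled" = noise$sigma0 * sqrt(pmax(F, 0)),
         "constant"      = rep(noise$sigma0, length(F)))
}

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

#' Simulate one noisy FRAP recovery curve
#'
#' Draws a noiseless backbone from [frap_model_curve()] — pre-bleach baseline
#' at `F_pre`, bleach event, diffusive recovery — and adds measurement noise
#' per the [noise_model()]. Pre-bleach samples sit at negative times on the
#' monitoring grid; the bleach event is at `t = 0`. The ground-truth
#' mobility parameters travel with the curve in the `D_true` / `Rf_true`
#' columns so parameter-recovery studies need no side table.
#'
#' @param beam A [beam_protocol()]. Protocols implying a bleach depth of 95%
#'   or more are rejected (outside the detector-linearity assumption).
#' @param D,R_f Ground-truth mobility: diffusion coefficient (um^2/s) and
#'   mobile fraction.
#' @param noise A [noise_model()].
#' @param seed Integer seed; the same seed reproduces the curve exactly.
#' @param cell_id Label for the curve.
#' @param F_pre Pre-bleach fluorescence level, arbitrary units.
#' @param condition,crosslinked,ligand Condition metadata carried through
#'   the pipeline.
#' @return A tibble with one row per sample: `cell_id`, `condition`,
#'   `crosslinked`, `ligand`, `t_s`, `F_au`, `phase` (`"pre"`/`"post"`),
#'   `D_true`, `Rf_true`.
#' @examples
#' beam <- beam_protocol(t_grid = seq(0.2, 60, by = 0.3))
#' curve <- simulate_frap_curve(beam, D = 0.03, R_f = 0.65, seed = 1)
#' @export
simulate_frap_curve <- function(beam, D, R_f, noise = noise_model(), seed = NULL,
                                cell_id = "cell_1", F_pre = 1,
                                condition = "untitled", crosslinked = FALSE,
                                ligand = "none") {
  stopifnot(inherits(beam, "beam_protocol"), inherits(noise, "noise_model"))
  if (bleach_depth(beam$K) >= 0.95) {
    stop("bleach depth >= 95% is outside the detector linearity assumption; reduce K",
         call. = FALSE)
  }
  pre_t <- -rev(seq_len(beam$n_pre)) * beam$monitor_interval
  post <- frap_model_curve(beam, D = D, R_f = R_f, F_pre = F_pre)
  backbone <- c(rep(F_pre, beam$n_pre), post$F)
  t_all <- c(pre_t, post$t)
  F_noisy <- with_seed(seed, {
    backbone + stats::rnorm(length(backbone), sd = noise_sd(noise, backbone))
  })
  tibble::tibble(
    cell_id = cell_id, condition = condition,
    crosslinked = crosslinked, ligand = ligand,
    t_s = t_all, F_au = pmax(F_noisy, 0),
    phase = rep(c("pre", "post"), c(beam$n_pre, nrow(post))),
    D_true = D, Rf_true = R_f
  )
}

#' Simulate a multi-condition cohort of FRAP curves
#'
#' Generates `n_cells` curves per condition from a design table, emulating a
#' patch/FRAP experiment in which each curve comes from a different cell.
#' Cell-to-cell variability is modelled by jittering the condition-level
#' ground truth: lognormal on D and logit-normal on R_f, both mean-preserving
#' with coefficient of variation `cell_cv`. Per-cell seeds are drawn from a
#' stream scrambled by the base seed, so cohorts are bit-reproducible and
#' different base seeds share no cell-level randomness.
#'
#' @param design A data frame with one row per condition and columns
#'   `condition`, `D`, `R_f`, `n_cells`, and optionally `crosslinked`
#'   (default `FALSE`) and `ligand` (default `"none"`).
#' @param beam A [beam_protocol()].
#' @param noise A [noise_model()].
#' @param seed Integer base seed.
#' @param cell_cv Between-cell coefficient of variation of D and R_f
#'   (default 0.15). `0` disables jitter.
#' @return A tibble of curves in the [simulate_frap_curve()] schema; cell ids
#'   are unique across the cohort.
#' @examples
#' design <- tibble::tibble(
#'   condition = c("free", "crosslinked"),
#'   crosslinked = c(FALSE, TRUE),
#'   D = 0.025, R_f = c(0.64, 0.39), n_cells = 5
#' )
#' beam <- beam_protocol(t_grid = seq(0.2, 60, by = 0.3))
#' cohort <- simulate_frap_cohort(design, beam, seed = 1)
#' @export
simulate_frap_cohort <- function(design, beam, noise = noise_model(), seed = 1,
                                 cell_cv = 0.15) {
  design <- tibble::as_tibble(design)
  needed <- c("condition", "D", "R_f", "n_cells")
  missing_cols <- setdiff(needed, names(design))
  if (length(missing_cols)) {
    stop("`design` lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"crosslinked" %in% names(design)) design$crosslinked <- FALSE
  if (!"ligand" %in% names(design)) design$ligand <- "none"
  if (any(design$n_cells < 2)) {
    stop("each condition needs n_cells >= 2", call. = FALSE)
  }
  check_scalar(cell_cv, "cell_cv", lower = 0)

  cells <- tidyr::uncount(design, .data$n_cells, .id = "cell_in_cond") |>
    dplyr::mutate(
      cell_index = dplyr::row_number(),
      cell_id = paste0(.data$condition, "_c", .data$cell_in_cond)
    )
  if (anyDuplicated(cells$cell_id)) {
    stop("duplicate cell_id generated; condition labels must be unique",
         call. = FALSE)
  }
  # per-cell seeds drawn from a stream scrambled by the base seed, so that
  # cohorts at different base seeds share no cell-level randomness
  cells$cell_seed <- with_seed(seed, sample.int(2^30 - 1L, nrow(cells)))
  purrr::pmap(cells, function(condition, D, R_f, crosslinked, ligand,
                              cell_in_cond, cell_index, cell_id, cell_seed,
                              ...) {
    truth <- with_seed(cell_seed * 2L + 1L, jitter_mobility(D, R_f, cell_cv))
    simulate_frap_curve(beam, D = truth$D, R_f = truth$R_f, noise = noise,
                        seed = cell_seed, cell_id = cell_id,
                        condition = condition, crosslinked = crosslinked,
                        ligand = ligand)
  }) |>
    purrr::list_rbind()
}

# lognormal jitter on D and logit-normal on R_f, both mean-preserving so
# condition-level expectations equal the design targets; the target CV is
# mapped onto the logit SD by the delta method, and the logit location is
# recentred numerically (plogis is nonlinear, so the naive location
# qlogis(p) would shift the mean toward 0.5)
jitter_mobility <- function(D, R_f, cv) {
  if (cv == 0) return(list(D = D, R_f = R_f))
  sdlog <- sqrt(log(1 + cv^2))
  D_j <- stats::rlnorm(1, meanlog = log(D) - sdlog^2 / 2, sdlog = sdlog)
  p <- min(max(R_f, 1e-6), 1 - 1e-6)
  sd_logit <- cv / (1 - p)
  mu <- logitnorm_location(p, sd_logit)
  R_j <- stats::plogis(stats::rnorm(1, mean = mu, sd = sd_logit))
  list(D = D_j, R_f = R_j)
}

# location mu with E[plogis(N(mu, sigma))] = target, by Gauss-Hermite
# quadrature inside a bisection; cached on (target, sigma)
logitnorm_location <- local({
  cache <- new.env(parent = emptyenv())
  gh <- NULL
  function(target, sigma) {
    key <- paste0(signif(target, 10), "_", signif(sigma, 10))
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    if (is.null(gh)) {
      # 21-node Gauss-Hermite rule via the Golub-Welsch eigen method
      n <- 21L
      off <- sqrt(seq_len(n - 1) / 2)
      J <- diag(0, n)
      J[cbind(seq_len(n - 1), seq_len(n - 1) + 1L)] <- off
      J[cbind(seq_len(n - 1) + 1L, seq_len(n - 1))] <- off
      e <- eigen(J, symmetric = TRUE)
      gh <<- list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2 / sqrt(pi))
      gh$weights <<- e$vectors[1, ]^2 # normalized: sum = 1
    }
    mean_at <- function(mu) {
      sum(gh$weights * stats::plogis(mu + sqrt(2) * sigma * gh$nodes))
    }
    mu <- stats::uniroot(function(m) mean_at(m) - target,
                         stats::qlogis(target) + c(-1, 1) * (1 + 4 * sigma),
                         tol = 1e-10)$root
    cache[[key]] <- mu
    mu
  }
})
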