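#' Stable-complex fraction from mobile fractions
#'
#' The central patch/FRAP statistic: when a fraction of the labelled
#' receptor resides in long-lived complexes with an IgG-immobilized partner,
#' its mobile fraction drops from `Rf_free` to `Rf_CL`, and the fraction of
#' molecules in such complexes is the relative reduction
#'
#' \deqn{C = 100 \cdot (R_{f,free} - R_{f,CL}) / R_{f,free}}
#'
#' in percent. The statistic is scale-invariant, so `Rf` values may be given
#' as fractions or percentages as long as both arms use the same scale.
#'
#' @param Rf_free Mobile fraction of the receptor with the partner free
#'   (uncrosslinked), percent or fraction (> 0). Vectorized.
#' @param Rf_CL Mobile fraction with the partner crosslinked; must not
#'   exceed `Rf_free`.
#' @return Complex fraction in percent, unrounded.
#' @examples
#' complex_fraction(64, 39) # ~39% of the receptor in stable complexes
#' complex_fraction(56, 18) # ~68% with two partners co-immobilized
#' @export
complex_fraction <- function(Rf_free, Rf_CL) {
  if (!is.numeric(Rf_free) || !is.numeric(Rf_CL) ||
      any(!is.finite(Rf_free)) || any(!is.finite(Rf_CL))) {
    stop("`Rf_free` and `Rf_CL` must be finite numbers", call. = FALSE)
  }
  if (any(Rf_free <= 0)) stop("`Rf_free` must be > 0", call. = FALSE)
  if (any(Rf_CL < 0)) stop("`Rf_CL` must be >= 0", call. = FALSE)
  if (any(Rf_CL > Rf_free)) {
    stop("no mobility reduction; complex fraction undefined (Rf_CL > Rf_free)",
         call. = FALSE)
  }
  100 * (Rf_free - Rf_CL) / Rf_free
}

#' Significance stars in the conventional tiers
#'
#' Tiers 0.05, 0.01, 1e-3, 1e-4 map to one through four asterisks;
#' `"ns"` otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of the same length.
#' @export
significance_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 1e-4 ~ "****",
    p < 1e-3 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

# two-sample Welch t test robust to zero-variance degenerate groups
safe_t_test <- function(a, b) {
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  }
  tryCatch(stats::t.test(a, b)$p.value, error = function(e) NA_real_)
}

#' Compare per-cell mobility estimates across conditions
#'
#' Group statistics in the convention of quantitative FRAP studies: with
#' more than two groups, a one-way ANOVA omnibus test followed by all-pairs
#' post-hoc contrasts with Bonferroni-adjusted p-values (pooled-SD pairwise
#' t tests); with exactly two groups, a Student's t test. Group summaries
#' are reported as mean +/- SEM. For `variable = "D"`, only cells whose D
#' estimate passed quality control (`d_reliable`) enter, which is why per-
#' group n can be smaller for D than for R_f.
#'
#' @param fits A per-cell fit tibble from [fit_frap_cohort()] (or any tibble
#'   with the grouping column, `Rf_hat`, `D_hat_um2_per_s`, `d_reliable`).
#' @param variable `"Rf"` or `"D"`.
#' @param group Name of the grouping column (default `"condition"`).
#' @param alpha Significance level in `(0, 0.5]`.
#' @return An object of class `group_comparison`: list with `means` (per-
#'   group mean, SEM, n), `pairwise` (adjusted p-values and stars),
#'   `omnibus_p` (ANOVA p, `NA` for two groups), `variable`, `alpha`.
#' @examples
#' beam <- beam_protocol(t_grid = seq(0.2, 60, by = 0.4))
#' design <- tibble::tibble(condition = c("free", "CL"),
#'                          crosslinked = c(FALSE, TRUE),
#'                          D = 0.025, R_f = c(0.64, 0.39), n_cells = 5)
#' fits <- fit_frap_cohort(simulate_frap_cohort(design, beam, seed = 3))
#' compare_groups(fits, "Rf")
#' @export
compare_groups <- function(fits, variable = c("Rf", "D"),
                           group = "condition", alpha = 0.05) {
  variable <- match.arg(variable)
  check_scalar(alpha, "alpha", lower = 0, upper = 0.5, strict = FALSE)
  if (alpha <= 0) stop("`alpha` must be in (0, 0.5]", call. = FALSE)
  value_col <- if (variable == "Rf") "Rf_hat" else "D_hat_um2_per_s"
  if (!all(c(group, value_col) %in% names(fits))) {
    stop("`fits` lacks column `", group, "` or `", value_col, "`", call. = FALSE)
  }
  dat <- fits
  if ("converged" %in% names(dat)) dat <- dat[isTRUE_vec(dat$converged), ]
  if (variable == "D" && "d_reliable" %in% names(dat)) {
    dat <- dat[isTRUE_vec(dat$d_reliable), ]
  }
  dat <- dat[is.finite(dat[[value_col]]), ]
  dat$.g <- factor(dat[[group]])
  dat$.y <- dat[[value_col]]

  counts <- table(dat$.g)
  if (length(counts) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(counts < 2L)) {
    stop("every group needs n >= 2; offending group(s): ",
         paste(names(counts)[counts < 2], collapse = ", "), call. = FALSE)
  }

  means <- dat |>
    dplyr::group_by(group_label = .data$.g) |>
    dplyr::summarise(
      mean = mean(.data$.y),
      sem = stats::sd(.data$.y) / sqrt(dplyr::n()),
      n = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::mutate(group_label = as.character(.data$group_label))

  lv <- levels(dat$.g)
  if (length(lv) == 2L) {
    omnibus_p <- NA_real_
    p <- safe_t_test(dat$.y[dat$.g == lv[1]], dat$.y[dat$.g == lv[2]])
    pairwise <- tibble::tibble(group1 = lv[1], group2 = lv[2], p_adj = p)
  } else {
    omnibus_p <- tryCatch(
      summary(stats::aov(.y ~ .g, data = dat))[[1]][["Pr(>F)"]][1],
      error = function(e) NA_real_)
    ptt <- tryCatch(
      stats::pairwise.t.test(dat$.y, dat$.g, p.adjust.method = "bonferroni",
                             pool.sd = TRUE),
      error = function(e) NULL)
    pairs <- utils::combn(lv, 2)
    p_adj <- apply(pairs, 2, function(pr) {
      val <- if (!is.null(ptt)) {
        m <- ptt$p.value
        v <- c(
          if (pr[2] %in% rownames(m) && pr[1] %in% colnames(m)) m[pr[2], pr[1]] else NA_real_,
          if (pr[1] %in% rownames(m) && pr[2] %in% colnames(m)) m[pr[1], pr[2]] else NA_real_
        )
        v[!is.na(v)][1]
      } else NA_real_
      if (length(val) == 0L || is.na(val)) {
        # fall back for degenerate zero-variance groups
        min(1, safe_t_test(dat$.y[dat$.g == pr[1]], dat$.y[dat$.g == pr[2]]) *
              ncol(pairs))
      } else val
    })
    pairwise <- tibble::tibble(group1 = pairs[1, ], group2 = pairs[2, ],
                               p_adj = as.numeric(p_adj))
  }
  pairwise$stars <- significance_stars(pairwise$p_adj)
  pairwise$significant <- !is.na(pairwise$p_adj) & pairwise$p_adj < alpha

  structure(
    list(means = means, pairwise = pairwise, omnibus_p = omnibus_p,
         variable = variable, alpha = alpha,
         test = if (length(lv) == 2L) "Student t" else "one-way ANOVA + Bonferroni"),
    class = "group_comparison"
  )
}

isTRUE_vec <- function(x) !is.na(x) & x

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s, %s, alpha = %g\n", x$variable, x$test, x$alpha))
  if (!is.na(x$omnibus_p)) cat(sprintf("  omnibus ANOVA p = %.3g\n", x$omnibus_p))
  print(x$means)
  print(x$pairwise)
  invisible(x)
}

#' @export
tidy.group_comparison <- function(x, ...) x$pairwise

#' @export
glance.group_comparison <- function(x, ...) {
  tibble::tibble(variable = x$variable, test = x$test,
                 omnibus_p = x$omnibus_p, n_groups = nrow(x$means),
                 alpha = x$alpha)
}

#' Classify a receptor-pair interaction from patch/FRAP arms
#'
#' The patch/FRAP decision rule. Complexes outliving the characteristic FRAP
#' time co-immobilize the labelled receptor with its crosslinked partner:
#' the mobile fraction R_f drops while D is untouched (`stable`). Complexes
#' turning over much faster than the FRAP time instead slow the receptor
#' down: D drops while R_f is untouched (`transient`). Both contrasts
#' significant gives `mixed`; neither, `none`. "Significantly lower" means
#' adjusted p below `alpha` together with a decrease in the group mean; "no
#' effect" is operationalized as p >= alpha.
#'
#' For a `stable` (or `mixed`) call the complex fraction is computed from the
#' group-mean mobile fractions via [complex_fraction()]; for a `transient`
#' call it is computed analogously from the relative reduction of mean D
#' (the bound fraction in the fast-exchange limit). An optional bootstrap
#' over cells gives a percentile confidence interval on the complex
#' fraction.
#'
#' @param fits_free Per-cell fit tibble for the arm with the partner free.
#' @param fits_cl Per-cell fit tibble for the arm with the partner
#'   IgG-crosslinked. Both arms must agree on `condition`-defining metadata
#'   other than the `crosslinked` flag (checked when `ligand` is present).
#' @param alpha Significance level.
#' @param n_boot Bootstrap replicates for the complex-fraction CI
#'   (0 disables).
#' @return An object of class `interaction_call`: classification, complex
#'   fraction (percent), p-values for the R_f and D contrasts, group
#'   summaries, and optionally a bootstrap CI.
#' @export
classify_interaction <- function(fits_free, fits_cl, alpha = 0.05,
                                 n_boot = 0) {
  for (nm in intersect(c("ligand"), intersect(names(fits_free), names(fits_cl)))) {
    if (!setequal(unique(fits_free[[nm]]), unique(fits_cl[[nm]]))) {
      stop("arms differ in `", nm, "`; compare like with like (use ligand_effect() for ligand contrasts)",
           call. = FALSE)
    }
  }
  arm <- dplyr::bind_rows(
    dplyr::mutate(fits_free, .arm = "free"),
    dplyr::mutate(fits_cl, .arm = "crosslinked")
  )
  cmp_Rf <- compare_groups(arm, "Rf", group = ".arm", alpha = alpha)
  # the D contrast can be unevaluable (too few QC-passing D estimates);
  # it is then recorded as NA and treated as showing no effect
  cmp_D <- tryCatch(compare_groups(arm, "D", group = ".arm", alpha = alpha),
                    error = function(e) NULL)
  p_Rf <- cmp_Rf$pairwise$p_adj[1]
  p_D <- if (is.null(cmp_D)) NA_real_ else cmp_D$pairwise$p_adj[1]
  mean_of <- function(cmp, lab) {
    if (is.null(cmp)) return(NA_real_)
    cmp$means$mean[cmp$means$group_label == lab]
  }
  Rf_free_m <- mean_of(cmp_Rf, "free"); Rf_cl_m <- mean_of(cmp_Rf, "crosslinked")
  D_free_m <- mean_of(cmp_D, "free"); D_cl_m <- mean_of(cmp_D, "crosslinked")

  rf_down <- !is.na(p_Rf) && p_Rf < alpha && Rf_cl_m < Rf_free_m
  d_down <- !is.na(p_D) && p_D < alpha && D_cl_m < D_free_m
  classification <- if (rf_down && d_down) "mixed"
    else if (rf_down) "stable"
    else if (d_down) "transient"
    else "none"

  cf <- switch(classification,
    stable = , mixed = complex_fraction(Rf_free_m, min(Rf_cl_m, Rf_free_m)),
    transient = complex_fraction(D_free_m, min(D_cl_m, D_free_m)),
    none = NA_real_)

  boot_ci <- NULL
  if (n_boot > 0 && classification %in% c("stable", "mixed")) {
    a <- fits_free$Rf_hat[is.finite(fits_free$Rf_hat)]
    b <- fits_cl$Rf_hat[is.finite(fits_cl$Rf_hat)]
    reps <- vapply(seq_len(n_boot), function(i) {
      m1 <- mean(sample(a, replace = TRUE))
      m2 <- mean(sample(b, replace = TRUE))
      if (m2 > m1) 0 else complex_fraction(m1, m2)
    }, numeric(1))
    boot_ci <- stats::quantile(reps, c(0.025, 0.975), names = FALSE)
  }

  structure(
    list(classification = classification, complex_fraction = cf,
         p_Rf = p_Rf, p_D = p_D, alpha = alpha,
         Rf_means = cmp_Rf$means,
         D_means = if (is.null(cmp_D)) cmp_Rf$means[0, ] else cmp_D$means,
         boot_ci = boot_ci,
         stars_Rf = significance_stars(p_Rf), stars_D = significance_stars(p_D)),
    class = "interaction_call"
  )
}

#' @export
print.interaction_call <- function(x, ...) {
  cat(sprintf("<interaction_call> %s", x$classification))
  if (is.finite(x$complex_fraction)) {
    cat(sprintf(", complex fraction %.0f%%", x$complex_fraction))
  }
  cat(sprintf("\n  R_f contrast: p = %.3g (%s);  D contrast: p = %.3g (%s)\n",
              x$p_Rf, x$stars_Rf, x$p_D, x$stars_D))
  if (!is.null(x$boot_ci)) {
    cat(sprintf("  bootstrap 95%% CI on complex fraction: [%.0f, %.0f]%%\n",
                x$boot_ci[1], x$boot_ci[2]))
  }
  invisible(x)
}

#' @export
tidy.interaction_call <- function(x, ...) {
  tibble::tibble(
    classification = x$classification,
    complex_fraction_pct = x$complex_fraction,
    p_Rf = x$p_Rf, p_D = x$p_D,
    stars_Rf = x$stars_Rf, stars_D = x$stars_D,
    alpha = x$alpha,
    ci_lo = if (is.null(x$boot_ci)) NA_real_ else x$boot_ci[1],
    ci_hi = if (is.null(x$boot_ci)) NA_real_ else x$boot_ci[2]
  )
}

#' Test a ligand effect on receptor mobility
#'
#' Two-group contrast of per-cell mobility estimates without vs with a
#' ligand (e.g. VEGF-A), under otherwise identical conditions. A thin,
#' explicitly-labelled wrapper around [compare_groups()].
#'
#' @param fits_base Per-cell fits without ligand.
#' @param fits_ligand Per-cell fits with ligand.
#' @param variable `"Rf"` (default) or `"D"`.
#' @param alpha Significance level.
#' @return A one-row tibble: ligand labels, group means +/- SEM, p-value,
#'   stars, direction and significance of the effect.
#' @export
ligand_effect <- function(fits_base, fits_ligand, variable = "Rf",
                          alpha = 0.05) {
  arm <- dplyr::bind_rows(
    dplyr::mutate(fits_base, .arm = "base"),
    dplyr::mutate(fits_ligand, .arm = "ligand")
  )
  cmp <- compare_groups(arm, variable, group = ".arm", alpha = alpha)
  m <- cmp$means
  base_m <- m$mean[m$group_label == "base"]
  lig_m <- m$mean[m$group_label == "ligand"]
  p <- cmp$pairwise$p_adj[1]
  tibble::tibble(
    contrast = "ligand", variable = variable,
    ligand_label = if ("ligand" %in% names(fits_ligand)) {
      paste(unique(fits_ligand$ligand), collapse = "+")
    } else "ligand",
    mean_base = base_m, sem_base = m$sem[m$group_label == "base"],
    mean_ligand = lig_m, sem_ligand = m$sem[m$group_label == "ligand"],
    p_adj = p, stars = significance_stars(p),
    direction = dplyr::case_when(lig_m < base_m ~ "decrease",
                                 lig_m > base_m ~ "increase",
                                 TRUE ~ "none"),
    significant = !is.na(p) & p < alpha
  )
}
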