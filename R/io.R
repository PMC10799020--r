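#' Read a tidy FRAP curve CSV
#'
#' Expects the schema written by [write_frap_curves()] / `cmd_simulate()`:
#' columns `cell_id`, `condition`, `crosslinked`, `ligand`, `t_s`, `F_au`,
#' `phase` (`pre`/`post`), one header line, UTF-8, '.' decimal. Schema
#' violations are reported naming the offending column, and malformed
#' values naming the row.
#'
#' @param path Path to the CSV file.
#' @return A curve tibble.
#' @export
read_frap_curves <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  needed <- c("cell_id", "condition", "crosslinked", "ligand", "t_s", "F_au", "phase")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("curve CSV lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("t_s", "F_au")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad)) {
      stop(sprintf("malformed value in column `%s`, row %d (line %d of file)",
                   col, bad[1], bad[1] + 1L), call. = FALSE)
    }
    df[[col]] <- v
  }
  bad_phase <- which(!df$phase %in% c("pre", "post"))
  if (length(bad_phase)) {
    stop(sprintf("malformed value in column `phase`, row %d: must be 'pre' or 'post'",
                 bad_phase[1]), call. = FALSE)
  }
  df$crosslinked <- as.logical(df$crosslinked)
  tibble::as_tibble(df)
}

#' Write FRAP curves to the tidy CSV schema
#'
#' @param curves A curve tibble.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_frap_curves <- function(curves, path) {
  cols <- c("cell_id", "condition", "crosslinked", "ligand", "t_s", "F_au", "phase")
  missing_cols <- setdiff(cols, names(curves))
  if (length(missing_cols)) {
    stop("curves lack column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  utils::write.csv(curves[, cols], path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a per-cell fit results CSV
#'
#' @param path Path to a results CSV written by `cmd_fit()` /
#'   [fit_frap_cohort()].
#' @return A results tibble.
#' @export
read_frap_results <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  needed <- c("cell_id", "condition", "Rf_hat", "D_hat_um2_per_s",
              "recovery_pct", "d_reliable", "converged")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("results CSV lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df$d_reliable <- as.logical(df$d_reliable)
  df$converged <- as.logical(df$converged)
  tibble::as_tibble(df)
}

log_msg <- function(...) message("[patchfrap] ", sprintf(...))

default_beam_from_config <- function(bc) {
  bc <- utils::modifyList(
    list(w = 0.77, K = 3, t_max = 120, dt_post = 0.4, n_pre = 10,
         monitor_interval = 0.4),
    bc %||% list()
  )
  beam_protocol(w = bc$w, K = bc$K,
                t_grid = seq(bc$dt_post, bc$t_max, by = bc$dt_post),
                n_pre = bc$n_pre, monitor_interval = bc$monitor_interval)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a cohort from a YAML run configuration
#'
#' Reads a configuration describing the beam, the noise model and a table of
#' conditions (each with ground-truth D, R_f and a cell count), simulates
#' the cohort, and writes two CSVs into `out_dir`: `curves.csv` (tidy curve
#' schema) and `ground_truth.csv` (per-cell true parameters). Run metadata
#' (seed, package version, config hash) is logged to stderr.
#'
#' @param config Path to a YAML file, or an equivalent nested list. See the
#'   demo config shipped at
#'   `system.file("extdata", "demo_config.yaml", package = "patchfrap")`.
#' @param seed Integer seed; identical seeds give byte-identical CSVs.
#' @param out_dir Output directory (created if needed; must be writable).
#' @return Invisibly, a list with the two output paths and the curve tibble.
#' @export
cmd_simulate <- function(config, seed = 1, out_dir = ".") {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  if (file.access(out_dir, 2) != 0) {
    stop("output directory not writable: ", out_dir, call. = FALSE)
  }
  design <- purrr::map(cfg$conditions, tibble::as_tibble) |> purrr::list_rbind()
  if (any(design$n_cells <= 0)) {
    stop("n_cells must be positive in every condition; offending condition(s): ",
         paste(design$condition[design$n_cells <= 0], collapse = ", "),
         call. = FALSE)
  }
  beam <- default_beam_from_config(cfg$beam)
  nz <- cfg$noise %||% list()
  noise <- noise_model(sigma0 = nz$sigma0 %||% 0.02,
                       scheme = nz$scheme %||% "signal-scaled")
  cell_cv <- cfg$cell_cv %||% 0.15

  log_msg("simulate: seed = %d, version = %s, config hash = %s",
          seed, as.character(utils::packageVersion("patchfrap")),
          rlang::hash(cfg))
  curves <- simulate_frap_cohort(design, beam, noise, seed = seed,
                                 cell_cv = cell_cv)
  curves_path <- file.path(out_dir, "curves.csv")
  truth_path <- file.path(out_dir, "ground_truth.csv")
  write_frap_curves(curves, curves_path)
  truth <- curves |>
    dplyr::distinct(.data$cell_id, .data$condition, .data$crosslinked,
                    .data$ligand, .data$D_true, .data$Rf_true)
  utils::write.csv(truth, truth_path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  log_msg("simulate: wrote %d curves (%d conditions) to %s",
          dplyr::n_distinct(curves$cell_id), nrow(design), curves_path)
  invisible(list(curves = curves_path, ground_truth = truth_path,
                 data = curves, beam = beam))
}

#' Fit every curve in a CSV and write per-cell results
#'
#' @param curves_csv Path to a tidy curve CSV.
#' @param w Spot e^-2 radius, um.
#' @param K Bleach parameter; `NULL` estimates it per curve from the
#'   observed bleach depth.
#' @param out Output CSV path.
#' @return Invisibly, the results tibble.
#' @export
cmd_fit <- function(curves_csv, w = 0.77, K = NULL, out = "results.csv") {
  curves <- read_frap_curves(curves_csv)
  res <- fit_frap_cohort(curves, w = w, K = K)
  utils::write.csv(res, out, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  log_msg("fit: %d curves, %d converged, %d with reliable D -> %s",
          nrow(res), sum(res$converged), sum(res$d_reliable), out)
  invisible(res)
}

#' Run patch/FRAP inference over a set of contrasts
#'
#' Each contrast names two condition labels present in the results table:
#' the arm with the partner free and the arm with the partner crosslinked
#' (type `"crosslink"`, the default), or without/with ligand (type
#' `"ligand"`). For crosslink contrasts with at least two cells per arm the
#' full decision rule of [classify_interaction()] runs; degenerate
#' single-value groups (e.g. published group means entered as one row each)
#' still yield the complex fraction, with the significance tests marked NA.
#'
#' Writes `report.csv` (one row per contrast) and `summary.txt` (human-
#' readable, with significance stars) into `out_dir`.
#'
#' @param results_csv Path to a per-cell results CSV.
#' @param contrasts Path to a YAML contrast list, or an equivalent list of
#'   lists with fields `name`, `free`, `crosslinked` (or `base`, `ligand`
#'   for ligand contrasts), optional `type`.
#' @param alpha Significance level.
#' @param out_dir Output directory.
#' @return Invisibly, the report tibble.
#' @export
cmd_infer <- function(results_csv, contrasts, alpha = 0.05, out_dir = ".") {
  res <- read_frap_results(results_csv)
  ctr <- if (is.character(contrasts)) yaml::read_yaml(contrasts) else contrasts
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  report <- purrr::map(ctr, function(ct) infer_one_contrast(res, ct, alpha)) |>
    purrr::list_rbind()
  if (is.null(report) || nrow(report) == 0L) {
    report <- tibble::tibble(
      name = character(), type = character(), classification = character(),
      complex_fraction_pct = numeric(), p_Rf = numeric(), p_D = numeric(),
      stars_Rf = character(), stars_D = character()
    )
  }
  report_path <- file.path(out_dir, "report.csv")
  utils::write.csv(report, report_path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  lines <- c(sprintf("patch/FRAP inference report (alpha = %g)", alpha),
             strrep("-", 50))
  for (i in seq_len(nrow(report))) {
    r <- report[i, ]
    lines <- c(lines, sprintf(
      "%-28s %-10s complex fraction %s  [Rf: %s  D: %s]",
      r$name, r$classification,
      ifelse(is.na(r$complex_fraction_pct), "  -",
             sprintf("%3.0f%%", r$complex_fraction_pct)),
      r$stars_Rf %||% "NA", r$stars_D %||% "NA"))
  }
  writeLines(lines, file.path(out_dir, "summary.txt"))
  log_msg("infer: %d contrast(s) -> %s", nrow(report), report_path)
  invisible(report)
}

infer_one_contrast <- function(res, ct, alpha) {
  type <- ct$type %||% "crosslink"
  lab_free <- ct$free %||% ct$base
  lab_cl <- ct$crosslinked %||% ct$ligand
  for (lab in c(lab_free, lab_cl)) {
    if (!lab %in% res$condition) {
      stop("unknown group label in contrast `", ct$name %||% "?", "`: ", lab,
           call. = FALSE)
    }
  }
  g_free <- res[res$condition == lab_free, ]
  g_cl <- res[res$condition == lab_cl, ]

  if (type == "ligand") {
    le <- ligand_effect(g_free, g_cl, variable = "Rf", alpha = alpha)
    return(tibble::tibble(
      name = ct$name %||% paste(lab_free, "vs", lab_cl), type = "ligand",
      classification = ifelse(le$significant, le$direction, "none"),
      complex_fraction_pct = NA_real_,
      p_Rf = le$p_adj, p_D = NA_real_,
      stars_Rf = le$stars, stars_D = NA_character_
    ))
  }

  if (nrow(g_free) >= 2 && nrow(g_cl) >= 2) {
    call <- classify_interaction(g_free, g_cl, alpha = alpha)
    out <- tidy.interaction_call(call)
    tibble::tibble(name = ct$name %||% paste(lab_free, "vs", lab_cl),
                   type = "crosslink",
                   classification = out$classification,
                   complex_fraction_pct = out$complex_fraction_pct,
                   p_Rf = out$p_Rf, p_D = out$p_D,
                   stars_Rf = out$stars_Rf, stars_D = out$stars_D)
  } else {
    # degenerate single-value groups: complex fraction from the means only
    m_free <- mean(g_free$Rf_hat, na.rm = TRUE)
    m_cl <- mean(g_cl$Rf_hat, na.rm = TRUE)
    cf <- if (m_cl <= m_free) complex_fraction(m_free, m_cl) else NA_real_
    tibble::tibble(name = ct$name %||% paste(lab_free, "vs", lab_cl),
                   type = "crosslink", classification = "untested",
                   complex_fraction_pct = cf,
                   p_Rf = NA_real_, p_D = NA_real_,
                   stars_Rf = NA_character_, stars_D = NA_character_)
  }
}
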