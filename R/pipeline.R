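#' Read a probe-level table from TSV
#'
#' Column contract: `sample_id`, `strain_id`, `condition`, `gene_id`,
#' `probe_id`, `placement_index`, `dx`, `intensity`, `scale`.
#'
#' @param path TSV path.
#' @return probe tibble.
#' @export
read_probe_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    dx = readr::col_integer(),
                    placement_index = readr::col_integer(),
                    intensity = readr::col_double(),
                    .default = readr::col_character()
                  ))
}

#' Read a wide expression matrix from TSV (genes x samples, NA = missing)
#'
#' @param path TSV path.
#' @return wide expression tibble.
#' @export
read_expression <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(gene_id = readr::col_character(),
                                          .default = readr::col_double()))
}

#' Write a wide expression matrix to TSV
#'
#' @param expr wide expression tibble.
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  readr::write_tsv(expr, path)
  invisible(path)
}

pipeline_log <- function(log_path, verbose, ...) {
  msg <- sprintf(...)
  if (verbose) message(msg)
  cat(msg, "\n", file = log_path, sep = "", append = TRUE)
}

#' Run the full simulate-to-report analysis pipeline
#'
#' Orchestrates the stages end to end on a synthetic cohort: `simulate`
#' (write design, probes, phenotypes, curves, groups and ground truth),
#' `normalize` (probe-to-gene normalization per condition plus
#' xylulose/glucose log-ratios), `growth` (log-linear rate fits and cohort
#' dispersion), `correlate` (group profiles, minimum-strain filter and the
#' group/phenotype scan) and `report` (JSON summary). Identical `config`
#' and seed reproduce identical outputs. Stage outputs already present in
#' `out_dir` are reused unless `force = TRUE`.
#'
#' @param config a [cohort_config()].
#' @param out_dir directory for all artifacts (created if needed).
#' @param stages subset of
#'   `c("simulate", "normalize", "growth", "correlate", "report")`.
#' @param span Lowess span for normalization.
#' @param min_strains minimum-strain filter `k` before group profiling.
#' @param alpha significance threshold for the correlation scan.
#' @param w_min,r2_min growth-window parameters.
#' @param force recompute stages even when their outputs exist.
#' @param verbose echo per-stage progress to the console (always logged to
#'   `run.log`).
#' @return invisibly, a list of class `growthexpr_run` with the stage
#'   results and file paths.
#' @export
run_pipeline <- function(config = cohort_config(),
                         out_dir,
                         stages = c("simulate", "normalize", "growth",
                                    "correlate", "report"),
                         span = 0.3, min_strains = 14, alpha = 0.01,
                         w_min = 5, r2_min = 0.99,
                         force = FALSE, verbose = FALSE) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  if (force || !file.exists(log_path)) cat("", file = log_path)
  paths <- list(
    design = file.path(out_dir, "design.tsv"),
    probes = file.path(out_dir, "probes.tsv"),
    phenotypes = file.path(out_dir, "phenotypes.tsv"),
    curves = file.path(out_dir, "curves.tsv"),
    groups = file.path(out_dir, "groups.gmt"),
    truth = file.path(out_dir, "truth.json"),
    log_ratios = file.path(out_dir, "log_ratios.tsv"),
    growth = file.path(out_dir, "growth_fits.tsv"),
    profiles = file.path(out_dir, "profiles.tsv"),
    correlations = file.path(out_dir, "correlations.tsv"),
    summary = file.path(out_dir, "summary.json"),
    config = file.path(out_dir, "run_config.yaml")
  )
  result <- list(config = config, paths = paths)

  # resolved configuration beside the outputs
  cfg_serial <- unclass(config)
  cfg_serial$coupling <- as.data.frame(config$coupling)
  cfg_serial$run <- list(span = span, min_strains = min_strains,
                         alpha = alpha, w_min = w_min, r2_min = r2_min)
  yaml::write_yaml(cfg_serial, paths$config)

  if ("simulate" %in% stages) {
    sim_files <- c(paths$design, paths$probes, paths$phenotypes,
                   paths$curves, paths$groups, paths$truth)
    if (!force && all(file.exists(sim_files))) {
      pipeline_log(log_path, verbose, "simulate: reusing existing outputs")
      cohort <- list(
        design = readr::read_tsv(paths$design, show_col_types = FALSE),
        probes = read_probe_table(paths$probes),
        phenotypes = readr::read_tsv(paths$phenotypes,
                                     show_col_types = FALSE),
        curves = readr::read_tsv(paths$curves, show_col_types = FALSE),
        groups = read_gmt(paths$groups)[c("group", "gene_id")],
        config = config
      )
    } else {
      cohort <- simulate_cohort(config)
      readr::write_tsv(cohort$design, paths$design)
      readr::write_tsv(cohort$probes, paths$probes)
      readr::write_tsv(cohort$phenotypes, paths$phenotypes)
      readr::write_tsv(cohort$curves, paths$curves)
      write_gmt(cohort$groups, paths$groups)
      jsonlite::write_json(cohort$truth, paths$truth, auto_unbox = TRUE,
                           digits = NA)
      pipeline_log(log_path, verbose,
                   "simulate: %d probes rows, %d strains, %d curve points",
                   nrow(cohort$probes),
                   length(unique(cohort$phenotypes$strain_id)),
                   nrow(cohort$curves))
    }
    result$cohort <- cohort
  } else {
    cohort <- list(
      probes = read_probe_table(paths$probes),
      phenotypes = readr::read_tsv(paths$phenotypes, show_col_types = FALSE),
      curves = readr::read_tsv(paths$curves, show_col_types = FALSE),
      groups = read_gmt(paths$groups)[c("group", "gene_id")],
      config = config
    )
    result$cohort <- cohort
  }

  conditions <- config$conditions
  if ("normalize" %in% stages) {
    if (!force && file.exists(paths$log_ratios)) {
      pipeline_log(log_path, verbose, "normalize: reusing existing outputs")
      log_ratios <- read_expression(paths$log_ratios)
      by_cond <- lapply(conditions, function(cond) {
        read_expression(file.path(out_dir, paste0("expr_", cond, ".tsv")))
      })
      names(by_cond) <- conditions
    } else {
      expr <- normalize_experiment(cohort$probes, span = span)
      samples <- distinct(cohort$probes, .data$sample_id, .data$strain_id,
                          .data$condition)
      by_cond <- split_by_condition(expr, samples)
      for (cond in names(by_cond)) {
        write_expression(by_cond[[cond]],
                         file.path(out_dir, paste0("expr_", cond, ".tsv")))
      }
      if (all(c("xylulose", "glucose") %in% names(by_cond))) {
        log_ratios <- compute_log_ratios(by_cond$xylulose, by_cond$glucose)
      } else if (length(by_cond) >= 2) {
        log_ratios <- compute_log_ratios(by_cond[[2]], by_cond[[1]])
      } else {
        log_ratios <- by_cond[[1]]
      }
      write_expression(log_ratios, paths$log_ratios)
      pipeline_log(log_path, verbose,
                   "normalize: %d genes x %d samples normalized",
                   nrow(log_ratios), ncol(log_ratios) - 1L)
    }
    result$expression <- by_cond
    result$log_ratios <- log_ratios
  }

  if ("growth" %in% stages) {
    if (!force && file.exists(paths$growth)) {
      pipeline_log(log_path, verbose, "growth: reusing existing outputs")
      fits <- readr::read_tsv(paths$growth, show_col_types = FALSE)
    } else {
      fits <- fit_growth_rates(cohort$curves, w_min = w_min, r2_min = r2_min)
      readr::write_tsv(fits, paths$growth)
      pipeline_log(log_path, verbose, "growth: %d curves fitted", nrow(fits))
    }
    result$growth <- fits
    result$dispersion <- fits %>%
      group_by(.data$condition) %>%
      summarise(cv = cohort_dispersion(.data$growth_rate), .groups = "drop")
  }

  if ("correlate" %in% stages) {
    if (is.null(result$log_ratios)) {
      log_ratios <- read_expression(paths$log_ratios)
    } else {
      log_ratios <- result$log_ratios
    }
    if (is.null(result$growth)) {
      fits <- readr::read_tsv(paths$growth, show_col_types = FALSE)
    } else {
      fits <- result$growth
    }
    filtered <- filter_min_strains(log_ratios, k = min_strains)
    profiles <- group_mean_profile(filtered, cohort$groups)
    readr::write_tsv(profiles, paths$profiles)
    target_cond <- if ("xylulose" %in% conditions) "xylulose"
                   else conditions[length(conditions)]
    scan <- scan_groups(profiles, fits, phenotype = "growth_rate",
                        condition = target_cond, alpha = alpha)
    readr::write_tsv(scan, paths$correlations)
    pipeline_log(log_path, verbose,
                 "correlate: %d groups scanned against %s growth rate",
                 nrow(scan), target_cond)
    result$profiles <- profiles
    result$scan <- scan
  }

  if ("report" %in% stages) {
    summary <- list(seed = config$seed)
    if (!is.null(result$dispersion)) {
      summary$growth_dispersion <- setNames(
        as.list(result$dispersion$cv), result$dispersion$condition)
    }
    if (!is.null(result$scan)) {
      top <- head(as.data.frame(result$scan[
        c("group", "phenotype", "r", "n", "p_value", "significant")]), 5)
      summary$top_correlations <- top
      anti <- result$scan$group[result$scan$top_anticorrelated]
      summary$top_anticorrelated_group <-
        if (length(anti) > 0) anti else NA
    }
    jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE)
    pipeline_log(log_path, verbose, "report: summary written")
    result$summary <- summary
  }

  class(result) <- "growthexpr_run"
  invisible(result)
}

#' @export
print.growthexpr_run <- function(x, ...) {
  cat("<growthexpr_run>\n")
  cat("  outputs in:", dirname(x$paths$summary), "\n")
  if (!is.null(x$dispersion)) {
    for (i in seq_len(nrow(x$dispersion))) {
      cat(sprintf("  growth-rate CV [%s]: %.3f\n",
                  x$dispersion$condition[i], x$dispersion$cv[i]))
    }
  }
  if (!is.null(x$scan)) {
    top <- x$scan[1, ]
    cat(sprintf("  strongest group correlation: %s (r = %.2f, p = %.2g)\n",
                top$group, top$r, top$p_value))
  }
  invisible(x)
}
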