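#' Read an analysis configuration
#'
#' Loads the YAML configuration driving [run_full_analysis()]. Relative
#' input paths are resolved against the directory of the configuration
#' file. The packaged configuration reproducing the thiosemicarbazide
#' study is at \code{system.file("extdata", "analysis.yaml", package =
#' "biomchrom")}.
#'
#' @param path YAML file.
#' @return named list of class \code{"analysis_config"}.
#' @export
read_analysis_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  cfg$inputs <- lapply(cfg$inputs, function(p) {
    if (is.null(p) || is.na(p) || !nzchar(p)) return(NULL)
    if (!grepl("^(/|[A-Za-z]:)", p)) p <- file.path(base, p)
    p
  })
  structure(cfg, class = "analysis_config")
}

stage_note <- function(...) message("[biomchrom] ", sprintf(...))

# long (compound_id, system_id, logkw, minus_S, r2, n) -> one row per compound
widen_retention_fits <- function(fits) {
  ids <- unique(fits$compound_id)
  out <- data.frame(compound_id = ids, stringsAsFactors = FALSE)
  for (sys in unique(fits$system_id)) {
    d <- fits[fits$system_id == sys, ]
    i <- match(ids, d$compound_id)
    out[[paste0("minus_S_", sys)]] <- d$minus_S[i]
    out[[paste0("logkw_", sys)]] <- d$logkw[i]
    out[[paste0("r2_", sys)]] <- d$r2[i]
    out[[paste0("n_", sys)]] <- d$n[i]
  }
  out
}

#' Run the full biomimetic-chromatography analysis
#'
#' Executes the pipeline end to end from an [read_analysis_config()]
#' configuration: retention fitting (when raw isocratic data are
#' provided; otherwise precomputed fits are loaded and the stage is
#' skipped with a notice), protein-column calibration (from a
#' reference-drug file when given, else from the configured calibration
#' coefficients), binding prediction, the configured descriptor
#' regressions, the per-pair-exclusion correlation matrix, descriptor
#' summary statistics, and the correlation-matrix PCA. All tables are
#' written as full-precision CSV/JSON; rounding is applied only in the
#' human-readable \code{report.txt}. Every exclusion applied is logged.
#'
#' @param config an \code{"analysis_config"} (or path to one).
#' @param out_dir output directory.
#' @return invisibly, a list with the in-memory results:
#'   \code{retention_fits}, \code{calibration}, \code{binding},
#'   \code{descriptors}, \code{models}, \code{correlations},
#'   \code{summary}, \code{pca}, and \code{files} (paths written).
#' @export
run_full_analysis <- function(config, out_dir) {
  if (is.character(config)) config <- read_analysis_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()

  ## --- retention stage ------------------------------------------------
  fits_wide <- NULL
  if (!is.null(config$inputs[["retention"]])) {
    stage_note("fitting retention models from %s", config$inputs[["retention"]])
    raw <- read_retention(config$inputs[["retention"]])
    fits_long <- fit_retention(raw)
    files$retention_fits <- file.path(out_dir, "retention_fits.csv")
    utils::write.csv(fits_long, files$retention_fits, row.names = FALSE, quote = FALSE)
    fits_wide <- widen_retention_fits(fits_long)
  } else if (!is.null(config$inputs[["retention_fits"]])) {
    stage_note("no raw retention data; loading precomputed fits from %s",
               config$inputs[["retention_fits"]])
    fits_wide <- utils::read.csv(config$inputs[["retention_fits"]])
  } else {
    stage_note("no retention inputs; skipping retention stage")
  }

  ## --- protein-binding stage ------------------------------------------
  calib <- list()
  binding <- NULL
  if (!is.null(config$inputs[["protein_logk"]])) {
    prot <- utils::read.csv(config$inputs[["protein_logk"]])
    refs <- if (!is.null(config$inputs[["references"]]))
      utils::read.csv(config$inputs[["references"]]) else NULL
    for (col_id in unique(prot$column_id)) {
      if (!is.null(refs) && any(refs$column_id == col_id)) {
        stage_note("calibrating %s column against %d reference drugs",
                   col_id, sum(refs$column_id == col_id))
        calib[[col_id]] <- fit_calibration(refs, col_id)
      } else if (!is.null(config$calibration[[col_id]])) {
        stage_note("using configured calibration coefficients for %s", col_id)
        cc <- config$calibration[[col_id]]
        calib[[col_id]] <- calibration_curve(col_id, cc$intercept, cc$slope)
      } else {
        stop(sprintf("no calibration available for protein column %s", col_id),
             call. = FALSE)
      }
    }
    binding <- do.call(rbind, lapply(names(calib), function(col_id) {
      d <- prot[prot$column_id == col_id, ]
      predict_binding(calib[[col_id]], d$compound_id, d$logk)
    }))
    files$binding <- file.path(out_dir, "binding.csv")
    utils::write.csv(binding, files$binding, row.names = FALSE, quote = FALSE)
  } else {
    stage_note("no protein-column retention; skipping binding stage")
  }

  ## --- descriptor table -----------------------------------------------
  desc <- fits_wide
  if (!is.null(binding)) {
    for (col_id in unique(binding$column_id)) {
      d <- binding[binding$column_id == col_id, ]
      add <- data.frame(compound_id = d$compound_id, stringsAsFactors = FALSE)
      add[[paste0("logk_", col_id)]] <- d$logk
      add[[paste0("logK_", col_id)]] <- d$logK
      add[[paste0("ppb_", col_id)]] <- d$ppb_display
      desc <- if (is.null(desc)) add else merge(desc, add, by = "compound_id")
    }
  }
  if (!is.null(config$inputs[["insilico"]])) {
    insil <- utils::read.csv(config$inputs[["insilico"]])
    desc <- if (is.null(desc)) insil else merge(desc, insil, by = "compound_id")
  }
  if (is.null(desc)) stop("no inputs produced a descriptor table", call. = FALSE)
  # externally supplied extra descriptor columns (e.g. QSAR-predicted log K)
  if (!is.null(config$inputs[["extra_descriptors"]])) {
    extra <- utils::read.csv(config$inputs[["extra_descriptors"]])
    desc <- merge(desc, extra, by = "compound_id")
  }
  files$descriptors <- file.path(out_dir, "descriptors.csv")
  utils::write.csv(desc, files$descriptors, row.names = FALSE, quote = FALSE)

  ## --- regressions -----------------------------------------------------
  models <- list()
  for (rg in config$regressions) {
    ex <- as.character(rg$exclude %||% character(0))
    if (length(ex))
      stage_note("regression %s ~ %s excludes compound(s) %s",
                 rg$response, rg$predictor, paste(ex, collapse = ", "))
    if (!all(c(rg$response, rg$predictor) %in% names(desc))) {
      stage_note("skipping regression %s ~ %s: column(s) absent",
                 rg$response, rg$predictor)
      next
    }
    models[[rg$name %||% paste(rg$response, rg$predictor, sep = "_vs_")]] <-
      fit_linear_excluding(desc, rg$response, rg$predictor, ex)
  }
  if (length(models)) {
    files$models <- file.path(out_dir, "models.json")
    jsonlite::write_json(lapply(models, unclass), files$models,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  ## --- correlation matrix ----------------------------------------------
  correlations <- NULL
  if (!is.null(config$correlations)) {
    cc <- config$correlations
    ex_map <- lapply(cc$exclude, as.character)
    have <- function(v) v[v %in% names(desc)]
    rows <- have(unlist(cc$rows)); cols <- have(unlist(cc$cols))
    if (length(rows) && length(cols)) {
      correlations <- correlation_matrix(desc, rows, cols, ex_map)
      correlations$cell <- vapply(seq_len(nrow(correlations)), function(i)
        format_correlation_cell(correlations[i, ]), character(1))
      files$correlations <- file.path(out_dir, "correlations.csv")
      utils::write.csv(correlations, files$correlations, row.names = FALSE)
    }
  }

  ## --- summary statistics ----------------------------------------------
  summary_tab <- NULL
  sc <- intersect(unlist(config$summary_columns) %||% character(0), names(desc))
  if (length(sc)) {
    summary_tab <- summarize_descriptors(desc, sc)
    files$summary <- file.path(out_dir, "summary.csv")
    utils::write.csv(summary_tab, files$summary, row.names = FALSE, quote = FALSE)
  }

  ## --- PCA --------------------------------------------------------------
  pca <- NULL
  pc <- intersect(unlist(config$pca$columns) %||% character(0), names(desc))
  if (length(pc) >= 2L) {
    pca <- descriptor_pca(desc, pc,
                          n_components = config$pca$n_components %||% 2L)
    files$eigenvalues <- file.path(out_dir, "eigenvalues.csv")
    utils::write.csv(data.frame(component = seq_along(pca$eigenvalues),
                                eigenvalue = pca$eigenvalues),
                     files$eigenvalues, row.names = FALSE, quote = FALSE)
    files$loadings <- file.path(out_dir, "loadings.csv")
    utils::write.csv(cbind(variable = rownames(pca$loadings_raw),
                           as.data.frame(pca$loadings_raw),
                           as.data.frame(pca$loadings_rotated)),
                     files$loadings, row.names = FALSE, quote = FALSE)
    files$scores <- file.path(out_dir, "scores.csv")
    utils::write.csv(cbind(compound_id = rownames(pca$scores),
                           as.data.frame(pca$scores_rotated)),
                     files$scores, row.names = FALSE, quote = FALSE)
  }

  ## --- report -----------------------------------------------------------
  files$report <- file.path(out_dir, "report.txt")
  render_report(files$report, config, fits_wide, calib, binding, models,
                correlations, summary_tab, pca)

  invisible(list(retention_fits = fits_wide, calibration = calib,
                 binding = binding, descriptors = desc, models = models,
                 correlations = correlations, summary = summary_tab,
                 pca = pca, files = files))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# plain-text report; every number is a rounded rendering of a persisted cell
render_report <- function(path, config, fits_wide, calib, binding, models,
                          correlations, summary_tab, pca) {
  rnd <- config$rounding %||% list(coef = 4, ppb = 1, r = 2, summary = 3)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)

  w("Biomimetic chromatography analysis report")
  w("=========================================")
  if (!is.null(fits_wide)) {
    w("")
    w("Retention parameters (log kw, -S per system)")
    num <- vapply(fits_wide, is.numeric, logical(1))
    out <- fits_wide
    out[num] <- lapply(out[num], round, rnd$coef)
    utils::write.table(out, con, row.names = FALSE, quote = FALSE, sep = "\t")
  }
  for (col_id in names(calib)) {
    w("")
    cv <- calib[[col_id]]
    w("Calibration %s: log K = %s + %s log k", col_id,
      format(round(cv$intercept, rnd$coef), nsmall = rnd$coef),
      format(round(cv$slope, rnd$coef), nsmall = rnd$coef))
    if (!is.na(cv$R))
      w("  n = %d, R = %.4f, R2 = %.4f, s = %.4f", cv$n, cv$R, cv$R2, cv$s_resid)
  }
  if (!is.null(binding)) {
    w("")
    w("Protein binding (log K, %%PPB clamped at 100)")
    out <- binding
    out$logK <- round(out$logK, rnd$coef)
    out$logk <- round(out$logk, rnd$coef)
    out$ppb <- round(out$ppb, rnd$ppb)
    out$ppb_display <- round(out$ppb_display, rnd$ppb)
    utils::write.table(out, con, row.names = FALSE, quote = FALSE, sep = "\t")
  }
  for (nm in names(models)) {
    m <- models[[nm]]
    w("")
    w("%s = %.4f (+-%.4f) + %.4f (+-%.4f) %s", m$response,
      m$intercept, m$se_intercept, m$slope, m$se_slope, m$predictor)
    w("  n = %d, R = %.4f, R2 = %.4f, R2adj = %.4f, F(1,%d) = %.2f, p < %.5f, s = %.5f",
      m$n, m$R, m$R2, m$R2_adj, m$n - 2L, m$F, ceiling(m$p * 1e5) / 1e5, m$s_resid)
    if (length(m$excluded_ids))
      w("  outliers excluded: %s", paste(m$excluded_ids, collapse = ", "))
  }
  if (!is.null(correlations)) {
    w("")
    w("Correlation matrix (r, excluded compounds in parentheses)")
    for (rw in unique(correlations$row)) {
      d <- correlations[correlations$row == rw, ]
      w("%-10s %s", rw, paste(sprintf("%-16s", d$cell), collapse = " "))
    }
  }
  if (!is.null(summary_tab)) {
    w("")
    w("Descriptor summary statistics")
    out <- summary_tab
    num <- vapply(out, is.numeric, logical(1))
    out[num] <- lapply(out[num], round, rnd$summary)
    utils::write.table(out, con, row.names = FALSE, quote = FALSE, sep = "\t")
  }
  if (!is.null(pca)) {
    w("")
    w("PCA eigenvalues: %s",
      paste(sprintf("%.3f", pca$eigenvalues), collapse = ", "))
    w("Varimax-rotated loadings (first %d components):",
      pca$n_components_retained)
    for (i in seq_len(nrow(pca$loadings_rotated)))
      w("  %-12s %s", rownames(pca$loadings_rotated)[i],
        paste(sprintf("%8.4f", pca$loadings_rotated[i, ]), collapse = " "))
  }
  invisible(path)
}
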