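#' Specification of a synthetic biomimetic-retention study
#'
#' Defines the generating process for a seeded synthetic study with the
#' statistical structure the analysis pipeline assumes: one latent
#' lipophilicity score per compound; per-system true (log kw, S) obtained
#' by linear mapping of the latent score with a one-factor correlation
#' structure; isocratic log k measurements on a per-system phi grid with
#' homoscedastic Gaussian noise; and protein-column retention linearly
#' linked to the latent score, converted to true binding constants through
#' fixed calibration lines.
#'
#' Defaults are tuned to the moments of the packaged thiosemicarbazide
#' study (18 compounds; e.g. C-18 log kw mean 2.700, sd 0.467) and to its
#' published protein-column calibration coefficients, so synthetic output
#' is magnitude-realistic.
#'
#' @param n_compounds number of compounds.
#' @param systems named list; each element a list with \code{logkw_mean},
#'   \code{logkw_sd}, \code{S_mean} (negative), \code{S_sd},
#'   \code{lambda} (loading of the latent score, in [-1, 1]), and
#'   \code{phi_grid}.
#' @param noise_sd measurement noise sd on log k.
#' @param protein_curves named list per protein column: \code{intercept},
#'   \code{slope} (log K = intercept + slope * log k), \code{logk_mean},
#'   \code{logk_sd}, \code{lambda}, \code{noise_sd} (calibration scatter
#'   on log K used when generating reference drugs), \code{logk_range}
#'   (reference-drug retention range).
#' @param reference_set_size reference drugs per protein column.
#' @param seed integer seed; a fixed seed makes all generator output
#'   byte-identical across calls.
#' @return an object of class \code{"synthetic_spec"}.
#' @export
synthetic_spec <- function(
    n_compounds = 18L,
    systems = list(
      C18  = list(logkw_mean = 2.700, logkw_sd = 0.467,
                  S_mean = -4.750, S_sd = 0.430, lambda = 0.92,
                  phi_grid = seq(0.4, 0.9, by = 0.1)),
      IAM  = list(logkw_mean = 1.799, logkw_sd = 0.471,
                  S_mean = -6.069, S_sd = 0.892, lambda = 0.92,
                  phi_grid = seq(0.05, 0.40, by = 0.05)),
      CHOL = list(logkw_mean = 2.971, logkw_sd = 0.594,
                  S_mean = -4.873, S_sd = 0.642, lambda = 0.92,
                  phi_grid = seq(0.3, 0.8, by = 0.1))
    ),
    noise_sd = 0.02,
    protein_curves = list(
      HSA = list(intercept = 0.2513, slope = 1.0525,
                 logk_mean = 1.350, logk_sd = 0.374, lambda = 0.90,
                 noise_sd = 0.05, logk_range = c(-0.5, 1.5)),
      AGP = list(intercept = 0.1733, slope = 0.8902,
                 logk_mean = 0.509, logk_sd = 0.199, lambda = 0.90,
                 noise_sd = 0.05, logk_range = c(-0.5, 1.6))
    ),
    reference_set_size = 6L,
    seed = 1L) {
  spec <- list(n_compounds = as.integer(n_compounds), systems = systems,
               noise_sd = noise_sd, protein_curves = protein_curves,
               reference_set_size = as.integer(reference_set_size),
               seed = as.integer(seed))
  validate_synthetic_spec(spec)
  structure(spec, class = "synthetic_spec")
}

validate_synthetic_spec <- function(spec) {
  if (spec$n_compounds < 1L) stop("n_compounds must be >= 1", call. = FALSE)
  if (spec$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  for (nm in names(spec$systems)) {
    s <- spec$systems[[nm]]
    if (s$logkw_sd < 0 || s$S_sd < 0)
      stop(sprintf("system %s: sds must be >= 0", nm), call. = FALSE)
    if (abs(s$lambda) > 1)
      stop(sprintf("system %s: lambda must lie in [-1, 1]", nm), call. = FALSE)
    if (!length(s$phi_grid))
      stop(sprintf("system %s: empty phi grid", nm), call. = FALSE)
  }
  for (nm in names(spec$protein_curves)) {
    p <- spec$protein_curves[[nm]]
    if (p$logk_sd < 0 || p$noise_sd < 0)
      stop(sprintf("protein column %s: sds must be >= 0", nm), call. = FALSE)
    if (abs(p$lambda) > 1)
      stop(sprintf("protein column %s: lambda must lie in [-1, 1]", nm), call. = FALSE)
  }
  if (spec$reference_set_size < 3L)
    stop("reference_set_size must be >= 3", call. = FALSE)
  invisible(spec)
}

# latent one-factor draw: lambda * z + sqrt(1 - lambda^2) * independent noise
one_factor_draw <- function(z, lambda) {
  lambda * z + sqrt(1 - lambda^2) * stats::rnorm(length(z))
}

#' Generate true compound-level descriptors
#'
#' Draws one latent lipophilicity score per compound and maps it linearly
#' into true per-system (log kw, S) and true protein-column retention and
#' binding constants according to the spec.
#'
#' @param spec a [synthetic_spec()].
#' @return wide data.frame of true values: \code{compound_id},
#'   \code{latent}, per system \code{logkw_<sys>} and \code{S_<sys>}, and
#'   per protein column \code{logk_<col>} and \code{logK_<col>}.
#' @export
generate_compounds <- function(spec) {
  validate_synthetic_spec(spec)
  set.seed(spec$seed)
  n <- spec$n_compounds
  z <- stats::rnorm(n)
  out <- data.frame(compound_id = sprintf("S%02d", seq_len(n)), latent = z,
                    stringsAsFactors = FALSE)
  for (nm in names(spec$systems)) {
    s <- spec$systems[[nm]]
    out[[paste0("logkw_", nm)]] <- s$logkw_mean + s$logkw_sd * one_factor_draw(z, s$lambda)
    # steeper (more negative) S for more lipophilic compounds
    out[[paste0("S_", nm)]] <- s$S_mean - s$S_sd * one_factor_draw(z, s$lambda)
  }
  for (nm in names(spec$protein_curves)) {
    p <- spec$protein_curves[[nm]]
    logk <- p$logk_mean + p$logk_sd * one_factor_draw(z, p$lambda)
    out[[paste0("logk_", nm)]] <- logk
    out[[paste0("logK_", nm)]] <- p$intercept + p$slope * logk
  }
  out
}

#' Generate isocratic retention measurements from true parameters
#'
#' For every compound and system, evaluates the retention model on the
#' system's phi grid and adds Gaussian measurement noise:
#' log k = log kw + S * phi + N(0, noise_sd).
#'
#' @param spec a [synthetic_spec()].
#' @param truth output of [generate_compounds()].
#' @return long data.frame: \code{compound_id}, \code{system_id},
#'   \code{phi}, \code{logk}.
#' @export
generate_isocratic <- function(spec, truth) {
  validate_synthetic_spec(spec)
  set.seed(spec$seed + 1L)
  rows <- lapply(names(spec$systems), function(nm) {
    s <- spec$systems[[nm]]
    grid <- s$phi_grid
    do.call(rbind, lapply(seq_len(nrow(truth)), function(i) {
      mu <- truth[[paste0("logkw_", nm)]][i] + truth[[paste0("S_", nm)]][i] * grid
      data.frame(compound_id = truth$compound_id[i], system_id = nm,
                 phi = grid,
                 logk = mu + stats::rnorm(length(grid), 0, spec$noise_sd),
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}

#' Generate a reference-drug calibration set
#'
#' Draws reference-drug retention uniformly over the column's stated
#' range, maps it to log K through the column's calibration line with
#' Gaussian calibration scatter, and converts to literature-style percent
#' binding, clipped to (0, 100].
#'
#' @param spec a [synthetic_spec()].
#' @param column_id name of a protein column in \code{spec$protein_curves}.
#' @return data.frame: \code{name}, \code{column_id}, \code{logk},
#'   \code{ppb_lit}.
#' @export
generate_references <- function(spec, column_id) {
  validate_synthetic_spec(spec)
  p <- spec$protein_curves[[column_id]]
  if (is.null(p)) stop(sprintf("unknown protein column '%s'", column_id), call. = FALSE)
  set.seed(spec$seed + 2L + match(column_id, names(spec$protein_curves)))
  m <- spec$reference_set_size
  logk <- stats::runif(m, p$logk_range[1L], p$logk_range[2L])
  logK <- p$intercept + p$slope * logk + stats::rnorm(m, 0, p$noise_sd)
  ppb <- pmin(ppb_from_logK(logK), 100)
  data.frame(name = sprintf("ref%02d", seq_len(m)), column_id = column_id,
             logk = logk, ppb_lit = ppb, stringsAsFactors = FALSE)
}

#' Write a complete synthetic study to disk
#'
#' Generates the true descriptor table, the isocratic measurements, the
#' protein-column retention table, and one reference set per protein
#' column, and writes them as CSV (\code{truth.csv}, \code{retention.csv},
#' \code{protein_logk.csv}, \code{references.csv}). Output is
#' byte-identical for a fixed spec.
#'
#' @param spec a [synthetic_spec()].
#' @param out_dir output directory (created if needed).
#' @return named list of file paths, invisibly.
#' @export
simulate_study <- function(spec, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  truth <- generate_compounds(spec)
  iso <- generate_isocratic(spec, truth)
  prot <- do.call(rbind, lapply(names(spec$protein_curves), function(nm)
    data.frame(compound_id = truth$compound_id, column_id = nm,
               logk = truth[[paste0("logk_", nm)]], stringsAsFactors = FALSE)))
  refs <- do.call(rbind, lapply(names(spec$protein_curves),
                                function(nm) generate_references(spec, nm)))
  paths <- list(
    truth = file.path(out_dir, "truth.csv"),
    retention = file.path(out_dir, "retention.csv"),
    protein_logk = file.path(out_dir, "protein_logk.csv"),
    references = file.path(out_dir, "references.csv")
  )
  utils::write.csv(truth, paths$truth, row.names = FALSE, quote = FALSE)
  utils::write.csv(iso, paths$retention, row.names = FALSE, quote = FALSE)
  utils::write.csv(prot, paths$protein_logk, row.names = FALSE, quote = FALSE)
  utils::write.csv(refs, paths$references, row.names = FALSE, quote = FALSE)
  invisible(paths)
}
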