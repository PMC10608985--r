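#' Retention factor from retention and dead times
#'
#' Computes the decadic log retention factor
#' \eqn{\log_{10} k = \log_{10}((t_r - t_0)/t_0)} from the retention time of
#' the analyte and the dead time (elution time of an unretained solute).
#'
#' @param t_r retention time(s) of the analyte, minutes.
#' @param t_0 dead time(s), minutes; recycled against \code{t_r}.
#' @return numeric vector of log10 retention factors.
#' @examples
#' logk_from_times(11, 1)   # k = 10 -> 1
#' logk_from_times(2.6, 1.3) # k = 1 -> 0
#' @export
logk_from_times <- function(t_r, t_0) {
  stopifnot(is.numeric(t_r), is.numeric(t_0))
  n <- max(length(t_r), length(t_0))
  t_r <- rep_len(t_r, n)
  t_0 <- rep_len(t_0, n)
  bad <- !is.finite(t_r) | !is.finite(t_0) | t_0 <= 0 | t_r <= t_0
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf(
      "invalid retention measurement: t_r = %g, t_0 = %g (need t_r > t_0 > 0)",
      t_r[i], t_0[i]), call. = FALSE)
  }
  log10((t_r - t_0) / t_0)
}

#' Fit the Soczewinski-Wachtmeister retention model
#'
#' Ordinary least squares of log k on the organic-modifier volume fraction
#' phi: \eqn{\log k = \log k_w + S \phi}. The intercept \code{logkw} is the
#' retention factor extrapolated to a purely aqueous mobile phase (the
#' chromatographic lipophilicity descriptor) and the slope \code{slope_S}
#' is the solvent-strength sensitivity, conventionally reported as -S.
#'
#' Duplicated phi values are averaged before fitting (with a warning);
#' a series whose log k values are all identical yields slope 0 and an
#' undefined r-squared, flagged \code{degenerate}.
#'
#' @param phi organic-modifier volume fractions (0 <= phi < 1), or a
#'   data.frame with columns \code{phi} and \code{logk} (and optionally
#'   \code{compound_id}, \code{system_id}).
#' @param logk decadic log retention factors (ignored when \code{phi} is a
#'   data.frame).
#' @param compound_id,system_id optional identifiers carried into the result.
#' @return an object of class \code{"retention_fit"}: list with
#'   \code{logkw}, \code{slope_S}, \code{r2}, \code{n_points},
#'   \code{phi_range}, \code{degenerate}, \code{compound_id},
#'   \code{system_id}.
#' @seealso [predict_logk()], [fit_retention()]
#' @examples
#' f <- fit_isocratic(seq(0.4, 0.9, 0.1), 2.0774 - 4.3603 * seq(0.4, 0.9, 0.1))
#' f$logkw; f$slope_S
#' @export
fit_isocratic <- function(phi, logk = NULL, compound_id = NA_character_,
                          system_id = NA_character_) {
  if (is.data.frame(phi)) {
    d <- phi
    if (!all(c("phi", "logk") %in% names(d)))
      stop("data.frame input must have columns 'phi' and 'logk'", call. = FALSE)
    if ("compound_id" %in% names(d)) compound_id <- as.character(d$compound_id[1L])
    if ("system_id" %in% names(d)) system_id <- as.character(d$system_id[1L])
    logk <- d$logk
    phi <- d$phi
  }
  stopifnot(is.numeric(phi), is.numeric(logk), length(phi) == length(logk))
  keep <- is.finite(phi) & is.finite(logk)
  phi <- phi[keep]; logk <- logk[keep]
  if (any(phi < 0 | phi >= 1))
    stop("phi must be a volume fraction in [0, 1)", call. = FALSE)
  if (anyDuplicated(phi)) {
    warning("duplicated phi values averaged before fitting", call. = FALSE)
    logk <- as.numeric(tapply(logk, phi, mean))
    phi <- sort(unique(phi))
  }
  if (length(unique(phi)) < 2L)
    stop("underdetermined fit: need >= 2 distinct phi values", call. = FALSE)

  degenerate <- length(unique(logk)) == 1L
  if (degenerate) {
    logkw <- logk[1L]
    slope <- 0
    r2 <- NA_real_
  } else {
    fit <- stats::lm(logk ~ phi)
    logkw <- unname(stats::coef(fit)[1L])
    slope <- unname(stats::coef(fit)[2L])
    r2 <- stats::cor(logk, stats::fitted(fit))^2
  }
  structure(list(
    compound_id = compound_id,
    system_id   = system_id,
    logkw       = logkw,
    slope_S     = slope,
    r2          = r2,
    n_points    = length(phi),
    phi_range   = range(phi),
    degenerate  = degenerate
  ), class = "retention_fit")
}

#' @export
print.retention_fit <- function(x, ...) {
  cat(sprintf("Isocratic retention fit%s%s\n",
              if (!is.na(x$compound_id)) paste0(": compound ", x$compound_id) else "",
              if (!is.na(x$system_id)) paste0(" on ", x$system_id) else ""))
  cat(sprintf("  log kw = %.4f   -S = %.4f   r2 = %s   n = %d\n",
              x$logkw, -x$slope_S,
              if (is.na(x$r2)) "NA (degenerate)" else sprintf("%.4f", x$r2),
              x$n_points))
  invisible(x)
}

#' Predict log k at a modifier fraction
#'
#' Forward evaluation of a fitted retention model. Values of \code{phi}
#' outside the fitted range are extrapolations and are flagged in the
#' \code{"extrapolated"} attribute of the result (log kw itself, phi = 0,
#' is the canonical extrapolation).
#'
#' @param fit a \code{"retention_fit"}.
#' @param phi modifier volume fraction(s).
#' @return numeric vector of predicted log k with attribute
#'   \code{"extrapolated"} (logical vector).
#' @export
predict_logk <- function(fit, phi) {
  stopifnot(inherits(fit, "retention_fit"), is.numeric(phi))
  out <- fit$logkw + fit$slope_S * phi
  attr(out, "extrapolated") <- phi < fit$phi_range[1L] | phi > fit$phi_range[2L]
  out
}

#' Fit retention models for every compound x system series
#'
#' Applies [fit_isocratic()] to each (compound_id, system_id) group of a
#' long measurement table and returns one row per series in the layout of
#' a study retention table.
#'
#' @param data data.frame with columns \code{compound_id}, \code{system_id},
#'   \code{phi} and either \code{logk} or both \code{t_r} and \code{t_0}.
#' @param phi_as_percent when TRUE the phi column is a percentage and is
#'   divided by 100 (a \code{percent_modifier} column is always treated so).
#' @return data.frame with columns \code{compound_id}, \code{system_id},
#'   \code{logkw}, \code{minus_S}, \code{r2}, \code{n}.
#' @export
fit_retention <- function(data, phi_as_percent = FALSE) {
  stopifnot(is.data.frame(data))
  if ("percent_modifier" %in% names(data) && !"phi" %in% names(data)) {
    data$phi <- data$percent_modifier
    phi_as_percent <- TRUE
  }
  if (!all(c("compound_id", "system_id", "phi") %in% names(data)))
    stop("retention data needs columns compound_id, system_id, phi", call. = FALSE)
  if (!"logk" %in% names(data)) {
    if (!all(c("t_r", "t_0") %in% names(data)))
      stop("retention data needs either logk or t_r and t_0 columns", call. = FALSE)
    data$logk <- logk_from_times(data$t_r, data$t_0)
  }
  if (phi_as_percent) data$phi <- data$phi / 100

  key <- interaction(data$compound_id, data$system_id, drop = TRUE)
  fits <- lapply(split(data, key), function(d)
    fit_isocratic(d$phi, d$logk,
                  compound_id = as.character(d$compound_id[1L]),
                  system_id = as.character(d$system_id[1L])))
  out <- do.call(rbind, lapply(fits, function(f)
    data.frame(compound_id = f$compound_id, system_id = f$system_id,
               logkw = f$logkw, minus_S = -f$slope_S, r2 = f$r2,
               n = f$n_points, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out[order(out$system_id, suppressWarnings(as.numeric(out$compound_id)),
            out$compound_id), , drop = FALSE]
}

#' Read a long-format isocratic retention table
#'
#' @param path CSV with columns \code{compound_id}, \code{system_id},
#'   \code{phi} (or \code{percent_modifier}) and \code{logk} (or \code{t_r},
#'   \code{t_0}).
#' @param phi_as_percent divide the phi column by 100.
#' @return data.frame ready for [fit_retention()] (phi already a fraction).
#' @export
read_retention <- function(path, phi_as_percent = FALSE) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("percent_modifier" %in% names(d) && !"phi" %in% names(d)) {
    d$phi <- d$percent_modifier / 100
    d$percent_modifier <- NULL
  } else if (phi_as_percent) {
    d$phi <- d$phi / 100
  }
  d
}

#' Write fitted retention parameters
#'
#' Writes one row per compound x system with \code{logkw}, \code{minus_S}
#' and \code{r2} rounded to 4 decimals, the usual reporting precision of
#' retention tables.
#'
#' @param fits output of [fit_retention()].
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_retention_fits <- function(fits, path) {
  out <- fits
  for (col in c("logkw", "minus_S", "r2")) out[[col]] <- round(out[[col]], 4)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
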