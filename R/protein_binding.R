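#' Percent plasma-protein binding from log K
#'
#' The Valko linearization of percent binding,
#' \deqn{\%PPB = 101 \cdot 10^{\log K} / (1 + 10^{\log K}),}
#' maps the binding constant onto (0, 101); the 101 factor keeps log K
#' finite at 100\% binding. Raw values may therefore exceed 100 and are
#' clamped only at report time (see [predict_binding()]).
#'
#' @param logK decadic log binding equilibrium constant(s).
#' @return percent binding, in (0, 101).
#' @seealso [logK_from_ppb()] for the exact inverse.
#' @examples
#' ppb_from_logK(0)       # 50.5
#' ppb_from_logK(1.0986)  # ~93.5
#' @export
ppb_from_logK <- function(logK) {
  stopifnot(is.numeric(logK), all(is.finite(logK)))
  101 * 10^logK / (1 + 10^logK)
}

#' log K from percent plasma-protein binding
#'
#' Exact inverse of [ppb_from_logK()]:
#' \eqn{\log K = \log_{10}(PPB / (101 - PPB))}. Used to linearize literature
#' \%PPB values of calibration drugs before regressing on column retention.
#'
#' @param ppb percent binding, strictly inside (0, 101); literature values
#'   of 100\% remain finite (log K = 2).
#' @return decadic log binding constant(s).
#' @examples
#' logK_from_ppb(50.5)  # 0
#' logK_from_ppb(100)   # 2
#' @export
logK_from_ppb <- function(ppb) {
  stopifnot(is.numeric(ppb))
  if (any(!is.finite(ppb) | ppb <= 0 | ppb >= 101))
    stop("ppb must lie strictly between 0 and 101", call. = FALSE)
  log10(ppb / (101 - ppb))
}

#' Calibrate an immobilized-protein column
#'
#' Fits the calibration line log K = a + b log k by ordinary least squares,
#' where log K is the linearized literature \%PPB of the reference drugs
#' ([logK_from_ppb()]) and log k their measured retention on the protein
#' column. The full regression statistics block is retained so calibration
#' quality can be reported alongside predictions.
#'
#' @param refs data.frame of reference drugs with columns \code{logk} and
#'   \code{ppb_lit} (literature percent binding, 0 < ppb <= 100); an
#'   optional \code{column_id} column is checked against \code{column_id}.
#' @param column_id column identifier, e.g. \code{"HSA"} or \code{"AGP"}.
#' @return an object of class \code{"calibration_curve"}: list with
#'   \code{column_id}, \code{intercept}, \code{slope}, \code{se_intercept},
#'   \code{se_slope}, \code{R}, \code{R2}, \code{R2_adj}, \code{s_resid},
#'   \code{n}.
#' @export
fit_calibration <- function(refs, column_id) {
  stopifnot(is.data.frame(refs), all(c("logk", "ppb_lit") %in% names(refs)))
  if ("column_id" %in% names(refs)) refs <- refs[refs$column_id == column_id, ]
  refs <- refs[is.finite(refs$logk) & is.finite(refs$ppb_lit), ]
  if (nrow(refs) < 3L)
    stop(sprintf("insufficient calibration: %d reference drugs for %s (need >= 3)",
                 nrow(refs), column_id), call. = FALSE)
  if (length(unique(refs$logk)) < 2L)
    stop("degenerate design: all reference log k identical", call. = FALSE)

  y <- logK_from_ppb(refs$ppb_lit)
  x <- refs$logk
  m <- stats::lm(y ~ x)
  sm <- summary(m)
  n <- length(x)
  structure(list(
    column_id    = column_id,
    intercept    = unname(stats::coef(m)[1L]),
    slope        = unname(stats::coef(m)[2L]),
    se_intercept = sm$coefficients[1L, 2L],
    se_slope     = sm$coefficients[2L, 2L],
    R            = sqrt(sm$r.squared),
    R2           = sm$r.squared,
    R2_adj       = sm$adj.r.squared,
    s_resid      = sm$sigma,
    n            = n
  ), class = "calibration_curve")
}

#' Construct a calibration curve from known coefficients
#'
#' Builds a \code{"calibration_curve"} directly from published or previously
#' fitted coefficients, for use when the reference-drug measurements
#' themselves are not at hand.
#'
#' @param column_id column identifier.
#' @param intercept,slope coefficients of log K = intercept + slope * log k.
#' @return a \code{"calibration_curve"} with fit statistics set to NA.
#' @export
calibration_curve <- function(column_id, intercept, slope) {
  stopifnot(is.numeric(intercept), is.numeric(slope),
            length(intercept) == 1L, length(slope) == 1L)
  structure(list(
    column_id = column_id, intercept = intercept, slope = slope,
    se_intercept = NA_real_, se_slope = NA_real_, R = NA_real_,
    R2 = NA_real_, R2_adj = NA_real_, s_resid = NA_real_, n = NA_integer_
  ), class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Protein-column calibration (%s):\n", x$column_id))
  cat(sprintf("  log K = %.4f (+-%s) + %.4f (+-%s) log k\n",
              x$intercept, fmt_or_na(x$se_intercept, 4),
              x$slope, fmt_or_na(x$se_slope, 4)))
  if (!is.na(x$R))
    cat(sprintf("  n = %d, R = %.4f, R2 = %.4f, R2adj = %.4f, s = %.4f\n",
                x$n, x$R, x$R2, x$R2_adj, x$s_resid))
  invisible(x)
}

fmt_or_na <- function(x, digits) if (is.na(x)) "NA" else sprintf(paste0("%.", digits, "f"), x)

#' Predict binding constants and percent binding
#'
#' Applies a protein-column calibration to measured retention factors:
#' log K = a + b log k, then percent binding via [ppb_from_logK()]. Raw
#' percent binding can exceed 100 because of the 101-scaled linearization;
#' \code{ppb_display} clamps it at 100 for reporting while \code{ppb}
#' keeps the raw value.
#'
#' @param curve a \code{"calibration_curve"}.
#' @param compound_id identifier(s).
#' @param logk measured log retention factor(s) on the protein column.
#' @return data.frame with columns \code{compound_id}, \code{column_id},
#'   \code{logk}, \code{logK}, \code{ppb}, \code{ppb_display}.
#' @examples
#' hsa <- calibration_curve("HSA", 0.2513, 1.0525)
#' predict_binding(hsa, "cmpd1", 0.8050)
#' @export
predict_binding <- function(curve, compound_id, logk) {
  stopifnot(inherits(curve, "calibration_curve"), is.numeric(logk))
  logK <- curve$intercept + curve$slope * logk
  ppb <- ppb_from_logK(logK)
  data.frame(
    compound_id = as.character(compound_id),
    column_id   = curve$column_id,
    logk        = logk,
    logK        = logK,
    ppb         = ppb,
    ppb_display = pmin(ppb, 100),
    stringsAsFactors = FALSE
  )
}
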