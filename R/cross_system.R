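#' Outlier-aware simple linear regression between descriptor columns
#'
#' Ordinary least squares of one descriptor column on another, after
#' removing a stated set of compounds, with the full statistics block used
#' in QSAR reporting: coefficients with standard errors, R, R-squared,
#' adjusted R-squared, the F statistic with its p-value, the residual
#' standard error, and the number of compounds retained. Rows with a
#' missing value in either column are dropped pairwise.
#'
#' @param table wide descriptor data.frame with a \code{compound_id} column.
#' @param response,predictor column names.
#' @param exclude compound ids omitted from the fit (the explicit,
#'   study-level outlier list; see [detect_outliers()] for a data-driven
#'   candidate list, which is never applied silently).
#' @return an object of class \code{"linear_model_fit"}: list with
#'   \code{response}, \code{predictor}, \code{intercept}, \code{slope},
#'   \code{se_intercept}, \code{se_slope}, \code{R}, \code{R2},
#'   \code{R2_adj}, \code{F}, \code{p}, \code{s_resid}, \code{n},
#'   \code{excluded_ids}.
#' @export
fit_linear_excluding <- function(table, response, predictor, exclude = NULL) {
  d <- descriptor_pair(table, response, predictor, exclude)
  if (nrow(d) < 3L)
    stop(sprintf("insufficient data: %d rows remain for %s ~ %s",
                 nrow(d), response, predictor), call. = FALSE)
  m <- stats::lm(y ~ x, data = d)
  sm <- summary(m)
  n <- nrow(d)
  Fv <- unname(sm$fstatistic[1L])
  structure(list(
    response     = response,
    predictor    = predictor,
    intercept    = unname(stats::coef(m)[1L]),
    slope        = unname(stats::coef(m)[2L]),
    se_intercept = sm$coefficients[1L, 2L],
    se_slope     = sm$coefficients[2L, 2L],
    R            = sqrt(sm$r.squared) * sign(unname(stats::coef(m)[2L])),
    R2           = sm$r.squared,
    R2_adj       = sm$adj.r.squared,
    F            = Fv,
    p            = stats::pf(Fv, 1L, n - 2L, lower.tail = FALSE),
    s_resid      = sm$sigma,
    n            = n,
    excluded_ids = sort_ids(exclude)
  ), class = "linear_model_fit")
}

# sort compound ids numerically when they all look numeric
sort_ids <- function(ids) {
  if (!length(ids)) return(character(0))
  ids <- as.character(ids)
  if (all(grepl("^-?[0-9]+$", ids))) ids[order(as.numeric(ids))] else sort(ids)
}

# resolve a response/predictor pair with exclusions and pairwise NA drop
descriptor_pair <- function(table, response, predictor, exclude = NULL) {
  stopifnot(is.data.frame(table), "compound_id" %in% names(table))
  for (col in c(response, predictor))
    if (!col %in% names(table))
      stop(sprintf("unknown descriptor column '%s'", col), call. = FALSE)
  ids <- as.character(table$compound_id)
  if (length(exclude)) {
    missing_ids <- setdiff(as.character(exclude), ids)
    if (length(missing_ids))
      stop(sprintf("exclusion references unknown compound id(s): %s",
                   paste(missing_ids, collapse = ", ")), call. = FALSE)
  }
  keep <- !(ids %in% as.character(exclude)) &
    is.finite(table[[response]]) & is.finite(table[[predictor]])
  data.frame(id = ids[keep], y = table[[response]][keep],
             x = table[[predictor]][keep], stringsAsFactors = FALSE)
}

#' @export
print.linear_model_fit <- function(x, ...) {
  cat(sprintf("%s = %.4f (+-%.4f) + %.4f (+-%.4f) %s\n",
              x$response, x$intercept, x$se_intercept,
              x$slope, x$se_slope, x$predictor))
  cat(sprintf("  n = %d, R = %.4f, R2 = %.4f, R2adj = %.4f, F(1,%d) = %.2f, p = %.3g, s = %.5f\n",
              x$n, x$R, x$R2, x$R2_adj, x$n - 2L, x$F, x$p, x$s_resid))
  if (length(x$excluded_ids))
    cat("  excluded compounds:", paste(x$excluded_ids, collapse = ", "), "\n")
  invisible(x)
}

#' Pairwise correlation matrix with per-pair outlier exclusions
#'
#' Pearson correlations between two sets of descriptor columns, where each
#' (row, col) pair may carry its own set of excluded compounds — the usual
#' presentation of chromatographic-descriptor versus calculated-logP
#' correlation tables, in which outliers are dropped per cell and noted in
#' parentheses.
#'
#' @param table wide descriptor data.frame with \code{compound_id}.
#' @param rows,cols descriptor column names; \code{cols} defaults to
#'   \code{rows} (square matrix).
#' @param exclude named list mapping \code{"row|col"} keys to compound-id
#'   vectors (either orientation of the key is honoured).
#' @return data.frame of cells: \code{row}, \code{col}, \code{r}, \code{n},
#'   \code{excluded} (comma-separated ids). Pairs are symmetric: swapping
#'   row and col with the same exclusions gives the same r.
#' @export
correlation_matrix <- function(table, rows, cols = rows, exclude = list()) {
  cells <- expand.grid(row = rows, col = cols, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(cells)), function(i) {
    rw <- cells$row[i]; cl <- cells$col[i]
    ex <- exclude[[paste(rw, cl, sep = "|")]]
    if (is.null(ex)) ex <- exclude[[paste(cl, rw, sep = "|")]]
    d <- descriptor_pair(table, rw, cl, ex)
    data.frame(row = rw, col = cl,
               r = if (rw == cl) 1 else stats::cor(d$y, d$x),
               n = nrow(d),
               excluded = paste(sort_ids(ex), collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Render a correlation cell in report notation
#'
#' Formats r rounded to two decimals with excluded compounds in
#' parentheses, e.g. \code{"0.84 (4, 16)"}.
#'
#' @param cell one row of a [correlation_matrix()] result.
#' @return character scalar.
#' @export
format_correlation_cell <- function(cell) {
  s <- sprintf("%.2f", cell$r)
  if (nzchar(cell$excluded))
    s <- paste0(s, " (", gsub(",", ", ", cell$excluded), ")")
  s
}

#' Summary statistics of a descriptor column
#'
#' Median (midpoint of the two central order statistics for even n),
#' arithmetic mean, sample standard deviation (n - 1 denominator), and
#' range (max - min), over the non-missing values.
#'
#' @param table wide descriptor data.frame.
#' @param column descriptor column name.
#' @return named list: \code{median}, \code{mean}, \code{sd}, \code{range}.
#' @export
summary_stats <- function(table, column) {
  if (!column %in% names(table))
    stop(sprintf("unknown descriptor column '%s'", column), call. = FALSE)
  v <- table[[column]]
  v <- v[is.finite(v)]
  if (length(v) < 2L)
    stop(sprintf("insufficient data in column '%s'", column), call. = FALSE)
  list(median = stats::median(v), mean = mean(v), sd = stats::sd(v),
       range = max(v) - min(v))
}

#' Summarize several descriptor columns
#'
#' @param table wide descriptor data.frame.
#' @param columns descriptor column names.
#' @return data.frame with one row per statistic (median, mean, sd, range)
#'   and one column per descriptor.
#' @export
summarize_descriptors <- function(table, columns) {
  stats_list <- lapply(columns, function(cl) unlist(summary_stats(table, cl)))
  out <- as.data.frame(do.call(cbind, stats_list))
  names(out) <- columns
  cbind(statistic = c("median", "mean", "sd", "range"), out,
        stringsAsFactors = FALSE)
}

#' Data-driven outlier candidates for a descriptor regression
#'
#' Ranks compounds by either the externally studentized residual of the
#' simple regression (flagging |t| above \code{threshold}) or by the
#' jackknife gain in R-squared when the compound is removed. The result is
#' a candidate list only; study-level exclusions are always applied
#' explicitly (see \code{exclude} in [fit_linear_excluding()]).
#'
#' @param table wide descriptor data.frame with \code{compound_id}.
#' @param response,predictor column names.
#' @param method \code{"studentized"} (default) or \code{"jackknife_r2"}.
#' @param threshold studentized-residual cutoff (default 2.5); for
#'   \code{"jackknife_r2"}, the minimum gain in R-squared (default 0.05
#'   when \code{threshold} is left at 2.5).
#' @return character vector of candidate compound ids, ordered from the
#'   strongest candidate down, with the ranking statistic as the
#'   \code{"statistic"} attribute; empty when nothing exceeds the cutoff.
#' @export
detect_outliers <- function(table, response, predictor,
                            method = c("studentized", "jackknife_r2"),
                            threshold = 2.5) {
  method <- match.arg(method)
  d <- descriptor_pair(table, response, predictor)
  if (nrow(d) < 4L)
    stop("need >= 4 rows for outlier detection", call. = FALSE)
  if (method == "studentized") {
    m <- stats::lm(y ~ x, data = d)
    e <- stats::residuals(m)
    if (sqrt(sum(e^2)) < 1e-10 * max(abs(d$y), 1)) {
      # exact fit: every residual is numerical noise, nothing to flag
      out <- character(0)
      attr(out, "statistic") <- stats::setNames(numeric(0), character(0))
      return(out)
    }
    t_i <- stats::rstudent(m)
    # deleting a gross outlier can leave an exact fit (0 deleted-sigma)
    t_i[!is.finite(t_i)] <- sign(e[!is.finite(t_i)]) * Inf
    ord <- order(abs(t_i), decreasing = TRUE)
    hit <- abs(t_i[ord]) > threshold
    out <- d$id[ord][hit]
    attr(out, "statistic") <- stats::setNames(t_i[ord][hit], out)
  } else {
    if (missing(threshold) || threshold == 2.5) threshold <- 0.05
    r2_full <- summary(stats::lm(y ~ x, data = d))$r.squared
    gain <- vapply(seq_len(nrow(d)), function(i)
      summary(stats::lm(y ~ x, data = d[-i, ]))$r.squared - r2_full,
      numeric(1))
    ord <- order(gain, decreasing = TRUE)
    hit <- gain[ord] > threshold
    out <- d$id[ord][hit]
    attr(out, "statistic") <- stats::setNames(gain[ord][hit], out)
  }
  out
}
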