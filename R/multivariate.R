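#' Column-wise z-scores of descriptor columns
#'
#' Centers and scales each selected column to mean 0 and sample standard
#' deviation 1 (n - 1 denominator), the preparation step for
#' correlation-matrix PCA of descriptors on different scales.
#'
#' @param table wide descriptor data.frame.
#' @param columns column names to standardize.
#' @return numeric matrix (compounds x variables) with compound ids as
#'   rownames where available.
#' @export
standardize <- function(table, columns) {
  for (col in columns) {
    if (!col %in% names(table))
      stop(sprintf("unknown descriptor column '%s'", col), call. = FALSE)
    if (!is.finite(stats::sd(table[[col]])) || stats::sd(table[[col]]) == 0)
      stop(sprintf("degenerate column '%s': zero variance", col), call. = FALSE)
  }
  m <- as.matrix(table[, columns, drop = FALSE])
  if (any(!is.finite(m))) stop("non-finite entries in descriptor columns", call. = FALSE)
  z <- scale(m)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  if ("compound_id" %in% names(table)) rownames(z) <- as.character(table$compound_id)
  z
}

# flip each column so its largest-magnitude entry is positive;
# returns the sign vector so scores can be flipped consistently
column_sign_convention <- function(L) {
  vapply(seq_len(ncol(L)), function(j) {
    v <- L[, j]
    s <- sign(v[which.max(abs(v))])
    if (s == 0) 1 else s
  }, numeric(1))
}

#' Varimax rotation of a loading matrix
#'
#' Orthogonal rotation of the first \code{n_components} loading columns
#' maximizing the varimax criterion (variance of squared loadings per
#' component), with optional Kaiser row normalization. Rotating a single
#' component is the identity. Communalities (row sums of squared loadings)
#' are preserved exactly; columns are sign-normalized so the
#' largest-magnitude loading in each is positive.
#'
#' @param loadings variables x components numeric matrix.
#' @param n_components number of components to rotate (default: all).
#' @param kaiser_normalize apply Kaiser row normalization (default TRUE).
#' @return list with \code{loadings} (rotated, sign-normalized),
#'   \code{rotmat} (the orthogonal rotation applied, including the sign
#'   flips).
#' @export
varimax_rotate <- function(loadings, n_components = ncol(loadings),
                           kaiser_normalize = TRUE) {
  loadings <- as.matrix(loadings)
  if (n_components > ncol(loadings))
    stop(sprintf("n_components = %d exceeds available components (%d)",
                 n_components, ncol(loadings)), call. = FALSE)
  L <- loadings[, seq_len(n_components), drop = FALSE]
  if (n_components < 2L) {
    return(list(loadings = L, rotmat = diag(n_components)))
  }
  v <- stats::varimax(L, normalize = kaiser_normalize, eps = 1e-14)
  Lr <- L %*% v$rotmat
  sgn <- column_sign_convention(Lr)
  Lr <- sweep(Lr, 2L, sgn, `*`)
  dimnames(Lr) <- list(rownames(loadings),
                       paste0("RC", seq_len(n_components)))
  list(loadings = Lr, rotmat = v$rotmat %*% diag(sgn, n_components))
}

#' Correlation-matrix PCA of a descriptor table
#'
#' Principal component analysis of the correlation matrix of the selected
#' descriptor columns: the eigenvalues sum to the number of variables,
#' loadings are eigenvectors scaled by the square root of their
#' eigenvalue (so squared loadings are variance fractions), and compound
#' scores come from the standardized data projected on the eigenvectors.
#' The first \code{n_components} loading columns are additionally Varimax
#' rotated ([varimax_rotate()]); rotation leaves communalities and total
#' explained variance unchanged. All loading and score columns follow the
#' sign convention that the largest-magnitude loading is positive.
#'
#' @param table wide descriptor data.frame with \code{compound_id}.
#' @param columns descriptor columns entering the PCA.
#' @param n_components components retained for rotation (default 2).
#' @param kaiser_normalize Kaiser row normalization in the rotation.
#' @return an object of class \code{"descriptor_pca"}: list with
#'   \code{variable_names}, \code{eigenvalues}, \code{loadings_raw}
#'   (variables x all components), \code{loadings_rotated} (variables x
#'   \code{n_components}), \code{scores} (compounds x all components, PC
#'   scores), \code{scores_rotated}, \code{n_components_retained}.
#' @examples
#' tab <- thiosemicarbazide_descriptors()
#' p <- descriptor_pca(tab, c("logkw_C18", "logkw_IAM", "logkw_Chol",
#'                            "logk_HSA", "logk_AGP"))
#' p$eigenvalues[1:2]
#' @export
descriptor_pca <- function(table, columns, n_components = 2L,
                           kaiser_normalize = TRUE) {
  Z <- standardize(table, columns)
  if (nrow(Z) < 3L) stop("need >= 3 compounds for PCA", call. = FALSE)
  ee <- eigen(stats::cor(Z), symmetric = TRUE)
  ev <- ee$values
  V <- ee$vectors
  # loadings on the factor-analysis scale
  L <- V %*% diag(sqrt(pmax(ev, 0)), length(ev))
  sgn <- column_sign_convention(L)
  L <- sweep(L, 2L, sgn, `*`)
  V <- sweep(V, 2L, sgn, `*`)
  dimnames(L) <- list(columns, paste0("PC", seq_along(ev)))
  scores <- Z %*% V
  colnames(scores) <- colnames(L)

  rot <- varimax_rotate(L, n_components, kaiser_normalize = kaiser_normalize)
  # rotated scores: rotate the component scores with the same orthogonal map
  scores_rot <- scores[, seq_len(n_components), drop = FALSE] %*% rot$rotmat
  colnames(scores_rot) <- colnames(rot$loadings)

  structure(list(
    variable_names = columns,
    eigenvalues = ev,
    loadings_raw = L,
    loadings_rotated = rot$loadings,
    scores = scores,
    scores_rotated = scores_rot,
    n_components_retained = as.integer(n_components)
  ), class = "descriptor_pca")
}

#' @export
print.descriptor_pca <- function(x, ...) {
  cat("Correlation-matrix PCA of", length(x$variable_names), "descriptors\n")
  cat("  eigenvalues:", paste(sprintf("%.3f", x$eigenvalues), collapse = ", "), "\n")
  cat(sprintf("  first %d components retained (%.1f%% of variance), Varimax rotated\n",
              x$n_components_retained,
              100 * sum(x$eigenvalues[seq_len(x$n_components_retained)]) /
                length(x$variable_names)))
  invisible(x)
}
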