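new_standardized <- function(z, strain_ids, indicators, reference_scores = NULL) {
  dimnames(z) <- list(strain_ids, indicators)
  structure(list(strain_ids = strain_ids, indicators = indicators, z = z,
                 reference_scores = reference_scores),
            class = "standardized_indicators")
}

#' @export
print.standardized_indicators <- function(x, ...) {
  cat("Standardized indicators:", length(x$strain_ids), "strains x",
      length(x$indicators), "indicators\n")
  if (!is.null(x$reference_scores)) cat("(carries reference scores)\n")
  invisible(x)
}

#' Column-wise z-score standardization
#'
#' Centres each indicator to mean 0 and scales to sample standard deviation 1
#' (denominator n - 1). Direction correction ([apply_directionality()])
#' should be applied first so that all columns point "higher is better".
#'
#' @param table a [strain_phenotype_table()] or numeric matrix.
#' @return an object of class `standardized_indicators` with elements
#'   `strain_ids`, `indicators`, `z`, `reference_scores` (NULL here).
#' @export
standardize <- function(table) {
  m <- if (inherits(table, "strain_phenotype_table")) table$values else as.matrix(table)
  if (nrow(m) < 2L) stop("need at least 2 strains to standardize")
  if (anyNA(m)) stop("missing values not allowed in scoring input")
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("constant column cannot be standardized: ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  }
  z <- scale(m, center = TRUE, scale = sds)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  ids <- rownames(m)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(m)))
  cols <- colnames(m)
  if (is.null(cols)) cols <- paste0("V", seq_len(ncol(m)))
  new_standardized(unclass(z), ids, cols)
}

#' Correlation-matrix PCA of standardized indicators
#'
#' Eigendecomposition of the Pearson correlation matrix of the indicator
#' columns. Loadings are scaled so that `loadings[j, i]` is the correlation
#' of variable j with component i (hence squared loadings — Cos2 — column-sum
#' to the eigenvalue and row-sum to 1 over all components). Each component's
#' sign is fixed so that its loading sum is non-negative, which makes
#' intermediate loadings reproducible across eigen-solvers; the Cos2 weights
#' used downstream are squares and thus sign-invariant.
#'
#' @param std a `standardized_indicators` object from [standardize()].
#' @return a list of class `pca_result`: `eigenvalues` (descending),
#'   `loadings` (variables x components), `cos2` (squared loadings),
#'   `explained_fraction`, `indicators`.
#' @export
pca_correlation <- function(std) {
  stopifnot(inherits(std, "standardized_indicators"))
  z <- std$z
  if (anyNA(z)) stop("missing values in standardized matrix")
  R <- stats::cor(z)
  if (anyNA(R)) stop("correlation matrix contains NA (singular input?)")
  e <- eigen(R, symmetric = TRUE)
  lambda <- pmax(e$values, 0)
  V <- e$vectors
  flip <- ifelse(colSums(V) < 0, -1, 1)
  V <- sweep(V, 2L, flip, `*`)
  loadings <- sweep(V, 2L, sqrt(lambda), `*`)
  dimnames(loadings) <- list(std$indicators, paste0("PC", seq_along(lambda)))
  structure(list(eigenvalues = lambda,
                 loadings = loadings,
                 cos2 = loadings^2,
                 explained_fraction = lambda / sum(lambda),
                 indicators = std$indicators),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("Correlation-matrix PCA,", length(x$eigenvalues), "components\n")
  cat("Eigenvalues:", paste(round(x$eigenvalues, 3), collapse = ", "), "\n")
  cat("Explained (%):",
      paste(round(100 * x$explained_fraction, 2), collapse = ", "), "\n")
  invisible(x)
}

#' Kaiser criterion component retention
#'
#' Retains components with eigenvalue strictly greater than 1 (a component of
#' a correlation-matrix PCA carrying less variance than a single original
#' variable is discarded).
#'
#' @param pca a `pca_result`.
#' @return integer vector of retained component indices in descending-
#'   eigenvalue order; may be empty.
#' @export
kaiser_select <- function(pca) {
  stopifnot(inherits(pca, "pca_result"))
  which(pca$eigenvalues > 1)
}

#' Eigenvalue-weighted Cos2 composite coefficients
#'
#' The composite score weights each indicator by the sum, over retained
#' components, of eigenvalue times Cos2 (squared loading): coefficient_j =
#' sum_i lambda_i * cos2[j, i]. All coefficients are non-negative, and each
#' retained component contributes weights summing to lambda_i^2 / lambda_i =
#' lambda_i across indicators.
#'
#' @param pca a `pca_result`.
#' @param retained integer vector of component indices, e.g. from
#'   [kaiser_select()].
#' @return named numeric coefficient vector, one entry per indicator.
#' @export
composite_coefficients <- function(pca, retained = kaiser_select(pca)) {
  stopifnot(inherits(pca, "pca_result"))
  if (!length(retained)) {
    stop("no components retained; consider falling back to the top component")
  }
  if (any(retained < 1 | retained > length(pca$eigenvalues))) {
    stop("retained indices out of range")
  }
  co <- pca$cos2[, retained, drop = FALSE]
  coef <- drop(co %*% pca$eigenvalues[retained])
  names(coef) <- pca$indicators
  coef
}

#' Score and rank strains by the composite coefficients
#'
#' Computes y_s = sum_j coef_j * z[s, j] and ranks strains in descending
#' order of y (rank 1 = strongest fermentation ability; ties broken by
#' ascending strain ID). If the standardized table carries reference scores,
#' the positive scale factor c minimizing sum((c*y - reference)^2) is fitted
#' and reported as a diagnostic.
#'
#' @param std a `standardized_indicators` object.
#' @param coefficients named numeric vector aligned to `std$indicators`.
#' @return a data.frame of class `score_table` with columns `strain`, `y`,
#'   `rank`, ordered by rank; attributes `coefficients` and (when reference
#'   scores exist) `scale_fit`.
#' @export
score_strains <- function(std, coefficients) {
  stopifnot(inherits(std, "standardized_indicators"))
  if (is.null(names(coefficients)) ||
      !setequal(names(coefficients), std$indicators)) {
    stop("coefficient names must match the table's indicators")
  }
  y <- drop(std$z[, std$indicators, drop = FALSE] %*%
              coefficients[std$indicators])
  ord <- order(-y, std$strain_ids)
  rank <- integer(length(y))
  rank[ord] <- seq_along(y)
  out <- data.frame(strain = std$strain_ids, y = y, rank = rank,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$rank), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "coefficients") <- coefficients[std$indicators]
  if (!is.null(std$reference_scores)) {
    ref <- std$reference_scores[std$strain_ids]
    yv <- y
    c_fit <- sum(yv * ref) / sum(yv^2)
    attr(out, "scale_fit") <- list(
      c = c_fit,
      max_rel_error = max(abs(c_fit * yv - ref) / abs(ref)))
  }
  class(out) <- c("score_table", class(out))
  out
}

#' Select the strongest and weakest strain groups
#'
#' @param scores a `score_table` from [score_strains()].
#' @param k group size; 2k must not exceed the number of strains.
#' @return a list of class `group_assignment` with `strong` (top-k strain
#'   IDs, best first), `weak` (bottom-k, worst first) and `k`.
#' @export
select_extremes <- function(scores, k = 3L) {
  stopifnot(inherits(scores, "score_table"))
  k <- as.integer(k)
  n <- nrow(scores)
  if (k < 1L) stop("k must be >= 1")
  if (2L * k > n) stop("2k = ", 2L * k, " exceeds number of strains (", n, ")")
  ord <- scores[order(scores$rank), , drop = FALSE]
  structure(list(strong = ord$strain[seq_len(k)],
                 weak = rev(ord$strain)[seq_len(k)],
                 k = k),
            class = "group_assignment")
}

#' @export
print.group_assignment <- function(x, ...) {
  cat("Strong (top-", x$k, "): ", paste(x$strong, collapse = ", "), "\n",
      "Weak (bottom-", x$k, "): ", paste(x$weak, collapse = ", "), "\n",
      sep = "")
  invisible(x)
}
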