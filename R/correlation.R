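#' Pairwise Pearson correlations among phenotype indicators
#'
#' Computes the full Pearson correlation matrix across indicator columns
#' together with two-sided p-values from the t-transform
#' t = r * sqrt((n - 2) / (1 - r^2)) on n - 2 degrees of freedom.
#'
#' @param table a [strain_phenotype_table()] or a numeric matrix with
#'   indicators in columns.
#' @return a list of class `correlation_result` with elements `indicators`,
#'   `r` (correlation matrix), `p` (two-sided p-values, NA on the diagonal)
#'   and `n` (number of strains).
#' @export
correlation_matrix <- function(table) {
  m <- if (inherits(table, "strain_phenotype_table")) table$values else as.matrix(table)
  if (nrow(m) < 3L) stop("need at least 3 strains for correlation p-values")
  if (anyNA(m)) stop("missing values not allowed in correlation input")
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("constant column (correlation undefined): ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  }
  n <- nrow(m)
  r <- stats::cor(m)
  # clamp |r|=1 before the t-transform; p underflows to 0 there anyway
  r_c <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  tval <- r_c * sqrt((n - 2) / (1 - r_c^2))
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  p[abs(r) >= 1 & row(r) != col(r)] <- 0
  diag(p) <- NA_real_
  structure(list(indicators = colnames(m), r = r, p = p, n = n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat("Pearson correlations over", x$n, "strains\n")
  print(round(x$r, 3))
  invisible(x)
}

#' Prune redundant indicators by correlation
#'
#' Greedy sweep in priority order: an indicator is kept iff its absolute
#' Pearson correlation with every already-kept indicator is below
#' `threshold`. Indicators correlated at or above the threshold are treated
#' as interchangeable and represented by the higher-priority member. The
#' default threshold 0.6 corresponds to the interchangeability band commonly
#' used for texture/acidity indicator panels; absolute values are used so
#' strong negative correlations also count as shared information.
#'
#' @param corr a `correlation_result` from [correlation_matrix()].
#' @param priority character vector ordering all indicators, earlier =
#'   preferred representative. Defaults to the column order of `corr`.
#' @param threshold minimum |r| (exclusive below, inclusive at) declaring a
#'   pair redundant; in (0, Inf). Values > 1 keep everything.
#' @return character vector of retained indicator names, in priority order.
#' @export
prune_redundant <- function(corr, priority = corr$indicators, threshold = 0.6) {
  stopifnot(inherits(corr, "correlation_result"))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop("threshold must be a single positive number")
  }
  missing <- setdiff(corr$indicators, priority)
  if (length(missing)) {
    stop("priority list missing indicators: ", paste(missing, collapse = ", "))
  }
  priority <- priority[priority %in% corr$indicators]
  kept <- character(0)
  for (ind in priority) {
    if (!length(kept) || all(abs(corr$r[ind, kept]) < threshold)) {
      kept <- c(kept, ind)
    }
  }
  kept
}

#' Subset a phenotype table to a set of indicators
#'
#' @param table a [strain_phenotype_table()].
#' @param indicators character vector of indicator names to keep, in order.
#' @return a `strain_phenotype_table` restricted to those columns.
#' @export
select_indicators <- function(table, indicators) {
  stopifnot(inherits(table, "strain_phenotype_table"))
  missing <- setdiff(indicators, table$indicators)
  if (length(missing)) stop("unknown indicators: ", paste(missing, collapse = ", "))
  strain_phenotype_table(table$values[, indicators, drop = FALSE],
                         table$strain_ids, indicators,
                         direction = table$direction[indicators])
}
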