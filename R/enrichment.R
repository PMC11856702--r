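#' Annotation table for overrepresentation analysis
#'
#' @param terms named list: term ID -> character vector of gene IDs.
#' @param background character vector: the gene universe (size N). Every
#'   annotated gene must belong to it.
#' @return a list of class `annotation_table`.
#' @export
annotation_table <- function(terms, background) {
  background <- unique(as.character(background))
  if (!length(terms) || is.null(names(terms))) stop("terms must be a named list")
  terms <- lapply(terms, function(g) unique(as.character(g)))
  empty <- lengths(terms) == 0L
  if (any(empty)) stop("empty term sets: ", paste(names(terms)[empty], collapse = ", "))
  stray <- setdiff(unique(unlist(terms)), background)
  if (length(stray)) {
    stop("annotated genes absent from background: ",
         paste(utils::head(stray, 5L), collapse = ", "))
  }
  structure(list(terms = terms, background = background),
            class = "annotation_table")
}

#' Read a two-column gene-to-term annotation TSV
#'
#' Expects columns `gene` and `term` (header optional if exactly two
#' columns). The background defaults to all genes appearing in the file
#' unless supplied.
#'
#' @param path TSV path.
#' @param background optional gene universe; default = all genes in the file.
#' @return an [annotation_table()].
#' @export
read_annotation_tsv <- function(path, background = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("gene", "term") %in% colnames(df))) {
    if (ncol(df) == 2L) colnames(df) <- c("gene", "term")
    else stop("annotation TSV needs 'gene' and 'term' columns")
  }
  if (is.null(background)) background <- unique(df$gene)
  annotation_table(split(df$gene, df$term), background)
}

#' Fold enrichment
#'
#' (k/n) / (K/N): the fraction of query genes annotated to a term relative
#' to the background fraction.
#'
#' @param k query genes annotated to the term.
#' @param n query size.
#' @param K background genes annotated to the term.
#' @param N background size.
#' @return numeric fold enrichment (0 when k = 0).
#' @export
fold_enrichment <- function(k, n, K, N) {
  check_counts(k, n, K, N)
  (k / n) / (K / N)
}

check_counts <- function(k, n, K, N) {
  vals <- c(k = k, n = n, K = K, N = N)
  if (any(vals < 0) || any(vals != floor(vals))) {
    stop("counts must be non-negative integers")
  }
  if (n <= 0 || K <= 0 || N <= 0) stop("n, K and N must be positive")
  if (k > min(n, K)) stop("k cannot exceed min(n, K)")
  if (n > N || K > N) stop("n and K cannot exceed N")
  invisible(TRUE)
}

#' Upper-tail hypergeometric p-value
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability that a random
#' query of size n drawn without replacement from a background of N genes,
#' K of which carry the annotation, contains at least k annotated genes.
#' Terms are accumulated in log space (log-binomials via [lchoose()] and a
#' log-sum-exp reduction) so that very small tail probabilities do not
#' underflow intermediate arithmetic.
#'
#' @inheritParams fold_enrichment
#' @return p-value in (0, 1].
#' @export
hypergeometric_pvalue <- function(k, n, K, N) {
  check_counts(k, n, K, N)
  if (k == 0) return(1)
  i <- seq.int(k, min(n, K))
  log_terms <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  m <- max(log_terms)
  p <- exp(m) * sum(exp(log_terms - m))
  min(p, 1)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up procedure: with sorted p-values p_(1) <= ... <= p_(m), the
#' adjusted value q_(i) = min over j >= i of m * p_(j) / j, capped at 1 and
#' mapped back to the input order.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return numeric vector of q-values in input order.
#' @export
bh_fdr <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  ord <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(m * p[ord] / seq_len(m)))))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

#' Hypergeometric overrepresentation test
#'
#' For each annotation term with at least one query hit, computes the
#' overlap k, fold enrichment, upper-tail hypergeometric p-value and BH FDR
#' across all reported terms. Query genes outside the background are
#' reported and dropped. Only overrepresentation (upper tail) is tested.
#'
#' @param query character vector of gene IDs.
#' @param annot an [annotation_table()].
#' @param include_zero_k also report (and include in the FDR family) terms
#'   with no query overlap; default FALSE.
#' @return a data.frame of class `enrichment_table`, sorted by ascending
#'   p-value, with columns `term`, `K`, `n`, `k`, `fold_enrichment`,
#'   `p_value`, `fdr`; attribute `dropped` lists out-of-background query
#'   genes.
#' @export
overrepresentation_test <- function(query, annot, include_zero_k = FALSE) {
  stopifnot(inherits(annot, "annotation_table"))
  query <- unique(as.character(query))
  dropped <- setdiff(query, annot$background)
  if (length(dropped)) {
    warning(length(dropped), " query gene(s) outside background dropped")
    query <- intersect(query, annot$background)
  }
  if (!length(query)) stop("empty query after intersecting with background")
  N <- length(annot$background)
  n <- length(query)
  rows <- lapply(names(annot$terms), function(tm) {
    genes <- annot$terms[[tm]]
    K <- length(genes)
    k <- length(intersect(genes, query))
    if (k == 0L && !include_zero_k) return(NULL)
    data.frame(term = tm, K = K, n = n, k = k,
               fold_enrichment = fold_enrichment(k, n, K, N),
               p_value = hypergeometric_pvalue(k, n, K, N),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    out <- data.frame(term = character(0), K = integer(0), n = integer(0),
                      k = integer(0), fold_enrichment = numeric(0),
                      p_value = numeric(0), fdr = numeric(0))
  } else {
    out <- do.call(rbind, rows)
    out$fdr <- bh_fdr(out$p_value)
    out <- out[order(out$p_value, out$term), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "dropped") <- dropped
  attr(out, "N") <- N
  class(out) <- c("enrichment_table", class(out))
  out
}
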