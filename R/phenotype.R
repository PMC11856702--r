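#' Strain phenotype table
#'
#' Container for raw strain-by-indicator measurements, e.g. total titratable
#' acidity (TTA, mL of 0.1-N NaOH), specific volume (mL/g), and
#' texture-profile indicators (hardness in N; springiness, cohesiveness,
#' gumminess, chewiness dimensionless). Each indicator carries a direction
#' flag: +1 if larger values indicate stronger fermentation ability,
#' -1 if smaller values do (e.g. hardness).
#'
#' @param values numeric matrix, strains in rows, indicators in columns.
#' @param strain_ids character vector of unique strain labels (defaults to
#'   rownames of `values`).
#' @param indicators character vector of indicator names (defaults to
#'   colnames of `values`).
#' @param direction named numeric vector of +1/-1 per indicator; see
#'   [default_directions()]. Missing entries default to +1.
#' @return an object of class `strain_phenotype_table`: a list with elements
#'   `strain_ids`, `indicators`, `values`, `direction`.
#' @export
strain_phenotype_table <- function(values, strain_ids = rownames(values),
                                   indicators = colnames(values),
                                   direction = NULL) {
  values <- as.matrix(values)
  if (is.null(strain_ids) || is.null(indicators)) {
    stop("strain_ids and indicators must be supplied or present as dimnames")
  }
  strain_ids <- as.character(strain_ids)
  indicators <- as.character(indicators)
  if (nrow(values) != length(strain_ids) || ncol(values) != length(indicators)) {
    stop("matrix dimensions inconsistent with strain/indicator labels")
  }
  if (anyDuplicated(strain_ids)) {
    stop("duplicate strain labels: ",
         paste(unique(strain_ids[duplicated(strain_ids)]), collapse = ", "))
  }
  if (anyDuplicated(indicators)) stop("duplicate indicator names")
  storage.mode(values) <- "double"
  all_missing <- colSums(!is.na(values)) == 0L
  if (any(all_missing)) {
    stop("indicator column entirely missing: ",
         paste(indicators[all_missing], collapse = ", "))
  }
  direction <- normalize_direction(direction, indicators)
  dimnames(values) <- list(strain_ids, indicators)
  structure(list(strain_ids = strain_ids, indicators = indicators,
                 values = values, direction = direction),
            class = "strain_phenotype_table")
}

normalize_direction <- function(direction, indicators) {
  out <- rep(1, length(indicators))
  names(out) <- indicators
  if (!is.null(direction)) {
    if (is.null(names(direction))) stop("direction map must be named")
    if (!all(direction %in% c(-1, 1))) stop("direction multipliers must be +1 or -1")
    unknown <- setdiff(names(direction), indicators)
    if (length(unknown)) {
      stop("direction entries for unknown indicators: ",
           paste(unknown, collapse = ", "))
    }
    out[names(direction)] <- direction
  }
  out
}

#' @export
print.strain_phenotype_table <- function(x, ...) {
  cat("Strain phenotype table:", length(x$strain_ids), "strains x",
      length(x$indicators), "indicators\n")
  cat("Indicators:", paste(x$indicators, collapse = ", "), "\n")
  flipped <- names(x$direction)[x$direction < 0]
  if (length(flipped)) cat("Lower-is-better:", paste(flipped, collapse = ", "), "\n")
  invisible(x)
}

#' Default indicator directionality
#'
#' Hardness is the only indicator flipped by default (smaller peak force means
#' a softer, better-leavened product, so its sign is reversed to keep all
#' indicators pointing "higher is better"). Other lower-is-better candidates
#' (gumminess, chewiness, pH when acidity is desired) are left to the user.
#'
#' @param indicators character vector of indicator names.
#' @return named numeric vector of +1/-1.
#' @export
default_directions <- function(indicators) {
  d <- rep(1, length(indicators))
  names(d) <- indicators
  d[tolower(indicators) == "hardness"] <- -1
  d
}

#' Read a strain phenotype table from delimited text
#'
#' Expects a header row of indicator names and a first column of strain
#' labels. The delimiter is auto-detected (comma or tab) unless given.
#'
#' @param path file path.
#' @param direction named +1/-1 vector per indicator (default: flip hardness
#'   only, via [default_directions()]).
#' @param delimiter single character, or NULL to auto-detect.
#' @return a [strain_phenotype_table()].
#' @export
read_phenotype_table <- function(path, direction = NULL, delimiter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delimiter)) {
    first <- readLines(path, n = 1L)
    delimiter <- if (grepl("\t", first)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          colClasses = "character", check.names = FALSE)
  if (ncol(df) < 2L) stop("need a strain column plus at least one indicator")
  strain_ids <- df[[1L]]
  if (anyDuplicated(strain_ids)) {
    stop("duplicate strain labels in ", path, ": ",
         paste(unique(strain_ids[duplicated(strain_ids)]), collapse = ", "))
  }
  indicators <- colnames(df)[-1L]
  vals <- matrix(NA_real_, nrow(df), length(indicators),
                 dimnames = list(strain_ids, indicators))
  for (j in seq_along(indicators)) {
    raw <- trimws(df[[j + 1L]])
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) & nzchar(raw) & raw != "NA")
    if (length(bad)) {
      stop(sprintf("non-numeric cell at row '%s', column '%s': '%s'",
                   strain_ids[bad[1L]], indicators[j], raw[bad[1L]]))
    }
    vals[, j] <- num
  }
  if (is.null(direction)) direction <- default_directions(indicators)
  strain_phenotype_table(vals, strain_ids, indicators, direction)
}

#' Write a phenotype table to delimited text
#'
#' Inverse of [read_phenotype_table()] for finite values.
#'
#' @param table a [strain_phenotype_table()].
#' @param path output file path.
#' @param delimiter field separator (default comma).
#' @export
write_phenotype_table <- function(table, path, delimiter = ",") {
  stopifnot(inherits(table, "strain_phenotype_table"))
  df <- data.frame(strain = table$strain_ids, table$values,
                   check.names = FALSE, row.names = NULL)
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Flip lower-is-better indicators
#'
#' Multiplies every column whose direction is -1 by -1 so that all indicators
#' point in the same "higher is better" direction, then resets all direction
#' flags to +1. Applying the result a second time with its own (reset) flags
#' is the identity.
#'
#' @param table a [strain_phenotype_table()].
#' @param direction named +1/-1 vector covering every indicator; defaults to
#'   the table's own direction field.
#' @return a direction-corrected `strain_phenotype_table`.
#' @export
apply_directionality <- function(table, direction = table$direction) {
  stopifnot(inherits(table, "strain_phenotype_table"))
  missing <- setdiff(table$indicators, names(direction))
  if (length(missing)) {
    stop("direction map missing indicators: ", paste(missing, collapse = ", "))
  }
  if (!all(direction[table$indicators] %in% c(-1, 1))) {
    stop("direction multipliers must be +1 or -1")
  }
  vals <- sweep(table$values, 2L, direction[table$indicators], `*`)
  strain_phenotype_table(vals, table$strain_ids, table$indicators,
                         direction = NULL)  # flags reset to +1
}

#' Load the packaged 36-strain standardized indicator fixture
#'
#' Returns the packaged table of 36 Saccharomyces cerevisiae strains with
#' four standardized (z-scored, direction-corrected) evaluation indicators
#' — TTA, specific volume, hardness, springiness — together with the
#' published composite fermentation-ability score per strain. The scores are
#' carried as reference metadata and are never recomputed by this loader.
#'
#' @return a `standardized_indicators` object (see [standardize()]) with a
#'   `reference_scores` element.
#' @export
load_strain_score_fixture <- function() {
  path <- system.file("extdata", "strain_scores_36.csv", package = "fermentrank",
                      mustWork = TRUE)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  z <- as.matrix(vapply(df[2:5], as.numeric, numeric(nrow(df))))
  rownames(z) <- df$strain
  new_standardized(z, strain_ids = df$strain,
                   indicators = colnames(df)[2:5],
                   reference_scores = stats::setNames(as.numeric(df$Score), df$strain))
}
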