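#' Run the full strain-evaluation pipeline
#'
#' Orchestrates: indicator correlation + redundancy pruning, directionality
#' correction, standardization, correlation-matrix PCA with Kaiser
#' retention, Cos2 composite scoring, extreme-group selection; then (when a
#' VCF or genotype TSV is configured) quality filtering, the strict
#' group-discriminating contrast between the strongest and weakest strains,
#' the non-synonymous restriction and gene aggregation; then (when an
#' annotation table is configured) the hypergeometric overrepresentation
#' test. Stages without configured inputs are skipped and marked as such.
#' Reruns with the same config and inputs produce identical report bodies.
#'
#' @param config a named list or the path to a YAML file. Recognised fields:
#'   `phenotypes` (CSV/TSV path, or the string "fixture" for the packaged
#'   36-strain table), `direction` (named list of +1/-1), `prune_threshold`
#'   (default 0.6), `priority` (character vector), `k` (default 3),
#'   `vcf` / `genotype_tsv`, `group_a` / `group_b` (override the scored
#'   extremes), `min_depth` (10), `min_qual` (20), `min_mq` (30),
#'   `require_full_groups` (TRUE), `consequence_key`/`gene_key`/`mq_key`,
#'   `annotation` (TSV path), `out_dir` (optional: write TSVs + report).
#' @return a list of class `run_report` carrying retained indicators,
#'   eigenvalues, coefficients, the score table, group assignment, contrast
#'   counts and the enrichment table; see the methods vignette.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  cfg <- function(name, default = NULL) {
    if (!is.null(config[[name]])) config[[name]] else default
  }
  report <- list(package_version = as.character(utils::packageVersion("fermentrank")),
                 config = config, stages = character(0))
  out_dir <- cfg("out_dir")
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(df, name) {
    if (!is.null(out_dir)) {
      utils::write.table(df, file.path(out_dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }

  ## -- phenotype stage ------------------------------------------------
  phen <- cfg("phenotypes")
  if (is.null(phen)) stop("stage phenotypes: no input configured")
  if (identical(phen, "fixture")) {
    std <- load_strain_score_fixture()
    report$retained_indicators <- std$indicators
    report$input_hashes <- list(
      phenotypes = unname(tools::md5sum(system.file(
        "extdata", "strain_scores_36.csv", package = "fermentrank"))))
  } else {
    direction <- cfg("direction")
    if (!is.null(direction)) direction <- unlist(direction)
    tab <- tryCatch(read_phenotype_table(phen, direction = direction),
                    error = function(e) stop("stage phenotypes: ",
                                             conditionMessage(e)))
    corr <- correlation_matrix(tab)
    emit(data.frame(indicator = corr$indicators, round(corr$r, 6)),
         "correlation.tsv")
    kept <- prune_redundant(corr,
                            priority = cfg("priority", corr$indicators),
                            threshold = cfg("prune_threshold", 0.6))
    report$retained_indicators <- kept
    std <- standardize(apply_directionality(select_indicators(tab, kept)))
    report$input_hashes <- list(phenotypes = unname(tools::md5sum(phen)))
  }

  ## -- scoring stage --------------------------------------------------
  pca <- pca_correlation(std)
  retained <- kaiser_select(pca)
  if (!length(retained)) retained <- 1L  # fall back to the top component
  coefs <- composite_coefficients(pca, retained)
  scores <- score_strains(std, coefs)
  k <- cfg("k", 3L)
  groups <- select_extremes(scores, k)
  report$eigenvalues <- pca$eigenvalues
  report$explained_fraction <- pca$explained_fraction
  report$retained_components <- retained
  report$coefficients <- as.list(coefs)
  report$scores <- scores
  report$groups <- list(strong = groups$strong, weak = groups$weak, k = k)
  report$stages <- c(report$stages, "phenotypes", "scoring")
  emit(cbind(scores,
             group = ifelse(scores$strain %in% groups$strong, "strong",
                     ifelse(scores$strain %in% groups$weak, "weak", ""))),
       "scores.tsv")

  ## -- contrast stage -------------------------------------------------
  vcf <- cfg("vcf"); gtsv <- cfg("genotype_tsv")
  if (!is.null(vcf) || !is.null(gtsv)) {
    gm <- if (!is.null(vcf)) {
      read_vcf_genotypes(vcf,
                         consequence_key = cfg("consequence_key", "CONSEQ"),
                         gene_key = cfg("gene_key", "GENE"),
                         mq_key = cfg("mq_key", "MQ"))
    } else {
      read_genotype_tsv(gtsv)
    }
    report$input_hashes$genotypes <- unname(tools::md5sum(c(vcf, gtsv)[1]))
    gm <- quality_filter(gm,
                         min_depth = cfg("min_depth", 10),
                         min_qual = cfg("min_qual", 20),
                         min_mq = cfg("min_mq", 30))
    ga <- cfg("group_a", groups$strong)
    gb <- cfg("group_b", groups$weak)
    contrast <- discriminating_sites(
      gm, ga, gb, require_full_groups = cfg("require_full_groups", TRUE))
    nonsyn <- filter_nonsynonymous(contrast)
    gene_summary <- aggregate_genes(nonsyn)
    report$contrast <- list(
      n_sites_all = contrast$n_sites, n_genes_all = contrast$n_genes,
      n_sites_nonsyn = nonsyn$n_sites, n_genes_nonsyn = nonsyn$n_genes,
      genes = nonsyn$genes)
    report$gene_summary <- gene_summary
    report$contrast_sites <- nonsyn$sites
    report$stages <- c(report$stages, "contrast")
    emit(nonsyn$sites, "contrast_sites.tsv")
    emit(gene_summary, "gene_summary.tsv")
  } else {
    report$contrast <- "skipped"
  }

  ## -- enrichment stage -----------------------------------------------
  annot_path <- cfg("annotation")
  if (!is.null(annot_path) && !identical(report$contrast, "skipped") &&
      length(report$contrast$genes)) {
    annot <- read_annotation_tsv(annot_path)
    enr <- overrepresentation_test(report$contrast$genes, annot,
                                   include_zero_k = cfg("include_zero_k", FALSE))
    report$enrichment <- enr
    report$stages <- c(report$stages, "enrichment")
    report$input_hashes$annotation <- unname(tools::md5sum(annot_path))
    emit(enr, "enrichment.tsv")
  } else {
    report$enrichment <- "skipped"
  }

  class(report) <- "run_report"
  if (!is.null(out_dir)) {
    jsonlite::write_json(report_as_json(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(format_report_md(report), file.path(out_dir, "report.md"))
  }
  report
}

report_as_json <- function(report) {
  r <- unclass(report)
  r$scores <- as.data.frame(r$scores)
  if (is.data.frame(r$enrichment)) r$enrichment <- as.data.frame(r$enrichment)
  r
}

format_report_md <- function(report) {
  lines <- c("# Strain evaluation run report", "",
             paste0("Stages run: ", paste(report$stages, collapse = ", ")), "",
             paste0("Retained indicators: ",
                    paste(report$retained_indicators, collapse = ", ")),
             paste0("Eigenvalues: ",
                    paste(round(report$eigenvalues, 4), collapse = ", ")),
             paste0("Retained components: ",
                    paste(report$retained_components, collapse = ", ")),
             paste0("Coefficients: ",
                    paste(sprintf("%s=%.4f", names(report$coefficients),
                                  unlist(report$coefficients)),
                          collapse = ", ")),
             paste0("Strong group: ", paste(report$groups$strong, collapse = ", ")),
             paste0("Weak group: ", paste(report$groups$weak, collapse = ", ")))
  if (!identical(report$contrast, "skipped")) {
    lines <- c(lines,
               sprintf("Discriminating sites (non-synonymous): %d over %d genes",
                       report$contrast$n_sites_nonsyn,
                       report$contrast$n_genes_nonsyn))
  } else {
    lines <- c(lines, "Contrast: skipped")
  }
  if (is.data.frame(report$enrichment)) {
    lines <- c(lines, sprintf("Enrichment: %d terms tested, top term %s",
                              nrow(report$enrichment),
                              report$enrichment$term[1]))
  } else {
    lines <- c(lines, "Enrichment: skipped")
  }
  lines
}

#' @export
print.run_report <- function(x, ...) {
  cat(format_report_md(x), sep = "\n")
  invisible(x)
}
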