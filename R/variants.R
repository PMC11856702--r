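#' Genotype states
#'
#' Per-site, per-strain genotype calls against the reference genome:
#' \describe{
#'   \item{REF}{both alleles consistent with the reference}
#'   \item{HOM}{both alleles inconsistent (homozygous alternate)}
#'   \item{HET}{heterozygous: one allele consistent, one not}
#'   \item{NO}{call unreliable (missing genotype or low sequencing quality)}
#'   \item{OTH}{arises only from multi-allelic decomposition: the genotype is
#'     reference-inconsistent but involves a different alternate allele than
#'     the decomposed row's; never matches a shared state in the contrast}
#' }
#' @export
GENOTYPE_STATES <- c("REF", "HOM", "HET", "NO", "OTH")

new_genotype_matrix <- function(sites, states, depth, samples) {
  states <- as.matrix(states)
  if (anyDuplicated(samples)) stop("duplicate sample IDs")
  stopifnot(nrow(states) == nrow(sites), ncol(states) == length(samples))
  bad <- !(states %in% GENOTYPE_STATES)
  if (any(bad)) stop("invalid genotype state: ", states[which(bad)[1L]])
  dimnames(states) <- list(NULL, samples)
  if (!is.null(depth)) {
    depth <- as.matrix(depth)
    stopifnot(all(dim(depth) == dim(states)))
    dimnames(depth) <- dimnames(states)
  }
  rownames(sites) <- NULL
  structure(list(sites = sites, states = states, depth = depth,
                 samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("Genotype matrix:", nrow(x$sites), "sites x", length(x$samples),
      "samples\n")
  tab <- table(factor(x$states, levels = GENOTYPE_STATES))
  cat("States:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

gt_to_state <- function(gt, alt_index) {
  # gt like "0/0", "0|1", "1/2", "./."; alt_index = which alt this row holds
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return("NO")
  alleles <- strsplit(gt, "[/|]")[[1L]]
  if (length(alleles) != 2L || any(!grepl("^[0-9.]+$", alleles))) return("NO")
  if (any(alleles == ".")) return("NO")
  a <- as.integer(alleles)
  hit <- sum(a == alt_index)
  nonref_other <- sum(a != 0L & a != alt_index)
  if (hit == 2L) "HOM"
  else if (hit == 1L && nonref_other == 0L) "HET"
  else if (nonref_other > 0L) "OTH"
  else "REF"
}

#' Read a multi-sample VCF into a genotype matrix
#'
#' Parses a VCF 4.x (plain or gzipped) with per-sample GT (and optionally DP)
#' fields. Multi-allelic records are decomposed into one row per alternate
#' allele; a sample's genotype is classified relative to that row's
#' alternate (genotypes carrying a different alternate become state `OTH`,
#' or the whole site is dropped when `drop_multiallelic_other = TRUE`).
#' Mapping quality and the consequence/gene annotation are taken from INFO
#' keys whose names are configurable.
#'
#' @param path VCF file path.
#' @param samples sample IDs to load (default: all in the header).
#' @param consequence_key,gene_key,mq_key INFO keys holding the functional
#'   consequence (values like "nonsynonymous"/"synonymous"), gene ID and
#'   mapping quality.
#' @param drop_multiallelic_other drop decomposed rows where any sample
#'   carries a different alternate allele (strict mode); default FALSE.
#' @return a `genotype_matrix`: `sites` data.frame (chrom, pos, ref, alt,
#'   qual, mq, consequence, gene), `states` and `depth` matrices, `samples`.
#' @export
read_vcf_genotypes <- function(path, samples = NULL,
                               consequence_key = "CONSEQ", gene_key = "GENE",
                               mq_key = "MQ",
                               drop_multiallelic_other = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  header_samples <- colnames(v@gt)[-1L]
  if (is.null(samples)) samples <- header_samples
  absent <- setdiff(samples, header_samples)
  if (length(absent)) {
    stop("requested samples absent from VCF header: ",
         paste(absent, collapse = ", "))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  info <- fix[, "INFO"]
  get_info <- function(key) {
    m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info))
    out <- rep(NA_character_, length(info))
    hit <- grepl(paste0(key, "="), info)
    out[hit] <- sub(paste0("^.*", key, "="), "",
                    regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info)))
    out
  }
  mq <- suppressWarnings(as.numeric(get_info(mq_key)))
  conseq <- get_info(consequence_key)
  gene <- get_info(gene_key)
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))

  rows <- list(); states_l <- list(); depth_l <- list()
  warned_gt <- FALSE
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1L]]
    for (a in seq_along(alts)) {
      st <- character(length(samples))
      for (s in seq_along(samples)) {
        g <- gt[i, samples[s]]
        st[s] <- gt_to_state(g, a)
        if (st[s] == "NO" && !is.na(g) && !(g %in% c(".", "./.", ".|."))) {
          if (!warned_gt) {
            warning("malformed GT '", g, "' treated as low quality")
            warned_gt <- TRUE
          }
        }
      }
      if (drop_multiallelic_other && any(st == "OTH")) next
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
        ref = fix[i, "REF"], alt = alts[a],
        qual = qual[i], mq = mq[i],
        consequence = conseq[i], gene = gene[i],
        stringsAsFactors = FALSE)
      states_l[[length(states_l) + 1L]] <- st
      depth_l[[length(depth_l) + 1L]] <- as.numeric(dp[i, samples])
    }
  }
  if (!length(rows)) stop("no usable records in ", path)
  sites <- do.call(rbind, rows)
  states <- do.call(rbind, states_l)
  depth <- do.call(rbind, depth_l)
  new_genotype_matrix(sites, states, depth, samples)
}

#' Read a plain-TSV genotype matrix
#'
#' Alternative to VCF input: a tab-separated file with columns `chrom`,
#' `pos`, `ref`, `alt`, `qual`, `mq`, `consequence`, `gene`, then one column
#' per strain holding states in REF/HOM/HET/NO.
#'
#' @param path TSV file path.
#' @return a `genotype_matrix` (depth is NULL).
#' @export
read_genotype_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- c("chrom", "pos", "ref", "alt", "qual", "mq",
                 "consequence", "gene")
  missing <- setdiff(c("chrom", "pos"), colnames(df))
  if (length(missing)) stop("TSV missing columns: ", paste(missing, collapse = ", "))
  samples <- setdiff(colnames(df), meta_cols)
  if (!length(samples)) stop("no sample state columns found")
  sites <- data.frame(
    chrom = as.character(df$chrom), pos = as.integer(df$pos),
    ref = if ("ref" %in% names(df)) df$ref else "N",
    alt = if ("alt" %in% names(df)) df$alt else "N",
    qual = if ("qual" %in% names(df)) as.numeric(df$qual) else NA_real_,
    mq = if ("mq" %in% names(df)) as.numeric(df$mq) else NA_real_,
    consequence = if ("consequence" %in% names(df)) df$consequence else NA_character_,
    gene = if ("gene" %in% names(df)) df$gene else NA_character_,
    stringsAsFactors = FALSE)
  states <- as.matrix(df[samples])
  new_genotype_matrix(sites, states, NULL, samples)
}

#' Apply site- and call-level quality filters
#'
#' Site-level: records with QUAL below `min_qual` or mapping quality below
#' `min_mq` are removed (thresholds inclusive: a site at exactly the
#' threshold passes). Call-level: a sample whose read depth at a site is
#' below `min_depth` has that call demoted to state `NO`. Sites or samples
#' with absent quality fields pass with a warning.
#'
#' @param matrix a `genotype_matrix`.
#' @param min_depth minimum per-sample read depth (default 10).
#' @param min_qual minimum variant quality score (default 20).
#' @param min_mq minimum mapping quality (default 30).
#' @return a filtered `genotype_matrix`.
#' @export
quality_filter <- function(matrix, min_depth = 10, min_qual = 20, min_mq = 30) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  if (min_depth < 0 || min_qual < 0 || min_mq < 0) {
    stop("quality thresholds must be non-negative")
  }
  qual <- matrix$sites$qual
  mq <- matrix$sites$mq
  if (anyNA(qual) || anyNA(mq)) {
    warning("absent QUAL/MQ values treated as passing")
  }
  keep <- (is.na(qual) | qual >= min_qual) & (is.na(mq) | mq >= min_mq)
  sites <- matrix$sites[keep, , drop = FALSE]
  states <- matrix$states[keep, , drop = FALSE]
  depth <- if (!is.null(matrix$depth)) matrix$depth[keep, , drop = FALSE] else NULL
  if (!is.null(depth)) {
    low <- !is.na(depth) & depth < min_depth
    states[low] <- "NO"
  }
  new_genotype_matrix(sites, states, depth, matrix$samples)
}

#' Group-discriminating variant sites
#'
#' A site discriminates in direction A->B iff every member of group A shares
#' one identical non-reference state s (HOM or HET) and no member of group B
#' carries state s. Both directions are evaluated and unioned, with the
#' direction recorded. HOM and HET are distinct mutation states: a group
#' uniformly heterozygous contrasts against a group without heterozygous
#' calls even if the latter is homozygous-alternate. By default
#' (`require_full_groups = TRUE`) sites where any involved strain has state
#' `NO` are excluded. `min_share` relaxes the "all members" requirement to a
#' fraction of the group (1 = strict rule).
#'
#' @param matrix a `genotype_matrix`.
#' @param group_a,group_b disjoint character vectors of sample IDs.
#' @param require_full_groups exclude sites with any NO call among the two
#'   groups (default TRUE).
#' @param min_share fraction of group-A members that must share s, in (0, 1];
#'   default 1 (every member).
#' @return a list of class `contrast_result`: `sites` data.frame (site
#'   metadata + `state`, `direction`), `genes`, `n_sites`, `n_genes`,
#'   `groups`, plus `n_unannotated` after [filter_nonsynonymous()].
#' @export
discriminating_sites <- function(matrix, group_a, group_b,
                                 require_full_groups = TRUE, min_share = 1) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  if (!length(group_a) || !length(group_b)) stop("groups must be non-empty")
  if (length(intersect(group_a, group_b))) stop("groups must be disjoint")
  absent <- setdiff(c(group_a, group_b), matrix$samples)
  if (length(absent)) stop("samples not in matrix: ", paste(absent, collapse = ", "))
  if (min_share <= 0 || min_share > 1) stop("min_share must be in (0, 1]")

  sa <- matrix$states[, group_a, drop = FALSE]
  sb <- matrix$states[, group_b, drop = FALSE]
  hits <- list()
  for (i in seq_len(nrow(sa))) {
    a <- sa[i, ]; b <- sb[i, ]
    if (require_full_groups && (any(a == "NO") || any(b == "NO"))) next
    for (dir in c("A->B", "B->A")) {
      src <- if (dir == "A->B") a else b
      dst <- if (dir == "A->B") b else a
      src_eff <- src[src != "NO"]; dst_eff <- dst[dst != "NO"]
      if (!length(src_eff)) next
      for (s in c("HOM", "HET")) {
        if (mean(src_eff == s) >= min_share && sum(src_eff == s) > 0 &&
            !any(dst_eff == s)) {
          hits[[length(hits) + 1L]] <- data.frame(
            site = i, state = s, direction = dir, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(hits)) {
    h <- do.call(rbind, hits)
    out <- cbind(site = h$site, matrix$sites[h$site, , drop = FALSE],
                 state = h$state, direction = h$direction)
    rownames(out) <- NULL
  } else {
    out <- cbind(site = integer(0), matrix$sites[0, , drop = FALSE],
                 state = character(0), direction = character(0))
  }
  genes <- unique(out$gene[!is.na(out$gene)])
  structure(list(sites = out, genes = genes,
                 n_sites = length(unique(out$site)), n_genes = length(genes),
                 groups = list(a = group_a, b = group_b),
                 n_unannotated = 0L),
            class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat("Group contrast:", x$n_sites, "discriminating sites over",
      x$n_genes, "genes\n")
  invisible(x)
}

#' Restrict a contrast result to non-synonymous variants
#'
#' Keeps sites annotated as non-synonymous (amino-acid-changing). Sites
#' lacking a consequence annotation are excluded and counted in
#' `n_unannotated`.
#'
#' @param result a `contrast_result`.
#' @return a filtered `contrast_result`.
#' @export
filter_nonsynonymous <- function(result) {
  stopifnot(inherits(result, "contrast_result"))
  conseq <- result$sites$consequence
  unann <- is.na(conseq) | conseq == ""
  keep <- !unann & conseq == "nonsynonymous"
  sites <- result$sites[keep, , drop = FALSE]
  rownames(sites) <- NULL
  genes <- unique(sites$gene[!is.na(sites$gene)])
  structure(list(sites = sites, genes = genes,
                 n_sites = length(unique(sites$site)), n_genes = length(genes),
                 groups = result$groups,
                 n_unannotated = sum(unann)),
            class = "contrast_result")
}

#' Aggregate discriminating sites by gene
#'
#' @param result a `contrast_result`.
#' @return a data.frame with columns `gene` and `n_sites`, sorted by
#'   decreasing site count then gene name.
#' @export
aggregate_genes <- function(result) {
  stopifnot(inherits(result, "contrast_result"))
  g <- result$sites$gene
  g <- g[!is.na(g)]
  if (!length(g)) {
    return(data.frame(gene = character(0), n_sites = integer(0)))
  }
  tab <- table(g)
  out <- data.frame(gene = names(tab), n_sites = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_sites, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a genotype state matrix as TSV
#'
#' Writes the site metadata plus one state column per strain, mirroring the
#' heat-map layout (rows = sites, columns = strains).
#'
#' @param matrix a `genotype_matrix`.
#' @param path output file path.
#' @export
write_genotype_tsv <- function(matrix, path) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  df <- cbind(matrix$sites, as.data.frame(matrix$states))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
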