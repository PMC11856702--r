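#' Simulate a strain phenotype panel driven by a latent fermentation ability
#'
#' Each strain draws a latent ability a ~ N(0, 1). Four informative
#' indicators load on it (TTA weakly at +0.3; specific volume and
#' springiness at +0.8; hardness at -0.8 on the raw scale, i.e. stronger
#' strains give softer product), each with independent Gaussian noise, then
#' shifted/scaled to realistic raw units (TTA ~4 mL 0.1-N NaOH, volume
#' ~2.4 mL/g, hardness ~25 N, springiness ~6.5). Optionally four redundant
#' indicators are derived as affine functions of their parents: pH tracks
#' TTA almost deterministically (r around 0.99) and cohesiveness, gumminess
#' and chewiness track hardness with correlations in the 0.6-1.0 band.
#'
#' @param n_strains number of strains (default 36).
#' @param noise_sd indicator noise standard deviation on the latent scale
#'   (default 0.3).
#' @param redundant also generate the four redundant indicators (default
#'   TRUE).
#' @param seed RNG seed.
#' @return list with `table` (a [strain_phenotype_table()]) and `truth`
#'   (list with `ability`, the latent factor per strain, and `loadings`).
#' @export
simulate_phenotypes <- function(n_strains = 36, noise_sd = 0.3,
                                redundant = TRUE, seed = 1) {
  stopifnot(n_strains >= 2, noise_sd >= 0)
  set.seed(seed)
  a <- stats::rnorm(n_strains)
  eps <- function() stats::rnorm(n_strains, sd = noise_sd)
  loadings <- c(TTA = 0.3, Volume = 0.8, Hardness = -0.8, Springiness = 0.8)
  tta  <- 4.0 + 0.5 * (loadings["TTA"] * a + eps())
  vol  <- 2.4 + 0.3 * (loadings["Volume"] * a + eps())
  hard <- 25  + 8.0 * (loadings["Hardness"] * a + eps())
  spr  <- 6.5 + 0.8 * (loadings["Springiness"] * a + eps())
  vals <- cbind(TTA = tta, Volume = vol, Hardness = hard, Springiness = spr)
  direction <- c(TTA = 1, Volume = 1, Hardness = -1, Springiness = 1)
  if (redundant) {
    ph   <- 4.6 + 0.10 * tta + stats::rnorm(n_strains, sd = 0.003)
    coh  <- 0.30 + 0.015 * hard + stats::rnorm(n_strains, sd = 0.05)
    gum  <- 0.7 * hard + stats::rnorm(n_strains, sd = 3)
    chew <- 2.5 * hard + stats::rnorm(n_strains, sd = 15)
    vals <- cbind(vals, pH = ph, Cohesiveness = coh,
                  Gumminess = gum, Chewiness = chew)
    direction <- c(direction, pH = 1, Cohesiveness = -1,
                   Gumminess = -1, Chewiness = -1)
  }
  ids <- paste0("S", seq_len(n_strains))
  rownames(vals) <- ids
  list(table = strain_phenotype_table(vals, ids, colnames(vals), direction),
       truth = list(ability = stats::setNames(a, ids), loadings = loadings))
}

#' Simulate a genotype matrix with planted group-discriminating variants
#'
#' Plants `n_planted` sites, spread over `n_planted_genes` genes, where every
#' member of group A shares one non-reference state (HOM, or HET for a
#' configurable fraction of planted sites) and every member of group B is
#' reference-consistent — the textbook group-discriminating configuration.
#' Background sites draw states independently per cell; by default
#' (`exclude_accidental = TRUE`) any background site that happens to satisfy
#' the strict contrast rule for the configured groups is redrawn, so the
#' planted list is exactly the discriminating set and the ground-truth
#' bookkeeping is exact. Missing calls and site-level quality failures are
#' applied after planting.
#'
#' @param n_sites total sites (default 500).
#' @param strains sample IDs (default S1..S36).
#' @param group_a,group_b strain ID vectors (defaults S1/S25/S33 and
#'   S18/S20/S35).
#' @param n_planted planted discriminating sites (default 33).
#' @param n_planted_genes genes carrying the planted sites (default 19).
#' @param planted_het_fraction fraction of planted sites whose shared state
#'   is HET rather than HOM (default 0.2).
#' @param frac_nonsyn_background fraction of background sites annotated
#'   non-synonymous (planted sites are always non-synonymous; default 0.5).
#' @param missing_rate per-cell probability of a missing (NO) call applied
#'   after planting (default 0).
#' @param qual_fail_rate fraction of background sites given failing QUAL or
#'   MQ (default 0).
#' @param exclude_accidental redraw background sites that accidentally
#'   discriminate (default TRUE).
#' @param seed RNG seed.
#' @return list with `matrix` (a `genotype_matrix`) and `truth` (data.frame
#'   of planted sites with chrom, pos, alt, gene, state; plus `genes`).
#' @export
simulate_genotypes <- function(n_sites = 500,
                               strains = paste0("S", 1:36),
                               group_a = c("S1", "S25", "S33"),
                               group_b = c("S18", "S20", "S35"),
                               n_planted = 33, n_planted_genes = 19,
                               planted_het_fraction = 0.2,
                               frac_nonsyn_background = 0.5,
                               missing_rate = 0, qual_fail_rate = 0,
                               exclude_accidental = TRUE, seed = 1) {
  if (n_planted > n_sites) stop("n_planted exceeds n_sites")
  if (n_planted_genes > n_planted && n_planted > 0) {
    stop("n_planted_genes cannot exceed n_planted")
  }
  if (length(intersect(group_a, group_b))) stop("groups must be disjoint")
  absent <- setdiff(c(group_a, group_b), strains)
  if (length(absent)) stop("group members not in strains: ",
                           paste(absent, collapse = ", "))
  stopifnot(missing_rate >= 0, missing_rate <= 1,
            qual_fail_rate >= 0, qual_fail_rate <= 1)
  set.seed(seed)
  n_strains <- length(strains)
  bases <- c("A", "C", "G", "T")
  pos <- sort(sample.int(12e6, n_sites))
  ref <- sample(bases, n_sites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  qual <- round(stats::runif(n_sites, 30, 60), 1)
  mq <- round(stats::runif(n_sites, 40, 60), 1)

  planted_idx <- if (n_planted > 0) sort(sample.int(n_sites, n_planted)) else integer(0)
  background_idx <- setdiff(seq_len(n_sites), planted_idx)

  # gene labels: planted genes PG01.., sizes as equal as possible
  gene <- character(n_sites)
  if (n_planted > 0) {
    sizes <- rep(n_planted %/% n_planted_genes, n_planted_genes)
    extra <- n_planted %% n_planted_genes
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    gene[planted_idx] <- rep(sprintf("PG%02d", seq_len(n_planted_genes)), sizes)
  }
  gene[background_idx] <- sprintf("BG%04d", sample.int(max(n_sites, 200),
                                                       length(background_idx)))
  conseq <- character(n_sites)
  conseq[planted_idx] <- "nonsynonymous"
  conseq[background_idx] <- ifelse(
    stats::runif(length(background_idx)) < frac_nonsyn_background,
    "nonsynonymous", "synonymous")

  a_cols <- match(group_a, strains)
  b_cols <- match(group_b, strains)
  state_probs <- c(REF = 0.80, HOM = 0.12, HET = 0.08)
  draw_row <- function() sample(names(state_probs), n_strains,
                                replace = TRUE, prob = state_probs)
  is_discriminating_row <- function(st) {
    for (cols in list(list(src = a_cols, dst = b_cols),
                      list(src = b_cols, dst = a_cols))) {
      src <- st[cols$src]; dst <- st[cols$dst]
      for (s in c("HOM", "HET")) {
        if (all(src == s) && !any(dst == s)) return(TRUE)
      }
    }
    FALSE
  }
  states <- matrix("REF", n_sites, n_strains, dimnames = list(NULL, strains))
  for (i in background_idx) {
    st <- draw_row()
    if (exclude_accidental) {
      while (is_discriminating_row(st)) st <- draw_row()
    }
    states[i, ] <- st
  }
  planted_state <- character(0)
  if (n_planted > 0) {
    n_het <- round(planted_het_fraction * n_planted)
    planted_state <- c(rep("HET", n_het), rep("HOM", n_planted - n_het))
    for (j in seq_along(planted_idx)) {
      i <- planted_idx[j]
      st <- rep("REF", n_strains)
      others <- setdiff(seq_len(n_strains), c(a_cols, b_cols))
      st[others] <- sample(names(state_probs), length(others),
                           replace = TRUE, prob = state_probs)
      st[a_cols] <- planted_state[j]
      st[b_cols] <- "REF"
      states[i, ] <- st
    }
  }
  if (qual_fail_rate > 0 && length(background_idx)) {
    n_fail <- round(qual_fail_rate * length(background_idx))
    fail <- sample(background_idx, n_fail)
    half <- fail[seq_len(floor(n_fail / 2))]
    qual[half] <- round(stats::runif(length(half), 5, 19.9), 1)
    mq[setdiff(fail, half)] <- round(stats::runif(length(setdiff(fail, half)), 5, 29.9), 1)
  }
  depth <- matrix(sample(15:40, n_sites * n_strains, replace = TRUE),
                  n_sites, n_strains, dimnames = list(NULL, strains))
  if (missing_rate > 0) {
    miss <- matrix(stats::runif(n_sites * n_strains) < missing_rate,
                   n_sites, n_strains)
    states[miss] <- "NO"
  }
  sites <- data.frame(chrom = "chrI", pos = pos, ref = ref, alt = alt,
                      qual = qual, mq = mq, consequence = conseq, gene = gene,
                      stringsAsFactors = FALSE)
  truth <- data.frame(chrom = rep("chrI", length(planted_idx)),
                      pos = pos[planted_idx],
                      alt = alt[planted_idx], gene = gene[planted_idx],
                      state = planted_state, stringsAsFactors = FALSE)
  list(matrix = new_genotype_matrix(sites, states, depth, strains),
       truth = list(planted = truth,
                    genes = unique(truth$gene),
                    group_a = group_a, group_b = group_b))
}

#' Simulate a gene-to-term annotation with one planted enriched term
#'
#' Builds a background universe, assigns random terms, then plants one term
#' whose overlap with the returned query is fixed by construction. With the
#' defaults (background 1000, term size 10, query size 20, overlap 8) the
#' planted fold enrichment is (8/20)/(10/1000) = 40.
#'
#' @param n_genes background universe size (default 1000).
#' @param n_terms number of random background terms (default 50).
#' @param planted_term_size genes annotated to the planted term (default 10).
#' @param query_size query gene-set size (default 20).
#' @param planted_overlap query genes inside the planted term (default 8).
#' @param seed RNG seed.
#' @return list with `annotation` (an [annotation_table()]), `query`
#'   (character vector) and `truth` (planted term ID and expected counts).
#' @export
simulate_annotations <- function(n_genes = 1000, n_terms = 50,
                                 planted_term_size = 10, query_size = 20,
                                 planted_overlap = 8, seed = 1) {
  if (planted_overlap > min(query_size, planted_term_size)) {
    stop("planted_overlap exceeds query or planted term size")
  }
  set.seed(seed)
  genes <- sprintf("G%04d", seq_len(n_genes))
  terms <- stats::setNames(
    lapply(seq_len(n_terms), function(i) {
      sample(genes, sample(5:50, 1L))
    }), sprintf("T%03d", seq_len(n_terms)))
  planted_genes <- sample(genes, planted_term_size)
  terms[["T_PLANTED"]] <- planted_genes
  query <- c(sample(planted_genes, planted_overlap),
             sample(setdiff(genes, planted_genes),
                    query_size - planted_overlap))
  list(annotation = annotation_table(terms, genes),
       query = query,
       truth = list(term = "T_PLANTED", k = planted_overlap, n = query_size,
                    K = planted_term_size, N = n_genes))
}

#' Write a genotype matrix as a plain-text VCF 4.2
#'
#' Serializes states as GT (REF -> 0/0, HOM -> 1/1, HET -> 0/1, NO -> ./.)
#' with per-sample DP when depth is present; QUAL and the MQ INFO field are
#' written with one decimal so that identical matrices serialize to
#' byte-identical files. Round-trips through [read_vcf_genotypes()].
#'
#' @param matrix a `genotype_matrix` (must not contain OTH states).
#' @param path output path.
#' @export
write_synthetic_vcf <- function(matrix, path) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  if (any(matrix$states == "OTH")) {
    stop("matrices with OTH states (decomposed multi-allelics) cannot be re-serialized")
  }
  con <- file(path, "w")
  on.exit(close(con))
  has_dp <- !is.null(matrix$depth)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=fermentrank-synthetic",
    '##INFO=<ID=MQ,Number=1,Type=Float,Description="Mapping quality">',
    '##INFO=<ID=CONSEQ,Number=1,Type=String,Description="Consequence">',
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene ID">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  if (has_dp) {
    header <- c(header,
      '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">')
  }
  header <- c(header,
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", matrix$samples), collapse = "\t"))
  writeLines(header, con)
  gt_map <- c(REF = "0/0", HOM = "1/1", HET = "0/1", NO = "./.")
  s <- matrix$sites
  for (i in seq_len(nrow(s))) {
    info <- sprintf("MQ=%.1f;CONSEQ=%s;GENE=%s", s$mq[i], s$consequence[i],
                    s$gene[i])
    gts <- gt_map[matrix$states[i, ]]
    if (has_dp) {
      fmt <- "GT:DP"
      calls <- paste(gts, matrix$depth[i, ], sep = ":")
    } else {
      fmt <- "GT"
      calls <- gts
    }
    writeLines(paste(c(s$chrom[i], s$pos[i], ".", s$ref[i], s$alt[i],
                       sprintf("%.1f", s$qual[i]), "PASS", info, fmt, calls),
                     collapse = "\t"), con)
  }
  invisible(path)
}
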