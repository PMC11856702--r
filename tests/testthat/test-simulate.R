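test_that("phenotype generator is seeded, structured and noise-limited", {
  s1 <- simulate_phenotypes(seed = 5)
  s2 <- simulate_phenotypes(seed = 5)
  expect_identical(s1$table$values, s2$table$values)
  expect_identical(s1$truth$ability, s2$truth$ability)
  expect_equal(dim(s1$table$values), c(36L, 8L))
  # redundant indicators carry the configured correlation structure
  cr <- correlation_matrix(s1$table)
  expect_gte(cr$r["pH", "TTA"], 0.95)
  for (ind in c("Cohesiveness", "Gumminess", "Chewiness")) {
    expect_gte(cr$r[ind, "Hardness"], 0.6)
  }
  # noiseless limit: positively-loaded indicators rank exactly like ability
  s0 <- simulate_phenotypes(noise_sd = 0, seed = 6)
  a <- s0$truth$ability
  expect_equal(order(s0$table$values[, "Volume"]), order(a))
  expect_equal(order(s0$table$values[, "Springiness"]), order(a))
  expect_equal(order(-s0$table$values[, "Hardness"]), order(a))
})

test_that("phenotype correlations converge to the configured structure", {
  big <- simulate_phenotypes(n_strains = 10000, seed = 77)
  cr <- correlation_matrix(big$table)
  # expected correlations implied by the generative model
  load_sd <- function(l, noise = 0.3) sqrt(l^2 + noise^2)
  exp_vh <- (0.8 * -0.8) / (load_sd(0.8) * load_sd(0.8))
  expect_equal(cr$r["Volume", "Hardness"], exp_vh, tolerance = 0.02)
  exp_tv <- (0.3 * 0.8) / (load_sd(0.3) * load_sd(0.8))
  expect_equal(cr$r["TTA", "Volume"], exp_tv, tolerance = 0.02)
})

test_that("genotype generator plants exactly the configured truth", {
  sim <- simulate_genotypes(seed = 13)
  expect_equal(nrow(sim$truth$planted), 33L)
  expect_equal(length(sim$truth$genes), 19L)
  expect_equal(nrow(sim$matrix$sites), 500L)
  # truth bookkeeping: every planted site satisfies the contrast rule on the
  # emitted matrix
  a_cols <- sim$truth$group_a
  b_cols <- sim$truth$group_b
  for (j in seq_len(nrow(sim$truth$planted))) {
    i <- match(sim$truth$planted$pos[j], sim$matrix$sites$pos)
    want <- oracle_contrast_one_site(sim$matrix$states[i, a_cols],
                                     sim$matrix$states[i, b_cols])
    expect_true(sim$truth$planted$state[j] %in% want$state)
  }
  # determinism
  sim2 <- simulate_genotypes(seed = 13)
  expect_identical(sim2$matrix$states, sim$matrix$states)
  expect_error(simulate_genotypes(n_planted = 5, n_planted_genes = 9),
               "n_planted_genes")
})

test_that("background-only matrices show the analytic false-positive rate", {
  # with accidental contrasts allowed, the strict 3-vs-3 rule fires on an
  # i.i.d. background site with probability
  # sum_s [ P(A all s) * P(B none s) ] counted over both directions
  p <- c(REF = 0.80, HOM = 0.12, HET = 0.08)
  p_one_dir <- p["HOM"]^3 * (1 - p["HOM"])^3 + p["HET"]^3 * (1 - p["HET"])^3
  # directions can't both fire for the same s; cross terms (A all HOM & B all
  # HET etc.) are rare and counted once per (s, direction) pair
  p_site <- 2 * p_one_dir -
    2 * (p["HOM"]^3 * p["HET"]^3)  # both directions fire jointly
  hits <- 0L; total <- 0L
  for (s in 1:20) {
    sim <- simulate_genotypes(n_sites = 600, n_planted = 0,
                              exclude_accidental = FALSE, seed = 900 + s)
    res <- discriminating_sites(sim$matrix, sim$truth$group_a,
                                sim$truth$group_b)
    hits <- hits + res$n_sites
    total <- total + 600L
  }
  expect_equal(hits / total, unname(p_site), tolerance = 0.35)
  # and the default generator suppresses them entirely
  sim0 <- simulate_genotypes(n_sites = 400, n_planted = 0, seed = 901)
  res0 <- discriminating_sites(sim0$matrix, sim0$truth$group_a,
                               sim0$truth$group_b)
  expect_equal(res0$n_sites, 0L)
})

test_that("missingness lowers recall to the complete-data fraction", {
  sim <- simulate_genotypes(missing_rate = 0.05, seed = 41)
  gm <- sim$matrix
  involved <- c(sim$truth$group_a, sim$truth$group_b)
  planted_rows <- match(sim$truth$planted$pos, gm$sites$pos)
  complete <- rowSums(gm$states[planted_rows, involved] == "NO") == 0
  res <- discriminating_sites(gm, sim$truth$group_a, sim$truth$group_b)
  recovered <- sim$truth$planted$pos %in% res$sites$pos
  # recall equals the complete-data fraction, site by site
  expect_identical(unname(recovered), unname(complete))
})

test_that("synthetic VCF writing is byte-stable and round-trips", {
  sim <- simulate_genotypes(n_sites = 50, seed = 19)
  f1 <- withr::local_tempfile(fileext = ".vcf")
  f2 <- withr::local_tempfile(fileext = ".vcf")
  write_synthetic_vcf(sim$matrix, f1)
  write_synthetic_vcf(simulate_genotypes(n_sites = 50, seed = 19)$matrix, f2)
  expect_identical(readLines(f1), readLines(f2))
  gm <- read_vcf_genotypes(f1)
  expect_equal(unname(gm$states), unname(sim$matrix$states))
  expect_equal(unname(gm$depth) * 1.0, unname(sim$matrix$depth) * 1.0)
  expect_equal(gm$sites$qual, sim$matrix$sites$qual)
  expect_equal(gm$sites$mq, sim$matrix$sites$mq)
  expect_equal(gm$sites$gene, sim$matrix$sites$gene)
  # low-quality cells serialize as ./. and come back as NO
  gm0 <- make_gm(rbind(c("NO", "HET")), samples = c("x", "y"))
  f3 <- withr::local_tempfile(fileext = ".vcf")
  write_synthetic_vcf(gm0, f3)
  expect_match(readLines(f3)[8], "\\./\\.")
  expect_equal(unname(read_vcf_genotypes(f3)$states[1, ]), c("NO", "HET"))
})

test_that("annotation generator honours its planted overlap", {
  sim <- simulate_annotations(seed = 2)
  expect_equal(length(sim$annotation$background), 1000L)
  k <- length(intersect(sim$query,
                        sim$annotation$terms[[sim$truth$term]]))
  expect_equal(k, sim$truth$k)
  # saturated case: fold = N / K
  sat <- simulate_annotations(planted_term_size = 10, query_size = 10,
                              planted_overlap = 10, seed = 3)
  et <- overrepresentation_test(sat$query, sat$annotation)
  expect_equal(et$fold_enrichment[et$term == "T_PLANTED"], 1000 / 10)
  # overlap at the independence expectation gives fold near 1
  ind <- simulate_annotations(n_genes = 1000, planted_term_size = 100,
                              query_size = 20, planted_overlap = 2, seed = 4)
  et2 <- overrepresentation_test(ind$query, ind$annotation)
  expect_equal(et2$fold_enrichment[et2$term == "T_PLANTED"], 1.0)
  expect_error(simulate_annotations(planted_overlap = 25), "exceeds")
  expect_identical(simulate_annotations(seed = 9)$query,
                   simulate_annotations(seed = 9)$query)
})
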