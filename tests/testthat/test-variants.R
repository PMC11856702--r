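test_that("GT strings map to the documented genotype states", {
  states <- c("REF", "HOM", "HET")
  gm <- make_gm(rbind(c("REF", "HOM", "HET")), samples = c("s1", "s2", "s3"))
  expect_equal(unname(gm$states[1, ]), states)
  # via a real VCF record
  f <- withr::local_tempfile(fileext = ".vcf")
  gm0 <- make_gm(rbind(c("REF", "HOM", "HET"), c("NO", "REF", "REF")),
                 samples = c("s1", "s2", "s3"))
  write_synthetic_vcf(gm0, f)
  rt <- read_vcf_genotypes(f)
  expect_equal(unname(rt$states[1, ]), c("REF", "HOM", "HET"))
  expect_equal(unname(rt$states[2, ]), c("NO", "REF", "REF"))
})

test_that("multi-allelic records decompose one row per alternate allele", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=MQ,Number=1,Type=Float,Description="MQ">',
    '##INFO=<ID=CONSEQ,Number=1,Type=String,Description="c">',
    '##INFO=<ID=GENE,Number=1,Type=String,Description="g">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2", "s3"), collapse = "\t"),
    paste(c("chrI", "100", ".", "A", "T,G", "50.0", "PASS",
            "MQ=60.0;CONSEQ=nonsynonymous;GENE=X", "GT",
            "1/1", "0/2", "1/2"), collapse = "\t")), f)
  gm <- read_vcf_genotypes(f)
  expect_equal(nrow(gm$sites), 2L)
  expect_equal(gm$sites$alt, c("T", "G"))
  # row for alt T: s1 hom for T, s2 carries the other alt, s3 het-for-T plus other
  expect_equal(unname(gm$states[1, ]), c("HOM", "OTH", "OTH"))
  # row for alt G: s1 carries only the other alt, s2 het for G
  expect_equal(unname(gm$states[2, ]), c("OTH", "HET", "OTH"))
  # strict mode drops rows touched by other-alt genotypes
  expect_error(read_vcf_genotypes(f, drop_multiallelic_other = TRUE),
               "no usable records")
})

test_that("requesting an absent sample errors", {
  f <- withr::local_tempfile(fileext = ".vcf")
  write_synthetic_vcf(make_gm(rbind(c("REF", "HOM")), samples = c("s1", "s2")), f)
  expect_error(read_vcf_genotypes(f, samples = c("s1", "missing")), "absent")
})

test_that("quality filtering removes failing sites and demotes shallow calls", {
  states <- rbind(c("HOM", "REF"), c("HET", "HOM"), c("REF", "REF"))
  gm <- make_gm(states, samples = c("a", "b"),
                qual = c(19.9, 20, 35), mq = c(60, 30, 29.9))
  out <- quality_filter(gm)
  # site 1 fails QUAL (19.9 < 20), site 3 fails MQ; site 2 is boundary-inclusive
  expect_equal(nrow(out$sites), 1L)
  expect_equal(out$sites$qual, 20)
  gm2 <- make_gm(rbind(c("HOM", "HET")), samples = c("a", "b"))
  gm2$depth <- rbind(c(10, 9))
  out2 <- quality_filter(gm2)
  expect_equal(unname(out2$states[1, ]), c("HOM", "NO"))
  expect_error(quality_filter(gm, min_depth = -1), "non-negative")
})

test_that("constructed quality fixture: planted failures are removed exactly", {
  set.seed(5)
  n <- 100
  qual <- rep(50, n); mq <- rep(60, n)
  bad <- sample(n, 40)
  qual[bad[1:20]] <- runif(20, 0, 19.9)
  mq[bad[21:40]] <- runif(20, 0, 29.9)
  gm <- make_gm(matrix("REF", n, 3), samples = c("a", "b", "c"),
                qual = qual, mq = mq)
  expect_equal(nrow(quality_filter(gm)$sites), 60L)
})

test_that("contrast rule matches the published example patterns", {
  gm <- make_gm(rbind(
    c("HOM", "HOM", "HOM", "REF", "REF", "HET"),   # discriminates, s = HOM
    c("HOM", "HET", "HOM", "REF", "REF", "REF"),   # not identical within A
    c("HET", "HET", "HET", "HOM", "HOM", "HOM")),  # both directions
    samples = c("a1", "a2", "a3", "b1", "b2", "b3"))
  res <- discriminating_sites(gm, c("a1", "a2", "a3"), c("b1", "b2", "b3"))
  expect_true(1 %in% res$sites$site)
  expect_equal(res$sites$state[res$sites$site == 1], "HOM")
  expect_false(2 %in% res$sites$site)
  # site 3: A uniformly HET (B has none), B uniformly HOM (A has none)
  expect_setequal(res$sites$direction[res$sites$site == 3], c("A->B", "B->A"))
  expect_error(discriminating_sites(gm, c("a1", "b1"), c("b1", "b2")),
               "disjoint")
})

test_that("contrast equals the brute-force oracle on every 3-vs-3 combination", {
  combos <- all_state_combos(3)
  n_a <- nrow(combos)
  # one site per (A-assignment, B-assignment) pair: 4096 sites
  states <- matrix(NA_character_, n_a * n_a, 6)
  idx <- 1L
  for (i in seq_len(n_a)) for (j in seq_len(n_a)) {
    states[idx, ] <- c(combos[i, ], combos[j, ])
    idx <- idx + 1L
  }
  samples <- c("a1", "a2", "a3", "b1", "b2", "b3")
  gm <- make_gm(states, samples = samples)
  for (rfg in c(TRUE, FALSE)) {
    res <- discriminating_sites(gm, samples[1:3], samples[4:6],
                                require_full_groups = rfg)
    got <- split(paste(res$sites$state, res$sites$direction),
                 res$sites$site)
    n_mismatch <- 0L
    for (s in seq_len(nrow(states))) {
      want <- oracle_contrast_one_site(states[s, 1:3], states[s, 4:6],
                                       require_full_groups = rfg)
      want_keys <- sort(paste(want$state, want$direction))
      got_keys <- sort(got[[as.character(s)]] %||% character(0))
      if (!identical(want_keys, got_keys)) n_mismatch <- n_mismatch + 1L
    }
    expect_equal(n_mismatch, 0L)
  }
})

test_that("contrast output is invariant to site/sample order and label swap", {
  sim <- simulate_genotypes(n_sites = 80, seed = 21)
  gm <- sim$matrix
  ga <- sim$truth$group_a; gb <- sim$truth$group_b
  res <- discriminating_sites(gm, ga, gb)
  key <- function(r) sort(paste(r$sites$pos, r$sites$state))
  # permute sites
  perm <- sample(nrow(gm$sites))
  gm2 <- gm
  gm2$sites <- gm$sites[perm, , drop = FALSE]; rownames(gm2$sites) <- NULL
  gm2$states <- gm$states[perm, , drop = FALSE]
  gm2$depth <- gm$depth[perm, , drop = FALSE]
  expect_identical(key(discriminating_sites(gm2, ga, gb)), key(res))
  # permute group member order
  expect_identical(key(discriminating_sites(gm, rev(ga), sample(gb))), key(res))
  # swapping the group labels swaps directions, same site set
  swapped <- discriminating_sites(gm, gb, ga)
  expect_setequal(swapped$sites$pos, res$sites$pos)
  expect_identical(sort(swapped$sites$pos[swapped$sites$direction == "B->A"]),
                   sort(res$sites$pos[res$sites$direction == "A->B"]))
})

test_that("enlarging group B can only shrink the A->B discriminating set", {
  set.seed(9)
  samples <- c(paste0("a", 1:3), paste0("b", 1:4))
  states <- matrix(sample(c("REF", "HOM", "HET"), 200 * 7, replace = TRUE,
                          prob = c(0.6, 0.25, 0.15)), 200, 7)
  gm <- make_gm(states, samples = samples)
  ab <- function(gb) {
    r <- discriminating_sites(gm, paste0("a", 1:3), gb)
    r$sites$site[r$sites$direction == "A->B"]
  }
  small <- ab(c("b1", "b2", "b3"))
  big <- ab(c("b1", "b2", "b3", "b4"))
  expect_true(all(big %in% small))
})

test_that("majority-share relaxation admits near-uniform groups", {
  gm <- make_gm(rbind(c("HOM", "HOM", "HET", "REF", "REF", "REF")),
                samples = c("a1", "a2", "a3", "b1", "b2", "b3"))
  strict <- discriminating_sites(gm, c("a1", "a2", "a3"), c("b1", "b2", "b3"))
  expect_equal(strict$n_sites, 0L)
  relaxed <- discriminating_sites(gm, c("a1", "a2", "a3"), c("b1", "b2", "b3"),
                                  min_share = 2 / 3)
  expect_equal(relaxed$n_sites, 1L)
  expect_equal(relaxed$sites$state, "HOM")
})

test_that("non-synonymous restriction and gene aggregation count correctly", {
  conseq <- c(rep("nonsynonymous", 5), rep("synonymous", 3), NA)
  gene <- c(rep("SEO1", 4), "COX10", "X1", "X2", "X3", "X4")
  states <- matrix(rep(c("HOM", "HOM", "HOM", "REF", "REF", "REF"), 9),
                   9, 6, byrow = TRUE)
  gm <- make_gm(states, samples = c("a1", "a2", "a3", "b1", "b2", "b3"),
                consequence = conseq, gene = gene)
  res <- discriminating_sites(gm, c("a1", "a2", "a3"), c("b1", "b2", "b3"))
  expect_equal(res$n_sites, 9L)
  ns <- filter_nonsynonymous(res)
  expect_equal(ns$n_sites, 5L)
  expect_equal(ns$n_unannotated, 1L)
  agg <- aggregate_genes(ns)
  expect_equal(agg, data.frame(gene = c("SEO1", "COX10"), n_sites = c(4L, 1L)))
  # identities
  expect_equal(filter_nonsynonymous(ns)$n_sites, 5L)
  empty <- filter_nonsynonymous(discriminating_sites(
    make_gm(matrix("REF", 2, 6),
            samples = c("a1", "a2", "a3", "b1", "b2", "b3")),
    c("a1", "a2", "a3"), c("b1", "b2", "b3")))
  expect_equal(empty$n_sites, 0L)
  expect_equal(nrow(aggregate_genes(empty)), 0L)
})

test_that("genotype TSV reader round-trips the state matrix", {
  sim <- simulate_genotypes(n_sites = 40, seed = 33)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_genotype_tsv(sim$matrix, f)
  gm <- read_genotype_tsv(f)
  expect_equal(unname(gm$states), unname(sim$matrix$states))
  expect_equal(gm$sites$pos, sim$matrix$sites$pos)
  expect_equal(gm$samples, sim$matrix$samples)
})
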