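# Independent oracles and fixture builders used across test files.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Brute-force transcription of the group-discriminating rule for one site:
# returns a data.frame of (state, direction) pairs, or a 0-row frame.
# Written directly from the rule statement, independent of the package code.
oracle_contrast_one_site <- function(a_states, b_states,
                                     require_full_groups = TRUE) {
  out <- data.frame(state = character(0), direction = character(0),
                    stringsAsFactors = FALSE)
  if (require_full_groups && any(c(a_states, b_states) == "NO")) return(out)
  for (dir in c("A->B", "B->A")) {
    src <- if (dir == "A->B") a_states else b_states
    dst <- if (dir == "A->B") b_states else a_states
    src <- src[src != "NO"]; dst <- dst[dst != "NO"]
    if (!length(src)) next
    for (s in c("HOM", "HET")) {
      if (all(src == s) && !any(dst == s)) {
        out <- rbind(out, data.frame(state = s, direction = dir,
                                     stringsAsFactors = FALSE))
      }
    }
  }
  out
}

# Exhaustive-enumeration hypergeometric upper tail: draw n of N genes where
# the first K are annotated; P(X >= k) by counting all C(N, n) draws.
oracle_hyper_enum <- function(k, n, K, N) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)
  mean(hits >= k)
}

# Build a genotype_matrix directly from a state matrix (bypasses I/O paths).
make_gm <- function(states, samples = colnames(states),
                    qual = NULL, mq = NULL, depth = NULL,
                    consequence = NULL, gene = NULL) {
  states <- as.matrix(states)
  ns <- nrow(states)
  sites <- data.frame(
    chrom = "chrI", pos = seq_len(ns) * 100L,
    ref = "A", alt = "T",
    qual = if (is.null(qual)) rep(50, ns) else qual,
    mq = if (is.null(mq)) rep(60, ns) else mq,
    consequence = if (is.null(consequence)) rep("nonsynonymous", ns) else consequence,
    gene = if (is.null(gene)) sprintf("G%03d", seq_len(ns)) else gene,
    stringsAsFactors = FALSE)
  colnames(states) <- samples
  gm <- list(sites = sites, states = states, depth = depth, samples = samples)
  class(gm) <- "genotype_matrix"
  gm
}

# All 4-state single-group assignments of length k, as a character matrix.
all_state_combos <- function(k, states = c("REF", "HOM", "HET", "NO")) {
  grid <- expand.grid(rep(list(states), k), stringsAsFactors = FALSE)
  as.matrix(grid)
}
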