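# Shared fixtures and independent oracles, built in code at test time.

# Brute-force hypergeometric upper tail: P(overlap >= x) when two k-sets
# (here sizes K and n) are drawn from N. Pure combinatorics, independent of
# stats::phyper.
enum_hyper_tail <- function(x, K, n, N) {
  i <- seq.int(x, min(K, n))
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# A tiny labeled expression matrix.
tiny_em <- function(values, groups) {
  expression_matrix(values, groups)
}

# Deterministic ranked list from explicit ordering (scores n..1).
rl_from_order <- function(genes) {
  ranked_list(stats::setNames(rev(seq_along(genes)), genes))
}

# A ranked list with the exactly reversed order of `rl`.
rl_reversed <- function(rl) {
  rl_from_order(rev(rl$gene_ids))
}

# A small deterministic compound bank as RankedLists over `genes`:
# `reversers` get the reversed disease order, others get seeded random
# permutations.
toy_bank <- function(disease, n_compounds, reversers = integer(0),
                     seed = 42) {
  set.seed(seed)
  genes <- disease$gene_ids
  out <- lapply(seq_len(n_compounds), function(j) {
    if (j %in% reversers) rl_reversed(disease)
    else rl_from_order(sample(genes))
  })
  stats::setNames(out, sprintf("cmpd_%02d", seq_len(n_compounds)))
}

# Write a minimal GDS-like file + group sidecar; returns both paths.
write_tiny_gds <- function() {
  gds <- tempfile(fileext = ".gds")
  grp <- tempfile(fileext = ".groups")
  writeLines(c(
    "ID_REF\ts1\ts2\ts3",
    "p1\t1.5\t2.5\t3.5",
    "p2\t0.1\t0.2\t0.3"
  ), gds)
  writeLines(c("s1\tnormal", "s2\tnormal", "s3\tdisease"), grp)
  list(gds = gds, groups = grp)
}
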