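## Shared small fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

## a small 5-strain, 3-lineage community on 30 kb genomes
smallCommunity <- function() {
  if (is.null(.fixture_env$small)) {
    cfg <- communityConfig(
      genome_length = 3e4, n_genes = 20, accessory_per_strain = 3,
      lineage_sizes = c(2, 2, 1), dominant_lineages = c(1L, 3L),
      n_planted = 3, host_decoy_length = 1.5e4,
      within_divergence = 0.01, between_divergence = 0.08
    )
    .fixture_env$small <- buildCommunity(cfg, seed = 42)
  }
  .fixture_env$small
}

## random nucleotide string
randSeq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

## slice reads (error-free, forward strand) from a sequence
sliceReads <- function(sequence, starts, len) {
  substring(sequence, starts + 1, starts + len)
}

## brute-force BH q-values: q_i = min_{j >= i} p_(j) * m / j
bruteForceBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}
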