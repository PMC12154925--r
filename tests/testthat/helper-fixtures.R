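# Shared fixture builders for the test suite. Everything is generated in
# code under fixed seeds; no data files.

aa_string <- function(n, ch = "A") paste(rep(ch, n), collapse = "")

toy_genome <- function(lengths = c(10L, 40L, 64L), genome_id = "toy") {
  genome_record(genome_id,
                protein_id = sprintf("p%d", seq_along(lengths) - 1L),
                ordinal = seq_along(lengths) - 1L,
                sequence = vapply(lengths, aa_string, ""))
}

# random row-stochastic matrix
random_stochastic <- function(L) {
  M <- matrix(stats::rexp(L * L), L, L)
  M / rowSums(M)
}

# deterministic non-adjacent planted pairs for an n-protein genome
pick_nonadjacent_pairs <- function(n_proteins, n_pairs, seed) {
  all_pairs <- which(upper.tri(diag(n_proteins)), arr.ind = TRUE) - 1L
  nonadj <- all_pairs[all_pairs[, 2L] - all_pairs[, 1L] >= 2L, , drop = FALSE]
  withr::with_seed(seed, nonadj[sample(nrow(nonadj), n_pairs), , drop = FALSE])
}
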