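# Seeded synthetic fixtures: random genomes, attention stacks with planted
# elevated-attention protein pairs, random Q/K/V tensors, and a
# partner-dependent masked-token task. All generators are pure functions of
# their arguments including the seed.

#' Generate a random multi-protein genome
#'
#' Protein lengths are uniform over `length_range`; sequences are i.i.d. over
#' the 20 canonical amino acids.
#'
#' @param n_proteins Number of proteins (>= 1).
#' @param length_range Length 2 vector `(min, max)` of protein lengths.
#' @param seed Integer seed; the generator is deterministic given it.
#' @param genome_id Identifier for the record.
#' @return A [genome_record()].
#' @export
make_synthetic_genome <- function(n_proteins, length_range = c(50L, 400L),
                                  seed = 0L, genome_id = "synthetic") {
  vb_assert(n_proteins >= 1L, "n_proteins must be >= 1")
  vb_assert(length(length_range) == 2L && length_range[1L] >= 1 &&
              length_range[1L] <= length_range[2L],
            "length_range must satisfy 1 <= min <= max")
  with_seed(seed, {
    rng <- length_range[1L]:length_range[2L]  # sample.int: safe when min == max
    lens <- rng[sample.int(length(rng), n_proteins, replace = TRUE)]
    seqs <- vapply(lens, function(n) {
      paste(sample(AA_CANONICAL, n, replace = TRUE), collapse = "")
    }, "")
    genome_record(genome_id,
                  protein_id = sprintf("p%03d", seq_len(n_proteins) - 1L),
                  ordinal = seq_len(n_proteins) - 1L,
                  sequence = seqs)
  })
}

#' Construct an attention stack object
#'
#' @param matrices List of layers, each a list of heads, each an L x L
#'   nonnegative matrix whose rows sum to 1 (within 1e-5).
#' @return Object of class `attention_stack` with fields `n_layers`,
#'   `n_heads`, `L`, `matrices`.
#' @export
attention_stack <- function(matrices) {
  vb_assert(length(matrices) >= 1L && length(matrices[[1L]]) >= 1L,
            "attention stack must contain at least one (layer, head) matrix")
  L <- nrow(matrices[[1L]][[1L]])
  for (l in seq_along(matrices)) {
    for (h in seq_along(matrices[[l]])) {
      M <- matrices[[l]][[h]]
      vb_assert(is.matrix(M) && nrow(M) == L && ncol(M) == L,
                "matrix (%d,%d) is not %dx%d", l, h, L, L)
      vb_assert(all(M >= 0), "matrix (%d,%d) has negative entries", l, h)
      vb_assert(max(abs(rowSums(M) - 1)) <= 1e-5,
                "matrix (%d,%d) rows do not sum to 1", l, h)
    }
  }
  structure(list(n_layers = length(matrices),
                 n_heads = length(matrices[[1L]]),
                 L = L, matrices = matrices),
            class = "attention_stack")
}

#' @export
print.attention_stack <- function(x, ...) {
  cat(sprintf("attention_stack: %d layers x %d heads, L = %d\n",
              x$n_layers, x$n_heads, x$L))
  invisible(x)
}

#' Generate a row-stochastic attention stack with planted interacting pairs
#'
#' Background attention is i.i.d. exponential weight, row-normalized; cells
#' between planted protein pairs (both orientations) are scaled by `snr`
#' before normalization, so their expected mass is `snr` times a background
#' inter-protein cell's.
#'
#' @param genome A [genome_record()].
#' @param planted_pairs Two-column matrix (or list of length-2 vectors) of
#'   0-based protein ordinal pairs to elevate; `i != j`.
#' @param snr Signal-to-noise ratio (> 1).
#' @param n_layers,n_heads Stack dimensions.
#' @param seed Integer seed.
#' @return An [attention_stack()] over the genome's unpadded length.
#' @export
plant_attention <- function(genome, planted_pairs, snr = 5,
                            n_layers = 4L, n_heads = 4L, seed = 0L) {
  vb_assert(snr > 1, "snr must be > 1")
  if (is.list(planted_pairs)) planted_pairs <- do.call(rbind, planted_pairs)
  planted_pairs <- matrix(as.integer(planted_pairs), ncol = 2L)
  n_prot <- nrow(genome$proteins)
  vb_assert(all(planted_pairs >= 0L & planted_pairs < n_prot),
            "planted ordinal out of range 0..%d", n_prot - 1L)
  vb_assert(all(planted_pairs[, 1L] != planted_pairs[, 2L]),
            "planted pairs must have i != j")
  L <- genome$total_length
  boost <- matrix(1, L, L)
  pr <- genome$proteins
  for (r in seq_len(nrow(planted_pairs))) {
    a <- planted_pairs[r, 1L] + 1L; b <- planted_pairs[r, 2L] + 1L
    ia <- pr$start[a]:pr$end[a]; ib <- pr$start[b]:pr$end[b]
    boost[ia, ib] <- snr
    boost[ib, ia] <- snr
  }
  with_seed(seed, {
    mats <- lapply(seq_len(n_layers), function(l) {
      lapply(seq_len(n_heads), function(h) {
        W <- matrix(stats::rexp(L * L), L, L) * boost
        W / rowSums(W)
      })
    })
    attention_stack(mats)
  })
}

#' Generate random Gaussian query/key/value tensors
#'
#' @param n_tokens Padded sequence length.
#' @param d_k Per-head key dimensionality.
#' @param n_heads Number of heads.
#' @param seed Integer seed.
#' @return Object of class `attention_inputs`: list with arrays `Q`, `K`, `V`
#'   of dim `(n_heads, n_tokens, d_k)` of standard-normal entries, and `d_k`.
#' @export
make_qkv <- function(n_tokens, d_k, n_heads, seed = 0L) {
  vb_assert(n_tokens >= 1L && d_k >= 1L && n_heads >= 1L,
            "n_tokens, d_k and n_heads must all be >= 1")
  with_seed(seed, {
    dims <- c(n_heads, n_tokens, d_k)
    structure(list(Q = array(stats::rnorm(prod(dims)), dims),
                   K = array(stats::rnorm(prod(dims)), dims),
                   V = array(stats::rnorm(prod(dims)), dims),
                   d_k = as.integer(d_k)),
              class = "attention_inputs")
  })
}

#' Generate a partner-dependent masked-token task
#'
#' Each genome holds `n_proteins` proteins of equal length; one designated
#' non-adjacent protein pair shares a copied motif (a fresh random motif per
#' genome) at a fixed offset, all other content is i.i.d. random. The masked
#' positions are the motif residues of the second partner, so their targets
#' are recoverable only by reading the first partner.
#'
#' @param n_genomes Number of task genomes.
#' @param motif_len Motif length (>= 1, <= protein_len).
#' @param seed Integer seed.
#' @param n_proteins Proteins per genome (>= 3, so a non-adjacent pair exists).
#' @param protein_len Length of every protein.
#' @param pair 0-based ordinals of the designated pair; must be non-adjacent.
#' @return Object of class `partner_task`: list with `items` (each a list of
#'   `genome`, `pair`, `masked_positions` — 1-based positions in the unpadded
#'   concatenation — and `targets`, the masked residues), plus the task
#'   parameters.
#' @export
make_partner_task <- function(n_genomes, motif_len = 12L, seed = 0L,
                              n_proteins = 5L, protein_len = 32L,
                              pair = c(1L, 3L)) {
  vb_assert(motif_len >= 1L && motif_len <= protein_len,
            "motif_len must be in 1..protein_len")
  vb_assert(n_proteins >= 3L,
            "genome too small to host a non-adjacent pair (need >= 3 proteins)")
  pair <- sort(as.integer(pair))
  vb_assert(pair[2L] - pair[1L] >= 2L, "designated pair must be non-adjacent")
  vb_assert(pair[1L] >= 0L && pair[2L] < n_proteins,
            "pair ordinals out of range 0..%d", n_proteins - 1L)
  with_seed(seed, {
    items <- lapply(seq_len(n_genomes), function(gi) {
      seqs <- vapply(seq_len(n_proteins), function(p) {
        paste(sample(AA_CANONICAL, protein_len, replace = TRUE), collapse = "")
      }, "")
      motif <- sample(AA_CANONICAL, motif_len, replace = TRUE)
      put_motif <- function(s) {
        ch <- strsplit(s, "", fixed = TRUE)[[1L]]
        ch[seq_len(motif_len)] <- motif
        paste(ch, collapse = "")
      }
      seqs[pair[1L] + 1L] <- put_motif(seqs[pair[1L] + 1L])
      seqs[pair[2L] + 1L] <- put_motif(seqs[pair[2L] + 1L])
      g <- genome_record(sprintf("task%04d", gi),
                         protein_id = sprintf("p%02d", seq_len(n_proteins) - 1L),
                         ordinal = seq_len(n_proteins) - 1L,
                         sequence = seqs)
      masked <- g$proteins$start[pair[2L] + 1L] + seq_len(motif_len) - 1L
      list(genome = g, pair = pair, masked_positions = masked, targets = motif)
    })
    structure(list(items = items, n_proteins = n_proteins,
                   protein_len = protein_len, motif_len = motif_len,
                   pair = pair, seed = as.integer(seed)),
              class = "partner_task")
  })
}
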