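# Block mask construction, BSR layout invariants, ALiBi slopes, and the
# block-sparse attention kernel against the dense masked-softmax oracle.

# second, fully independent dense implementation: per-row loops, no matrix
# algebra shared with the package's oracle
dense_reference_loops <- function(inputs, dense_mask, slopes = NULL) {
  d <- dim(inputs$Q); H <- d[1]; Lp <- d[2]; dk <- d[3]
  out <- array(0, d)
  for (h in seq_len(H)) {
    for (i in seq_len(Lp)) {
      keys <- which(dense_mask[i, ])
      if (length(keys) == 0) next
      sc <- vapply(keys, function(j) {
        s <- sum(inputs$Q[h, i, ] * inputs$K[h, j, ]) / sqrt(dk)
        if (!is.null(slopes)) s <- s - slopes[h] * abs(i - j)
        s
      }, 0)
      w <- exp(sc - max(sc)); w <- w / sum(w)
      for (m in seq_along(keys)) {
        out[h, i, ] <- out[h, i, ] + w[m] * inputs$V[h, keys[m], ]
      }
    }
  }
  out
}

test_that("block mask implements the self/adjacent/ppi policy exactly", {
  # 1 protein of 64 aa: full 2x2 intra
  lay <- segment_genome(toy_genome(64L), 32)
  m <- build_block_mask(lay, NULL)
  expect_equal(length(m$col_ind), 4L)
  expect_true(all(m$origin == "self"))

  # 3 single-block proteins, ppi (0,2): 3 self + 4 adjacent + 2 ppi
  lay3 <- segment_genome(toy_genome(c(32L, 32L, 32L)), 32)
  m3 <- build_block_mask(lay3, data.frame(I = 0L, J = 2L))
  expect_equal(length(m3$col_ind), 9L)
  expect_equal(as.integer(table(factor(m3$origin,
                                       c("self", "adjacent", "ppi")))),
               c(3L, 4L, 2L))

  # interacting proteins with n1, n2 blocks add 2 * n1 * n2 ppi blocks
  layb <- segment_genome(toy_genome(c(64L, 32L, 96L)), 32)
  base <- build_block_mask(layb, NULL)
  with_ppi <- build_block_mask(layb, data.frame(I = 0L, J = 2L))
  expect_equal(length(with_ppi$col_ind) - length(base$col_ind), 2L * 2L * 3L)

  expect_error(build_block_mask(lay3, data.frame(I = 0L, J = 7L)),
               "unknown protein ordinal")
})

test_that("BSR layout is well-formed and block-symmetric", {
  g <- make_synthetic_genome(6, c(20, 70), seed = 1)
  lay <- segment_genome(g, 32)
  m <- build_block_mask(lay, data.frame(I = c(0L, 1L), J = c(3L, 5L)))
  expect_equal(length(m$row_ptr), m$n_block_rows + 1L)
  expect_true(all(diff(m$row_ptr) >= 0))
  expect_equal(m$row_ptr[m$n_block_rows + 1L] - 1L, length(m$col_ind))
  stored <- cbind(rep(seq_len(m$n_block_rows), diff(m$row_ptr)), m$col_ind)
  for (r in seq_len(m$n_block_rows)) {
    cols <- bsr_row_cols(m, r)
    expect_true(all(diff(cols) > 0))  # strictly increasing within a row
  }
  # symmetry: (r, c) stored iff (c, r) stored
  key <- paste(stored[, 1], stored[, 2])
  rkey <- paste(stored[, 2], stored[, 1])
  expect_setequal(key, rkey)
})

test_that("alibi slopes follow the halving schedule and bias is translation-invariant", {
  s <- alibi_slopes(8)
  expect_equal(s, 2^-(1:8))
  expect_true(all(diff(s) < 0))
  expect_true(all(s > 0))
  expect_error(alibi_slopes(0), ">= 1")
  # bias at distance 0 is 0 and depends only on |i - j| by construction
  expect_equal(-s[3] * abs(17 - 17), 0)
  expect_equal(-s[2] * abs(10 - 14), -s[2] * abs(110 - 114))
})

test_that("full mask without bias equals unmasked dense attention", {
  lay <- segment_genome(toy_genome(c(32L, 32L)), 32)
  full <- build_block_mask(lay, NULL)  # 2 proteins: self+adjacent = full
  inp <- make_qkv(64, 8, 2, seed = 1)
  sp <- block_sparse_attention(inp, full, lay)
  for (h in 1:2) {
    S <- matrix(inp$Q[h, , ], 64, 8) %*% t(matrix(inp$K[h, , ], 64, 8)) / sqrt(8)
    P <- exp(S - apply(S, 1, max)); P <- P / rowSums(P)
    expect_equal(sp[h, , ], P %*% matrix(inp$V[h, , ], 64, 8),
                 tolerance = 1e-12)
  }
})

test_that("uniform softmax limit: identical keys average the value rows", {
  lay <- segment_genome(toy_genome(40L), 32)  # 40 aa -> 2 blocks, 24 PAD
  m <- build_block_mask(lay, NULL)
  inp <- make_qkv(64, 4, 1, seed = 2)
  inp$K[1, , ] <- matrix(1, 64, 4)  # identical K rows -> uniform weights
  out <- block_sparse_attention(inp, m, lay)
  np <- non_pad_positions(lay)
  expected <- colMeans(matrix(inp$V[1, np, ], length(np), 4))
  for (q in np) expect_equal(out[1, q, ], expected, tolerance = 1e-12)
})

test_that("package oracle agrees with an independent loop implementation", {
  withr::with_seed(3, {
    for (rep in 1:10) {
      g <- make_synthetic_genome(sample(2:4, 1), c(10, 40),
                                 seed = sample(1e6, 1))
      lay <- segment_genome(g, 32)
      m <- build_block_mask(lay, NULL)
      inp <- make_qkv(lay$padded_length, 4, 2, seed = sample(1e6, 1))
      slopes <- if (rep %% 2 == 0) alibi_slopes(2) else NULL
      dm <- dense_mask_from_bsr(m, lay)
      expect_equal(dense_masked_attention_oracle(inp, dm, slopes),
                   dense_reference_loops(inp, dm, slopes), tolerance = 1e-7)
    }
  })
})

test_that("delta softmax: one allowed key returns that key's value row", {
  lay <- segment_genome(toy_genome(32L), 32)
  inp <- make_qkv(32, 4, 1, seed = 4)
  dm <- matrix(FALSE, 32, 32)
  dm[cbind(1:32, c(2:32, 1))] <- TRUE
  out <- dense_masked_attention_oracle(inp, dm)
  for (i in 1:32) {
    expect_equal(out[1, i, ], inp$V[1, ifelse(i == 32, 1, i + 1), ])
  }
})

test_that("block-sparse attention equals the dense oracle on random instances", {
  # random sizes, random extra ppi masks, with and without ALiBi
  withr::with_seed(5, {
    for (rep in 1:25) {
      n_prot <- sample(2:6, 1)
      g <- make_synthetic_genome(n_prot, c(10, 60), seed = sample(1e6, 1))
      lay <- segment_genome(g, 32)
      ppi <- NULL
      nonadj <- which(upper.tri(diag(n_prot)), arr.ind = TRUE) - 1L
      nonadj <- nonadj[nonadj[, 2] - nonadj[, 1] >= 2, , drop = FALSE]
      if (nrow(nonadj) > 0) {
        take <- sample(nrow(nonadj), sample(0:min(2, nrow(nonadj)), 1))
        if (length(take) > 0) {
          ppi <- data.frame(I = nonadj[take, 1], J = nonadj[take, 2])
        }
      }
      m <- build_block_mask(lay, ppi)
      dk <- sample(c(8L, 16L, 32L), 1)
      H <- sample(1:4, 1)
      inp <- make_qkv(lay$padded_length, dk, H, seed = sample(1e6, 1))
      slopes <- if (runif(1) < 0.5) alibi_slopes(H) else NULL
      sp <- block_sparse_attention(inp, m, lay, slopes)
      de <- dense_masked_attention_oracle(inp, dense_mask_from_bsr(m, lay),
                                          slopes)
      keep <- non_pad_positions(lay)
      expect_lt(max(abs(sp[, keep, , drop = FALSE] -
                          de[, keep, , drop = FALSE])), 1e-5)
    }
  })
})

test_that("recovered attention weights over allowed keys sum to one", {
  g <- make_synthetic_genome(3, c(30, 50), seed = 6)
  lay <- segment_genome(g, 32)
  m <- build_block_mask(lay, data.frame(I = 0L, J = 2L))
  inp <- make_qkv(lay$padded_length, 8, 2, seed = 7)
  # probe with one-hot V columns: output row sums recover total weight
  probe <- inp
  probe$V <- array(1, dim(inp$V))
  out <- block_sparse_attention(probe, m, lay)
  np <- non_pad_positions(lay)
  expect_lt(max(abs(out[, np, 1] - 1)), 1e-6)
})

test_that("masking monotonicity: dropping a block pair leaves other rows unchanged", {
  lay <- segment_genome(toy_genome(c(32L, 32L, 32L, 32L)), 32)
  m_with <- build_block_mask(lay, data.frame(I = 0L, J = 2L))
  m_without <- build_block_mask(lay, NULL)
  inp <- make_qkv(lay$padded_length, 8, 2, seed = 8)
  o1 <- block_sparse_attention(inp, m_with, lay)
  o2 <- block_sparse_attention(inp, m_without, lay)
  # rows of proteins 1 and 3 (blocks 2 and 4) have unchanged key sets
  unchanged <- c(block_positions(lay, 2), block_positions(lay, 4))
  expect_equal(o1[, unchanged, ], o2[, unchanged, ])
  # rows of protein 0 changed (their key set shrank)
  expect_gt(max(abs(o1[, block_positions(lay, 1), ] -
                      o2[, block_positions(lay, 1), ])), 1e-8)
})

test_that("analytic gradients match finite differences", {
  g <- make_synthetic_genome(2, c(20, 30), seed = 9)
  lay <- segment_genome(g, 32)
  m <- build_block_mask(lay, NULL)
  inp <- make_qkv(lay$padded_length, 4, 2, seed = 10)
  slopes <- alibi_slopes(2)
  withr::with_seed(11, W <- array(rnorm(prod(dim(inp$Q))), dim(inp$Q)))
  W[, is.na(lay$position_map$ordinal), ] <- 0  # PAD outputs are discarded
  f <- function(inputs) sum(block_sparse_attention(inputs, m, lay, slopes) * W)
  an <- block_sparse_attention_vjp(inp, m, lay, W, slopes)
  eps <- 1e-6
  withr::with_seed(12, {
    for (nm in c("Q", "K", "V")) {
      for (rep in 1:8) {
        i <- sample(length(inp[[nm]]), 1)
        ip <- inp; ip[[nm]][i] <- ip[[nm]][i] + eps
        im <- inp; im[[nm]][i] <- im[[nm]][i] - eps
        fd <- (f(ip) - f(im)) / (2 * eps)
        a <- an[[paste0("d", nm)]][i]
        expect_lt(abs(fd - a) / max(abs(fd), abs(a), 1e-8), 1e-4)
      }
    }
  })
})

test_that("padding removal restores residue dimensions and round-trips", {
  lay0 <- segment_genome(toy_genome(c(32L, 64L)), 32)  # zero padding
  x <- matrix(rnorm(96 * 3), 96)
  expect_equal(remove_padding(x, lay0), x)

  lay <- segment_genome(toy_genome(33L), 32)
  y <- matrix(rnorm(64 * 2), 64)
  expect_equal(nrow(remove_padding(y, lay)), 33L)

  g <- make_synthetic_genome(4, c(10, 50), seed = 13)
  lay2 <- segment_genome(g, 32)
  z <- matrix(rnorm(g$total_length * 5), g$total_length)
  expect_equal(remove_padding(expand_padding(z, lay2), lay2), z)
  expect_error(remove_padding(matrix(0, 10, 2), lay2), "match")
})

test_that("sparsity stats count stored versus dense blocks", {
  lay <- segment_genome(toy_genome(rep(32L, 10)), 32)
  st <- sparsity_stats(build_block_mask(lay, NULL), lay)
  expect_equal(st$stored_blocks, 28L)
  expect_equal(st$dense_blocks, 100)
  expect_equal(st$fraction, 0.28)
  st2 <- sparsity_stats(build_block_mask(lay, data.frame(I = 0L, J = 5L)), lay)
  expect_equal(st2$stored_blocks, 30L)
  # full mask on a 2-protein genome
  lay2 <- segment_genome(toy_genome(c(32L, 32L)), 32)
  expect_equal(sparsity_stats(build_block_mask(lay2, NULL), lay2)$fraction, 1.0)
})

test_that("BSR masks serialize to manifest + binary and back", {
  g <- make_synthetic_genome(5, c(20, 70), seed = 14)
  lay <- segment_genome(g, 32)
  m <- build_block_mask(lay, data.frame(I = 1L, J = 4L))
  prefix <- file.path(withr::local_tempdir(), "mask")
  write_bsr_mask(m, prefix)
  expect_equal(read_bsr_mask(prefix), m, ignore_attr = TRUE)
})
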