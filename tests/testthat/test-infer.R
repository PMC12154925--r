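# Stage-1 interaction inference: APC, quantile selection, pair scores,
# top-k selection and retention curves, each against independent oracles.

# explicit double-loop evaluation of the APC formula, kept deliberately
# naive and separate from the vectorized implementation
apc_oracle <- function(M) {
  L <- nrow(M)
  tot <- sum(M)
  N <- matrix(0, L, L)
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      apc_ij <- sum(M[i, ]) * sum(M[, j]) / tot
      apc_ji <- sum(M[j, ]) * sum(M[, i]) / tot
      N[i, j] <- ((M[i, j] - apc_ij) + (M[j, i] - apc_ji)) / 2
    }
  }
  N
}

test_that("apc_correct matches the double-loop oracle and known values", {
  M <- matrix(1:9, 3, byrow = TRUE)
  N <- apc_correct(M)
  expect_equal(N[1, 1], -0.6)
  expect_equal(N[1, 2], 0.0)
  expect_equal(N, apc_oracle(M))
  withr::with_seed(11, {
    for (rep in 1:5) {
      M <- matrix(runif(36), 6)
      expect_equal(apc_correct(M), apc_oracle(M), tolerance = 1e-12)
    }
  })
})

test_that("APC of a constant matrix is zero and all-zero input errors", {
  expect_equal(apc_correct(matrix(3.5, 4, 4)), matrix(0, 4, 4))
  expect_error(apc_correct(matrix(0, 3, 3)), "all-zero")
})

test_that("corrected matrices are symmetric with zero margins", {
  withr::with_seed(42, {
    for (rep in 1:100) {
      M <- random_stochastic(sample(3:12, 1))
      N <- apc_correct(M)
      expect_lt(max(abs(N - t(N))), 1e-12)
      expect_lt(max(abs(rowSums(N))), 1e-9)
      expect_lt(max(abs(colSums(N))), 1e-9)
    }
  })
})

test_that("aggregate_heads reduces over layers and heads as documented", {
  g <- make_synthetic_genome(3, c(5, 8), seed = 1)
  L <- g$total_length
  withr::with_seed(2, {
    M1 <- random_stochastic(L); M2 <- random_stochastic(L)
  })
  single <- attention_stack(list(list(M1)))
  expect_equal(aggregate_heads(single, "mean"), apc_correct(M1),
               ignore_attr = TRUE)
  twin <- attention_stack(list(list(M1, M1)))
  expect_equal(aggregate_heads(twin, "mean"), aggregate_heads(twin, "per_head_max"),
               ignore_attr = TRUE)
  st <- attention_stack(list(list(M1, M2)))
  expect_true(all(aggregate_heads(st, "mean") <=
                    aggregate_heads(st, "per_head_max") + 1e-12))
})

test_that("quantile selection is nearest-rank with strict inequality", {
  withr::with_seed(3, P <- matrix(sample(1:16), 4))
  s <- select_top_quantile(P, 25)
  expect_equal(nrow(s$pairs), 4L)
  expect_setequal(s$values, 13:16)
  expect_equal(sort(s$scores), c(0, 1/3, 2/3, 1))
  # constant matrix: strict > never holds
  expect_equal(nrow(select_top_quantile(matrix(1, 3, 3), 50)$pairs), 0L)
  # t = 100: everything except the unique minimum
  s100 <- select_top_quantile(P, 100)
  expect_equal(nrow(s100$pairs), 15L)
  expect_false(1 %in% s100$values)
  expect_error(select_top_quantile(P, 0), "\\(0, 100\\]")
  expect_error(select_top_quantile(P, 101), "\\(0, 100\\]")
})

test_that("selected-set size obeys the quantile bound on distinct values", {
  withr::with_seed(4, {
    for (rep in 1:20) {
      L <- sample(4:12, 1)
      N <- matrix(sample(seq_len(L^2)), L)  # distinct values
      t <- runif(1, 1, 99)
      s <- select_top_quantile(N, t)
      expect_true(nrow(s$pairs) %in%
                    c(floor(t / 100 * L^2), ceiling(t / 100 * L^2)))
    }
  })
})

test_that("minmax scores rescale linearly with the degenerate-case rule", {
  expect_equal(minmax_scores(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(minmax_scores(5), 1.0)
  expect_equal(minmax_scores(c(3, 3, 3)), c(1, 1, 1))
  withr::with_seed(5, v <- rnorm(50))
  expect_equal(order(minmax_scores(v)), order(v))
  expect_error(minmax_scores(numeric(0)), "empty")
})

test_that("pair scores match an exhaustive double-loop oracle", {
  g <- make_synthetic_genome(4, c(4, 9), seed = 6, genome_id = "t4")
  L <- g$total_length
  withr::with_seed(7, N <- apc_correct(random_stochastic(L)))
  sel <- select_top_quantile(N, 20)
  tab <- pair_interaction_scores(g, sel)

  # oracle: loop over every residue pair of every protein pair
  score_of <- matrix(NA_real_, L, L)
  score_of[sel$pairs] <- sel$scores
  pr <- g$proteins
  for (r in seq_len(nrow(tab))) {
    I <- tab$I[r] + 1L; J <- tab$J[r] + 1L
    acc <- 0
    for (i in pr$start[I]:pr$end[I]) {
      for (j in pr$start[J]:pr$end[J]) {
        if (!is.na(score_of[i, j])) acc <- acc + score_of[i, j]
      }
    }
    expect_equal(tab$A[r], acc / (pr$length[I] * pr$length[J]))
  }
  # structural invariants
  expect_equal(sort(tab$rank), seq_len(nrow(tab)))
  expect_equal(tab$total[1], choose(4, 2))
  expect_true(all(tab$A >= 0 & tab$A <= 1))
  expect_true(all(tab$rel_rank > 0 & tab$rel_rank <= 1))
  expect_equal(tab$adjacent, tab$J - tab$I == 1L)
})

test_that("pairs with no selected cells score zero", {
  g <- toy_genome(c(5L, 5L, 5L))
  sel <- structure(list(t = 10, threshold = 0,
                        pairs = cbind(i = 1L, j = 7L), values = 1,
                        scores = 1),
                   class = "selected_pairs")
  tab <- pair_interaction_scores(g, sel)
  expect_equal(tab$A[tab$I == 0 & tab$J == 2], 0)
  expect_equal(tab$A[tab$I == 0 & tab$J == 1], 1 / 25)
})

test_that("select_interactions keeps top-k non-adjacent pairs only", {
  tab <- data.frame(I = c(0L, 0L, 1L, 0L), J = c(2L, 3L, 3L, 1L),
                    A = c(0.9, 0.5, 0.7, 0.95),
                    adjacent = c(FALSE, FALSE, FALSE, TRUE))
  tab <- tab[order(-tab$A), ]
  tab$rank <- seq_len(4); tab$total <- 4L; tab$rel_rank <- tab$rank / 4
  sel <- select_interactions(tab, 2)
  expect_equal(nrow(sel), 2L)
  expect_setequal(paste(sel$I, sel$J), c("0 2", "1 3"))
  # 2-protein genome: only pair is adjacent -> empty set
  tab2 <- data.frame(I = 0L, J = 1L, A = 1, adjacent = TRUE, rank = 1L,
                     total = 1L, rel_rank = 1)
  expect_equal(nrow(select_interactions(tab2, 50)), 0L)
})

test_that("retention curve counts ranks under thresholds and saturates", {
  rc <- retention_curve(c(3, 12, 60), c(10, 50, 100))
  expect_equal(rc$retained_pct, c(100 / 3, 200 / 3, 100))
  expect_equal(retention_curve(c(2, 5), 5)$retained_pct, 100)
  withr::with_seed(8, {
    ranks <- sample(1:200, 40, replace = TRUE)
    rc <- retention_curve(ranks)
    expect_equal(rc$threshold, c(10L, 20L, 35L, 50L, 100L))
    expect_true(all(diff(rc$retained_pct) >= 0))
    expect_true(all(rc$retained_pct <= 100))
  })
  expect_error(retention_curve(integer(0)), "empty")
})

test_that("infer_interactions recovers planted pairs end to end", {
  g <- make_synthetic_genome(8, c(15, 30), seed = 9, genome_id = "pl")
  planted <- rbind(c(0L, 4L), c(2L, 6L))
  st <- plant_attention(g, planted, snr = 8, n_layers = 2, n_heads = 2,
                        seed = 10)
  fit <- infer_interactions(st, g, t = 10, k = 2)
  expect_s3_class(fit, "ppi_fit")
  expect_setequal(paste(fit$selected$I, fit$selected$J),
                  paste(planted[, 1], planted[, 2]))
  expect_output(print(fit), "ppi_fit")
})
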