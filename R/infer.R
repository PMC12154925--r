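# Stage 1: attention-derived protein-protein interaction inference.
#
# Per-head token attention maps are corrected with Average Product Correction
# (APC) and symmetrized, reduced across layers/heads, thresholded at an upper
# quantile into a selected cell set S, min-max scored, and aggregated into a
# per-protein-pair score A from which the top-k non-adjacent pairs are taken
# as putative interactions.

#' Average Product Correction of an attention matrix
#'
#' Computes `N = (M - APC + t(M - APC)) / 2` where
#' `APC[i, j] = rowsum_i * colsum_j / total`. APC removes the background
#' signal carried by promiscuously attending positions; the corrected matrix
#' is symmetric and every row and column sums to zero analytically.
#'
#' @param M Square nonnegative matrix with positive total sum.
#' @return Corrected, symmetrized matrix of the same dimension.
#' @examples
#' apc_correct(matrix(1:9, 3, byrow = TRUE))
#' @export
apc_correct <- function(M) {
  vb_assert(is.matrix(M) && nrow(M) == ncol(M), "M must be square")
  vb_assert(all(M >= 0), "M must be nonnegative")
  tot <- sum(M)
  vb_assert(tot > 0, "M must have positive total sum (all-zero input)")
  apc <- outer(rowSums(M), colSums(M)) / tot
  D <- M - apc
  (D + t(D)) / 2
}

#' Reduce an attention stack to one corrected matrix
#'
#' Applies [apc_correct()] to every (layer, head) matrix and reduces
#' elementwise across them.
#'
#' @param stack An [attention_stack()].
#' @param mode `"mean"` (default) or `"per_head_max"`.
#' @return L x L corrected matrix with attribute `aggregation` describing the
#'   reduction.
#' @export
aggregate_heads <- function(stack, mode = c("mean", "per_head_max")) {
  mode <- match.arg(mode)
  vb_assert(inherits(stack, "attention_stack"), "stack must be an attention_stack")
  vb_assert(stack$n_layers >= 1L && stack$n_heads >= 1L, "empty attention stack")
  acc <- NULL
  n <- 0L
  for (l in seq_len(stack$n_layers)) {
    for (h in seq_len(stack$n_heads)) {
      N <- apc_correct(stack$matrices[[l]][[h]])
      if (is.null(acc)) {
        acc <- N
      } else if (mode == "mean") {
        acc <- acc + N
      } else {
        acc <- pmax(acc, N)
      }
      n <- n + 1L
    }
  }
  if (mode == "mean") acc <- acc / n
  attr(acc, "aggregation") <- sprintf("%s over %d layers x %d heads",
                                      mode, stack$n_layers, stack$n_heads)
  acc
}

#' Select the top t% of corrected attention cells
#'
#' The selected set S holds every cell of `N` whose value is strictly greater
#' than the nearest-rank empirical `(1 - t/100)` quantile of all L^2 entries;
#' selected values are min-max normalized into scores in `[0, 1]`.
#'
#' @param N Corrected attention matrix (square).
#' @param t Percentage in (0, 100].
#' @return Object of class `selected_pairs`: list with `t`, `threshold` (the
#'   quantile value q), `pairs` (two-column matrix of 1-based cell indices),
#'   `values` and `scores`.
#' @export
select_top_quantile <- function(N, t = 10) {
  vb_assert(is.matrix(N) && nrow(N) == ncol(N), "N must be square")
  vb_assert(t > 0 && t <= 100, "t must lie in (0, 100]")
  vals <- sort(as.vector(N))
  m <- length(vals)
  q <- vals[max(1L, ceiling((1 - t / 100) * m))]
  sel <- which(N > q, arr.ind = TRUE)
  dimnames(sel) <- list(NULL, c("i", "j"))
  v <- N[sel]
  structure(list(t = t, threshold = q, pairs = sel, values = v,
                 scores = if (length(v) > 0L) minmax_scores(v) else numeric(0)),
            class = "selected_pairs")
}

#' @export
print.selected_pairs <- function(x, ...) {
  cat(sprintf("selected_pairs: t=%g%%, threshold=%.6g, |S|=%d\n",
              x$t, x$threshold, nrow(x$pairs)))
  invisible(x)
}

#' Min-max normalize a set of values into scores
#'
#' `score(x) = (x - min) / (max - min)`; if all values are equal every score
#' is 1 (every selected value attains the maximum).
#'
#' @param values Nonempty numeric vector.
#' @return Scores in `[0, 1]`, same length and order.
#' @export
minmax_scores <- function(values) {
  vb_assert(length(values) > 0L, "cannot min-max normalize an empty set")
  lo <- min(values); hi <- max(values)
  if (hi == lo) return(rep(1, length(values)))
  (values - lo) / (hi - lo)
}

#' Aggregate selected cells into protein-pair interaction scores
#'
#' For each unordered protein pair (I, J), `A = sum(score(i, j)) / (n_I *
#' n_J)` over selected cells with residue i in protein I and j in protein J
#' (one orientation; the selected set is symmetric). Pairs with no selected
#' cells get A = 0. Rows are ranked by descending A, ties broken by (I, J)
#' lexicographic order.
#'
#' @param genome A [genome_record()].
#' @param selected A `selected_pairs` over the genome's unpadded length.
#' @return Object of classes `pair_score_table`/`data.frame` with columns
#'   `I`, `J` (0-based ordinals, I < J), `A`, `adjacent` (J == I + 1),
#'   `rank`, `total`, `rel_rank` (= rank / total).
#' @export
pair_interaction_scores <- function(genome, selected) {
  n_prot <- nrow(genome$proteins)
  lens <- genome$proteins$length
  L <- genome$total_length
  pairs <- selected$pairs
  if (nrow(pairs) > 0L) {
    vb_assert(all(pairs >= 1L & pairs <= L),
              "selected token index out of genome range 1..%d", L)
  }
  # accumulate score sums per ordered (protI < protJ) cell orientation
  acc <- matrix(0, n_prot, n_prot)
  if (nrow(pairs) > 0L) {
    pi_ <- token_protein(genome, pairs[, 1L])
    pj_ <- token_protein(genome, pairs[, 2L])
    keep <- pi_ < pj_
    if (any(keep)) {
      sums <- rowsum(selected$scores[keep],
                     group = pi_[keep] * n_prot + pj_[keep])
      g <- as.integer(rownames(sums))
      acc[cbind(g %/% n_prot + 1L, g %% n_prot + 1L)] <- sums[, 1L]
    }
  }
  idx <- which(upper.tri(acc), arr.ind = TRUE)
  I <- idx[, 1L] - 1L
  J <- idx[, 2L] - 1L
  A <- acc[idx] / (lens[idx[, 1L]] * lens[idx[, 2L]])
  ord <- order(-A, I, J)
  tab <- data.frame(I = I, J = J, A = A, adjacent = (J - I == 1L))[ord, ]
  tab$rank <- seq_len(nrow(tab))
  tab$total <- nrow(tab)
  tab$rel_rank <- tab$rank / tab$total
  rownames(tab) <- NULL
  class(tab) <- c("pair_score_table", "data.frame")
  tab
}

#' Select the top-k non-adjacent interacting pairs
#'
#' Genomically adjacent proteins attend strongly to each other regardless of
#' function and are always allowed in the attention mask, so only
#' non-consecutive pairs compete for the interaction budget.
#'
#' @param table A `pair_score_table`.
#' @param k Selection budget; default 50.
#' @return Object of classes `interaction_set`/`data.frame`: the k highest-A
#'   non-adjacent rows (fewer if fewer exist), columns `I`, `J`, `A`, `rank`.
#' @export
select_interactions <- function(table, k = 50L) {
  vb_assert(k >= 0L, "k must be >= 0")
  cand <- table[!table$adjacent, , drop = FALSE]
  cand <- cand[order(cand$rank), , drop = FALSE]
  out <- utils::head(cand[, c("I", "J", "A", "rank")], k)
  rownames(out) <- NULL
  class(out) <- c("interaction_set", "data.frame")
  out
}

#' Retention of designated pairs under rank-selection thresholds
#'
#' For each threshold X, the percentage of designated pairs whose rank among
#' non-adjacent pairs is at most X. Used to choose the interaction budget k.
#'
#' @param ranks Integer vector of designated-pair ranks (>= 1), pooled over
#'   genomes.
#' @param thresholds Integer thresholds; default the grid `c(10, 20, 35, 50,
#'   100)`.
#' @return Data frame with columns `threshold` and `retained_pct` (0..100),
#'   monotone non-decreasing in `threshold`.
#' @export
retention_curve <- function(ranks, thresholds = c(10L, 20L, 35L, 50L, 100L)) {
  vb_assert(length(ranks) > 0L, "empty rank list")
  vb_assert(all(ranks >= 1L), "ranks must be >= 1")
  thresholds <- sort(as.integer(thresholds))
  pct <- vapply(thresholds, function(x) 100 * mean(ranks <= x), 0)
  data.frame(threshold = thresholds, retained_pct = pct)
}

#' Infer putative protein-protein interactions from an attention stack
#'
#' Runs the full stage-1 pipeline: APC correction and head/layer reduction,
#' upper-quantile cell selection with min-max scoring, per-pair aggregation,
#' and top-k selection among non-adjacent pairs.
#'
#' @param stack An [attention_stack()] over the genome's unpadded length.
#' @param genome The matching [genome_record()].
#' @param t Upper-quantile percentage for cell selection; default 10.
#' @param agg Head/layer reduction, `"mean"` or `"per_head_max"`.
#' @param k Interaction budget (top-k non-adjacent pairs); default 50.
#' @return Object of class `ppi_fit`: list with the pair score `table`, the
#'   `selected` interaction set, the selection `threshold`, and the call
#'   parameters.
#' @examples
#' g <- make_synthetic_genome(6, c(20, 30), seed = 1)
#' st <- plant_attention(g, rbind(c(0, 3)), snr = 8, n_layers = 2,
#'                       n_heads = 2, seed = 2)
#' fit <- infer_interactions(st, g, t = 10, k = 3)
#' print(fit)
#' @export
infer_interactions <- function(stack, genome, t = 10, agg = "mean", k = 50L) {
  vb_assert(stack$L == genome$total_length,
            "attention stack L = %d does not match genome length %d",
            stack$L, genome$total_length)
  N <- aggregate_heads(stack, mode = agg)
  sel <- select_top_quantile(N, t = t)
  tab <- pair_interaction_scores(genome, sel)
  structure(list(genome_id = genome$genome_id,
                 table = tab,
                 selected = select_interactions(tab, k = k),
                 threshold = sel$threshold,
                 n_selected_cells = nrow(sel$pairs),
                 t = t, agg = agg, k = as.integer(k)),
            class = "ppi_fit")
}

#' @export
print.ppi_fit <- function(x, ...) {
  cat(sprintf("ppi_fit for genome '%s'\n", x$genome_id))
  cat(sprintf("  %d protein pairs scored; t = %g%%, aggregation = %s\n",
              nrow(x$table), x$t, x$agg))
  cat(sprintf("  %d selected cells above threshold %.4g\n",
              x$n_selected_cells, x$threshold))
  cat(sprintf("  top-%d non-adjacent interactions selected (%d found)\n",
              x$k, nrow(x$selected)))
  invisible(x)
}

#' @method summary ppi_fit
#' @export
summary.ppi_fit <- function(object, ...) {
  cat(sprintf("ppi_fit for genome '%s'\n", object$genome_id))
  cat("Selected non-adjacent interactions:\n")
  print(utils::head(object$selected, 10L))
  cat("Pair score distribution:\n")
  print(summary(object$table$A))
  invisible(object)
}

#' @method plot ppi_fit
#' @export
plot.ppi_fit <- function(x, ...) {
  tab <- x$table
  graphics::plot(tab$rank, tab$A, log = "y",
                 xlab = "rank", ylab = "interaction score A",
                 main = sprintf("Pair scores, genome '%s'", x$genome_id),
                 pch = ifelse(tab$adjacent, 1, 19),
                 col = ifelse(tab$adjacent, "grey50", "firebrick"), ...)
  graphics::legend("topright", pch = c(1, 19), col = c("grey50", "firebrick"),
                   legend = c("adjacent", "non-adjacent"), bty = "n")
  invisible(x)
}

#' Coerce a ppi_fit to the interaction-table file layout
#'
#' @param fit A `ppi_fit`.
#' @param selected_only If TRUE, only the selected top-k interaction set.
#' @return Data frame in the `genome_id i j score rank adjacent` layout
#'   accepted by [write_interaction_table()].
#' @export
as_interaction_table <- function(fit, selected_only = FALSE) {
  src <- if (selected_only) {
    s <- fit$selected
    data.frame(genome_id = fit$genome_id, i = s$I, j = s$J, score = s$A,
               rank = s$rank, adjacent = FALSE)
  } else {
    data.frame(genome_id = fit$genome_id, i = fit$table$I, j = fit$table$J,
               score = fit$table$A, rank = fit$table$rank,
               adjacent = fit$table$adjacent)
  }
  src
}
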