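# Model- and embedding-quality metrics: perplexity, silhouette, pairwise
# distance statistics, k-fold single-layer classification, and pooling of
# token embeddings to protein/genome level.

#' Perplexity of predicted distributions
#'
#' `exp` of the mean negative log-likelihood of the targets. Equals the
#' vocabulary size for a uniform predictor and 1 for perfect one-hot
#' predictions.
#'
#' @param probs Matrix of predicted distributions, one row per position,
#'   columns over the vocabulary; rows must sum to 1 within 1e-6.
#' @param targets Integer vector of target column indices (or character,
#'   matched against `colnames(probs)`).
#' @param floor Optional positive probability floor; without it a zero
#'   probability at a target is an error.
#' @return Positive real, always >= 1 for normalized rows.
#' @export
perplexity <- function(probs, targets, floor = NULL) {
  probs <- rbind(probs)
  vb_assert(max(abs(rowSums(probs) - 1)) <= 1e-6,
            "each predicted distribution must sum to 1")
  if (is.character(targets)) {
    targets <- match(targets, colnames(probs))
    vb_assert(!anyNA(targets), "target not found among vocabulary columns")
  }
  vb_assert(length(targets) == nrow(probs),
            "need one target per distribution row")
  p <- probs[cbind(seq_len(nrow(probs)), targets)]
  if (!is.null(floor)) {
    p <- pmax(p, floor)
  } else {
    vb_assert(all(p > 0), "zero probability at a target position")
  }
  exp(-mean(log(p)))
}

#' Mean silhouette score of labeled embeddings
#'
#' Standard silhouette `s(i) = (b - a) / max(a, b)` under Euclidean distance
#' (a: mean intra-cluster distance, b: nearest other-cluster mean distance);
#' singleton clusters contribute 0. Computed via [cluster::silhouette()].
#'
#' @param embeddings Numeric matrix, one row per item.
#' @param labels Cluster/species labels, one per row; at least 2 distinct.
#' @return Mean silhouette in `[-1, 1]`.
#' @export
silhouette_score <- function(embeddings, labels) {
  embeddings <- as.matrix(embeddings)
  vb_assert(nrow(embeddings) == length(labels),
            "labels must align with embedding rows")
  vb_assert(all(is.finite(embeddings)), "embeddings contain non-finite entries")
  cl <- as.integer(factor(labels))
  vb_assert(length(unique(cl)) >= 2L, "silhouette needs at least 2 labels")
  sil <- cluster::silhouette(cl, stats::dist(embeddings))
  mean(sil[, "sil_width"])
}

#' Pairwise Euclidean distance statistics of sampled embeddings
#'
#' Samples `sample_size` items without replacement (seeded), computes all
#' pairwise Euclidean distances, and summarizes their distribution.
#'
#' @param embeddings Numeric matrix, one row per item (>= 2 rows).
#' @param sample_size Number of items to sample; defaults to all.
#' @param seed Sampling seed.
#' @param breaks Passed to [graphics::hist()]; default `"Sturges"`.
#' @return List with `iqr`, `range` (max minus min distance), `histogram`
#'   (counts/breaks, not plotted) and `n_pairs`.
#' @export
pairwise_distance_stats <- function(embeddings, sample_size = NULL, seed = 0L,
                                    breaks = "Sturges") {
  embeddings <- as.matrix(embeddings)
  n <- nrow(embeddings)
  vb_assert(n >= 2L, "need at least 2 items")
  if (is.null(sample_size)) sample_size <- n
  vb_assert(sample_size >= 2L && sample_size <= n,
            "sample_size must lie in 2..%d", n)
  idx <- with_seed(seed, sort(sample(n, sample_size)))
  d <- as.vector(stats::dist(embeddings[idx, , drop = FALSE]))
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  list(iqr = stats::IQR(d), range = max(d) - min(d),
       histogram = h, n_pairs = length(d))
}

macro_f1 <- function(truth, predicted, levels) {
  f1s <- vapply(levels, function(lv) {
    tp <- sum(predicted == lv & truth == lv)
    fp <- sum(predicted == lv & truth != lv)
    fn <- sum(predicted != lv & truth == lv)
    if (2 * tp + fp + fn == 0) return(0)
    2 * tp / (2 * tp + fp + fn)
  }, 0)
  mean(f1s)
}

#' Stratified k-fold macro-F1 of a single-layer softmax classifier
#'
#' The classifier is a single linear layer with softmax (multinomial
#' logistic regression, fit via [nnet::multinom()]); folds are stratified by
#' class and seeded.
#'
#' @param embeddings Numeric matrix, one row per item.
#' @param labels Class labels, one per row; each class needs >= k items.
#' @param k Number of folds; default 10.
#' @param seed Fold-assignment seed.
#' @return Mean macro-F1 over the k folds.
#' @export
kfold_linear_f1 <- function(embeddings, labels, k = 10L, seed = 0L) {
  embeddings <- as.matrix(embeddings)
  labels <- factor(labels)
  vb_assert(nrow(embeddings) == length(labels),
            "labels must align with embedding rows")
  counts <- table(labels)
  if (any(counts < k)) {
    stop(sprintf("class '%s' has %d items, fewer than k = %d folds",
                 names(counts)[counts < k][1L], min(counts), k), call. = FALSE)
  }
  folds <- with_seed(seed, {
    f <- integer(length(labels))
    for (lv in levels(labels)) {
      i <- which(labels == lv)
      f[i] <- sample(rep_len(seq_len(k), length(i)))
    }
    f
  })
  df <- data.frame(y = labels, embeddings)
  scores <- vapply(seq_len(k), function(fold) {
    train <- df[folds != fold, , drop = FALSE]
    test <- df[folds == fold, , drop = FALSE]
    fit <- nnet::multinom(y ~ ., data = train, trace = FALSE,
                          maxit = 200, MaxNWts = 1e6)
    pred <- stats::predict(fit, newdata = test)
    macro_f1(as.character(test$y), as.character(pred), levels(labels))
  }, 0)
  mean(scores)
}

#' Pool token embeddings to protein or genome level
#'
#' Arithmetic mean of token embeddings over each protein's (or the whole
#' genome's) residues; PAD positions carry no tokens and are excluded by
#' construction.
#'
#' @param token_embeddings Matrix with one row per residue, in genome order
#'   (unpadded; rows align with the layout's non-PAD positions).
#' @param layout The genome's [segment_genome()] layout.
#' @param level `"protein"` (one row per protein) or `"genome"` (one row).
#' @return Embedding matrix; protein rows are named by 0-based ordinal.
#' @export
pool_embeddings <- function(token_embeddings, layout,
                            level = c("protein", "genome")) {
  level <- match.arg(level)
  token_embeddings <- as.matrix(token_embeddings)
  vb_assert(nrow(token_embeddings) == layout$total_length,
            "token rows %d do not match layout residue count %d",
            nrow(token_embeddings), layout$total_length)
  if (level == "genome") {
    matrix(colMeans(token_embeddings), nrow = 1L,
           dimnames = list("genome", colnames(token_embeddings)))
  } else {
    ords <- layout$position_map$ordinal[non_pad_positions(layout)]
    sums <- rowsum(token_embeddings, group = ords)
    counts <- as.vector(table(ords))
    out <- sums / counts
    rownames(out) <- rownames(sums)
    out
  }
}
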