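# Distance-stratified attention statistics and benchmarking of inferred
# interactions against reference labels (STRING-style confidence tables).

#' Distance-stratified attention profile
#'
#' Cells of a token attention map are stratified by residue separation
#' `d = |i - j|` in unpadded concatenated-genome coordinates: short `d <=
#' b1`, medium `b1 < d <= b2`, long `d > b2` (defaults 100 and 500). Reports
#' the mean attention per category and each category's share of total
#' attention mass. Categories a genome is too short to host are absent (NA),
#' not zero.
#'
#' @param M Square attention matrix over unpadded positions.
#' @param boundaries Length-2 increasing vector of category boundaries.
#' @return Object of class `distance_profile`: list with `mean` and `share`
#'   (named numeric over short/medium/long; shares of present categories sum
#'   to 1) and `boundaries`.
#' @export
distance_profile <- function(M, boundaries = c(100L, 500L)) {
  vb_assert(is.matrix(M) && nrow(M) == ncol(M), "M must be square")
  vb_assert(length(boundaries) == 2L && boundaries[1L] < boundaries[2L],
            "boundaries must be increasing and of length 2")
  L <- nrow(M)
  d <- abs(outer(seq_len(L), seq_len(L), "-"))
  cat_idx <- findInterval(d, c(boundaries[1L] + 1L, boundaries[2L] + 1L)) + 1L
  categories <- c("short", "medium", "long")
  means <- shares <- stats::setNames(rep(NA_real_, 3L), categories)
  mass <- numeric(3L)
  for (k in 1:3) {
    cells <- cat_idx == k
    if (any(cells)) {
      means[k] <- mean(M[cells])
      mass[k] <- sum(M[cells])
    }
  }
  tot <- sum(mass)
  present <- !is.na(means)
  if (tot > 0) shares[present] <- mass[present] / tot
  structure(list(mean = means, share = shares, boundaries = boundaries),
            class = "distance_profile")
}

#' @export
print.distance_profile <- function(x, ...) {
  cat(sprintf("distance_profile (boundaries %d/%d):\n",
              x$boundaries[1L], x$boundaries[2L]))
  print(round(rbind(mean = x$mean, share = x$share), 5))
  invisible(x)
}

#' Prevalence of the dominant attention distance category
#'
#' For each genome profile, the category with the highest mean attention
#' (ties resolved toward the lower-distance category); returns the share of
#' genomes dominated by each category.
#'
#' @param profiles Nonempty list of [distance_profile()] objects.
#' @return Named numeric over short/medium/long summing to 1.
#' @export
dominant_sector_prevalence <- function(profiles) {
  vb_assert(length(profiles) > 0L, "empty profile list")
  categories <- c("short", "medium", "long")
  dom <- vapply(profiles, function(p) {
    m <- p$mean
    m[is.na(m)] <- -Inf
    categories[which.max(m)]  # which.max takes the first (lower-distance) tie
  }, "")
  counts <- table(factor(dom, levels = categories))
  stats::setNames(as.numeric(counts) / length(profiles), categories)
}

#' Per-head long-range attention enrichment
#'
#' For each (layer, head) of a stack, the fraction of attention mass at
#' residue separation greater than `boundary`.
#'
#' @param stack An [attention_stack()] over one genome.
#' @param boundary Long-range boundary in residues; default 500.
#' @return `n_layers x n_heads` matrix of long-range shares in `[0, 1]`.
#' @export
head_long_range_enrichment <- function(stack, boundary = 500L) {
  L <- stack$L
  long_cells <- abs(outer(seq_len(L), seq_len(L), "-")) > boundary
  out <- matrix(0, stack$n_layers, stack$n_heads,
                dimnames = list(sprintf("layer%d", seq_len(stack$n_layers)),
                                sprintf("head%d", seq_len(stack$n_heads))))
  for (l in seq_len(stack$n_layers)) {
    for (h in seq_len(stack$n_heads)) {
      M <- stack$matrices[[l]][[h]]
      out[l, h] <- sum(M[long_cells]) / sum(M)
    }
  }
  out
}

# Mann-Whitney AUC by concordant-pair counting; ties count 0.5.
auc_concordant <- function(scores, positive) {
  npos <- sum(positive); nneg <- sum(!positive)
  vb_assert(npos > 0L, "no positive labels: AUC undefined")
  vb_assert(nneg > 0L, "no negative labels: AUC undefined")
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Benchmark inferred interactions against reference labels
#'
#' Labeled pairs with confidence at or above the threshold are positives.
#' Predicted positives are the pairs present in the selected interaction
#' set (F1, accuracy); the AUC uses the continuous per-pair scores A via
#' concordant-pair counting (ties 0.5), with a seeded bootstrap CI obtained
#' by resampling labeled pairs with replacement.
#'
#' @param table A `pair_score_table` of all evaluated pairs.
#' @param selected An `interaction_set` (the predicted positives).
#' @param labels Data frame with 0-based ordinal columns `I`, `J` and
#'   `confidence` in `[0, 1]`; must cover the evaluated pairs.
#' @param conf Positive-label confidence threshold; default 0.500.
#' @param n_boot Bootstrap replicates for the AUC CI; default 1000.
#' @param seed Bootstrap seed.
#' @return Object of class `ppi_benchmark`: list with `f1`, `precision`,
#'   `recall`, `accuracy`, `auc`, `auc_ci` (95% percentile interval),
#'   `n_labeled`, `n_positive`.
#' @export
evaluate_against_reference <- function(table, selected, labels, conf = 0.500,
                                       n_boot = 1000L, seed = 0L) {
  vb_assert(all(c("I", "J", "confidence") %in% names(labels)),
            "labels need columns I, J, confidence")
  vb_assert(all(labels$confidence >= 0 & labels$confidence <= 1),
            "confidences must lie in [0, 1]")
  lab <- labels
  flip <- lab$I > lab$J
  if (any(flip)) {
    tmp <- lab$I[flip]; lab$I[flip] <- lab$J[flip]; lab$J[flip] <- tmp
  }
  vb_assert(!anyDuplicated(paste(lab$I, lab$J)), "duplicate labeled pairs")
  key <- function(i, j) paste(i, j, sep = ":")
  tab_key <- key(table$I, table$J)
  lab_key <- key(lab$I, lab$J)
  idx <- match(lab_key, tab_key)
  vb_assert(!anyNA(idx), "labeled pair (%s) absent from the score table",
            lab_key[is.na(idx)][1L])
  scores <- table$A[idx]
  positive <- lab$confidence >= conf
  predicted <- lab_key %in% key(selected$I, selected$J)
  tp <- sum(predicted & positive); fp <- sum(predicted & !positive)
  fn <- sum(!predicted & positive); tn <- sum(!predicted & !positive)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  accuracy <- (tp + tn) / length(positive)
  auc <- auc_concordant(scores, positive)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      i <- sample(length(scores), replace = TRUE)
      if (length(unique(positive[i])) < 2L) return(NA_real_)
      auc_concordant(scores[i], positive[i])
    }, 0)
  })
  ci <- stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  structure(list(f1 = f1, precision = precision, recall = recall,
                 accuracy = accuracy, auc = auc, auc_ci = ci,
                 n_labeled = length(positive), n_positive = sum(positive),
                 conf = conf, n_boot = as.integer(n_boot)),
            class = "ppi_benchmark")
}

#' @export
print.ppi_benchmark <- function(x, ...) {
  cat(sprintf(
    "ppi_benchmark over %d labeled pairs (%d positive at confidence >= %.3f)\n",
    x$n_labeled, x$n_positive, x$conf))
  cat(sprintf("  F1 = %.3f (precision %.3f, recall %.3f), accuracy = %.3f\n",
              x$f1, x$precision, x$recall, x$accuracy))
  cat(sprintf("  AUC = %.3f, bootstrap 95%% CI [%.3f, %.3f] (%d reps)\n",
              x$auc, x$auc_ci[1L], x$auc_ci[2L], x$n_boot))
  invisible(x)
}
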