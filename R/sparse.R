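# Stage 2: biologically informed block-sparse attention.
#
# The mask policy allows three kinds of block pairs: intra-protein (self),
# consecutive proteins (adjacent, both directions), and inferred PPI pairs
# (both directions). The mask is stored in Block Sparse Row (BSR) layout and
# drives masked multi-head scaled-dot-product attention with optional ALiBi
# linear position bias. A dense masked-softmax oracle verifies the kernel.

#' Build the biologically informed block mask in BSR layout
#'
#' Allowed blocks are all block pairs within each protein (self), all block
#' pairs between proteins p and p+1 in both directions (adjacent), and all
#' block pairs between each interacting protein pair in both directions
#' (ppi) — nothing else. Where policies overlap the origin tag records the
#' strongest: self > adjacent > ppi.
#'
#' @param layout A [segment_genome()] block layout.
#' @param interactions An `interaction_set` (or data frame with 0-based
#'   ordinal columns `I`, `J`); may be empty.
#' @return Object of class `bsr_layout`: list with `block_size`,
#'   `n_block_rows`, `row_ptr` (1-based CSR pointers, length n_block_rows+1),
#'   `col_ind` (block column indices, sorted within each row) and `origin`
#'   (`"self"`, `"adjacent"` or `"ppi"` per stored block).
#' @export
build_block_mask <- function(layout, interactions = NULL) {
  n_prot <- length(layout$n_blocks)
  nb <- sum(layout$n_blocks)
  blocks_of <- function(p) {  # p: 1-based protein index
    layout$first_block[p] + seq_len(layout$n_blocks[p]) - 1L
  }
  # collect (row, col, origin_code) triples; code 1=self, 2=adjacent, 3=ppi
  rows <- integer(0); cols <- integer(0); code <- integer(0)
  add <- function(pa, pb, cd) {
    ba <- blocks_of(pa); bb <- blocks_of(pb)
    g <- expand.grid(r = ba, c = bb)
    rows <<- c(rows, g$r); cols <<- c(cols, g$c)
    code <<- c(code, rep(cd, nrow(g)))
  }
  for (p in seq_len(n_prot)) add(p, p, 1L)
  if (n_prot > 1L) {
    for (p in seq_len(n_prot - 1L)) {
      add(p, p + 1L, 2L); add(p + 1L, p, 2L)
    }
  }
  if (!is.null(interactions) && nrow(interactions) > 0L) {
    vb_assert(all(c("I", "J") %in% names(interactions)),
              "interactions need columns I and J")
    vb_assert(all(interactions$I >= 0L & interactions$I < n_prot &
                    interactions$J >= 0L & interactions$J < n_prot),
              "interaction references unknown protein ordinal")
    for (r in seq_len(nrow(interactions))) {
      a <- interactions$I[r] + 1L; b <- interactions$J[r] + 1L
      add(a, b, 3L); add(b, a, 3L)
    }
  }
  # dedupe, keeping the strongest origin (lowest code)
  key <- (rows - 1L) * nb + cols
  ord <- order(key, code)
  key <- key[ord]; code <- code[ord]
  keep <- !duplicated(key)
  key <- key[keep]; code <- code[keep]
  r <- (key - 1L) %/% nb + 1L
  c_ <- (key - 1L) %% nb + 1L
  row_ptr <- cumsum(c(1L, tabulate(r, nbins = nb)))
  structure(list(block_size = layout$block_size,
                 n_block_rows = nb,
                 row_ptr = as.integer(row_ptr),
                 col_ind = as.integer(c_),
                 origin = c("self", "adjacent", "ppi")[code]),
            class = "bsr_layout")
}

#' @export
print.bsr_layout <- function(x, ...) {
  cat(sprintf("bsr_layout: B=%d, %d block rows, %d stored blocks (%s)\n",
              x$block_size, x$n_block_rows, length(x$col_ind),
              paste(sprintf("%s=%d", names(table(x$origin)),
                            as.integer(table(x$origin))), collapse = ", ")))
  invisible(x)
}

# block column indices allowed for block row r
bsr_row_cols <- function(mask, r) {
  if (mask$row_ptr[r] > mask$row_ptr[r + 1L] - 1L) return(integer(0))
  mask$col_ind[mask$row_ptr[r]:(mask$row_ptr[r + 1L] - 1L)]
}

#' ALiBi slope schedule
#'
#' Per-head slopes `m_h = 2^(-8h / n_heads)` for `h = 1..n_heads`; the bias
#' added to the pre-softmax score of query i and key j is `-m_h * |i - j|`.
#'
#' @param n_heads Number of heads (>= 1).
#' @return Numeric vector of positive, strictly decreasing slopes.
#' @export
alibi_slopes <- function(n_heads) {
  vb_assert(n_heads >= 1L, "n_heads must be >= 1")
  2^(-8 * seq_len(n_heads) / n_heads)
}

#' Block-sparse masked multi-head scaled-dot-product attention
#'
#' For each query row the softmax runs over the union of key positions in
#' that row's allowed blocks; PAD key positions are excluded via a -Inf
#' score. Rows at PAD query positions are filled with zeros and are discarded
#' by [remove_padding()]. No full `L' x L'` score matrix is ever
#' materialized: temporaries are per block row.
#'
#' @param inputs An `attention_inputs` (arrays `Q`, `K`, `V` of dim
#'   `(heads, padded_length, d_k)`).
#' @param mask A [build_block_mask()] BSR layout.
#' @param layout The matching [segment_genome()] layout.
#' @param slopes Optional ALiBi slopes from [alibi_slopes()] (length = heads);
#'   distances are measured in padded coordinates.
#' @return Array of dim `(heads, padded_length, d_k)` of contextual outputs.
#' @export
block_sparse_attention <- function(inputs, mask, layout, slopes = NULL) {
  check_attention_shapes(inputs, mask, layout, slopes)
  H <- dim(inputs$Q)[1L]; Lp <- dim(inputs$Q)[2L]; dk <- dim(inputs$Q)[3L]
  B <- mask$block_size
  pad <- is.na(layout$position_map$ordinal)
  out <- array(0, c(H, Lp, dk))
  scale <- 1 / sqrt(dk)
  for (h in seq_len(H)) {
    Qh <- matrix(inputs$Q[h, , ], Lp, dk)
    Kh <- matrix(inputs$K[h, , ], Lp, dk)
    Vh <- matrix(inputs$V[h, , ], Lp, dk)
    for (r in seq_len(mask$n_block_rows)) {
      cols <- bsr_row_cols(mask, r)
      qrows <- block_positions(layout, r)
      if (length(cols) == 0L) {
        if (any(!pad[qrows])) {
          stop(sprintf("query block row %d has no allowed key blocks", r),
               call. = FALSE)
        }
        next
      }
      kcols <- as.vector(vapply(cols, function(b) block_positions(layout, b),
                                integer(B)))
      S <- (Qh[qrows, , drop = FALSE] %*% t(Kh[kcols, , drop = FALSE])) * scale
      if (!is.null(slopes)) {
        S <- S - slopes[h] * abs(outer(qrows, kcols, "-"))
      }
      S[, pad[kcols]] <- -Inf
      mx <- apply(S, 1L, max)
      live <- is.finite(mx)
      if (any(!live & !pad[qrows])) {
        stop(sprintf(
          "query row in block %d has zero allowed non-PAD keys", r),
          call. = FALSE)
      }
      P <- exp(S - ifelse(live, mx, 0))
      P[!live, ] <- 0
      P <- P / pmax(rowSums(P), .Machine$double.xmin)
      out[h, qrows, ] <- P %*% Vh[kcols, , drop = FALSE]
    }
  }
  out
}

#' Vector-Jacobian product (backward pass) of block-sparse attention
#'
#' Given the upstream gradient with respect to the attention output, returns
#' gradients with respect to Q, K and V. Upstream gradient rows at PAD query
#' positions are ignored (those outputs are discarded downstream).
#'
#' @param inputs,mask,layout,slopes As in [block_sparse_attention()].
#' @param upstream Array of dim `(heads, padded_length, d_k)`.
#' @return List with arrays `dQ`, `dK`, `dV` of the input shape.
#' @export
block_sparse_attention_vjp <- function(inputs, mask, layout, upstream,
                                       slopes = NULL) {
  check_attention_shapes(inputs, mask, layout, slopes)
  H <- dim(inputs$Q)[1L]; Lp <- dim(inputs$Q)[2L]; dk <- dim(inputs$Q)[3L]
  B <- mask$block_size
  pad <- is.na(layout$position_map$ordinal)
  dQ <- array(0, c(H, Lp, dk)); dK <- dQ; dV <- dQ
  scale <- 1 / sqrt(dk)
  for (h in seq_len(H)) {
    Qh <- matrix(inputs$Q[h, , ], Lp, dk)
    Kh <- matrix(inputs$K[h, , ], Lp, dk)
    Vh <- matrix(inputs$V[h, , ], Lp, dk)
    Gh <- matrix(upstream[h, , ], Lp, dk)
    for (r in seq_len(mask$n_block_rows)) {
      cols <- bsr_row_cols(mask, r)
      if (length(cols) == 0L) next
      qrows <- block_positions(layout, r)
      kcols <- as.vector(vapply(cols, function(b) block_positions(layout, b),
                                integer(B)))
      G <- Gh[qrows, , drop = FALSE]
      G[pad[qrows], ] <- 0
      S <- (Qh[qrows, , drop = FALSE] %*% t(Kh[kcols, , drop = FALSE])) * scale
      if (!is.null(slopes)) {
        S <- S - slopes[h] * abs(outer(qrows, kcols, "-"))
      }
      S[, pad[kcols]] <- -Inf
      mx <- apply(S, 1L, max)
      live <- is.finite(mx)
      P <- exp(S - ifelse(live, mx, 0))
      P[!live, ] <- 0
      P <- P / pmax(rowSums(P), .Machine$double.xmin)
      dV[h, kcols, ] <- dV[h, kcols, ] + t(P) %*% G
      dP <- G %*% t(Vh[kcols, , drop = FALSE])
      dS <- P * (dP - rowSums(dP * P))
      dQ[h, qrows, ] <- dQ[h, qrows, ] +
        (dS %*% Kh[kcols, , drop = FALSE]) * scale
      dK[h, kcols, ] <- dK[h, kcols, ] +
        (t(dS) %*% Qh[qrows, , drop = FALSE]) * scale
    }
  }
  list(dQ = dQ, dK = dK, dV = dV)
}

check_attention_shapes <- function(inputs, mask, layout, slopes) {
  d <- dim(inputs$Q)
  vb_assert(length(d) == 3L && identical(d, dim(inputs$K)) &&
              identical(d, dim(inputs$V)),
            "Q, K, V must share shape (heads, padded_length, d_k)")
  vb_assert(d[2L] == layout$padded_length,
            "inputs padded length %d does not match layout %d",
            d[2L], layout$padded_length)
  vb_assert(mask$block_size == layout$block_size,
            "mask block size %d does not match layout %d",
            mask$block_size, layout$block_size)
  vb_assert(mask$n_block_rows * mask$block_size == layout$padded_length,
            "mask block rows inconsistent with layout")
  if (!is.null(slopes)) {
    vb_assert(length(slopes) == d[1L],
              "need one ALiBi slope per head (%d)", d[1L])
  }
  invisible(TRUE)
}

#' Expand a BSR mask to a dense position-level boolean mask
#'
#' PAD key columns are masked out; PAD query rows keep their allowed keys
#' (their outputs are discarded downstream anyway).
#'
#' @param mask A `bsr_layout`.
#' @param layout The matching `block_layout`.
#' @return `padded_length x padded_length` logical matrix.
#' @export
dense_mask_from_bsr <- function(mask, layout) {
  Lp <- layout$padded_length
  M <- matrix(FALSE, Lp, Lp)
  for (r in seq_len(mask$n_block_rows)) {
    cols <- bsr_row_cols(mask, r)
    if (length(cols) == 0L) next
    kcols <- unlist(lapply(cols, function(b) block_positions(layout, b)))
    M[block_positions(layout, r), kcols] <- TRUE
  }
  M[, is.na(layout$position_map$ordinal)] <- FALSE
  M
}

#' Dense masked-attention oracle
#'
#' Textbook masked `softmax(Q K^T / sqrt(d_k) + bias) V` computed with the
#' full score matrix; the verification oracle for
#' [block_sparse_attention()].
#'
#' @param inputs An `attention_inputs`.
#' @param dense_mask `L' x L'` logical matrix of allowed (query, key) cells
#'   with PAD keys already excluded, e.g. from [dense_mask_from_bsr()].
#' @param slopes Optional ALiBi slopes (length = heads).
#' @return Array of dim `(heads, L', d_k)`; rows with no allowed keys are
#'   zero-filled (an error if any such row is a non-PAD query — pass a
#'   layout-consistent mask).
#' @export
dense_masked_attention_oracle <- function(inputs, dense_mask, slopes = NULL) {
  d <- dim(inputs$Q)
  H <- d[1L]; Lp <- d[2L]; dk <- d[3L]
  vb_assert(nrow(dense_mask) == Lp && ncol(dense_mask) == Lp,
            "dense mask must be %d x %d", Lp, Lp)
  out <- array(0, c(H, Lp, dk))
  for (h in seq_len(H)) {
    Qh <- matrix(inputs$Q[h, , ], Lp, dk)
    Kh <- matrix(inputs$K[h, , ], Lp, dk)
    Vh <- matrix(inputs$V[h, , ], Lp, dk)
    S <- Qh %*% t(Kh) / sqrt(dk)
    if (!is.null(slopes)) {
      pos <- seq_len(Lp)
      S <- S - slopes[h] * abs(outer(pos, pos, "-"))
    }
    S[!dense_mask] <- -Inf
    mx <- apply(S, 1L, max)
    live <- is.finite(mx)
    P <- exp(S - ifelse(live, mx, 0))
    P[!live, ] <- 0
    P <- P / pmax(rowSums(P), .Machine$double.xmin)
    out[h, , ] <- P %*% Vh
  }
  out
}

#' Strip padding rows from a padded attention output
#'
#' @param padded_output Array `(heads, padded_length, d_k)` or matrix
#'   `(padded_length, d)`.
#' @param layout The `block_layout` that produced the padding.
#' @return Same structure with PAD rows dropped (`padded_length` becomes the
#'   genome's residue count), residue order preserved.
#' @export
remove_padding <- function(padded_output, layout) {
  keep <- non_pad_positions(layout)
  if (is.matrix(padded_output)) {
    vb_assert(nrow(padded_output) == layout$padded_length,
              "output rows %d do not match padded length %d",
              nrow(padded_output), layout$padded_length)
    padded_output[keep, , drop = FALSE]
  } else {
    vb_assert(length(dim(padded_output)) == 3L &&
                dim(padded_output)[2L] == layout$padded_length,
              "output dim 2 does not match padded length %d",
              layout$padded_length)
    padded_output[, keep, , drop = FALSE]
  }
}

#' Embed an unpadded row matrix into padded-block space
#'
#' Inverse of [remove_padding()] for residue rows; PAD rows are zero.
#'
#' @param x Matrix with one row per residue (genome order).
#' @param layout The target `block_layout`.
#' @return Matrix with `padded_length` rows.
#' @export
expand_padding <- function(x, layout) {
  vb_assert(nrow(x) == layout$total_length,
            "x has %d rows, layout expects %d residues", nrow(x),
            layout$total_length)
  out <- matrix(0, layout$padded_length, ncol(x))
  out[non_pad_positions(layout), ] <- x
  out
}

#' Sparsity statistics of a block mask
#'
#' @param mask A `bsr_layout`.
#' @param layout The matching `block_layout`.
#' @return List with `stored_blocks`, `dense_blocks` (= total blocks squared)
#'   and `fraction` = stored / dense.
#' @export
sparsity_stats <- function(mask, layout) {
  nb <- sum(layout$n_blocks)
  vb_assert(nb == mask$n_block_rows, "mask and layout block counts differ")
  stored <- length(mask$col_ind)
  list(stored_blocks = stored, dense_blocks = nb^2,
       fraction = stored / nb^2)
}
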