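# Desk-scale masked-language-model harness: a tiny pre-norm transformer
# encoder whose attention layer is block_sparse_attention, trained with
# manual backpropagation and Adam. It exists to show that a biologically
# informed mask lets the model learn cross-protein dependencies; it is not a
# production model.

VOCAB_AA <- AA_CANONICAL          # prediction targets: the 20 residues
TOK_MASK <- 21L
TOK_PAD <- 22L
VOCAB_SIZE <- 22L

#' Configuration for the tiny encoder
#'
#' @param n_layers Encoder layers (<= 4).
#' @param n_heads Attention heads; must divide `model_dim`.
#' @param model_dim Model width; `d_k = model_dim / n_heads`.
#' @param block_size Attention block size B.
#' @param mask_rate Fraction of residues masked when the dataset does not fix
#'   masked positions (BERT-style: replaced by the mask token).
#' @param lr Adam learning rate.
#' @param epochs Training epochs.
#' @param init_sd Standard deviation of the Gaussian parameter
#'   initialization.
#' @param seed Integer seed governing initialization, shuffling and masking.
#' @return List of class `tiny_encoder_config`.
#' @export
tiny_encoder_config <- function(n_layers = 2L, n_heads = 4L, model_dim = 64L,
                                block_size = 32L, mask_rate = 0.15,
                                lr = 3e-3, epochs = 15L, init_sd = 0.1,
                                seed = 0L) {
  vb_assert(n_layers >= 1L && n_layers <= 4L, "n_layers must be in 1..4")
  vb_assert(model_dim %% n_heads == 0L, "model_dim must be divisible by n_heads")
  vb_assert(mask_rate > 0 && mask_rate < 1, "mask_rate must lie in (0, 1)")
  structure(list(n_layers = as.integer(n_layers), n_heads = as.integer(n_heads),
                 model_dim = as.integer(model_dim),
                 d_k = as.integer(model_dim / n_heads),
                 block_size = as.integer(block_size),
                 mask_rate = mask_rate, lr = lr, init_sd = init_sd,
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "tiny_encoder_config")
}

tokenize_residues <- function(sequence) {
  ids <- match(strsplit(sequence, "", fixed = TRUE)[[1L]], VOCAB_AA)
  vb_assert(!anyNA(ids), "sequence contains residues outside the 20-letter vocabulary")
  ids
}

# --- layer primitives -------------------------------------------------------

ln_forward <- function(x, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv_std <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv_std
  y <- sweep(xhat, 2L, gamma, "*")
  y <- sweep(y, 2L, beta, "+")
  list(y = y, xhat = xhat, inv_std = inv_std)
}

ln_backward <- function(dy, cache, gamma) {
  xhat <- cache$xhat
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2L, gamma, "*")
  d <- ncol(dy)
  rs1 <- rowSums(dxhat)
  rs2 <- rowSums(dxhat * xhat)
  dx <- (cache$inv_std / d) * (d * dxhat - rs1 - xhat * rs2)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

split_heads <- function(Xm, H, dk) {
  Lp <- nrow(Xm)
  arr <- array(0, c(H, Lp, dk))
  for (h in seq_len(H)) arr[h, , ] <- Xm[, ((h - 1L) * dk + 1L):(h * dk)]
  arr
}

merge_heads <- function(arr) {
  H <- dim(arr)[1L]; Lp <- dim(arr)[2L]; dk <- dim(arr)[3L]
  out <- matrix(0, Lp, H * dk)
  for (h in seq_len(H)) out[, ((h - 1L) * dk + 1L):(h * dk)] <- arr[h, , ]
  out
}

init_mlm_params <- function(config, max_len) {
  d <- config$model_dim
  init_sd <- if (is.null(config$init_sd)) 0.02 else config$init_sd
  rn <- function(nr, nc, sd = init_sd) {
    matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)
  }
  params <- list(E = rn(VOCAB_SIZE, d), P = rn(max_len, d))
  for (l in seq_len(config$n_layers)) {
    pre <- sprintf("L%d.", l)
    params[[paste0(pre, "g1")]] <- rep(1, d)
    params[[paste0(pre, "b1")]] <- rep(0, d)
    params[[paste0(pre, "Wq")]] <- rn(d, d)
    params[[paste0(pre, "Wk")]] <- rn(d, d)
    params[[paste0(pre, "Wv")]] <- rn(d, d)
    params[[paste0(pre, "Wo")]] <- rn(d, d)
    params[[paste0(pre, "g2")]] <- rep(1, d)
    params[[paste0(pre, "b2")]] <- rep(0, d)
    params[[paste0(pre, "W1")]] <- rn(d, 4L * d)
    params[[paste0(pre, "c1")]] <- rep(0, 4L * d)
    params[[paste0(pre, "W2")]] <- rn(4L * d, d)
    params[[paste0(pre, "c2")]] <- rep(0, d)
  }
  params$gf <- rep(1, d); params$bf <- rep(0, d)
  params$Wout <- rn(d, length(VOCAB_AA))
  params$bout <- rep(0, length(VOCAB_AA))
  params
}

# Forward pass over one padded token sequence. masked_rows index padded
# positions whose targets enter the loss. Returns loss, per-row logits and
# (optionally) the cache needed for backward.
mlm_forward <- function(params, tokens, masked_rows, target_ids, mask, layout,
                        config, need_cache = FALSE) {
  H <- config$n_heads; dk <- config$d_k
  Lp <- length(tokens)
  x <- params$E[tokens, , drop = FALSE] + params$P[seq_len(Lp), , drop = FALSE]
  cache <- list(tokens = tokens, x0_rows = Lp, layers = vector("list", config$n_layers))
  for (l in seq_len(config$n_layers)) {
    pre <- sprintf("L%d.", l)
    lc <- list(x_in = x)
    ln1 <- ln_forward(x, params[[paste0(pre, "g1")]], params[[paste0(pre, "b1")]])
    a_in <- ln1$y
    Qm <- a_in %*% params[[paste0(pre, "Wq")]]
    Km <- a_in %*% params[[paste0(pre, "Wk")]]
    Vm <- a_in %*% params[[paste0(pre, "Wv")]]
    inputs <- structure(list(Q = split_heads(Qm, H, dk),
                             K = split_heads(Km, H, dk),
                             V = split_heads(Vm, H, dk), d_k = dk),
                        class = "attention_inputs")
    att <- block_sparse_attention(inputs, mask, layout)
    att_c <- merge_heads(att)
    x <- x + att_c %*% params[[paste0(pre, "Wo")]]
    ln2 <- ln_forward(x, params[[paste0(pre, "g2")]], params[[paste0(pre, "b2")]])
    m_in <- ln2$y
    pre_act <- sweep(m_in %*% params[[paste0(pre, "W1")]], 2L,
                     params[[paste0(pre, "c1")]], "+")
    hmid <- pmax(pre_act, 0)
    x <- x + sweep(hmid %*% params[[paste0(pre, "W2")]], 2L,
                   params[[paste0(pre, "c2")]], "+")
    if (need_cache) {
      lc$ln1 <- ln1; lc$a_in <- a_in; lc$inputs <- inputs; lc$att_c <- att_c
      lc$x_mid <- lc$x_in + att_c %*% params[[paste0(pre, "Wo")]]
      lc$ln2 <- ln2; lc$m_in <- m_in; lc$hmid <- hmid
      cache$layers[[l]] <- lc
    }
  }
  lnf <- ln_forward(x, params$gf, params$bf)
  logits <- sweep(lnf$y %*% params$Wout, 2L, params$bout, "+")
  lm <- logits[masked_rows, , drop = FALSE]
  lm <- lm - apply(lm, 1L, max)
  logZ <- log(rowSums(exp(lm)))
  loss <- mean(logZ - lm[cbind(seq_along(target_ids), target_ids)])
  if (need_cache) {
    cache$lnf <- lnf; cache$x_final <- x
    cache$softmax_masked <- exp(lm - logZ)
  }
  list(loss = loss, logits = logits, cache = if (need_cache) cache else NULL)
}

mlm_backward <- function(params, cache, masked_rows, target_ids, mask, layout,
                         config) {
  H <- config$n_heads; dk <- config$d_k
  Lp <- cache$x0_rows
  grads <- list()
  n_mask <- length(masked_rows)
  dlogits <- matrix(0, Lp, length(VOCAB_AA))
  dm <- cache$softmax_masked
  dm[cbind(seq_along(target_ids), target_ids)] <-
    dm[cbind(seq_along(target_ids), target_ids)] - 1
  dlogits[masked_rows, ] <- dm / n_mask
  grads$Wout <- t(cache$lnf$y) %*% dlogits
  grads$bout <- colSums(dlogits)
  dy <- dlogits %*% t(params$Wout)
  bk <- ln_backward(dy, cache$lnf, params$gf)
  grads$gf <- bk$dgamma; grads$bf <- bk$dbeta
  dx <- bk$dx
  for (l in rev(seq_len(config$n_layers))) {
    pre <- sprintf("L%d.", l)
    lc <- cache$layers[[l]]
    # MLP block (residual: dx reaches both branch and skip)
    dmout <- dx
    grads[[paste0(pre, "W2")]] <- t(lc$hmid) %*% dmout
    grads[[paste0(pre, "c2")]] <- colSums(dmout)
    dhmid <- dmout %*% t(params[[paste0(pre, "W2")]])
    dpre <- dhmid * (lc$hmid > 0)
    grads[[paste0(pre, "W1")]] <- t(lc$m_in) %*% dpre
    grads[[paste0(pre, "c1")]] <- colSums(dpre)
    dm_in <- dpre %*% t(params[[paste0(pre, "W1")]])
    bk <- ln_backward(dm_in, lc$ln2, params[[paste0(pre, "g2")]])
    grads[[paste0(pre, "g2")]] <- bk$dgamma
    grads[[paste0(pre, "b2")]] <- bk$dbeta
    dx <- dx + bk$dx
    # attention block
    dproj <- dx
    grads[[paste0(pre, "Wo")]] <- t(lc$att_c) %*% dproj
    datt_c <- dproj %*% t(params[[paste0(pre, "Wo")]])
    upstream <- split_heads(datt_c, H, dk)
    vjp <- block_sparse_attention_vjp(lc$inputs, mask, layout, upstream)
    dQm <- merge_heads(vjp$dQ); dKm <- merge_heads(vjp$dK); dVm <- merge_heads(vjp$dV)
    grads[[paste0(pre, "Wq")]] <- t(lc$a_in) %*% dQm
    grads[[paste0(pre, "Wk")]] <- t(lc$a_in) %*% dKm
    grads[[paste0(pre, "Wv")]] <- t(lc$a_in) %*% dVm
    da_in <- dQm %*% t(params[[paste0(pre, "Wq")]]) +
      dKm %*% t(params[[paste0(pre, "Wk")]]) +
      dVm %*% t(params[[paste0(pre, "Wv")]])
    bk <- ln_backward(da_in, lc$ln1, params[[paste0(pre, "g1")]])
    grads[[paste0(pre, "g1")]] <- bk$dgamma
    grads[[paste0(pre, "b1")]] <- bk$dbeta
    dx <- dx + bk$dx
  }
  # embeddings
  dE <- matrix(0, VOCAB_SIZE, config$model_dim)
  sums <- rowsum(dx, group = cache$tokens)
  dE[as.integer(rownames(sums)), ] <- sums
  grads$E <- dE
  dP <- matrix(0, nrow(params$P), config$model_dim)
  dP[seq_len(Lp), ] <- dx
  grads$P <- dP
  grads
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- g * 0
      state$v[[nm]] <- g * 0
    }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# Normalize a dataset into items of (genome, masked_positions, targets);
# masked_positions/targets may be NULL (random masking per epoch).
mlm_items <- function(dataset) {
  if (inherits(dataset, "partner_task")) return(dataset$items)
  vb_assert(is.list(dataset) && length(dataset) > 0L, "empty dataset")
  lapply(dataset, function(it) {
    if (inherits(it, "genome_record")) list(genome = it) else it
  })
}

#' Train the tiny masked-language-model encoder
#'
#' BERT-style masking (masked residues replaced by the mask token, no
#' 80/10/10 split); the output softmax runs over the 20 residue classes.
#' Items carrying fixed `masked_positions`/`targets` (e.g. from
#' [make_partner_task()]) use them; otherwise positions are drawn per epoch
#' at `config$mask_rate`.
#'
#' @param config A [tiny_encoder_config()].
#' @param dataset A `partner_task`, or a list of `genome_record`s / items.
#' @param mask A `bsr_layout` shared by all items, or a list of one per item.
#' @return Object of class `mlm_model`: list with `params`, `config`,
#'   `loss_trajectory` (per-epoch mean cross-entropy) and the layouts used.
#' @export
train_mlm <- function(config, dataset, mask) {
  items <- mlm_items(dataset)
  vb_assert(length(items) > 0L, "empty dataset")
  layouts <- lapply(items, function(it) segment_genome(it$genome, config$block_size))
  masks <- if (inherits(mask, "bsr_layout")) rep(list(mask), length(items)) else mask
  vb_assert(length(masks) == length(items), "need one mask per item")
  max_len <- max(vapply(layouts, function(l) l$padded_length, 1L))
  with_seed(config$seed, {
    params <- init_mlm_params(config, max_len)
    state <- list(t = 0L, m = list(), v = list())
    trajectory <- numeric(config$epochs)
    prepared <- lapply(seq_along(items), function(i) {
      it <- items[[i]]; lay <- layouts[[i]]
      toks <- rep(TOK_PAD, lay$padded_length)
      np <- non_pad_positions(lay)
      toks[np] <- tokenize_residues(genome_sequence(it$genome))
      rows_fixed <- NULL; targ_fixed <- NULL
      if (!is.null(it$masked_positions)) {
        rows_fixed <- np[it$masked_positions]
        targ_fixed <- match(it$targets, VOCAB_AA)
      }
      list(tokens = toks, np = np, rows_fixed = rows_fixed,
           targets_fixed = targ_fixed)
    })
    for (ep in seq_len(config$epochs)) {
      losses <- numeric(length(items))
      for (i in sample(seq_along(items))) {
        pp <- prepared[[i]]
        if (is.null(pp$rows_fixed)) {
          n_m <- max(1L, round(config$mask_rate * length(pp$np)))
          rows <- sort(sample(pp$np, n_m))
          targ <- pp$tokens[rows]
        } else {
          rows <- pp$rows_fixed
          targ <- pp$targets_fixed
        }
        toks <- pp$tokens
        toks[rows] <- TOK_MASK
        fw <- mlm_forward(params, toks, rows, targ, masks[[i]], layouts[[i]],
                          config, need_cache = TRUE)
        gr <- mlm_backward(params, fw$cache, rows, targ, masks[[i]],
                           layouts[[i]], config)
        up <- adam_step(params, gr, state, config$lr)
        params <- up$params; state <- up$state
        losses[i] <- fw$loss
      }
      trajectory[ep] <- mean(losses)
    }
    structure(list(params = params, config = config,
                   loss_trajectory = trajectory),
              class = "mlm_model")
  })
}

#' @export
print.mlm_model <- function(x, ...) {
  cat(sprintf("mlm_model: %d layers x %d heads, dim %d; %d epochs\n",
              x$config$n_layers, x$config$n_heads, x$config$model_dim,
              length(x$loss_trajectory)))
  cat(sprintf("  loss %0.4f -> %0.4f\n", x$loss_trajectory[1L],
              x$loss_trajectory[length(x$loss_trajectory)]))
  invisible(x)
}

#' Masked-token prediction accuracy
#'
#' Fraction of masked positions whose argmax prediction equals the target;
#' computed only over masked positions, never PAD.
#'
#' @param model A trained [train_mlm()] `mlm_model`.
#' @param dataset A `partner_task` or item list with fixed masked positions.
#' @param mask A `bsr_layout` (or list of one per item) used at evaluation.
#' @return Accuracy in `[0, 1]`.
#' @export
masked_token_accuracy <- function(model, dataset, mask) {
  items <- mlm_items(dataset)
  config <- model$config
  masks <- if (inherits(mask, "bsr_layout")) rep(list(mask), length(items)) else mask
  n_ok <- 0L; n_tot <- 0L
  for (i in seq_along(items)) {
    it <- items[[i]]
    vb_assert(!is.null(it$masked_positions) && length(it$masked_positions) > 0L,
              "dataset item %d has no masked positions", i)
    lay <- segment_genome(it$genome, config$block_size)
    np <- non_pad_positions(lay)
    toks <- rep(TOK_PAD, lay$padded_length)
    toks[np] <- tokenize_residues(genome_sequence(it$genome))
    rows <- np[it$masked_positions]
    targ <- match(it$targets, VOCAB_AA)
    toks[rows] <- TOK_MASK
    fw <- mlm_forward(model$params, toks, rows, targ, masks[[i]], lay, config)
    pred <- max.col(fw$logits[rows, , drop = FALSE], ties.method = "first")
    n_ok <- n_ok + sum(pred == targ)
    n_tot <- n_tot + length(targ)
  }
  n_ok / n_tot
}
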