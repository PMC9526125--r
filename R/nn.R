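# Compact transformer encoder for token classification, implemented directly
# on BLAS matrix ops. Pre-layer-norm residual blocks (normalization inside the
# residual branch, a final normalization before the head) train stably from
# random initialization at practical learning rates without warmup. Positional
# information enters as a fixed per-head linear distance penalty on the
# attention logits (attention-with-linear-biases) rather than learned absolute
# position embeddings: relative, translation-invariant positions generalize
# across report layouts instead of memorizing window positions. Trained with
# Adam on masked token-level cross-entropy. All state is plain R matrices so
# models are seed-reproducible and serialization-free.

nn_config <- function(vocab_size, n_labels, d_model = 128L, n_heads = 4L,
                      n_layers = 2L, d_ff = 256L, max_len = 128L) {
  stopifnot(d_model %% n_heads == 0)
  list(vocab_size = as.integer(vocab_size), n_labels = as.integer(n_labels),
       d_model = as.integer(d_model), n_heads = as.integer(n_heads),
       n_layers = as.integer(n_layers), d_ff = as.integer(d_ff),
       max_len = as.integer(max_len), d_head = as.integer(d_model / n_heads),
       # directional distance-decay slopes per head (left = toward preceding
       # tokens, right = toward following ones). Measurement names precede
       # their values in most report layouts, so half the heads look sharply
       # left, the rest are symmetric local-to-global.
       alibi_left = rep(c(0.5, 0.125, 0.0625, 0.004), length.out = n_heads),
       alibi_right = rep(c(2, 0.5, 0.0625, 0.004), length.out = n_heads))
}

nn_init <- function(cfg, seed = 1L) {
  with_seed(seed, {
    d <- cfg$d_model; f <- cfg$d_ff
    rmat <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 0.02), nr, nc)
    p <- list(tok_emb = rmat(cfg$vocab_size, d),
              ln0_g = rep(1, d), ln0_b = rep(0, d))
    for (l in seq_len(cfg$n_layers)) {
      p[[paste0("l", l, "_Wq")]] <- rmat(d, d); p[[paste0("l", l, "_bq")]] <- rep(0, d)
      p[[paste0("l", l, "_Wk")]] <- rmat(d, d); p[[paste0("l", l, "_bk")]] <- rep(0, d)
      p[[paste0("l", l, "_Wv")]] <- rmat(d, d); p[[paste0("l", l, "_bv")]] <- rep(0, d)
      p[[paste0("l", l, "_Wo")]] <- rmat(d, d); p[[paste0("l", l, "_bo")]] <- rep(0, d)
      p[[paste0("l", l, "_ln1g")]] <- rep(1, d); p[[paste0("l", l, "_ln1b")]] <- rep(0, d)
      p[[paste0("l", l, "_W1")]] <- rmat(d, f); p[[paste0("l", l, "_b1")]] <- rep(0, f)
      p[[paste0("l", l, "_W2")]] <- rmat(f, d); p[[paste0("l", l, "_b2")]] <- rep(0, d)
      p[[paste0("l", l, "_ln2g")]] <- rep(1, d); p[[paste0("l", l, "_ln2b")]] <- rep(0, d)
    }
    p$lnf_g <- rep(1, d); p$lnf_b <- rep(0, d)
    # zero head => uniform label scores at initialization
    p$head_W <- matrix(0, d, cfg$n_labels)
    p$head_b <- rep(0, cfg$n_labels)
    p
  })
}

.ln_eps <- 1e-5

row_max <- function(M) M[cbind(seq_len(nrow(M)), max.col(M, ties.method = "first"))]

softmax_rows <- function(M) {
  E <- exp(M - row_max(M))
  E / rowSums(E)
}

# broadcast a row vector over rows via a BLAS outer product (cheaper than sweep)
bcast <- function(n, v) tcrossprod(rep.int(1, n), v)

ln_forward <- function(X, g, b) {
  mu <- rowMeans(X)
  Xc <- X - mu
  inv <- 1 / sqrt(rowMeans(Xc * Xc) + .ln_eps)
  Xhat <- Xc * inv
  list(Y = Xhat * bcast(nrow(X), g) + bcast(nrow(X), b), Xhat = Xhat, inv = inv)
}

# standard layer-norm backward given cached Xhat and inv
ln_backward <- function(dY, cache, g) {
  Xhat <- cache$Xhat
  dg <- colSums(dY * Xhat)
  db <- colSums(dY)
  dXhat <- dY * bcast(nrow(dY), g)
  dX <- cache$inv * (dXhat - rowMeans(dXhat) - Xhat * rowMeans(dXhat * Xhat))
  list(dX = dX, dg = dg, db = db)
}

add_bias <- function(X, b) X + bcast(nrow(X), b)

# ids, mask: B x T matrices (mask TRUE for real tokens). Flat row order is
# sequence-major: row (b-1)*T + t.
nn_forward <- function(p, ids, mask, cfg, keep_attn = FALSE, dropout = 0) {
  B <- nrow(ids); T <- ncol(ids)
  flat_ids <- as.vector(t(ids))
  E <- p$tok_emb[flat_ids, , drop = FALSE]
  ln0 <- ln_forward(E, p$ln0_g, p$ln0_b)
  X <- ln0$Y
  d <- cfg$d_model; H <- cfg$n_heads; dh <- cfg$d_head
  scale <- 1 / sqrt(dh)
  delta <- outer(seq_len(T), seq_len(T), "-")  # i - j: positive when key j precedes query i
  d_left <- pmax(delta, 0); d_right <- pmax(-delta, 0)
  attn_bias <- purrr::map(seq_len(H), function(h) {
    -cfg$alibi_left[h] * d_left - cfg$alibi_right[h] * d_right
  })
  pad <- !mask
  layers <- vector("list", cfg$n_layers)
  attn_maps <- if (keep_attn) vector("list", cfg$n_layers) else NULL
  for (l in seq_len(cfg$n_layers)) {
    Wq <- p[[paste0("l", l, "_Wq")]]; Wk <- p[[paste0("l", l, "_Wk")]]
    Wv <- p[[paste0("l", l, "_Wv")]]; Wo <- p[[paste0("l", l, "_Wo")]]
    ln1 <- ln_forward(X, p[[paste0("l", l, "_ln1g")]], p[[paste0("l", l, "_ln1b")]])
    Y1 <- ln1$Y
    Q <- add_bias(Y1 %*% Wq, p[[paste0("l", l, "_bq")]])
    K <- add_bias(Y1 %*% Wk, p[[paste0("l", l, "_bk")]])
    V <- add_bias(Y1 %*% Wv, p[[paste0("l", l, "_bv")]])
    O <- matrix(0, B * T, d)
    A_list <- vector("list", B * H)
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * T + 1L):(b * T)
      Qb <- Q[rows, , drop = FALSE]; Kb <- K[rows, , drop = FALSE]
      Vb <- V[rows, , drop = FALSE]
      has_pad <- any(pad[b, ])
      for (h in seq_len(H)) {
        cols <- ((h - 1L) * dh + 1L):(h * dh)
        S <- tcrossprod(Qb[, cols, drop = FALSE], Kb[, cols, drop = FALSE]) * scale +
          attn_bias[[h]]
        if (has_pad) S[, pad[b, ]] <- -1e9
        A <- softmax_rows(S)
        A_list[[(b - 1L) * H + h]] <- A
        O[rows, cols] <- A %*% Vb[, cols, drop = FALSE]
      }
    }
    if (keep_attn) attn_maps[[l]] <- A_list
    O2 <- add_bias(O %*% Wo, p[[paste0("l", l, "_bo")]])
    Mo <- NULL
    if (dropout > 0) {
      Mo <- matrix((runif(length(O2)) >= dropout) / (1 - dropout), nrow(O2), ncol(O2))
      O2 <- O2 * Mo
    }
    X_mid <- X + O2
    ln2 <- ln_forward(X_mid, p[[paste0("l", l, "_ln2g")]], p[[paste0("l", l, "_ln2b")]])
    Y2 <- ln2$Y
    pre <- add_bias(Y2 %*% p[[paste0("l", l, "_W1")]], p[[paste0("l", l, "_b1")]])
    Hh <- pre * (pre > 0)
    Fo <- add_bias(Hh %*% p[[paste0("l", l, "_W2")]], p[[paste0("l", l, "_b2")]])
    Mf <- NULL
    if (dropout > 0) {
      Mf <- matrix((runif(length(Fo)) >= dropout) / (1 - dropout), nrow(Fo), ncol(Fo))
      Fo <- Fo * Mf
    }
    layers[[l]] <- list(ln1 = ln1, Y1 = Y1, Q = Q, K = K, V = V, A_list = A_list,
                        O = O, X_mid = X_mid, ln2 = ln2, Y2 = Y2, pre = pre, H = Hh,
                        Mo = Mo, Mf = Mf)
    X <- X_mid + Fo
  }
  lnf <- ln_forward(X, p$lnf_g, p$lnf_b)
  logits <- add_bias(lnf$Y %*% p$head_W, p$head_b)
  list(logits = logits,
       cache = list(flat_ids = flat_ids, B = B, T = T, ln0 = ln0,
                    layers = layers, lnf = lnf),
       attn = attn_maps)
}

nn_backward <- function(p, cache, dlogits, cfg) {
  B <- cache$B; T <- cache$T
  d <- cfg$d_model; H <- cfg$n_heads; dh <- cfg$d_head
  scale <- 1 / sqrt(dh)
  g <- list()
  g$head_W <- crossprod(cache$lnf$Y, dlogits)
  g$head_b <- colSums(dlogits)
  bkf <- ln_backward(tcrossprod(dlogits, p$head_W), cache$lnf, p$lnf_g)
  g$lnf_g <- bkf$dg; g$lnf_b <- bkf$db
  dX <- bkf$dX
  for (l in rev(seq_len(cfg$n_layers))) {
    lc <- cache$layers[[l]]
    # FFN branch: X_out = X_mid + FFN(LN2(X_mid))
    dFo <- if (is.null(lc$Mf)) dX else dX * lc$Mf
    g[[paste0("l", l, "_W2")]] <- crossprod(lc$H, dFo)
    g[[paste0("l", l, "_b2")]] <- colSums(dFo)
    dH <- tcrossprod(dFo, p[[paste0("l", l, "_W2")]])
    dpre <- dH * (lc$pre > 0)
    g[[paste0("l", l, "_W1")]] <- crossprod(lc$Y2, dpre)
    g[[paste0("l", l, "_b1")]] <- colSums(dpre)
    bk2 <- ln_backward(tcrossprod(dpre, p[[paste0("l", l, "_W1")]]), lc$ln2,
                       p[[paste0("l", l, "_ln2g")]])
    g[[paste0("l", l, "_ln2g")]] <- bk2$dg; g[[paste0("l", l, "_ln2b")]] <- bk2$db
    dX_mid <- dX + bk2$dX
    # attention branch: X_mid = X_in + Wo(attn(LN1(X_in)))
    dO2 <- if (is.null(lc$Mo)) dX_mid else dX_mid * lc$Mo
    g[[paste0("l", l, "_Wo")]] <- crossprod(lc$O, dO2)
    g[[paste0("l", l, "_bo")]] <- colSums(dO2)
    dO <- tcrossprod(dO2, p[[paste0("l", l, "_Wo")]])
    dQ <- matrix(0, B * T, d); dK <- matrix(0, B * T, d); dV <- matrix(0, B * T, d)
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * T + 1L):(b * T)
      Qb <- lc$Q[rows, , drop = FALSE]; Kb <- lc$K[rows, , drop = FALSE]
      Vb <- lc$V[rows, , drop = FALSE]; dOb_all <- dO[rows, , drop = FALSE]
      for (h in seq_len(H)) {
        cols <- ((h - 1L) * dh + 1L):(h * dh)
        A <- lc$A_list[[(b - 1L) * H + h]]
        dOb <- dOb_all[, cols, drop = FALSE]
        dA <- tcrossprod(dOb, Vb[, cols, drop = FALSE])
        dV[rows, cols] <- crossprod(A, dOb)
        dS <- A * (dA - rowSums(dA * A))
        dQ[rows, cols] <- dS %*% Kb[, cols, drop = FALSE] * scale
        dK[rows, cols] <- crossprod(dS, Qb[, cols, drop = FALSE]) * scale
      }
    }
    g[[paste0("l", l, "_Wq")]] <- crossprod(lc$Y1, dQ); g[[paste0("l", l, "_bq")]] <- colSums(dQ)
    g[[paste0("l", l, "_Wk")]] <- crossprod(lc$Y1, dK); g[[paste0("l", l, "_bk")]] <- colSums(dK)
    g[[paste0("l", l, "_Wv")]] <- crossprod(lc$Y1, dV); g[[paste0("l", l, "_bv")]] <- colSums(dV)
    dY1 <- tcrossprod(dQ, p[[paste0("l", l, "_Wq")]]) +
      tcrossprod(dK, p[[paste0("l", l, "_Wk")]]) +
      tcrossprod(dV, p[[paste0("l", l, "_Wv")]])
    bk1 <- ln_backward(dY1, lc$ln1, p[[paste0("l", l, "_ln1g")]])
    g[[paste0("l", l, "_ln1g")]] <- bk1$dg; g[[paste0("l", l, "_ln1b")]] <- bk1$db
    dX <- dX_mid + bk1$dX
  }
  bk0 <- ln_backward(dX, cache$ln0, p$ln0_g)
  g$ln0_g <- bk0$dg; g$ln0_b <- bk0$db
  dE <- bk0$dX
  g$tok_emb <- matrix(0, cfg$vocab_size, d)
  agg <- rowsum(dE, group = cache$flat_ids)
  g$tok_emb[as.integer(rownames(agg)), ] <- agg
  g
}

# labels: B x T integer (1-based label ids), NA on padding.
nn_loss_grad <- function(p, ids, mask, labels, cfg, dropout = 0) {
  fw <- nn_forward(p, ids, mask, cfg, dropout = dropout)
  flat_lab <- as.vector(t(labels))
  valid <- which(!is.na(flat_lab))
  probs <- softmax_rows(fw$logits)
  loss <- -mean(log(probs[cbind(valid, flat_lab[valid])] + 1e-12))
  Y <- matrix(0, nrow(probs), ncol(probs))
  Y[cbind(valid, flat_lab[valid])] <- 1
  dlogits <- probs - Y
  dlogits[setdiff(seq_len(nrow(probs)), valid), ] <- 0
  dlogits <- dlogits / length(valid)
  list(loss = loss, grads = nn_backward(p, fw$cache, dlogits, cfg))
}

adam_init <- function(p) {
  list(m = purrr::map(p, ~ .x * 0), v = purrr::map(p, ~ .x * 0), t = 0L)
}

# Adam with decoupled weight decay on weight matrices (gains/biases exempt)
adam_step <- function(p, g, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      weight_decay = 0) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(p)) {
    gi <- g[[nm]]
    if (is.null(gi)) next
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * gi
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * gi * gi
    step <- (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
    if (weight_decay > 0 && is.matrix(p[[nm]])) step <- step + weight_decay * p[[nm]]
    p[[nm]] <- p[[nm]] - lr * step
  }
  list(p = p, state = st)
}
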