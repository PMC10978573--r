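# Internal BERT-style encoder: token + learned positional embeddings,
# pre-LayerNorm multi-head self-attention blocks with GELU feed-forward,
# and a linear vocabulary head. Forward, backward and AdamW are written
# directly in base R matrix ops; activations are cached per layer for the
# backward pass. Row layout of all (B*L) x d matrices is batch-major:
# row (b-1)*L + l holds position l of sequence b.

.softmax_rows <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}

.gelu <- function(x) x * stats::pnorm(x)
.dgelu <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

.ln_forward <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * inv
  Y <- sweep(xhat, 2L, g, "*")
  Y <- sweep(Y, 2L, b, "+")
  list(Y = Y, xhat = xhat, inv = inv)
}

.ln_backward <- function(dY, cache, g) {
  dxhat <- sweep(dY, 2L, g, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  dX <- cache$inv * (dxhat - m1 - cache$xhat * m2)
  list(dX = dX,
       dg = colSums(dY * cache$xhat),
       db = colSums(dY))
}

.init_params <- function(cfg) {
  d <- cfg$embedding_dim
  ff <- cfg$feedforward_dim
  V <- .vocab_size()
  rn <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 0.02), nr, nc)
  p <- list(
    tok_emb = rn(V, d),
    pos_emb = rn(cfg$max_positions, d),
    lnf_g = rep(1, d), lnf_b = rep(0, d),
    W_out = rn(d, V), b_out = rep(0, V)
  )
  for (l in seq_len(cfg$n_layers)) {
    pre <- sprintf("L%d.", l)
    p[[paste0(pre, "Wq")]] <- rn(d, d); p[[paste0(pre, "bq")]] <- rep(0, d)
    p[[paste0(pre, "Wk")]] <- rn(d, d); p[[paste0(pre, "bk")]] <- rep(0, d)
    p[[paste0(pre, "Wv")]] <- rn(d, d); p[[paste0(pre, "bv")]] <- rep(0, d)
    p[[paste0(pre, "Wo")]] <- rn(d, d); p[[paste0(pre, "bo")]] <- rep(0, d)
    p[[paste0(pre, "ln1_g")]] <- rep(1, d); p[[paste0(pre, "ln1_b")]] <- rep(0, d)
    p[[paste0(pre, "ln2_g")]] <- rep(1, d); p[[paste0(pre, "ln2_b")]] <- rep(0, d)
    p[[paste0(pre, "W1")]] <- rn(d, ff); p[[paste0(pre, "b1")]] <- rep(0, ff)
    p[[paste0(pre, "W2")]] <- rn(ff, d); p[[paste0(pre, "b2")]] <- rep(0, d)
  }
  p
}

.param_count <- function(params) sum(vapply(params, length, integer(1)))

.affine <- function(X, W, b) sweep(X %*% W, 2L, b, "+")

# ids: integer B x L token-id matrix (CLS/SEP included, PAD allowed).
.encoder_forward <- function(params, cfg, ids, train = FALSE) {
  B <- nrow(ids); L <- ncol(ids)
  if (L > cfg$max_positions)
    stop("sequence length ", L, " exceeds max_positions ", cfg$max_positions)
  idv <- as.integer(t(ids))
  posv <- rep(seq_len(L), B)
  X <- params$tok_emb[idv, , drop = FALSE] + params$pos_emb[posv, , drop = FALSE]
  d <- cfg$embedding_dim
  nh <- cfg$n_heads
  dh <- d %/% nh
  pad_id <- .special_id("PAD")
  has_pad <- any(ids == pad_id)
  keymask <- NULL
  if (has_pad) {
    # additive mask per sequence: -1e30 on PAD key columns
    keymask <- lapply(seq_len(B), function(b) {
      m <- rep(0, L); m[ids[b, ] == pad_id] <- -1e30
      matrix(m, L, L, byrow = TRUE)
    })
  }
  p <- if (train) cfg$dropout else 0
  caches <- vector("list", cfg$n_layers)
  for (l in seq_len(cfg$n_layers)) {
    pre <- sprintf("L%d.", l)
    Xin <- X
    ln1 <- .ln_forward(X, params[[paste0(pre, "ln1_g")]], params[[paste0(pre, "ln1_b")]])
    H <- ln1$Y
    Q <- .affine(H, params[[paste0(pre, "Wq")]], params[[paste0(pre, "bq")]])
    K <- .affine(H, params[[paste0(pre, "Wk")]], params[[paste0(pre, "bk")]])
    V <- .affine(H, params[[paste0(pre, "Wv")]], params[[paste0(pre, "bv")]])
    conc <- matrix(0, B * L, d)
    A_list <- vector("list", B)
    sc <- 1 / sqrt(dh)
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * L + 1L):(b * L)
      Ab <- vector("list", nh)
      for (h in seq_len(nh)) {
        cols <- ((h - 1L) * dh + 1L):(h * dh)
        S <- tcrossprod(Q[rows, cols, drop = FALSE], K[rows, cols, drop = FALSE]) * sc
        if (has_pad) S <- S + keymask[[b]]
        A <- .softmax_rows(S)
        conc[rows, cols] <- A %*% V[rows, cols, drop = FALSE]
        Ab[[h]] <- A
      }
      A_list[[b]] <- Ab
    }
    O <- .affine(conc, params[[paste0(pre, "Wo")]], params[[paste0(pre, "bo")]])
    drop1 <- NULL
    if (p > 0) {
      drop1 <- matrix(stats::rbinom(length(O), 1L, 1 - p), nrow(O)) / (1 - p)
      O <- O * drop1
    }
    X <- Xin + O
    Xmid <- X
    ln2 <- .ln_forward(X, params[[paste0(pre, "ln2_g")]], params[[paste0(pre, "ln2_b")]])
    H2 <- ln2$Y
    Z1 <- .affine(H2, params[[paste0(pre, "W1")]], params[[paste0(pre, "b1")]])
    G <- .gelu(Z1)
    F2 <- .affine(G, params[[paste0(pre, "W2")]], params[[paste0(pre, "b2")]])
    drop2 <- NULL
    if (p > 0) {
      drop2 <- matrix(stats::rbinom(length(F2), 1L, 1 - p), nrow(F2)) / (1 - p)
      F2 <- F2 * drop2
    }
    X <- Xmid + F2
    caches[[l]] <- list(ln1 = ln1, H = H, Q = Q, K = K, V = V, A = A_list,
                        conc = conc, drop1 = drop1, ln2 = ln2, H2 = H2,
                        Z1 = Z1, G = G, drop2 = drop2)
  }
  lnf <- .ln_forward(X, params$lnf_g, params$lnf_b)
  list(h = lnf$Y,
       cache = list(layers = caches, lnf = lnf, idv = idv, posv = posv,
                    B = B, L = L))
}

# dH: gradient w.r.t. the final hidden states (B*L x d).
# Returns grads for every parameter except the vocabulary head (handled by
# the caller, which knows which rows carry loss).
.encoder_backward <- function(params, cfg, cache, dH) {
  B <- cache$B; L <- cache$L
  d <- cfg$embedding_dim
  nh <- cfg$n_heads
  dh <- d %/% nh
  g <- list()
  lb <- .ln_backward(dH, cache$lnf, params$lnf_g)
  g$lnf_g <- lb$dg; g$lnf_b <- lb$db
  dX <- lb$dX
  sc <- 1 / sqrt(dh)
  for (l in rev(seq_len(cfg$n_layers))) {
    pre <- sprintf("L%d.", l)
    cc <- cache$layers[[l]]
    # FFN block
    dF2 <- dX
    if (!is.null(cc$drop2)) dF2 <- dF2 * cc$drop2
    g[[paste0(pre, "W2")]] <- crossprod(cc$G, dF2)
    g[[paste0(pre, "b2")]] <- colSums(dF2)
    dG <- dF2 %*% t(params[[paste0(pre, "W2")]])
    dZ1 <- dG * .dgelu(cc$Z1)
    g[[paste0(pre, "W1")]] <- crossprod(cc$H2, dZ1)
    g[[paste0(pre, "b1")]] <- colSums(dZ1)
    dH2 <- dZ1 %*% t(params[[paste0(pre, "W1")]])
    lb2 <- .ln_backward(dH2, cc$ln2, params[[paste0(pre, "ln2_g")]])
    g[[paste0(pre, "ln2_g")]] <- lb2$dg
    g[[paste0(pre, "ln2_b")]] <- lb2$db
    dX <- dX + lb2$dX   # residual: dXmid = dX(out) + d from LN path
    # Attention block
    dO <- dX
    if (!is.null(cc$drop1)) dO <- dO * cc$drop1
    g[[paste0(pre, "Wo")]] <- crossprod(cc$conc, dO)
    g[[paste0(pre, "bo")]] <- colSums(dO)
    dconc <- dO %*% t(params[[paste0(pre, "Wo")]])
    dQ <- matrix(0, B * L, d); dK <- matrix(0, B * L, d); dV <- matrix(0, B * L, d)
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * L + 1L):(b * L)
      for (h in seq_len(nh)) {
        cols <- ((h - 1L) * dh + 1L):(h * dh)
        A <- cc$A[[b]][[h]]
        dCh <- dconc[rows, cols, drop = FALSE]
        Vh <- cc$V[rows, cols, drop = FALSE]
        dA <- tcrossprod(dCh, Vh)
        dV[rows, cols] <- crossprod(A, dCh)
        dS <- A * (dA - rowSums(dA * A))
        dQ[rows, cols] <- (dS %*% cc$K[rows, cols, drop = FALSE]) * sc
        dK[rows, cols] <- crossprod(dS, cc$Q[rows, cols, drop = FALSE]) * sc
      }
    }
    g[[paste0(pre, "Wq")]] <- crossprod(cc$H, dQ)
    g[[paste0(pre, "bq")]] <- colSums(dQ)
    g[[paste0(pre, "Wk")]] <- crossprod(cc$H, dK)
    g[[paste0(pre, "bk")]] <- colSums(dK)
    g[[paste0(pre, "Wv")]] <- crossprod(cc$H, dV)
    g[[paste0(pre, "bv")]] <- colSums(dV)
    dHln <- dQ %*% t(params[[paste0(pre, "Wq")]]) +
            dK %*% t(params[[paste0(pre, "Wk")]]) +
            dV %*% t(params[[paste0(pre, "Wv")]])
    lb1 <- .ln_backward(dHln, cc$ln1, params[[paste0(pre, "ln1_g")]])
    g[[paste0(pre, "ln1_g")]] <- lb1$dg
    g[[paste0(pre, "ln1_b")]] <- lb1$db
    dX <- dX + lb1$dX
  }
  # Embedding grads
  V <- .vocab_size()
  dTok <- matrix(0, V, cfg$embedding_dim)
  rs <- rowsum(dX, cache$idv)
  dTok[as.integer(rownames(rs)), ] <- rs
  dPos <- matrix(0, cfg$max_positions, cfg$embedding_dim)
  rs2 <- rowsum(dX, cache$posv)
  dPos[as.integer(rownames(rs2)), ] <- rs2
  g$tok_emb <- dTok
  g$pos_emb <- dPos
  g
}

# Cross-entropy over labelled rows of the final hidden states.
# rows: indices into the (B*L) layout; targets: token ids.
# Returns loss (nats per labelled position), dH (full matrix) and head grads.
.mlm_loss_backward <- function(params, h, rows, targets) {
  Hr <- h[rows, , drop = FALSE]
  logits <- .affine(Hr, params$W_out, params$b_out)
  pr <- .softmax_rows(logits)
  n <- length(rows)
  loss <- -mean(log(pmax(pr[cbind(seq_len(n), targets)], 1e-12)))
  dlog <- pr
  dlog[cbind(seq_len(n), targets)] <- dlog[cbind(seq_len(n), targets)] - 1
  dlog <- dlog / n
  dW_out <- crossprod(Hr, dlog)
  db_out <- colSums(dlog)
  dH <- matrix(0, nrow(h), ncol(h))
  dH[rows, ] <- dlog %*% t(params$W_out)
  list(loss = loss, dH = dH, dW_out = dW_out, db_out = db_out)
}

.mlm_loss_only <- function(params, h, rows, targets) {
  Hr <- h[rows, , drop = FALSE]
  logits <- .affine(Hr, params$W_out, params$b_out)
  pr <- .softmax_rows(logits)
  -mean(log(pmax(pr[cbind(seq_along(rows), targets)], 1e-12)))
}

# ---- AdamW -----------------------------------------------------------------

.adam_new <- function(params) {
  zero <- lapply(params, function(p) p * 0)
  list(m = zero, v = zero, t = 0L)
}

.adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, weight_decay = 0.01) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(grads)) {
    gr <- grads[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * gr
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * gr * gr
    upd <- (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
    if (weight_decay > 0 && is.matrix(params[[nm]]))
      upd <- upd + weight_decay * params[[nm]]
    params[[nm]] <- params[[nm]] - lr * upd
  }
  list(params = params, state = st)
}

# Linear warmup then linear decay to zero.
.lr_at <- function(step, total_steps, lr, warmup_frac = 0.1) {
  w <- max(1, floor(warmup_frac * total_steps))
  if (step <= w) return(lr * step / w)
  lr * max(0.05, (total_steps - step) / max(1, total_steps - w))
}
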