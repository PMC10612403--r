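# Core numerics for the self-attention encoder: parameter initialisation,
# forward pass with attention capture, and the hand-written backward pass.
# All passes operate on one sequence at a time (T x d matrices); batching is
# done by gradient accumulation in the training loop, which makes the
# micro-batch / accumulation split exactly equivalent to one large batch.

LN_EPS <- 1e-5

# sinusoidal positional encoding, rows = positions, cols = embedding dims
positional_encoding <- function(T, d) {
  pos <- seq_len(T) - 1
  i <- seq_len(d) - 1
  angle <- outer(pos, 10000^(-(i %/% 2 * 2) / d))
  pe <- matrix(0, T, d)
  even <- i %% 2 == 0
  pe[, even] <- sin(angle[, even, drop = FALSE])
  pe[, !even] <- cos(angle[, !even, drop = FALSE])
  pe
}

glorot <- function(nin, nout) {
  matrix(rnorm(nin * nout, sd = sqrt(2 / (nin + nout))), nin, nout)
}

# parameter container; draws from the current RNG state
init_params <- function(config, n_classes) {
  d <- config$embed_dim; f <- config$ff_dim; V <- length(config$vocab)
  layer <- function() list(
    Wq = glorot(d, d), bq = numeric(d),
    Wk = glorot(d, d), bk = numeric(d),
    Wv = glorot(d, d), bv = numeric(d),
    Wo = glorot(d, d), bo = numeric(d),
    g1 = rep(1, d), b1 = numeric(d),
    W1 = glorot(d, f), bf1 = numeric(f),
    W2 = glorot(f, d), bf2 = numeric(d),
    g2 = rep(1, d), b2 = numeric(d))
  list(E = matrix(rnorm(V * d, sd = 1 / sqrt(d)), V, d),
       layers = replicate(config$n_layers, layer(), simplify = FALSE),
       gh = rep(1, d), bh = numeric(d),
       Wc = glorot(d, n_classes), bc = numeric(n_classes))
}

zero_like <- function(x) {
  if (is.list(x)) lapply(x, zero_like) else x * 0
}

softmax_rows <- function(S) {
  S <- S - apply(S, 1L, max)
  E <- exp(S)
  E / rowSums(E)
}

softmax_vec <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

ln_fwd <- function(X, g, b) {
  mu <- rowMeans(X)
  Xc <- X - mu
  sdv <- sqrt(rowMeans(Xc^2) + LN_EPS)
  Xhat <- Xc / sdv
  list(Y = sweep(Xhat, 2L, g, "*") + rep(b, each = nrow(X)),
       Xhat = Xhat, sdv = sdv)
}

# standard layer-norm backward (population variance)
ln_bwd <- function(dY, cache, g) {
  Xhat <- cache$Xhat
  dXhat <- sweep(dY, 2L, g, "*")
  m1 <- rowMeans(dXhat)
  m2 <- rowMeans(dXhat * Xhat)
  list(dX = (dXhat - m1 - Xhat * m2) / cache$sdv,
       dg = colSums(dY * Xhat),
       db = colSums(dY))
}

# Forward pass over one tokenized sequence.
# dropout_mask: NULL (evaluation) or a premultiplied keep/scale vector of
# length embed_dim applied to the normalised CLS embedding.
# Returns logits, the (L*H, T, T) attention tensor and the cache needed by
# encoder_backward.
encoder_forward <- function(params, config, tokens,
                            dropout_mask = NULL, keep_cache = TRUE,
                            X0_override = NULL) {
  d <- config$embed_dim; H <- config$n_heads; L <- config$n_layers
  dh <- d %/% H
  idx <- tokens$tokens
  T <- tokens$T
  # embeddings are scaled by sqrt(d) before the O(1) sinusoidal positions
  # are added, so token identity is not drowned by position
  X0 <- if (is.null(X0_override))
    params$E[idx, , drop = FALSE] * sqrt(d) + positional_encoding(T, d)
  else X0_override
  scal <- 1 / sqrt(dh)

  # pre-LN blocks: x + Attn(LN(x)), then r + FFN(LN(r))
  attn <- array(NA_real_, c(L * H, T, T))
  caches <- vector("list", L)
  X <- X0
  for (l in seq_len(L)) {
    p <- params$layers[[l]]
    ln1 <- ln_fwd(X, p$g1, p$b1)
    N1 <- ln1$Y
    Q <- N1 %*% p$Wq + rep(p$bq, each = T)
    K <- N1 %*% p$Wk + rep(p$bk, each = T)
    Vm <- N1 %*% p$Wv + rep(p$bv, each = T)
    A_heads <- vector("list", H)
    O <- matrix(0, T, d)
    for (h in seq_len(H)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      A <- softmax_rows(tcrossprod(Q[, cols, drop = FALSE],
                                   K[, cols, drop = FALSE]) * scal)
      A_heads[[h]] <- A
      attn[(l - 1L) * H + h, , ] <- A
      O[, cols] <- A %*% Vm[, cols, drop = FALSE]
    }
    R1 <- X + O %*% p$Wo + rep(p$bo, each = T)
    ln2 <- ln_fwd(R1, p$g2, p$b2)
    N2 <- ln2$Y
    Z1 <- N2 %*% p$W1 + rep(p$bf1, each = T)
    F1 <- pmax(Z1, 0)
    X2 <- R1 + F1 %*% p$W2 + rep(p$bf2, each = T)
    if (keep_cache)
      caches[[l]] <- list(X = X, ln1 = ln1, N1 = N1, Q = Q, K = K, V = Vm,
                          A = A_heads, O = O, R1 = R1, ln2 = ln2, N2 = N2,
                          Z1 = Z1, F1 = F1)
    X <- X2
  }
  cls_i <- which(tokens$special_mask & tokens$symbols == TOK_CLS)
  cvec <- X[cls_i, ]
  lnh <- ln_fwd(matrix(cvec, 1L), params$gh, params$bh)
  ch <- drop(lnh$Y)
  chd <- if (is.null(dropout_mask)) ch else ch * dropout_mask
  logits <- drop(chd %*% params$Wc) + params$bc
  list(logits = logits, attn = attn,
       cache = if (keep_cache)
         list(X0 = X0, idx = idx, caches = caches, Xfinal = X,
              cls_i = cls_i, lnh = lnh, ch = ch, chd = chd,
              dropout_mask = dropout_mask, T = T))
}

# Backward pass from a gradient on the logits.  Returns the parameter
# gradient (same shape as params) and the gradient with respect to the
# input embedding matrix X0 (T x d), used by gradient-based saliency.
encoder_backward <- function(params, config, cache, dlogits) {
  d <- config$embed_dim; H <- config$n_heads; L <- config$n_layers
  dh <- d %/% H
  T <- cache$T
  scal <- 1 / sqrt(dh)
  g <- zero_like(params)

  g$Wc <- outer(cache$chd, dlogits)
  g$bc <- dlogits
  dchd <- drop(params$Wc %*% dlogits)
  dch <- if (is.null(cache$dropout_mask)) dchd else dchd * cache$dropout_mask
  lb <- ln_bwd(matrix(dch, 1L), cache$lnh, params$gh)
  g$gh <- lb$dg; g$bh <- lb$db
  dX <- matrix(0, T, d)
  dX[cache$cls_i, ] <- lb$dX

  for (l in rev(seq_len(L))) {
    p <- params$layers[[l]]
    cc <- cache$caches[[l]]
    gl <- g$layers[[l]]

    # X2 = R1 + relu(LN(R1) W1 + b) W2 + b
    dR1 <- dX
    dF2 <- dX
    gl$W2 <- crossprod(cc$F1, dF2)
    gl$bf2 <- colSums(dF2)
    dF1 <- tcrossprod(dF2, p$W2)
    dZ1 <- dF1 * (cc$Z1 > 0)
    gl$W1 <- crossprod(cc$N2, dZ1)
    gl$bf1 <- colSums(dZ1)
    dN2 <- tcrossprod(dZ1, p$W1)
    lb2 <- ln_bwd(dN2, cc$ln2, p$g2)
    gl$g2 <- lb2$dg; gl$b2 <- lb2$db
    dR1 <- dR1 + lb2$dX

    # R1 = X + MultiHead(LN(X)) Wo + bo
    dXlayer <- dR1
    dAttnOut <- dR1
    gl$Wo <- crossprod(cc$O, dAttnOut)
    gl$bo <- colSums(dAttnOut)
    dO <- tcrossprod(dAttnOut, p$Wo)

    dQ <- matrix(0, T, d); dK <- matrix(0, T, d); dV <- matrix(0, T, d)
    for (h in seq_len(H)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      A <- cc$A[[h]]
      dOh <- dO[, cols, drop = FALSE]
      Vh <- cc$V[, cols, drop = FALSE]
      dA <- tcrossprod(dOh, Vh)
      dV[, cols] <- crossprod(A, dOh)
      dS <- A * (dA - rowSums(dA * A))
      dS <- dS * scal
      dQ[, cols] <- dS %*% cc$K[, cols, drop = FALSE]
      dK[, cols] <- crossprod(dS, cc$Q[, cols, drop = FALSE])
    }
    gl$Wq <- crossprod(cc$N1, dQ); gl$bq <- colSums(dQ)
    gl$Wk <- crossprod(cc$N1, dK); gl$bk <- colSums(dK)
    gl$Wv <- crossprod(cc$N1, dV); gl$bv <- colSums(dV)
    dN1 <- tcrossprod(dQ, p$Wq) + tcrossprod(dK, p$Wk) +
      tcrossprod(dV, p$Wv)
    lb1 <- ln_bwd(dN1, cc$ln1, p$g1)
    gl$g1 <- lb1$dg; gl$b1 <- lb1$db
    dXlayer <- dXlayer + lb1$dX
    g$layers[[l]] <- gl
    dX <- dXlayer
  }
  dE <- matrix(0, nrow(params$E), d)
  for (t in seq_len(T)) {
    r <- cache$idx[t]
    dE[r, ] <- dE[r, ] + dX[t, ] * sqrt(d)
  }
  g$E <- dE
  list(grad = g, dX0 = dX)
}

# accumulate one gradient structure into another (same shapes)
grad_add <- function(a, b, w = 1) {
  if (is.list(a)) Map(grad_add, a, b, MoreArgs = list(w = w)) else a + w * b
}

cross_entropy <- function(logits, y) {
  p <- softmax_vec(logits)
  list(loss = -log(max(p[y], 1e-300)), dlogits = {
    d <- p; d[y] <- d[y] - 1; d
  }, prob = p)
}
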