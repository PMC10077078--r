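# ---------------------------------------------------------------------------
# Minimal convolutional-network engine.
#
# Activations live in layout (P, N, C): P = H*W spatial positions
# (column-major within the image), N = batch, C = channels. Convolutions are
# 3x3 'valid', computed by gathering image patches into a matrix (im2col) and
# multiplying by the weight matrix, so all heavy arithmetic is one BLAS call
# per layer per batch. The backward scatter (col2im) is a precomputed sparse
# matrix-vector product. 2x2/stride-2 max pooling drops a trailing odd
# row/column.
# ---------------------------------------------------------------------------

conv_geom <- function(H, W, Cin, k = 3L) {
  Hout <- H - k + 1L
  Wout <- W - k + 1L
  i <- rep(seq_len(Hout), Wout)
  j <- rep(seq_len(Wout), each = Hout)
  anchor <- i + (j - 1L) * H
  offs <- as.vector(outer(0:(k - 1L), (0:(k - 1L)) * H, "+"))
  ent <- as.vector(outer(offs, (0:(Cin - 1L)) * H * W, "+"))
  I <- as.vector(outer(ent, anchor - 1L, "+")) + 1L  # entry-fastest, then pos
  scatter <- Matrix::sparseMatrix(i = I, j = seq_along(I), x = 1,
                                  dims = c(H * W * Cin, length(I)))
  list(H = H, W = W, Cin = Cin, k = k, Hout = Hout, Wout = Wout,
       P = Hout * Wout, I = I, scatter = scatter)
}

pool_geom <- function(H, W) {
  Hp <- H %/% 2L
  Wp <- W %/% 2L
  i <- rep(seq_len(Hp), Wp)
  j <- rep(seq_len(Wp), each = Hp)
  idx <- function(a, b) (2L * i - 1L + a) + (2L * j - 1L + b - 1L) * H
  list(H = H, W = W, Hp = Hp, Wp = Wp, P = Hp * Wp,
       idx = list(idx(0L, 0L), idx(1L, 0L), idx(0L, 1L), idx(1L, 1L)))
}

conv_forward <- function(A, g, Wm, b) {
  # A: (H*W, N, Cin) -> out (P, N, Cout); returns cache for backward
  N <- dim(A)[2]
  M <- matrix(aperm(A, c(1, 3, 2)), g$H * g$W * g$Cin, N)
  P <- M[g$I, , drop = FALSE]
  dim(P) <- c(g$k * g$k * g$Cin, g$P * N)
  Z <- crossprod(P, Wm)
  Z <- Z + matrix(b, nrow(Z), length(b), byrow = TRUE)
  dim(Z) <- c(g$P, N, length(b))
  list(out = Z, P = P, N = N)
}

conv_backward <- function(dOut, cache, g, Wm) {
  N <- cache$N
  Cout <- dim(dOut)[3]
  dZ <- matrix(dOut, g$P * N, Cout)
  dW <- cache$P %*% dZ
  db <- colSums(dZ)
  dP <- tcrossprod(Wm, dZ)               # (k2Cin, P*N)
  dim(dP) <- c(g$k * g$k * g$Cin * g$P, N)
  dM <- as.matrix(g$scatter %*% dP)      # (H*W*Cin, N)
  dA <- aperm(array(dM, c(g$H * g$W, g$Cin, N)), c(1, 3, 2))
  list(dA = dA, dW = dW, db = db)
}

pool_forward <- function(A, pg) {
  A1 <- A[pg$idx[[1]], , , drop = FALSE]
  A2 <- A[pg$idx[[2]], , , drop = FALSE]
  A3 <- A[pg$idx[[3]], , , drop = FALSE]
  A4 <- A[pg$idx[[4]], , , drop = FALSE]
  out <- pmax(A1, A2, A3, A4)
  list(out = out, slices = list(A1, A2, A3, A4))
}

pool_backward <- function(dOut, cache, pg, N, C) {
  out <- pmax(cache$slices[[1]], cache$slices[[2]],
              cache$slices[[3]], cache$slices[[4]])
  dA <- array(0, c(pg$H * pg$W, N, C))
  taken <- array(FALSE, dim(out))
  for (q in 1:4) {
    m <- (cache$slices[[q]] == out) & !taken
    taken <- taken | m
    dA[pg$idx[[q]], , ] <- m * dOut
  }
  dA
}

he_init <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
}

# Build parameter list + geometry for the given architecture.
cnn_init <- function(side, conv_widths, dense_units, n_classes) {
  H <- side; Wd <- side; Cin <- 1L
  geoms <- list(); pools <- list(); params <- list(conv = list())
  for (li in seq_along(conv_widths)) {
    if (H < 3L || Wd < 3L) {
      stop2("input side ", side, " too small for ", length(conv_widths),
            " conv blocks")
    }
    g <- conv_geom(H, Wd, Cin)
    pg <- pool_geom(g$Hout, g$Wout)
    geoms[[li]] <- g; pools[[li]] <- pg
    params$conv[[li]] <- list(W = he_init(9L * Cin, conv_widths[li]),
                              b = rep(0, conv_widths[li]))
    Cin <- conv_widths[li]; H <- pg$Hp; Wd <- pg$Wp
  }
  if (H < 1L || Wd < 1L) stop2("input side too small: empty feature map")
  emb_dim <- Cin
  params$W1 <- he_init(emb_dim, dense_units)
  params$b1 <- rep(0, dense_units)
  params$W2 <- he_init(dense_units, n_classes)
  params$b2 <- rep(0, n_classes)
  list(params = params, geoms = geoms, pools = pools, emb_dim = emb_dim,
       conv_widths = conv_widths, side = side, n_classes = n_classes)
}

# Forward pass. X: array (side*side, N, 1). Returns logits, probs, embedding
# and (if keep = TRUE) every cache needed for the backward pass.
cnn_forward <- function(net, params, X, dropout_rate = 0, train = FALSE,
                        keep = FALSE) {
  N <- dim(X)[2]
  A <- X
  caches <- list()
  for (li in seq_along(net$geoms)) {
    g <- net$geoms[[li]]; pg <- net$pools[[li]]
    cf <- conv_forward(A, g, params$conv[[li]]$W, params$conv[[li]]$b)
    R <- pmax(cf$out, 0)
    pf <- pool_forward(R, pg)
    if (keep) caches[[li]] <- list(conv = cf, relu = R, pool = pf)
    A <- pf$out
  }
  lastC <- net$conv_widths[length(net$conv_widths)]
  Pn <- dim(A)[1]
  emb <- matrix(colMeans(matrix(A, Pn, N * lastC)), N, lastC)
  H1 <- emb %*% params$W1
  H1 <- H1 + matrix(params$b1, N, length(params$b1), byrow = TRUE)
  R1 <- pmax(H1, 0)
  drop_mask <- NULL
  if (train && dropout_rate > 0) {
    drop_mask <- matrix((stats::runif(length(R1)) >= dropout_rate) /
                          (1 - dropout_rate), nrow(R1), ncol(R1))
    R1 <- R1 * drop_mask
  }
  logits <- R1 %*% params$W2
  logits <- logits + matrix(params$b2, N, length(params$b2), byrow = TRUE)
  mx <- apply(logits, 1, max)
  ex <- exp(logits - mx)
  probs <- ex / rowSums(ex)
  out <- list(logits = logits, probs = probs, emb = emb)
  if (keep) {
    out$caches <- caches; out$R1 <- R1; out$H1 <- H1
    out$drop_mask <- drop_mask; out$last_pool_P <- Pn; out$N <- N
  }
  out
}

# Backward pass from dLogits; returns gradients for every parameter and,
# when to_conv = TRUE, the gradient at the last conv ReLU output (Grad-CAM).
cnn_backward <- function(net, params, fw, dLogits, to_conv = FALSE) {
  N <- fw$N
  grads <- list(conv = vector("list", length(net$geoms)))
  grads$W2 <- crossprod(fw$R1, dLogits)
  grads$b2 <- colSums(dLogits)
  dR1 <- tcrossprod(dLogits, params$W2)
  if (!is.null(fw$drop_mask)) dR1 <- dR1 * fw$drop_mask
  dH1 <- dR1 * (fw$H1 > 0)
  grads$W1 <- crossprod(fw$emb, dH1)
  grads$b1 <- colSums(dH1)
  dEmb <- tcrossprod(dH1, params$W1)       # (N, lastC)
  Pn <- fw$last_pool_P
  lastC <- ncol(dEmb)
  dA <- array(rep(as.vector(dEmb), each = Pn) / Pn, c(Pn, N, lastC))
  for (li in rev(seq_along(net$geoms))) {
    g <- net$geoms[[li]]; pg <- net$pools[[li]]
    ch <- net$conv_widths[li]
    cc <- fw$caches[[li]]
    dR <- pool_backward(dA, cc$pool, pg, N, ch)
    if (to_conv && li == length(net$geoms)) {
      grads$d_last_relu <- dR
    }
    dZ <- dR * (cc$conv$out > 0)
    cb <- conv_backward(dZ, cc$conv, g, params$conv[[li]]$W)
    grads$conv[[li]] <- list(W = cb$dW, b = cb$db)
    dA <- cb$dA
  }
  grads
}

# --- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  zero_like <- function(p) rapply(p, function(x) x * 0, how = "replace")
  list(m = zero_like(params), v = zero_like(params), t = 0)
}

adam_step <- function(params, grads, state, lr, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  upd <- function(p, g, m, v) {
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g * g
    mh <- m / (1 - b1^state$t)
    vh <- v / (1 - b2^state$t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (k in seq_along(p)) {
        r <- walk(p[[k]], g[[k]], m[[k]], v[[k]])
        out_p[[k]] <- r$p; out_m[[k]] <- r$m; out_v[[k]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else upd(p, g, m, v)
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = state$t))
}

cross_entropy <- function(probs, Y) {
  -mean(log(pmax(rowSums(probs * Y), 1e-12)))
}
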