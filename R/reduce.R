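#' Reducer configuration
#'
#' Parametric 2-D reduction of latent embedding matrices with an
#' out-of-sample `transform`. Two backends: `triplet` (a small
#' neural network trained with a margin triplet loss over
#' nearest-neighbour positives and random non-neighbour negatives -- the
#' fidelity path) and `linear` (projection onto the top two principal
#' directions -- deterministic, closed-form, used wherever downstream
#' modules need an oracle-testable reduction).
#'
#' @param backend `"triplet"` or `"linear"`.
#' @param k_neighbors neighbourhood size for triplet mining (>= 1).
#' @param margin triplet-loss margin.
#' @param hidden hidden width of the triplet network.
#' @param epochs training epochs (triplet backend).
#' @param learning_rate Adam learning rate (triplet backend).
#' @param seed integer seed (triplet backend).
#' @return object of class `reducer_config` (out_dims is fixed at 2).
#' @export
reducer_config <- function(backend = c("triplet", "linear"),
                           k_neighbors = 15, margin = 1.0, hidden = 16,
                           epochs = 30, learning_rate = 0.01, seed = 1) {
  backend <- match.arg(backend)
  if (k_neighbors < 1) stop2("k_neighbors must be >= 1")
  structure(list(backend = backend, out_dims = 2L,
                 k_neighbors = as.integer(k_neighbors), margin = margin,
                 hidden = as.integer(hidden), epochs = as.integer(epochs),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "reducer_config")
}

#' Fit a 2-D reducer
#'
#' Linear backend: columns are centred and projected onto the top two
#' right singular vectors (principal directions). Triplet backend: every
#' point serves as an anchor paired with one of its `k_neighbors` exact
#' nearest neighbours (positive) and a random non-neighbour (negative);
#' a one-hidden-layer network mapping d to 2 is trained with the margin
#' triplet loss max(0, |f(a)-f(p)|^2 - |f(a)-f(n)|^2 + margin) by Adam.
#'
#' @param X numeric matrix n x d (n >= k_neighbors + 2, d >= 2).
#' @param config a [reducer_config()].
#' @return object of class `fitted_reducer` with a pure `transform`.
#' @export
fit_reducer <- function(X, config = reducer_config()) {
  stopifnot(inherits(config, "reducer_config"))
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  if (d < 2) stop2("need at least 2 input dimensions")
  if (config$backend == "triplet" && n < config$k_neighbors + 2) {
    stop2("n = ", n, " rows is too small: need at least k_neighbors + 2 = ",
          config$k_neighbors + 2)
  }
  if (n < 3) stop2("need at least 3 rows")
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  fp <- c(n = n, d = d, sum = sum(X), ss = sum(X^2))  # training fingerprint
  if (config$backend == "linear") {
    sv <- svd(Xc, nu = 0, nv = 2)
    # sign convention: largest-|loading| entry of each axis is positive
    V <- sv$v
    for (j in 1:2) if (V[which.max(abs(V[, j])), j] < 0) V[, j] <- -V[, j]
    return(structure(list(backend = "linear", center = center, V = V,
                          config = config, fingerprint = fp),
                     class = "fitted_reducer"))
  }
  # triplet backend
  with_seed(config$seed, "reducer", {
    k <- config$k_neighbors
    D <- as.matrix(stats::dist(Xc))
    diag(D) <- Inf
    nbr <- t(apply(D, 1, function(r) order(r)[seq_len(k)]))
    sdx <- stats::sd(as.vector(Xc)); if (sdx == 0) sdx <- 1
    Xs <- Xc / sdx
    h <- config$hidden
    W1 <- he_init(d, h); b1 <- rep(0, h)
    W2 <- he_init(h, 2); b2 <- rep(0, 2)
    params <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
    opt <- adam_init(params)
    fwd <- function(p, M) {
      H <- pmax(M %*% p$W1 + matrix(p$b1, nrow(M), h, byrow = TRUE), 0)
      list(H = H, Y = H %*% p$W2 + matrix(p$b2, nrow(M), 2, byrow = TRUE))
    }
    loss_hist <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      pos <- nbr[cbind(seq_len(n), sample.int(k, n, replace = TRUE))]
      neg <- vapply(seq_len(n), function(i) {
        repeat {
          j <- sample.int(n, 1)
          if (j != i && !(j %in% nbr[i, ])) return(j)
        }
      }, 1L)
      fa <- fwd(params, Xs); fpn <- fwd(params, Xs[pos, , drop = FALSE])
      fn <- fwd(params, Xs[neg, , drop = FALSE])
      dp <- fa$Y - fpn$Y; dn <- fa$Y - fn$Y
      viol <- rowSums(dp^2) - rowSums(dn^2) + config$margin
      act <- viol > 0
      loss_hist[ep] <- mean(pmax(viol, 0))
      # gradients of mean hinge loss wrt the three projections
      gA <- 2 * (dp - dn) * act / n
      gP <- -2 * dp * act / n
      gN <- 2 * dn * act / n
      grads <- list(W1 = 0 * params$W1, b1 = 0 * params$b1,
                    W2 = 0 * params$W2, b2 = 0 * params$b2)
      acc <- function(f, M, G, grads) {
        dH <- tcrossprod(G, params$W2) * (f$H > 0)
        grads$W2 <- grads$W2 + crossprod(f$H, G)
        grads$b2 <- grads$b2 + colSums(G)
        grads$W1 <- grads$W1 + crossprod(M, dH)
        grads$b1 <- grads$b1 + colSums(dH)
        grads
      }
      grads <- acc(fa, Xs, gA, grads)
      grads <- acc(fpn, Xs[pos, , drop = FALSE], gP, grads)
      grads <- acc(fn, Xs[neg, , drop = FALSE], gN, grads)
      st <- adam_step(params, grads, opt, config$learning_rate)
      params <- st$params; opt <- st$state
    }
    structure(list(backend = "triplet", center = center, scale = sdx,
                   params = params, hidden = h, config = config,
                   loss_history = loss_hist, fingerprint = fp),
              class = "fitted_reducer")
  })
}

#' Transform new points with a fitted reducer
#'
#' A pure function of its input after fit: identical rows map to identical
#' coordinates.
#'
#' @param reducer a `fitted_reducer`.
#' @param X_new numeric matrix with the fit-time number of columns.
#' @return numeric matrix n x 2, rows aligned with the input.
#' @export
transform_coords <- function(reducer, X_new) {
  stopifnot(inherits(reducer, "fitted_reducer"))
  X_new <- as.matrix(X_new)
  d <- length(reducer$center)
  if (ncol(X_new) != d) {
    stop2("X_new has ", ncol(X_new), " columns; reducer was fit with ", d)
  }
  Xc <- sweep(X_new, 2, reducer$center)
  if (reducer$backend == "linear") {
    out <- Xc %*% reducer$V
  } else {
    Xs <- Xc / reducer$scale
    p <- reducer$params
    H <- pmax(Xs %*% p$W1 + matrix(p$b1, nrow(Xs), reducer$hidden,
                                   byrow = TRUE), 0)
    out <- H %*% p$W2 + matrix(p$b2, nrow(Xs), 2, byrow = TRUE)
  }
  colnames(out) <- c("dim1", "dim2")
  rownames(out) <- rownames(X_new)
  out
}

#' Write 2-D coordinates with aligned record ids
#'
#' @param coords n x 2 matrix (rownames = record ids, or supply `ids`).
#' @param path output CSV.
#' @param ids optional record ids.
#' @return invisibly, `path`.
#' @export
write_coords <- function(coords, path, ids = rownames(coords)) {
  df <- data.frame(record_id = ids %||% seq_len(nrow(coords)),
                   dim1 = coords[, 1], dim2 = coords[, 2])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
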