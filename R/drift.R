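#' Drift-monitor configuration
#'
#' @param n_trees random-forest size (>= 100, for stable out-of-bag
#'   probabilities).
#' @param min_batch smallest sample size accepted on either side of a
#'   comparison.
#' @param n_batches number of candidate batches drawn by [drift_monitor()].
#' @param batch_size images per candidate batch (>= min_batch).
#' @param alpha significance level for the drift flag.
#' @param seed integer seed.
#' @return object of class `drift_config`.
#' @export
drift_config <- function(n_trees = 500, min_batch = 50, n_batches = 50,
                         batch_size = 100, alpha = 0.01, seed = 1) {
  if (n_trees < 100) stop2("n_trees must be >= 100 for OOB stability")
  if (batch_size < min_batch) stop2("batch_size must be >= min_batch")
  structure(list(n_trees = as.integer(n_trees),
                 min_batch = as.integer(min_batch),
                 n_batches = as.integer(n_batches),
                 batch_size = as.integer(batch_size),
                 alpha = alpha, seed = as.integer(seed)),
            class = "drift_config")
}

# Exact permutation p-value of the two-sample KS statistic, conditional on
# the pooled sample (so ties are handled): dynamic programme over the
# distinct pooled values counting label assignments whose running ECDF
# difference stays strictly below the observed D at every checkpoint.
ks_exact_p <- function(a, b, d_obs) {
  m <- length(a); n <- length(b)
  t_k <- rle(sort(c(a, b)))$lengths
  tol <- 1e-10
  f <- numeric(m + 1)          # f[i+1] = #ways with i a's used so far
  f[1] <- 1
  used <- 0L
  iv <- 0:m
  for (tk in t_k) {
    g <- numeric(m + 1)
    for (ik in 0:tk) {         # tk is small; inner update is vectorized
      w <- choose(tk, ik)
      if (ik == 0) g <- g + w * f
      else g[(ik + 1):(m + 1)] <- g[(ik + 1):(m + 1)] +
          w * f[1:(m + 1 - ik)]
    }
    used <- used + tk
    jv <- used - iv
    bad <- jv < 0 | jv > n | abs(iv / m - jv / n) >= d_obs - tol
    g[bad] <- 0
    f <- g
  }
  1 - f[m + 1] / choose(m + n, m)
}

# Asymptotic Kolmogorov distribution: P(D >= d) with effective sample size
# ne = m n / (m + n).
ks_asymp_p <- function(m, n, d) {
  lambda <- sqrt(m * n / (m + n)) * d
  if (lambda < 1e-8) return(1)
  j <- 1:100
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))
  min(1, max(0, p))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum of the absolute difference of the two empirical
#' cumulative distribution functions. The two-sided P value is computed by
#' exact permutation enumeration (a dynamic programme over the pooled
#' sample, valid under ties) when `length(a) * length(b) <= 10000`, and by
#' the asymptotic Kolmogorov distribution otherwise.
#'
#' @param a,b non-empty numeric samples.
#' @return list with `D`, `p`, `n_a`, `n_b` and `method`.
#' @export
ks_2sample <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0) stop2("both samples must be non-empty")
  m <- length(a); n <- length(b)
  pooled <- sort(unique(c(a, b)))
  ca <- vapply(pooled, function(v) sum(a <= v), 0) / m
  cb <- vapply(pooled, function(v) sum(b <= v), 0) / n
  D <- max(abs(ca - cb))
  if (D == 0) {
    return(list(D = 0, p = 1, n_a = m, n_b = n, method = "degenerate"))
  }
  if (m * n <= 10000) {
    p <- ks_exact_p(a, b, D)
    method <- "exact"
  } else {
    p <- ks_asymp_p(m, n, D)
    method <- "asymptotic"
  }
  list(D = D, p = p, n_a = m, n_b = n, method = method)
}

# Cancel exact duplicate pairs across the two sides: each candidate row
# that is bit-identical to a still-unmatched reference row removes both.
# Duplicates carry no evidence of distributional change, but a flexible
# classifier would otherwise memorize them and mistake re-submitted images
# for drift.
dedup_pairs <- function(R, C) {
  kr <- apply(R, 1, paste, collapse = "\r")
  kc <- apply(C, 1, paste, collapse = "\r")
  use_r <- rep(TRUE, nrow(R)); use_c <- rep(TRUE, nrow(C))
  avail <- split(seq_along(kr), kr)
  for (j in seq_along(kc)) {
    hits <- avail[[kc[j]]]
    if (length(hits) > 0) {
      use_r[hits[1]] <- FALSE
      use_c[j] <- FALSE
      avail[[kc[j]]] <- hits[-1]
    }
  }
  list(R = R[use_r, , drop = FALSE], C = C[use_c, , drop = FALSE])
}

#' Score one candidate batch against a reference (classifier two-sample test)
#'
#' Trains a random forest to discriminate reference from candidate
#' coordinates on a stratified random half of each side, scores the
#' held-out halves with the fitted forest (per-image drift probabilities of
#' the "candidate" class), and compares the two held-out score
#' distributions with [ks_2sample()]. Because the scored points never
#' entered training, their scores are independent draws under the
#' no-drift null and the permutation-exact KS P value is valid; under
#' drift, candidate scores concentrate near 1 and the P value collapses.
#' Exact duplicate reference/candidate row pairs are cancelled before
#' testing (they carry no evidence of drift); a candidate batch that is an
#' exact copy of reference rows therefore returns D = 0, p = 1.
#'
#' @param reference_coords numeric matrix m x k (typically the 2-D reduced
#'   embedding of the reference set).
#' @param candidate_coords numeric matrix b x k.
#' @param config a [drift_config()].
#' @return object of class `drift_batch_result`: list with `D`, `p`,
#'   `n_ref`, `n_cand`, and the held-out per-image drift scores
#'   (`scores_ref`, `scores_cand`).
#' @export
score_batch <- function(reference_coords, candidate_coords,
                        config = drift_config()) {
  stopifnot(inherits(config, "drift_config"))
  R <- as.matrix(reference_coords); C <- as.matrix(candidate_coords)
  if (nrow(R) < config$min_batch || nrow(C) < config$min_batch) {
    stop2("both sides need at least min_batch = ", config$min_batch, " rows")
  }
  if (ncol(R) != ncol(C)) stop2("coordinate dimensions differ")
  n_ref <- nrow(R); n_cand <- nrow(C)
  dd <- dedup_pairs(R, C)
  if (nrow(dd$C) < 2 || nrow(dd$R) < 2) {
    # candidate indistinguishable from reference rows
    return(structure(list(D = 0, p = 1, n_ref = n_ref, n_cand = n_cand,
                          method = "duplicates", scores_ref = numeric(0),
                          scores_cand = numeric(0)),
                     class = "drift_batch_result"))
  }
  R <- dd$R; C <- dd$C
  with_seed(config$seed, "score_batch", {
    tr_r <- sample(nrow(R), nrow(R) %/% 2)
    tr_c <- sample(nrow(C), nrow(C) %/% 2)
    dtr <- as.data.frame(rbind(R[tr_r, , drop = FALSE],
                               C[tr_c, , drop = FALSE]))
    names(dtr) <- paste0("x", seq_len(ncol(dtr)))
    dtr$.y <- factor(rep(c("ref", "cand"), c(length(tr_r), length(tr_c))),
                     levels = c("ref", "cand"))
    rf <- ranger::ranger(dependent.variable.name = ".y", data = dtr,
                         num.trees = config$n_trees, probability = TRUE,
                         seed = derive_seed(config$seed, "rf"),
                         num.threads = 1)
    score <- function(X) {
      dx <- as.data.frame(X)
      names(dx) <- paste0("x", seq_len(ncol(dx)))
      stats::predict(rf, dx, num.threads = 1)$predictions[, "cand"]
    }
    scores_ref <- score(R[-tr_r, , drop = FALSE])
    scores_cand <- score(C[-tr_c, , drop = FALSE])
    ks <- ks_2sample(scores_ref, scores_cand)
    structure(list(D = ks$D, p = ks$p, n_ref = n_ref, n_cand = n_cand,
                   method = ks$method, scores_ref = scores_ref,
                   scores_cand = scores_cand),
              class = "drift_batch_result")
  })
}

#' Repeated-batch drift monitoring
#'
#' Draws `n_batches` random batches of `batch_size` rows from the candidate
#' pool (sampling without replacement within a batch, with replacement
#' across batches), scores each against the reference with [score_batch()],
#' and summarizes the P-value distribution. The drift flag is raised when
#' the median P value falls below `alpha`.
#'
#' @param reference_coords reference coordinate matrix.
#' @param candidate_pool candidate coordinate matrix (>= batch_size rows).
#' @param config a [drift_config()].
#' @return object of class `drift_monitor_result`: list with `batches`
#'   (list of `drift_batch_result`), `p_values`, `summary` (median and
#'   quartiles), and `drift` (logical flag).
#' @export
drift_monitor <- function(reference_coords, candidate_pool,
                          config = drift_config()) {
  stopifnot(inherits(config, "drift_config"))
  pool <- as.matrix(candidate_pool)
  if (nrow(pool) < config$batch_size) {
    stop2("candidate pool (", nrow(pool), ") smaller than batch_size (",
          config$batch_size, ")")
  }
  batches <- with_seed(config$seed, "monitor", {
    lapply(seq_len(config$n_batches), function(i) {
      ix <- sample.int(nrow(pool), config$batch_size)
      cfg_i <- config
      cfg_i$seed <- derive_seed(config$seed, paste0("batch_", i))
      score_batch(reference_coords, pool[ix, , drop = FALSE], cfg_i)
    })
  })
  pv <- vapply(batches, `[[`, 0, "p")
  qs <- stats::quantile(pv, c(0.25, 0.5, 0.75), names = FALSE)
  structure(list(batches = batches, p_values = pv,
                 summary = c(q1 = qs[1], median = qs[2], q3 = qs[3]),
                 alpha = config$alpha,
                 drift = unname(qs[2] < config$alpha)),
            class = "drift_monitor_result")
}

#' Write a drift-monitor report as JSON
#'
#' @param result a `drift_monitor_result`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_drift_report <- function(result, path) {
  rep <- list(
    per_batch = lapply(result$batches, function(b) {
      list(D = b$D, p = b$p, n_ref = b$n_ref, n_cand = b$n_cand)
    }),
    summary = as.list(result$summary),
    alpha = result$alpha,
    drift = result$drift)
  writeLines(as.character(jsonlite::toJSON(rep, auto_unbox = TRUE,
                                           digits = NA)), path)
  invisible(path)
}

#' Box plot of drift-monitor P values across scenarios
#'
#' @param results named list of `drift_monitor_result` objects.
#' @param ... passed to [graphics::boxplot()].
#' @return invisibly, the boxplot statistics.
#' @export
plot_drift <- function(results, ...) {
  pv <- lapply(results, `[[`, "p_values")
  invisible(graphics::boxplot(pv, ylab = "KS P value", log = "y",
                              col = c("forestgreen", "steelblue",
                                      "firebrick")[seq_along(pv) %% 3 + 1],
                              ...))
}
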