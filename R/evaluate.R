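#' Exact Clopper-Pearson binomial confidence interval
#'
#' Beta-quantile form: lower = qbeta(alpha/2; x, n-x+1), upper =
#' qbeta(1-alpha/2; x+1, n-x); the lower bound is exactly 0 when x = 0 and
#' the upper exactly 1 when x = n.
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param conf confidence level (default 0.95).
#' @return named numeric `c(lower, upper)` on the proportion scale.
#' @export
clopper_pearson <- function(x, n, conf = 0.95) {
  if (n < 1 || x < 0 || x > n) stop2("need 0 <= x <= n, n >= 1")
  a <- 1 - conf
  lower <- if (x == 0) 0 else stats::qbeta(a / 2, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - a / 2, x + 1, n - x)
  c(lower = lower, upper = upper)
}

metric_ci <- function(x, n, conf = 0.95, method = "clopper-pearson") {
  if (n == 0) {
    return(structure(list(estimate = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, x = x, n = n,
                          method = method, undefined = TRUE),
                     class = "metric_ci"))
  }
  ci <- clopper_pearson(x, n, conf)
  structure(list(estimate = x / n, ci_low = unname(ci[1]),
                 ci_high = unname(ci[2]), x = x, n = n, method = method,
                 undefined = FALSE),
            class = "metric_ci")
}

#' @method format metric_ci
#' @export
format.metric_ci <- function(x, ...) {
  if (x$undefined) return("undefined (zero denominator)")
  sprintf("%d%% (%d of %d; 95%% CI: %d%%, %d%%)",
          round_half_up(100 * x$estimate), x$x, x$n,
          round_half_up(100 * x$ci_low), round_half_up(100 * x$ci_high))
}

#' @method print metric_ci
#' @export
print.metric_ci <- function(x, ...) cat(format(x), "\n")

#' Confusion matrix from truth and predicted probabilities or labels
#'
#' Predicted labels are the class of greatest probability when a
#' probability matrix is supplied. Rows are truth, columns predictions.
#'
#' @param truth true labels.
#' @param predicted predicted labels, or a probability matrix with class
#'   columns.
#' @param classes class order (default: [ngt_classes()] when applicable).
#' @return K x K integer matrix of class `table`.
#' @export
confusion_matrix <- function(truth, predicted, classes = NULL) {
  truth <- as.character(truth)
  if (is.matrix(predicted)) {
    predicted <- colnames(predicted)[max.col(predicted, ties.method = "first")]
  }
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) stop2("length mismatch")
  if (is.null(classes)) {
    u <- unique(c(truth, predicted))
    classes <- if (all(u %in% ngt_classes())) {
      intersect(ngt_classes(), u)
    } else sort(u)
  }
  table(truth = factor(truth, classes), predicted = factor(predicted, classes))
}

#' One-vs-rest class metrics with exact Clopper-Pearson intervals
#'
#' Accuracy, positive predictive value, sensitivity and specificity of one
#' class against the rest, each carried with its (x, n) counts so every
#' reported percentage is reconstructible. Intervals are Clopper-Pearson
#' throughout; for PPV this choice (rather than an unstated alternative) is
#' recorded in the `method` field.
#'
#' @param cm confusion matrix from [confusion_matrix()].
#' @param class class name.
#' @return named list of `metric_ci` objects (accuracy, ppv, sensitivity,
#'   specificity).
#' @export
class_metrics <- function(cm, class) {
  if (!class %in% rownames(cm)) stop2("class '", class, "' not in matrix")
  n <- sum(cm)
  tp <- cm[class, class]
  fp <- sum(cm[, class]) - tp
  fn <- sum(cm[class, ]) - tp
  tn <- n - tp - fp - fn
  list(accuracy = metric_ci(tp + tn, n),
       ppv = metric_ci(tp, tp + fp, method = "clopper-pearson (PPV method unstated upstream)"),
       sensitivity = metric_ci(tp, tp + fn),
       specificity = metric_ci(tn, tn + fp))
}

# Rank/pairwise AUC with ties counted half (Mann-Whitney form).
auc_rank <- function(scores, labels) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop2("both label values must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve and AUC with bootstrap confidence interval
#'
#' AUC by the rank (pairwise-comparison) definition with ties counted one
#' half; the 95% CI is the percentile interval over `n_boot` seeded
#' case-resampling bootstrap replicates (resamples with a single class are
#' redrawn).
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels binary labels (0/1, logical, or a 2-level factor where the
#'   second level is positive).
#' @param n_boot bootstrap replicates (default 2000).
#' @param seed integer seed.
#' @param conf confidence level.
#' @return object of class `roc_result`: list with `auc`, `ci_low`,
#'   `ci_high`, `n_boot`, and `points` (`data.frame` fpr, tpr per
#'   threshold).
#' @export
roc_auc <- function(scores, labels, n_boot = 2000, seed = 1, conf = 0.95) {
  if (is.factor(labels)) labels <- as.integer(labels == levels(labels)[2])
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels))
  auc <- auc_rank(scores, labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  pts <- data.frame(
    fpr = vapply(thr, function(t) sum(scores >= t & labels == 0) / n0, 0),
    tpr = vapply(thr, function(t) sum(scores >= t & labels == 1) / n1, 0))
  boot <- with_seed(seed, "roc_boot", {
    n <- length(scores)
    vapply(seq_len(n_boot), function(i) {
      repeat {
        ix <- sample.int(n, n, replace = TRUE)
        if (length(unique(labels[ix])) == 2) break
      }
      auc_rank(scores[ix], labels[ix])
    }, 0)
  })
  a <- 1 - conf
  qs <- stats::quantile(boot, c(a / 2, 1 - a / 2), names = FALSE)
  structure(list(auc = auc, ci_low = qs[1], ci_high = qs[2],
                 n_boot = n_boot, points = pts),
            class = "roc_result")
}

#' Cohen kappa between two raters
#'
#' Unweighted kappa from the cross-table: observed agreement po = trace
#' fraction, chance agreement pe = sum of row-marginal x column-marginal
#' fractions, kappa = (po - pe) / (1 - pe). When both raters are constant
#' and equal (pe = 1) kappa is defined as 1.
#'
#' @param ratings_a,ratings_b equal-length rating vectors over one label
#'   space.
#' @return object of class `agreement_result`: list with `po`, `pe`,
#'   `kappa`, `n`, `table`.
#' @export
cohen_kappa <- function(ratings_a, ratings_b) {
  a <- as.character(ratings_a); b <- as.character(ratings_b)
  if (length(a) != length(b)) stop2("rating vectors differ in length")
  if (length(a) == 0) stop2("empty ratings")
  lev <- sort(unique(c(a, b)))
  tab <- table(factor(a, lev), factor(b, lev))
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  kappa <- if (abs(1 - pe) < 1e-12) 1 else (po - pe) / (1 - pe)
  structure(list(po = po, pe = pe, kappa = kappa, n = n, table = tab),
            class = "agreement_result")
}

#' Pairwise kappa matrix over a panel of readers
#'
#' @param ratings matrix or data.frame, one column per reader, one row per
#'   item.
#' @return list with `matrix` (symmetric, unit diagonal), `mean` and `sd`
#'   over the off-diagonal upper triangle.
#' @export
kappa_matrix <- function(ratings) {
  ratings <- as.data.frame(ratings)
  R <- ncol(ratings)
  if (R < 2) stop2("need at least 2 readers")
  K <- matrix(1, R, R, dimnames = list(names(ratings), names(ratings)))
  for (i in seq_len(R - 1)) for (j in (i + 1):R) {
    k <- cohen_kappa(ratings[[i]], ratings[[j]])$kappa
    K[i, j] <- K[j, i] <- k
  }
  up <- K[upper.tri(K)]
  list(matrix = K, mean = mean(up),
       sd = if (length(up) < 2) 0 else stats::sd(up))
}

#' Paired two-tailed t test on per-reader kappa values
#'
#' One kappa per reader per condition (e.g. unaided vs aided); the test is
#' the paired Student t on the differences with df = n - 1. Zero-variance
#' differences are flagged as degenerate (p reported as 0 when the mean
#' difference is nonzero, 1 otherwise).
#'
#' @param kappas_a,kappas_b equal-length paired vectors, n >= 2.
#' @param paired set `FALSE` for the two-sample (Welch) variant.
#' @return list with `t`, `p`, `df`, `mean_diff`, `degenerate`.
#' @export
paired_kappa_test <- function(kappas_a, kappas_b, paired = TRUE) {
  if (length(kappas_a) != length(kappas_b) && paired) {
    stop2("paired vectors differ in length")
  }
  if (length(kappas_a) < 2 || length(kappas_b) < 2) stop2("need n >= 2")
  if (!paired) {
    ht <- stats::t.test(kappas_a, kappas_b)
    return(list(t = unname(ht$statistic), p = ht$p.value,
                df = unname(ht$parameter), mean_diff = diff(rev(ht$estimate)),
                degenerate = FALSE))
  }
  d <- kappas_b - kappas_a
  n <- length(d)
  sdd <- stats::sd(d)
  if (sdd == 0) {
    return(list(t = if (mean(d) == 0) 0 else Inf * sign(mean(d)),
                p = if (mean(d) == 0) 1 else 0,
                df = n - 1, mean_diff = mean(d), degenerate = TRUE))
  }
  t <- mean(d) / (sdd / sqrt(n))
  p <- 2 * stats::pt(-abs(t), df = n - 1)
  list(t = t, p = p, df = n - 1, mean_diff = mean(d), degenerate = FALSE)
}

#' Multi-class Brier score
#'
#' Mean squared distance between the probability rows and the one-hot truth.
#' Probability averaging across ensemble constituents can only lower it
#' (convexity), which is the mechanism behind the ensemble's improved
#' calibration.
#'
#' @param probs n x K probability matrix with class columns.
#' @param truth true labels (matching column names).
#' @return a single number (lower is better).
#' @export
brier_score <- function(probs, truth) {
  truth <- as.character(truth)
  Y <- matrix(0, length(truth), ncol(probs))
  Y[cbind(seq_along(truth), match(truth, colnames(probs)))] <- 1
  mean(rowSums((probs - Y)^2))
}

#' Reliability curve and expected calibration error
#'
#' Equal-width probability bins; per bin the mean predicted probability and
#' the observed event frequency; ECE is the frequency-weighted mean
#' absolute gap. Empty bins are skipped and reported.
#'
#' @param probs predicted probabilities in [0, 1].
#' @param labels binary outcomes.
#' @param bins number of equal-width bins (default 10).
#' @return list with `points` (`data.frame` bin, n, mean_pred, obs_freq),
#'   `ece`, `empty_bins`.
#' @export
calibration_curve <- function(probs, labels, bins = 10) {
  if (any(probs < 0 | probs > 1)) stop2("probs must lie in [0, 1]")
  labels <- as.integer(labels)
  edges <- seq(0, 1, length.out = bins + 1)
  bin <- pmin(findInterval(probs, edges, rightmost.closed = TRUE), bins)
  pts <- do.call(rbind, lapply(seq_len(bins), function(k) {
    ix <- bin == k
    if (!any(ix)) return(NULL)
    data.frame(bin = k, n = sum(ix), mean_pred = mean(probs[ix]),
               obs_freq = mean(labels[ix]))
  }))
  ece <- sum(pts$n / length(probs) * abs(pts$mean_pred - pts$obs_freq))
  list(points = pts, ece = ece,
       empty_bins = setdiff(seq_len(bins), pts$bin))
}

#' Feed score from a 3-class probability triplet
#'
#' The probability that feeding is safe is the satisfactory-class
#' probability; the binary feed / do-not-feed decision applies the
#' configured threshold.
#'
#' @param prob_triplet numeric length-3 vector or n x 3 matrix (columns
#'   satisfactory, malpositioned, bronchial) summing to 1 per row.
#' @param threshold decision threshold (default 0.5).
#' @return list with `score` (numeric vector) and `decision` (character,
#'   "feed"/"do_not_feed").
#' @export
feed_score <- function(prob_triplet, threshold = 0.5) {
  p <- if (is.matrix(prob_triplet)) prob_triplet else
    matrix(prob_triplet, 1, length(prob_triplet))
  if (ncol(p) != 3 || any(abs(rowSums(p) - 1) > 1e-6) || any(p < -1e-9)) {
    stop2("malformed probability triplet(s)")
  }
  sc <- if (!is.null(colnames(p)) && "satisfactory" %in% colnames(p)) {
    p[, "satisfactory"]
  } else p[, 1]
  list(score = unname(sc),
       decision = ifelse(sc >= threshold, "feed", "do_not_feed"))
}

#' Per-class performance table
#'
#' One row per class with accuracy, PPV, sensitivity and specificity, each
#' as estimate, x, n and CI bounds (raw proportions retained; percentages
#' rounded half-up only in the formatted columns).
#'
#' @param cm confusion matrix.
#' @return `data.frame` with one row per class x metric.
#' @export
performance_table <- function(cm) {
  do.call(rbind, lapply(rownames(cm), function(cl) {
    ms <- class_metrics(cm, cl)
    do.call(rbind, lapply(names(ms), function(nm) {
      m <- ms[[nm]]
      data.frame(class = cl, metric = nm, estimate = m$estimate,
                 x = m$x, n = m$n, ci_low = m$ci_low, ci_high = m$ci_high,
                 pct = round_half_up(100 * m$estimate),
                 ci_low_pct = round_half_up(100 * m$ci_low),
                 ci_high_pct = round_half_up(100 * m$ci_high),
                 method = m$method, stringsAsFactors = FALSE)
    }))
  }))
}

#' ROC plot
#' @param roc a `roc_result`.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, NULL.
#' @export
plot_roc <- function(roc, ...) {
  graphics::plot(roc$points$fpr, roc$points$tpr, type = "l", lwd = 2,
                 xlab = "False-positive rate", ylab = "True-positive rate",
                 ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  graphics::legend("bottomright",
                   sprintf("AUC %.2f (%.2f, %.2f)", roc$auc, roc$ci_low,
                           roc$ci_high), bty = "n")
  invisible(NULL)
}

#' Kappa heat map
#' @param km result of [kappa_matrix()].
#' @param ... passed to [graphics::image()].
#' @return invisibly, NULL.
#' @export
plot_kappa_matrix <- function(km, ...) {
  K <- km$matrix
  R <- nrow(K)
  graphics::image(seq_len(R), seq_len(R), t(K[R:1, ]), zlim = c(-1, 1),
                  axes = FALSE, xlab = "", ylab = "",
                  col = grDevices::hcl.colors(21, "Blues", rev = TRUE), ...)
  graphics::axis(1, seq_len(R), colnames(K), las = 2)
  graphics::axis(2, seq_len(R), rev(rownames(K)), las = 2)
  for (i in seq_len(R)) for (j in seq_len(R)) {
    graphics::text(j, R - i + 1, sprintf("%.2f", K[i, j]), cex = 0.8)
  }
  invisible(NULL)
}
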