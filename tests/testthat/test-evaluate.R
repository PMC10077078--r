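test_that("Clopper-Pearson intervals hit the textbook boundary rules", {
  ci <- clopper_pearson(19, 24)
  expect_equal(unname(ci["lower"]), qbeta(0.025, 19, 6), tolerance = 1e-12)
  expect_equal(unname(ci["upper"]), qbeta(0.975, 20, 5), tolerance = 1e-12)
  expect_equal(round_half_up(100 * ci[["lower"]]), 58)

  expect_equal(clopper_pearson(0, 20)[["lower"]], 0)
  expect_equal(clopper_pearson(20, 20)[["upper"]], 1)
  expect_error(clopper_pearson(5, 0), "n >= 1")

  m <- ngtmonitor:::metric_ci(0, 0)
  expect_true(m$undefined)
  expect_match(format(m), "undefined")
})

test_that("confusion matrix and per-class metrics carry reconstructible counts", {
  truth <- c(rep("satisfactory", 6), rep("malpositioned", 3), "bronchial")
  probs <- matrix(0, 10, 3,
                  dimnames = list(NULL, ngt_classes()))
  pred <- c("satisfactory", "satisfactory", "satisfactory", "malpositioned",
            "satisfactory", "satisfactory", "malpositioned", "malpositioned",
            "bronchial", "bronchial")
  probs[cbind(1:10, match(pred, colnames(probs)))] <- 1
  cm <- confusion_matrix(truth, probs)
  expect_equal(sum(cm), 10)
  expect_equal(cm["satisfactory", "satisfactory"], 5)

  ms <- class_metrics(cm, "bronchial")
  expect_equal(ms$sensitivity$x / ms$sensitivity$n, 1)
  expect_equal(ms$ppv$x, 1); expect_equal(ms$ppv$n, 2)
  tab <- performance_table(cm)
  expect_true(all(abs(tab$estimate - tab$x / tab$n) < 1e-12, na.rm = TRUE))
})

test_that("rank AUC equals the brute-force pairwise oracle", {
  fix <- roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1), n_boot = 50)
  expect_equal(fix$auc, 0.75)

  perfect <- roc_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1),
                     n_boot = 50)
  expect_equal(perfect$auc, 1)

  set.seed(51)
  for (rep in 1:20) {
    n <- sample(10:200, 1)
    sc <- sample(seq(0, 1, by = 0.05), n, TRUE)  # many ties
    lb <- rbinom(n, 1, 0.5)
    if (length(unique(lb)) < 2) next
    expect_equal(roc_auc(sc, lb, n_boot = 10)$auc, auc_bruteforce(sc, lb),
                 tolerance = 1e-12)
  }

  null <- roc_auc(rnorm(500), rbinom(500, 1, 0.5), n_boot = 100, seed = 2)
  expect_equal(null$auc, 0.5, tolerance = 0.06)
  expect_true(null$ci_low <= null$auc && null$auc <= null$ci_high)
  expect_error(roc_auc(rnorm(5), rep(1, 5)), "both label")
})

test_that("bootstrap AUC interval covers the true value at nominal rate", {
  set.seed(52)
  true_auc <- pnorm(1 / sqrt(2))   # N(1,1) positives vs N(0,1) negatives
  cover <- 0
  reps <- 200
  for (i in 1:reps) {
    lb <- rbinom(60, 1, 0.5)
    if (length(unique(lb)) < 2) lb[1:2] <- c(0, 1)
    sc <- rnorm(60, mean = lb)
    r <- roc_auc(sc, lb, n_boot = 500, seed = i)
    cover <- cover + (r$ci_low <= true_auc && true_auc <= r$ci_high)
  }
  expect_gte(cover / reps, 0.90)
  expect_lte(cover / reps, 0.99)
})

test_that("Cohen kappa matches the hand-computed cross-table oracle", {
  a <- rep(c("feed", "feed", "dnf", "dnf"), c(20, 5, 10, 15))
  b <- rep(c("feed", "dnf", "feed", "dnf"), c(20, 5, 10, 15))
  k <- cohen_kappa(a, b)
  expect_equal(k$po, 0.70)
  expect_equal(k$pe, 0.50)
  expect_equal(k$kappa, 0.40)

  expect_equal(cohen_kappa(a, a)$kappa, 1)
  expect_equal(cohen_kappa(a, b)$kappa, cohen_kappa(b, a)$kappa)
  expect_equal(cohen_kappa(rep("x", 5), rep("x", 5))$kappa, 1)  # pe = 1
  expect_error(cohen_kappa(a, b[1:10]), "length")

  set.seed(53)
  ia <- sample(c("u", "v"), 1000, TRUE)
  ib <- sample(c("u", "v"), 1000, TRUE)
  expect_lt(abs(cohen_kappa(ia, ib)$kappa), 0.08)
})

test_that("kappa matrix is symmetric with unit diagonal and stable summaries", {
  two <- data.frame(r1 = c("a", "b", "a"), r2 = c("a", "b", "a"))
  km <- kappa_matrix(two)
  expect_equal(unname(km$matrix), matrix(1, 2, 2))
  expect_equal(km$mean, 1); expect_equal(km$sd, 0)

  set.seed(54)
  r1 <- sample(c("f", "d"), 60, TRUE)
  r2 <- ifelse(runif(60) < 0.8, r1, sample(c("f", "d"), 60, TRUE))
  r3 <- ifelse(runif(60) < 0.6, r1, sample(c("f", "d"), 60, TRUE))
  df <- data.frame(r1, r2, r3)
  km3 <- kappa_matrix(df)
  expect_equal(km3$matrix, t(km3$matrix))
  expect_equal(unname(diag(km3$matrix)), rep(1, 3))
  expect_equal(km3$matrix["r1", "r2"], cohen_kappa(r1, r2)$kappa)
  # permuting reader order permutes the matrix consistently
  kmp <- kappa_matrix(df[, c(3, 1, 2)])
  expect_equal(kmp$matrix["r1", "r2"], km3$matrix["r1", "r2"])
  expect_error(kappa_matrix(df[, 1, drop = FALSE]), "2 readers")
})

test_that("paired kappa t test matches the closed form and flags degeneracy", {
  same <- paired_kappa_test(c(0.5, 0.6, 0.7), c(0.5, 0.6, 0.7))
  expect_equal(same$t, 0); expect_equal(same$p, 1)

  degen <- paired_kappa_test(c(0.5, 0.5, 0.5, 0.5, 0.5),
                             c(0.6, 0.6, 0.6, 0.6, 0.6))
  expect_true(degen$degenerate)
  expect_equal(degen$p, 0)

  d <- c(0.12, 0.05, 0.2, 0.1, 0.13)
  res <- paired_kappa_test(rep(0, 5), d)
  expect_equal(res$t, mean(d) / (sd(d) / sqrt(5)), tolerance = 1e-12)
  expect_equal(res$df, 4)
  expect_equal(res$p, 2 * pt(-abs(res$t), 4), tolerance = 1e-12)
  expect_error(paired_kappa_test(0.1, 0.2), "n >= 2")

  welch <- paired_kappa_test(rep(0, 5), d, paired = FALSE)
  expect_false(welch$degenerate)
})

test_that("calibration curve and ECE behave on canonical inputs", {
  set.seed(55)
  p <- runif(5000)
  y <- rbinom(5000, 1, p)
  cal <- calibration_curve(p, y)
  expect_lt(cal$ece, 0.03)

  expect_equal(calibration_curve(rep(1, 10), rep(1, 10))$ece, 0)
  expect_equal(calibration_curve(rep(0.5, 10), rep(1, 10))$ece, 0.5)
  expect_error(calibration_curve(c(-0.1, 0.5), c(0, 1)), "\\[0, 1\\]")
  few <- calibration_curve(c(0.05, 0.95), c(0, 1))
  expect_length(few$empty_bins, 8L)
})

test_that("feed score is the satisfactory-class probability", {
  expect_equal(feed_score(c(satisfactory = 1, malpositioned = 0,
                            bronchial = 0))$score, 1)
  f <- feed_score(c(satisfactory = 0, malpositioned = 0.6, bronchial = 0.4))
  expect_equal(f$score, 0)
  expect_equal(f$decision, "do_not_feed")
  expect_error(feed_score(c(0.5, 0.2)), "malformed")
  expect_error(feed_score(c(0.5, 0.2, 0.2)), "malformed")

  # pipeline composition: feed-score ROC against a consensus decision
  set.seed(56)
  probs <- matrix(rexp(300), 100, 3); probs <- probs / rowSums(probs)
  colnames(probs) <- ngt_classes()
  consensus <- ifelse(probs[, 1] + rnorm(100, sd = 0.3) > 0.4,
                      "feed", "do_not_feed")
  r <- roc_auc(feed_score(probs)$score,
               as.integer(consensus == "feed"), n_boot = 50)
  expect_true(r$auc > 0.5 && r$auc <= 1)
})
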