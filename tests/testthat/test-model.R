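test_that("engine backpropagation matches central-difference gradients", {
  set.seed(42)
  side <- 12
  net <- ngtmonitor:::cnn_init(side, c(4, 6), 32, 3)
  params <- net$params
  N <- 3
  X <- array(rnorm(side * side * N), c(side * side, N, 1))
  Y <- diag(3)[sample(1:3, N, TRUE), , drop = FALSE]
  fw <- ngtmonitor:::cnn_forward(net, params, X, keep = TRUE)
  grads <- ngtmonitor:::cnn_backward(net, params, fw, (fw$probs - Y) / N)
  loss_at <- function(p) {
    f <- ngtmonitor:::cnn_forward(net, p, X)
    ngtmonitor:::cross_entropy(f$probs, Y)
  }
  num_grad <- function(set, get) {
    eps <- 1e-5
    (loss_at(set(params, get(params) + eps)) -
       loss_at(set(params, get(params) - eps))) / (2 * eps)
  }
  checks <- list(
    list(an = grads$conv[[1]]$W[3, 2],
         get = function(p) p$conv[[1]]$W[3, 2],
         set = function(p, v) { p$conv[[1]]$W[3, 2] <- v; p }),
    list(an = grads$conv[[2]]$W[10, 4],
         get = function(p) p$conv[[2]]$W[10, 4],
         set = function(p, v) { p$conv[[2]]$W[10, 4] <- v; p }),
    list(an = grads$conv[[2]]$b[1],
         get = function(p) p$conv[[2]]$b[1],
         set = function(p, v) { p$conv[[2]]$b[1] <- v; p }),
    list(an = grads$W1[5, 7],
         get = function(p) p$W1[5, 7],
         set = function(p, v) { p$W1[5, 7] <- v; p }),
    list(an = grads$b2[2],
         get = function(p) p$b2[2],
         set = function(p, v) { p$b2[2] <- v; p }))
  for (ch in checks) {
    ng <- num_grad(ch$set, ch$get)
    expect_equal(ch$an, ng, tolerance = 1e-6)
  }
})

test_that("training separates a linearly separable toy within 30 epochs", {
  toy <- toy_quadrant_images(200, seed = 1)
  val <- toy_quadrant_images(40, seed = 2)
  cfg <- tiny_classifier_config(max_epochs = 30, patience = 30, seed = 1)
  fit <- train_classifier(toy$images, toy$labels, val$images, val$labels, cfg)
  p <- predict_proba(fit, toy$images)
  acc <- mean(colnames(p)[max.col(p)] == toy$labels)
  expect_equal(acc, 1.0)
  expect_true(all(abs(rowSums(p) - 1) < 1e-6))
})

test_that("early stopping halts after `patience` flat epochs and keeps the best weights", {
  toy <- toy_quadrant_images(60, seed = 3)
  val <- toy_quadrant_images(20, seed = 4)
  # learning rate 0 freezes the network, so validation loss is constant
  cfg <- tiny_classifier_config(learning_rate = 0, patience = 3,
                                max_epochs = 30, seed = 1)
  fit <- train_classifier(toy$images, toy$labels, val$images, val$labels, cfg)
  expect_equal(fit$stopped_epoch, 1 + 3)
  expect_equal(fit$best_epoch, 1L)

  cfg2 <- tiny_classifier_config(max_epochs = 8, patience = 8, seed = 2)
  fit2 <- train_classifier(toy$images, toy$labels, val$images, val$labels,
                           cfg2)
  expect_equal(fit2$best_val_loss, min(fit2$history$val_loss))
})

test_that("training is deterministic given config and seed", {
  toy <- toy_quadrant_images(60, seed = 5)
  val <- toy_quadrant_images(20, seed = 6)
  cfg <- tiny_classifier_config(max_epochs = 4, patience = 4, seed = 11,
                                dropout_rate = 0.1)
  f1 <- train_classifier(toy$images, toy$labels, val$images, val$labels, cfg)
  f2 <- train_classifier(toy$images, toy$labels, val$images, val$labels, cfg)
  expect_identical(f1$history, f2$history)
  # inference is augmentation-free and deterministic
  expect_identical(predict_proba(f1, toy$images[1:5]),
                   predict_proba(f1, toy$images[1:5]))
  e <- extract_embeddings(f1, toy$images[c(1, 1)])
  expect_identical(e[1, ], e[2, ])
})

test_that("config invariants and degenerate inputs are enforced", {
  expect_error(classifier_config(dense_units = 16), "32")
  expect_error(classifier_config(dropout_rate = 0.3), "0.2")
  expect_error(classifier_config(patience = 0), "patience")
  cfg <- tiny_classifier_config(max_epochs = 1, patience = 1)
  expect_error(train_classifier(list(), character(0), list(), character(0),
                                cfg), "empty")
  toy <- toy_quadrant_images(20, seed = 7)
  expect_warning(
    train_classifier(toy$images, rep("A", 20), toy$images[1:4],
                     rep("A", 4), cfg),
    "single class")
})

test_that("ensemble averaging is idempotent and improves the Brier score", {
  toy <- toy_quadrant_images(40, seed = 8)
  val <- toy_quadrant_images(16, seed = 9)
  cfg <- tiny_classifier_config(max_epochs = 3, patience = 3, seed = 3)
  fit <- train_classifier(toy$images, toy$labels, val$images, val$labels, cfg)
  single <- predict_proba(fit, val$images)
  duo <- ensemble_proba(list(fit, fit), val$images)
  expect_equal(duo, single, tolerance = 1e-12)
  expect_true(all(abs(rowSums(duo) - 1) < 1e-6))
  expect_error(ensemble_proba(list(), val$images), "empty")

  # Brier convexity: ensemble is never worse than the constituents' mean,
  # checked numerically on random probability triplets
  set.seed(10)
  for (rep in 1:5) {
    p1 <- matrix(stats::rexp(300), 100, 3); p1 <- p1 / rowSums(p1)
    p2 <- matrix(stats::rexp(300), 100, 3); p2 <- p2 / rowSums(p2)
    colnames(p1) <- colnames(p2) <- c("a", "b", "c")
    truth <- sample(c("a", "b", "c"), 100, TRUE)
    b_ens <- brier_oracle((p1 + p2) / 2, truth)
    b_mean <- (brier_oracle(p1, truth) + brier_oracle(p2, truth)) / 2
    expect_lte(b_ens, b_mean + 1e-12)
  }
})

test_that("hyperband schedules brackets correctly and avoids divergent configs", {
  sched <- hyperband_schedule(9, 3)
  expect_length(sched, 3L)           # s_max = 2
  expect_equal(sched[[1]]$n_configs, c(9, 3, 1))
  expect_equal(sched[[1]]$epochs, c(1, 3, 9))
  expect_error(hyperband_schedule(0), "at least 1")

  toy <- toy_quadrant_images(40, seed = 12)
  val <- toy_quadrant_images(16, seed = 13)
  base <- tiny_classifier_config(seed = 5)

  # singleton space returns the single configuration unchanged
  res1 <- tune_hyperband(list(dense_units = 48), toy$images, toy$labels,
                         val$images, val$labels, budget_epochs = 1,
                         base_config = base, seed = 1)
  expect_equal(res1$best_config$dense_units, 48L)

  # a planted divergent configuration (huge learning rate) is never chosen
  res2 <- tune_hyperband(list(learning_rate = list(1e-3, 50)),
                         toy$images, toy$labels, val$images, val$labels,
                         budget_epochs = 3, base_config = base, seed = 2)
  expect_equal(res2$best_config$learning_rate, 1e-3)
  expect_gt(nrow(res2$trials), 0L)
})

test_that("grad-CAM maps are rectified, shaped, and vanish for detached classes", {
  toy <- toy_quadrant_images(60, seed = 14)
  val <- toy_quadrant_images(20, seed = 15)
  cfg <- tiny_classifier_config(max_epochs = 5, patience = 5, seed = 6)
  fit <- train_classifier(toy$images, toy$labels, val$images, val$labels, cfg)
  s <- grad_cam(fit, toy$images[[1]], "A")
  expect_equal(dim(s$map), c(16L, 16L))
  expect_true(all(s$map >= 0))
  expect_error(grad_cam(fit, toy$images[[1]], "Z"), "class space")

  # detaching the class score (zero output weights) gives an all-zero map
  fit0 <- fit
  fit0$params$W2[, 1] <- 0
  fit0$params$b2[1] <- 0
  s0 <- grad_cam(fit0, toy$images[[1]], "A")
  expect_equal(max(s0$map), 0)
})

test_that("classifier round-trips through its single-file container", {
  toy <- toy_quadrant_images(30, seed = 16)
  cfg <- tiny_classifier_config(max_epochs = 2, patience = 2, seed = 7)
  fit <- train_classifier(toy$images, toy$labels, toy$images[1:6],
                          toy$labels[1:6], cfg)
  f <- tempfile(fileext = ".rds")
  save_classifier(fit, f)
  back <- load_classifier(f)
  expect_identical(predict_proba(back, toy$images[1:3]),
                   predict_proba(fit, toy$images[1:3]))
})
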