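#' Classifier configuration
#'
#' A small configurable convolutional network with a
#' global-average-pooling (GAP) head: `length(conv_widths)` blocks of
#' (3x3 conv, ReLU, 2x2 max pool), GAP over the final feature maps, one
#' dense ReLU layer with dropout, and a softmax output. The penultimate
#' dense width is constrained to [32, 512] and the dropout rate to
#' [0, 0.2], the ranges searched during tuning. Training uses Adam at
#' `learning_rate` on batches of `batch_size` minimizing categorical
#' cross-entropy, with per-batch random augmentation (brightness scaling,
#' small rotation, horizontal flip) and early stopping once validation loss
#' has not improved for `patience` consecutive epochs.
#'
#' The default input side (48 px; pair it with 64 px for the two-resolution
#' ensemble) keeps single-CPU training fast; production-scale sides such as
#' 764/1024 remain configurable.
#'
#' @param input_side input resolution in pixels (images are resized to
#'   `input_side` x `input_side` by bilinear interpolation, ignoring aspect
#'   ratio).
#' @param conv_widths integer vector of channel counts per conv block.
#' @param dense_units penultimate dense width, in [32, 512].
#' @param dropout_rate dropout on the dense layer, in [0, 0.2].
#' @param learning_rate Adam learning rate.
#' @param batch_size images per batch.
#' @param patience early-stopping patience in epochs (>= 1).
#' @param max_epochs hard epoch cap.
#' @param augment named numeric vector `c(brightness, rotation, hflip)`:
#'   brightness scale fraction, max rotation in degrees, flip probability.
#' @param seed integer seed controlling init, shuffling and augmentation.
#' @return object of class `classifier_config`.
#' @export
classifier_config <- function(input_side = 48,
                              conv_widths = c(8, 16, 32),
                              dense_units = 64,
                              dropout_rate = 0.1,
                              learning_rate = 1e-3,
                              batch_size = 32,
                              patience = 10,
                              max_epochs = 40,
                              augment = c(brightness = 0.1, rotation = 5,
                                          hflip = 0.5),
                              seed = 1) {
  if (dense_units < 32 || dense_units > 512) {
    stop2("dense_units must lie in [32, 512]")
  }
  if (dropout_rate < 0 || dropout_rate > 0.2) {
    stop2("dropout_rate must lie in [0, 0.2]")
  }
  if (patience < 1) stop2("patience must be >= 1")
  structure(list(input_side = as.integer(input_side),
                 conv_widths = as.integer(conv_widths),
                 dense_units = as.integer(dense_units),
                 dropout_rate = dropout_rate,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 augment = augment,
                 seed = as.integer(seed)),
            class = "classifier_config")
}

# Resize a list of pixel matrices (or a (H,W,N) array) to side x side by
# bilinear interpolation ignoring aspect ratio; values scaled to [0, 1].
# Returns array (side*side, N, 1) in the engine's activation layout.
images_to_batch <- function(images, side, scale = 65535) {
  if (is.array(images) && length(dim(images)) == 3) {
    images <- lapply(seq_len(dim(images)[3]), function(i) images[, , i])
  }
  if (is.matrix(images)) images <- list(images)
  N <- length(images)
  X <- array(0, c(side * side, N, 1))
  for (i in seq_len(N)) {
    m <- images[[i]]
    if (inherits(m, "synth_image")) m <- m$pixels
    m <- m / scale
    if (!all(dim(m) == c(side, side))) {
      m <- t(EBImage::imageData(EBImage::resize(EBImage::Image(t(m)),
                                                w = side, h = side)))
    }
    X[, i, 1] <- as.vector(m)
  }
  X
}

augment_batch <- function(X, side, augment) {
  N <- dim(X)[2]
  br <- augment[["brightness"]]
  rot <- augment[["rotation"]]
  fp <- augment[["hflip"]]
  for (i in seq_len(N)) {
    m <- matrix(X[, i, 1], side, side)
    if (rot > 0) {
      a <- stats::runif(1, -rot, rot)
      img <- EBImage::rotate(EBImage::Image(t(m)), a,
                             output.dim = c(side, side), bg.col = 0)
      m <- t(EBImage::imageData(img))
    }
    if (fp > 0 && stats::runif(1) < fp) m <- m[, rev(seq_len(side))]
    if (br > 0) m <- m * (1 + stats::runif(1, -br, br))
    X[, i, 1] <- as.vector(m)
  }
  X
}

labels_to_onehot <- function(labels, classes) {
  Y <- matrix(0, length(labels), length(classes),
              dimnames = list(NULL, classes))
  Y[cbind(seq_along(labels), match(as.character(labels), classes))] <- 1
  Y
}

#' Train the convolutional classifier
#'
#' Images are resized to the configured input side by bilinear interpolation
#' (aspect ratio not preserved) and standardized by the training-set mean
#' and sd. Each training batch is randomly augmented; validation images are
#' never augmented. Training stops when validation loss has not improved for
#' `patience` consecutive epochs (or at `max_epochs`) and the weights of the
#' best validation epoch are returned.
#'
#' @param images training images: list of grayscale matrices (any sizes) on
#'   a [0, 65535] scale.
#' @param labels training labels (character/factor).
#' @param val_images,val_labels validation set, same formats.
#' @param config a [classifier_config()].
#' @param classes class space (default: the sorted unique training labels,
#'   or [ngt_classes()] when labels are a subset of it).
#' @param verbose print per-epoch losses.
#' @return object of class `ngt_classifier` with the fitted weights,
#'   per-epoch `history` (`data.frame` epoch, train_loss, val_loss) and the
#'   stopping epoch.
#' @export
train_classifier <- function(images, labels, val_images, val_labels, config,
                             classes = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "classifier_config"))
  if (length(images) == 0) stop2("empty training set")
  labels <- as.character(labels)
  if (is.null(classes)) {
    classes <- if (all(labels %in% ngt_classes())) ngt_classes()
               else sort(unique(labels))
  }
  if (length(unique(labels)) < 2) {
    warning("training labels contain a single class; model will be degenerate")
  }
  side <- config$input_side
  X <- images_to_batch(images, side)
  Xv <- images_to_batch(val_images, side)
  mu <- mean(X); sdv <- stats::sd(as.vector(X))
  if (sdv == 0) sdv <- 1
  X <- (X - mu) / sdv
  Xv <- (Xv - mu) / sdv
  Y <- labels_to_onehot(labels, classes)
  Yv <- labels_to_onehot(as.character(val_labels), classes)
  n <- dim(X)[2]

  with_seed(config$seed, "train", {
    net <- cnn_init(side, config$conv_widths, config$dense_units,
                    length(classes))
    params <- net$params
    opt <- adam_init(params)
    best <- list(loss = Inf, params = params, epoch = 0L)
    since_improve <- 0L
    hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                       val_loss = numeric(0))
    for (ep in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      tr_losses <- c()
      for (start in seq(1, n, by = config$batch_size)) {
        ix <- ord[start:min(start + config$batch_size - 1, n)]
        Xb <- X[, ix, , drop = FALSE]
        Xb <- augment_batch(Xb, side, config$augment)
        fw <- cnn_forward(net, params, Xb, config$dropout_rate,
                          train = TRUE, keep = TRUE)
        Yb <- Y[ix, , drop = FALSE]
        tr_losses <- c(tr_losses, cross_entropy(fw$probs, Yb))
        dLogits <- (fw$probs - Yb) / length(ix)
        grads <- cnn_backward(net, params, fw, dLogits)
        st <- adam_step(params, grads[names(params)], opt,
                        config$learning_rate)
        params <- st$params; opt <- st$state
      }
      vl <- batched_loss(net, params, Xv, Yv)
      hist <- rbind(hist, data.frame(epoch = ep,
                                     train_loss = mean(tr_losses),
                                     val_loss = vl))
      if (verbose) {
        message(sprintf("epoch %d: train %.4f val %.4f", ep,
                        mean(tr_losses), vl))
      }
      if (vl < best$loss - 1e-12) {
        best <- list(loss = vl, params = params, epoch = ep)
        since_improve <- 0L
      } else {
        since_improve <- since_improve + 1L
        if (since_improve >= config$patience) break
      }
    }
    structure(list(net = net, params = best$params, classes = classes,
                   config = config, mu = mu, sd = sdv,
                   history = hist, best_epoch = best$epoch,
                   best_val_loss = best$loss,
                   stopped_epoch = nrow(hist)),
              class = "ngt_classifier")
  })
}

batched_loss <- function(net, params, X, Y, chunk = 128L) {
  n <- dim(X)[2]
  tot <- 0
  for (start in seq(1, n, by = chunk)) {
    ix <- start:min(start + chunk - 1, n)
    fw <- cnn_forward(net, params, X[, ix, , drop = FALSE])
    tot <- tot + cross_entropy(fw$probs, Y[ix, , drop = FALSE]) * length(ix)
  }
  tot / n
}

check_fitted <- function(model) {
  if (!inherits(model, "ngt_classifier") || is.null(model$params)) {
    stop2("model is not a fitted classifier")
  }
}

model_forward <- function(model, images, chunk = 128L, keep = FALSE) {
  check_fitted(model)
  X <- images_to_batch(images, model$config$input_side)
  X <- (X - model$mu) / model$sd
  n <- dim(X)[2]
  probs <- NULL; emb <- NULL
  for (start in seq(1, n, by = chunk)) {
    ix <- start:min(start + chunk - 1, n)
    fw <- cnn_forward(model$net, model$params, X[, ix, , drop = FALSE])
    probs <- rbind(probs, fw$probs)
    emb <- rbind(emb, fw$emb)
  }
  colnames(probs) <- model$classes
  list(probs = probs, emb = emb)
}

#' Predict class probabilities
#'
#' Inference is augmentation-free and deterministic; probability rows sum
#' to 1.
#'
#' @param model a fitted `ngt_classifier`.
#' @param images list of grayscale matrices on a [0, 65535] scale.
#' @return numeric matrix n x K of class probabilities.
#' @export
predict_proba <- function(model, images) {
  model_forward(model, images)$probs
}

#' Extract global-average-pooling embeddings
#'
#' @inheritParams predict_proba
#' @return numeric matrix n x d (d = final conv width).
#' @export
extract_embeddings <- function(model, images) {
  model_forward(model, images)$emb
}

#' Average probabilities of an ensemble
#'
#' Each constituent resizes the input to its own resolution and predicts;
#' the ensemble output is the arithmetic mean of the constituent probability
#' rows (which therefore still sum to 1).
#'
#' @param models non-empty list of fitted `ngt_classifier` objects sharing
#'   one class space.
#' @param images list of grayscale matrices.
#' @return probability matrix n x K.
#' @export
ensemble_proba <- function(models, images) {
  if (length(models) == 0) stop2("empty model list")
  cls <- models[[1]]$classes
  for (m in models) {
    if (!identical(m$classes, cls)) stop2("models disagree on the class space")
  }
  ps <- lapply(models, predict_proba, images = images)
  Reduce(`+`, ps) / length(ps)
}

#' Concatenated ensemble embeddings
#'
#' Column-binds the GAP vectors of every constituent (the combined latent
#' representation used for attribution and drift monitoring).
#'
#' @inheritParams ensemble_proba
#' @return numeric matrix n x sum(d_i).
#' @export
ensemble_embeddings <- function(models, images) {
  do.call(cbind, lapply(models, extract_embeddings, images = images))
}

#' Grad-CAM saliency map
#'
#' Gradient-weighted class activation mapping of the final convolutional
#' layer: per-channel weights are the spatial means of the gradient of the
#' target-class logit with respect to the final conv feature maps; the map
#' is the rectified (negatives clamped to 0) weighted channel sum,
#' bilinearly upsampled to the model input resolution.
#'
#' @param model fitted `ngt_classifier`.
#' @param image one grayscale matrix on a [0, 65535] scale.
#' @param target_class class name (must belong to the model's class space).
#' @return object of class `saliency`: list with `map` (non-negative matrix,
#'   input_side x input_side) and `target_class`.
#' @export
grad_cam <- function(model, image, target_class) {
  check_fitted(model)
  k <- match(target_class, model$classes)
  if (is.na(k)) stop2("target_class '", target_class,
                      "' not in the model's class space")
  side <- model$config$input_side
  X <- images_to_batch(list(image), side)
  X <- (X - model$mu) / model$sd
  fw <- cnn_forward(model$net, model$params, X, keep = TRUE)
  dLogits <- matrix(0, 1, length(model$classes))
  dLogits[1, k] <- 1
  grads <- cnn_backward(model$net, model$params, fw, dLogits, to_conv = TRUE)
  nblocks <- length(model$net$geoms)
  A <- fw$caches[[nblocks]]$relu          # (P, 1, C) post-ReLU feature maps
  dA <- grads$d_last_relu
  C <- dim(A)[3]
  alpha <- vapply(seq_len(C), function(c) mean(dA[, 1, c]), 0)
  g <- model$net$geoms[[nblocks]]
  cam <- matrix(0, g$Hout, g$Wout)
  for (c in seq_len(C)) {
    cam <- cam + alpha[c] * matrix(A[, 1, c], g$Hout, g$Wout)
  }
  cam <- pmax(cam, 0)
  up <- t(EBImage::imageData(EBImage::resize(EBImage::Image(t(cam)),
                                             w = side, h = side)))
  up <- pmax(up, 0)
  structure(list(map = up, target_class = target_class), class = "saliency")
}

#' Hyperband bracket schedule
#'
#' Bookkeeping of the Hyperband successive-halving brackets for maximum
#' resource `R` (epochs) and reduction factor `eta`: s_max =
#' floor(log_eta(R)); bracket s starts n = ceil((s_max+1)/(s+1) * eta^s)
#' configurations at r = R * eta^-s epochs and successively keeps the top
#' 1/eta.
#'
#' @param R maximum epochs per configuration.
#' @param eta reduction factor (default 3).
#' @return list of brackets, each with vectors `n_configs` and `epochs` per
#'   rung.
#' @export
hyperband_schedule <- function(R, eta = 3) {
  if (R < 1) stop2("budget must be at least 1 epoch")
  s_max <- floor(log(R) / log(eta))
  lapply(s_max:0, function(s) {
    n <- ceiling((s_max + 1) / (s + 1) * eta^s)
    r <- R * eta^(-s)
    i <- 0:s
    list(s = s,
         n_configs = pmax(1L, floor(n * eta^(-i))),
         epochs = pmax(1L, round(r * eta^i)))
  })
}

sample_search_space <- function(space, base, seed, idx) {
  with_seed(seed, paste0("hp_", idx), {
    cfg <- unclass(base)
    for (nm in names(space)) {
      v <- space[[nm]]
      cfg[[nm]] <- if (is.list(v)) {
        v[[sample.int(length(v), 1)]]
      } else if (is.numeric(v) && length(v) == 2 && v[1] < v[2]) {
        x <- stats::runif(1, v[1], v[2])
        if (nm %in% c("dense_units", "batch_size", "input_side")) round(x) else x
      } else if (length(v) > 1) {
        v[[sample.int(length(v), 1)]]
      } else v
    }
    do.call(classifier_config, cfg[names(cfg) %in% names(formals(classifier_config))])
  })
}

#' Hyperband hyperparameter search
#'
#' Runs the Hyperband brackets of [hyperband_schedule()]: each rung trains
#' the surviving configurations from scratch with the rung's epoch budget
#' and keeps the 1/eta with the lowest validation loss. Returns the
#' configuration with the lowest validation loss seen anywhere, along with
#' the full trial ledger.
#'
#' @param search_space named list; each element is either a length-2 numeric
#'   range, a vector/list of candidate values, or a single fixed value.
#'   Names must be [classifier_config()] arguments.
#' @param images,labels,val_images,val_labels training and validation data.
#' @param budget_epochs maximum epochs `R` for a single configuration.
#' @param eta reduction factor.
#' @param base_config defaults for parameters not searched.
#' @param seed integer seed.
#' @return list with `best_config`, `best_val_loss` and `trials`
#'   (`data.frame`: bracket, rung, trial id, epochs, val_loss).
#' @export
tune_hyperband <- function(search_space, images, labels, val_images,
                           val_labels, budget_epochs, eta = 3,
                           base_config = classifier_config(), seed = 1) {
  if (budget_epochs < 1) stop2("budget must be at least 1 epoch")
  sched <- hyperband_schedule(budget_epochs, eta)
  trials <- data.frame()
  best <- list(loss = Inf, config = NULL)
  cfg_counter <- 0
  for (br in sched) {
    cfgs <- lapply(seq_len(br$n_configs[1]), function(i) {
      sample_search_space(search_space, base_config, seed,
                          paste0(br$s, "_", i))
    })
    for (rung in seq_along(br$epochs)) {
      losses <- vapply(seq_along(cfgs), function(ci) {
        cfg <- cfgs[[ci]]
        cfg$max_epochs <- br$epochs[rung]
        cfg$patience <- max(cfg$patience, br$epochs[rung])  # no early exit below budget
        fit <- train_classifier(images, labels, val_images, val_labels, cfg)
        fit$best_val_loss
      }, 0)
      cfg_counter <- cfg_counter + length(cfgs)
      trials <- rbind(trials, data.frame(
        bracket = br$s, rung = rung,
        trial = seq_along(cfgs) + nrow(trials),
        epochs = br$epochs[rung], val_loss = losses))
      if (min(losses) < best$loss) {
        best <- list(loss = min(losses),
                     config = cfgs[[which.min(losses)]])
      }
      keep <- if (rung < length(br$epochs)) {
        order(losses)[seq_len(br$n_configs[rung + 1])]
      } else seq_along(cfgs)
      cfgs <- cfgs[keep]
    }
  }
  list(best_config = best$config, best_val_loss = best$loss, trials = trials)
}

#' Grad-CAM tube-tip localization rate
#'
#' For correctly classified synthetic images, checks whether the Grad-CAM
#' saliency for the true class concentrates at the planted tube tip: mean
#' saliency inside a disc of `radius` pixels around the tip (scaled to the
#' model input resolution) must exceed the mean outside. Returns the
#' fraction of checked images that pass.
#'
#' @param model fitted `ngt_classifier`.
#' @param images list of `synth_image` objects (ground-truth tips).
#' @param radius disc radius in input-resolution pixels (default 15).
#' @param max_images cap on the number of correct images checked (the first
#'   `max_images` in order).
#' @return list with `rate`, `n_checked`, `n_correct`.
#' @export
tip_localization_rate <- function(model, images, radius = 15,
                                  max_images = Inf) {
  truth <- vapply(images, `[[`, "", "label")
  probs <- predict_proba(model, images)
  pred <- colnames(probs)[max.col(probs, ties.method = "first")]
  correct <- which(pred == truth)
  checked <- correct[seq_len(min(length(correct), max_images))]
  side <- model$config$input_side
  rr <- matrix(seq_len(side), side, side)
  cc <- matrix(seq_len(side), side, side, byrow = TRUE)
  hits <- vapply(checked, function(i) {
    im <- images[[i]]
    s <- grad_cam(model, im, truth[i])
    sc <- (side - 1) / (nrow(im$pixels) - 1)
    tip <- im$tip_xy * sc + 1      # 1-based input-resolution coordinates
    inside <- (rr - tip[["row"]])^2 + (cc - tip[["col"]])^2 <= radius^2
    mean(s$map[inside]) > mean(s$map[!inside])
  }, TRUE)
  list(rate = mean(hits), n_checked = length(checked),
       n_correct = length(correct))
}

#' Save / load a fitted classifier
#'
#' Single-file container (RDS) embedding the weights, normalization
#' constants and the full configuration.
#'
#' @param model fitted `ngt_classifier`.
#' @param path file path.
#' @return `save_classifier`: invisibly `path`; `load_classifier`: the
#'   model.
#' @export
save_classifier <- function(model, path) {
  check_fitted(model)
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  m <- readRDS(path)
  check_fitted(m)
  m
}
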