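# Shared fixtures and tiny oracles, all built in code at test time.

# Brute-force pairwise AUC oracle: fraction of positive-negative pairs the
# positive outranks, ties counted one half.
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

brier_oracle <- function(probs, truth, classes = colnames(probs)) {
  Y <- matrix(0, length(truth), length(classes))
  Y[cbind(seq_along(truth), match(truth, classes))] <- 1
  mean(rowSums((probs - Y)^2))
}

# A six-record cohort in which one record fails each QC rule (resolution,
# body part, view, age) and two pass everything.
qc_fixture <- function() {
  data.frame(
    record_id = paste0("r", 1:6),
    patient_id = paste0("p", 1:6),
    study_date = rep("2018-06-01", 6),
    birth_date = c("1950-01-01", "1950-01-01", "1950-01-01",
                   "2010-01-01", "1950-01-01", "1960-05-05"),
    sex = "F",
    view = c("AP", "AP", "LATERAL", "AP", "PA", "AP"),
    body_part = c("CHEST", "ABDOMEN", "CHEST", "CHEST", "Chest", "chest"),
    width = c(1023L, 2000L, 2000L, 2000L, 2048L, 3000L),
    height = c(2000L, 2000L, 2000L, 2000L, 2048L, 3000L),
    manufacturer = "system_a",
    department = "general_wards",
    report_text = "Nasogastric tube in situ.",
    label = "satisfactory",
    stringsAsFactors = FALSE
  )
}

# Tiny linearly separable image problem: class A has a bright top-left
# quadrant, class B a bright bottom-right quadrant.
toy_quadrant_images <- function(n, side = 16, seed = 1) {
  set.seed(seed)
  labels <- rep(c("A", "B"), length.out = n)
  images <- lapply(seq_len(n), function(i) {
    m <- matrix(stats::rnorm(side * side, 10000, 1500), side, side)
    h <- side %/% 2
    if (labels[i] == "A") m[1:h, 1:h] <- m[1:h, 1:h] + 40000
    else m[(h + 1):side, (h + 1):side] <- m[(h + 1):side, (h + 1):side] + 40000
    pmin(pmax(m, 0), 65535)
  })
  list(images = images, labels = labels)
}

tiny_classifier_config <- function(...) {
  defaults <- list(input_side = 16, conv_widths = c(4, 8),
                   dense_units = 32, dropout_rate = 0,
                   augment = c(brightness = 0, rotation = 0, hflip = 0))
  do.call(classifier_config, utils::modifyList(defaults, list(...)))
}
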