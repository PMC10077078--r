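test_that("manifest generation honours size, priors and determinism", {
  empty <- generate_manifest(synth_config(n_images = 0))
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("record_id", "label", "rater3") %in% names(empty)))

  one_class <- generate_manifest(
    synth_config(n_images = 50, class_priors = c(1, 0, 0)))
  expect_equal(unname(table(one_class$label)[["satisfactory"]]), 50L)

  # class counts converge to the configured prevalence (binomial-SD oracle)
  priors <- c(satisfactory = 0.579, malpositioned = 0.353, bronchial = 0.068)
  man <- generate_manifest(synth_config(n_images = 7081,
                                        class_priors = priors, seed = 11))
  counts <- table(factor(man$label, names(priors)))
  expected <- c(4100, 2500, 481)
  for (k in 1:3) {
    sd_k <- sqrt(7081 * priors[k] * (1 - priors[k]))
    expect_lt(abs(counts[[k]] - expected[k]), 3 * sd_k + 1)
  }

  cfg <- synth_config(n_images = 40, seed = 5)
  expect_identical(generate_manifest(cfg), generate_manifest(cfg))

  expect_error(synth_config(class_priors = c(0.5, 0.4, 0.2)), "sum to 1")
  expect_error(synth_config(n_images = -1), "n_images")
})

test_that("rendered images are deterministic with planted class geometry", {
  cfg <- synth_config(n_images = 30, noise_sd = 0, seed = 3)
  man <- generate_manifest(cfg)
  rec <- man[1, ]
  im1 <- render_image(rec, cfg)
  im2 <- render_image(rec, cfg)
  expect_identical(im1$pixels, im2$pixels)

  # planted manufacturer offset recovered exactly at zero noise
  rec_a <- rec; rec_a$manufacturer <- "system_a"   # offset 0
  cfg200 <- cfg
  cfg200$manufacturer_levels <- c(system_a = 0, system_b = 200)
  rec_b <- rec_a; rec_b$manufacturer <- "system_b"
  d <- mean(render_image(rec_b, cfg200)$pixels) -
    mean(render_image(rec_a, cfg200)$pixels)
  expect_equal(d, 200, tolerance = 1e-6)

  # bronchial tips land in the declared bronchial region
  recb <- rec; recb$label <- "bronchial"
  for (id in c("x1", "x2", "x3")) {
    recb$record_id <- id
    im <- render_image(recb, cfg)
    box <- class_tip_region("bronchial", cfg$image_size)
    expect_gte(im$tip_xy[["row"]], box[["r0"]])
    expect_lte(im$tip_xy[["row"]], box[["r1"]])
    expect_gte(im$tip_xy[["col"]], box[["c0"]])
    expect_lte(im$tip_xy[["col"]], box[["c1"]])
  }

  rec_bad <- rec; rec_bad$label <- "lateral"
  expect_error(render_image(rec_bad, cfg), "label")
  expect_true(all(im1$pixels >= 0 & im1$pixels <= 65535))
})

test_that("synthetic embeddings honour centers, dimension and planted effects", {
  centers <- rbind(a = c(0, 0, 0), b = c(4, 0, 0))
  es0 <- synth_embeddings(c(a = 5, b = 5), centers, noise_sd = 0)
  expect_equal(dim(es0$X), c(10L, 3L))
  expect_true(all(es0$X[es0$labels == "a", ] == 0))
  expect_true(all(es0$X[es0$labels == "b", 1] == 4))

  expect_error(
    synth_embeddings(c(a = 5), matrix(0, 1, 3),
                     tag_effects = list(t = list(levels = "x",
                                                 offsets = matrix(0, 1, 2)))),
    "dimension")

  es <- synth_embeddings(c(a = 100), matrix(0, 1, 2), noise_sd = 1, seed = 9)
  expect_identical(es$X,
                   synth_embeddings(c(a = 100), matrix(0, 1, 2),
                                    noise_sd = 1, seed = 9)$X)
})

test_that("drift injection shifts, filters, and leaves the input untouched", {
  es <- synth_embeddings(c(a = 400), matrix(0, 1, 4), noise_sd = 1, seed = 2)
  same <- apply_drift(es, drift_spec("mean_shift", magnitude = 0))
  expect_equal(same$X, es$X)

  shifted <- apply_drift(es, drift_spec("mean_shift", magnitude = 5))
  sds <- apply(es$X, 2, sd)
  expect_equal(colMeans(shifted$X) - colMeans(es$X), 5 * sds,
               tolerance = 1e-10)
  expect_equal(colMeans(es$X), colMeans(es$X))  # original untouched
  expect_match(attr(shifted, "drift_note"), "mean_shift")

  # disjoint age band on an all-elderly cohort errors out explicitly
  cohort <- data.frame(record_id = "a", study_date = "2018-01-01",
                       birth_date = "1948-01-01")  # aged 70
  expect_error(apply_drift(cohort, drift_spec("age_band", band = c(16, 62))),
               "empty cohort")
  kept <- apply_drift(cohort, drift_spec("age_band", band = c(62, 76)))
  expect_equal(nrow(kept), 1L)

  expect_error(drift_spec("age_band", band = c(76, 62)), "ordered")
  expect_error(drift_spec("mean_shift"), "magnitude")

  co <- data.frame(record_id = 1:3, manufacturer = c("a", "b", "a"))
  sw <- apply_drift(co, drift_spec("manufacturer_swap", to = "c"))
  expect_true(all(sw$manufacturer == "c"))
  expect_equal(co$manufacturer, c("a", "b", "a"))
})

test_that("manifest and embedding files round-trip", {
  cfg <- synth_config(n_images = 12, seed = 8)
  man <- generate_manifest(cfg)
  f <- tempfile(fileext = ".csv")
  write_manifest(man, f)
  expect_equal(read_manifest(f), man)

  es <- synth_embeddings(c(a = 4, b = 3), rbind(a = c(0, 0), b = c(3, 0)),
                         noise_sd = 0.5, seed = 4)
  g <- tempfile(fileext = ".csv")
  write_embeddings(es, g)
  back <- read_embeddings(g)
  expect_equal(unname(back$X), unname(es$X), tolerance = 1e-12)
  expect_equal(as.character(back$labels), as.character(es$labels))
})

test_that("images survive a write/read cycle", {
  cfg <- synth_config(n_images = 2, image_size = 32, seed = 6)
  man <- generate_manifest(cfg)
  imgs <- render_cohort(man, cfg)
  d <- tempfile("imgs")
  write_images(imgs, d, format = "tiff")
  back <- read_images(d, man$record_id, format = "tiff")
  expect_equal(back[[1]], imgs[[1]]$pixels, tolerance = 1.1)
})
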