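test_that("age encodes as exact calendar-day differences", {
  expect_equal(encode_age("2000-01-01", "2000-01-01"), 0L)
  expect_equal(encode_age("2000-01-31", "2000-01-01"), 30L)
  expect_equal(encode_age("2001-02-01", "2000-02-01"), 366L)  # leap year
  expect_error(encode_age("2000-01-01", "2001-01-01"), "birth")
})

test_that("tag R2 recovers exact, null and categorical structure", {
  set.seed(31)
  n <- 2000
  z <- rnorm(n)
  coords <- cbind(2 * z + 1, -3 * z + 2)   # exact linear function of the tag
  expect_equal(tag_r2(coords, encode_tag(z, "z"))$r2, 1, tolerance = 1e-10)

  indep <- rnorm(n)
  coords2 <- cbind(rnorm(n), rnorm(n))
  expect_lt(tag_r2(coords2, encode_tag(indep, "noise"))$r2, 0.01)

  # categorical R2 equals the pooled group-means eta-squared oracle
  g <- sample(c("a", "b", "c"), n, TRUE)
  coords3 <- cbind(rnorm(n, ifelse(g == "a", 1, 0)), rnorm(n))
  r2 <- tag_r2(coords3, encode_tag(g, "g"))$r2
  eta2_pooled <- {
    sst <- 0; ssb <- 0
    for (j in 1:2) {
      y <- coords3[, j]
      m <- tapply(y, g, mean)
      ssb <- ssb + sum(tapply(y, g, length) * (m - mean(y))^2)
      sst <- sst + sum((y - mean(y))^2)
    }
    ssb / sst
  }
  expect_equal(r2, eta2_pooled, tolerance = 1e-10)

  expect_warning(r0 <- tag_r2(coords3, encode_tag(rep("x", n), "const")),
                 "constant")
  expect_equal(r0$r2, 0)

  # scale-free: a common affine map of the coordinates leaves R2 unchanged
  resc <- cbind(10 * coords3[, 1] - 5, 10 * coords3[, 2] + 7)
  expect_equal(tag_r2(resc, encode_tag(g, "g"))$r2, r2, tolerance = 1e-10)
})

test_that("cumulative R2 is monotone and additive for orthogonal effects", {
  ec <- cumulative_r2(cbind(rnorm(50), rnorm(50)), list())
  expect_equal(ec$r2, 0)

  set.seed(32)
  n <- 2000
  # two independent binary tags pushing orthogonal directions, calibrated to
  # individual R2 of 0.2 and 0.1 against total variance
  t1 <- rbinom(n, 1, 0.5); t2 <- rbinom(n, 1, 0.5)
  # total pooled variance: 2*noise^2 + 0.25 d1^2 + 0.25 d2^2 = V
  # choose noise = 1; solve d1, d2 so 0.25 d1^2 = 0.2 V and 0.25 d2^2 = 0.1 V
  V <- 2 / (1 - 0.3)
  d1 <- sqrt(0.2 * V / 0.25); d2 <- sqrt(0.1 * V / 0.25)
  coords <- cbind(d1 * t1 + rnorm(n), d2 * t2 + rnorm(n))
  e1 <- encode_tag(t1, "t1"); e2 <- encode_tag(t2, "t2")
  r1 <- tag_r2(coords, e1)$r2
  r2 <- tag_r2(coords, e2)$r2
  rj <- cumulative_r2(coords, list(e1, e2))$r2
  expect_lt(abs(r1 - 0.2), 0.03)
  expect_lt(abs(r2 - 0.1), 0.03)
  expect_lt(abs(rj - 0.3), 0.02)
  expect_gte(rj + 1e-12, r1)

  noise_tag <- encode_tag(rnorm(n), "noise")
  expect_gte(cumulative_r2(coords, list(e1, noise_tag))$r2 + 1e-12,
             cumulative_r2(coords, list(e1))$r2)
})

test_that("tags rank by explained variance with alphabetical tie-breaks", {
  set.seed(33)
  n <- 1500
  za <- rnorm(n); zb <- rnorm(n); zc <- rnorm(n)
  coords <- cbind(3 * za + 1.5 * zb + 0.5 * zc + rnorm(n), rnorm(n))
  tags <- list(big = encode_tag(za, "big"), mid = encode_tag(zb, "mid"),
               small = encode_tag(zc, "small"))
  rk <- rank_tags(coords, tags)
  expect_equal(rk$tag, c("big", "mid", "small"))
  expect_equal(rk$rank, 1:3)

  # all-null effects: tiny R2 everywhere, alphabetical order
  tags0 <- list(zeta = encode_tag(rnorm(n), "zeta"),
                alpha = encode_tag(rnorm(n), "alpha"),
                mu = encode_tag(rnorm(n), "mu"))
  coords0 <- cbind(rnorm(n), rnorm(n))
  rk0 <- rank_tags(coords0, tags0)
  expect_true(all(rk0$r2 < 0.01))

  # exact ties (zero-variance tags) fall back to alphabetical order
  tied <- list(zeta = encode_tag(rep("x", n), "zeta"),
               alpha = encode_tag(rep("y", n), "alpha"))
  rkt <- rank_tags(coords0, tied)
  expect_equal(rkt$tag, c("alpha", "zeta"))

  rk1 <- rank_tags(coords, tags["big"])
  expect_equal(rk1$rank, 1L)
})
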