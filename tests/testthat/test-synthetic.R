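test_that("generation is fully determined by the seed", {
  s <- synthetic_spec(n_samples = 30, seed = 5, views = c(a = 10, b = 8),
                      missing_rate = 0.05)
  d1 <- generate_multiomics(s)
  d2 <- generate_multiomics(s)
  expect_identical(d1$labels, d2$labels)
  for (v in seq_along(d1$views)) {
    expect_identical(d1$views[[v]]$values, d2$views[[v]]$values)
  }
  d3 <- generate_multiomics(synthetic_spec(n_samples = 30, seed = 6,
                                           views = c(a = 10, b = 8)))
  expect_false(identical(d1$views[[1]]$values, d3$views[[1]]$values))
})

test_that("class labels follow the requested proportions exactly", {
  d <- generate_multiomics(synthetic_spec(
    n_samples = 100, n_classes = 2, class_proportions = c(0.5, 0.5),
    views = c(a = 4), seed = 1))
  expect_equal(as.integer(table(d$labels)), c(50L, 50L))

  d5 <- generate_multiomics(synthetic_spec(
    n_samples = 103, n_classes = 5, class_proportions = rep(0.2, 5),
    views = c(a = 10), seed = 2))
  counts <- as.integer(table(d5$labels))
  expect_equal(sum(counts), 103L)
  expect_true(all(abs(counts - 103 * 0.2) < 1))
})

test_that("spec validation rejects malformed inputs", {
  expect_error(synthetic_spec(n_classes = 1), "at least 2")
  expect_error(synthetic_spec(class_proportions = c(0.7, 0.2)), "sum to 1")
  expect_error(synthetic_spec(n_classes = 2,
                              class_proportions = c(1, 0)), "positive")
  expect_error(synthetic_spec(views = c(a = 1)), "2 features")
  expect_error(synthetic_spec(missing_rate = 1), "\\[0, 1\\)")
})

test_that("noise-free directional data has exact within-class cosine 1 despite jitter", {
  d <- generate_multiomics(synthetic_spec(
    n_samples = 20, noise_sd = 0, scale_jitter_sd = 0.5,
    signal_mode = "directional", views = c(a = 15), seed = 3))
  x <- d$views[[1]]$values
  for (cls in 1:2) {
    rows <- which(d$labels == cls)
    for (i in rows[-1]) {
      expect_equal(cosine_similarity(x[rows[1], ], x[i, ]), 1.0)
    }
  }
})

test_that("row rescaling leaves cosine unchanged but changes RBF", {
  d <- generate_multiomics(synthetic_spec(n_samples = 10, views = c(a = 8),
                                          seed = 4))
  x <- d$views[[1]]$values
  x2 <- x
  x2[3, ] <- 7 * x2[3, ]
  cos1 <- cosine_matrix(x)
  cos2 <- cosine_matrix(x2)
  expect_equal(cos1, cos2, tolerance = 1e-12, ignore_attr = TRUE)
  g <- median_gamma(x)
  r1 <- exp(-g * squared_distances(x))
  r2 <- exp(-g * squared_distances(x2))
  expect_gt(max(abs(r1 - r2)), 1e-6)
})

test_that("between-class cosine separation is monotone in signal strength", {
  strengths <- c(0, 0.5, 1, 2, 4, 8)
  mean_between <- sapply(strengths, function(s) {
    d <- generate_multiomics(synthetic_spec(
      n_samples = 30, noise_sd = 0, scale_jitter_sd = 0,
      signal_strength = s, views = c(a = 20), seed = 9))
    x <- d$views[[1]]$values
    cm <- cosine_matrix(x)
    between <- outer(d$labels, d$labels, "!=") & upper.tri(cm)
    mean(cm[between])
  })
  expect_true(all(diff(mean_between) <= 1e-10))
  expect_lt(mean_between[length(strengths)], mean_between[1])
})

test_that("inject_missing removes the exact count and keeps rows/columns alive", {
  v <- tiny_view(10, 10)
  expect_identical(inject_missing(v, 0), v)
  m1 <- inject_missing(v, 0.1, seed = 2)
  expect_equal(sum(is.na(m1$values)), 10L)
  m2 <- inject_missing(v, 0.1, seed = 2)
  expect_identical(m1$values, m2$values)
  m3 <- inject_missing(v, 0.1, seed = 3)
  expect_false(identical(m1$values, m3$values))
  heavy <- inject_missing(tiny_view(12, 6, seed = 8), 0.6, seed = 1)
  expect_true(all(rowSums(!is.na(heavy$values)) >= 1))
  expect_true(all(colSums(!is.na(heavy$values)) >= 1))
  expect_error(inject_missing(v, 1), "\\[0, 1\\)")
})

test_that("datasets survive a write/read round trip", {
  dir <- withr::local_tempdir()
  d <- generate_multiomics(synthetic_spec(n_samples = 12,
                                          views = c(a = 6, b = 5),
                                          missing_rate = 0.1, seed = 11))
  write_dataset(d, dir)
  d2 <- read_dataset(dir)
  expect_identical(d2$labels, d$labels)
  expect_equal(names(d2$views), names(d$views))
  for (v in seq_along(d$views)) {
    expect_equal(d2$views[[v]]$values, d$views[[v]]$values,
                 tolerance = 1e-12)
    expect_identical(d2$views[[v]]$sample_ids, d$views[[v]]$sample_ids)
  }
})
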