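test_that("gcn_layer implements the propagation rule", {
  # edgeless graph: normalized = I, identity weights, rectifier inert
  H <- matrix(abs(rnorm(12)), 4, 3)
  expect_equal(gcn_layer(H, diag(4), diag(3)), H)

  # 2-node complete unit graph: normalized entries all 1/2
  norm2 <- matrix(0.5, 2, 2)
  H2 <- rbind(c(2, 0), c(0, 2))
  expect_equal(gcn_layer(H2, norm2, diag(2), apply_activation = FALSE),
               matrix(1, 2, 2))

  expect_equal(gcn_layer(H, diag(4), matrix(0, 3, 2)), matrix(0, 4, 2))
  expect_error(gcn_layer(H, diag(3), diag(3)), "mismatch")
})

test_that("gcn_layer agrees with a double-loop message-passing oracle", {
  set.seed(10)
  for (rep in 1:6) {
    A <- matrix(runif(25), 5, 5)
    H <- matrix(rnorm(5 * 4), 5, 4)
    theta <- matrix(rnorm(4 * 3), 4, 3)
    for (act in c(TRUE, FALSE)) {
      expect_equal(gcn_layer(H, A, theta, act),
                   oracle_gcn_layer(H, A, theta, act), tolerance = 1e-9)
    }
  }
})

test_that("per-view forward passes emit probability rows", {
  v <- tiny_view(9, 6, seed = 20)
  g <- build_graph(v$values, similarity_config(k = 3))
  params <- init_gcn_params(6, 3, hidden_dim = 5, seed = 2)
  probs <- gcn_forward(v, g, params)
  expect_equal(unname(rowSums(probs)), rep(1, 9), tolerance = 1e-6)
  expect_true(all(probs >= 0))

  # zero weights -> zero logits -> uniform rows
  zero <- params
  zero$theta0[] <- 0; zero$theta1[] <- 0
  expect_equal(gcn_forward(v, g, zero), matrix(1 / 3, 9, 3),
               tolerance = 1e-12, ignore_attr = TRUE)

  # fully connected variant equals the edgeless graph and ignores the graph
  eg <- sample_graph(matrix(0, 9, 9), v$sample_ids)
  expect_equal(fcn_forward(v, params), gcn_forward(v, eg, params))
})

test_that("joint sample permutation permutes predictions identically", {
  v <- tiny_view(8, 5, seed = 21)
  g <- build_graph(v$values, similarity_config(k = 2))
  params <- init_gcn_params(5, 2, hidden_dim = 4, seed = 3)
  base <- gcn_forward(v, g, params)
  perm <- sample(8)
  vp <- omics_view(v$values[perm, ], modality = v$modality)
  gp <- sample_graph(g$weights[perm, perm], vp$sample_ids)
  expect_equal(gcn_forward(vp, gp, params), base[perm, ],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("the cross-view tensor is the flattened outer product", {
  p1 <- matrix(c(1, 0), 1, 2)
  p2 <- matrix(c(0, 1), 1, 2)
  expect_equal(vcdn_tensor(list(p1, p2))$flat[1, ], c(0, 1, 0, 0))

  q1 <- matrix(c(0.6, 0.4), 1, 2)
  q2 <- matrix(c(0.3, 0.7), 1, 2)
  expect_equal(vcdn_tensor(list(q1, q2))$flat[1, ],
               c(0.18, 0.42, 0.12, 0.28))

  set.seed(11)
  preds <- lapply(1:3, function(i) row_softmax(matrix(rnorm(12), 4, 3)))
  flat <- vcdn_tensor(preds)$flat
  expect_equal(rowSums(flat), rep(1, 4), tolerance = 1e-6)
  expect_error(vcdn_tensor(preds[1]), "at least 2")
})

test_that("tensor marginalization recovers every view's prediction", {
  set.seed(12)
  for (c in c(2, 5)) {
    for (m in c(2, 3)) {
      preds <- lapply(seq_len(m),
                      function(i) row_softmax(matrix(rnorm(6 * c), 6, c)))
      tens <- vcdn_tensor(preds)
      idx <- tensor_index(c, m)
      # cross-check the flattening itself against explicit enumeration
      expect_equal(tens$flat[2, ],
                   oracle_tensor_row(lapply(preds, function(p) p[2, ])),
                   tolerance = 1e-12)
      for (v in seq_len(m)) {
        marg <- vapply(seq_len(c), function(a) {
          rowSums(tens$flat[, idx[, v] == a, drop = FALSE])
        }, numeric(6))
        expect_equal(marg, preds[[v]], tolerance = 1e-9)
      }
    }
  }
})

test_that("the fusion head produces distributions and is deterministic", {
  set.seed(13)
  preds <- lapply(1:3, function(i) row_softmax(matrix(rnorm(10), 5, 2)))
  tens <- vcdn_tensor(preds)
  params <- init_vcdn_params(2, 3, seed = 4)
  out1 <- vcdn_forward(tens, params)
  out2 <- vcdn_forward(tens, params)
  expect_identical(out1, out2)
  expect_equal(rowSums(out1), rep(1, 5), tolerance = 1e-6)

  zero <- params
  zero$fc1[] <- 0; zero$fc2[] <- 0; zero$out[] <- 0
  expect_equal(vcdn_forward(tens, zero), matrix(0.5, 5, 2))
})

test_that("average fusion behaves as an elementwise mean", {
  a <- matrix(c(1, 0, 0, 1), 2, 2)
  b <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(average_fusion(list(a, a)), a)
  expect_equal(average_fusion(list(a, b)), matrix(0.5, 2, 2))
  set.seed(14)
  preds <- lapply(1:3, function(i) row_softmax(matrix(rnorm(8), 4, 2)))
  expect_equal(rowSums(average_fusion(preds)), rep(1, 4), tolerance = 1e-9)
})

test_that("analytic gradients match finite differences through the fusion path", {
  set.seed(15)
  n <- 8; cls <- 3; m <- 2
  dims <- c(5, 4); hid <- 4
  x <- lapply(dims, function(d) matrix(abs(rnorm(n * d)), n, d))
  adj <- lapply(1:m, function(v) {
    build_graph(x[[v]], similarity_config("rbf_similarity", gamma = 0.3,
                                          k = 3))$normalized
  })
  ax <- lapply(1:m, function(v) adj[[v]] %*% x[[v]])
  y <- one_hot(sample(1:cls, n, replace = TRUE), cls)
  tr <- c(1, 2, 4, 6, 7)
  idx_mat <- tensor_index(cls, m)
  params <- list(
    gcn = lapply(1:m, function(v) {
      list(theta0 = matrix(rnorm(dims[v] * hid) * 0.3, dims[v], hid),
           theta1 = matrix(rnorm(hid * cls) * 0.3, hid, cls))
    }),
    vcdn = list(fc1 = matrix(rnorm(cls^m * 6) * 0.2, cls^m, 6),
                fc2 = matrix(rnorm(6 * 5) * 0.2, 6, 5),
                out = matrix(rnorm(5 * cls) * 0.2, 5, cls)))
  loss_of <- function(p) {
    mvgc_loss(mvgc_forward(p, ax, adj, TRUE, TRUE), y, tr, m)
  }
  fw <- mvgc_forward(params, ax, adj, TRUE, TRUE)
  g <- mvgc_backward(params, fw, y, ax, adj, tr, TRUE, TRUE, idx_mat)
  eps <- 1e-6
  probe <- function(set_entry, analytic) {
    p1 <- set_entry(params, eps); p2 <- set_entry(params, -eps)
    num <- (loss_of(p1) - loss_of(p2)) / (2 * eps)
    expect_equal(num, analytic, tolerance = 1e-5)
  }
  probe(function(p, e) { p$gcn[[1]]$theta0[2, 3] <- p$gcn[[1]]$theta0[2, 3] + e; p },
        g$gcn[[1]]$theta0[2, 3])
  probe(function(p, e) { p$gcn[[2]]$theta1[1, 2] <- p$gcn[[2]]$theta1[1, 2] + e; p },
        g$gcn[[2]]$theta1[1, 2])
  probe(function(p, e) { p$vcdn$fc1[4, 2] <- p$vcdn$fc1[4, 2] + e; p },
        g$vcdn$fc1[4, 2])
  probe(function(p, e) { p$vcdn$fc2[3, 1] <- p$vcdn$fc2[3, 1] + e; p },
        g$vcdn$fc2[3, 1])
  probe(function(p, e) { p$vcdn$out[2, 2] <- p$vcdn$out[2, 2] + e; p },
        g$vcdn$out[2, 2])
})
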