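test_that("stratified splits respect class proportions and determinism", {
  labels <- rep(1:2, each = 50)
  plan <- stratified_split(labels, 0.7, seed = 1, val_fraction = 0)
  expect_length(plan$val_idx, 0)
  for (cls in 1:2) {
    expect_equal(sum(labels[plan$train_idx] == cls), 35L)
    expect_equal(sum(labels[plan$test_idx] == cls), 15L)
  }
  expect_identical(stratified_split(labels, 0.7, seed = 1, val_fraction = 0),
                   plan)

  plan_v <- stratified_split(labels, 0.7, seed = 2, val_fraction = 0.2)
  all_idx <- sort(c(plan_v$train_idx, plan_v$val_idx, plan_v$test_idx))
  expect_identical(all_idx, seq_along(labels))
  expect_length(intersect(plan_v$train_idx, plan_v$test_idx), 0)
  expect_length(intersect(plan_v$val_idx, plan_v$test_idx), 0)

  set.seed(30)
  for (rep in 1:10) {
    lab <- sample(1:3, 40, replace = TRUE, prob = c(0.5, 0.3, 0.2))
    if (min(table(lab)) < 2) next
    p <- stratified_split(lab, 0.7, seed = rep, val_fraction = 0)
    for (cls in 1:3) {
      n_c <- sum(lab == cls)
      got <- sum(lab[p$train_idx] == cls)
      expect_lte(abs(got - 0.7 * n_c), 1)
    }
  }
  expect_error(stratified_split(c(1, 1, 2), 0.7), "at least 2")
})

test_that("training is deterministic and separable data is learned perfectly", {
  d <- tiny_dataset(n = 30, seed = 31, noise_sd = 0)
  graphs <- lapply(d$views, build_graph, config = similarity_config(k = 4))
  cfg <- train_config(max_epochs = 60, patience = 60, pretrain_epochs = 0,
                      hidden_dim = 8)
  m1 <- train_pipeline(d, graphs, "full", cfg, seed = 0)
  m2 <- train_pipeline(d, graphs, "full", cfg, seed = 0)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)

  # monotone early loss decline, then perfect training accuracy
  expect_true(all(diff(m1$history$train_loss[1:10]) < 0))
  pred <- predict_pipeline(m1, d, graphs)
  tr_idx <- c(m1$split$train_idx, m1$split$val_idx)
  acc <- mean(max.col(pred$fused[tr_idx, ]) == d$labels[tr_idx])
  expect_equal(acc, 1.0)
})

test_that("early stopping halts after `patience` stale epochs", {
  d <- tiny_dataset(n = 20, seed = 32)
  graphs <- lapply(d$views, build_graph, config = similarity_config(k = 3))
  frozen <- train_config(learning_rate = 0, max_epochs = 50, patience = 1,
                         pretrain_epochs = 0, hidden_dim = 4)
  m <- train_pipeline(d, graphs, "full", frozen, seed = 1)
  expect_equal(m$stopped_epoch, 2L)
  expect_equal(m$best_epoch, 1L)
})

test_that("model variants wire their architectures correctly", {
  d <- tiny_dataset(n = 24, seed = 33)
  graphs <- lapply(d$views, build_graph, config = similarity_config(k = 3))
  cfg <- fast_config()
  for (variant in c("full", "no_vcdn", "no_gcn")) {
    m <- train_pipeline(d, graphs, variant, cfg, seed = 2)
    pred <- predict_pipeline(m, d, graphs)
    expect_equal(unname(rowSums(pred$fused)), rep(1, 24), tolerance = 1e-6)
    if (variant == "no_vcdn") {
      expect_null(m$params$vcdn)
      expect_equal(pred$fused, average_fusion(pred$view_probs))
    } else {
      expect_false(is.null(m$params$vcdn))
    }
  }
  # the fully connected ablation ignores graph structure
  m_fcn <- train_pipeline(d, graphs, "no_gcn", cfg, seed = 2)
  other <- lapply(d$views, build_graph, config = similarity_config(k = 5))
  expect_equal(predict_pipeline(m_fcn, d, graphs)$fused,
               predict_pipeline(m_fcn, d, other)$fused)
})

test_that("training never consults labels outside the training side", {
  d <- tiny_dataset(n = 24, seed = 34)
  graphs <- lapply(d$views, build_graph, config = similarity_config(k = 3))
  cfg <- fast_config()
  split <- stratified_split(d$labels, cfg$train_fraction, 3,
                            cfg$val_fraction)
  m1 <- train_pipeline(d, graphs, "full", cfg, seed = 3, split = split)
  poisoned <- d
  poisoned$labels[split$test_idx] <-
    (poisoned$labels[split$test_idx] %% 2L) + 1L
  m2 <- train_pipeline(poisoned, graphs, "full", cfg, seed = 3,
                       split = split)
  expect_identical(m1$params, m2$params)
})
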