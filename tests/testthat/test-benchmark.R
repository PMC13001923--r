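test_that("grid search enumerates the grids and honors tie-breaking order", {
  d <- tiny_dataset(n = 20, seed = 50)
  cfg <- fast_config()
  single <- grid_search(d, "rbf_similarity", gamma_grid = 0.3,
                        k = 3, config = cfg, seed = 1)
  expect_equal(single$gamma, 0.3)
  expect_equal(nrow(attr(single, "grid")), 1L)

  # hybrid default grids enumerate |gamma| x |weight| candidates
  expect_equal(length(10^(-4:1)) * length(seq(0.1, 0.9, by = 0.2)), 30L)
  small <- grid_search(d, "hybrid_similarity", gamma_grid = c(0.1, 1),
                       weight_grid = c(0.3, 0.7), k = 3, config = cfg,
                       seed = 1)
  g <- attr(small, "grid")
  expect_equal(nrow(g), 4L)
  # candidates visited in (gamma, weight) ascending order
  expect_equal(g$gamma, c(0.1, 0.1, 1, 1))
  expect_equal(g$weight, c(0.3, 0.7, 0.3, 0.7))
})

test_that("grid-search selection is invariant to test-label poisoning", {
  d <- tiny_dataset(n = 20, seed = 51)
  cfg <- fast_config()
  split <- stratified_split(d$labels, cfg$train_fraction, 2,
                            cfg$val_fraction)
  pick1 <- grid_search(d, "rbf_similarity", gamma_grid = c(0.01, 0.1, 1),
                       k = 3, config = cfg, seed = 2, split = split)
  poisoned <- d
  poisoned$labels[split$test_idx] <-
    (poisoned$labels[split$test_idx] %% 2L) + 1L
  pick2 <- grid_search(poisoned, "rbf_similarity",
                       gamma_grid = c(0.01, 0.1, 1), k = 3, config = cfg,
                       seed = 2, split = split)
  expect_equal(pick1$gamma, pick2$gamma)
  expect_equal(attr(pick1, "grid"), attr(pick2, "grid"))
})

test_that("the benchmark report has the promised bookkeeping", {
  d <- tiny_dataset(n = 20, seed = 52)
  cfgs <- default_graph_configs(k = 3)
  tc <- fast_config(seeds = 0:1)
  rep <- run_benchmark(d, cfgs, "full", tc)
  expect_equal(nrow(rep), 6L * 2L)  # six graph configs x two seeds
  expect_setequal(unique(rep$graph), METRIC_CHOICES)

  summ <- benchmark_summary(rep)
  for (i in seq_len(nrow(summ))) {
    sel <- rep$graph == summ$graph[i]
    expect_equal(summ$accuracy_mean[i], mean(rep$accuracy[sel]))
    expect_equal(summ$auc_macro_sd[i], sd(rep$auc_macro[sel]))
  }

  # duplicated seeds force zero dispersion
  dup <- run_benchmark(d, cfgs["cosine_similarity"], "full",
                       fast_config(seeds = c(0, 0)))
  expect_equal(sd(dup$auc_macro), 0)
})

test_that("pairwise comparison reports t-tests, CIs and effect sizes", {
  d <- tiny_dataset(n = 20, seed = 53)
  cfgs <- default_graph_configs(k = 3)[c("cosine_similarity",
                                         "rbf_similarity")]
  rep <- run_benchmark(d, cfgs, "full", fast_config(seeds = 0:2))
  cmp <- compare_to_reference(rep, "cosine_similarity", "accuracy")
  expect_equal(nrow(cmp), 1L)
  ref <- rep$accuracy[rep$graph == "cosine_similarity"]
  oth <- rep$accuracy[rep$graph == "rbf_similarity"]
  expect_equal(cmp$p_value, paired_ttest(ref, oth))
  expect_equal(cmp$cohens_d, cohens_d(ref, oth))
  expect_true(cmp$ref_ci_low <= cmp$mean_ref &&
                cmp$mean_ref <= cmp$ref_ci_high)
})

test_that("identical configurations produce byte-identical benchmark CSVs", {
  dir <- withr::local_tempdir()
  d <- tiny_dataset(n = 18, seed = 54)
  cfgs <- default_graph_configs(k = 3)[c("cosine_similarity",
                                         "rbf_distance")]
  tc <- fast_config(seeds = 0:1)
  f1 <- file.path(dir, "a.csv"); f2 <- file.path(dir, "b.csv")
  run_benchmark(d, cfgs, "full", tc, csv = f1)
  run_benchmark(d, cfgs, "full", tc, csv = f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})
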