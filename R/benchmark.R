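## Benchmark harness: hyperparameter grid search on the training split,
## the repeated-split benchmark over graph constructions and model
## variants, and summary/comparison reports.

#' Grid search for RBF/hybrid graph hyperparameters
#'
#' Enumerates the gamma grid (and, for hybrid metrics, the mixing-weight
#' grid), builds the candidate graphs, trains on the training indices and
#' scores internal validation accuracy of the fused prediction. Test
#' labels are never consulted. Ties resolve toward the smaller gamma, then
#' the smaller weight (candidates are enumerated in that order and only a
#' strictly better score replaces the incumbent).
#'
#' @param dataset Dataset with `views` and `labels`.
#' @param metric One of the six metric names.
#' @param gamma_grid Candidate bandwidths (default `10^(-4:1)`).
#' @param weight_grid Candidate alpha/beta values (default
#'   `seq(0.1, 0.9, by = 0.2)`).
#' @param k Neighbours per node.
#' @param config [train_config()] used for the candidate fits.
#' @param seed Seed for splitting/initialization.
#' @param split Optional fixed [stratified_split()] plan.
#' @return The winning [similarity_config()], with the score and the
#'   scored grid attached as attributes.
#' @export
grid_search <- function(dataset, metric, gamma_grid = 10^(-4:1),
                        weight_grid = seq(0.1, 0.9, by = 0.2), k = 10,
                        config = train_config(max_epochs = 200),
                        seed = 0L, split = NULL) {
  metric <- match.arg(metric, METRIC_CHOICES)
  if (length(gamma_grid) == 0) stop("gamma_grid must be non-empty")
  uses_gamma <- metric %in% c("rbf_similarity", "rbf_distance",
                              "hybrid_similarity", "hybrid_distance")
  uses_weight <- metric %in% c("hybrid_similarity", "hybrid_distance")
  if (uses_weight && length(weight_grid) == 0) {
    stop("weight_grid must be non-empty")
  }
  gamma_grid <- if (uses_gamma) sort(gamma_grid) else NA_real_
  weight_grid <- if (uses_weight) sort(weight_grid) else NA_real_
  if (is.null(split)) {
    split <- stratified_split(dataset$labels, config$train_fraction, seed,
                              config$val_fraction)
  }
  va <- if (length(split$val_idx) > 0) split$val_idx else split$train_idx
  grid <- expand.grid(weight = weight_grid, gamma = gamma_grid)
  grid <- grid[order(grid$gamma, grid$weight), , drop = FALSE]
  rownames(grid) <- NULL
  best <- NULL
  scores <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cand <- similarity_config(
      metric = metric,
      gamma = if (uses_gamma) grid$gamma[i] else "median",
      beta = if (uses_weight) grid$weight[i] else 0.5,
      alpha = if (uses_weight) grid$weight[i] else 0.5,
      k = k)
    graphs <- lapply(dataset$views, build_graph, config = cand)
    model <- train_pipeline(dataset, graphs, "full", config, seed,
                            split = split)
    pred <- predict_pipeline(model, dataset, graphs)
    scores[i] <- mean(max.col(pred$fused[va, , drop = FALSE],
                              ties.method = "first") ==
                        dataset$labels[va])
    if (is.null(best) || scores[i] > best$score) {
      best <- list(config = cand, score = scores[i])
    }
  }
  out <- best$config
  attr(out, "score") <- best$score
  attr(out, "grid") <- cbind(grid, score = scores)
  out
}

#' Run the repeated-split benchmark
#'
#' For every graph configuration and model variant, trains on each seed's
#' stratified split and evaluates the fused prediction on that split's
#' test set. Graphs are built once per configuration over all samples
#' (transductive protocol; only labels are masked).
#'
#' @param dataset Dataset with `views` and `labels`.
#' @param graph_configs Named list of [similarity_config()]s (defaults to
#'   all six metrics with median-heuristic gamma).
#' @param variants Model variants to run.
#' @param config A [train_config()]; its `seeds` define the splits.
#' @param csv Optional path: the tidy per-split table is also written as
#'   CSV (deterministic bytes for a fixed configuration).
#' @return A `benchmark_report` data.frame, one row per
#'   (graph config, variant, seed), with all test metrics.
#' @export
run_benchmark <- function(dataset,
                          graph_configs = default_graph_configs(),
                          variants = "full",
                          config = train_config(), csv = NULL) {
  rows <- list()
  for (gname in names(graph_configs)) {
    gconf <- graph_configs[[gname]]
    graphs <- lapply(dataset$views, build_graph, config = gconf)
    for (variant in variants) {
      for (seed in config$seeds) {
        model <- train_pipeline(dataset, graphs, variant, config, seed)
        pred <- predict_pipeline(model, dataset, graphs)
        rep <- evaluate(pred$fused, dataset$labels, model$split$test_idx)
        rows[[length(rows) + 1L]] <- data.frame(
          graph = gname, metric = gconf$metric, variant = variant,
          seed = seed, accuracy = rep$accuracy,
          sensitivity = rep$sensitivity, specificity = rep$specificity,
          precision = rep$precision, f1_macro = rep$f1_macro,
          f1_weighted = rep$f1_weighted, auc_macro = rep$auc_macro,
          best_epoch = model$best_epoch, stopped_epoch = model$stopped_epoch,
          stringsAsFactors = FALSE)
      }
    }
  }
  report <- do.call(rbind, rows)
  class(report) <- c("benchmark_report", class(report))
  if (!is.null(csv)) {
    utils::write.csv(format(report, digits = 15, trim = TRUE, scientific = FALSE),
                     csv, row.names = FALSE, quote = FALSE)
  }
  report
}

#' The six default graph configurations
#'
#' All six metrics with the median-heuristic RBF bandwidth, balanced
#' hybrid weights, and a common k.
#'
#' @param k Neighbours per node.
#' @param beta,alpha Hybrid mixing weights.
#' @export
default_graph_configs <- function(k = 10, beta = 0.5, alpha = 0.5) {
  configs <- lapply(METRIC_CHOICES, function(mt) {
    similarity_config(metric = mt, gamma = "median", beta = beta,
                      alpha = alpha, k = k)
  })
  names(configs) <- METRIC_CHOICES
  configs
}

#' Mean +/- SD summary of a benchmark report
#'
#' @param report A [run_benchmark()] data.frame.
#' @param metrics Metric columns to summarize.
#' @return Data frame with one row per (graph, variant) and mean/sd
#'   columns per metric.
#' @export
benchmark_summary <- function(report,
                              metrics = c("accuracy", "f1_macro",
                                          "f1_weighted", "auc_macro")) {
  groups <- unique(report[, c("graph", "variant")])
  out <- lapply(seq_len(nrow(groups)), function(i) {
    sel <- report$graph == groups$graph[i] &
      report$variant == groups$variant[i]
    row <- groups[i, , drop = FALSE]
    row$n_splits <- sum(sel)
    for (mt in metrics) {
      row[[paste0(mt, "_mean")]] <- mean(report[[mt]][sel])
      row[[paste0(mt, "_sd")]] <- stats::sd(report[[mt]][sel])
    }
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Pairwise statistical comparison against a reference configuration
#'
#' Paired two-tailed t-tests (paired by split seed), 95% CIs of each
#' configuration's mean, and pooled-SD Cohen's d of the reference against
#' every other configuration.
#'
#' @param report A [run_benchmark()] data.frame (single variant).
#' @param reference `graph` name to compare everything against.
#' @param metric Score column to compare.
#' @return Data frame with one row per non-reference configuration.
#' @export
compare_to_reference <- function(report, reference = "cosine_similarity",
                                 metric = "auc_macro") {
  ref <- report[report$graph == reference, ]
  ref <- ref[order(ref$seed), ]
  others <- setdiff(unique(report$graph), reference)
  out <- lapply(others, function(g) {
    oth <- report[report$graph == g, ]
    oth <- oth[order(oth$seed), ]
    ci_r <- ci95(ref[[metric]])
    ci_o <- ci95(oth[[metric]])
    data.frame(reference = reference, other = g, metric = metric,
               mean_ref = mean(ref[[metric]]), mean_other = mean(oth[[metric]]),
               p_value = paired_ttest(ref[[metric]], oth[[metric]]),
               cohens_d = cohens_d(ref[[metric]], oth[[metric]]),
               ref_ci_low = ci_r[["low"]], ref_ci_high = ci_r[["high"]],
               other_ci_low = ci_o[["low"]], other_ci_high = ci_o[["high"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
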