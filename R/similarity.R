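## The six similarity/distance measures used for sample-graph construction,
## plus the median heuristic for the RBF bandwidth. On non-negative input
## vectors: cosine similarity/distance lie in [0, 1], RBF similarity in
## (0, 1], RBF distance in [0, 1), and the hybrids in the convex hulls of
## their components.

METRIC_CHOICES <- c("cosine_similarity", "cosine_distance",
                    "rbf_similarity", "rbf_distance",
                    "hybrid_similarity", "hybrid_distance")

check_pair <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  invisible(NULL)
}

check_nonzero_norm <- function(x, label = "vector") {
  if (sum(x^2) == 0) stop(label, " has zero norm; direction undefined")
  invisible(NULL)
}

#' Cosine similarity between two sample vectors
#'
#' `(x . y) / (||x|| ||y||)`: how directionally aligned two vectors are,
#' irrespective of magnitude. In `[0, 1]` for non-negative inputs.
#'
#' @param x,y Numeric vectors of equal length and nonzero norm.
#' @export
cosine_similarity <- function(x, y) {
  check_pair(x, y)
  check_nonzero_norm(x, "x"); check_nonzero_norm(y, "y")
  sum(x * y) / sqrt(sum(x^2) * sum(y^2))
}

#' Cosine distance
#'
#' The complement `1 - cosine_similarity(x, y)`.
#' @inheritParams cosine_similarity
#' @export
cosine_distance <- function(x, y) 1 - cosine_similarity(x, y)

#' Angular distance
#'
#' `arccos(cosine_similarity(x, y)) / pi`, a true metric on directions; the
#' cosine value is clamped to `[-1, 1]` before `arccos`.
#' @inheritParams cosine_similarity
#' @export
angular_distance <- function(x, y) {
  acos(min(1, max(-1, cosine_similarity(x, y)))) / pi
}

#' RBF (Gaussian) similarity
#'
#' `exp(-gamma ||x - y||^2)`; `gamma > 0` sets how quickly similarity
#' decays with Euclidean distance.
#' @inheritParams cosine_similarity
#' @param gamma Positive kernel bandwidth parameter.
#' @export
rbf_similarity <- function(x, y, gamma) {
  check_pair(x, y)
  if (!is.numeric(gamma) || gamma <= 0) stop("gamma must be positive")
  exp(-gamma * sum((x - y)^2))
}

#' RBF distance
#'
#' `1 - exp(-gamma ||x - y||^2)`.
#' @inheritParams rbf_similarity
#' @export
rbf_distance <- function(x, y, gamma) 1 - rbf_similarity(x, y, gamma)

#' Hybrid (cosine + RBF) similarity
#'
#' `beta * cosine + (1 - beta) * RBF`; `beta = 1` is pure cosine, `beta =
#' 0` pure RBF.
#' @inheritParams rbf_similarity
#' @param beta Mixing weight in `[0, 1]`.
#' @export
hybrid_similarity <- function(x, y, beta, gamma) {
  if (beta < 0 || beta > 1) stop("beta must be in [0, 1]")
  beta * cosine_similarity(x, y) + (1 - beta) * rbf_similarity(x, y, gamma)
}

#' Hybrid (cosine + RBF) distance
#'
#' `alpha * cosine_distance + (1 - alpha) * rbf_distance`; `alpha` weights
#' angular against spatial divergence.
#' @inheritParams rbf_similarity
#' @param alpha Mixing weight in `[0, 1]`.
#' @export
hybrid_distance <- function(x, y, alpha, gamma) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  alpha * cosine_distance(x, y) + (1 - alpha) * rbf_distance(x, y, gamma)
}

#' Median-heuristic RBF bandwidth
#'
#' `gamma = 1 / (2 * median ||x_i - x_j||^2)` over all unordered sample
#' pairs. Zero-distance pairs are included in the median; an error is
#' raised only when the median itself is zero (degenerate data).
#'
#' @param view An `omics_view` (or plain matrix) with at least 2 samples.
#' @return A positive scalar.
#' @export
median_gamma <- function(view) {
  values <- if (inherits(view, "omics_view")) view$values else as.matrix(view)
  n <- nrow(values)
  if (n < 2) stop("median_gamma needs at least 2 samples")
  d2 <- squared_distances(values)
  med <- stats::median(d2[upper.tri(d2)])
  if (med == 0) stop("median pairwise distance is 0; data degenerate")
  1 / (2 * med)
}

# Full pairwise squared Euclidean distance matrix (clamped at 0).
squared_distances <- function(values) {
  sq <- rowSums(values^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(values)
  pmax(d2, 0)
}

# Full pairwise cosine similarity matrix; errors on zero-norm samples.
cosine_matrix <- function(values, sample_ids = rownames(values)) {
  norms <- sqrt(rowSums(values^2))
  if (any(norms == 0)) {
    bad <- if (is.null(sample_ids)) which(norms == 0) else
      sample_ids[norms == 0]
    stop("zero-norm sample(s) under cosine metric: ",
         paste(bad, collapse = ", "))
  }
  s <- tcrossprod(values / norms)
  pmin(pmax(s, -1), 1)
}

#' Similarity-graph configuration
#'
#' @param metric One of the six metric names (see `METRIC_CHOICES`).
#' @param gamma Positive RBF bandwidth, or the string `"median"` to apply
#'   the median heuristic per view.
#' @param beta Hybrid-similarity weight in `[0, 1]` (ignored otherwise).
#' @param alpha Hybrid-distance weight in `[0, 1]` (ignored otherwise).
#' @param k Neighbours retained per node before symmetrization.
#' @return A `similarity_config` list.
#' @export
similarity_config <- function(metric = "cosine_similarity", gamma = "median",
                              beta = 0.5, alpha = 0.5, k = 10) {
  metric <- match.arg(metric, METRIC_CHOICES)
  if (is.numeric(gamma)) {
    if (gamma <= 0) stop("gamma must be positive")
  } else if (!identical(gamma, "median")) {
    stop('gamma must be a positive number or "median"')
  }
  if (beta < 0 || beta > 1) stop("beta must be in [0, 1]")
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (k < 1) stop("k must be at least 1")
  structure(list(metric = metric, gamma = gamma, beta = beta, alpha = alpha,
                 k = as.integer(k)),
            class = "similarity_config")
}

# Pairwise metric matrix for a config (gamma already resolved to a number
# when needed). Returns the raw metric values (similarity or distance).
pairwise_metric <- function(values, config, sample_ids = rownames(values)) {
  needs_rbf <- config$metric %in% c("rbf_similarity", "rbf_distance",
                                    "hybrid_similarity", "hybrid_distance")
  if (needs_rbf && !is.numeric(config$gamma)) {
    stop("gamma must be resolved to a number before pairwise_metric")
  }
  switch(config$metric,
    cosine_similarity = cosine_matrix(values, sample_ids),
    cosine_distance = 1 - cosine_matrix(values, sample_ids),
    rbf_similarity = exp(-config$gamma * squared_distances(values)),
    rbf_distance = 1 - exp(-config$gamma * squared_distances(values)),
    hybrid_similarity = config$beta * cosine_matrix(values, sample_ids) +
      (1 - config$beta) * exp(-config$gamma * squared_distances(values)),
    hybrid_distance = config$alpha * (1 - cosine_matrix(values, sample_ids)) +
      (1 - config$alpha) * (1 - exp(-config$gamma * squared_distances(values)))
  )
}
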