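## Sample-graph construction: full pairwise metric -> affinity -> per-node
## top-k sparsification -> union (max) symmetrization -> self-loops and
## symmetric normalization D^{-1/2} (A + I) D^{-1/2} for graph convolution.

#' Build a sample similarity graph
#'
#' Steps: (1) compute the full pairwise metric matrix; (2) convert
#' distances to affinities `w = 1 - d` so all edge weights are
#' similarities (clamped to `[0, 1]`); (3) for each node keep its k
#' strongest neighbours (self excluded; ties toward the lower sample
#' index); (4) symmetrize by elementwise maximum, so an edge survives if
#' either endpoint selected it (this union rule prevents isolated nodes,
#' which fragment the graph and starve message passing); (5) zero the
#' diagonal of A, add self-loops `A~ = A + I`, and form the normalized
#' operator `D~^{-1/2} A~ D~^{-1/2}`.
#'
#' The graph is built over all samples; in the transductive training
#' protocol, labels (not graph membership) are what is masked at test
#' nodes.
#'
#' @param view An `omics_view` (or plain matrix).
#' @param config A [similarity_config()]; `gamma = "median"` is resolved
#'   with [median_gamma()] on this view.
#' @return A `sample_graph` with elements `weights` (symmetric, zero
#'   diagonal, entries in `[0, 1]`), `normalized`, `sample_ids`, and the
#'   resolved `config`.
#' @export
build_graph <- function(view, config = similarity_config()) {
  values <- if (inherits(view, "omics_view")) view$values else as.matrix(view)
  sample_ids <- rownames(values)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  n <- nrow(values)
  if (config$k >= n) stop("k must be smaller than the number of samples")
  needs_rbf <- config$metric %in% c("rbf_similarity", "rbf_distance",
                                    "hybrid_similarity", "hybrid_distance")
  if (needs_rbf && identical(config$gamma, "median")) {
    config$gamma <- median_gamma(values)
  }
  m <- pairwise_metric(values, config, sample_ids)
  is_distance <- grepl("distance$", config$metric)
  w <- if (is_distance) 1 - m else m
  w <- pmin(pmax(w, 0), 1)

  keep <- matrix(0, n, n)
  for (i in seq_len(n)) {
    cand <- w[i, ]
    cand[i] <- -Inf
    best <- order(-cand, seq_len(n), method = "radix")[seq_len(config$k)]
    keep[i, best] <- w[i, best]
  }
  a <- pmax(keep, t(keep))
  diag(a) <- 0
  sample_graph(a, sample_ids, config)
}

#' Assemble a sample graph from a weight matrix
#'
#' Validates symmetry and range, then attaches self-loops and the
#' symmetric-normalized operator.
#'
#' @param weights Symmetric non-negative n x n matrix with zero diagonal.
#' @param sample_ids Sample identifiers (length n).
#' @param config Optional [similarity_config()] provenance.
#' @export
sample_graph <- function(weights, sample_ids = rownames(weights),
                         config = NULL) {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  if (max(abs(weights - t(weights))) > 1e-12) {
    stop("weights must be symmetric")
  }
  if (any(diag(weights) != 0)) stop("weights must have a zero diagonal")
  if (any(weights < 0) || any(weights > 1)) {
    stop("weights must lie in [0, 1]")
  }
  a_tilde <- weights + diag(n)
  d_inv_sqrt <- 1 / sqrt(rowSums(a_tilde))
  normalized <- a_tilde * outer(d_inv_sqrt, d_inv_sqrt)
  dimnames(weights) <- dimnames(normalized) <- list(sample_ids, sample_ids)
  structure(list(weights = weights, normalized = normalized,
                 sample_ids = sample_ids, config = config),
            class = "sample_graph")
}

#' @export
print.sample_graph <- function(x, ...) {
  n <- nrow(x$weights)
  n_edges <- sum(x$weights > 0) / 2
  cat(sprintf("<sample_graph: %d nodes, %d edges%s>\n", n, n_edges,
              if (!is.null(x$config)) paste0(", metric ", x$config$metric)
              else ""))
  invisible(x)
}

#' Export a graph's adjacency as Matrix Market
#'
#' Writes the sparse weight matrix to `<path>.mtx` and the sample
#' identifiers (one per line, in matrix order) to `<path>.samples.txt`.
#'
#' @param graph A `sample_graph`.
#' @param path Output path stem.
#' @export
write_graph_mtx <- function(graph, path) {
  sp <- Matrix::Matrix(graph$weights, sparse = TRUE)
  Matrix::writeMM(sp, paste0(path, ".mtx"))
  writeLines(graph$sample_ids, paste0(path, ".samples.txt"))
  invisible(path)
}

#' Read a graph written by [write_graph_mtx()]
#'
#' @param path Path stem used when writing.
#' @export
read_graph_mtx <- function(path) {
  w <- as.matrix(Matrix::readMM(paste0(path, ".mtx")))
  ids <- readLines(paste0(path, ".samples.txt"))
  sample_graph(w, ids)
}
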