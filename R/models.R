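## Per-view two-layer graph convolutional classifiers and the
## view-correlation tensor fusion head, with the two ablation variants
## (average fusion instead of the tensor network; fully connected layers
## instead of graph convolution). All dense algebra is base R / BLAS.

relu <- function(x) pmax(x, 0)

# Numerically stable row-wise softmax.
row_softmax <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Glorot-uniform weight matrix.
glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

#' Initialize two-layer GCN weights
#'
#' Glorot-uniform `input_dim x hidden` and `hidden x c` matrices (no
#' biases); the hidden width defaults to 64.
#'
#' @param input_dim Feature count of the view.
#' @param n_classes Class count c.
#' @param hidden_dim Hidden-layer width.
#' @param seed Integer seed for the draw.
#' @export
init_gcn_params <- function(input_dim, n_classes, hidden_dim = 64,
                            seed = 1L) {
  with_seed(seed, {
    structure(list(theta0 = glorot(input_dim, hidden_dim),
                   theta1 = glorot(hidden_dim, n_classes),
                   hidden_dim = hidden_dim),
              class = "gcn_params")
  })
}

#' One graph-convolution layer
#'
#' `sigma(normalized %*% H %*% theta)`, the standard propagation rule with
#' symmetric-normalized self-looped adjacency; the rectifier `sigma` is
#' omitted when `apply_activation` is `FALSE` (final layers emit logits).
#'
#' @param H Node-feature matrix (n x d).
#' @param normalized The `normalized` operator of a [sample_graph()].
#' @param theta Weight matrix (d x d').
#' @param apply_activation Apply the rectifier?
#' @export
gcn_layer <- function(H, normalized, theta, apply_activation = TRUE) {
  if (ncol(normalized) != nrow(H)) stop("graph/feature shape mismatch")
  if (ncol(H) != nrow(theta)) stop("feature/weight shape mismatch")
  out <- normalized %*% H %*% theta
  if (apply_activation) relu(out) else out
}

check_alignment <- function(view, graph) {
  if (!identical(view$sample_ids, graph$sample_ids)) {
    stop("view and graph sample orders differ")
  }
}

#' Forward pass of one per-view GCN classifier
#'
#' Two propagation layers (rectified hidden layer of width
#' `params$hidden_dim`, then a c-logit layer) followed by a row-wise
#' softmax.
#'
#' @param view An `omics_view`.
#' @param graph The matching `sample_graph`.
#' @param params [init_gcn_params()] weights.
#' @return An n x c class-probability matrix (rows on the simplex).
#' @export
gcn_forward <- function(view, graph, params) {
  check_alignment(view, graph)
  h <- gcn_layer(view$values, graph$normalized, params$theta0)
  logits <- gcn_layer(h, graph$normalized, params$theta1,
                      apply_activation = FALSE)
  row_softmax(logits)
}

#' Fully connected ablation forward pass
#'
#' Identical to [gcn_forward()] with the normalized adjacency replaced by
#' the identity: no message passing, same widths.
#'
#' @inheritParams gcn_forward
#' @export
fcn_forward <- function(view, params) {
  h <- relu(view$values %*% params$theta0)
  row_softmax(h %*% params$theta1)
}

#' Cross-view probability tensor
#'
#' For each sample, the outer product of the per-view class-probability
#' vectors, flattened row-major with view 1 as the slowest-varying index:
#' entry `(a1, ..., am)` is `prod_i y_i[a_i]` and sits at flat position
#' `((a1-1) c + (a2-1)) c + ... + am`.
#'
#' @param predictions List of m >= 2 n x c probability matrices sharing n
#'   and c.
#' @return A `cross_view_tensor` with the `n x c^m` matrix `flat` plus `c`
#'   and `m`.
#' @export
vcdn_tensor <- function(predictions) {
  m <- length(predictions)
  if (m < 2) stop("at least 2 views are required")
  n <- nrow(predictions[[1]])
  c <- ncol(predictions[[1]])
  for (p in predictions) {
    if (nrow(p) != n || ncol(p) != c) {
      stop("all predictions must share n and c")
    }
  }
  flat <- predictions[[1]]
  for (v in seq_len(m)[-1]) {
    w <- ncol(flat)
    flat <- flat[, rep(seq_len(w), each = c), drop = FALSE] *
      predictions[[v]][, rep(seq_len(c), times = w), drop = FALSE]
  }
  colnames(flat) <- NULL
  structure(list(flat = flat, c = c, m = m), class = "cross_view_tensor")
}

#' Initialize fusion-head weights
#'
#' Two fully connected layers of 128 and 64 units over the flattened
#' `c^m` tensor, then a c-dim output projection feeding the softmax.
#'
#' @param n_classes Class count c.
#' @param n_views View count m.
#' @param seed Integer seed.
#' @export
init_vcdn_params <- function(n_classes, n_views, seed = 1L) {
  with_seed(seed, {
    structure(list(fc1 = glorot(n_classes^n_views, 128),
                   fc2 = glorot(128, 64),
                   out = glorot(64, n_classes)),
              class = "vcdn_params")
  })
}

#' Fusion-head forward pass
#'
#' `flat -> fc1 -> rectifier -> fc2 -> rectifier -> out -> softmax`.
#'
#' @param tensor A [vcdn_tensor()].
#' @param params [init_vcdn_params()] weights.
#' @return An n x c probability matrix.
#' @export
vcdn_forward <- function(tensor, params) {
  u1 <- relu(tensor$flat %*% params$fc1)
  u2 <- relu(u1 %*% params$fc2)
  row_softmax(u2 %*% params$out)
}

#' Average fusion (tensor-network ablation)
#'
#' Elementwise mean of the per-view probability matrices.
#'
#' @param predictions List of n x c probability matrices.
#' @export
average_fusion <- function(predictions) {
  Reduce(`+`, predictions) / length(predictions)
}
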