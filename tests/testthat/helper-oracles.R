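# Independent reference implementations used as oracles. These follow the
# definitions literally (scalar loops, explicit enumeration) and share no
# code with the package internals they check.

# Literal scalar metric between two vectors.
oracle_metric <- function(x, y, metric, gamma = NULL, beta = NULL,
                          alpha = NULL) {
  cos <- sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  rbf <- if (!is.null(gamma)) exp(-gamma * sum((x - y)^2)) else NA
  switch(metric,
    cosine_similarity = cos,
    cosine_distance = 1 - cos,
    rbf_similarity = rbf,
    rbf_distance = 1 - rbf,
    hybrid_similarity = beta * cos + (1 - beta) * rbf,
    hybrid_distance = alpha * (1 - cos) + (1 - alpha) * (1 - rbf))
}

# Exhaustive reference graph construction: enumerates every pair with the
# scalar oracle metric, applies affinity conversion, per-node top-k with
# ties to the lower index, union symmetrization, and dense normalization.
oracle_graph <- function(values, metric, k, gamma = NULL, beta = NULL,
                         alpha = NULL) {
  n <- nrow(values)
  w <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      mv <- oracle_metric(values[i, ], values[j, ], metric, gamma, beta,
                          alpha)
      if (grepl("distance$", metric)) mv <- 1 - mv
      w[i, j] <- min(max(mv, 0), 1)
    }
  }
  keep <- matrix(0, n, n)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    ord <- others[order(-w[i, others], others)]
    sel <- ord[seq_len(k)]
    keep[i, sel] <- w[i, sel]
  }
  a <- pmax(keep, t(keep))
  diag(a) <- 0
  a_t <- a + diag(n)
  d <- diag(1 / sqrt(rowSums(a_t)))
  list(weights = a, normalized = d %*% a_t %*% d)
}

# Brute-force median-heuristic bandwidth by explicit pair enumeration.
oracle_median_gamma <- function(values) {
  n <- nrow(values)
  d2 <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d2 <- c(d2, sum((values[i, ] - values[j, ])^2))
    }
  }
  1 / (2 * median(d2))
}

# Naive double-loop message passing: out[i, ] = sum_j A[i, j] * H[j, ] %*%
# theta, optionally rectified.
oracle_gcn_layer <- function(H, A, theta, activate = TRUE) {
  n <- nrow(H)
  out <- matrix(0, n, ncol(theta))
  for (i in seq_len(n)) {
    acc <- rep(0, ncol(H))
    for (j in seq_len(n)) acc <- acc + A[i, j] * H[j, ]
    out[i, ] <- acc %*% theta
  }
  if (activate) out[out < 0] <- 0
  out
}

# Explicit multi-index enumeration of the cross-view tensor for one sample.
oracle_tensor_row <- function(prob_rows) {
  m <- length(prob_rows)
  c <- length(prob_rows[[1]])
  flat <- numeric(c^m)
  pos <- 0
  rec <- function(level, prod) {
    for (a in seq_len(c)) {
      p2 <- prod * prob_rows[[level]][a]
      if (level == m) {
        pos <<- pos + 1
        flat[pos] <<- p2
      } else {
        rec(level + 1, p2)
      }
    }
  }
  rec(1, 1)
  flat
}

# Literal KNN imputation per its definition: shared-coordinate Euclidean
# distances, neighbours ordered by (distance, index), donors must observe
# the target feature.
oracle_knn_impute <- function(values, k) {
  n <- nrow(values)
  out <- values
  for (i in seq_len(n)) {
    for (f in seq_len(ncol(values))) {
      if (!is.na(values[i, f])) next
      d <- rep(Inf, n)
      for (j in seq_len(n)) {
        if (j == i) next
        sh <- which(!is.na(values[i, ]) & !is.na(values[j, ]))
        if (length(sh) > 0) d[j] <- sqrt(sum((values[i, sh] - values[j, sh])^2))
      }
      ord <- order(d, seq_len(n))
      ord <- ord[ord != i & is.finite(d[ord])]
      donors <- ord[!is.na(values[ord, f])]
      donors <- donors[seq_len(min(k, length(donors)))]
      out[i, f] <- mean(values[donors, f])
    }
  }
  out
}

# Confusion counts by explicit comparison, per class one-vs-rest.
oracle_confusion <- function(pred, truth, cls) {
  tp <- sum(pred == cls & truth == cls)
  fp <- sum(pred == cls & truth != cls)
  fn <- sum(pred != cls & truth == cls)
  tn <- sum(pred != cls & truth != cls)
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}
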