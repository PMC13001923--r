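## End-to-end training of the multi-view graph classifier: per-view
## two-layer GCNs plus the tensor fusion head, jointly minimizing the sum
## of cross-entropies of every view head and the fusion head at training
## nodes. Gradients are derived analytically and applied with
## adaptive-moment (Adam) updates; early stopping watches validation loss.
##
## Variants: "full" (GCNs + tensor fusion), "no_vcdn" (average fusion),
## "no_gcn" (identity adjacency, i.e. fully connected layers, fusion kept).

#' Training configuration
#'
#' @param learning_rate Adam step size.
#' @param weight_decay L2 penalty added to every gradient.
#' @param max_epochs Epoch cap.
#' @param patience Early stopping: halt after this many consecutive epochs
#'   without validation-loss improvement.
#' @param train_fraction Fraction of samples on the training side of each
#'   split.
#' @param val_fraction Fraction of the training side carved out
#'   (stratified) as the validation set that drives early stopping.
#' @param hidden_dim Hidden width of the per-view classifiers.
#' @param pretrain_epochs Epochs of view-head-only training before the
#'   joint phase, so the fusion head starts from informative view
#'   predictions instead of backpropagating noise from its random
#'   initialization into the graph classifiers.
#' @param seeds Integer seeds, one per benchmark split.
#' @export
train_config <- function(learning_rate = 0.001, weight_decay = 5e-4,
                         max_epochs = 2500, patience = 20,
                         train_fraction = 0.7, val_fraction = 0.2,
                         hidden_dim = 64, pretrain_epochs = 100,
                         seeds = 0:4) {
  if (patience < 1) stop("patience must be at least 1")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)")
  }
  if (val_fraction < 0 || val_fraction >= 1) {
    stop("val_fraction must be in [0, 1)")
  }
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 train_fraction = train_fraction,
                 val_fraction = val_fraction,
                 hidden_dim = as.integer(hidden_dim),
                 pretrain_epochs = as.integer(pretrain_epochs),
                 seeds = as.integer(seeds)),
            class = "train_config")
}

#' Stratified train/validation/test split
#'
#' Allocates each class proportionally to the train side (largest-remainder
#' rounding, leftovers placed deterministically from the seed), then carves
#' a stratified validation set out of the training side. Per-class
#' train-vs-test counts match the requested ratio within one sample.
#'
#' @param labels Integer class vector (1..K).
#' @param train_fraction Fraction on the training side.
#' @param seed Integer seed.
#' @param val_fraction Fraction of the training side used for validation.
#' @return A `split_plan` with disjoint, exhaustive `train_idx`, `val_idx`,
#'   `test_idx`.
#' @export
stratified_split <- function(labels, train_fraction = 0.7, seed = 0L,
                             val_fraction = 0.1) {
  classes <- sort(unique(labels))
  n_c <- vapply(classes, function(k) sum(labels == k), integer(1))
  if (any(n_c < 2)) {
    stop("every class needs at least 2 members for stratified splitting")
  }
  with_seed(seed, {
    n_train_c <- floor(train_fraction * n_c)
    leftover <- round(train_fraction * length(labels)) - sum(n_train_c)
    if (leftover > 0) {
      rem <- train_fraction * n_c - n_train_c
      pick <- order(-rem, sample.int(length(classes)),
                    method = "radix")[seq_len(leftover)]
      n_train_c[pick] <- n_train_c[pick] + 1L
    }
    # every class keeps at least one sample on each side
    n_train_c <- pmin(pmax(n_train_c, 1L), n_c - 1L)

    train_side <- integer(0); test_idx <- integer(0); val_idx <- integer(0)
    for (ci in seq_along(classes)) {
      members <- sample(which(labels == classes[ci]))
      tr <- members[seq_len(n_train_c[ci])]
      test_idx <- c(test_idx, members[-seq_len(n_train_c[ci])])
      if (val_fraction > 0 && length(tr) >= 2) {
        n_val <- max(1L, round(val_fraction * length(tr)))
        n_val <- min(n_val, length(tr) - 1L)
        val_idx <- c(val_idx, tr[seq_len(n_val)])
        tr <- tr[-seq_len(n_val)]
      }
      train_side <- c(train_side, tr)
    }
    structure(list(train_idx = sort(train_side), val_idx = sort(val_idx),
                   test_idx = sort(test_idx), seed = as.integer(seed)),
              class = "split_plan")
  })
}

one_hot <- function(labels, n_classes) {
  y <- matrix(0, length(labels), n_classes)
  y[cbind(seq_along(labels), labels)] <- 1
  y
}

cross_entropy <- function(probs, y_onehot, idx) {
  p <- probs[cbind(idx, max.col(y_onehot[idx, , drop = FALSE],
                                ties.method = "first"))]
  -mean(log(pmax(p, 1e-12)))
}

# Multi-index table for the flattened c^m tensor: row j holds (a1, ..., am)
# with view 1 slowest-varying.
tensor_index <- function(c, m) {
  g <- as.matrix(expand.grid(rep(list(seq_len(c)), m)))
  g <- g[, rev(seq_len(m)), drop = FALSE]
  colnames(g) <- NULL
  g
}

adam_step <- function(theta, grad, state, t, lr, wd,
                      b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  g <- grad + wd * theta
  state$m <- b1 * state$m + (1 - b1) * g
  state$v <- b2 * state$v + (1 - b2) * g * g
  m_hat <- state$m / (1 - b1^t)
  v_hat <- state$v / (1 - b2^t)
  list(theta = theta - lr * m_hat / (sqrt(v_hat) + eps), state = state)
}

# Joint forward pass over all views and the fusion head. `ax` holds the
# precomputed (normalized %*% X) per view (or X itself without a graph),
# `adj` the normalized operators. Returns every intermediate needed by the
# backward pass.
mvgc_forward <- function(p, ax, adj, use_graph, use_vcdn) {
  m <- length(ax)
  zs <- hs <- ah <- probs <- vector("list", m)
  for (v in seq_len(m)) {
    zs[[v]] <- ax[[v]] %*% p$gcn[[v]]$theta0
    hs[[v]] <- relu(zs[[v]])
    ah[[v]] <- if (use_graph) adj[[v]] %*% hs[[v]] else hs[[v]]
    probs[[v]] <- row_softmax(ah[[v]] %*% p$gcn[[v]]$theta1)
  }
  out <- list(zs = zs, hs = hs, ah = ah, probs = probs)
  if (use_vcdn) {
    out$tens <- vcdn_tensor(probs)$flat
    out$u1p <- out$tens %*% p$vcdn$fc1
    out$u1 <- relu(out$u1p)
    out$u2p <- out$u1 %*% p$vcdn$fc2
    out$u2 <- relu(out$u2p)
    out$fused <- row_softmax(out$u2 %*% p$vcdn$out)
  } else {
    out$fused <- average_fusion(probs)
  }
  out
}

# Summed cross-entropy of every view head plus the fusion head at `idx`.
mvgc_loss <- function(fw, y, idx, m) {
  l <- cross_entropy(fw$fused, y, idx)
  for (v in seq_len(m)) l <- l + cross_entropy(fw$probs[[v]], y, idx)
  l
}

# Analytic gradients of mvgc_loss at the training nodes `tr` with respect
# to every weight matrix. The fusion path backpropagates through the
# flattened probability tensor: for view v, dL/dP_v[, a] sums the tensor
# gradient over all multi-indices whose v-th component is a, weighted by
# the product of the other views' probabilities at those indices. With
# `view_only`, the fusion term is dropped (pretraining phase).
mvgc_backward <- function(p, fw, y, ax, adj, tr, use_graph, use_vcdn,
                          idx_mat, view_only = FALSE) {
  m <- length(ax)
  n <- nrow(y)
  k_classes <- ncol(y)
  n_tr <- length(tr)
  mask <- rep(0, n); mask[tr] <- 1 / n_tr
  g <- list(gcn = vector("list", m))
  if (view_only) {
    for (v in seq_len(m)) {
      pv <- fw$probs[[v]]
      d_logits <- (pv - y) * mask
      g1 <- crossprod(fw$ah[[v]], d_logits)
      d_h <- d_logits %*% t(p$gcn[[v]]$theta1)
      if (use_graph) d_h <- adj[[v]] %*% d_h
      d_z <- d_h * (fw$zs[[v]] > 0)
      g$gcn[[v]] <- list(theta0 = crossprod(ax[[v]], d_z), theta1 = g1)
    }
    return(g)
  }
  if (use_vcdn) {
    d_o <- (fw$fused - y) * mask
    g$vcdn <- list(fc1 = NULL, fc2 = NULL, out = crossprod(fw$u2, d_o))
    d_u2 <- (d_o %*% t(p$vcdn$out)) * (fw$u2p > 0)
    g$vcdn$fc2 <- crossprod(fw$u1, d_u2)
    d_u1 <- (d_u2 %*% t(p$vcdn$fc2)) * (fw$u1p > 0)
    g$vcdn$fc1 <- crossprod(fw$tens, d_u1)
    d_t <- d_u1 %*% t(p$vcdn$fc1)
  } else {
    # fused = mean of view probs: d(CE)/d(fused), shared across views
    d_q <- -(y / pmax(fw$fused, 1e-12)) * mask / m
  }
  for (v in seq_len(m)) {
    pv <- fw$probs[[v]]
    if (use_vcdn) {
      prod_other <- matrix(1, n, nrow(idx_mat))
      for (u in seq_len(m)[-v]) {
        prod_other <- prod_other * fw$probs[[u]][, idx_mat[, u],
                                                 drop = FALSE]
      }
      contrib <- d_t * prod_other
      d_pv <- vapply(seq_len(k_classes), function(a) {
        rowSums(contrib[, idx_mat[, v] == a, drop = FALSE])
      }, numeric(n))
    } else {
      d_pv <- d_q
    }
    # back through the softmax, plus the view head's own CE shortcut
    d_logits <- pv * (d_pv - rowSums(d_pv * pv)) + (pv - y) * mask
    g1 <- crossprod(fw$ah[[v]], d_logits)
    d_h <- d_logits %*% t(p$gcn[[v]]$theta1)
    if (use_graph) d_h <- adj[[v]] %*% d_h
    d_z <- d_h * (fw$zs[[v]] > 0)
    g$gcn[[v]] <- list(theta0 = crossprod(ax[[v]], d_z), theta1 = g1)
  }
  g
}

#' Train the multi-view graph classifier
#'
#' Joint end-to-end training: the loss is the sum of cross-entropies of
#' every per-view prediction and the fused prediction, averaged over
#' training nodes only (test labels are never touched; the graphs span all
#' samples — the transductive protocol). Optimized with Adam at the
#' configured rate and weight decay; training halts when the validation
#' loss has not improved for `patience` consecutive epochs, and the
#' parameters from the best validation epoch are returned.
#'
#' @param dataset A `synthetic_dataset` (or any list with `views` and
#'   `labels`).
#' @param graphs List of `sample_graph`s, one per view, same sample order.
#' @param variant `"full"`, `"no_vcdn"` (average fusion) or `"no_gcn"`
#'   (fully connected ablation).
#' @param config A [train_config()].
#' @param seed Split and initialization seed.
#' @param split Optional precomputed [stratified_split()] plan.
#' @return A `trained_model` with best-validation parameters, the split,
#'   and a per-epoch loss history.
#' @export
train_pipeline <- function(dataset, graphs,
                           variant = c("full", "no_vcdn", "no_gcn"),
                           config = train_config(), seed = 0L,
                           split = NULL) {
  variant <- match.arg(variant)
  views <- dataset$views
  labels <- dataset$labels
  m <- length(views)
  n <- length(labels)
  k_classes <- max(labels)
  if (variant != "no_gcn") {
    if (length(graphs) != m) stop("need one graph per view")
    for (v in seq_len(m)) check_alignment(views[[v]], graphs[[v]])
  }
  if (is.null(split)) {
    split <- stratified_split(labels, config$train_fraction, seed,
                              config$val_fraction)
  }
  tr <- split$train_idx
  va <- split$val_idx
  if (length(va) == 0) va <- tr  # fall back: stop on training loss

  y <- one_hot(labels, k_classes)
  use_graph <- variant != "no_gcn"
  adj <- if (use_graph) lapply(graphs, `[[`, "normalized") else NULL
  x <- lapply(views, `[[`, "values")
  ax <- if (use_graph) {
    lapply(seq_len(m), function(v) adj[[v]] %*% x[[v]])
  } else x
  use_vcdn <- variant != "no_vcdn" && m >= 2
  idx_mat <- if (use_vcdn) tensor_index(k_classes, m) else NULL

  params <- with_seed(seed, {
    p <- list(gcn = lapply(seq_len(m), function(v) {
      list(theta0 = glorot(ncol(x[[v]]), config$hidden_dim),
           theta1 = glorot(config$hidden_dim, k_classes))
    }))
    if (use_vcdn) {
      p$vcdn <- list(fc1 = glorot(k_classes^m, 128), fc2 = glorot(128, 64),
                     out = glorot(64, k_classes))
    }
    p
  })
  adam_m <- rapply(params, function(w) w * 0, how = "replace")
  adam_v <- adam_m

  forward <- function(p) {
    mvgc_forward(p, ax, adj, use_graph, use_vcdn)
  }
  loss_at <- function(fw, idx) mvgc_loss(fw, y, idx, m)
  # model selection and early stopping track the fused head's validation
  # cross-entropy: the summed objective is dominated by the view heads and
  # can bottom out while the fusion head is still untrained
  val_loss_at <- function(fw, idx) cross_entropy(fw$fused, y, idx)
  backward <- function(p, fw) {
    mvgc_backward(p, fw, y, ax, adj, tr, use_graph, use_vcdn, idx_mat)
  }

  step <- 0L
  update_params <- function(grads) {
    step <<- step + 1L
    for (v in seq_len(m)) {
      for (nm in c("theta0", "theta1")) {
        upd <- adam_step(params$gcn[[v]][[nm]], grads$gcn[[v]][[nm]],
                         list(m = adam_m$gcn[[v]][[nm]],
                              v = adam_v$gcn[[v]][[nm]]),
                         step, config$learning_rate, config$weight_decay)
        params$gcn[[v]][[nm]] <<- upd$theta
        adam_m$gcn[[v]][[nm]] <<- upd$state$m
        adam_v$gcn[[v]][[nm]] <<- upd$state$v
      }
    }
    if (use_vcdn && !is.null(grads$vcdn)) {
      for (nm in c("fc1", "fc2", "out")) {
        upd <- adam_step(params$vcdn[[nm]], grads$vcdn[[nm]],
                         list(m = adam_m$vcdn[[nm]], v = adam_v$vcdn[[nm]]),
                         step, config$learning_rate, config$weight_decay)
        params$vcdn[[nm]] <<- upd$theta
        adam_m$vcdn[[nm]] <<- upd$state$m
        adam_v$vcdn[[nm]] <<- upd$state$v
      }
    }
  }

  # view-head-only warm-up before the joint phase
  if (use_vcdn && config$pretrain_epochs > 0) {
    for (pe in seq_len(config$pretrain_epochs)) {
      fw <- mvgc_forward(params, ax, adj, use_graph, use_vcdn = FALSE)
      grads <- mvgc_backward(params, fw, y, ax, adj, tr, use_graph,
                             use_vcdn = FALSE, idx_mat, view_only = TRUE)
      update_params(grads)
    }
  }

  best <- list(loss = Inf, params = params, epoch = 0L)
  streak <- 0L
  history <- vector("list", config$max_epochs)
  stopped <- config$max_epochs
  for (epoch in seq_len(config$max_epochs)) {
    fw <- forward(params)
    train_loss <- loss_at(fw, tr)
    val_loss <- val_loss_at(fw, va)
    if (!is.finite(train_loss) || !is.finite(val_loss)) {
      stop(sprintf("non-finite loss at epoch %d (train %g, val %g)",
                   epoch, train_loss, val_loss))
    }
    history[[epoch]] <- c(epoch = epoch, train_loss = train_loss,
                          val_loss = val_loss)
    if (val_loss < best$loss) {
      best <- list(loss = val_loss, params = params, epoch = epoch)
      streak <- 0L
    } else {
      streak <- streak + 1L
      if (streak >= config$patience) { stopped <- epoch; break }
    }
    grads <- backward(params, fw)
    update_params(grads)
  }
  history <- as.data.frame(do.call(rbind, history[!vapply(history, is.null,
                                                          logical(1))]))
  structure(list(params = best$params, variant = variant, split = split,
                 config = config, seed = as.integer(seed),
                 n_classes = k_classes, history = history,
                 best_epoch = best$epoch, stopped_epoch = stopped),
            class = "trained_model")
}

#' Predictions of a trained model
#'
#' @param model A `trained_model`.
#' @param dataset The dataset it was trained on (transductive: all nodes
#'   are scored).
#' @param graphs The per-view graphs used in training.
#' @return List with `view_probs` (per-view n x c matrices) and `fused`.
#' @export
predict_pipeline <- function(model, dataset, graphs) {
  m <- length(dataset$views)
  use_graph <- model$variant != "no_gcn"
  probs <- lapply(seq_len(m), function(v) {
    p <- list(theta0 = model$params$gcn[[v]]$theta0,
              theta1 = model$params$gcn[[v]]$theta1,
              hidden_dim = model$config$hidden_dim)
    if (use_graph) gcn_forward(dataset$views[[v]], graphs[[v]], p)
    else fcn_forward(dataset$views[[v]], p)
  })
  fused <- if (!is.null(model$params$vcdn) && m >= 2) {
    vcdn_forward(vcdn_tensor(probs),
                 structure(model$params$vcdn, class = "vcdn_params"))
  } else {
    average_fusion(probs)
  }
  list(view_probs = probs, fused = fused)
}
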