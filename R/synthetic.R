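## Synthetic multi-omics generator.
##
## Emulates the data regime the benchmark assumes: m aligned views per
## sample, class signal expressed as a shared *direction* in feature space
## (so angular similarity separates classes), per-sample multiplicative
## scale jitter standing in for batch effects (to which cosine similarity
## is invariant while Euclidean/RBF measures are not), additive Gaussian
## noise, and optional missing entries for imputation testing.

# Run `expr` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specify a synthetic multi-omics dataset
#'
#' @param n_samples Number of samples.
#' @param n_classes Number of classes (2 for a binary AD-vs-control style
#'   task, 5 for a PAM50-style subtyping task).
#' @param views Named integer vector: feature count per modality.
#' @param signal_mode `"directional"` (classes differ by direction in
#'   feature space), `"magnitude"` (classes share one direction and differ
#'   only by scalar offsets), or `"mixed"`.
#' @param signal_strength Non-negative scalar controlling prototype
#'   separation: 0 makes all class directions identical, large values make
#'   them near-orthogonal.
#' @param scale_jitter_sd SD of the per-sample log-normal multiplicative
#'   scale factor (batch-effect surrogate).
#' @param noise_sd SD of additive Gaussian feature noise.
#' @param missing_rate Fraction of entries set missing in each view.
#' @param class_proportions Simplex vector of class frequencies.
#' @param seed Integer seed; generation is fully determined by it.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_samples = 150,
                           n_classes = 2,
                           views = c(mrna = 100, meth = 100, mirna = 50),
                           signal_mode = c("directional", "magnitude", "mixed"),
                           signal_strength = 4,
                           scale_jitter_sd = 0.5,
                           noise_sd = 0.6,
                           missing_rate = 0,
                           class_proportions = rep(1 / n_classes, n_classes),
                           seed = 1L) {
  signal_mode <- match.arg(signal_mode)
  if (n_samples < 1) stop("n_samples must be positive")
  if (n_classes < 2) stop("n_classes must be at least 2")
  if (length(views) < 1) stop("at least one view is required")
  if (any(views < 2)) stop("every view needs at least 2 features")
  if (is.null(names(views)) || any(!nzchar(names(views)))) {
    names(views) <- paste0("view", seq_along(views))
  }
  if (length(class_proportions) != n_classes) {
    stop("class_proportions must have length n_classes")
  }
  if (any(class_proportions <= 0)) {
    stop("class_proportions must all be positive")
  }
  if (abs(sum(class_proportions) - 1) > 1e-12) {
    stop("class_proportions must sum to 1")
  }
  if (signal_strength < 0 || scale_jitter_sd < 0 || noise_sd < 0) {
    stop("signal_strength, scale_jitter_sd and noise_sd must be non-negative")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must be in [0, 1)")
  }
  structure(
    list(n_samples = as.integer(n_samples), n_classes = as.integer(n_classes),
         views = views, signal_mode = signal_mode,
         signal_strength = signal_strength, scale_jitter_sd = scale_jitter_sd,
         noise_sd = noise_sd, missing_rate = missing_rate,
         class_proportions = class_proportions, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# Largest-remainder allocation of n samples to class proportions.
allocate_classes <- function(n, proportions) {
  base <- floor(n * proportions)
  extra <- n - sum(base)
  if (extra > 0) {
    rem <- n * proportions - base
    give <- order(rem, seq_along(rem), decreasing = c(TRUE, FALSE),
                  method = "radix")[seq_len(extra)]
    base[give] <- base[give] + 1
  }
  as.integer(base)
}

# Class prototypes for one view: unit-norm non-negative marker directions on
# disjoint feature blocks (mutually orthogonal by construction), blended with
# a shared non-negative baseline weighted by 1/(1 + signal_strength).
make_prototypes <- function(n_features, n_classes, signal_strength) {
  baseline <- abs(stats::rnorm(n_features))
  baseline <- baseline / sqrt(sum(baseline^2))
  block <- rep_len(seq_len(n_classes), n_features)
  w <- 1 / (1 + signal_strength)
  proto <- matrix(0, n_classes, n_features)
  for (c in seq_len(n_classes)) {
    marker <- numeric(n_features)
    idx <- which(block == c)
    marker[idx] <- abs(stats::rnorm(length(idx)))
    marker <- marker / sqrt(sum(marker^2))
    proto[c, ] <- w * baseline + (1 - w) * marker
  }
  proto
}

#' Generate a synthetic multi-omics dataset
#'
#' In directional mode, sample i of class c in view v is
#' `s_i * max(p_vc + eps_i, 0)` with non-negative class prototype `p_vc`,
#' additive noise `eps_i ~ N(0, noise_sd^2)` (the sum truncated at 0 so the
#' data stay non-negative) and per-sample scale `s_i = exp(N(0,
#' scale_jitter_sd^2))` shared across that sample's features within the
#' view. In magnitude mode classes share one direction and differ only by
#' scalar offsets, so angular measures cannot separate them.
#'
#' @param spec A [synthetic_spec()].
#' @return A `synthetic_dataset` list with elements `views` (list of
#'   [omics_view()]), `labels` (integer classes 1..K, named by sample),
#'   `prototypes` (per-view class-direction matrices) and `spec`.
#' @export
generate_multiomics <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) spec <- do.call(synthetic_spec, spec)
  with_seed(spec$seed, {
    counts <- allocate_classes(spec$n_samples, spec$class_proportions)
    if (any(counts < 2)) {
      stop("every class needs at least 2 samples; increase n_samples or proportions")
    }
    labels <- sample(rep.int(seq_len(spec$n_classes), counts))
    sample_ids <- sprintf("S%03d", seq_len(spec$n_samples))
    names(labels) <- sample_ids

    views <- vector("list", length(spec$views))
    prototypes <- vector("list", length(spec$views))
    names(views) <- names(prototypes) <- names(spec$views)

    for (v in seq_along(spec$views)) {
      p <- spec$views[[v]]
      proto <- make_prototypes(p, spec$n_classes, spec$signal_strength)
      # magnitude mode: one shared direction, class-specific scalar offsets
      shared <- proto[1, , drop = TRUE]
      offsets <- 1 + spec$signal_strength * (seq_len(spec$n_classes) - 1)
      scale_i <- exp(stats::rnorm(spec$n_samples, 0, spec$scale_jitter_sd))
      eps <- matrix(stats::rnorm(spec$n_samples * p, 0, spec$noise_sd),
                    spec$n_samples, p)
      base <- switch(spec$signal_mode,
        directional = proto[labels, , drop = FALSE],
        magnitude = outer(offsets[labels], shared),
        mixed = proto[labels, , drop = FALSE] * offsets[labels]
      )
      values <- scale_i * pmax(base + eps, 0)
      dimnames(values) <- list(sample_ids,
                               sprintf("%s_f%04d", names(spec$views)[v],
                                       seq_len(p)))
      view <- omics_view(values, modality = names(spec$views)[v])
      if (spec$missing_rate > 0) {
        view <- inject_missing(view, spec$missing_rate,
                               seed = spec$seed + 7919L * v)
      }
      views[[v]] <- view
      prototypes[[v]] <- proto
    }
    structure(list(views = views, labels = labels,
                   prototypes = prototypes, spec = spec),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset: %d samples, %d classes, %d views (%s)>\n",
              length(x$labels), x$spec$n_classes, length(x$views),
              paste(names(x$views), collapse = ", ")))
  invisible(x)
}

#' Set entries of a view to missing
#'
#' Marks `round(rate * n_entries)` uniformly chosen entries as `NA`, while
#' guaranteeing that no row or column loses all of its observed values.
#'
#' @param view An `omics_view`.
#' @param rate Fraction of entries to remove, in `[0, 1)`.
#' @param seed Integer seed; the mask is fully determined by it.
#' @return The view with missing entries injected.
#' @export
inject_missing <- function(view, rate, seed = 1L) {
  stopifnot_view(view)
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)")
  if (rate == 0) return(view)
  values <- view$values
  n <- nrow(values); p <- ncol(values)
  target <- round(rate * n * p)
  if (target == 0) return(view)
  with_seed(seed, {
    order_idx <- sample.int(n * p)
    row_obs <- rowSums(!is.na(values))
    col_obs <- colSums(!is.na(values))
    taken <- 0L
    for (idx in order_idx) {
      if (taken >= target) break
      i <- ((idx - 1L) %% n) + 1L
      j <- ((idx - 1L) %/% n) + 1L
      if (is.na(values[i, j])) next
      if (row_obs[i] <= 1L || col_obs[j] <= 1L) next
      values[i, j] <- NA_real_
      row_obs[i] <- row_obs[i] - 1L
      col_obs[j] <- col_obs[j] - 1L
      taken <- taken + 1L
    }
  })
  view$values <- values
  view
}

#' Write a synthetic dataset to disk
#'
#' Each view goes to `<name>.tsv` ([write_view_tsv()] dialect), labels to
#' `labels.csv` (columns `sample_id`, `class`), and the generating spec to
#' `spec.json`.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if absent).
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(dataset$views)) {
    write_view_tsv(dataset$views[[nm]], file.path(dir, paste0(nm, ".tsv")))
  }
  utils::write.csv(
    data.frame(sample_id = names(dataset$labels),
               class = unname(dataset$labels)),
    file.path(dir, "labels.csv"), row.names = FALSE, quote = FALSE)
  spec <- dataset$spec
  spec$views <- as.list(spec$views)
  jsonlite::write_json(unclass(spec), file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Directory containing the view TSVs, `labels.csv` and
#'   `spec.json`.
#' @return A `synthetic_dataset` (without prototypes).
#' @export
read_dataset <- function(dir) {
  spec_raw <- jsonlite::read_json(file.path(dir, "spec.json"),
                                  simplifyVector = TRUE)
  spec_raw$views <- unlist(spec_raw$views)
  spec <- do.call(synthetic_spec, spec_raw)
  views <- lapply(names(spec$views), function(nm) {
    read_view_tsv(file.path(dir, paste0(nm, ".tsv")), modality = nm)
  })
  names(views) <- names(spec$views)
  lab <- utils::read.csv(file.path(dir, "labels.csv"),
                         stringsAsFactors = FALSE)
  labels <- as.integer(lab$class)
  names(labels) <- lab$sample_id
  structure(list(views = views, labels = labels, prototypes = NULL,
                 spec = spec),
            class = "synthetic_dataset")
}
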