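## Per-modality preprocessing chain: log transform, variability filtering,
## KNN imputation, quantile normalization, final feature selection.
##
## Stage order (see the methods vignette): log2(1+x) -> coarse variability
## filter -> KNN imputation -> quantile normalization -> final selection.
## Quantile normalization is ill-defined with missing entries, so imputation
## runs first.

#' Log-transform a view
#'
#' Replaces every observed entry x by `log2(1 + x)`; missing entries are
#' preserved. Base 2 with a pseudocount of 1 is the genomics convention.
#'
#' @param view An `omics_view` with non-negative observed values.
#' @return The transformed view.
#' @export
log_transform <- function(view) {
  stopifnot_view(view)
  if (any(view$values < 0, na.rm = TRUE)) {
    stop("log_transform requires non-negative values")
  }
  view$values[] <- log2(1 + view$values)
  view
}

#' Quantile-normalize a view across samples
#'
#' Forces every sample's value distribution to the across-sample mean
#' order-statistic distribution while preserving within-sample ranks, so
#' feature scales become comparable across samples. Delegates to
#' [limma::normalizeQuantiles()] with samples as arrays.
#'
#' @param view A complete `omics_view` (run after imputation).
#' @return The normalized view.
#' @export
quantile_normalize <- function(view) {
  stopifnot_view(view)
  if (anyNA(view$values)) {
    stop("quantile_normalize requires a complete matrix; impute first")
  }
  normed <- t(limma::normalizeQuantiles(t(view$values)))
  dimnames(normed) <- dimnames(view$values)
  view$values <- normed
  view
}

# Indices of the n_keep features with largest SD across samples; ties go to
# the earlier feature index, and the original ordering is preserved.
top_sd_features <- function(values, n_keep) {
  sds <- apply(values, 2, stats::sd, na.rm = TRUE)
  sds[is.na(sds)] <- 0
  sort(order(-sds, seq_along(sds), method = "radix")[seq_len(n_keep)])
}

#' Keep the most variable features
#'
#' Retains exactly the `n_keep` features with largest standard deviation
#' across samples (missing entries ignored). Surviving features keep their
#' original order; ties break toward the earlier feature index.
#'
#' @param view An `omics_view`.
#' @param n_keep Number of features to keep, between 1 and `n_features`.
#' @return The filtered view.
#' @export
filter_by_variability <- function(view, n_keep) {
  stopifnot_view(view)
  p <- ncol(view$values)
  if (n_keep < 1 || n_keep > p) stop("n_keep must be in [1, n_features]")
  keep <- top_sd_features(view$values, n_keep)
  view$values <- view$values[, keep, drop = FALSE]
  view$feature_ids <- view$feature_ids[keep]
  view
}

#' Final fixed-size feature selection
#'
#' Same SD ranking as [filter_by_variability()], applied to the
#' post-imputation matrix to standardize input dimensions.
#'
#' @inheritParams filter_by_variability
#' @param n_final Number of features to retain.
#' @export
select_features <- function(view, n_final) {
  filter_by_variability(view, n_final)
}

#' K-nearest-neighbour imputation
#'
#' Fills each missing entry (i, f) with the mean of feature f over the k
#' samples nearest to i, where distance is Euclidean restricted to
#' coordinates observed in both samples. Neighbours lacking feature f fall
#' back to the next nearest; ties in distance break toward the lower sample
#' index.
#'
#' @param view An `omics_view`; every sample must have at least one
#'   observed entry.
#' @param k Number of donor neighbours (default 5, the standard choice for
#'   high-dimensional omics matrices).
#' @return The view with no missing entries.
#' @export
knn_impute <- function(view, k = 5) {
  stopifnot_view(view)
  values <- view$values
  if (!anyNA(values)) return(view)
  n <- nrow(values)
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k < n_samples")
  obs <- !is.na(values)
  if (any(rowSums(obs) == 0)) stop("every sample needs >= 1 observed entry")
  all_miss <- colSums(obs) == 0
  if (any(all_miss)) {
    stop("feature(s) missing in all samples: ",
         paste(view$feature_ids[all_miss], collapse = ", "))
  }
  filled <- values
  need <- which(rowSums(!obs) > 0)
  for (i in need) {
    d <- rep(Inf, n)
    for (j in seq_len(n)[-i]) {
      shared <- obs[i, ] & obs[j, ]
      if (any(shared)) {
        d[j] <- sqrt(sum((values[i, shared] - values[j, shared])^2))
      }
    }
    nb <- order(d, seq_len(n), method = "radix")
    nb <- nb[nb != i & is.finite(d[nb])]
    for (f in which(!obs[i, ])) {
      donors <- nb[obs[nb, f]]
      if (length(donors) == 0) {
        stop("no donor sample observes feature ", view$feature_ids[f])
      }
      donors <- donors[seq_len(min(k, length(donors)))]
      filled[i, f] <- mean(values[donors, f])
    }
  }
  view$values <- filled
  view
}

#' Run the full preprocessing chain on one view
#'
#' log2(1+x) -> coarse variability filter -> KNN imputation -> quantile
#' normalization -> final feature selection. Each stage can be toggled per
#' modality.
#'
#' @param view An `omics_view`.
#' @param n_pool Coarse pre-imputation pool size (capped at the view's
#'   width).
#' @param n_final Final feature count (capped at the pool size).
#' @param k Imputation neighbour count.
#' @param log,quantile Logical toggles for the normalization stages.
#' @return The fully preprocessed view.
#' @export
preprocess_view <- function(view, n_pool = 1000, n_final = 200, k = 5,
                            log = TRUE, quantile = TRUE) {
  stopifnot_view(view)
  if (log) view <- log_transform(view)
  view <- filter_by_variability(view, min(n_pool, ncol(view$values)))
  view <- knn_impute(view, k = k)
  if (quantile) view <- quantile_normalize(view)
  select_features(view, min(n_final, ncol(view$values)))
}
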