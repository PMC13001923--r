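#' Construct an omics view
#'
#' An `omics_view` holds one modality's samples x features matrix together
#' with aligned sample and feature identifiers. Values are non-negative
#' reals; `NA` marks entries that are missing prior to imputation.
#'
#' @param values Numeric matrix, samples in rows, features in columns.
#' @param sample_ids Character vector of unique sample identifiers
#'   (defaults to the matrix rownames).
#' @param feature_ids Character vector of unique feature identifiers
#'   (defaults to the matrix colnames).
#' @param modality Name of the omics modality (e.g. `"mrna"`).
#' @return An object of class `omics_view`.
#' @export
omics_view <- function(values, sample_ids = rownames(values),
                       feature_ids = colnames(values), modality = "omics") {
  values <- as.matrix(values)
  if (is.null(sample_ids)) {
    sample_ids <- paste0("S", seq_len(nrow(values)))
  }
  if (is.null(feature_ids)) {
    feature_ids <- paste0("F", seq_len(ncol(values)))
  }
  sample_ids <- as.character(sample_ids)
  feature_ids <- as.character(feature_ids)
  if (length(sample_ids) != nrow(values)) {
    stop("length(sample_ids) must equal nrow(values)")
  }
  if (length(feature_ids) != ncol(values)) {
    stop("length(feature_ids) must equal ncol(values)")
  }
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  if (anyDuplicated(feature_ids)) stop("feature_ids must be unique")
  if (any(values < 0, na.rm = TRUE)) {
    stop("omics_view values must be non-negative")
  }
  dimnames(values) <- list(sample_ids, feature_ids)
  structure(
    list(values = values, sample_ids = sample_ids,
         feature_ids = feature_ids, modality = modality),
    class = "omics_view"
  )
}

#' @export
print.omics_view <- function(x, ...) {
  n_miss <- sum(is.na(x$values))
  cat(sprintf("<omics_view '%s': %d samples x %d features%s>\n",
              x$modality, nrow(x$values), ncol(x$values),
              if (n_miss > 0) sprintf(", %d missing", n_miss) else ""))
  invisible(x)
}

#' @export
dim.omics_view <- function(x) dim(x$values)

stopifnot_view <- function(view) {
  if (!inherits(view, "omics_view")) stop("expected an omics_view")
  invisible(view)
}

#' Write an omics view to TSV
#'
#' The file has a header row of feature identifiers; the first column,
#' named `sample_id`, carries the sample identifiers. Missing entries are
#' written as empty fields.
#'
#' @param view An `omics_view`.
#' @param path Output file path.
#' @export
write_view_tsv <- function(view, path) {
  stopifnot_view(view)
  df <- data.frame(sample_id = view$sample_ids, view$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read an omics view from TSV
#'
#' @param path File written by [write_view_tsv()].
#' @param modality Modality name to attach.
#' @return An `omics_view`; empty fields become `NA`.
#' @export
read_view_tsv <- function(path, modality = "omics") {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = "")
  values <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  omics_view(values, sample_ids = df[[1]],
             feature_ids = colnames(df)[-1], modality = modality)
}
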