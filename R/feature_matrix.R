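#' Samples-by-features matrix
#'
#' Numeric matrix of samples (rows) by features (columns: bucket centres or
#' metabolite names) with a flag recording whether total-area normalization
#' has been applied.
#'
#' @param values Numeric matrix, samples x features.
#' @param sample_ids Character vector of row labels (unique).
#' @param feature_ids Character vector of column labels (unique).
#' @param normalized Logical flag.
#' @return An object of class `feature_matrix` (a matrix with dimnames and a
#'   `normalized` attribute).
#' @export
feature_matrix <- function(values, sample_ids = rownames(values),
                           feature_ids = colnames(values),
                           normalized = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids) || is.null(feature_ids)) {
    stop("sample_ids and feature_ids are required")
  }
  sample_ids <- as.character(sample_ids)
  feature_ids <- as.character(feature_ids)
  if (length(sample_ids) != nrow(values)) stop("sample_ids length != nrow")
  if (length(feature_ids) != ncol(values)) stop("feature_ids length != ncol")
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (anyDuplicated(feature_ids)) stop("duplicate feature ids")
  if (anyNA(values) || any(!is.finite(values))) stop("non-finite feature values")
  dimnames(values) <- list(sample_ids, feature_ids)
  structure(values, normalized = isTRUE(normalized), class = c("feature_matrix", "matrix"))
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d samples x %d features%s\n",
              nrow(x), ncol(x),
              if (isTRUE(attr(x, "normalized"))) " (total-area normalized)" else ""))
  invisible(x)
}

#' @rdname feature_matrix
#' @param fm A `feature_matrix`.
#' @export
is_normalized <- function(fm) isTRUE(attr(fm, "normalized"))

fm_values <- function(fm) {
  v <- unclass(fm)
  attr(v, "normalized") <- NULL
  v
}

#' Total-area normalization
#'
#' Scales every sample row so that its sum equals
#' `cfg$normalization_total`, removing dilution differences between
#' samples. Idempotent; invariant to a global intensity rescaling of any
#' one sample.
#'
#' @param fm A [feature_matrix()].
#' @param cfg A [preprocess_config()]; only `normalization_total` is used.
#' @return The normalized `feature_matrix`.
#' @export
normalize_total_area <- function(fm, cfg = preprocess_config()) {
  stopifnot(inherits(fm, "feature_matrix"))
  v <- fm_values(fm)
  totals <- rowSums(v)
  bad <- totals <= 0
  if (any(bad)) {
    stop("non-positive total area for sample(s): ",
         paste(rownames(v)[bad], collapse = ", "))
  }
  feature_matrix(v * (cfg$normalization_total / totals),
                 rownames(v), colnames(v), normalized = TRUE)
}

#' Read / write a feature matrix as CSV
#'
#' The CSV has a header of feature ids and a leading `sample_id` column.
#'
#' @param path File path.
#' @param normalized Flag recorded on the object after reading.
#' @return `read_feature_matrix` returns a [feature_matrix()];
#'   `write_feature_matrix` returns `path` invisibly.
#' @export
read_feature_matrix <- function(path, normalized = FALSE) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop("feature CSV needs a sample_id column")
  ids <- as.character(df$sample_id)
  v <- as.matrix(df[setdiff(names(df), "sample_id")])
  feature_matrix(v, ids, colnames(v), normalized = normalized)
}

#' @rdname read_feature_matrix
#' @param fm A [feature_matrix()].
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  df <- data.frame(sample_id = rownames(fm), fm_values(fm),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
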