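#' Sample metadata for the paired cohort design
#'
#' Validates a sample-to-subject-to-group mapping. Groups are the three
#' study arms: `B` (periodontitis at baseline), `AT` (same patients after
#' non-surgical therapy) and `HI` (independent healthy individuals). Every
#' subject with an `AT` sample must also have a `B` sample so that paired
#' analyses are well defined.
#'
#' @param df Data frame with columns `sample_id`, `subject_id`, `group`.
#' @return The validated data frame, class `sample_metadata`, with `group`
#'   a factor with levels `B`, `AT`, `HI` (unused levels kept).
#' @export
sample_metadata <- function(df) {
  req <- c("sample_id", "subject_id", "group")
  if (!all(req %in% names(df))) {
    stop("metadata needs columns: ", paste(req, collapse = ", "))
  }
  if (nrow(df) == 0L) stop("metadata is empty")
  df$sample_id <- as.character(df$sample_id)
  df$subject_id <- as.character(df$subject_id)
  grp <- as.character(df$group)
  allowed <- c("B", "AT", "HI")
  bad <- setdiff(unique(grp), allowed)
  if (length(bad) > 0L) {
    stop("unknown group token(s) ", paste(bad, collapse = ", "),
         "; allowed: ", paste(allowed, collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicated sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  # one sample per subject x group
  if (anyDuplicated(paste(df$subject_id, grp))) {
    stop("a subject has more than one sample in the same group")
  }
  at_subj <- unique(df$subject_id[grp == "AT"])
  b_subj <- unique(df$subject_id[grp == "B"])
  orphan <- setdiff(at_subj, b_subj)
  if (length(orphan) > 0L) {
    stop("AT sample(s) without a baseline B sample for subject(s): ",
         paste(orphan, collapse = ", "))
  }
  df$group <- factor(grp, levels = allowed)
  df <- df[, req]
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' Read / write sample metadata CSV
#'
#' The CSV has columns `sample_id`, `subject_id`, `group` with group tokens
#' in `{B, AT, HI}`. `read_metadata(write_metadata(x))` round-trips exactly.
#'
#' @param path File path.
#' @return `read_metadata` returns a [sample_metadata()] data frame.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("no such metadata file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  sample_metadata(df)
}

#' @rdname read_metadata
#' @param md A [sample_metadata()] data frame.
#' @export
write_metadata <- function(md, path) {
  stopifnot(inherits(md, "sample_metadata"))
  out <- data.frame(sample_id = md$sample_id, subject_id = md$subject_id,
                    group = as.character(md$group), stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Baseline/after-treatment pairing map
#'
#' @param md A [sample_metadata()] data frame.
#' @return Data frame with one row per paired subject: `subject_id`,
#'   `sample_B`, `sample_AT`.
#' @export
pairing_map <- function(md) {
  stopifnot(inherits(md, "sample_metadata"))
  b <- md[md$group == "B", c("subject_id", "sample_id")]
  at <- md[md$group == "AT", c("subject_id", "sample_id")]
  m <- merge(b, at, by = "subject_id", suffixes = c("_B", "_AT"))
  data.frame(subject_id = m$subject_id, sample_B = m$sample_id_B,
             sample_AT = m$sample_id_AT, stringsAsFactors = FALSE)
}

# align metadata rows to a feature matrix's sample order
align_metadata <- function(fm, md) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(md, "sample_metadata"))
  missing <- setdiff(rownames(fm), md$sample_id)
  if (length(missing) > 0L) {
    stop("samples absent from metadata: ", paste(missing, collapse = ", "))
  }
  md[match(rownames(fm), md$sample_id), , drop = FALSE]
}
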