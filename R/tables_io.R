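#' Read a feature count table
#'
#' Reads a tab-separated features-x-samples table of non-negative integer read
#' counts. The header row holds sample IDs; the first column holds feature IDs
#' (the first header cell may be `#FeatureID`). Lines starting with `#` before
#' the header are treated as comments. Orientation is fixed as features in
#' rows; a transposed file is never auto-detected (pass `transpose = TRUE`
#' explicitly if the file has samples in rows).
#'
#' @param path Path to a TSV file.
#' @param transpose If `TRUE`, the file is read samples-x-features and
#'   transposed. Default `FALSE`.
#' @return A `count_table`: an integer matrix (features x samples) with
#'   feature IDs as rownames and sample IDs as colnames.
#' @export
read_count_table <- function(path, transpose = FALSE) {
  if (!file.exists(path)) stop("count table file not found: ", path)
  lines <- readLines(path)
  # leading comment lines: "#..." that are not the "#FeatureID<TAB>..." header
  is_hdr <- function(l) startsWith(l, "#FeatureID\t") || !startsWith(l, "#")
  first <- which(vapply(lines, is_hdr, logical(1)))[1]
  if (is.na(first)) stop("count table has no header row: ", path)
  con <- textConnection(lines[first:length(lines)])
  on.exit(close(con))
  df <- read.delim(con, header = TRUE, check.names = FALSE,
                   colClasses = "character", comment.char = "")
  if (ncol(df) < 2) stop("count table needs a feature-ID column and at least one sample: ", path)
  feature_ids <- df[[1]]
  sample_ids <- colnames(df)[-1]
  mat <- suppressWarnings(
    vapply(df[-1], function(col) as.numeric(col), numeric(nrow(df)))
  )
  mat <- matrix(mat, nrow = nrow(df), dimnames = list(feature_ids, sample_ids))
  if (transpose) mat <- t(mat)
  as_count_table(mat)
}

#' Validate a matrix as a count table
#'
#' @param mat Numeric matrix of counts, features in rows, samples in columns,
#'   with both dimnames set.
#' @return The validated matrix with class `count_table`.
#' @export
as_count_table <- function(mat) {
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("count table requires feature IDs (rownames) and sample IDs (colnames)")
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric or missing count at feature '%s', sample '%s'",
                 rownames(mat)[bad[1]], colnames(mat)[bad[2]]))
  }
  if (any(mat < 0)) {
    bad <- which(mat < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at feature '%s', sample '%s'",
                 rownames(mat)[bad[1]], colnames(mat)[bad[2]]))
  }
  if (any(mat != round(mat))) {
    bad <- which(mat != round(mat), arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer count at feature '%s', sample '%s'",
                 rownames(mat)[bad[1]], colnames(mat)[bad[2]]))
  }
  dup <- unique(rownames(mat)[duplicated(rownames(mat))])
  if (length(dup)) stop("duplicated feature ID(s): ", paste(dup, collapse = ", "))
  dup <- unique(colnames(mat)[duplicated(colnames(mat))])
  if (length(dup)) stop("duplicated sample ID(s): ", paste(dup, collapse = ", "))
  empty <- colnames(mat)[colSums(mat) == 0]
  if (length(empty)) stop("sample(s) with zero total counts: ", paste(empty, collapse = ", "))
  structure(mat, class = c("count_table", class(matrix())))
}

#' @export
`[.count_table` <- function(x, i, j, ..., drop = FALSE) {
  out <- unclass(x)[i, j, ..., drop = drop]
  if (is.matrix(out)) class(out) <- class(x)
  out
}

#' Write a count table to TSV
#'
#' Inverse of [read_count_table()]: integer tables round-trip bit-identically.
#'
#' @param table A `count_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path) {
  df <- data.frame("#FeatureID" = rownames(table), check.names = FALSE)
  df <- cbind(df, as.data.frame(unclass(table), check.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or validate sample metadata
#'
#' Metadata is a TSV with columns `sample_id`, `group` (one of `disturbed`,
#' `control`), `assay` (one of `taxonomic`, `functional`) and a free-text
#' `label`; extra columns (e.g. recorded child seeds from the simulator) are
#' kept. A sample may appear once per assay.
#'
#' @param path Path to a metadata TSV.
#' @return A data.frame of class `sample_metadata`.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  as_sample_metadata(read.delim(path, header = TRUE, check.names = FALSE))
}

#' @param df Data frame with the columns described above.
#' @rdname read_sample_metadata
#' @export
as_sample_metadata <- function(df) {
  need <- c("sample_id", "group", "assay")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  if (!"label" %in% colnames(df)) df$label <- ""
  if (any(df$sample_id == "" | is.na(df$sample_id))) stop("metadata has empty sample_id")
  bad <- setdiff(unique(df$group), c("disturbed", "control"))
  if (length(bad)) stop("unknown group value(s): ", paste(bad, collapse = ", "),
                        " (expected 'disturbed' or 'control')")
  bad <- setdiff(unique(df$assay), c("taxonomic", "functional"))
  if (length(bad)) stop("unknown assay value(s): ", paste(bad, collapse = ", "),
                        " (expected 'taxonomic' or 'functional')")
  dup <- df$sample_id[duplicated(df[c("sample_id", "assay")])]
  if (length(dup)) stop("duplicated (sample_id, assay) metadata row(s): ",
                        paste(unique(dup), collapse = ", "))
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' Write sample metadata to TSV
#' @param metadata A `sample_metadata` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(metadata, path) {
  write.table(as.data.frame(metadata), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Extract one sample's abundance vector from a count table
#'
#' Zero-count features are dropped (all estimators operate on observed
#' features only).
#'
#' @param table A `count_table`.
#' @param sample_id A sample ID present in the table.
#' @return An [abundance_vector()].
#' @export
column_vector <- function(table, sample_id) {
  stopifnot(inherits(table, "count_table"))
  if (!sample_id %in% colnames(table))
    stop("unknown sample ID: ", sample_id)
  x <- unclass(table)[, sample_id]
  abundance_vector(x, sample_id = sample_id)
}

#' Partition a table's samples into disturbed and control groups
#'
#' Keeps only samples whose metadata rows match `assay`, and checks that every
#' such sample in the table has a metadata row.
#'
#' @param table A `count_table`.
#' @param metadata A `sample_metadata` data.frame.
#' @param assay `"taxonomic"` or `"functional"`.
#' @return A list with elements `disturbed` and `control`, each a list of
#'   [abundance_vector()]s (exhaustive and disjoint for the requested assay).
#' @export
split_groups <- function(table, metadata, assay = c("taxonomic", "functional")) {
  assay <- match.arg(assay)
  stopifnot(inherits(table, "count_table"))
  metadata <- as_sample_metadata(as.data.frame(metadata))
  md <- metadata[metadata$assay == assay, , drop = FALSE]
  wanted <- intersect(colnames(table), md$sample_id)
  missing <- setdiff(colnames(table), metadata$sample_id)
  if (length(missing))
    stop("sample(s) without metadata: ", paste(missing, collapse = ", "))
  if (!length(wanted))
    stop("no samples in the table match assay '", assay, "'")
  grp <- md$group[match(wanted, md$sample_id)]
  vecs <- lapply(wanted, function(s) column_vector(table, s))
  list(disturbed = vecs[grp == "disturbed"], control = vecs[grp == "control"])
}
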