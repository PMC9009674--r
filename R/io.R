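#' Read a mutation-type count matrix
#'
#' Tab-delimited text: first column = mutation-type labels, header row of
#' sample IDs, remaining columns = non-negative integer counts.  Bare
#' SBS96 labels in the `ACA>AAA` dialect are normalized to the bracket form
#' `A[C>A]A`.
#'
#' @param path File path.
#' @return Validated count matrix with dimnames.
#' @export
read_count_matrix <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_double(),
    readr::col_character()), progress = FALSE)
  if (ncol(df) < 3L)
    stop("expected a label column plus at least 2 sample columns in ", path,
         call. = FALSE)
  labels <- normalize_type_labels(df[[1L]], path)
  V <- as.matrix(df[, -1L, drop = FALSE])
  if (anyNA(V))
    stop("non-numeric or missing count in ", path, call. = FALSE)
  if (any(V < 0)) {
    bad <- which(V < 0, arr.ind = TRUE)[1L, ]
    stop("negative count in ", path, " at data row ", bad[1L],
         ", sample '", colnames(V)[bad[2L]], "'", call. = FALSE)
  }
  if (any(abs(V - round(V)) > 1e-8)) {
    bad <- which(abs(V - round(V)) > 1e-8, arr.ind = TRUE)[1L, ]
    stop("non-integer count in ", path, " at data row ", bad[1L],
         ", sample '", colnames(V)[bad[2L]], "'", call. = FALSE)
  }
  rownames(V) <- labels
  validate_counts(V)
  V
}

# Accept "A[C>A]A" as-is; rewrite "ACA>AAA" to bracket form; otherwise pass
# labels through untouched (non-SBS96 catalogs such as INDEL-83 keep their
# own dialect).
normalize_type_labels <- function(labels, path) {
  labels <- as.character(labels)
  if (anyDuplicated(labels))
    stop("duplicated mutation-type labels in ", path, call. = FALSE)
  alt <- grepl("^[ACGT]{3}>[ACGT]{3}$", labels)
  if (any(alt)) {
    from <- labels[alt]
    labels[alt] <- paste0(
      substr(from, 1, 1), "[", substr(from, 2, 2), ">",
      substr(from, 6, 6), "]", substr(from, 3, 3))
  }
  labels
}

#' Write a count matrix, profile matrix or activity matrix
#'
#' Tab-delimited with the row labels in a leading column, the inverse of
#' [read_count_matrix()].
#'
#' @param x Matrix with dimnames.
#' @param path Output path.
#' @param label_column Header for the label column. Default
#'   `"MutationType"`.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(x, path, label_column = "MutationType") {
  df <- tibble::as_tibble(x, rownames = label_column)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a reference signature catalog
#'
#' COSMIC-style tab-delimited table: mutation-type label column plus one
#' column per reference signature.  Columns are validated non-negative and
#' normalized to unit sums.
#'
#' @param path File path.
#' @return P x S numeric matrix, unit column sums.
#' @export
read_catalog <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_double(),
    readr::col_character()), progress = FALSE)
  labels <- normalize_type_labels(df[[1L]], path)
  W <- as.matrix(df[, -1L, drop = FALSE])
  if (anyNA(W) || any(W < 0))
    stop("catalog in ", path, " has missing or negative entries",
         call. = FALSE)
  s <- colSums(W)
  if (any(s == 0))
    stop("catalog in ", path, " has an all-zero signature column",
         call. = FALSE)
  rownames(W) <- labels
  sweep(W, 2L, s, "/")
}
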