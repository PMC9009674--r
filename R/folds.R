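#' Balanced cell-wise hold-out masks for K-fold cross-validation
#'
#' Builds the K deterministic hold-out patterns used for cross-validating a
#' count-matrix factorization.  In fold `k`, sample `n` has the mutation
#' types `p` with `(p - 1) mod K == (n + k - 2) mod K` held out, i.e. every
#' K-th type starting from a base offset that rotates across samples and
#' folds.  Each sample therefore loses `floor(P/K)` or `ceiling(P/K)` types
#' per fold ("balanced separation"), each cell is held out in exactly one
#' fold, and the pattern never depends on the observed counts — the
#' held-out cells are missing completely at random by construction.
#'
#' @param P Number of mutation types (rows).
#' @param N Number of samples (columns).
#' @param K Number of folds, `2 <= K <= P`. Default 10.
#' @return List of K logical P x N matrices (`TRUE` = held out in this
#'   fold), each with attributes `fold` and `K`.
#' @export
#' @examples
#' m <- balanced_folds(96, 3, K = 10)
#' which(m[[1]][, 1]) # types 1, 11, ..., 91 of the first sample
balanced_folds <- function(P, N, K = 10L) {
  P <- as.integer(P); N <- as.integer(N); K <- as.integer(K)
  if (K < 2L || K > P)
    stop("K must satisfy 2 <= K <= P (got K = ", K, ", P = ", P, ")",
         call. = FALSE)
  row_res <- (seq_len(P) - 1L) %% K
  lapply(seq_len(K), function(k) {
    col_res <- (seq_len(N) + k - 2L) %% K
    m <- outer(row_res, col_res, "==")
    attr(m, "fold") <- k
    attr(m, "K") <- K
    m
  })
}

#' Tabulate a hold-out scheme for audit
#'
#' @param folds List of masks from [balanced_folds()].
#' @param row_labels,col_labels Optional labels; defaults to indices.
#' @return Tibble with one row per cell: `sample`, `mutation_type`, `fold`.
#' @export
fold_table <- function(folds, row_labels = NULL, col_labels = NULL) {
  P <- nrow(folds[[1L]]); N <- ncol(folds[[1L]])
  if (is.null(row_labels)) row_labels <- as.character(seq_len(P))
  if (is.null(col_labels)) col_labels <- as.character(seq_len(N))
  fold_of <- matrix(0L, P, N)
  for (k in seq_along(folds)) fold_of[folds[[k]]] <- k
  tibble::tibble(
    sample = rep(col_labels, each = P),
    mutation_type = rep(row_labels, times = N),
    fold = as.integer(fold_of)
  )
}

#' Three-way train/validation/test cell split
#'
#' Splits the P x N cell grid into disjoint training, validation and test
#' subsets using whole balanced folds, e.g. fractions 0.9/0.05/0.05 become
#' 18 + 1 + 1 of K = 20 folds.  The last fold(s) serve as the test set and
#' the fold(s) before them as validation.
#'
#' @param P,N Matrix dimensions.
#' @param fractions Length-3 numeric `(train, validation, test)` summing to
#'   1; each must be a whole multiple of `1/K` for `K = round(1/min(fractions))`.
#' @return List of three logical P x N matrices: `train`, `validation`,
#'   `test`, which partition the cell grid.
#' @export
three_way_split <- function(P, N, fractions = c(0.9, 0.05, 0.05)) {
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must be three numbers summing to 1", call. = FALSE)
  K <- as.integer(round(1 / min(fractions)))
  counts <- fractions * K
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop("fractions are not whole multiples of 1/", K,
         "; nearest representable split is ",
         paste(round(counts) / K, collapse = "/"), call. = FALSE)
  }
  counts <- as.integer(round(counts))
  folds <- balanced_folds(P, N, K)
  join <- function(idx) {
    m <- Reduce(`|`, folds[idx])
    attributes(m) <- attributes(m)["dim"]
    m
  }
  n_test <- counts[3L]; n_val <- counts[2L]
  test_idx <- seq.int(K - n_test + 1L, K)
  val_idx <- seq.int(K - n_test - n_val + 1L, K - n_test)
  list(train = join(seq_len(K - n_val - n_test)),
       validation = join(val_idx),
       test = join(test_idx))
}
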