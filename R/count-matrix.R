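#' Canonical SBS96 mutation-type labels
#'
#' The 96 single-base-substitution categories in substitution-major order:
#' the six pyrimidine-centered substitution classes (C>A, C>G, C>T, T>A,
#' T>C, T>G), and within each class the 16 flanking contexts in alphabetical
#' order (`A[C>A]A`, `A[C>A]C`, ..., `T[C>A]T`).
#'
#' @return Character vector of length 96.
#' @export
#' @examples
#' head(sbs96_types())
sbs96_types <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  ctx <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    as.vector(t(outer(ctx, ctx, function(l, r) paste0(l, "[", s, "]", r))))
  }))
}

#' Validate a mutation-type count matrix
#'
#' Checks the invariants of a P x N count matrix: non-negative entries,
#' at least two mutation types and two samples, unique row and column
#' labels.  Integrality is enforced for count data but can be relaxed for
#' real-valued model means (e.g. noiseless low-rank matrices).
#'
#' @param V Numeric matrix, mutation types in rows, samples in columns.
#' @param integer Require integral entries? Default `TRUE`.
#' @param arg Name used in error messages.
#' @return `V`, invisibly, with labels filled in if absent.
#' @export
validate_counts <- function(V, integer = TRUE, arg = "V") {
  if (!is.matrix(V) || !is.numeric(V))
    stop(arg, " must be a numeric matrix", call. = FALSE)
  if (nrow(V) < 2L || ncol(V) < 2L)
    stop(arg, " must have at least 2 mutation types and 2 samples", call. = FALSE)
  if (anyNA(V) || any(!is.finite(V)))
    stop(arg, " contains missing or non-finite entries", call. = FALSE)
  if (any(V < 0)) {
    bad <- which(V < 0, arr.ind = TRUE)[1L, ]
    stop(arg, " has a negative entry at row ", bad[1L], ", column ", bad[2L],
         call. = FALSE)
  }
  if (integer && any(abs(V - round(V)) > 1e-8))
    stop(arg, " must contain integer counts", call. = FALSE)
  if (is.null(rownames(V))) rownames(V) <- paste0("type", seq_len(nrow(V)))
  if (is.null(colnames(V))) colnames(V) <- paste0("sample", seq_len(ncol(V)))
  if (anyDuplicated(rownames(V)))
    stop(arg, " has duplicated mutation-type labels", call. = FALSE)
  if (anyDuplicated(colnames(V)))
    stop(arg, " has duplicated sample labels", call. = FALSE)
  invisible(V)
}

#' Exclude hypermutator samples by mutation burden
#'
#' Drops every sample whose total mutation count per megabase strictly
#' exceeds `threshold_per_mb`.  The conventional cutoff for whole-genome
#' human tumors is 10 mutations/Mb over a ~3000 Mb genome; hypermutators
#' dominate the factorization objective and can mask signatures carried by
#' the rest of the cohort.
#'
#' @param V Count matrix (types x samples).
#' @param genome_size_mb Genome size in megabases used to convert counts to
#'   a per-Mb burden. Default 3000 (human whole genome).
#' @param threshold_per_mb Exclusion threshold in mutations/Mb. Default 10.
#' @return The filtered matrix. Dropped sample IDs are attached as
#'   `attr(, "dropped")` and reported via a message.
#' @export
#' @examples
#' V <- cbind(low = c(10, 20), high = c(2e5, 2e5))
#' rownames(V) <- c("t1", "t2")
#' filter_hypermutators(V, genome_size_mb = 30)
filter_hypermutators <- function(V, genome_size_mb = 3000, threshold_per_mb = 10) {
  stopifnot(is.numeric(genome_size_mb), genome_size_mb > 0,
            is.numeric(threshold_per_mb), threshold_per_mb > 0)
  if (is.null(colnames(V))) colnames(V) <- paste0("sample", seq_len(ncol(V)))
  burden <- colSums(V) / genome_size_mb
  drop <- burden > threshold_per_mb
  if (all(drop))
    stop("all samples exceed ", threshold_per_mb,
         " mutations/Mb; nothing left to analyze", call. = FALSE)
  if (any(drop))
    message("excluding ", sum(drop), " hypermutator sample(s): ",
            paste(colnames(V)[drop], collapse = ", "))
  out <- V[, !drop, drop = FALSE]
  attr(out, "dropped") <- colnames(V)[drop]
  out
}

#' Generalized Kullback-Leibler divergence
#'
#' \eqn{D_{KL}(V \| M) = \sum v \log(v/m) + m - v} over a cell subset, with
#' the convention \eqn{0 \log 0 = 0}.  Model means are floored at 1e-12 so a
#' degenerate iterate cannot produce an infinite divergence.  Minimizing
#' this divergence in `M = W H` is equivalent to Poisson maximum likelihood.
#'
#' @param V Observed matrix (non-negative).
#' @param M Model-mean matrix, same shape.
#' @param cells Optional cell subset: a logical matrix of the same shape or
#'   a vector of linear cell indices. Default: all cells.
#' @return Non-negative scalar; 0 iff `V == M` on every selected cell.
#' @export
#' @examples
#' kl_divergence(matrix(2), matrix(1)) # 2*log(2) - 1
kl_divergence <- function(V, M, cells = NULL) {
  if (!is.matrix(V)) V <- as.matrix(V)
  if (!is.matrix(M)) M <- as.matrix(M)
  if (!all(dim(V) == dim(M)))
    stop("V and M must have identical dimensions", call. = FALSE)
  if (any(V < 0)) stop("V has negative entries", call. = FALSE)
  idx <- cells_to_index(cells, dim(V))
  .kl_cells_cpp(V, M, idx - 1L, is.null(idx))
}

# Normalize a cell-subset argument to 1-based linear indices (NULL = all).
cells_to_index <- function(cells, dims) {
  if (is.null(cells)) return(NULL)
  if (is.logical(cells)) {
    if (!all(dim(cells) == dims))
      stop("logical cell mask must match the matrix dimensions", call. = FALSE)
    return(which(cells))
  }
  idx <- as.integer(cells)
  if (length(idx) && (min(idx) < 1L || max(idx) > prod(dims)))
    stop("cell indices out of range", call. = FALSE)
  idx
}

#' Observed-data log-likelihood of a Poisson NMF fit
#'
#' Returns \eqn{-D_{KL}(V \| WH)} over the observed cells.  The Poisson
#' log-factorial constant is dropped, so only differences and orderings of
#' this value are meaningful (the quantity maximized over multistarts and
#' monitored for convergence).
#'
#' @param V Count matrix.
#' @param W Profile matrix (P x r).
#' @param H Activity matrix (r x N).
#' @param observed Cell subset treated as observed (logical matrix or linear
#'   indices); default all cells.
#' @return Scalar, `<= 0` in general, `0` iff `W %*% H` reproduces `V`
#'   exactly on the observed cells.
#' @export
observed_loglik <- function(V, W, H, observed = NULL) {
  -kl_divergence(V, W %*% H, cells = observed)
}

#' Rescale a factorization so profile columns sum to one
#'
#' Signature profiles are only identified up to a positive diagonal rescaling
#' between `W` and `H`; the convention is unit column sums for `W`, with the
#' compensating scale moved into the activities so `W %*% H` is unchanged.
#'
#' @param W Profile matrix (P x r), no all-zero column.
#' @param H Activity matrix (r x N).
#' @return List with elements `W` (unit column sums) and `H` (rescaled).
#' @export
normalize_factorization <- function(W, H) {
  if (nrow(H) != ncol(W))
    stop("H must have one row per column of W", call. = FALSE)
  s <- colSums(W)
  if (any(s == 0)) {
    stop("signature column(s) ", paste(which(s == 0), collapse = ", "),
         " are all zero; the factorization is degenerate", call. = FALSE)
  }
  list(W = sweep(W, 2L, s, "/"), H = H * s)
}

#' Cosine similarity between two non-negative profiles
#'
#' \eqn{u \cdot v / (\|u\| \|v\|)}; lies in \[0, 1\] for non-negative
#' vectors and is invariant to positive rescaling of either argument.
#' A value of one denotes a perfect match.
#'
#' @param u,v Non-negative numeric vectors of equal length.
#' @return Scalar in \[0, 1\].
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) stop("profiles differ in length", call. = FALSE)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    stop("cosine similarity is undefined for a zero vector", call. = FALSE)
  sum(u * v) / (nu * nv)
}
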