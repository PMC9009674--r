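#' Median imputation of held-out cells
#'
#' Initial completion of the count matrix before the ECM iterations: every
#' held-out cell is replaced by the median of the observed (training) cells
#' in its row, so the starting point never reads validation values.
#'
#' @param V Count matrix.
#' @param mask Logical matrix (`TRUE` = held out) or `NULL` for none.
#' @return Completed numeric matrix.
#' @export
init_impute <- function(V, mask = NULL) {
  if (is.null(mask) || !any(mask)) return(V)
  if (!all(dim(mask) == dim(V)))
    stop("mask must match the matrix dimensions", call. = FALSE)
  V0 <- V
  for (p in seq_len(nrow(V))) {
    held <- mask[p, ]
    if (!any(held)) next
    if (all(held))
      stop("row ", p, " has no observed cells; cannot initialize", call. = FALSE)
    V0[p, held] <- stats::median(V[p, !held])
  }
  V0
}

#' Random starting point for the ECM iterations
#'
#' Draws `W0` with i.i.d. uniform(0,1) entries normalized to unit column
#' sums, and `H0` with i.i.d. uniform(0,1) entries rescaled per sample so
#' its column totals equal those of the completed matrix `V0` (hence
#' `colSums(W0 %*% H0) == colSums(V0)` exactly, which puts the initial
#' model means on the right scale).
#'
#' @param P,N Matrix dimensions.
#' @param r Rank (number of signatures).
#' @param seed Integer seed; the same seed gives a bit-identical start.
#' @param V0 Completed matrix whose column totals set the activity scale.
#' @return List with strictly positive `W` (P x r) and `H` (r x N).
#' @export
random_init <- function(P, N, r, seed, V0) {
  withr::with_seed(as.integer(seed), {
    W0 <- matrix(runif(P * r), P, r)
    W0 <- sweep(W0, 2L, colSums(W0), "/")
    H0 <- matrix(runif(r * N), r, N)
    scale <- colSums(V0) / colSums(H0)
    H0 <- sweep(H0, 2L, pmax(scale, 1e-12), "*")
    list(W = W0, H = H0)
  })
}

#' E-step: impute held-out cells with the current model mean
#'
#' Observed cells are copied from `V`; each held-out cell `(p, n)` is set
#' to \eqn{\sum_j w_{pj} h_{jn}}, its conditional expectation under the
#' current Poisson model.
#'
#' @inheritParams init_impute
#' @param W,H Current factors.
#' @return Completed matrix `V*`.
#' @export
e_step <- function(V, mask, W, H) {
  if (is.null(mask) || !any(mask)) return(V)
  Vstar <- V
  M <- W %*% H
  Vstar[mask] <- M[mask]
  Vstar
}

#' One conditional-maximization pass (CM1 then CM2)
#'
#' Applies one full pass of the generalized-KL multiplicative updates to the
#' completed matrix: first the profile update (`W` given `H`), then the
#' activity update (`H` given the already-updated `W`).  Each pass cannot
#' increase \eqn{D_{KL}(V^* \| WH)}.  Model means and denominators are
#' floored at 1e-12.
#'
#' @param Vstar Completed (imputed) matrix.
#' @param W,H Current factors, strictly positive.
#' @return List with updated `W` and `H`.
#' @export
cm_update <- function(Vstar, W, H) {
  M <- pmax(W %*% H, 1e-12)
  W <- W * ((Vstar / M) %*% t(H))
  W <- sweep(W, 2L, pmax(rowSums(H), 1e-12), "/")
  M <- pmax(W %*% H, 1e-12)
  H <- H * (t(W) %*% (Vstar / M))
  H <- sweep(H, 1L, pmax(colSums(W), 1e-12), "/")
  list(W = W, H = H)
}

#' Fit the Poisson NMF with held-out cells by ECM
#'
#' Runs the full expectation/conditional-maximization algorithm from one
#' random start: median imputation of held-out cells, a seeded random
#' `(W0, H0)`, then alternating E-step imputation and multiplicative CM
#' updates until the relative change of the observed-data log-likelihood
#' falls below `tol` or `max_iterations` is reached.  The observed-data
#' log-likelihood is non-decreasing along the iterations (standard EM
#' ascent; held-out cells never contribute to it).
#'
#' @param V Count matrix (types x samples); non-negative, real-valued
#'   matrices are accepted (e.g. noiseless model means).
#' @param mask Logical hold-out matrix or `NULL` (fit on all cells; then the
#'   algorithm is exactly classical KL-NMF by multiplicative updates).
#' @param r Rank (number of signatures), `>= 1`.
#' @param seed Integer seed for the random start.
#' @param tol Convergence tolerance on
#'   `|l_t - l_{t-1}| / (|l_{t-1}| + 1)`. Default 1e-5.
#' @param max_iterations Iteration cap. Default 2000.
#' @return An `ecm_fit`: list with `W`, `H`, `observed_loglik`,
#'   `n_iterations`, `converged`, `loglik_trace`, `seed`, `rank`.
#' @export
fit_ecm <- function(V, mask = NULL, r, seed = 1L, tol = 1e-5,
                    max_iterations = 2000L) {
  V <- validate_counts(V, integer = FALSE)
  r <- as.integer(r)
  stopifnot(r >= 1L, tol >= 0)
  V0 <- init_impute(V, mask)
  init <- random_init(nrow(V), ncol(V), r, seed, V0)
  .fit_ecm_from(V, mask, init$W, init$H, r, seed, tol, max_iterations)
}

# Core fit from explicit starting factors (shared by fit_ecm/fit_multistart
# so multistart computes the median imputation once).
.fit_ecm_from <- function(V, mask, W0, H0, r, seed, tol, max_iterations) {
  held <- if (is.null(mask)) integer(0) else which(mask)
  res <- .ecm_fit_cpp(V, held - 1L, W0, H0, tol, as.integer(max_iterations))
  if (isTRUE(res$failed))
    stop("ECM produced a non-finite likelihood at iteration ",
         res$n_iterations, " (seed ", seed, ", rank ", r, ")", call. = FALSE)
  dimnames(res$W) <- list(rownames(V), NULL)
  dimnames(res$H) <- list(NULL, colnames(V))
  structure(
    list(W = res$W, H = res$H,
         observed_loglik = res$observed_loglik,
         n_iterations = res$n_iterations,
         converged = res$converged,
         loglik_trace = as.numeric(res$loglik_trace),
         seed = as.integer(seed), rank = r),
    class = "ecm_fit")
}

#' @export
print.ecm_fit <- function(x, ...) {
  cat("Poisson NMF ECM fit: rank", x$rank,
      "| observed log-lik", format(x$observed_loglik, digits = 8),
      "|", x$n_iterations, "iterations",
      if (x$converged) "(converged)" else "(not converged)", "\n")
  invisible(x)
}

#' @export
glance.ecm_fit <- function(x, ...) {
  tibble::tibble(rank = x$rank, observed_loglik = x$observed_loglik,
                 n_iterations = x$n_iterations, converged = x$converged,
                 seed = x$seed)
}

# Deterministic per-start seed from (master_seed, rank, fold, start); keeps
# multistart results independent of execution order and worker count.
derive_seed <- function(master_seed, rank, fold, start) {
  s <- (as.numeric(master_seed) %% 1000003) * 1009 +
    as.numeric(rank) * 262147 + as.numeric(fold) * 20011 +
    as.numeric(start) * 127
  as.integer(s %% 2147483647) + 1L
}

#' Multistart ECM fit
#'
#' Runs [fit_ecm()] from `n_starts` deterministically derived seeds and
#' keeps the fit with the largest observed-data log-likelihood (ties broken
#' by the lowest start index).  The multiplicative updates only find local
#' optima, so many random starts are required; the published protocol uses
#' 300.  Per-start seeds are a pure function of
#' `(master_seed, rank, fold, start)`, so the selected fit does not depend
#' on execution order or on `n_workers`.
#'
#' @inheritParams fit_ecm
#' @param n_starts Number of random starts. Default 300.
#' @param master_seed Master seed for the whole procedure.
#' @param fold Fold index used in seed derivation (0 for a full-matrix fit).
#' @param n_workers Processes for `parallel::mclapply()`; default 1 (serial).
#' @return The best `ecm_fit`, with `n_starts` and `master_seed` attached.
#' @export
fit_multistart <- function(V, mask = NULL, r, n_starts = 300L,
                           master_seed = 1L, tol = 1e-5,
                           max_iterations = 2000L, fold = 0L,
                           n_workers = 1L) {
  V <- validate_counts(V, integer = FALSE)
  stopifnot(n_starts >= 1L)
  V0 <- init_impute(V, mask)
  P <- nrow(V); N <- ncol(V)
  seeds <- vapply(seq_len(n_starts), function(i)
    derive_seed(master_seed, r, fold, i), integer(1))
  one <- function(i) {
    init <- random_init(P, N, r, seeds[i], V0)
    tryCatch(
      .fit_ecm_from(V, mask, init$W, init$H, as.integer(r), seeds[i],
                    tol, max_iterations),
      error = function(e) e)
  }
  fits <- if (n_workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(seq_len(n_starts), one, mc.cores = n_workers)
  } else {
    lapply(seq_len(n_starts), one)
  }
  ok <- !vapply(fits, inherits, logical(1), what = "condition")
  if (!any(ok)) {
    stop("all ", n_starts, " ECM starts failed; first error: ",
         conditionMessage(fits[[1L]]), call. = FALSE)
  }
  lls <- vapply(fits[ok], function(f) f$observed_loglik, numeric(1))
  best <- fits[ok][[which.max(lls)]]
  best$n_starts <- as.integer(n_starts)
  best$master_seed <- as.integer(master_seed)
  best
}
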