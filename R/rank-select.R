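#' Held-out prediction error of a fitted fold
#'
#' The generalized KL divergence between the observed held-out counts and
#' the model means `W %*% H`, evaluated over the held-out cells only.  This
#' is the per-fold validation prediction error \eqn{ERR_{r,k}} (up to the
#' dropped Poisson constant).
#'
#' @param V Count matrix.
#' @param mask Logical hold-out matrix used when fitting.
#' @param fit An `ecm_fit` trained with this mask.
#' @return Non-negative scalar.
#' @export
fold_error <- function(V, mask, fit) {
  if (!inherits(fit, "ecm_fit")) stop("fit must be an ecm_fit", call. = FALSE)
  if (!all(dim(mask) == dim(V)))
    stop("mask does not match the matrix", call. = FALSE)
  if (nrow(fit$W) != nrow(V) || ncol(fit$H) != ncol(V))
    stop("fit dimensions do not match V; was it trained on this matrix?",
         call. = FALSE)
  kl_divergence(V, fit$W %*% fit$H, cells = mask)
}

#' Select the number of signatures by cross-validation
#'
#' For each candidate rank `r` and each of `K` balanced folds, fits the
#' Poisson NMF by multistart ECM with the fold's cells held out, and scores
#' the fold by the held-out KL prediction error.  The per-rank curve
#' \eqn{ERR_r = \sum_k ERR_{r,k}} typically falls while signatures are
#' missing (underfitting) and rises once redundant signatures start fitting
#' noise (overfitting); the selected rank `r*` minimizes it, with ties
#' broken toward the smaller rank.
#'
#' @param V Count matrix (types x samples).
#' @param r_min,r_max Rank grid bounds. Defaults 1 and 10.
#' @param K Number of balanced folds. Default 10.
#' @param n_starts Random starts per (rank, fold) fit. Default 300.
#' @param master_seed Master seed; results are reproducible from it alone.
#' @param tol,max_iterations ECM convergence controls.
#' @param n_workers Workers for the multistart loop (results are identical
#'   for any worker count).
#' @return A `rank_selection` object; see [tidy.rank_selection()],
#'   [glance.rank_selection()] and [autoplot.rank_selection()].
#' @export
#' @examples
#' \donttest{
#' V <- sim_single_signature(n_tumors = 30, seed = 1)
#' sel <- select_rank(V, r_min = 1, r_max = 2, K = 5, n_starts = 3)
#' sel$selected_rank
#' }
select_rank <- function(V, r_min = 1L, r_max = 10L, K = 10L,
                        n_starts = 300L, master_seed = 1L, tol = 1e-5,
                        max_iterations = 2000L, n_workers = 1L) {
  V <- validate_counts(V)
  P <- nrow(V); N <- ncol(V)
  r_min <- as.integer(r_min); r_max <- as.integer(r_max)
  if (r_min < 1L || r_min > r_max || r_max > min(P, N))
    stop("require 1 <= r_min <= r_max <= min(P, N)", call. = FALSE)
  folds <- balanced_folds(P, N, K)
  grid <- seq.int(r_min, r_max)

  per_fold <- purrr::map_dfr(grid, function(r) {
    purrr::map_dfr(seq_len(K), function(k) {
      fit <- tryCatch(
        fit_multistart(V, folds[[k]], r, n_starts = n_starts,
                       master_seed = master_seed, tol = tol,
                       max_iterations = max_iterations, fold = k,
                       n_workers = n_workers),
        error = function(e)
          stop("fit failed at rank ", r, ", fold ", k, ": ",
               conditionMessage(e), call. = FALSE))
      tibble::tibble(
        rank = r, fold = k,
        error = fold_error(V, folds[[k]], fit),
        training_error = -fit$observed_loglik,
        loglik = fit$observed_loglik,
        n_iterations = fit$n_iterations,
        converged = fit$converged)
    })
  })

  curve <- per_fold |>
    dplyr::group_by(.data$rank) |>
    dplyr::summarise(error = sum(.data$error),
                     training_error = sum(.data$training_error),
                     .groups = "drop")
  selected <- curve$rank[which.min(curve$error)]
  if (selected == r_max)
    warning("selected rank equals r_max (", r_max,
            "); the rank grid may be too small", call. = FALSE)
  structure(
    list(per_fold = per_fold, curve = curve,
         selected_rank = as.integer(selected),
         r_min = r_min, r_max = r_max, K = as.integer(K),
         n_starts = as.integer(n_starts),
         master_seed = as.integer(master_seed),
         dims = c(P = P, N = N)),
    class = "rank_selection")
}

#' @export
print.rank_selection <- function(x, ...) {
  cat("Cross-validated signature number selection\n")
  cat("  matrix:", x$dims[["P"]], "types x", x$dims[["N"]], "samples |",
      x$K, "folds |", x$n_starts, "starts\n")
  cat("  rank grid:", x$r_min, "..", x$r_max,
      "| selected rank:", x$selected_rank, "\n")
  invisible(x)
}

#' Tidy the per-fold prediction errors
#'
#' @param x A `rank_selection`.
#' @param ... Unused.
#' @return Tibble with one row per (rank, fold): held-out `error`, in-sample
#'   `training_error`, fit log-likelihood and convergence metadata.
#' @export
tidy.rank_selection <- function(x, ...) x$per_fold

#' One-row summary of a rank selection
#'
#' @inheritParams tidy.rank_selection
#' @return Tibble with the selected rank, its validation error, and the
#'   settings used.
#' @export
glance.rank_selection <- function(x, ...) {
  sel <- x$curve[x$curve$rank == x$selected_rank, ]
  tibble::tibble(selected_rank = x$selected_rank,
                 min_error = sel$error,
                 r_min = x$r_min, r_max = x$r_max, K = x$K,
                 n_starts = x$n_starts, master_seed = x$master_seed)
}

#' Prediction-error curve plot
#'
#' Validation prediction error against the number of signatures, with the
#' selected rank highlighted; optionally the (rescaled) training error for
#' the classic underfit/overfit picture.
#'
#' @param object A `rank_selection`.
#' @param training Overlay the training-error curve? Default `FALSE`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rank_selection <- function(object, training = FALSE, ...) {
  curve <- object$curve
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$rank, y = .data$error)) +
    ggplot2::geom_line(color = "#b2182b") +
    ggplot2::geom_point(color = "#b2182b") +
    ggplot2::geom_point(
      data = curve[curve$rank == object$selected_rank, ],
      color = "#b2182b", size = 3) +
    ggplot2::scale_x_continuous(breaks = curve$rank) +
    ggplot2::labs(x = "number of signatures",
                  y = "validation prediction error") +
    ggplot2::theme_minimal()
  if (training) {
    rng <- range(curve$error)
    trng <- range(curve$training_error)
    rescaled <- (curve$training_error - trng[1]) /
      max(trng[2] - trng[1], 1e-12) * (rng[2] - rng[1]) + rng[1]
    p <- p + ggplot2::geom_line(
      data = transform(curve, error = rescaled),
      color = "#2166ac", linetype = 2)
  }
  p
}

#' Held-out test error at a fixed rank
#'
#' Benchmarks a chosen number of signatures on an untouched test subset:
#' the model is fitted with the test cells treated as missing (training and
#' validation cells observed), then scored by the KL divergence between the
#' observed test counts and their imputed model means.
#'
#' @param V Count matrix.
#' @param split Three-way cell split from [three_way_split()].
#' @param r Number of signatures to fit.
#' @inheritParams select_rank
#' @return Non-negative scalar prediction error on the test cells.
#' @export
test_error <- function(V, split, r, n_starts = 300L, master_seed = 1L,
                       tol = 1e-5, max_iterations = 2000L, n_workers = 1L) {
  stopifnot(is.list(split), all(c("train", "validation", "test") %in% names(split)))
  fit <- fit_multistart(V, split$test, r, n_starts = n_starts,
                        master_seed = master_seed, tol = tol,
                        max_iterations = max_iterations, fold = 0L,
                        n_workers = n_workers)
  fold_error(V, split$test, fit)
}
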