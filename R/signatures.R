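#' Extract signature profiles and activities at a fixed rank
#'
#' Fits the Poisson NMF on the full matrix (no held-out cells) by
#' multistart ECM — with an empty hold-out pattern the algorithm is exactly
#' classical generalized-KL NMF — keeps the best start by log-likelihood,
#' and normalizes the result so each profile column sums to one.
#' Signatures are ordered by descending total activity and labelled
#' `DN1, DN2, ...`.
#'
#' @param V Count matrix (types x samples).
#' @param r_star Number of signatures to extract (typically the rank
#'   selected by [select_rank()]).
#' @inheritParams select_rank
#' @return A `signature_fit`: list with `W` (P x r, unit column sums), `H`
#'   (r x N), `rank`, `observed_loglik` and fit metadata.
#' @export
extract_signatures <- function(V, r_star, n_starts = 300L, master_seed = 1L,
                               tol = 1e-5, max_iterations = 2000L,
                               n_workers = 1L) {
  fit <- fit_multistart(V, mask = NULL, r = r_star, n_starts = n_starts,
                        master_seed = master_seed, tol = tol,
                        max_iterations = max_iterations, fold = 0L,
                        n_workers = n_workers)
  norm <- normalize_factorization(fit$W, fit$H)
  ord <- order(rowSums(norm$H), decreasing = TRUE)
  W <- norm$W[, ord, drop = FALSE]
  H <- norm$H[ord, , drop = FALSE]
  ids <- paste0("DN", seq_len(ncol(W)))
  colnames(W) <- ids
  rownames(H) <- ids
  structure(
    list(W = W, H = H, rank = fit$rank,
         observed_loglik = fit$observed_loglik,
         n_iterations = fit$n_iterations, converged = fit$converged,
         n_starts = fit$n_starts, master_seed = fit$master_seed),
    class = "signature_fit")
}

#' @export
print.signature_fit <- function(x, ...) {
  cat("De novo signature fit:", x$rank, "signatures,",
      nrow(x$W), "mutation types,", ncol(x$H), "samples\n")
  cat("  observed log-lik", format(x$observed_loglik, digits = 8),
      if (x$converged) "(converged)\n" else "(not converged)\n")
  invisible(x)
}

#' Tidy signature profiles or activities
#'
#' @param x A `signature_fit`.
#' @param matrix `"profiles"` (default) for the long form of `W`, or
#'   `"activities"` for the long form of `H`.
#' @param ... Unused.
#' @return Tibble in long form.
#' @export
tidy.signature_fit <- function(x, matrix = c("profiles", "activities"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "profiles") {
    tibble::as_tibble(x$W, rownames = "mutation_type") |>
      tidyr::pivot_longer(-"mutation_type", names_to = "signature",
                          values_to = "weight")
  } else {
    tibble::as_tibble(t(x$H), rownames = "sample") |>
      tidyr::pivot_longer(-"sample", names_to = "signature",
                          values_to = "activity")
  }
}

#' @export
glance.signature_fit <- function(x, ...) {
  tibble::tibble(rank = x$rank, observed_loglik = x$observed_loglik,
                 n_iterations = x$n_iterations, converged = x$converged,
                 n_starts = x$n_starts, master_seed = x$master_seed)
}

#' Signature profile plot
#'
#' Bar plot of each profile over the mutation types, faceted by signature.
#' When the row labels are SBS96-style (`A[C>A]A`), bars are colored by
#' substitution class in the conventional order.
#'
#' @param object A `signature_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.signature_fit <- function(object, ...) {
  df <- tidy(object)
  types <- rownames(object$W)
  df$mutation_type <- factor(df$mutation_type, levels = types)
  cls <- regmatches(types, regexpr("[CT]>[ACGT]", types))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$mutation_type,
                                        y = .data$weight))
  if (length(cls) == length(types)) {
    df$class <- factor(rep(cls, times = ncol(object$W)),
                       levels = unique(cls))
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$mutation_type,
                                          y = .data$weight,
                                          fill = .data$class)) +
      ggplot2::scale_fill_manual(values = c(
        "C>A" = "#03bcee", "C>G" = "#010101", "C>T" = "#e32926",
        "T>A" = "#cac9c9", "T>C" = "#a1cf63", "T>G" = "#ecc6c5"),
        guide = "none")
  }
  p + ggplot2::geom_col() +
    ggplot2::facet_wrap(~signature, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "probability") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(
      angle = 90, vjust = 0.5, size = 4))
}

#' Annotate de novo signatures against a reference catalog
#'
#' For each de novo signature, finds the reference profile with the highest
#' cosine similarity.  A signature is reported as matched when its best
#' similarity strictly exceeds `threshold` (0.8 conventionally; 0.9 as a
#' stringent alternative); several de novo signatures may match the same
#' reference entry, and unmatched signatures are flagged as potentially
#' novel.  Catalog rows are reordered to the analyzed mutation-type order.
#'
#' @param W Profile matrix (P x r) with mutation-type rownames, e.g. from
#'   [extract_signatures()].
#' @param catalog Reference matrix (P x S) with mutation-type rownames and
#'   signature-id colnames, e.g. from [read_catalog()].
#' @param threshold Matching threshold on cosine similarity. Default 0.8.
#' @return Tibble with columns `de_novo`, `best_match`, `cosine`, `matched`.
#' @export
match_to_catalog <- function(W, catalog, threshold = 0.8) {
  if (is.list(W) && !is.null(W$W)) W <- W$W
  if (is.null(rownames(W)) || is.null(rownames(catalog)))
    stop("both W and catalog need mutation-type rownames", call. = FALSE)
  missing_in_cat <- setdiff(rownames(W), rownames(catalog))
  extra <- setdiff(rownames(catalog), rownames(W))
  if (length(missing_in_cat) || length(extra)) {
    stop("mutation-type labels differ between W and catalog; ",
         "absent from catalog: ",
         paste(head(missing_in_cat, 5), collapse = ", "),
         if (length(extra)) paste0("; extra in catalog: ",
                                   paste(head(extra, 5), collapse = ", ")),
         call. = FALSE)
  }
  catalog <- catalog[rownames(W), , drop = FALSE]
  purrr::map_dfr(seq_len(ncol(W)), function(j) {
    sims <- vapply(seq_len(ncol(catalog)),
                   function(s) cosine_similarity(W[, j], catalog[, s]),
                   numeric(1))
    best <- which.max(sims)
    tibble::tibble(
      de_novo = colnames(W)[j] %||% paste0("DN", j),
      best_match = colnames(catalog)[best],
      cosine = sims[best],
      matched = sims[best] > threshold)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
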