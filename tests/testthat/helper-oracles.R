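# Independent oracles and small fixture builders shared across tests.
# The oracle code deliberately uses explicit element-wise loops, a separate
# code path from both the compiled engine and the R-level cm_update().

# Generalized KL divergence by direct summation.
kl_oracle <- function(V, M, cells = NULL) {
  if (is.null(cells)) cells <- matrix(TRUE, nrow(V), ncol(V))
  tot <- 0
  for (p in seq_len(nrow(V))) {
    for (n in seq_len(ncol(V))) {
      if (!cells[p, n]) next
      v <- V[p, n]; m <- max(M[p, n], 1e-12)
      tot <- tot + if (v > 0) v * log(v / m) + m - v else m
    }
  }
  tot
}

# One generalized-KL multiplicative update pass (W then H), looped form.
mu_pass_oracle <- function(V, W, H) {
  P <- nrow(V); N <- ncol(V); r <- ncol(W)
  M <- pmax(W %*% H, 1e-12)
  W2 <- W
  for (p in seq_len(P)) {
    for (j in seq_len(r)) {
      num <- 0
      for (n in seq_len(N)) num <- num + H[j, n] * V[p, n] / M[p, n]
      W2[p, j] <- W[p, j] * num / max(sum(H[j, ]), 1e-12)
    }
  }
  M2 <- pmax(W2 %*% H, 1e-12)
  H2 <- H
  for (j in seq_len(r)) {
    for (n in seq_len(N)) {
      num <- 0
      for (p in seq_len(P)) num <- num + W2[p, j] * V[p, n] / M2[p, n]
      H2[j, n] <- H[j, n] * num / max(sum(W2[, j]), 1e-12)
    }
  }
  list(W = W2, H = H2)
}

# Plain KL-NMF by repeated multiplicative updates (no missing cells),
# starting from given factors; mirrors the classical algorithm that the
# empty-mask ECM must coincide with.
mu_run_oracle <- function(V, W, H, n_iter) {
  for (i in seq_len(n_iter)) {
    upd <- mu_pass_oracle(V, W, H)
    W <- upd$W; H <- upd$H
  }
  list(W = W, H = H)
}

# Small random count matrix with a planted low-rank Poisson structure.
small_poisson_fixture <- function(P = 20, N = 15, r = 2, seed = 1,
                                  scale = 50) {
  withr::with_seed(seed, {
    W <- matrix(rgamma(P * r, shape = 0.5), P, r)
    W <- sweep(W, 2, colSums(W), "/")
    H <- matrix(runif(r * N, 0.5 * scale, 1.5 * scale), r, N)
    V <- matrix(rpois(P * N, W %*% H), P, N)
    rownames(V) <- paste0("type", seq_len(P))
    colnames(V) <- paste0("s", seq_len(N))
    list(V = V, W = W, H = H)
  })
}

# Match each true signature to its best-cosine de novo column.
recovered_ids <- function(W_hat, W_true, threshold = 0.8) {
  hits <- vapply(seq_len(ncol(W_true)), function(j) {
    best <- max(vapply(seq_len(ncol(W_hat)),
                       function(k) cosine_similarity(W_true[, j], W_hat[, k]),
                       numeric(1)))
    best > threshold
  }, logical(1))
  colnames(W_true)[hits]
}
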