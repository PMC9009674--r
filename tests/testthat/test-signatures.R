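test_that("extraction recovers well-separated signatures from clean data", {
  # sparse exposures (as in real cohorts) keep the factorization
  # identifiable; activities reach the 1e4-scale high-count regime
  W_true <- standin_signatures(2, seed = 41)
  withr::with_seed(6, {
    H_true <- matrix(runif(2 * 30, 0, 2e4), 2, 30)
    H_true[sample(length(H_true), 18)] <- 0
  })
  V <- simulate_poisson_nmf(W_true, H_true, seed = 17)
  ex <- extract_signatures(V, 2, n_starts = 5, master_seed = 3)
  expect_s3_class(ex, "signature_fit")
  expect_equal(colSums(ex$W), c(DN1 = 1, DN2 = 1), tolerance = 1e-9)
  # signatures ordered by descending total activity
  expect_true(all(diff(rowSums(ex$H)) <= 0))
  best <- vapply(1:2, function(j) {
    max(cosine_similarity(W_true[, j], ex$W[, 1]),
        cosine_similarity(W_true[, j], ex$W[, 2]))
  }, numeric(1))
  expect_true(all(best >= 0.99))
})

test_that("noiseless low-rank input is reproduced nearly exactly", {
  # identifiability needs separable activities: each signature gets pure
  # tumors, otherwise the exact factorization is not unique
  W_true <- standin_signatures(2, seed = 8, P = 40)
  withr::with_seed(10, {
    H_true <- matrix(runif(2 * 15, 0, 300), 2, 15)
    H_true[1, 1:3] <- c(300, 250, 200); H_true[2, 1:3] <- 0
    H_true[2, 4:6] <- c(300, 250, 200); H_true[1, 4:6] <- 0
  })
  V <- W_true %*% H_true
  ex <- extract_signatures(V, 2, n_starts = 8, master_seed = 11, tol = 1e-9)
  rel_kl <- kl_divergence(V, ex$W %*% ex$H) / sum(V)
  expect_lt(rel_kl, 1e-6)
  best <- vapply(1:2, function(j)
    max(apply(ex$W, 2, cosine_similarity, u = W_true[, j])), numeric(1))
  expect_true(all(best >= 0.999))
})

test_that("the update operator and extraction are row-permutation equivariant", {
  # exact equivariance of one E-step + CM pass under a row permutation
  fx <- small_poisson_fixture(P = 24, N = 12, r = 2, seed = 23, scale = 200)
  perm <- withr::with_seed(1, sample(24))
  W0 <- matrix(runif(24 * 2, 0.1, 1), 24, 2)
  H0 <- matrix(runif(2 * 12, 1, 10), 2, 12)
  u1 <- cm_update(fx$V + 0.0, W0, H0)
  u2 <- cm_update(fx$V[perm, ] + 0.0, W0[perm, ], H0)
  expect_equal(u1$W[perm, ], u2$W, tolerance = 1e-12)
  expect_equal(u1$H, u2$H, tolerance = 1e-12)
  # extraction from the permuted matrix finds the same signatures
  # (up to the random start, hence compared at the cosine level)
  e1 <- extract_signatures(fx$V, 2, n_starts = 4, master_seed = 9)
  e2 <- extract_signatures(fx$V[perm, ], 2, n_starts = 4, master_seed = 9)
  for (j in 1:2)
    expect_gt(cosine_similarity(e1$W[perm, j], e2$W[, j]), 0.999)
})

test_that("catalog matching reports argmax matches with the 0.8 default", {
  expect_equal(formals(match_to_catalog)$threshold, 0.8)
  cat96 <- standin_signatures(5, seed = 77)
  colnames(cat96) <- paste0("REF", 1:5)
  # de novo = catalog column 3 plus a slightly perturbed column 1
  W <- cbind(cat96[, 3], cat96[, 1] * 0.9 + cat96[, 2] * 0.1)
  rownames(W) <- rownames(cat96)
  colnames(W) <- c("DN1", "DN2")
  rep <- match_to_catalog(W, cat96)
  expect_equal(rep$best_match[1], "REF3")
  expect_equal(rep$cosine[1], 1, tolerance = 1e-12)
  expect_true(all(rep$matched))
  # brute-force argmax agreement
  for (j in 1:2) {
    sims <- apply(cat96, 2, cosine_similarity, u = W[, j])
    expect_equal(rep$best_match[j], names(which.max(sims)))
    expect_equal(rep$cosine[j], max(sims))
  }
  # duplicate matches are allowed: two copies of REF2 both map to REF2
  W2 <- cbind(DN1 = cat96[, 2], DN2 = cat96[, 2])
  rep2 <- match_to_catalog(W2, cat96)
  expect_equal(rep2$best_match, c("REF2", "REF2"))
  # unmatched signatures are flagged novel under a stringent threshold
  flatW <- matrix(1 / 96, 96, 1,
                  dimnames = list(rownames(cat96), "DN1"))
  rep3 <- match_to_catalog(flatW, cat96, threshold = 0.9)
  expect_false(any(rep3$matched))
})

test_that("catalog matching validates label agreement and reorders rows", {
  cat96 <- standin_signatures(3, seed = 13)
  W <- standin_signatures(2, seed = 14)
  shuffled <- cat96[rev(seq_len(96)), ]
  r1 <- match_to_catalog(W, cat96)
  r2 <- match_to_catalog(W, shuffled)
  expect_equal(r1, r2)
  bad <- cat96; rownames(bad)[1] <- "X[C>A]A"
  expect_error(match_to_catalog(W, bad), "labels differ")
})

test_that("tidy and autoplot expose profiles and activities", {
  fx <- small_poisson_fixture(P = 96, N = 10, r = 2, seed = 37, scale = 100)
  rownames(fx$V) <- sbs96_types()
  ex <- extract_signatures(fx$V, 2, n_starts = 2, master_seed = 1,
                           max_iterations = 200)
  prof <- tidy(ex)
  expect_named(prof, c("mutation_type", "signature", "weight"))
  expect_equal(nrow(prof), 96 * 2)
  act <- tidy(ex, matrix = "activities")
  expect_named(act, c("sample", "signature", "activity"))
  expect_s3_class(autoplot(ex), "ggplot")
  expect_equal(glance(ex)$rank, 2L)
})
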