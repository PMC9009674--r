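test_that("init_impute fills held-out cells with training-row medians", {
  V <- matrix(c(2, 4, 6, 9,
                1, 1, 5, 7), 2, 4, byrow = TRUE)
  mask <- matrix(FALSE, 2, 4); mask[1, 4] <- TRUE
  V0 <- init_impute(V, mask)
  expect_equal(V0[1, 4], 4)            # median of observed {2, 4, 6}
  expect_equal(V0[2, ], V[2, ])
  expect_identical(init_impute(V, NULL), V)
  # validation values are never read: corrupting them changes nothing
  V_bad <- V; V_bad[1, 4] <- 1e6
  expect_equal(init_impute(V_bad, mask), V0)
  all_held <- matrix(TRUE, 2, 4)
  expect_error(init_impute(V, all_held), "no observed cells")
})

test_that("random_init is seed-deterministic with the documented scalings", {
  V0 <- matrix(rpois(96 * 5, 30), 96, 5)
  a <- random_init(96, 5, 3, seed = 11, V0 = V0)
  b <- random_init(96, 5, 3, seed = 11, V0 = V0)
  expect_identical(a, b)
  expect_false(identical(a, random_init(96, 5, 3, seed = 12, V0 = V0)))
  expect_equal(colSums(a$W), rep(1, 3))
  expect_equal(colSums(a$W %*% a$H), colSums(V0))
  expect_true(all(a$W > 0) && all(a$H > 0))
})

test_that("e_step imputes held-out cells with the model mean only", {
  W <- matrix(c(0.5, 0.5), 2, 1); H <- matrix(c(2, 2), 1, 2)
  V <- matrix(5, 2, 2)
  mask <- matrix(FALSE, 2, 2); mask[1, 1] <- TRUE
  Vs <- e_step(V, mask, W, H)
  expect_equal(Vs[1, 1], 1)            # w-row . h-col = 0.5*2
  expect_equal(Vs[-1, ], V[-1, ])
  expect_identical(e_step(V, NULL, W, H), V)
})

test_that("cm_update matches the looped multiplicative-update oracle", {
  withr::with_seed(5, {
    for (i in 1:5) {
      P <- 7; N <- 6; r <- 2
      V <- matrix(rpois(P * N, 15), P, N) + 0.0
      W <- matrix(runif(P * r, 0.1, 1), P, r)
      H <- matrix(runif(r * N, 1, 10), r, N)
      ours <- cm_update(V, W, H)
      theirs <- mu_pass_oracle(V, W, H)
      expect_equal(ours$W, theirs$W, tolerance = 1e-12)
      expect_equal(ours$H, theirs$H, tolerance = 1e-12)
      # one pass never increases the divergence
      expect_lte(kl_divergence(V, ours$W %*% ours$H),
                 kl_divergence(V, W %*% H) + 1e-9)
    }
  })
})

test_that("an exact factorization is a fixed point of the updates", {
  withr::with_seed(9, {
    W <- matrix(runif(8, 0.2, 1), 4, 2)
    H <- matrix(runif(6, 2, 8), 2, 3)
    V <- W %*% H
    upd <- cm_update(V, W, H)
    expect_equal(upd$W, W, tolerance = 1e-12)
    expect_equal(upd$H, H, tolerance = 1e-12)
  })
})

test_that("fit_ecm recovers a noiseless rank-1 matrix and honors defaults", {
  withr::with_seed(21, {
    w <- rgamma(20, 1); w <- w / sum(w)
    h <- runif(10, 50, 150)
    V <- w %*% t(h)
  })
  fit <- fit_ecm(V, mask = NULL, r = 1, seed = 3)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$W %*% fit$H - V) / V), 1e-4)
  expect_equal(formals(fit_ecm)$tol, 1e-5)
  expect_equal(formals(fit_ecm)$max_iterations, 2000L)
})

test_that("observed log-likelihood ascends along ECM iterations", {
  fx <- small_poisson_fixture(seed = 14)
  mask <- balanced_folds(nrow(fx$V), ncol(fx$V), 10)[[2]]
  fit <- fit_ecm(fx$V, mask, r = 2, seed = 5, tol = 1e-8)
  tr <- fit$loglik_trace
  expect_gte(min(diff(tr) + 1e-9 * (abs(tr[-length(tr)]) + 1)), 0)
  # and the reported loglik is the trace's last value
  expect_equal(fit$observed_loglik, tr[length(tr)])
})

test_that("empty-mask ECM coincides with classical multiplicative updates", {
  fx <- small_poisson_fixture(P = 12, N = 8, r = 2, seed = 3)
  V <- fx$V + 0.0
  init <- random_init(12, 8, 2, seed = 77, V0 = V)
  fit <- fit_ecm(V, mask = NULL, r = 2, seed = 77, tol = 0,
                 max_iterations = 20)
  oracle <- mu_run_oracle(V, init$W, init$H, 20)
  expect_equal(unname(fit$W), oracle$W, tolerance = 1e-10)
  expect_equal(unname(fit$H), oracle$H, tolerance = 1e-10)
})

test_that("fits never read held-out values", {
  fx <- small_poisson_fixture(seed = 31)
  mask <- balanced_folds(nrow(fx$V), ncol(fx$V), 5)[[1]]
  V2 <- fx$V
  V2[mask] <- V2[mask] + 1000L     # corrupt only the held-out cells
  f1 <- fit_ecm(fx$V, mask, r = 2, seed = 9)
  f2 <- fit_ecm(V2, mask, r = 2, seed = 9)
  expect_equal(f1$W, f2$W, tolerance = 1e-12)
  expect_equal(f1$H, f2$H, tolerance = 1e-12)
  expect_equal(f1$observed_loglik, f2$observed_loglik, tolerance = 1e-12)
})

test_that("fitting a scaled matrix scales the fitted means", {
  withr::with_seed(8, {
    w <- rgamma(15, 1); w <- w / sum(w)
    h <- runif(8, 40, 80)
    V <- w %*% t(h)
  })
  f1 <- fit_ecm(V, NULL, r = 1, seed = 2, tol = 1e-9)
  f3 <- fit_ecm(3 * V, NULL, r = 1, seed = 2, tol = 1e-9)
  expect_equal(f3$W %*% f3$H, 3 * (f1$W %*% f1$H), tolerance = 1e-3)
})

test_that("multistart keeps the best start and is order-independent", {
  fx <- small_poisson_fixture(seed = 55)
  mask <- balanced_folds(nrow(fx$V), ncol(fx$V), 5)[[3]]
  fit <- fit_multistart(fx$V, mask, r = 2, n_starts = 6, master_seed = 4,
                        fold = 3)
  singles <- vapply(1:6, function(i) {
    s <- sigcv:::derive_seed(4, 2, 3, i)
    fit_ecm(fx$V, mask, r = 2, seed = s)$observed_loglik
  }, numeric(1))
  expect_equal(fit$observed_loglik, max(singles))
  expect_equal(formals(fit_multistart)$n_starts, 300L)
})

test_that("multistart is reproducible under different worker counts", {
  fx <- small_poisson_fixture(seed = 71)
  mask <- balanced_folds(nrow(fx$V), ncol(fx$V), 5)[[1]]
  f1 <- fit_multistart(fx$V, mask, r = 2, n_starts = 6, master_seed = 10,
                       n_workers = 1)
  f2 <- fit_multistart(fx$V, mask, r = 2, n_starts = 6, master_seed = 10,
                       n_workers = 2)
  expect_equal(f1$W, f2$W, tolerance = 1e-15)
  expect_equal(f1$H, f2$H, tolerance = 1e-15)
  expect_identical(f1$seed, f2$seed)
})
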