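#' Sample a count matrix from the Poisson NMF model
#'
#' Draws every cell independently from a Poisson distribution with mean
#' `(W %*% H)[p, n]` — the generative model under which the factorization
#' is a maximum-likelihood estimate.
#'
#' @param W Profile matrix (P x r), non-negative.
#' @param H Activity matrix (r x N), non-negative.
#' @param seed Integer seed; the draw is deterministic per seed.
#' @return Integer count matrix (P x N) with the labels of `W`/`H`; the
#'   generating `W`, `H` and seed are attached as `attr(, "truth")`.
#' @export
simulate_poisson_nmf <- function(W, H, seed = 1L) {
  stopifnot(ncol(W) == nrow(H), all(W >= 0), all(H >= 0))
  M <- W %*% H
  V <- withr::with_seed(as.integer(seed), {
    matrix(rpois(length(M), lambda = M), nrow(M), ncol(M))
  })
  rownames(V) <- rownames(W) %||% paste0("type", seq_len(nrow(V)))
  colnames(V) <- colnames(H) %||% paste0("tumor", seq_len(ncol(V)))
  attr(V, "truth") <- list(W = W, H = H, seed = as.integer(seed))
  V
}

#' Random unit-sum mutation-type profile
#'
#' Draws a symmetric Dirichlet profile (gamma normalization): small
#' `concentration` gives a spiky profile dominated by few mutation types,
#' large gives a flat one.
#'
#' @param seed Integer seed.
#' @param concentration Dirichlet concentration, `> 0`. Default 0.5.
#' @param P Number of mutation types. Default 96 (labels [sbs96_types()]).
#' @return Non-negative vector summing to 1.
#' @export
random_profile <- function(seed = 1L, concentration = 0.5, P = 96L) {
  stopifnot(concentration > 0)
  g <- withr::with_seed(as.integer(seed),
                        rgamma(P, shape = concentration, rate = 1))
  g <- pmax(g, 1e-12)
  pr <- g / sum(g)
  names(pr) <- if (P == 96L) sbs96_types() else paste0("type", seq_len(P))
  pr
}

#' Seeded stand-in signature profiles
#'
#' Deterministic synthetic signature profiles used where a study would plug
#' in reference-catalog columns (which are not bundled).  Each signature
#' concentrates most of its mass (default 75%) in one of the six SBS96
#' substitution-class blocks — cycling C>A, C>G, C>T, T>A, T>C, T>G — with
#' a spiky within-block Dirichlet and a flatter remainder spread over all
#' types, so distinct signatures have low mutual cosine similarity (well
#' separated) while single profiles are spiky-but-not-degenerate, the
#' qualitative structure of real single-base-substitution signatures.
#'
#' @param n Number of signatures.
#' @param seed Integer seed.
#' @param dominance Mass placed on the dominant substitution block.
#' @param P Number of mutation types; the block structure is used when
#'   `P == 96`, otherwise plain Dirichlet profiles are drawn.
#' @return P x n matrix with unit column sums, columns `S1..Sn`.
#' @export
standin_signatures <- function(n, seed = 101L, dominance = 0.75, P = 96L) {
  stopifnot(n >= 1L, dominance > 0, dominance < 1)
  W <- withr::with_seed(as.integer(seed), {
    sapply(seq_len(n), function(j) {
      if (P == 96L) {
        block <- ((j - 1L) %% 6L) * 16L + seq_len(16L)
        spiky <- pmax(rgamma(16L, shape = 0.15), 1e-12)
        flat <- pmax(rgamma(P, shape = 2), 1e-12)
        pr <- flat / sum(flat) * (1 - dominance)
        pr[block] <- pr[block] + spiky / sum(spiky) * dominance
        pr
      } else {
        g <- pmax(rgamma(P, shape = 0.2), 1e-12)
        g / sum(g)
      }
    })
  })
  rownames(W) <- if (P == 96L) sbs96_types() else paste0("type", seq_len(P))
  colnames(W) <- paste0("S", seq_len(n))
  W
}

#' Single-signature simulation design
#'
#' One signature, 500 tumors: per-tumor activities drawn i.i.d. uniform on
#' \[20000, 40000\] and counts Poisson with the rank-1 mean `W %*% H`.  Any
#' rank the selection procedure finds beyond 1 on such data is a false
#' positive.  The default profile is a fixed seeded stand-in, moderately
#' spiky and dominated by C>A and T>A types (the qualitative shape of a
#' mid-entropy real signature).
#'
#' @param profile Optional unit-sum profile (length P); default a fixed
#'   stand-in.
#' @param n_tumors Number of tumors. Default 500.
#' @param activity_range Uniform activity bounds. Default `c(20000, 40000)`.
#' @param seed Integer seed.
#' @return Integer count matrix (P x `n_tumors`) with `attr(, "truth")`.
#' @export
sim_single_signature <- function(profile = NULL, n_tumors = 500L,
                                 activity_range = c(20000, 40000),
                                 seed = 1L) {
  if (is.null(profile)) profile <- design_one_profile()
  stopifnot(abs(sum(profile) - 1) < 1e-6, all(profile >= 0))
  h <- withr::with_seed(as.integer(seed) + 1L,
                        runif(n_tumors, activity_range[1], activity_range[2]))
  W <- matrix(profile, ncol = 1,
              dimnames = list(names(profile), "S1"))
  H <- matrix(h, nrow = 1,
              dimnames = list("S1", paste0("tumor", seq_len(n_tumors))))
  simulate_poisson_nmf(W, H, seed = seed)
}

# Fixed stand-in profile for the single-signature design: ~45% C>A, ~30%
# T>A, remainder flat — spikier than a flat clock-like signature, flatter
# than a single-peak one.
design_one_profile <- function() {
  withr::with_seed(2026L, {
    pr <- rep(0, 96L)
    ca <- 1:16; ta <- 49:64
    pr[ca] <- rgamma(16, shape = 0.6); pr[ca] <- pr[ca] / sum(pr[ca]) * 0.45
    pr[ta] <- rgamma(16, shape = 0.6); pr[ta] <- pr[ta] / sum(pr[ta]) * 0.30
    rest <- setdiff(1:96, c(ca, ta))
    g <- rgamma(length(rest), shape = 2)
    pr[rest] <- g / sum(g) * 0.25
    names(pr) <- sbs96_types()
    pr
  })
}

#' Bootstrap-activity simulation design
#'
#' Emulates a cohort by resampling signature activities from a reference
#' study: with reference profiles `W_ref` fixed, each simulated tumor's
#' activity column is assembled by drawing reference tumors uniformly with
#' replacement — jointly for each group of co-occurring signatures in
#' `joint_groups` (one reference tumor supplies the whole group, preserving
#' their dependence), independently for every ungrouped signature — and
#' counts are Poisson with mean `W_ref %*% H_boot`.
#'
#' @param W_ref Reference profiles (P x r, unit column sums).
#' @param H_ref Reference activities (r x N_ref).
#' @param n_tumors Number of simulated tumors. Default 200.
#' @param joint_groups List of signature index (or rowname) vectors
#'   resampled jointly; e.g. `list(c(1, 4), c(2, 6))` for two dependent
#'   pairs. Default none.
#' @param seed Integer seed.
#' @return Integer count matrix with `attr(, "truth")` (including the
#'   bootstrap activity matrix).
#' @export
sim_bootstrap_activities <- function(W_ref, H_ref, n_tumors = 200L,
                                     joint_groups = list(), seed = 1L) {
  stopifnot(ncol(W_ref) == nrow(H_ref), ncol(H_ref) >= 1L)
  r <- nrow(H_ref); n_ref <- ncol(H_ref)
  groups <- lapply(joint_groups, function(g) {
    if (is.character(g)) match(g, rownames(H_ref)) else as.integer(g)
  })
  if (length(groups) && anyNA(unlist(groups)))
    stop("joint_groups refer to unknown signatures", call. = FALSE)
  singles <- setdiff(seq_len(r), unlist(groups))
  units <- c(groups, as.list(singles))
  H_boot <- withr::with_seed(as.integer(seed) + 1L, {
    Hb <- matrix(0, r, n_tumors)
    for (n in seq_len(n_tumors)) {
      for (u in units) {
        Hb[u, n] <- H_ref[u, sample.int(n_ref, 1L)]
      }
    }
    Hb
  })
  dimnames(H_boot) <- list(rownames(H_ref), paste0("tumor", seq_len(n_tumors)))
  simulate_poisson_nmf(W_ref, H_boot, seed = seed)
}

#' Eight-signature simulation with mutation-calling errors
#'
#' Emulates miscalled mutations on top of a true eight-signature Poisson
#' model: activities are uniform on \[0, 100\] with a fraction of entries
#' zeroed (sparse real-data-like exposures), the error-free matrix `V0` is
#' Poisson with mean `W %*% H`, and each cell then receives an independent
#' error count uniform on `[0, a * b_n]` rounded to the nearest integer,
#' where `b_n` is tumor `n`'s average count per mutation type in `V0`.
#' `error_level = 0` adds no errors; the published stress levels are 0,
#' 0.4, 0.8 and 1.2.
#'
#' @param W8 Profile matrix with unit-sum columns; default eight stand-in
#'   signatures covering all six substitution classes
#'   ([standin_signatures()]).
#' @param n_tumors Number of tumors. Default 300.
#' @param error_level Error level `a >= 0`. Default 0.
#' @param zero_fraction Fraction of activity entries set to zero.
#'   Default 0.3.
#' @param activity_range Uniform activity bounds. Default `c(0, 100)`.
#' @param seed Integer seed.
#' @return Integer count matrix with `attr(, "truth")` (including the
#'   error-free `V0` and the added error matrix).
#' @export
sim_with_errors <- function(W8 = NULL, n_tumors = 300L, error_level = 0,
                            zero_fraction = 0.3,
                            activity_range = c(0, 100), seed = 1L) {
  stopifnot(error_level >= 0, zero_fraction >= 0, zero_fraction < 1)
  if (is.null(W8)) W8 <- standin_signatures(8L)
  r <- ncol(W8)
  H <- withr::with_seed(as.integer(seed) + 1L, {
    H <- matrix(runif(r * n_tumors, activity_range[1], activity_range[2]),
                r, n_tumors)
    nz <- round(zero_fraction * length(H))
    if (nz > 0) H[sample.int(length(H), nz)] <- 0
    H
  })
  dimnames(H) <- list(colnames(W8), paste0("tumor", seq_len(n_tumors)))
  V0 <- simulate_poisson_nmf(W8, H, seed = seed)
  b <- colMeans(V0)
  E <- withr::with_seed(as.integer(seed) + 2L, {
    round(matrix(runif(length(V0)), nrow(V0), ncol(V0)) *
            rep(error_level * b, each = nrow(V0)))
  })
  V <- V0 + E
  attr(V, "truth") <- list(W = W8, H = H, V0 = V0, errors = E,
                           error_level = error_level,
                           seed = as.integer(seed))
  V
}
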