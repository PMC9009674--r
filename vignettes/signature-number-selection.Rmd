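---
title: "Choosing the number of mutational signatures by cross-validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Choosing the number of mutational signatures by cross-validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigcv)
```

## The model

A mutation-type count matrix $V$ ($P$ types $\times$ $N$ tumors, canonically
$P = 96$ single-base-substitution categories) is modelled as independent
Poisson counts with a low-rank mean,
$$v_{pn} \sim \mathrm{Poisson}\Big(\textstyle\sum_{j=1}^{r} w_{pj}\,h_{jn}\Big),$$
where the columns of $W$ are unit-sum signature profiles and $H$ holds the
per-tumor activities. Maximizing this likelihood is the same as minimizing
the generalized Kullback–Leibler divergence
$D_{KL}(V \,\|\, WH) = \sum v\log(v/m) + m - v$, the classical NMF
objective, and the classical multiplicative update algorithm is an
expectation/conditional-maximization (ECM) scheme for the Poisson model.
Throughout the package the Poisson log-factorial constant is dropped: every
reported "log-likelihood" is $-D_{KL}$ over the cells involved, so only
differences and orderings are meaningful.

The number of signatures $r$ is the model-complexity dial. In-sample fit
improves monotonically with $r$ (our `training_error` curves show this on
every run), so $r$ must be chosen out-of-sample.

## Balanced cell-wise cross-validation

Ordinary K-fold splitting by tumors cannot work — a factorization needs
every tumor's column — so folds are made of *cells*. In fold $k$, tumor $n$
has held out exactly the types $p$ with
$(p-1) \bmod K = (n+k-2) \bmod K$: every $K$-th type, with the offset
rotating across tumors and folds. Consequences, all unit-tested:

* each tumor loses $\lfloor P/K\rfloor$ or $\lceil P/K\rceil$ types per
  fold (balanced — no tumor is ever stripped of a large share of its
  types, which a random hold-out can do);
* the $K$ masks partition the cell grid;
* the pattern is a pure function of $(P, N, K, k)$, independent of the
  data: held-out cells are missing completely at random, so estimates on
  the training cells are not biased by the hold-out.

Index note: the fold algebra is 1-based, matching how the rotation is
usually written; the stored masks are plain logical matrices.

## ECM with missing cells

Existing NMF fitters cannot digest a matrix with holes; the ECM algorithm
here can:

1. **Initialization.** Held-out cells are imputed with the median of their
   row's training cells; $W^0$ is uniform-random with unit column sums,
   and $H^0$ uniform-random rescaled so each tumor's initial expected
   total equals its (completed) observed total. The scaling is our choice
   (only the number of random starts is canonical); it puts the first
   iterate on the right scale and costs nothing.
2. **E-step.** Each held-out cell is replaced by its conditional
   expectation $\sum_j w_{pj} h_{jn}$ under the current fit.
3. **CM1/CM2.** One full pass of the generalized-KL multiplicative
   updates on the completed matrix: $W$ given $H$, then $H$ given the
   already-updated $W$. With no held-out cells the whole iteration reduces
   exactly to classical KL-NMF (asserted to $10^{-10}$ against an
   independent loop-level transcription of the updates).
4. **Convergence.** Stop when
   $|\ell_t - \ell_{t-1}| / (|\ell_{t-1}| + 1) < \mathrm{tol}$, where
   $\ell$ is the observed-data log-likelihood ($-D_{KL}$ over training
   cells only). The $+1$ makes the criterion scale-robust when $\ell$
   crosses zero. Defaults: tol $10^{-5}$, at most 2000 iterations.
   EM theory guarantees $\ell$ never decreases; the test suite checks the
   whole trace on hundreds of random masked instances with $10^{-9}$
   slack for floating-point.

Numerical guards: model means and update denominators are floored at
$10^{-12}$, and $0\log 0 = 0$; degenerate factors decay to the floor
instead of producing NaN. The hot loop is compiled (RcppArmadillo); the
exposed R functions `init_impute()`, `e_step()`, `cm_update()` are the
same algebra step by step and are tested against the compiled path.

Multiplicative updates only find local optima, so each (rank, fold) fit is
restarted from many seeds (default 300) and the best training likelihood
kept. Per-start seeds are a deterministic function of
(master seed, rank, fold, start index), so results are identical whatever
the execution order or `n_workers` — reproducibility is a hard contract,
not a convenience.

## Selecting the rank

For each candidate $r$ and fold $k$ the held-out prediction error is
$ERR_{r,k} = D_{KL}(V_k^{\mathrm{val}} \,\|\, \hat W \hat H)$ over the
held-out cells, and $ERR_r = \sum_k ERR_{r,k}$. The selected $r^*$
minimizes $ERR_r$; ties break to the smaller rank (parsimony — the tie
case is not addressed canonically, so we choose the conservative side).
Selection at the top of the grid triggers a warning to enlarge the grid.
Validation errors reuse the converged fit's means as predictions; there is
no re-fitting after convergence. A three-way split helper
(`three_way_split()`, default 90/5/5 built from 20 balanced folds, the
last fold as test and the one before as validation — the role assignment
is our convention) supports benchmarking a chosen rank on untouched cells
via `test_error()`.

Signatures are finally extracted at $r^*$ on the full matrix (empty mask,
hence plain multistart KL-NMF), normalized to unit profile sums, ordered by
descending total activity, and annotated against a catalog by cosine
similarity: matched if $> 0.8$ (0.9 as the stringent variant), argmax per
de-novo signature without forcing a one-to-one assignment — two flat
de-novo signatures legitimately may both match the same flat reference.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `r_min`, `r_max` | 1, 10 | candidate rank grid; enlarge for pan-cancer-scale cohorts |
| `K` | 10 | balanced folds; 20 gives a 5% validation share |
| `n_starts` | 300 | random starts per fit; the main compute dial |
| `tol` | 1e-5 | relative log-likelihood stopping tolerance |
| `max_iterations` | 2000 | ECM iteration cap |
| `threshold` | 0.8 | cosine match cutoff (0.9 stringent) |
| `genome_size_mb` | 3000 | for burden filtering (human WGS); which size a given cohort used is configuration, not inference |
| `burden_threshold` | 10 /Mb | hypermutator exclusion cutoff |

## The simulators, and what they do and do not show

`simulate_poisson_nmf()` draws counts from the exact model. Three study
designs are built on it:

* **single signature** — one fixed profile, 500 tumors by default,
  activities uniform on $[20000, 40000]$; any selected rank beyond 1 is a
  false positive;
* **bootstrap activities** — profiles fixed, activity columns resampled
  with replacement from a reference cohort, dependent signature pairs
  jointly and the rest independently (independent resampling for the
  ungrouped signatures is our reading; resampling them from a shared
  tumor index would be the alternative), 200 tumors by default;
* **calling errors** — eight signatures covering all six substitution
  classes, activities uniform on $[0, 100]$ with 30% of entries zeroed
  (the zero fraction is our choice, exposed as a parameter), plus
  per-cell error counts uniform on $[0, a\,b_n]$ rounded to integers,
  where $b_n$ is the tumor's mean per-type error-free count and the error
  level $a$ ranges over $0, 0.4, 0.8, 1.2$.

An identifiability caveat worth knowing when building recovery benchmarks:
if all profiles are strictly positive and every activity stays well inside
a narrow positive range, the exact factorization is not unique — profiles
can be mixed slightly without leaving the nonnegative cone, so no
algorithm can return the generating $W$ to high cosine similarity. Real
cohorts are identifiable because exposures hit zero; the package's
recovery tests therefore use sparse activities (zeroed entries or pure
tumors).

Reference profiles are not bundled, so seeded *stand-in* profiles
(`standin_signatures()`) take their place: each concentrates 75% of its
mass in one substitution-class block with spiky within-block structure.
They reproduce the qualitative geometry that matters for selection — well
separated, spiky-but-not-degenerate — but they are synthetic: tests
passing on them demonstrate the selection mechanism, not recovery of any
particular real signature, and real cohorts have flatter, more mutually
similar profiles (where near-duplicate matches genuinely occur). Real
data also violate the model in ways none of the simulators emulate:
overdispersion, correlated types, sample-specific artifacts.

## Desk-scale study conditions

The shipped test suite and `scripts/acceptance.R` run every design end to
end at reduced scale, chosen once so the whole suite completes in tens of
minutes on a single CPU while every scientific conclusion is preserved:

* single-signature selection: 20 replicates, 50 tumors (tests) or 100
  tumors (acceptance script), rank grid 1–4, 10 folds, 20 starts,
  iteration cap 400–500;
* calling-error recovery: 3 replicates at each error level
  $a \in \{0, 0.4, 0.8, 1.2\}$, 100 tumors, grid 1–10, 20 starts;
* bootstrap design: 3 replicates, 120 reference and 100 simulated tumors,
  nine stand-in signatures (six common, three rare), 10 starts; the six
  common signatures must be recovered at cosine $> 0.8$ in every
  replicate.

The published protocol values (300 starts, 2000 iterations, 500/200/300
tumors) remain the package defaults.

## Known limitations

* The Poisson model ignores overdispersion; strongly overdispersed cohorts
  may select extra "noise" signatures at any method of this family.
* Multistart mitigates but cannot eliminate local optima; for flat,
  mutually similar signatures the extracted profiles at $r^*$ can mix.
* The burden filter needs the genome size actually sequenced; exomes and
  panels must override the 3000 Mb default.
* No VCF/MAF parsing: the package starts from a count matrix, and no
  reference catalog is bundled — supply a COSMIC-format file for
  annotation.
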