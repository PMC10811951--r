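---
title: "Methods: factored similarity operators and randomized PCA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: factored similarity operators and randomized PCA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genopca)
```

## The problem

Principal components of a between-individual similarity matrix are the
standard correction for population stratification in genetic association
studies. Given a sparse loci-by-individuals genotype matrix
$G \in \mathbb{R}^{n \times m}$ (rows = variants, columns = individuals),
all the similarities in common use are dense $m \times m$ matrices, and both
their construction ($O(nm^2)$) and their eigendecomposition ($O(m^3)$)
become infeasible as cohorts reach tens or hundreds of thousands of
individuals. The observation this package is built on is that most of these
similarities are Gram matrices in disguise: they can be written exactly as
$S = X^\top X$ with

$$X = a \cdot v \odot (G \ominus w),$$

where $\ominus$ subtracts a centering vector $w$ from every row (or column)
of $G$, $\odot$ rescales by a multiplier vector $v$, and $a$ is a scalar.
Centering densifies a sparse matrix, so $X$ is never formed; instead every
product $Xy$ and $X^\top z$ is evaluated as a sparse product with $G$ plus a
rank-one analytic correction, e.g. for the column axis

$$Xy = a\,\bigl(v \circ (Gy)\bigr) - a\,(v \circ w)\,\textstyle\sum_j y_j .$$

With these two primitives, a randomized SVD delivers the top-$k$
eigenvectors of $S$ in $O(qk\,nm + k^2(n+m))$ time and $O((n+m)k)$ auxiliary
memory — linear in both $n$ and $m$ — without ever materialising $S$ or $X$.

## The five similarities and their factorizations

Writing $p = \mu_r(G)/2$ for half row means, $q_i = 2p_i(1-p_i)$,
$s$ for column sums and $C$ for the appropriately centered $G$:

| similarity | definition | $a$ | $v$ | $w$ | axis |
|---|---|---|---|---|---|
| covariance | $\tfrac{1}{n-1}C^\top C$, columns centered | $1/\sqrt{n-1}$ | $\mathbb{1}_m$ | column means | row |
| weighted Jaccard | $\tfrac{1}{4n}G^\top \mathrm{diag}(weights)G$ | $1/\sqrt{4n}$ | $\sqrt{weights}$ | $\mathbb{0}_n$ | column |
| GRM (robust) | $C^\top C / \sum_i q_i$ | $1/\sqrt{\sum_i q_i}$ | $\mathbb{1}_n$ | $2p$ | column |
| GRM (non-robust) | $\tfrac{1}{n} C^\top \mathrm{diag}(1/q) C$ | $1/\sqrt{n}$ | $1/\sqrt{q}$ | $2p$ | column |
| approx. Jaccard | $G^\top G / (2\max s)$ | $1/\sqrt{2\max s}$ | $\mathbb{1}_m$ | $\mathbb{0}_m$ | row |

The first four decompositions are *exact*: `crossprod(materialize_dense(F))`
reproduces the dense reference implementation entrywise to $10^{-10}$, and
this is asserted over seeded random inputs in the test suite.

The exact Jaccard matrix $J_{ij} = A_{ij}/O_{ij}$ (intersection over union
of the binary columns) is the exception. Its intersection counts are
bilinear ($A = G^\top G$), but the union counts in the denominator are not,
so no parameterization of the factored form can reproduce it. The
approximate Jaccard matrix replaces every union by its universal upper bound
$2\max(s)$, giving $\hat J = A/(2\max s)$. Two properties follow
immediately: $\hat J \le J$ entrywise wherever the union is non-empty (the
approximation never overstates similarity), and $\hat J \succeq 0$ since it
is proportional to a Gram matrix.

### A note on the positive-definiteness of the exact Jaccard matrix

A natural argument for why $J$ itself cannot be factored is to exhibit a $J$
with negative eigenvalues. Our seeded random search
(`find_non_psd_jaccard()`) never finds one beyond floating-point noise, and
for the most negative floating-point instance encountered, exact rational
arithmetic puts the smallest eigenvalue at exactly zero. This is consistent
with the known result that the binary Jaccard (Tanimoto) similarity is the
min–max kernel and hence positive semidefinite. The package therefore does
*not* rely on non-PSD-ness as the obstruction: the obstruction used here is
structural (the union count is not a bilinear function of the columns), and
the corresponding suite check that a non-PSD instance exists is expected to
fail and is kept as an honest negative result.

## Weighted Jaccard details

The weighted Jaccard procedure is implemented literally: `numAlleles`$=2n$;
rows whose sum exceeds $n$ are bit-inverted (minor-allele inversion);
row sums $s$ are then **recomputed on the inverted matrix** before
`totalPairs`$= s(s-1)/2$ and
`weights`$=$`numAlleles`$($`numAlleles`$-1)/$`totalPairs`, because the
inversion exists precisely to express counts on the minor allele and stale
sums would weight inverted rows inconsistently. Loci with fewer than two
carriers (`totalPairs`$=0$) get weight 0 — they carry no pairwise-sharing
information — rather than dividing by zero.

The count basis is dimensionally odd: row sums range over $[0, m]$ while
the threshold and allele total are expressed in $n$. With $n \ge m$ (the
usual genomic regime) the inversion never triggers under the literal
reading. Both readings are provided: `count_basis = "loci"` (default,
literal) and `count_basis = "individuals"` (`numAlleles`$=2m$, inversion
when a row sum exceeds $m/2$, the conventional minor-allele rule).

## Randomized SVD

For a target rank $k$ (valid range $2 \le k \le 0.5\min(m,n)$; smaller $k$
only behind `unsafe = TRUE`), a Gaussian test matrix with $2k$ columns is
pushed through $q$ power iterations, giving
$Y = (X^\top X)^q X^\top \Omega$; a QR factorization of $Y$ yields the
orthonormal range basis $Q \in \mathbb{R}^{m \times 2k}$, the small
projected matrix $B = Q^\top X^\top$ is decomposed by one exact SVD, and
$U = Q\tilde U$ (truncated to $k$ columns) are the returned eigenvectors of
$X^\top X$, with eigenvalues the squared singular values. The sketch is run
in the orientation that keeps $Q$ in the $m$-dimensional space because the
eigenvectors of the $m \times m$ similarity necessarily have length $m$.
Exactly $q{+}1$ operator applications of each of $X$ and $X^\top$ are
performed ($2q{+}2$ in total), which the fast path instruments and the suite
asserts — the complexity contract is checked by counting, never by timing.

Choices worth recording:

* **Default $q = 2k$.** Larger $q$ improves accuracy monotonically (in the
  mean); the expected spectral error obeys
  $\mathbb{E}\|X - U\Sigma V^\top\| \le
  [1 + 4\sqrt{2\min(m,n)/(k-1)}]^{1/(2q+1)} \sigma_{k+1}$
  (`svd_error_bound()`), which tends to the optimal $\sigma_{k+1}$ as
  $q \to \infty$.
* **Sign convention.** Eigenvectors are defined up to sign; each returned
  column is flipped so its largest-magnitude entry is positive, making runs
  reproducible and files byte-comparable.
* **Stabilization.** The literal algorithm performs no re-orthonormalisation
  between power iterations; an optional `stabilize = TRUE` inserts a QR per
  iteration for very large $q$, default off.
* **Degenerate operators.** An all-zero operator returns zero eigenvalues
  and a `degenerate` flag rather than an error.
* **Accuracy is gap-limited.** On unstructured Bernoulli genotypes the
  similarity spectrum is nearly flat and sketched power iteration at
  moderate $q$ resolves only well-separated eigenvectors: at a relative
  eigengap of about $0.05$, $q = 10$ reaches cosine similarity with the
  dense eigenvector of roughly $0.9$, not $0.999$ (an independent
  randomized-SVD implementation behaves identically). Strongly separated
  leading components — the situation population structure creates in real
  cohorts — are recovered to machine-level cosine. The test suite asserts
  the conditional claim as stated and two borderline-gap draws fail it;
  they are kept failing deliberately.

## Error bounds for the Jaccard approximation

For symmetric $J, \hat J$ with sorted eigenvalues, the Davis–Kahan
$\sin\theta$ theorem gives the chain

$$\min_{\epsilon=\pm1}\|u_1 - \epsilon\hat u_1\|_2
  \;\le\; \sqrt{2}\,|\sin\angle(u_1,\hat u_1)|
  \;\le\; 2\sqrt{2}\,\frac{\|J-\hat J\|_{op}}
      {\max(\lambda_1-\lambda_2,\ \hat\lambda_1-\hat\lambda_2)} .$$

`jaccard_bound_report()` evaluates all three quantities. The operator norm
is relaxed to the Frobenius norm by default (always an upper bound, cheap);
eigengaps come from a dense solver, from the power method with deflation
(100 iterations per stage), or — fully a priori — from Gershgorin discs.
The Gershgorin gap is only usable when the topmost connected component of
the disc union contains a single disc; otherwise the bound is reported as
vacuous (`Inf` with a flag) rather than raising an error, since degenerate
spectra are legitimate inputs.

The matrix bound depends only on the two matrices, not on which eigenvector
is examined, so the report's matrix-bound column is constant across orders.
For higher-order eigenvectors the angle bound uses the order-$i$ eigenpair;
a consecutive-gap generalisation
$\max(\lambda_i - \lambda_{i+1}, \hat\lambda_i - \hat\lambda_{i+1})$ of the
matrix bound is available through `matrix_bound(order = i)` but is an
explicit extrapolation of the first-order theorem, so the suite asserts the
full chain only at order 1.

## The simulator: what it does and does not claim

* `sim_binary(n, m, pi, seed)` — i.i.d. Bernoulli($\pi$) entries, default
  experiment setting $\pi = 0.1$; no linkage or row/column structure, and
  all-zero rows/columns are retained (downstream code must, and does,
  tolerate them). The total count of ones is drawn from
  Binomial($nm, \pi$) and placed uniformly, which is distributionally
  identical to entrywise draws but never allocates a dense block.
* `sim_dosage(n, m, maf_low = 0.05, maf_high = 0.5, seed)` — per-locus
  allele frequency uniform in the MAF band, genotypes Binomial(2, $p_i$);
  the band defaults to the conventional common-variant range.
* `sim_stratified(...)` — Balding–Nichols two-level frequency model
  (ancestral frequencies uniform in $[0.05, 0.5]$, population frequencies
  Beta-perturbed with divergence $F$); emulates discrete stratified
  populations well enough for the leading PC to separate groups at
  $F = 0.1$, but has no linkage disequilibrium, admixture, or relatedness.

Every generator takes one explicit integer seed and restores the caller's
RNG state: identical seeds give bit-identical matrices, and all randomized
algorithms are replayable from their recorded seeds. A green test on this
simulator establishes correctness of the algebra and the stated statistical
properties; it does not establish performance claims on real cohorts, which
involve linkage structure and far larger scales.

## Numerical conventions

* Jaccard $0/0$ entries (empty unions) are defined as 0.
* Monomorphic loci get weight 0 in the non-robust GRM (the limit of their
  vanishing contribution), and an all-monomorphic input is an error for the
  robust GRM (its normalizer would be 0).
* Symmetry of dense similarities is enforced by averaging with the
  transpose, removing BLAS order-of-operation asymmetry ($\sim 10^{-16}$).
* Dense materialisation and dense-oracle paths refuse inputs beyond a size
  guard (`max_elements`), since densifying is what the package exists to
  avoid.
* External matrix files are 1-based (Matrix Market convention); everything
  in memory is ordinary R 1-based indexing.

## Command-line interface

`inst/cli/genopca.R` is a thin Rscript over the exported functions with
subcommands `simulate`, `similarity`, `pca`, and `bounds`, YAML/JSON config
support, and a provenance sidecar (`<out>.json`, recording eigenvalues,
$k$, $q$, seed, method) next to every PCA output. `pca --matrix jaccard`
falls back to the dense eigendecomposition with a warning, since no factored
operator exists for the exact Jaccard matrix; `bounds` refuses non-binary
input because the other decompositions are exact and need no approximation
bound.
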