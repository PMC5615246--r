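---
title: "Methods: adaptive-partitioning MI network inference"
author: "aracnekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adaptive-partitioning MI network inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The inference problem

`aracnekit` reconstructs transcriptional regulatory networks from a gene
expression matrix (genes × samples) and a list of candidate regulators
(transcription factors, TFs).  Only TF → gene edges are hypothesized.  The
pipeline is the ARACNE recipe: score every TF–gene pair with mutual
information (MI), keep pairs whose MI exceeds a permutation-null threshold,
and remove presumptively indirect edges with the data processing
inequality (DPI).  Optionally, the whole procedure is repeated over
bootstrap resamples and edges are claimed by a Poisson occurrence test.

# Mutual information by adaptive partitioning

Expression profiles are first rank-transformed per gene
(`rank_transform()`), which makes each marginal exactly uniform and every
downstream quantity invariant to monotone per-gene transforms — the raw
units, log scaling, or library-size normalization of the input are
immaterial.  Ties are broken uniformly at random from a stream derived
deterministically from `(seed, gene index)`, because the estimator requires
strict permutations; with heavily tied data (e.g. zero-inflated counts)
this injects seed-dependent noise into otherwise equal values, which is the
standard price of a strict-rank scheme.

`apmi_pair()` estimates MI (in nats) by adaptively quartering the 2-D rank
plane.  Starting from the full square, a rectangle containing `n` points is
split at the integer midpoints of its two rank intervals whenever

* `n >= min_points` (default 8) and both widths are at least 2, and
* the chi-square statistic `T = sum((n_q - n/4)^2 / (n/4))` of its four
  quadrant counts exceeds `chi2_crit` (default 7.815, the 0.95 quantile of
  chi-square with 3 degrees of freedom),

and is otherwise a leaf.  A leaf with `n > 0` points and widths `w_x`,
`w_y` contributes `(n/M) * log(n*M / (w_x*w_y))`; since ranked marginals
are uniform, this is the plug-in `log` density ratio term and the total is
the usual adaptive-partitioning MI estimate, clamped at zero.  Splitting is
always at the midpoint of the rank interval (fixed quartering), not at the
median of the contained points.

Two numerical choices matter:

* **Breadth-first queue.**  The partition tree is traversed with a FIFO
  queue of rectangles rather than recursion.  This is a traversal-order
  change only; `apmi_pair_recursive()` is a depth-first reference
  implementation kept in the package precisely so tests can assert the two
  agree to 1e-10 on arbitrary inputs.  Empty quadrants are dropped at
  creation (their contribution is zero), which keeps the queue within
  `M - 3` entries; the observed maximum is returned as a diagnostic.
* **Order-canonical summation.**  Leaf contributions are sorted before
  summing, so the estimate is exactly invariant under swapping the two
  variables (the leaf multiset is symmetric; only traversal order is not).
  TF–TF entries of the candidate matrix are additionally computed once and
  mirrored.

With defaults, the estimator recovers the bivariate Gaussian closed form
`-0.5 * log(1 - rho^2)` to well within 0.1 nats at M = 1000 (see
`tests/testthat/test-acceptance.R`), and returns values near zero for
independent pairs.

# The permutation null and its discreteness

`sample_null_mis()` destroys all gene–gene dependence by independently
shuffling each gene's row, then scores `n0` random TF–gene pairs (default
100,000).  `mi_threshold()` converts the resulting empirical distribution
into an MI cutoff at a requested p-value: the smallest observed value whose
empirical survival is at most `p`.  Because the empirical distribution
cannot resolve probabilities below `1/n0`, smaller p-values (the typical
production setting is p = 1e-8) are extrapolated from an exponential model
of the right tail — a least-squares line of `log(survival)` against MI over
the largest `ceiling(n0/1000)` (at least 50) distinct upper-tail values —
floored at the empirical maximum.

Users should know two structural facts about this null:

* **Atom at zero.**  Under independence, the root rectangle is a 2×2 table
  with *fixed margins* (exactly half the ranks fall in each half-plane), so
  the root chi-square statistic has effectively 1 degree of freedom, not 3.
  With the conventional `chi2_crit = 7.815` the root splits with
  probability ≈ 0.005, and a non-split root yields MI = 0 *exactly*.  The
  null therefore has ~99% of its mass at 0 and a discrete family of
  positive values above it.  Consequently the realized type-I rate at
  threshold(p) is conservative: ≈ 0.005–0.01 for any nominal p in
  (0.01, 0.9), and close to nominal only for p ≲ 0.01.  The package keeps
  the conventional constant (it is a parameter, `chi2_crit`) and documents
  the conservatism rather than silently recalibrating.
* **Support limited by the pair universe.**  Null MI values are drawn from
  the TF × gene pair set of one permuted matrix, so the number of distinct
  null values is at most the number of pairs.  On small matrices (tens of
  genes) the null may contain no positive value at all, in which case no
  threshold below p = 1 is resolvable and `mi_threshold()` fails with an
  explanatory error.  Production-scale inputs (hundreds to thousands of
  genes) are unaffected.

# Thresholding and DPI

`apply_threshold()` masks edges with `mi >= threshold` without touching MI
values.  `dpi()` then visits every unordered TF pair whose TF–TF edge
survived, and every third gene connected to both: the edge whose MI is
strictly below `min(other two) * (1 - tolerance)` is marked for removal.
All decisions are made against a snapshot of the input mask and applied at
the end, so the result is independent of triangle evaluation order — the
property that makes a fully parallel DPI equal the serial one, and which
the tests assert against a brute-force triple loop.  Ties are kept:
removing equal-MI edges would make output depend on floating-point noise.
`tolerance` defaults to 0 (strict DPI); 1 disables pruning.

# Bootstrap consolidation

With `bootstraps = B >= 1`, the pipeline reruns on B column resamples
(drawn with replacement; bootstrap `b` uses seed `seed + b`, so any single
run is independently reproducible) and accumulates two matrices: per-edge
MI sums and occurrence counts.  The MI threshold is computed once on the
full matrix and reused across bootstraps — rebuilding a 100,000-value null
per resample buys nothing statistically; a flag
(`recompute_null_per_bootstrap`) enables it for sensitivity analysis.

`consolidate()` claims edges via a Poisson model of occurrences scattering
uniformly over the edge universe: with `E_possible = N_tf*N_genes - N_tf`
directed non-self slots, `lambda = total occurrences / E_possible`, an edge
seen `k` times has `p = P(Poisson(lambda) >= k)`, Bonferroni-corrected over
the edges actually observed (`k >= 1`) — the set actually tested, and the
more conservative of the common readings.  Both `lambda` and the universe
are model choices, so `lambda` is an explicit argument.  Claimed edges
report their mean per-run MI.  Note the arithmetic consequence: at very
small B (2–3) even an edge present in every run may not reach significance
after correction; the conventional production setting is B = 10.

# The synthetic generator

`generate_grn()` + `simulate_expression()` produce ground-truth networks
and data with exactly the statistical structure the pipeline assumes: root
TFs are i.i.d. standard normal; each regulated gene is
`link(weighted sum of regulators) + N(0, noise_sd)`; a `cascade_fraction`
of TFs are wired as middle nodes of root → middle → target chains, giving
exact Markov triples for which `I(t1;g) <= min(I(t1;t2), I(t2;g))` holds in
the generating law — the testable premise of DPI.  Link weights are drawn
uniformly from [0.6, 1] so direct dependencies are detectable at moderate
sample size; the `tanh` sigmoid link exercises nonlinearity while
preserving sign.  The generator makes no attempt to mimic RNA-seq count
noise (negative binomial dispersion, library-size effects): ranking makes
the estimator invariant to any monotone marginal distortion, so such
realism would not change what the tests can show.  What passing tests
demonstrate is recovery of (non)linear dependence structure and correct
pruning of indirect chains — not robustness to artifacts outside this
model, such as batch effects or shared technical covariance, which can
create genuine statistical dependence that no MI method distinguishes from
regulation.

# Problem sizes and defaults used for validation

The shipped test-and-validation settings, chosen as the smallest sizes at
which each property is statistically decidable: estimator checks at
M ∈ {8, …, 64} (oracle agreement, 200 pairs) and M = 1000 (Gaussian closed
form, 20 replicates); type-I calibration with 30 TFs among 150 independent
genes at M = 200, n0 = 10,000, 3000 test pairs; chain pruning on a
TF1 → TF2 → G1 chain embedded among 18 decoy TFs and 100 background genes
at M = 500 (the decoys and background give the permutation null enough
distinct pairs to resolve its threshold, see above), 20 replicates; full
recovery on 20 TFs × 200 targets at density 0.05, M = 500, sigmoid link,
noise 0.5, where recall and precision are stable within ±0.05 across
seeds.  End-to-end runs use p = 0.05 with n0 in the low thousands, matching
what the small null universes can resolve; production-scale data supports
the default p = 1e-8 with n0 = 100,000 via the tail extrapolation.

# Known limitations

* Only TF-rooted edges are modeled; gene–gene dependence outside the TF
  universe is invisible.
* The type-I conservatism described above means nominal p-values above
  ~0.01 overstate the realized false-positive rate at these defaults.
* DPI removes *every* triangle-weakest edge, including true direct edges
  that happen to be weakest in a feed-forward loop; this is inherent to
  the method, not to this implementation.
* Conditional MI (three-way partitioning) and closed-form null models are
  out of scope.
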