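---
title: "Sequence descriptors and weighted sparse representation for PPI prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence descriptors and weighted sparse representation for PPI prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SparsePPI)
```

## The problem

Experimental protein–protein interaction (PPI) screens are noisy and
expensive, so sequence-only predictors are used to triage candidate pairs.
This package implements a pipeline that maps each protein sequence to a
fixed-length numeric vector, compresses it, concatenates the two partners of
a candidate pair, and classifies the pair with a weighted
sparse-representation classifier (WSRC). No structural or annotation input is
used — only the amino acid sequences and a labelled training set of pairs.

## Per-protein descriptors

### The unit-circle F-vector (40 dimensions)

The 20 residues are partitioned into six physicochemical classes: aliphatic
(AVLIMC), aromatic (FWYH), polar (STNQ), positive (KR), negative (DE) and
special-conformation (GP). Ten fixed *combination patterns* regroup these six
classes into four super-groups labelled B, J, O, U; in every pattern B merges
three classes (always including the aliphatic class) and J, O, U keep one
class each. Under one pattern a protein sequence becomes a string over
{B, J, O, U}.

Each super-group owns one quadrant of the unit circle. The q-th occurrence
(out of $X_n$) of letter $X$ is placed at angle

$$\theta = \mathrm{base}(X) + \frac{\pi}{2}\,\frac{q}{X_n + 1},$$

with base angles $0, \pi/2, \pi, 3\pi/2$ for B, J, O, U. A sequence thus
draws a deterministic point cloud on the circle, and the descriptor keeps its
first and second moments $(M_x, M_y, V_x, V_y)$ — means and $n-1$-denominator
variances of the coordinates. Ten patterns times four moments give the
40-dimensional F-vector. For a single-residue sequence the variance is
defined as 0, keeping the encoder total.

### Composition/transition of the binary profile (400 dimensions)

The sequence is also expanded into a 20 × n binary occupancy matrix (row
order A,R,N,D,C,E,Q,G,H,I,L,K,M,F,P,S,T,W,Y,V; each column has exactly one
1). Every row is split into $L = 4$ contiguous near-equal segments
(boundaries at $\lfloor i\,n/L \rfloor$), and each segment is summarised by
five percent-scale statistics: frequency of 0s and of 1s (denominator $m$),
overlapping "11" pairs (denominator $m-1$), overlapping "111" triples
(denominator $m-2$), and adjacent unequal bits (denominator $m-1$). The
denominators follow the worked 20-residue example that fixes them (19 and 18
for $m = 20$); a statistic whose denominator is not positive is 0. This
yields $20 \times 4 \times 5 = 400$ features in percent units.

The segmentation rule itself is underdetermined by the descriptor's usual
statement ("divide each row into $L$ sub-vectors"), so we use the standard
floor-based near-equal split, which is reproducible and keeps lengths within
one of each other. The worked example treats its 20-residue string as one
segment, so it is exercised through `segment_stats()` directly.

## Pair representation

The two descriptors concatenate to a 440-dimensional raw feature. PCA
(mean-centred, no scaling by default) reduces this to $k = 30$ dimensions
per protein; a pair is the concatenation of its two projected partners
(60 dimensions), in the orientation given by the pair list. Component signs
are fixed (largest-magnitude loading positive) so results are deterministic.

Two deliberate defaults:

* **Fold-wise PCA.** In cross-validation the PCA basis is fitted on proteins
  appearing in training pairs only, and held-out pairs are projected into
  that basis. A `global_pca` flag fits on all proteins instead; the default
  avoids information leakage from test proteins.
* **No unit-variance scaling.** The percent-scale CT block carries most of
  the variance relative to the circle-scale F block. A `scale_features` flag
  enables per-feature scaling; on the synthetic data it reduced accuracy
  (the high-variance CT directions are exactly where the signal lives), so
  plain centring remains the default.

## Weighted sparse representation classification

Training pair vectors form the columns of a dictionary $X \in
\mathbb{R}^{d\times n}$, normalised to unit $\ell_2$ norm; the query $y$ is
normalised too (the tolerance below is only meaningful on that scale; a flag
disables it). There is no parametric training — WSRC is a lazy classifier.

Classification solves

$$\hat\alpha = \arg\min \sum_i w_i\,|\alpha_i| \quad \text{s.t.}\quad
\lVert y - X\alpha \rVert_2 \le \epsilon,$$

with $\epsilon = 0.005$, and weights $w_i$ from the Gaussian similarity
$\exp(-\lVert y-x_i\rVert^2 / 2\sigma^2)$ with $\sigma = 1.5$. The class
whose coefficients alone reconstruct $y$ with the smallest Euclidean
residual wins; ties go to the non-interacting class (conservative for
screening). The continuous score used for ROC curves is
$r_{\text{non}} - r_{\text{int}}$, positive meaning interacting, so
label and score sign always agree.

### Weight direction

The similarity-as-weight form penalises *near* samples more once columns are
normalised (similarities fall in roughly [0.41, 1] at $\sigma = 1.5$), which
runs against the locality rationale that near samples should carry small
penalties and large coefficients. Both conventions are exposed:
`weight_mode = "literal"` (the default) uses the similarity itself;
`"inverse"` uses its reciprocal. On the synthetic benchmark the inverse mode
is worth a few accuracy points; the literal form remains the default because
it is the form the method is usually stated in. As $\sigma \to \infty$ both
modes collapse to unweighted sparse representation (verified in the tests).

### Solver

With $\beta_i = w_i \alpha_i$ the problem is basis-pursuit denoising in a
column-rescaled dictionary. The residual norm of the lasso path is monotone
in the penalty, so the solver brackets the largest penalty whose solution
lies inside the $\epsilon$-ball and refines the bracket over successively
finer penalty grids (coordinate descent via glmnet at each grid, convergence
threshold 1e-12, final bracket width below `solver_tol`). Feasibility is
checked first through the least-squares residual; an unreachable ball raises
an error in `solve_weighted_l1()`. During classification with fewer training
columns than dimensions the ball can be legitimately unreachable, so
`wsrc_classify()` enlarges it to the least-squares residual — the solution
is then the sparsest-weighted representation of the query's projection onto
the dictionary's column space. On random instances ($d = 10$, $n = 20$) the
objective agrees with an independent high-accuracy convex solver (scipy,
solving the weighted problem directly without the substitution) to about
1e-5 relative; the test suite enforces 1e-4.

### A known geometric limitation

Sign-free $\ell_1$ representation cannot distinguish a class from its
antipode: if the two classes sit at $\pm\mu$, a negative coefficient on an
opposite-class column reconstructs the query as well as a same-class column,
and literal weighting even prefers it. Two-class data with *orthogonal*
(or generally non-collinear) class directions is the geometry WSRC is suited
to; the classifier tests use orthogonal class means for exactly this reason.
Real pair-vector data is unlikely to be antipodal, but this failure mode is
worth knowing when interpreting scores.

## Evaluation harness

Stratified k-fold cross-validation (default 5 folds; fold sizes per class
differ by at most one) with per-fold Sn, Sp, Acc, Mcc and Mann–Whitney AUC,
averaged across folds; a `repeats` parameter (default 1) averages several
independent partitions, supporting the common 10 × 5-fold protocol. All
randomness derives from a single integer seed and runs are bit-reproducible.
Metrics with zero denominators (possible only in degenerate folds) are
defined as 0.

## Negative sampling

Given a positive pair set, negatives are drawn so that (1) no drawn pair
(unordered) occurs among positives or earlier negatives and self-pairs are
excluded, (2) choosing $n$ equal to the positive count balances the dataset,
and (3) per-protein usage stays as even as possible: proteins are drawn
lowest-usage-first with random tie-breaking, and the greedy draw is
restarted (up to 100 attempts) if it traps itself or exceeds a usage spread
of one. The even-usage draw is our operationalisation of the usual goal
that every protein contribute about equally to the negative set; no
standard algorithm exists for it.

## The synthetic generator

The generator emulates a domain-mediated interaction: 200 random sequences
(uniform residues, backbone lengths uniform in 100–200), half carrying a
proline/glycine/tryptophan-rich 64-residue domain ("a"), half a charge-rich
one ("b"), inserted at a random position. Interacting pairs join an a-protein
with a b-protein (100 pairs); non-interacting pairs join two same-class
proteins (100 pairs, half a–a, half b–b, usage-balanced). The domain shifts
residue composition strongly enough that the CT descriptor separates the
classes; the defaults were chosen so the dataset is separable by design —
a 64-residue domain in a 100–200 residue backbone is comparable to a real
interaction domain in a small protein.

What the generator does *not* emulate: homology structure between related
proteins (real benchmarks are typically filtered to <40% identity with
external tools before use), compositional bias of real proteomes,
length–degree correlations of interaction networks, and noisy labels. A high
synthetic accuracy therefore demonstrates that the pipeline recovers a
composition-level interaction rule end to end, not that it attains any
particular accuracy on curated benchmark datasets, which are external inputs
to this package.

## Problem sizes and numerical choices

Cross-validation on the default synthetic dataset (200 proteins, 200 pairs,
5 folds) takes a few minutes on one core; the dominating cost is one
weighted-$\ell_1$ solve per classified pair (dictionary 60 × 160). The test
suite uses this size for the end-to-end check and much smaller instances
(tens of proteins, $d \le 20$ solver instances) elsewhere. Other numerical
conventions collected in one place: sample variance uses $n-1$ with the
single-point convention 0; CT statistics with non-positive denominators are
0; PCA sign fixing as above; solver feasibility slack $10\cdot$`solver_tol`
in the tests; residual ties classify as non-interacting.
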