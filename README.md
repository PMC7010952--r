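# SparsePPI

Sequence-only prediction of protein–protein interactions (PPIs) with
composition-based descriptors and weighted sparse representation
classification. The package is aimed at computational biologists who have a
labelled set of interacting / non-interacting protein pairs (e.g. a curated
interactome subset plus sampled negatives) and want a reproducible,
annotation-free classifier with a full cross-validation harness.

## Method

Each protein sequence is encoded twice:

* **F-vector (40-d).** The 20 residues are reduced to six physicochemical
  classes, regrouped under ten fixed patterns into four super-groups
  B/J/O/U, one per quadrant of the unit circle. The q-th occurrence of
  letter X (of X_n total) sits at angle `base(X) + (π/2)·q/(X_n+1)`; the
  descriptor keeps the coordinate moments (M_x, M_y, V_x, V_y) per pattern.
* **Composition/transition (400-d).** The 20 × n binary occupancy profile is
  split row-wise into 4 near-equal segments; each segment is summarised by
  the percent frequencies of `0`, `1`, overlapping `11` and `111`, and
  adjacent unequal bits.

The combined 440-d feature is reduced to 30-d by PCA (fitted per training
fold), and a candidate pair (A, B) is the 60-d concatenation of its two
projected partners. Classification represents the query pair as a sparse
combination of training pairs:

    min Σᵢ wᵢ|αᵢ|   subject to   ‖y − Xα‖₂ ≤ ε,

with Gaussian-similarity weights `wᵢ = exp(−‖y−xᵢ‖²/2σ²)` (ε = 0.005,
σ = 1.5), assigning the class whose coefficients reconstruct `y` with the
least residual; the score `r_non − r_int` drives ROC/AUC. Evaluation uses
stratified 5-fold cross-validation reporting Sn, Sp, Acc, Mcc and AUC, with
optional repeats (10 × 5-fold protocol).

## Worked example

```r
library(SparsePPI)

# descriptor building blocks
round(f_vector("METKDGIRWA")[1:4], 4)
#>  v1.mx  v1.my  v1.vx  v1.vy
#> 0.1273 0.2591 0.5376 0.4810

round(segment_stats("11000011101010011010"), 2)
#>   freq0   freq1  freq11 freq111   trans
#>   50.00   50.00   21.05    5.56   57.89
```

The first four F-vector entries are the circle moments of "METKDGIRWA"
reduced under the first pattern ("BOBJOUBJBB"); the segment statistics are
the composition (50% zeros, 50% ones, 21.05% overlapping `11`, 5.56% `111`)
and transition (57.89%) of one binary-profile row.

End to end on synthetic data (200 proteins carrying one of two 64-residue
interaction domains; 100 interacting + 100 non-interacting pairs):

```r
ds <- generate_synthetic(seed = 101)
cross_validate(ds$proteins, ds$pairs, seed = 202)
#> 5-fold CV (1 repeat, seed 202), 200 pairs
#>   Sn  = 0.9500
#>   Sp  = 0.9500
#>   Acc = 0.9500
#>   Mcc = 0.9009
#>   AUC = 0.9920
```

An accuracy of 0.95 with Mcc 0.90 means the pipeline recovers the
domain-complementarity rule from sequence alone; a label-shuffled control
run lands near 0.5 accuracy (no signal). Real benchmark datasets (FASTA +
tab-separated pair lists) are run the same way through `cmd_cv()` or the
`exec/sparseppi` wrapper.

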