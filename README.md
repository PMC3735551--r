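# repwm — iterative refinement of mono- and dinucleotide PWMs

`repwm` discovers putative transcription-factor binding sites (TFBSs) on
TSS-aligned promoter sequences by iterative position-weight-matrix
refinement. PWMs built from the few experimentally validated sites in
curated collections are notoriously unspecific; `repwm` grows the
training set from promoter content itself: it finds the promoter region
where matrix hits are statistically over-represented (the *functional
window*), folds the sites discovered there back into the matrix, and
iterates — optimising motif length and matching cut-off along the way —
until an internal classification objective stops improving.

For whom: computational biologists with (a) a small set of aligned,
gap-free binding sites for a TF and (b) a set of equal-length,
TSS-aligned promoters, who want a sharper scoring model and a list of
putative new sites, plus the synthetic benchmarks to validate the
machinery end to end.

## The model in brief

A matrix plus its matching cut-off forms the scoring suite ⟨W, c⟩.
Weights are background-corrected log-odds, shifted so the best letter of
every column scores 0:

    w_bi = ln(p_bi / e_b) − c_i ,   p_bi = (n_bi + s_i) / (n_m + 4 s_i)

with the pseudocount `s_i = 1` only for columns containing a zero count,
`e_b` the pooled promoter background, and `c_i` the per-column maximum
raw weight. The matching score of a window is the sum of selected column
weights, so scores live in `[min_score, 0]` and the consensus scores 0.
The dinucleotide variant applies the same construction to the 16
overlapping base pairs (rows AA, AT, AG, AC, TA, TT, TG, TC, GA, GT, GG,
GC, CA, CT, CG, CC; 16 × (L−1)), capturing dependence between adjacent
motif positions.

Positional over-representation at window start p is measured by the
z-score `z(p) = (O(p) − E) / σ` of the per-position promoter hit count O,
computed over a descending grid of cut-offs; qualifying positions
(z ≥ 3), read from the contiguous sustained range of the grid, are fused
into functional windows. Refinement then iterates scan → rebuild →
cut-off grid search → ±1-nt length variants (cl/cr/el/er), maximising
the Matthews correlation coefficient of each candidate's hits against
the previous cycle's hits, until Cor reaches 1 or stops improving.

## Worked example

Plant a degenerate 8-nt motif (70%-consensus `TTGACGTA`) into 10% of
2000 random 600-nt promoters at offsets 500–510, train an initial PWM
from just 10 planted sites, and let refinement recover the rest:

```r
library(repwm)

prom    <- generate_promoters(2000, 600, seed = 42)
fmat    <- consensus_frequency_matrix("TTGACGTA", 0.7)
planted <- plant_motif(prom, fmat, c(500, 510), plant_rate = 0.1, seed = 43)

set.seed(44)
train <- site_set(sample(planted$truth$site, 10))
res   <- refine(train, planted$promoters, matrix_type = "mono")
res
#> refinement_result
#>   window [500, 518), final L = 8, cut-off = -5.500
#>   4 cycle(s), final Cor = 0.9905, converged (Cor = 1): FALSE
#>   159 discovered site(s)
res$trajectory
#>   cycle       cor L cutoff n_sites
#> 1     1 0.9504091 8   -5.5     165
#> 2     2 0.9601825 8   -5.5     158
#> 3     3 0.9807137 8   -5.5     164
#> 4     4 0.9904726 8   -5.5     168
```

The detected functional window `[500, 518)` is exactly the planted
region (offsets 500–510 plus the motif length), and the trajectory shows
Cor increasing monotonically over four cycles. The recovered sites
reproduce the generating frequency matrix almost perfectly:

```r
rec <- site_frequency_matrix(res$sites)
mean(vapply(1:8, function(j) cor(rec[, j], fmat[, j]), numeric(1)))
#> [1] 0.991
```

`information_content(res$sites)` exports the per-column bits (here
0.6–1.5 bits, as expected for a 70%-consensus motif) for logo drawing,
and `evaluate_model()` scores any suite on embedding tests built by
`build_site_test()`/`reshuffle_replicates()` with the half-motif-±1-nt
matching tolerance, reporting precision, recall and MCC per replicate
and averaged.

A command-line interface wraps the same functions
(`exec/repwm <build|scan|zscan|refine|synth|evaluate|logo>`), writing a
JSON manifest next to every output for reproducibility.

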