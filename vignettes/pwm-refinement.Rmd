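---
title: "Iterative PWM refinement: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Iterative PWM refinement: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repwm)
```

## The problem

Position weight matrices (PWMs) are the standard model for the sequence
specificity of a transcription factor (TF). Built from a handful of
experimentally validated binding sites, they tend to be weak predictors:
scanned against a genome they produce many false positives, because the
few training sites under-sample the true variability of the binding
motif. `repwm` implements an iterative refinement strategy that grows the
training set directly from promoter sequence content: if a motif is
functional, its occurrences should be *positionally over-represented* on
promoters aligned at the transcription start site (TSS). The region of
over-representation (the *functional window*) is detected statistically,
and sites discovered there are folded back into the matrix, iterating
until an internal classification objective stops improving.

## Matrix models

Both matrix types are corrected log-odds models against a promoter
background, in the fixed alphabet order A, T, G, C.

**Mononucleotide PWM (4 × L).** For base $b$ at motif column $i$:

$$w_{bi} = \ln\frac{p_{bi}}{e_b} - c_i, \qquad
  p_{bi} = \frac{n_{bi} + s_i}{n_m + 4 s_i}$$

where $n_{bi}$ counts base $b$ at column $i$ over the $n_m$ aligned
training sites, and $e_b$ is the background fraction of $b$ pooled over
the whole promoter region (position-independent). The pseudocount $s_i$
is 1 for columns containing a zero count and 0 otherwise: it keeps the
logarithm finite and gives very rare letters a well-defined penalty,
while leaving fully observed columns untouched. The shift $c_i$ is the
per-column maximum of the raw log-odds, so that after shifting the best
letter of every column scores exactly 0. Consequently every matching
score $S(\mathrm{seq}) = \sum_i w_{\mathrm{seq}_i, i}$ lies in
$[\,\text{min\_score}, 0\,]$, the consensus scores 0, and matching
cut-offs are non-positive numbers.

**Dinucleotide PWM (16 × (L−1)).** The same construction applied to
overlapping dinucleotides at columns $(i, i+1)$, rows ordered AA, AT,
AG, AC, TA, TT, TG, TC, GA, GT, GG, GC, CA, CT, CG, CC, with the
pseudocount denominator using the 16-letter alphabet. Adjacent motif
positions are often statistically dependent (a first-order Markov
property of binding sites); the dinucleotide model captures that
dependence. Its background $e_d$ is the pooled *empirical* promoter
dinucleotide distribution rather than the product $e_b e_{b'}$, so
background neighbour dependence is corrected for as well — a deliberate
choice: with the product form, genome-wide dinucleotide skew (e.g. CpG
depletion) would masquerade as motif signal.

A matrix plus its matching cut-off $c$ forms the complete scoring suite
$\langle W, c \rangle$; a window is a *hit* when $S \ge c$ (closed
comparison, so the consensus always qualifies at $c = 0$; ties at the
cut-off are compared with a $10^{-9}$ tolerance so that results do not
depend on floating-point summation order).

## Signal detection

For each window start position $p$ on the TSS-aligned promoters, $O(p)$
counts the promoters with a hit starting at $p$ (capped at one per
promoter per start). The positional z-score is

$$z(p) = \frac{O(p) - E}{\sigma},$$

with $E$ the mean and $\sigma$ the *population* standard deviation of
$O$ over all start positions. Positions with $z \ge 3$ qualify as
candidate signal. Because the z-profile depends strongly on the unknown
cut-off, the package computes the profile over a descending grid of
cut-offs (default: 0 down to the matrix minimum in steps of 0.5) — the
numerical form of a cut-off × position heat map.

Two readings of that grid matter, and both follow the heat-map logic:

* **Window collection.** Qualifying positions are collected over the
  *leading contiguous run* of qualifying cut-offs (from the stringent
  end down to where the signal stops being sustained). Qualifying rows
  separated from that run are ignored: near the score floor almost
  every position is a hit, $\sigma$ collapses, and chance fluctuations
  produce $z \ge 3$ at arbitrary positions. Collected positions closer
  than the motif length $L$ are fused into one window.
* **Initial cut-off.** Each window's initial cut-off $c_0$ is the most
  *permissive* cut-off at which its peak remains qualified ("sustained
  up to $c_0$"). A permissive $c_0$ deliberately admits degenerate
  candidate sites; the refinement loop exists to sort them. Choosing
  the stringent end instead makes cycle 1 reproduce the consensus-only
  hit set exactly and the optimisation terminates without learning
  anything — an instructive failure mode we verified on synthetic data.

Several windows may qualify. Cor-based selection (below) is only
meaningful among windows of comparable signal strength — a window with
two hits reproduces them trivially — so windows whose peak z is more
than one z-unit below the strongest are dropped first; among the rest,
each is refined and the best final correlation wins (ties: more
discovered sites, then higher peak z).

## The refinement loop

Starting from $\langle W^0, c_0 \rangle$ inside the selected window:

1. scan the window; the current suite's hits are the reference
   ("true") set for this cycle;
2. union the discovered site sequences with the training sites and
   rebuild the matrix $W^i$;
3. grid-search the cut-off $c \in [c_1, c_2]$ (default: matrix minimum
   to 0, step 0.5) maximising the Matthews correlation coefficient
   (MCC, *Cor*) of $\langle W^i, c \rangle$'s hits against the
   reference set;
4. from the current hits, build the four one-nucleotide length
   variants — clip left (`cl`), clip right (`cr`), extend left (`el`),
   extend right (`er`) — rebuild and grid-search each, and keep the
   best-Cor candidate among the unchanged and variant matrices;
5. accept the candidate, reassign it as the reference suite, and
   repeat until Cor reaches 1, stops improving, or a hard cap of 20
   cycles (typical convergence: a handful of cycles).

Confusion counts during iteration follow the overlap convention: TP is
the number of (promoter, start) hits shared with the reference set, FP
the surplus new hits, FN the missed reference hits, and TN complements
their sum to $N_\mathrm{total} = n_p \cdot \max(1,\,\mathrm{span} - L +
1)$, the number of possible placements in the window. When a variant
changes the motif length, its hit starts are mapped back to the
original-length frame (clip-left and extend-left shift the left edge by
∓1) before the comparison, so that the same physical site matches
across lengths.

Tie-breaking in steps 3–4 prefers, in order: the unmodified length, the
shorter motif, the more stringent cut-off. Stability and parsimony
motivate the order; the descending cut-off grid makes the last rule
automatic. Extensions that would cross a promoter boundary drop the
affected hit from that variant only; clipping below a minimum motif
length (default 5 nt) skips the variant.

## Synthetic benchmarks

The generator module produces all test inputs:

* `generate_promoters()` — i.i.d. promoters from a base-fraction model
  (default uniform; EPD-style 600 nt, TSS placed so sequences span
  −499..+100). Real promoter sets have positional composition
  structure near the TSS that i.i.d. sequences lack, so passing tests
  demonstrate correct behaviour of the machinery, not performance on
  real genomes.
* `plant_motif()` — overwrites a site sampled column-wise from a
  frequency matrix into a chosen fraction of promoters at a uniform
  offset within a window, recording every insertion in a truth table.
  The package's parameter-recovery benchmark uses 2000 promoters of
  600 nt with an 8-nt motif from a 70%-consensus matrix planted in 10%
  of promoters at offsets 500–510 — enough planted instances (~200)
  for a clear positional signal while keeping the discovery problem
  non-trivial, and sized so the whole benchmark runs in well under a
  minute.
* `build_site_test()` / `reshuffle_replicates()` — the embedding
  benchmark: aligned sites (with their unaligned flanks preserved
  verbatim) are placed so the aligned block starts at a fixed position
  (default 27) in 300-nt sequences padded with equally distributed
  random nucleotides; replicates (default 10) permute only the padding
  (30 successive permutations), conserving its composition exactly.
  Flank permutation exists as an option but is off by default.

Seeding: one master seed; per-replicate streams are derived
deterministically from it, so every generated object is byte-identical
across runs with the same configuration.

## Evaluation conventions

On synthetic tests a truth motif is recovered (TP) when some hit start
lies within $\lfloor L/2 \rfloor + 1$ nt of the nearer motif edge — the
half-motif-plus-one reading of the matching tolerance, the more
generous of the two possible integer readings for odd $L$. Each truth
motif credits at most one hit; surplus matching hits count as FP. FN is
the number of unrecovered motifs and TN complements to
$N_\mathrm{total} = \mathrm{test\_size} \cdot (\mathrm{seq\_len} - L +
1)$. A looser whole-motif-length tolerance mode (`tolerance = L`) is
available for comparisons where the competing method's reported hit
position is offset by an unknown in-matrix shift. Precision, recall
and MCC are undefined (reported "n/a") when their denominators vanish.
`percent_change()` expresses method-comparison deltas as a signed
percentage of the baseline count.

## Numerical and degenerate-input choices

* Background frequencies of zero (possible only on degenerate promoter
  sets) are floored at $1/(\mathrm{total}+k)$ for alphabet size $k$ and
  the vector renormalised, with a warning.
* `information_content()` uses $IC_i = 2 + \sum_b f_{bi} \log_2 f_{bi}$
  with $0 \log 0 = 0$ and **no** small-sample correction; the logo
  literature is split on the correction and the uncorrected form keeps
  the invariant-column value exactly 2 bits.
* $\sigma = 0$ (constant positional counts) yields a z-profile of
  exactly 0 everywhere rather than NaN.
* Only the forward strand is scanned; promoter sets are assumed
  strand-oriented by their TSS annotation. This is documented rather
  than configurable because every downstream coordinate convention
  (windows, truth tables, tolerances) assumes it.
* Sequences containing unknown nucleotides (N) are dropped at load
  time with a logged count; sites must be gap-free.

## Problem sizes used by the shipped checks

The test suite exercises scanning against a brute-force oracle on 20 ×
600-nt promoters, exhaustive score enumeration on a 4^6 sequence space,
and the full parameter-recovery benchmark above (2000 × 600 nt, seed
1337). The acceptance script re-runs the recovery benchmark from
scratch at the caller's seed and then evaluates the refined matrix on a
10-replicate embedding test built from 25 held-back planted sites.
These sizes are the package's reference conditions; all are chosen to
make sampling noise small relative to the asserted effects.

## Known limitations

* Background models above order 0 (Markov promoter backgrounds) are
  not implemented; the dinucleotide background correction captures
  neighbour dependence only inside the motif model.
* z-scores are used as a detection heuristic; no analytical p-values
  or multiple-testing control across positions is attempted.
* The refinement objective is greedy per cycle; there is no stochastic
  restart, so a poor initial window/cut-off estimate propagates. The
  multi-window evaluation mitigates but does not eliminate this.
* Scores are uncalibrated log-odds sums; they are comparable within a
  matrix, not across matrices of different lengths.
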