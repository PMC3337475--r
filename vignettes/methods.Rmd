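---
title: "Methods: motif scanning, consolidation and module detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motif scanning, consolidation and module detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cermod)
```

This vignette documents the models and the numerical and design choices
behind the package. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The setting

In nematodes, most known regulatory elements sit within ~2 kb upstream of
the translational start, and transcription-factor binding sites cluster
into *cis*-regulatory modules (CRMs) that drive spatial/temporal
expression. The package implements the computational chain used to work
with a genome-scale catalogue of conserved motifs in that setting:
promoter extraction, PWM scanning, matrix deduplication, module
detection, association screens, and evaluation against curated regulatory
regions.

## PWMs and scanning

A motif is a 4×W count matrix. Weights are natural-log odds
`ln(p̂_bj / q_b)` against a background `q` (worm-like intergenic DNA is
~36% GC; the default background is uniform and every function takes an
explicit `background()`).

**Pseudocounts.** One total pseudo-observation per column, split by the
background: `p̂_b = (n_b + 4·pseudo·q_b) / (N + 4·pseudo)` with
`pseudo = 0.25` per base by default. A column proportional to the
background therefore has all-zero weights, and zero counts stay finite.
The same smoothing is used inside the ALLR statistic so the package has a
single smoothing policy.

**Ambiguity codes.** `N` scores its column's background expectation
`Σ_b q_b w_bj` — a neutral contribution, so masked sequence neither
creates nor destroys hits.

**Cutoffs.** `default_cutoff()` computes the exact distribution of the
score of a random background site by dynamic programming over per-column
score distributions discretized to 0.01 natural-log units (error far
below any downstream decision boundary), and returns the smallest
*attainable* score whose upper-tail probability is ≤ `p_site`. Snapping
to an attainable score leaves the hit set unchanged relative to the raw
bin-edge threshold and makes degenerate cases exact (a single-column
matrix at `p_site = 0.25` returns the consensus weight itself). When even
the maximum score's tail exceeds `p_site`, the returned cutoff is one
discretization step above the maximum, i.e. deliberately unattainable.
The original scanning tool's "default cutoff" is not recoverable, so the
per-site probability is an explicit knob; `1e-3` is the default used for
genome-scale scans that pool thousands of matrices.

**Ties.** Sites scoring exactly the cutoff are kept (`≥`), matching the
inclusive `≥` used for the Z-score peaks.

## ALLR consolidation

Matrix similarity is the per-column average log likelihood ratio summed
over an ungapped alignment, maximized over all offsets with at least 5
overlapping columns (the shortest motif length in the catalogue;
one-column overlaps produce meaningless ALLR) and both orientations.
`0·log 0 = 0` for unsmoothed zero-count bases. Ties break
deterministically: orientation "same", then smaller |offset|, then larger
overlap.

Redundancy uses the published calibration — ALLR > 6.57 and overlap
> 68.1% — with *strict* inequalities as printed. The overlap denominator
is the shorter matrix length, so a motif nested inside a longer one can
reach 100%; any other reading makes the 68.1% threshold behave
erratically for unequal lengths. Consolidation is greedy: the
highest-ranked matrix (rank supplied by the caller, e.g. the discovery
program's total score; ties lexicographic on id) absorbs everything
redundant to it, then the next survivor, until exhaustion. The output is
a partition, deterministic and independent of input order.

## Module detection

1. **Density.** Every hit contributes 1 to each position it covers.
   Coverage (not site starts) is used: "binding sites per position" reads
   naturally as coverage, and it makes the 30-bp extension gap — the
   longest motif length — coherent with site extent.
2. **Z profile.** Counts are standardized with the mean and *population*
   SD of the same sequence (the per-sequence scope follows from
   normalizing "in the sequence"). A flat profile has no local
   enrichment: `sd = 0 ⇒ z ≡ 0`.
3. **Peaks.** Positions with `z ≥ 3.09`, the standard-normal quantile at
   upper-tail 0.001 (verified analytically in the acceptance suite).
4. **Extension.** Peaks are processed from the highest Z down (ties by
   coordinate — highest-confidence seeds first, and deterministic). A
   peak inside an already-grown module is consumed and seeds nothing.
   Each seed's boundary repeatedly jumps to the next `z > 0` position
   strictly less than 30 bp away; the module spans the leftmost to
   rightmost absorbed position; overlapping modules merge.

Whether the original implementation counted starts or coverage, and in
which order it consumed peaks, is not stated anywhere we could check;
both choices above are recorded here as this package's own.

## Association statistics

* **Occupancy** `Σ exp(score)` over all windows on both strands, no
  cutoff — the displayed sum has no threshold, and summing both strands
  matches TF biophysics. The proportionality constant is irrelevant
  because downstream use is correlation.
* **Correlation screen**: Pearson r on shared genes,
  `t = r√(n−2)/√(1−r²)`, two-sided p on n−2 df; `|r| = 1` reports a
  `t = Inf` sentinel.
* **Expression coherence**: threshold distance D = 5% quantile (default;
  exposed) of Euclidean pair distances over the whole matrix; EC =
  fraction of within-cluster pairs with distance ≤ D; p by Monte Carlo
  over equal-size random gene sets with add-one smoothing
  `(b+1)/(n_null+1)`, which can never report zero. Genes with missing
  values are dropped pairwise, without rescaling.
* **GO enrichment**: term gene sets are propagated up the hierarchy
  (direct ∪ all descendants), then upper-tail cumulative hypergeometric
  p-values.
* **Fisher enrichment** for tissue/gene-list categories; odds ratio with
  a Haldane +0.5 correction when a cell is zero. Tissue collapsing
  (e.g. 88 spatio-temporal patterns to 49 tissues) is input-side.
* **Multiple testing**: Bonferroni, the conservative reproducible choice;
  the upstream work never names its correction. Correction scope for the
  location screen defaults to global (all motif × sample tests).

## Evaluation and the placement simulation

An experimental module is *hit* by ≥ 1 bp of overlap. For PPV the default
rule is the symmetric any-overlap; a stricter `containment_frac` rule
(≥ 50% of the prediction inside the union of experimental regions) is
available, because "located within" is genuinely ambiguous. Reported
percentages round half-up to one decimal (so 219/934 prints 23.4).

The placement simulation redraws each predicted module's start uniformly
in its promoter, preserving per-gene module counts and lengths; simulated
modules may overlap each other (nothing forbids it). Empirical p-values
are add-one smoothed. The published real-data benchmark values cannot be
recomputed without the curated module compendium, so the machinery is
validated on constructed cases with closed-form answers (a 1-bp module
against a half-covered 100-bp promoter has hit probability exactly 0.5).

## The synthetic world

`synth_module_world()` is the stated world for end-to-end checks:
20 promoters of 2 kb at 36% GC, each with one 150-bp window holding 12
non-overlapping sites sampled from a strongly conserved 12-bp motif
(97% dominant base per column), plus 20 unplanted controls; all
generators are pure functions of (parameters, seed).

Its scan stringency is `p_site = 1e-5` and is part of the world, not a
tuning knob: with a *single* matrix, the genome-scale default `1e-3`
would put ~4 background hits on every 2-kb control promoter, and against
an otherwise empty profile each isolated hit is a Z ≥ 3.09 spike — a
false module on nearly every control. At `1e-5` the expected number of
background hits per control is far below one, while planted sites (score
near the consensus) stay above the cutoff. The general lesson, worth
stating: the density Z-score is a *relative* statistic, so a sparse scan
background must be matched by a stringent per-site probability; the loose
default presumes pooling thousands of matrices into a dense background.

What a green planted-world test establishes: the detector finds dense
clusters of strong sites against an i.i.d. background and stays quiet on
that background. What it does not establish: performance on real
promoters with repeats, compositional heterogeneity, weak/degenerate
sites or overlapping motif families — none of which the generator
emulates (only GC content is matched to worm intergenic DNA).

The coherence calibration uses a null world of 400 genes × 20
conditions with clusters of 40 and 199 Monte-Carlo nulls: large enough
that the EC statistic's discreteness (780 pairs) does not distort the
add-one-smoothed p-value's uniformity at the KS α = 0.01 check, small
enough to run in about half a minute.

## Degenerate inputs and numerical conventions

* Zero-total matrix column with `pseudo = 0`: an error, not a silent NaN.
* Sequence shorter than the motif: scanning returns an empty hit table;
  occupancy returns 0 with a warning.
* `sd = 0` density profiles and empty prediction sets (PPV undefined,
  flagged `NA`) are handled explicitly.
* All internal coordinates are 0-based half-open; 1-based inclusive
  coordinates exist only at the display boundary in the io module
  (`one_based_to_bed()` / `bed_to_one_based()`).
* Seeds are explicit everywhere randomness exists; generator calls
  restore the caller's RNG state.

## Known limitations

* The consolidation step that merges overlapping within-query site
  intervals ahead of matrix-level clustering is not implemented; the
  matrix-level greedy consolidation carries the full contract here.
* No higher-order background models for scanning p-values.
* The GO reader is a minimal term→gene + parent→child edge list, not an
  OBO parser.
* Coverage fractions for ortholog calling are consumed as precomputed
  columns; whether they were originally per-HSP or per-protein is
  unknowable from the available text, so the reader documents the
  expectation instead of recomputing.
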