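---
title: "Methods: C-rich ssDNA motif grammars, binding isotherms, and colocalization statistics"
author: "c4kit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: C-rich ssDNA motif grammars, binding isotherms, and colocalization statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(c4kit)
```

## The scientific problem

When a guanine-rich DNA strand folds into a G-quadruplex (G4), its
complementary cytosine-rich strand (the "C4") is left exposed as
single-stranded DNA. Engineered KH-domain probes bind this C-rich single
strand, so genomic G4 formation can be mapped *indirectly* by profiling
C4 exposure — an orthogonal readout to antibody-based G4 mapping. c4kit
implements the quantitative machinery such a study rests on: the
sequence grammar of what the probe can recognize, the binding
thermodynamics that calibrate the probe, and the genomic colocalization
statistics that compare probe-derived peak sets and coverage tracks. A
seeded synthetic-data module generates inputs with known ground truth so
that every stage is testable end to end.

## Recognition grammars

The grammar's building block is a **C-tract**: a *maximal* run of
cytosines. Maximality makes parsing unambiguous — a run is delimited by
non-C bases (or the sequence ends), so tract boundaries never depend on
scan order.

* **Recognition unit** (`scan_units()`): two C3+ tracts joined by a
  spacer of 1–7 nt (`CCCN1–7CCC`), or a lone C-run of length ≥ 7. A
  lone 6-run is excluded (binding collapses there), and a spacer of 8 nt
  is out of grammar. When a tract can both stand alone (≥ 7 C) and pair
  with its successor, the scanner takes the two-tract unit: it spans
  more sequence and uses more binding surface.
* **C4 motif** (`scan_c4()`): a chain of consecutive C3+ tracts with
  loops of 1–7 nt. `min_tracts = 4` corresponds to the full complement
  of a canonical G4; `min_tracts = 2` is the experimentally determined
  binding minimum. Chains are *maximal*: the scanner prefers the largest
  tract count, so the four-tract hit set is nested (by span containment)
  inside the two-tract hit set.
* **PQS classes** (`scan_pqs()`), scanned on the G-rich strand of both
  orientations: `canonical4G` (≥ 4 G3+ tracts, loops 1–7), `twoQuartet`
  (≥ 4 G2+ tracts, loops 1–7), `GVBQ` (four tracts, exactly one GG
  vacancy among three intact G3+ tracts), `longLoop15` (loops up to 15
  with at least one ≥ 8, so the class is disjoint from `canonical4G`),
  and `bulged` (exactly one of four tracts split by a 1–3 nt non-G
  bulge). The long-loop, vacancy and bulged grammars are only *cited*
  in the literature that produced the public PQS annotation files, not
  printed; the definitions above are this package's documented
  approximations, and their parameters are plain function arguments.

Design choices worth stating explicitly:

* **Loops may contain the tract base** in runs too short to be a tract
  themselves (e.g. `CC` inside a C4 loop); tracts are maximal runs, so
  this never creates ambiguity. In the `bulged` grammar, loops may not
  contain an intact G3+ run — an intact tract is never skipped over.
* **Overlap resolution** is leftmost-greedy with maximal tract count,
  then maximal span, with no re-scanning inside a consumed hit. For the
  chain classes this is automatic (maximal chains are disjoint); for
  the window classes (`GVBQ`, `bulged`) candidate windows are selected
  left to right.
* **Strands are resolved independently**: plus- and minus-strand hits
  may overlap each other. This preserves an exact duality — the C4
  hits of a sequence are the mirror image of the canonical-G4 hits of
  its reverse complement — which the test suite checks property-style
  against a brute-force enumerator.
* **N bases** match neither tract nor loop, so no hit spans an assembly
  gap. A `bulged` composite tract's bulge must likewise be N-free.

## The binding model

An electrophoretic mobility shift titration measures the bound fraction
$Y$ of a fixed total DNA concentration $T_0$ against a gradient of total
protein $X$. Because $T_0$ (20 nM in the standard design) is comparable
to the dissociation constants of interest, the dilute-ligand hyperbola
$X/(X+K_d)$ is *not* valid; mass action for the 1:1 complex gives the
quadratic ligand-depletion form

$$Y = \frac{(T_0 + X + K_d) - \sqrt{(T_0 + X + K_d)^2 - 4\,T_0 X}}{2\,T_0},$$

the admissible root of the quadratic in the complex concentration
(`bound_fraction()`). The test suite checks it against an independent
root-finding equilibrium solver on a parameter grid, and checks the
dilute limit analytically. Band quantification enters through
`fraction_from_gel()`: the free band shrinks as protein is added, so
$Y = 1 - \mathrm{free}/\mathrm{total}$, the only reading consistent with
$Y(0) = 0$ and $Y$ increasing in $X$.

`fit_kd()` minimizes the residual sum of squares over $K_d \ge 0$ with
$T_0$ fixed and known. The problem has one parameter, so the optimizer
is a deterministic derivative-free search: a log-spaced bracketing grid
(400 points spanning six orders of magnitude around the design
concentrations) followed by golden-section/parabolic refinement within
the bracketing interval. Repeated fits of the same series are bitwise
identical. A series with all-zero bound fractions has a flat objective
in the large-$K_d$ limit and is returned with `converged = FALSE`
rather than a spurious estimate; an estimate pinned at the upper search
bound is likewise flagged.

### Bootstrap confidence intervals

The original study reports point estimates only; the interval is this
package's extension. `bootstrap_ci()` is a residual-resampling bootstrap
with two standard small-sample refinements, both of which matter at a
typical titration size of eight points:

* the resampling pool holds **centered, leverage-studentized residuals**
  $r_i/\sqrt{1-h_i}$, where $h_i$ are hat values of the local
  linearization of the binding curve at the fitted constant. Raw
  residuals understate the noise precisely at the high-leverage
  mid-transition points that drive the fit;
* the interval is the **studentized bootstrap-t**: each resample's
  deviation is pivoted by its own linearized standard error, so the
  (large, at $n = 8$) randomness of the noise-variance estimate itself
  propagates into the interval.

A plain percentile interval on raw residuals measurably undercovers
under this package's own noise model — the generator adds Gaussian noise
to the bound fraction and clips to $[0,1]$, which censors the residuals
at the low-concentration points and deflates the resampling pool. The
acceptance suite runs the calibration experiment (200 replicate
titrations at noise SD 0.05, 1000 resamples each) and requires empirical
coverage of the 95% interval between 90% and 98%; the bootstrap-t
construction sits near 94% where the raw percentile interval reaches
only ~80%. Resampled bound fractions are clipped to $[0,1]$, mirroring
the measurement bound.

## Colocalization statistics

* `rpgc_normalize()` rescales a binned track by one global constant so
  the genome-wide mean bin value is 1 (1× coverage equivalent).
* `track_correlation()` re-bins tracks to a common grid (default 300
  bp) by averaging constituent bins, drops bins intersecting a
  user-supplied blacklist, and computes pairwise Pearson correlations
  (Spearman behind a flag). With `remove_outliers`, bins where either
  track of a pair exceeds its `median + 200 × MAD` are dropped for that
  pair. The exact outlier heuristic of the reference coverage tools is
  not published; this robust rule is deterministic, documented, and
  configurable, which is what a comparison statistic needs.
* `overlap_fraction(A, B)` is the fraction of A-peaks touching at least
  one B-peak by ≥ 1 bp (threshold configurable) — asymmetric by design,
  matching how peak-colocalization percentages are quoted.
* `upset_counts()` merges the union of all peak sets into disjoint
  intervals (book-ended intervals merge, the interval-tool default) and
  assigns each merged interval to the exact subset of sets it touches,
  so counts sum to the number of union intervals.
* `profile_matrix()` samples a track in fixed steps across ±flank
  around region midpoints (summit information is not assumed), ordering
  rows by descending mean — the order heatmaps are drawn in.
  `mean_signal_at()` gives the strand-aware composite profile around
  anchor positions such as TSSs.
* `promoter_partition()` splits hits at the TSS ± 3 kb boundary
  (≥ 1 bp overlap with the window counts as promoter-proximal).

Coordinates are 0-based half-open at every file boundary (`read_bed()`,
`write_bed()`, `read_bedgraph()`, `load_tss()`); in memory, interval
sets are `GRanges`. The TSS of a minus-strand gene is `end − 1` under
the half-open convention. Binned tracks drop the trailing partial bin of
each chromosome so every bin has equal width — constant bin width is an
assumption of the correlation statistics. bedGraph regridding uses the
coverage-weighted mean with uncovered basepairs counting as zero, which
conserves mass exactly on covered regions.

## What the synthetic generators emulate

`make_genome()` plants motifs drawn uniformly from their grammar (tract
lengths 3–5, loops 1–7, random strand) into i.i.d. background at a
requested GC content (default 0.41, the human genome-wide value), with
three guarantees that make truth *exhaustive*:

* background segments are re-drawn by rejection until they contain no
  accidental hit of the planted class on either strand;
* each background segment carries 8-bp A/T insulators at its ends, so
  no tract can extend and no chain can bridge (loops cap at 7 nt) a
  background/motif boundary;
* planted loops are drawn from `{A, T}`, so the planted string scans as
  exactly one hit of its class with the designed tract count.

Rejection re-sampling, rather than post-hoc masking, is what makes
scanner false-positive counts exactly testable: the acceptance suite
plants 50 C4 motifs in a megabase and requires exactly 50 hits at the
truth coordinates.

`make_peak_pair()` places peaks (default width 250 bp, a typical
tagmentation peak scale) on a non-overlapping slot grid and forces
exactly `round(frac_overlap × n_a)` A-peaks to intersect a B-peak — the
published colocalization percentages can thus be planted as generator
inputs and recovered by `overlap_fraction()` to within `1/n_a`.

`make_coverage()` draws per-bin Poisson counts at a background rate
(default 10 counts per 50-bp bin, a deeply sequenced library) with a
triangular profile inside peaks normalized so the in-peak *mean* rate is
exactly `background_rate × enrichment`; the enrichment recovery bound
and the shared-signal/independent-track correlation behavior follow
analytically from these settings (at the defaults the expected
shared-signal correlation is ≈ 0.9).

`make_titration()` evaluates the closed form on the printed
concentration gradient and adds Gaussian noise on the bound fraction,
clipped to $[0,1]$ — noise on the fitted quantity itself, the simplest
model consistent with what the fit consumes. Band-level noise can be
emulated through `fraction_from_gel()` inversion instead.

All generators run under a fixed seed through an RNG-state-preserving
wrapper, so outputs are bit-reproducible and never perturb the caller's
random stream.

### What passing these tests does not show

The generators emulate the *statistical geometry* the analysis assumes,
not real data: background is i.i.d. (no repeats, no CpG islands, no
chromatin structure), coverage noise is Poisson without fragment-length
or mappability structure, peaks are rectangles on a slot grid, and
titration noise is homoskedastic. Recovery on synthetic data validates
the algorithms and their contracts; it does not validate biological
conclusions drawn from real sequencing data, and the published
full-scale colocalization percentages (which require alignment and peak
calling of public datasets) are emulated here only as planted
geometry.

## Problem sizes and numerical choices

The shipped experiments use a 1-Mb genome with 50 planted motifs, 500-bp
random sequences (100 of them) for scanner/oracle equivalence, 10⁴–10⁵
bins for correlation checks, and 200 replicate titrations for bootstrap
calibration — sizes at which every behavior being tested is already
asymptotically stable while the whole suite stays fast to run. Fit
tolerances (grid refinement to ~10⁻¹⁰ relative) are far inside the 0.1%
recovery requirement; equality of the closed form with the equilibrium
solver is required at 10⁻⁹. Ties in profile-row ordering keep input
order; degenerate inputs (all-zero tracks, empty peak sets, all-zero
titrations, infeasible motif packing) error or flag rather than
returning silently wrong values.

## Known limitations

* The long-loop, vacancy and bulged PQS grammars are documented
  approximations of cited-but-unprinted definitions.
* Thermodynamic stability scoring (G4Hunter-style), RNA G4s and i-motif
  structure prediction are out of scope — the probe binds the unfolded
  C-rich strand, not the folded i-motif.
* The binding model is 1:1 with fixed amplitude; cooperative (Hill) and
  competition fits are not provided.
* BAM/FASTQ handling, alignment and peak calling are upstream of this
  package: it consumes their BED/bedGraph outputs.
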