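---
title: "Mapping plastid inheritance strength: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping plastid inheritance strength: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Seed-plant chloroplast genomes (plastomes) do not measurably recombine, so
when two plastomes meet in one zygote after biparental transmission they
compete as intact linkage blocks, and some ("strong") plastomes
systematically displace others. The measurable phenotype is the percentage
of variegated (heteroplasmic) seedlings in marker crosses against a white
tester plastome. `plastidrive` implements the computational machinery for
asking *where in the genome* and *in which metabolites* that competitive
ability is encoded:

1. window-wise divergence counting on aligned plastomes and correlation of
   divergence with inheritance strength, with multiple-testing control and
   an optional phylogenetic correction;
2. classification of plastomes into strength classes from transmission
   frequencies;
3. the crossing and enzyme-assay statistics around the phenotype; and
4. a repeated cross-validated LASSO model predicting strength from lipid
   levels.

Because a non-recombining genome offers no within-genome randomization,
correlation mapping here establishes association, not causation: every
polymorphism fixed in a weak lineage associates with weakness regardless of
functional relevance. That caveat drives two design elements below — the
phylogenetic generalized least squares (PGLS) variant, and a synthetic-data
generator that plants known causal loci so the pipeline's behavior under
confounding can be measured rather than assumed.

## Divergence counting

The unit of analysis is an alignment column, classified against a designated
reference row. Within a window of the *ungapped* reference coordinate
system:

* a substitution column counts 1;
* a deletion column (gap in the sample) counts 1 — so an n-bp deletion
  counts n;
* an insertion column (gap in the reference) counts 1 and is assigned to the
  reference position immediately 5' of the insertion run, which keeps the
  window grid defined purely on reference coordinates. Insertions upstream
  of the first reference base anchor to position 0 and therefore fall
  outside every window.
* IUPAC ambiguity codes count only when their base set excludes the
  reference base (N never counts): a conservative divergence measure.

Counting per column rather than per mutational event makes the statistic a
total-sequence-divergence measure and keeps it deterministic; an event-based
count would need an indel model deciding what "one event" is.

One copy of the plastome's large inverted repeat (IR~A~) is excised before
counting (`strip_inverted_repeat()`), since it would otherwise contribute
every change twice.

Windows are `window_size` (default 1000 bp) wide at `step` (default 10 bp)
spacing, and only full windows are emitted: the window count is
`floor((L - w)/s) + 1`. Adjacent windows with identical count vectors are
collapsed into one row before testing (`collapse_windows()`); this shrinks
the Benjamini–Hochberg family to the number of *distinguishable* tests,
which matters because a 10-bp step makes neighboring windows nearly always
identical wherever the alignment is monomorphic. Collapsing is lossless
(`expand_windows()` inverts it) and cannot change any window's correlation,
since the correlation depends only on the count vector.

## Correlation mapping

Per collapsed window, Pearson's r and Spearman's rho between the per-sample
change counts and the strength phenotype:

* Pearson p-values are the usual two-sided t-approximation on n − 2 df.
* Spearman p-values are **exact permutation values by full enumeration** for
  n ≤ 8 samples (mid-ranks make this valid under ties; enumeration is
  deterministic, so no seed is involved) and t-approximate otherwise. The
  study-scale sample sets (13–18 plastomes) always use the t-approximation;
  the exact path exists for small candidate subsets.
* Windows with zero count variance have no defined correlation; they are
  flagged and *excluded from the BH family* (m is reduced), rather than
  being given p = 1, which would dilute the adjustment with non-tests.
* BH is applied separately per metric, since the two tracks are reported
  side by side.
* The phenotype's direction convention (`low_is_strong` /
  `high_is_strong`) is carried as a label and echoed in every output; the
  pipeline never flips signs silently, because the same percent-biparental
  number means opposite things in reciprocal cross directions.

When a single "top" window must be named (as in the recovery analyses
below), windows are ranked by **raw** p-value with an |r| tie-break — not by
adjusted p, because BH step-up produces long runs of exactly tied adjusted
values and ranking on them silently selects the left-most window of a tie
run.

`region_correlation()` applies the same machinery to one user-chosen
interval (candidate loci such as the *accD* 5' coding region or the *ycf2*
promoter/5'-UTR), and `pgls_windows()` replaces the ordinary correlation
with a generalized least squares regression of phenotype on window counts
under a Brownian-motion tip covariance from a user-supplied tree. The fit
whitens both sides by the Cholesky factor of the covariance and reports a
two-sided Wald p on n − 2 df. Pagel's lambda may be fixed by the user
(off-diagonal scaling); there is no likelihood optimization — with a dozen
tips, estimating lambda per window would be noise masquerading as
flexibility. On a star tree the covariance is proportional to the identity
and PGLS reproduces OLS exactly, which the tests assert to 1e-10, and the
whole fit is cross-checked against an independent GLS implementation
(`nlme::gls` with a Brownian correlation).

## Classifying inheritance strength

Transmission-frequency profiles (one value per cross series, in percent)
are clustered in two steps, mirroring common practice:

1. `estimate_k()`: partitioning-around-medoids for each k in 2..10, scored
   by average silhouette width; k* is the argmax. PAM is used for selection
   because medoid-based silhouettes are stable on small n.
2. `kmeans_classify()`: seeded k-means (Lloyd, Euclidean distance, 100
   random restarts by default) at the chosen — or user-forced — k. Classes
   are relabelled 1..k by ascending mean weakness so class 1 is always the
   strongest; the `strong` argument states whether low or high frequencies
   mean strength in the series at hand.

Frequencies are clustered unscaled by default: both series share percentage
units, so standardization would only re-weight them arbitrarily (a
`standardize` flag exists). `swap_rate()` quantifies stability across
seeds or k choices as the minimal fraction of samples whose labels differ
under the best label permutation (exhaustive matching, k ≤ 8); it is the
tool for judging a user-forced k, but the package never auto-selects k by
anything other than the silhouette criterion — "biological
interpretability" is a decision, not an algorithm, and stays with the user.

## Crossing and assay statistics

* `biparental_percent()` pools counts, not percentages: the season-pooled
  value is the total-count-weighted mean of per-season percentages.
* `fisher_vs_reference()` sums seasons and runs a two-sided Fisher's exact
  test on the 2×2 table against the reference line (sidedness is a
  documented choice; the conditional-MLE odds ratio is reported).
* `kruskal_wallis()` is the tie-corrected omnibus across lines; the
  all-values-tied case is defined as H = 0, p = 1 (the tie correction
  otherwise degenerates to 0/0). The post hoc (`pairwise_vs_reference()`)
  is two-sided Mann–Whitney per line vs the reference with BH across lines
  — a documented choice where no procedure is canonical.
* `chloroplast_concentration()` is the counting-chamber formula
  `10 * mean count per B square / 4e-6`; `accase_activity()` divides fixed
  radioactivity (dpm) by the incubation time (20 min default), averages
  technical replicates, subtracts the control rate and divides by the
  chloroplast count. Replicates are averaged *before* control subtraction
  (an order the assay description leaves open; with a per-measurement
  control the two orders differ only when replicate counts are unequal).
* `relative_activity_tests()` expresses each line relative to the reference
  within each experiment and tests the ratios against 1 by a two-tailed
  paired t test with BH across lines. Zero-variance ratio sets are flagged
  (p = NA), never reported as p = 0.

## Predicting strength from lipids

The response is the ordinal inheritance class (1–5) treated as a numeric
Gaussian response. The pipeline is:

1. `normalize_series()`: per series and lipid, log-transform and subtract
   the median over that series' class-1 samples, making class-1 genotypes
   the common reference across series (their per-series median is 0 for
   every lipid afterwards; a flag blocks double normalization).
2. `merge_series()`: row-concatenate the series restricted to lipids
   measured in every series; everything else is dropped and reported.
3. `run_repeated_lasso()`: `n_runs` (default 100) leave-two-genotypes-out
   runs. Each run holds out *all replicate samples* of two seeded-random
   genotypes, fits an L1-penalized (alpha = 1) regression with the penalty
   chosen by inner 10-fold cross-validation at the 1-SE rule, and records
   cvR, the Pearson correlation between actual and predicted strengths over
   the held-out samples. cvR pools the replicates of both held-out
   genotypes — a correlation over two genotype means would be ±1 by
   construction. Held-out sets with constant actuals (two same-class
   genotypes) or constant predictions (null model) give an undefined cvR:
   flagged, kept, excluded from summaries.
4. `select_predictive()`: avgW per lipid = mean |coefficient| across runs;
   predictive iff avgW strictly exceeds 1 SD of all avgW values. The signed
   mean coefficient gives the direction. The alternative reading of the
   score — |mean coefficient|, which cancels sign-flipping lipids — is
   available as `rule = "abs_mean"`.
5. `class_enrichment()`: per lipid class, a two-sided Fisher's exact test
   of predictive × in-class membership, reported as raw p and odds ratio
   with no multiplicity correction (the class counts are small and the
   numbers are descriptive).

Holdout identity and fold assignment derive deterministically from the
config seed and run index, so the whole 100-run experiment is
bit-reproducible.

## The synthetic-data generator

`simulate_plastome_set()` builds an ancestor with embedded homopolymer runs
and tandem-repeat loci, evolves samples along a random coalescent tree, and
emits the *true* alignment — column homology is known from the simulation's
column registry, deliberately bypassing alignment software (computing MSAs
is out of scope, and realignment would blur the planted truth). The
mutational spectrum emulates a plastome-mutator background: substitutions
anywhere; 1-bp slippage indels at the oligo(N) runs; whole-motif-unit
indels at the repeat loci. A sample's phenotype is
`sum(beta_l * change_count at causal locus l) + Gaussian noise`
(`noise_sd` optionally relative to the genetic-signal SD), emitted raw,
rescaled to percent, and discretized into classes 1–5 so both phenotype
encodings can be exercised. The manifest records per-sample signal, noise
and per-locus planted counts, computed from the generator's own registry
bookkeeping — the tests assert it equals `count_changes()` on every causal
locus, tying generator and counter together without sharing code.

Default rates were chosen once for realism at test scale: substitution rate
2e-4 per bp per unit branch length on a coalescent tree of depth ~2 gives
roughly seven substitutions per 20-kb sample, matching the handful of
mutation events per variant plastome seen in mutator-derived material;
oligo runs at 1.5 per kb (6–12 bp), slippage at 0.1 events per run per unit
length, and repeat loci of 20 × 9-bp units at 1.5 unit-indel events per
unit length.

What the generator does *not* emulate: codon structure and selection, rate
heterogeneity, heteroplasmy dynamics, circularity (inputs are linearized),
and realistic base composition. Passing recovery tests therefore show the
*statistical* machinery behaves as specified under the assumed generative
model — not that real plastome alignments satisfy that model.

`simulate_crosses()` draws variegated counts binomially per line and
season; `simulate_lipidome()` builds a 3-series, 16-genotype, 5-replicate
lipidome (184 lipids, 102 shared across series after per-series dropout)
with log-scale class effects on planted lipids, series offsets and
replicate noise, so the normalization, merge and LASSO layers see exactly
the structure they assume.

## Calibration and recovery properties the tests compute

* Window arithmetic obeys the closed form over randomized geometries; a
  140,110-bp reference under the 1-kb/10-bp geometry yields 13,912 windows.
* Correlation, BH and exact-permutation p-values match brute-force oracles
  (1e-10); Fisher and Kruskal–Wallis match enumeration oracles (1e-12).
* PGLS ≡ OLS on star trees (1e-10); on Brownian simulations over a fixed
  16-tip tree with planted slope 2, the mean recovered slope over 200
  replicates stays within 10%.
* Planted-locus recovery: 14 samples, 20-kb genomes, one causal repeat
  locus, noise at 0.5 × signal SD — the top BH-significant window overlaps
  the planted locus in ≥ 95% of 20 seeded simulations, and with the causal
  effect removed the mean BH-significant fraction at q < 0.05 stays below
  0.05 over 50 simulations. The occasional miss under these conditions is
  phylogenetic confounding — another tree-structured mutational hotspot
  outscoring the causal one — which is precisely the failure mode the PGLS
  variant exists to expose.
* The LASSO pipeline recovers ≥ 6 of 8 planted lipids with ≤ 3 false
  positives in ≥ 9 of 10 seeded pipeline runs at the stated noise.

Problem sizes (20-kb genomes, 14–16 samples, 10–100 LASSO runs) are the
package's chosen test scale: large enough that the collapsed-window family,
the confounding structure and the holdout geometry are non-trivial, small
enough that the full suite runs in minutes on one CPU. `ancestor_length`
scales to full plastome size (~140 kb) for heavier use.

## Known limitations

* PGLS assumes the supplied tree and Brownian covariance; with ~14 tips
  there is little power to check either, and lambda is user-fixed, not
  estimated.
* Count-based correlation treats an n-bp indel as n changes; a single long
  indel can dominate a window.
* `swap_rate()`'s exhaustive matching stops at k = 8.
* The ordinal class treated as Gaussian response is a convenience; with 5
  levels and strong effects it is adequate, but no proportional-odds
  alternative is provided.
* Enrichment p-values on a dozen-class partition of ~100 lipids are
  descriptive at best; the package reports them raw and leaves judgment to
  the reader.
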