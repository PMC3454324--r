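---
title: "Methods: conserved motif scanning and cooperativity analysis for HREs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conserved motif scanning and cooperativity analysis for HREs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrescan)
```

## The scientific problem

Hypoxia-inducible factor (HIF) binds the short consensus RCGTG (the
hypoxia response element, HRE), yet only a small fraction of the genomic
RCGTG instances are bound and transactivated in cells. One hypothesis for
this selectivity is cooperativity: binding sites for other
stress-responsive transcription factors (AP1/CREB, CEBP, NFY, ...) located
near functional HREs. `hrescan` implements a complete computational
pipeline to test that hypothesis: it builds a *core* set of
well-supported, hypoxia-responsive, evolutionarily conserved HIF binding
regions and a matched *background* set of conserved RCGTG regions with no
hypoxic response, scans both with position weight matrices (PWMs) under
calibrated thresholds and a cross-species conservation filter, and asks
which motifs separate core from background.

## PWM model and scoring

A PWM is stored as raw counts $f(b,i)$ over bases $b$ at positions
$i = 1..L$ with per-column totals $N_i$. Corrected probabilities add a
pseudocount distributed by the background:

$$p(b,i) = \frac{f(b,i) + c\,p(b)}{N_i + c}, \qquad c = \sqrt{N_i}
\text{ by default.}$$

Weights are log-odds against the background, $W(b,i) = \log_2
p(b,i)/p(b)$, and the per-position information content is Stormo's
relative entropy $D_i = \sum_b p(b,i)\log_2 p(b,i)/p(b)$ (bits;
non-negative, and at most $\log_2 1/\min_b p(b)$ — 2 bits under a uniform
background). A window $b_1..b_L$ scores

$$S = \sum_i D_i\, W(b_i, i),$$

i.e. informative positions dominate the score. $S$ is min-max normalized
to $[0,1]$ using the attainable bounds $S_{min} = \sum_i D_i \min_b
W(b,i)$ and $S_{max} = \sum_i D_i \max_b W(b,i)$, so the per-position
argmax sequence scores exactly 1. Windows containing `N` are flagged
unscannable and score 0, which keeps per-region window counts stable.
When a zero pseudocount produces $-\infty$ weights, the affected windows
are likewise hard mismatches scoring 0; the normalization bounds are
taken over finite weights only.

The pseudocount magnitude and the logarithm base are configurable; the
defaults ($\sqrt{N_i}$, base 2) follow common TRANSFAC/MATCH practice.
Because every threshold is calibrated on the same normalized scale, the
base choice cancels downstream.

The mask used by the conservation filter marks positions with
$D_i \ge 0.6\, D_{max}$ ("information content over 60%"), where $D_{max}$
is the maximal relative entropy achievable under the background. Making
the cutoff a fraction of the attainable maximum keeps the mask meaningful
for non-uniform backgrounds.

## Threshold calibration (minFN / minFP / minSum)

Three stringencies are calibrated per matrix:

* **minFN** (low stringency): sample 10,000 sequences position-wise from
  $p(\cdot,i)$ and choose the score threshold whose achieved detection is
  closest to 90%. With a continuous score distribution this is exactly
  the 10% empirical quantile; for short or highly discrete matrices,
  tied score values make some detection levels unattainable, and the
  closest-achievable rule (ties resolved toward higher detection, the
  side that minimizes false negatives) avoids overshooting the contract
  by the size of a tie block.
* **minFP** (high stringency): scan a background corpus and take the
  smallest threshold whose hit rate is at most 1 per 10,000 bp. The
  corpus stands in for coding sequence; when none is supplied a 1 Mbp
  i.i.d. sequence at 52% GC (coding-like) is generated. Candidate
  thresholds are the observed scores plus 1.0; if even 1.0 exceeds the
  rate (e.g. a corpus saturated with consensus sites) the threshold is
  1.0 with a warning flag.
* **minSum** (intermediate): on an even grid of 100 thresholds between
  minFN and minFP, minimize $FN(t) + FP(t)$, where $FN(t)$ is the
  fraction of matrix samples below $t$ and $FP(t)$ is the corpus hit
  rate at $t$ normalized by the rate at minFN and clipped to $[0,1]$.
  The normalization makes a rate-per-bp commensurable with a fraction;
  it is exposed as a strategy option. Ties go to the lowest threshold.

The ordering minFN ≤ minSum ≤ minFP holds by construction and is
asserted across a battery of synthetic matrices. Calibration is
deterministic under a seed, and the strand policy during calibration
always matches the scan-time policy so thresholds gate the same counting
rules they were calibrated under.

## Conservation-filtered scanning

Regions are multiple alignments (reference species first) with a map from
reference positions to alignment columns. RCGTG consensus instances are
located on both strands by default (HREs are orientation-independent);
PWM scans default to the reference strand, both policies configurable.

A hit is *conserved* when at least 4 species — counting the reference and
necessarily including mouse — carry the reference base at every masked
position of the motif (all five positions for RCGTG; the over-60%-IC
positions for a PWM). Gaps and `N` count as mismatches; a required
species missing from the alignment simply fails the filter rather than
erroring. Minus-strand hits are checked on the same alignment columns,
since base identity is strand-symmetric. Whether the reference counts
toward the four species is genuinely ambiguous in the field's phrasing;
both the count and the required set are parameters.

The per-region presence/absence matrix records a 1 when a region has at
least one conserved hit at the chosen stringency; hit sets are nested
across stringencies, so raising stringency can only turn 1s into 0s.

## Region sets

The core set integrates four kinds of evidence: ChIP binding locations
common to two or more studies (1 bp overlap, duplicates collapsed with
study-order precedence), a conserved RCGTG inside a conserved element,
hypoxic induction of the neighboring gene at FDR 0.02 in the expression
meta-analysis, and extension of the HBS over flanking conserved sequence.
Extension grows the interval symmetrically in 10 bp steps while the
fraction of the whole candidate span covered by conserved elements stays
above 50%, capped at 2 kb. The ">50% presence" rule alone does not
determine a unique maximal interval; growth step, symmetry, and cap are
the package's choices and are configurable. Note a geometric consequence
of the whole-span rule: an HBS centered in an isolated element extends to
roughly twice the element's width before coverage reaches one half. A
coverage rule applied to each increment instead would stop at the element
edge; the whole-span form is used because it matches the stated
">50% presence" reading and degrades gracefully for fragmented element
tracks.

Background candidates are genes whose every probe sits within 0.25
standard deviations of the global mean log-fold in every expression
dataset — genes with no evidence of hypoxic modulation. From those, a
seeded sample without replacement matches the core set's
genomic-location-class proportions (promoter / 5'UTR / intron / 3'UTR;
promoter = 2 kb upstream through the TSS, configurable). Base
composition is reported (GC summaries of both sets) rather than enforced;
the matching procedure for composition is not uniquely defined, so a
post-hoc report keeps the construction transparent.

## Tiling-array region calling

Replicate log-ratio tracks are variance-stabilized with an asinh-glog
transform (per-replicate MAD scale, median-centered) — a deliberately
simple stabilizer whose internals are the package's own; quantile
normalization is available as an alternative. Per-probe significance
uses a one-sample shrinkage t: per-probe variances are shrunk toward a
grand prior variance with prior degrees of freedom estimated by a method
of moments on the sample-variance distribution (modelled as a scaled F),
with two-sided p-values on the combined degrees of freedom and BH
adjustment across probes. When the moments show no excess variance
dispersion the prior dominates and the statistic approaches a z-test;
probes with fewer than two usable replicates get p = 1 and a flag.

The smoothed level of a probe is the 0.75 quantile of replicate-mean
levels within ±100 bp of its midpoint (parameters `quant` and
`winHalfSize`, matched to ~80 bp probe spacing). The null upper bound is
the 0.99 quantile of a symmetric null reconstructed by reflecting the
sub-mode left tail of the smoothed distribution around its mode — bound
probes inflate only the right tail, so the left tail estimates the null;
a plain empirical quantile is available as a fallback. Enriched regions
are maximal runs of probes above the bound with midpoints at most 200 bp
apart (`distCutOff`), at least 4 probes long (`minProbesInRow`), at
least one probe under the 0.02 FDR gate, and at least 8 probes counting
the run plus flanking probes within `distCutOff` (poor-coverage filter).
Regions are ranked by best adjusted p, then maximum smoothed level; both
counts (run and run-plus-flank) are reported.

## Expression meta-analysis

Replicate signals are averaged with a null-majority rule: if half or more
of the replicates are null, the average is null. A probe is induced when
its log2 hypoxia/normoxia ratio exceeds the dataset mean by 2.6 SD (mean
and SD over non-null log-ratios), or when the normoxic average is null
while the hypoxic one is not. Basal expression is significant iff the
normoxic average is non-null. Induction calls are invariant to a global
rescaling of either condition, since a multiplicative factor shifts all
log-ratios equally.

Evidence is combined across datasets per gene — best probe per gene for
induction, any probe for basal significance, both rules configurable —
as standardized log-ratios (zero where null) under Stouffer's method
(Fisher's method optional), followed by BH adjustment over genes and the
0.02 FDR gate. This combination is a deliberate, documented stand-in for
a full effect-size meta-analysis; it feeds the same downstream gate.

The association analyses compare induction percentages between
basal-expressed and basal-null strata per dataset (paired Wilcoxon across
datasets; exactly equal strata yield p = 1 by convention since the
signed-rank statistic is undefined on all-zero differences), a pooled
2×2 uncorrected chi-square, and the four-way
HBS-presence × induction classification whose percentages sum to 100 per
dataset.

## Enrichment statistics

Per PWM, the 2×2 table of presence against core/background labels is
tested one-sided (overrepresentation in core) with Fisher's exact test —
the hypergeometric upper tail — at p < 0.05 with *no* multiple-testing
correction, faithfully to the method being reproduced; a BH column is
reported alongside for transparency.

Feature selection uses CFS (correlation-based feature selection) with
symmetrical uncertainty $SU(X,Y) = 2 I(X;Y)/(H(X)+H(Y))$ as the
correlation measure for discrete variables, subset merit

$$\mathrm{Merit}(S) = \frac{k\,\bar r_{cf}}{\sqrt{k + k(k-1)\bar r_{ff}}},$$

and forward best-first search that stops after 5 consecutive
non-improving expansions (ties broken toward the lowest feature index,
so duplicated features select deterministically). The search is run on
the training split of each fold of a stratified 10-fold cross-validation,
repeated 10 times with reshuffled folds; each feature's selection count
therefore ranges from 0 to 100. Stratification allocates each class
proportionally with seeded shuffling and round-robin remainders.

## What the synthetic data emulates — and what it does not

The generator produces every input with known truth:

* **Aligned region sets**: 120 core and 3500 background regions of
  400 bp at 42% GC across five species (human reference, chimp, dog,
  cow, mouse), each with a central conserved RCGTG inside a ~150 bp
  conserved element. A high-information TGACGTCA-like cooperating motif
  (the CRE/AP1-family palindrome, a realistic positive control) is
  planted at rate 0.30 in core and 0.10 in background regions, with
  instances sampled from the matrix itself. `conserved_fraction`
  defaults to 1, so the planting rates are the conserved-hit rates;
  non-conserved instances get their mouse row scrambled over the motif,
  preserving alignment geometry. Other species are mutated i.i.d. at a
  0.15 substitution rate outside protected positions — a single-rate
  simplification of mammalian noncoding divergence (real chimp identity
  is far higher, mouse lower). Alignments are gapless; the
  position-to-column map is exercised by gapped fixtures in the tests.
  Decoy PWMs are column- and base-shuffled copies of the planted matrix,
  preserving its information profile.
* **Tiling tracks**: 2000 probes at 80 bp spacing, 4 replicates,
  N(0, 0.25) baseline log-ratios, and 20 planted bound regions of 5
  probes with +3 noise-SD effect in every replicate.
* **Expression datasets**: 5 datasets of 2000 genes, log-normal basal
  signals, log-ratio SD 0.5, 5% of genes induced at +4 SD (the same
  genes in every dataset), and 5% of measurements nulled at random.

Real data differ in ways the generator deliberately ignores: phylogenetic
correlation among species, indels, sequence composition structure
(CpG islands, repeats), probe-specific effects and spatial artifacts on
arrays, and correlated expression noise across genes. Passing the
recovery suites therefore demonstrates that the *algorithms* implement
their contracts and recover planted structure at realistic effect sizes
— not that the thresholds are optimal for any particular real dataset.

## Numerical choices and degenerate inputs

* Zero score range (a completely uninformative matrix) normalizes to 1,
  so degenerate matrices calibrate to full detection instead of
  dividing by zero.
* Presence scanning checks candidate windows best-score-first and
  short-circuits on the first conserved hit.
* The moments estimate of the shrinkage prior is clamped to valid
  degrees of freedom (greater than 4; infinite when the variance of the
  sample variances shows no excess dispersion, capped at $10^6$ for the
  t quantile).
* Fold assignment, background sampling, decoy construction and all
  generators are pure functions of their seed; repeated calls are
  bit-identical.
* BED output is written with explicit integer formatting (no scientific
  notation), 0-based half-open, as the format requires.

## Problem sizes used by the shipped checks

The test suite and acceptance script run entirely on synthetic data at
the sizes stated above: 10,000-sequence calibration samples, a 1 Mbp
calibration corpus, 120/3500-region sets over 20 simulation seeds for
the end-to-end recovery study, 100-seed threshold-ordering batteries at
reduced sample sizes, complete enumeration of 2×2 tables with margins up
to 50 for the exact-test oracle, and 50 random instances of up to 10
features for the search-vs-exhaustive comparison. These sizes were
chosen so each property is measured at the scale its contract states
while the whole suite stays comfortably reproducible on a single CPU.

## Known limitations

* The conservation filter is identity-based; it does not weight species
  by branch length and cannot credit compensatory substitutions.
* The minFP contract is relative to the supplied corpus; a corpus that
  misrepresents the target sequence class shifts the threshold.
* CFS best-first search is a heuristic; it matches exhaustive search on
  small instances but carries no global guarantee for hundreds of
  correlated matrices.
* The shrinkage t and glog stabilizer are intentionally simple; they
  reproduce the analysis structure, not any specific package's numerics.
* With `conserved_fraction` below 1 the planting rate no longer equals
  the conserved-hit rate, and enrichment power drops accordingly.
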