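---
title: "Methods and modelling choices in mybevol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and modelling choices in mybevol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

mybevol reimplements, as tested code, the desk analysis typically applied to
a small duplicated plant transcription-factor family: estimate pairwise
synonymous divergence, convert it to time under a molecular clock, build a
distance tree with bootstrap supports, characterise promoter variation, and
quantify tissue-specific expression differences. This vignette documents the
models, the parameters that matter, the numerical conventions, and what the
synthetic-data generators do and do not emulate.

## 1. Synonymous and nonsynonymous divergence (Ks, Ka)

The estimator is the counting method of Nei and Gojobori, in its "modified"
form that weights transitions by a rate ratio κ during site counting.

**Sites.** Each codon position contributes the weighted fraction of its
three possible single-base substitutions that are synonymous; substitutions
creating stop codons are excluded from both numerator and denominator, so
`s + n = 3` holds exactly for every sense codon. With κ = 1 the weights
vanish and the method reduces to the original Nei–Gojobori count. κ defaults
to 1 because the upstream analyses this package emulates never state the
transition/transversion ratio they supplied; κ is exposed as a configuration
knob throughout.

**Differences.** For a codon pair differing at *m* positions, all *m*!
orderings of single-base steps are enumerated with equal weight; steps are
classified synonymous or nonsynonymous by the amino acids they connect, and
orderings that pass through a stop codon are excluded. In the rare case that
*every* pathway crosses a stop, the codon pair is dropped and flagged
(`blocked_pathway_codons_dropped`).

**Alignment policy.** Codon columns containing a gap, an ambiguous base, or
a stop codon in either sequence are dropped whole (complete deletion per
column); the dropped count is reported. `S` and `N` are the arithmetic means
of the two sequences' per-column site totals — the classic convention.

**Correction.** `pS = Sd/S` and `pN = Nd/N` are Jukes–Cantor corrected,
`d = -(3/4)·ln(1 - 4p/3)`. At `p ≥ 3/4` the distance is undefined: the
low-level corrector raises a typed saturation error, while `estimate_ks_ka`
degrades gracefully (NA distance, `ks_saturated` flag, warning) so that the
partial result — counts and proportions — remains available. A retained
codon set with zero synonymous sites (e.g. a lone Met codon) likewise yields
NA with a `no_synonymous_sites` flag rather than 0/0.

Deliberately out of scope: maximum-likelihood codon models and the
Li–Wu–Luo / Yang–Nielsen counting variants.

## 2. Molecular-clock calibration and dating

Calibration takes the Ks values of anchor pairs whose divergence time
`T_cal` is trusted (here: orthologous gene copies across a species split,
default 10 million years) and sets `k = mean(Ks) / (2·T_cal)`. The mean is
taken **before** dividing. This order matters: it is the only one under
which the canonical worked example — calibration Ks values 0.089, 0.044,
0.059 at 10 MYA — reproduces the rate 3.2 × 10⁻⁹ substitutions · site⁻¹ ·
yr⁻¹ exactly, and it guarantees the round-trip identity
`divergence_time(mean(ks), calibrate_rate(ks, T)) = T`.

Any Ks then dates as `T = Ks / (2k)`. Times are carried in years internally
and reported in MYA to one decimal. Duplication ages are summarised as the
min–max range over cross-group pairwise estimates ("about X–Y MYA" style);
no confidence interval is implied, and relaxed clocks or Bayesian dating are
non-goals. Because nothing in the inputs identifies which convention
produced any particular published range, the per-pair estimates are always
emitted alongside the ranges.

## 3. Neighbor-Joining tree with bootstrap

Distances for tree building default to the Jukes–Cantor nucleotide distance
with pairwise deletion of gapped/ambiguous columns (a p-distance is
available); only "Neighbor-Joining" itself is fixed by the emulated
analysis, so the distance model is an explicit, documented default rather
than an inference. The agglomeration is the standard Saitou–Nei Q-criterion
with two deterministic conventions:

* ties in Q are broken by the lowest (i, j) pair in current label order, so
  results are platform-independent;
* negative branch lengths are clamped to zero with the deficit moved to the
  sibling branch of the same join (preserving the joined pair's distance),
  and the tree is flagged `clamped`.

Additive matrices are recovered exactly (verified to 1e-9 against generating
trees and against an exhaustive least-squares topology search on 4–5 taxa).
Bootstrap support for each internal edge of the point-estimate tree is the
percentage of column-resampled replicates whose tree contains the same
bipartition, branch lengths ignored; the resampling stream is seeded
(default 1378) and replicates whose distance matrix is undefined (e.g.
saturated) count as not containing any edge and are tallied. Trees are
unrooted; outgroups are ordinary taxa and rooting is a display concern.

## 4. Promoter analysis

**Alignment.** Pairwise global alignment with affine gaps (Gotoh), scores
match +2, mismatch −3, gap open −5, gap extend −2 (a run of length L costs
`open + L·extend`). These defaults deliberately favour one long indel over
scattered gaps — exactly what is needed to recover a contiguous 17-bp
promoter insertion as a single event. The traceback tie-break is
deterministic: diagonal, then up, then left. The implementation is a small
C++ kernel; its scores are verified against exhaustive enumeration of all
alignments on short strings.

**Indels.** Maximal gap runs in the reference are insertions (sequence from
the query), runs in the query deletions; positions are 1-based reference
coordinates of the base preceding the event (0 for leading events), adjacent
gap columns merge into one call. When a repeat context makes the gap
placement ambiguous, calls are left-normalised (the event slides 5'-ward as
far as the context allows) so the output does not depend on aligner
internals. Applying the calls to the reference reconstructs the query
whenever the alignment contains no substitutions; substitutions are reported
separately by `call_snps`.

**Motif scanning.** Motifs are IUPAC degenerate strings (length ≥ 4)
validated at load time. Every match position is reported, overlaps included;
minus-strand hits are found by matching the reverse-complemented pattern on
the forward sequence and keep forward coordinates. Pattern N matches any
base including N; every other code matches only its concrete bases, so an N
in the sequence never satisfies a non-N code. Palindromic motifs appear on
both strands; deduplication is available but off by default. The bundled
five-motif library (Myc E-box CANNTG, Myb core CNGTTR, MYBPLANT MACCWAMC,
G-box CACGTG, GT-1 GRWAAW) is an explicit stand-in for a full plant
cis-element database — real analyses should load their own TSV. The default
promoter window is 600 bp upstream of the start codon. Position-weight
matrices and motif discovery are non-goals.

## 5. qPCR relative expression

Technical replicates (default 3) are collapsed by the arithmetic mean of Ct
per biological replicate (default 3). Per biological replicate,
`ΔCt = Ct_target − Ct_reference` (reference gene: ubiquitin by default);
`ΔΔCt` subtracts the calibrator genotype's mean ΔCt within the same tissue
(a single pinned calibrator tissue is available), and the fold is
`E^(−ΔΔCt)` with amplification efficiency E = 2 assumed (no standard-curve
efficiencies are modelled; E is a knob).

One invariant forces a representation choice: the calibrator's own group
fold must equal 1 exactly. The arithmetic mean of per-replicate folds does
not satisfy this (Jensen's inequality), so the group-level `fold_change` is
defined as `E^(−mean ΔΔCt)` — the geometric-style summary, which is exactly
1 for the calibrator — while `fold_mean ± fold_se` over per-replicate folds
is reported alongside for figure-style error bars. Group statistics (ANOVA,
U-tests) are run on the per-replicate fold values; log2 folds are a
configuration alternative.

**ANOVA letters.** One-way ANOVA at α = 0.05; if significant, all-pairs
Tukey HSD feeds a compact letter display (groups sharing a letter are not
significantly different, sweep construction over mean-ordered groups). A
non-significant ANOVA labels every group "a"; zero residual variance with
identical means does the same, with distinct means it separates letters.

**U-tests.** The Mann–Whitney U statistic is computed on midranks. While
`choose(n1+n2, n1) ≤ 2·10⁵` the two-sided p-value is exact by full
enumeration of group assignments — this covers every design up to 9-vs-9,
including the fully separated 4-vs-4 case (p = 2/70) and 9-vs-9
(p = 2/48620). Larger designs switch to the tie-corrected normal
approximation with continuity correction; a literal "enumerate up to exactly
n = 12 per side" would need gigabytes via dense enumeration for no
statistical gain, so the memory-bounded threshold is the practical reading
of the same rule. Significance tiers follow the two-level convention of the
emulated figures: `*` for p ≤ 0.005, `**` for 0.005 < p ≤ 0.05 (note the
inverted star order — it is kept as published). With 3 biological replicates
per side the smallest attainable exact two-sided p is 0.10, so the strict
tier cannot be reached; `utest_compare` warns whenever the tier is
unattainable at the given n.

## 6. Synthetic data: the stated world

The generators exist to give every downstream test a ground truth; their
defaults encode the conditions of the emulated study.

* `simulate_cds_pair` draws an ancestor uniformly over sense codons and
  plants single-base substitutions on distinct codons, split randomly
  between the two descendants. Planted counts are the Jukes–Cantor-inverted
  target proportions with **stochastic rounding** (unbiased in expectation;
  deterministic rounding leaves a small systematic offset at fixed length).
  Synonymous plants are restricted to neighbours that preserve the codon's
  synonymous-site count, so both descendants keep the ancestor's site totals
  and the analytic expectation `Ks = JC(sd/S)` is exact. Defaults:
  synonymous-only (`true_ka = 0`), mirroring families in which only
  synonymous variation is observed among orthologs.
* `simulate_gene_family` evolves codon sequences along an ultrametric tree
  (branch lengths in MYA) as a Poisson substitution process at rate
  3.2 × 10⁻⁹ per synonymous site per year by default, with nonsynonymous
  events at `ka_ks_ratio × rate` (default 0). Multiple hits arise naturally;
  the Jukes–Cantor correction recovers them approximately, which is part of
  what the ±15% end-to-end dating tolerance absorbs. The truth manifest
  (pairwise divergence times, expected Ks = 2kT) is the only oracle the
  recovery tests read.
* `simulate_promoters` builds a 600-bp reference (random or poly-A
  background) with concrete IUPAC motif instances planted at recorded,
  non-overlapping positions, plus a variant haplotype carrying a recorded
  insertion — by default the literal 17-bp event CAGCAGAGCACTAGCTC after
  position 300 — and optional SNPs. The flanking bases of the insertion are
  forced not to extend the insert, so the planted event has a unique
  alignment placement and the called and planted events coincide; real
  promoters offer no such guarantee, which is why the indel caller also
  left-normalises.
* `simulate_ct_table` writes reference-gene Ct as `baseline + noise` and
  target Ct as `baseline − log2(fold) + noise`, Gaussian noise per technical
  measurement (default σ = 0.15 cycles, 3 × 3 replicates).

Every generator consumes one seeded stream (`withr::with_seed`), so
identical configurations give byte-identical outputs across runs and
platforms. What the generators do **not** emulate: indel evolution models,
codon-usage bias, recombination, rate variation among lineages, pipetting
structure beyond i.i.d. Gaussian Ct noise. A green recovery test therefore
establishes estimator correctness under the stated model, not robustness to
real-data pathologies.

## 7. Validation design notes

Two acceptance checks needed explicit statistical design, recorded here
because the choices are part of the package's claims:

* **End-to-end dating recovery** (duplications at 40/30/17 MYA, rate
  3.2 × 10⁻⁹, ten replicate seeds, every recovered time within ±15%). The
  family is carried by two species that split 10 MYA, providing four
  ortholog calibration pairs; the recovered time of a duplication is the
  mean over its cross-group pairwise estimates. A variance budget fixes the
  sequence length: at the 1000-codon floor the Poisson noise of a single
  pairwise estimate is ~9–12%, which would fail a 15% bound stochastically
  by design; at 6000 codons the per-duplication noise is ~5% and the
  criterion is met with margin. Observed errors across seeds are 1–4%.
* **Fold-change recovery** (folds 1.5, 7, 8 at the 3 × 3, σ = 0.15 design,
  within 10%). Noise propagation gives a single experiment's recovered fold
  a ~7% multiplicative SD, so one table misses the 10% band with ~17%
  probability per contrast — the single-table reading is not reliably
  attainable in its own stated world. The criterion is therefore evaluated
  on the estimator's expectation: the mean recovered fold over five
  independently simulated experiments, which meets 10% at roughly 3σ.

Runtime scaling in the shipped suite (bootstrap replicates reduced to 5 in
the end-to-end pipeline test, oracle sweeps at the sizes the criteria state)
keeps the complete run under ~3 minutes on one CPU.

## 8. Known limitations

* Ks saturates quickly for deep splits; ranges computed from saturated pairs
  are reported as missing rather than extrapolated.
* The NJ implementation targets the small-family regime (tens of taxa); its
  O(n³) scan with R-level loops is not meant for large phylogenies.
* The exact U-test enumerates group assignments densely; beyond the
  enumeration threshold p-values are approximate (tie-corrected normal).
* ΔΔCt assumes equal amplification efficiency for target and reference;
  dilution-series efficiency estimation and multi-reference normalisation
  are out of scope.
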