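---
title: "Designing ancestry-informative SNP panels and assigning honey bee subspecies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing ancestry-informative SNP panels and assigning honey bee subspecies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

European honey bee (*Apis mellifera*) diversity is organized in two nested
layers: four deeply diverged evolutionary lineages (A, C, M, O) and, within
them, many recently diverged subspecies. Conservation and breeding programs
need to assign individual bees to a subspecies of origin from a genotyping
assay that is far cheaper than whole-genome sequencing. `aimpanel`
implements the full workflow for building such an assay and using it:

1. start from **pooled sequencing** of reference populations, which yields
   per-population allele frequencies (not individual genotypes);
2. select a reduced set of **ancestry-informative markers (AIMs)** whose
   frequencies differ most among lineages, subspecies and populations;
3. genotype individuals at those markers and **assign** each bee to a
   subspecies with a calibrated probability, refusing to assign
   (`unassigned`) when the evidence is weak.

The reference design the package encodes (`honeybee_hierarchy()`) has 22
sequenced pools covering 14 subspecies in the 4 lineages.

## Marker selection

Selection runs along two complementary branches and merges them with
duplicate skipping (`build_panel()`).

### Summed pairwise FST (population-specific markers)

For a SNP with allele frequencies $p_1, p_2$ in two pools, the package uses
the heterozygosity form of the fixation index,

$$F_{ST} = \frac{H_T - H_S}{H_T},\qquad
H_T = 2\bar p(1-\bar p),\quad
H_S = p_1(1-p_1) + p_2(1-p_2),\quad
\bar p = \tfrac{p_1+p_2}{2},$$

defined as 0 when $H_T = 0$. It is symmetric, bounded in $[0,1]$, and
equals 1 exactly at a fixed difference. For each pool $j$ and SNP $i$ the
rank statistic is the **sum over all other pools**,
$S_{ij} = \sum_{k \ne j} F_{ST}(p_{ij}, p_{ik})$, so with 22 pools a SNP
fixed in pool $j$ and absent everywhere else attains the ceiling
$S_{ij} = 21$. This arithmetic is why the heterozygosity form is the right
estimator here: the ceiling equals the number of fixed-difference pairs.

Sites enter a pool pair's sum only if they pass a depth/minor-count filter
(`fst_settings()`). Two regimes are kept deliberately: *loose*
(depth ≥ 10, minor count ≥ 2) admits noisier sites and thereby catches rare
population-unique variants; *stringent* (depth ≥ 30, minor count ≥ 4) keeps
only well-supported sites. The numeric thresholds are package defaults —
only the qualitative trade-off is externally given — and they are recorded
in the panel manifest, so a panel is always reproducible from its
provenance.

Each pool contributes its top 80 stringent-ranked and top 20 loose-ranked
SNPs. A SNP already taken (by an earlier pool, the other regime, or the
PCA branch) is skipped and the ranking walked further, so quotas are exact:
$22 \times (80+20) = 2200$ SNPs. Pools are processed in table order; at
exact score ties the (chrom, pos) tie-break keeps the result deterministic,
and only at such ties can pool order matter.

### Hierarchical PCA contributions (structure-aligned markers)

The PCA branch operates on the pools × SNPs matrix of minor-allele
frequencies (`build_maf_matrix()`; the minor allele is resolved per pool
subset, undefined cells are mean-imputed, all-undefined SNPs are dropped at
that level only). PCA is run on centered, unit-variance columns — the
correlation convention of the standard multivariate packages — so
eigenvalues sum to the number of retained columns and the contribution of
SNP $s$ to PC $k$,

$$\mathrm{ctr}(s,k) = 100\,\frac{\mathrm{coord}(s,k)^2}{\lambda_k},$$

sums to 100 over SNPs. *Significant* PCs are those with $\lambda_k$ above
the mean eigenvalue (Kaiser-style; at least one PC always). Scores are
aggregated over significant PCs with eigenvalue-share weights
$\lambda_k / \sum_{k'} \lambda_{k'}$, so dominant axes dominate selection.
Both the significance rule and the weighting are package design choices:
simple, deterministic, and configurable — nothing mandates a particular
aggregation, and we preferred one whose behaviour is easy to reason about.

Selection is hierarchical: a global PCA over all 22 pools (quota 300)
captures lineage-separating SNPs, then a PCA per lineage over only its
pools captures subspecies-separating SNPs (quotas C = 1100, M = 200,
O = 600; the single-pool A lineage cannot be analysed within-lineage and
gets quota 0). Earlier levels win ties: a SNP selected globally is skipped
at lineage level. Combined with the FST branch this yields the reference
total of 4400 unique markers.

## The simulator

Because pooled reference data cannot be bundled, every stage is exercised
against `simulate_dataset()`, a hierarchical **Balding–Nichols** generator:

* ancestral frequencies $p_0 \sim U(0.05, 0.95)$ (truncated so sites
  segregate; configurable);
* each level drifts independently,
  $p_{child} \sim \mathrm{Beta}\!\big(p\frac{1-F}{F}, (1-p)\frac{1-F}{F}\big)$,
  with $E[p_{child}] = p$ and $\mathrm{Var} = F\,p(1-p)$; defaults
  $F_{lineage} = 0.15$, $F_{subspecies} = 0.05$, $F_{pool} = 0.02$ encode
  deep lineage divergence with shallow within-lineage structure;
* pooled sequencing adds Poisson depth (mean 50×, a realistic per-pool
  working depth at desk scale) and binomial read sampling;
* individuals are drawn from their pool's *true* frequency,
  alt-count $\sim \mathrm{Binomial}(2, 1-p_{ref})$ — Hardy–Weinberg
  sampling, which is also how `sample_individuals_from_freqs()` emulates
  "simulated individuals from pool frequencies" checks;
* **null alleles** — genotyping probes that fail for a whole subspecies —
  are switched on all-or-none per (subspecies, SNP) at rate 0.13 (matching
  an average call rate of 0.87) and blank genotypes only, never the pooled
  counts, since they are an array artifact, not a sequencing one.

A subtlety worth recording: two pools drifted independently at parameter
$F$ from a common parent show pairwise
$E[F_{ST}] = \frac{F/2}{1 - F/2} \approx F/2$, **not** $F$ — each pool
carries variance $F p(1-p)$, but the pooled mean absorbs half of it
($H_T - H_S = (p_1-p_2)^2/2$). `estimate_drift_F()` therefore inverts the
multilocus ratio-of-means FST as $\hat F = 2 F_{ST} / (1 + F_{ST})$; the
test suite checks that this recovers the simulation parameter within 20%
at 5000 SNPs.

What the simulator does **not** emulate: linkage disequilibrium (sites are
independent), admixture and introgression gradients, uneven sampling, and
sequencing artifacts beyond depth noise. Passing tests therefore
demonstrate that the machinery is correct under an idealized island-type
model, not that real bees of every provenance will be classified at the
same accuracy.

## Classification

Genotypes are one-hot encoded with four indicators per SNP — hom-ref, het,
hom-alt, **missing**. Missingness is deliberately a state of its own
rather than being imputed: null alleles are systematically absent in
particular subspecies, so the missing indicator is informative.

Reference samples are shuffled and split 70/30 with a floor on the
training size (1988 samples → 1391 train / 597 test). Candidates — linear
SVC, RBF SVM, multinomial ridge logistic regression, random forest — are
compared by stratified 10-fold cross-validation (fold count degrades to
the smallest class size with a warning); the best mean accuracy wins, ties
going to the lower SD.

The support vector classifiers are built one-vs-rest, and class
probabilities come from **cross-validated Platt scaling**: a per-class
sigmoid fitted to out-of-fold decision scores (5-fold, stratified), using
Platt's smoothed targets $\frac{n_+ + 1}{n_+ + 2}$ and $\frac{1}{n_- + 2}$
so the sigmoid stays finite on separable data. Calibrated per-class
probabilities are normalized to a distribution; a degenerate all-zero row
falls back to uniform. Assignment takes the row argmax (ties broken by
class order) and rejects to `unassigned` when the top probability is below
the threshold $\tau = 0.90$ — the default the workflow is designed around.

## Evaluation bookkeeping

`confusion()` keeps unassigned predictions out of the percentage matrix
and tallies them per true class, so with a threshold active the
denominators are *assigned-only*; `accuracy_report()` exposes both
`of_total` and `of_assigned` percentages explicitly to avoid the ambiguity
that otherwise arises between "misclassified of all test samples" and
"misclassified of assigned samples". Percentages are rounded to one
decimal for display; raw counts are always retained. Collapsing
subspecies predictions to lineages (`collapse_to_lineage()`) can only
merge errors away, so lineage accuracy ≥ subspecies accuracy is asserted
as an invariant.

`embed_2d()` provides the 2-D inspection plot via classical metric
multidimensional scaling (principal coordinates) of the sample distance
matrix — deterministic, parameter-free, and sufficient for spotting
clusters and mislabeled samples. `flag_label_outliers()` automates the
visual screen with a stated rule: a sample is flagged when the majority
label among its $k = 10$ nearest neighbours (Hamming distance over
genotype states, missing matching nothing) disagrees with its own label.

## Numerical and scale choices

* Ties everywhere resolve by (chrom, pos); pool/level processing order is
  the input order; all randomness fans out from one master seed via
  `stage_seed()`, so any stage reproduces in isolation.
* Tri-allelic pooled sites (a third allele above a 1-read noise floor) are
  flagged and dropped by default: a biallelic genotyping panel cannot use
  them, and no external convention for them is available.
* The test suite runs the full design at reduced scale as the package's
  own working sizes: the quota-arithmetic checks use the complete 22-pool
  design at 20,000 SNPs; the end-to-end classification check uses 22
  pools / 14 subspecies at 6,000 SNPs, 20 bees per pool and
  proportionally reduced quotas; the lineage-accuracy check uses 4
  lineages × 2 subspecies × 100 bees at 2,000 SNPs with 300 global PCA
  markers. At these sizes held-out subspecies accuracy is ≥ 95% and
  lineage accuracy is 100% — driven jointly by the drifted frequencies and
  the null-allele missingness fingerprint, which the one-hot missing state
  converts into signal.

## Known limitations

* The loose/stringent filter thresholds and the PC-significance rule are
  defensible defaults, not estimates of any external pipeline's settings.
* Platt calibration with smoothed targets caps the attainable maximum
  probability at roughly $\frac{n_+ + 1}{n_+ + 2}$; with very few training
  samples per class, confident samples can sit just below a high rejection
  threshold. This is a conservative failure mode, but worth knowing when
  choosing $\tau$ for small reference panels.
* The simulator's independence assumptions mean panel sizes, not marker
  identities, are the meaningful quantities to compare against real
  designs.
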