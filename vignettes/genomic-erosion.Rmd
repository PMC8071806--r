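---
title: "Methods: quantifying genomic erosion with erodr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying genomic erosion with erodr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erodr)
```

`erodr` measures genomic erosion — declining diversity, rising inbreeding,
and shifting deleterious variation — in small populations sampled in two
eras. This vignette documents the statistical definitions, the algorithms,
the synthetic-data model used for validation, and the numerical choices,
with the reasoning behind each.

## Data model

Everything operates on a `variant_dataset`: an ordered biallelic site table
(scaffold, position, REF/ALT, indel flag, ancestral allele, GERP score,
effect category, gene), a sites × samples ALT-dosage matrix in
`{0, 1, 2, NA}`, per-sample metadata (population, era, mean coverage) and
the contig table of retained scaffolds. Derived-allele dosages are computed
on demand by `derived_dosage()`: sites whose ancestral allele is ALT are
flipped (`2 − dosage`), and sites with unknown or mismatching ancestral
state become `NA` so they drop out of load computations while still
contributing to heterozygosity and ROH. This keeps polarization an explicit,
reversible annotation rather than a destructive transformation.

## Site and genotype filters

`apply_site_filters()` applies, in order: per-genotype depth (calls below
1/3 of the sample's mean coverage become missing — low-coverage historical
genomes otherwise inflate apparent homozygosity), per-genotype quality
(GQ < 30 becomes missing), removal of SNPs within ±5 bp (inclusive) of any
indel record along with the indel records themselves (alignment artifacts
cluster there), and removal of masked positions (CpG dinucleotides from
`find_cpg_sites()`, repeats) and of whole excluded scaffolds (sex-linked
scaffolds, which violate the diploid-dosage assumptions; they are also
dropped from the contig table so genome lengths stay consistent). Retained
genotypes are never altered, so the pass is idempotent; a per-rule removal
log is attached to the result.

## Heterozygosity

`genome_heterozygosity()` reports θ = 1000 × (heterozygous SNP calls) /
(callable length). The denominator must count all callable positions, not
just variant sites; absent a per-sample callability track, the retained
scaffold length is the standard approximation, and comparisons between
samples filtered identically are unaffected by its bias.

## ROH detection

The detector formalizes a sliding-window heterozygote-density rule. On one
scaffold's ordered called SNPs, a candidate run is a set of consecutive
SNPs in which **every window of `window_snps` (default 50) consecutive SNPs
contains at most `max_het` (default 1) heterozygotes** — equivalently, the
run contains no `max_het + 1` heterozygotes whose index span is smaller
than `window_snps`. Runs never bridge inter-SNP gaps over `max_gap`
(default 500 kb; a long gap is evidence of missing data, not homozygosity).
Maximal runs are found in linear time from the violating heterozygote pairs
via a suffix minimum of their left-truncation points, then trimmed to their
outermost homozygous SNPs (a run should not be delimited by heterozygotes),
filtered to `min_length` (100 kb) and `min_snps` (25, guarding against
sparse regions), and overlapping trimmed runs merged.

The tolerance of one heterozygote per 50 SNPs absorbs genotyping error in
historical genomes; 100 kb is the conventional shortest reportable ROH and
2 Mb separates recent inbreeding from ancient background. The test suite
checks the detector against an independent exhaustive-scan oracle (per-start
window extension over cumulative heterozygote counts) on 1,000 random
instances; this oracle caught a real indexing defect in the `max_het = 0`
path during development.

`froh()` divides the summed length of segments above a threshold by the
genome length, refusing overlapping input segments.

## GERP-weighted relative load

For one individual, `relative_load()` is

\[
L = \frac{\sum_{i \in S} d_i \, g_i}{\sum_{i \in S} d_i},
\]

where \(d_i\) is derived dosage, \(g_i\) the GERP score and \(S\) the
non-indel sites with known ancestral allele and score above the threshold.
The default threshold 4 targets strongly constrained sites; 1 (all
non-neutral sites) is available for sensitivity analysis because the two
conventions coexist in the literature. A sample with no qualifying derived
allele yields an explicit `undefined` flag rather than 0/0.

`allele_sharing()` classifies deleterious sites as private or shared after
drawing exactly six alleles per population per site **without replacement**
(`rhyper`), equalizing sample sizes so that a better-sampled population does
not appear to hold more private variation. Six alleles (three diploid
genomes) is the largest depth every population can supply in the motivating
design.

## Coding burden, fixation and translocation risk

`burden()` counts, per effect category, the sites at which an individual
carries ≥ 1 derived allele, split heterozygous/homozygous (allele counting
available via `count_alleles = TRUE`). `population_summary()` partitions a
population's LoF sites into fixed (every non-missing genotype homozygous
derived — at the motivating sample sizes a call-rate gate would discard
most sites, so the default `min_call_rate = 0`), private (absent from every
other population) and private-and-fixed. `translocation_risk()` counts the
donor's LoF variants with recipient frequency 0 — the new deleterious
alleles an assisted-gene-flow translocation would introduce — and
`simulate_gene_flow()` re-runs any statistic after copying the donor into
the recipient population (e.g., to count previously fixed variants that
become masked).

## F_ST and the PBS scan

`pairwise_fst()` defaults to Hudson's estimator with per-SNP components

\[
N = (p_1 - p_2)^2 - \frac{p_1(1-p_1)}{n_1 - 1} - \frac{p_2(1-p_2)}{n_2 - 1},
\qquad
D = p_1(1-p_2) + p_2(1-p_1),
\]

(\(n\) = allele counts) combined as a **ratio of averages**,
\(\sum N / \sum D\) — the form that is consistent under SNP aggregation and
robust at small, unequal sample sizes, which is why it is preferred over
averaging per-SNP ratios. Per-SNP negative numerators are retained (they
carry information about sampling noise); only the final estimate is clamped
to \([0, 1]\) as required by the PBS transform. SNPs with under two called
alleles in either population or monomorphic across both are dropped.
Weir–Cockerham (1984) is available for sensitivity analysis and agrees with
Hudson at large balanced sizes.

`pbs()` uses branch lengths \(T = -\log(1 - F_{ST})\) and
\(PBS_A = (T_{AB} + T_{AC} - T_{BC})/2\). The three branches always satisfy
\(PBS_A + PBS_B + PBS_C = (T_{AB}+T_{AC}+T_{BC})/2\), which the tests verify
to 1e-12 on 10,000 random triples. A saturated pair (\(F_{ST} = 1\)) yields
infinite branches, propagated as `Inf` (and `Inf − Inf` on the focal branch
of two saturated pairs is resolved to `Inf`, since the focal branch is the
shared cause); `cap_and_call()` then replaces `+Inf` with the population's
maximum finite PBS and `−Inf` with its minimum — capping, rather than
dropping, keeps genuinely extreme genes in the outlier set without letting
them dominate percentiles. Outliers are genes strictly above PBS 3; the
99.8th percentile of the capped distribution (type-7 quantile, R's default
linear interpolation) is reported for context.

## Group comparisons

`pairwise_t_tests()` runs two-sided Welch t-tests for every group pair —
Welch because group sizes of 3–8 with unequal variances make the pooled
test anticonservative; Student's is available by flag. No multiple-testing
adjustment is applied by default (matching the descriptive reporting style;
`p_adjust` accepts any `stats::p.adjust` method). `percent_difference(a, b)`
is `100(a − b)/b` and `fold_change(modern, historical)` is their ratio. The
acceptance suite calibrates the t-test's type-I error to 0.05 ± 0.03 under
a symmetric null built by splitting one simulated population into two
arbitrary groups.

## The synthetic-data generator

`simulate_dataset()` draws, per site: an ancestral frequency from a
symmetric Beta(0.5, 0.5) (a U-shaped spectrum qualitatively matching a
neutral site-frequency spectrum), per-population frequencies from the
**Balding–Nichols** model with drift parameter `fst` (so the expected
Hudson F_ST between two populations each drifted by \(F\) is \(F\) — used
as a generator check), and binomial genotypes. Inbreeding is planted
explicitly: per sample, non-overlapping tracts are drawn from a length
mixture (60% uniform 100–500 kb, else 1–5 Mb, spanning the observable ROH
range) until the target genome fraction is reached, and all genotypes
inside a tract are overwritten with homozygous calls — homozygous derived
with probability equal to the site's population frequency, which is what
identity by descent of two haplotypes produces under random mating. The
truth tables record the **planted** tracts and fraction, the per-population
frequencies and the per-site deleteriousness labels, so parameter recovery
is judged against what was actually planted.

GERP scores come from a three-class mixture (20% constrained in (4, 6),
20% intermediate (1, 4), 60% neutral (−3, 1)); genes are placed to cover
~30% of the genome, with in-gene sites labeled synonymous/missense/LoF at
0.5/0.4/0.1; 2% of records are 2-bp indels; 10% of SNPs have an
ALT-ancestral allele to exercise polarization; per-genotype depths are
Poisson around each sample's mean coverage (9–29X). The default
`simulation_config()` mirrors a three-population, two-era, 19-genome study
with inbreeding targets rising sharply in the most recently collapsed
population.

Realism limits, stated plainly: sites are independent (no linkage except
the planted tracts), the frequency model has no mutation/selection balance
(so deleterious classes have neutral frequency spectra), indels carry no
real alleles, and genotype quality is a constant 99 unless perturbed.
These are deliberate: each omission keeps a closed-form expectation
available for a test.

Two calibration facts found while testing, recorded rather than hidden:
tract placement is best-effort — on miniature genomes (≲ 10 Mb) with long
tracts and high targets, gap fragmentation can undershoot the requested
fraction (hence truth records the planted value; at the 50 Mb study scale
the shortfall is < 0.015); and at 200 haplotypes a sample frequency within
0.05 of the truth for 99% of sites is not attainable (binomial noise alone
exceeds it), so recovery tests use a 0.1 bound.

`simulate_selection_scan()` plants exactly one gene whose focal-population
frequencies are drawn with a much larger drift parameter (0.6 vs 0.05
background), giving a known outlier for power measurement: the planted gene
ranks in the top 1% of focal PBS in ≥ 9/10 seeds at 200 genes × 50 SNPs ×
10 diploids per population.

## Problem sizes and budgets

The shipped configurations are sized for laptop-scale determinism: 25,000
sites on a 50 Mb genome for the study design (full pipeline in seconds),
1,000 random instances ≤ 500 SNPs for the ROH oracle (≈ 25 s), 10 scan
seeds for selection power (≈ 1 min), and 200 null simulations for t-test
calibration (≈ 30 s). The whole test suite runs in under a minute; the
acceptance script (`scripts/acceptance.R`) in well under one.
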