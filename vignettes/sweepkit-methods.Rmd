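---
title: "Detecting selection and breed-discriminant variants with sweepkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting selection and breed-discriminant variants with sweepkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepkit)
library(dplyr)
```

sweepkit implements the comparative-genomics toolchain used to characterise
a phenotypically distinctive chicken breed -- the North American Araucana
(NAA), kept for blue eggshells, ear-tufts, a pea comb and rumplessness --
against reference breeds (Korean Araucana, Korean Domestic, White Leghorn)
from a jointly called multi-sample SNP set. Three statistical components
carry the analysis, and everything else in the package exists to feed,
validate or summarise them:

1. a **creeping-window pooled-heterozygosity (ZHp) scan** that finds genomic
   regions where one group's variation has collapsed, the signature of a
   selective sweep;
2. a **random-forest discriminant analysis** that ranks individual SNPs by
   how strongly they separate the focal group from all others, validated by
   multidimensional scaling of the forest's proximity matrix and a
   Monte-Carlo permutation test of the Davies-Bouldin cluster-separation
   index;
3. **trait-confirmation logic**: two-locus genotype classification for
   rumplessness, carrier-pattern filtering of structural-variant deletion
   tables for the ear-tuft trait, and read-depth log2 copy-number ratios for
   the pea-comb duplication.

The package also ships a synthetic-data generator so each stage can be
exercised and tested end-to-end without access to the original sequencing
data.

## Site filtering

Variants enter the pipeline as a long tidy table (one row per site per
sample) read from a multi-sample VCF. The default `filter_criteria()`
reproduce a stringent post-calling filter: biallelic single-base SNPs on
autosomes, site QUAL strictly above 40, RMS mapping quality (INFO `MQ`)
strictly above 40, per-sample depth of at least 3 in *every* sample, and no
missing genotypes. The strict/non-strict boundaries (`QUAL > 40`, `MQ > 40`,
`DP >= 3`) follow the filter's printed definition literally; the boundary
cases are pinned by tests. MQ is taken from the site-level INFO field
because per-read mapping qualities are no longer available in a VCF.

Rejections are tallied by the *first* failing rule in the fixed order
autosome, SNP, biallelic, QUAL, MQ, DP, missingness. The kept set is
order-independent; only the attribution needs a convention. An optional
greedy LD pruner (`ld_prune()`, r² 0.2 within 500 kb) is provided for
relatedness analyses but no default pipeline applies it, because the
corresponding thinning step in the original toolchain is under-documented.

## Relatedness views

Group structure is established before any discriminant analysis.
`ibs_dissimilarity()` computes 1 − identity-by-state from dosages (equal to
half the mean absolute dosage difference), feeding an average-linkage
dendrogram exportable as Newick. `pca_embed()` uses Patterson scaling --
dosages centred by twice the allele frequency and scaled by
`sqrt(2p(1-p))` -- so PCs are comparable to the population-genetics
standard. Monomorphic columns carry no information under this scaling and
are dropped.

## The creeping-window ZHp scan

Windows grow SNP-by-SNP from each start SNP subject to three rules: the
window spans at most 40 kb, adjacent SNPs are less than 10 kb apart (a gap
of exactly 10 kb breaks the window), and only windows with at least 50 SNPs
are scored. These defaults are the published parameterisation of the method;
all are exposed in `window_params()`. Because the publication does not state
how window starts advance, `start_step` defaults to 1 (a window attempted at
every SNP) and is exposed; we make no attempt to reproduce the original
study's window *counts*, which depend on that unstated choice.

Per window, allele observations are pooled across the group's samples. The
default counting mode pools the AD allele-depth fields (read counts), since
the statistic is sensitive to the number of reads observed; a genotype mode
(two observations per sample per site) supports AD-less VCFs. With pooled
major/minor sums the window's pooled heterozygosity is

$$ H_p = \frac{2\,\Sigma n_{MAJ}\,\Sigma n_{MIN}}{(\Sigma n_{MAJ}+\Sigma n_{MIN})^2} \in [0, 0.5], $$

zero when the minor allele disappears (fixation) and 0.5 at perfect balance.
Site-level ties contribute equally to both sums. ZHp standardises Hp by the
mean and *sample* standard deviation across all windows of the scan --
genome-wide by default, per-chromosome behind a flag (the original
presentation pools chromosomes into one genome-wide panel, which is what the
default mirrors). Windows with ZHp ≤ −6 are classified as strong selection,
−6 < ZHp ≤ −4 as suggestive, both boundaries inclusive.

Strong windows whose intervals overlap or abut merge into sweep regions
(`merge_sweep_regions()`), reported with window count, mean and sample-SD of
member ZHp (SD is reported absent for single-window regions) and overlapping
gene names. `zhp_summary()` reports distribution statistics with the mode
computed after rounding to two decimals, matching how such tables are
printed.

### The half-set robustness check

Because pooled-read statistics scale with group size, a sweep found in a
six-bird group is re-checked in a phenotype-balanced half of that group:
`half_set_check()` stratifies the group by a trait column (largest-remainder
rounding of stratum targets, error if the requested balance is impossible),
re-runs the identical scan on the subset, and reports each full-set strong
region's subset window count, mean/SD ZHp and whether the subset mean stays
at or below the suggestive threshold (−4). "Pass" is defined on the region
mean, matching how half-set results are summarised in the motivating study.

## Random-forest discriminant markers

`fit_random_forest()` wraps the canonical `randomForest` implementation on
the dosage matrix with focal-vs-rest labels: 500 trees, `mtry =
floor(sqrt(p))`, OOB-restricted proximities, per-feature permutation
importance (raw mean decrease in accuracy). Those are the de-facto defaults
of the implementation the field uses, and all are exposed.

Two practical caveats are worth stating plainly. First, exact MDA values are
not invariant to feature order under a fixed seed -- the tree-growing RNG
stream is tied to column indices -- so stability should be judged on the
recovered marker *set*, which is what the tests do. Second, with few samples
and thousands of features, MDA *rankings* converge much more slowly than
classification accuracy: 500 trees classify perfectly long before the
relative order of near-equivalent top markers settles. The package's
recovery experiments therefore run 3,000 trees; with 500 trees an
occasional planted marker drifts to rank ~100 purely from importance-
estimation noise. If you need a stable ranked list, grow more trees than
you would for prediction.

Separation is validated on the 2-D classical (Torgerson) MDS of
`1 − proximity`. The Davies-Bouldin index
$DB = \text{mean}_i \max_{j\ne i} (s_i+s_j)/d(c_i,c_j)$
summarises cluster quality (lower = tighter, better separated), and
`db_permutation_test()` permutes labels over the fixed embedding, preserving
class sizes, reporting the plus-one-corrected
$p = (1 + \#\{DB_{perm} \le DB_{obs}\})/(n_{perm}+1)$. With the default 999
permutations the smallest achievable p is 1/1000, matching a "< 0.001"
report. Labels are permuted on the embedding (not refit through the forest),
which tests the geometric separation the MDS plot displays.

`select_candidate_markers()` applies the published candidate rule while
walking the MDA-ranked list: the site must (a) not be intergenic per the
supplied annotation, (b) carry the alternate allele in a strict majority of
focal samples (4 of 6 qualifies, 3 of 6 does not), and (c) show the
discriminant pattern -- every focal sample het or hom-alt, every non-focal
sample het or hom-ref. Note (c) implies (b) whenever it holds; both are
enforced for transparency. `nearest_genes()` reports the ten nearest genes
per marker by interval distance (0 inside a gene; negative 5'-ward, positive
3'-ward; ties to the lower gene start), filtered to ±40 kb -- the scale at
which linkage disequilibrium decays in chicken, which bounds how far a
regulatory marker plausibly acts.

## Trait confirmation

**Rumplessness (Rp).** Two linked SNPs upstream of the IRX1/IRX2 cluster
(SV1 chr2:86,770,373; SV2 chr2:86,870,271; A reference, C alternate) track
the dominant rumpless trait. `classify_rp_genotype()` treats genotypes as
unordered pairs and reports the joint class: wildtype, het at both, hom-alt
at both, mixed het/hom, or -- flagged as a violation because it has never
been observed -- a variant at exactly one locus. `tabulate_rp()` builds the
phenotype × class contingency table and the violation list (single-locus
variants, and tailed birds carrying any variant class). The shipped
genotyping records total 142 birds; the study text says 141, an arithmetic
discrepancy in the source that the package surfaces by reporting the
tabulated sum.

**Ear-tufts.** Deletion calls on chromosome 15 are filtered by carrier
pattern. `tufted_specific_deletions()` keeps records present (0/1 or 1/1,
pass-filter or unfiltered call alike; a strict pass-only mode exists) in at
least one tufted bird and absent in every clean-faced bird;
`candidate_tuft_deletion()` applies the sharper dominant-hemizygous
signature -- heterozygous in *every* tufted bird, absent in all others. On
the shipped 21-record table these rules keep 7 and exactly 1 record
respectively; the surviving record (15:1,019,583–1,027,972, 8,389 bp, an
entire TXNRD2 exon) is the ear-tuft candidate. Deletion size follows the
breakpoint convention `stop − start`, which every printed record obeys. The
published table's sample header is garbled (one bird twice, one never); the
shipped fixture assigns columns NAA01–NAA06 in order, consistent with the
published per-bird phenotypes, and documents the correction.

**Pea comb.** Depth-window counts (4 kb grid) for a test/reference sample
pair yield `log2((x_t/N_t)/(x_r/N_r))` with `N` the sample's total count; a
two-sided p-value comes from the normal approximation to the log-ratio of
two Poisson counts (variance `1/x_t + 1/x_r` on the natural-log scale), the
model of the upstream depth-comparison tool. Windows with a zero count are
flagged undefined and excluded from medians. Significant copy-number
segments are maximal runs of ≥ 4 grid-consecutive windows with p ≤ 0.001 and
|log2| ≥ 0.6, sign-consistent within the run. `region_median_log2()` and
`cnv_region_median_matrix()` reproduce the pairwise region-median summary
used to confirm the SOX5 intron-1 duplication; all defined overlapping
windows enter the median (whether only significant windows did in the
original summary is unstated; using all is the conservative choice).

A design note on precision: the per-window log2 ratio at depth ~100 has a
standard deviation of ~0.15, so a median over the 4 windows of a 14 kb
region is reproducible only to ~±0.2 per sample pair. Duplication-recovery
checks therefore either aggregate across sample pairs (as the original
pairwise table does) or use longer planted duplications, and planted
duplications are kept small relative to the simulated genome so that
total-count normalisation does not absorb the signal.

## The synthetic-data generator

`simulate_genotypes()` emulates the joint, filtered SNP set the analyses
assume, not raw reads. Ancestral allele frequencies are Uniform(0.05, 0.95);
group frequencies follow the Balding-Nichols construction (Beta with mean
`p`, variance `fst·p(1−p)`), the standard stand-in for population structure
when no generative model is published; diploid dosages are Binomial(2, q).
Depth is Poisson floored at one read; allele depths are Binomial(DP,
dosage/2); QUAL and MQ are Uniform(41, 100) so simulated sites survive the
default filters (a `low_quality_rate` knob plants filter violations, and
`missing_rate` plants missing genotypes, because the defaults -- matching a
0%-missing filter -- would otherwise never exercise those rules).

The default fixture is desk-scale: 2 chromosomes × 2 Mb at 1 SNP/200 bp
(~20k sites), 15 samples in the four-group design (6+3+3+3), divergence
fst = 0.1, and one planted 100 kb full-fixation sweep in the focal group.
These sizes keep a full scan under a second while leaving ≥ 50 SNPs per
40 kb window on average, and the published effect sizes being unavailable in
allele-frequency terms, the planted effects are chosen for testability:
full fixation for sweeps, the exact discriminant pattern for markers, 8-fold
for duplications.

Planting operators are deterministic given the RNG seed: `plant_sweep()`
raises the group's major allele to the target frequency (never lowering an
existing majority, so `fixation = 0.5` is a no-op), rewriting allele depths
to match; `plant_discriminant_markers()` rewrites chosen sites to the
alternating het/hom-alt focal pattern with hom-ref elsewhere. Fixtures
round-trip byte-identically through the VCF/GFF3/TSV/JSON writers.

One fixture choice deserves its own paragraph. Marker-recovery experiments
plant into an `fst = 0` background. Under a divergent background
(fst = 0.1), among 5,000 sites roughly 1–2% satisfy the full candidate
genotype pattern by drift alone -- occasionally perfectly. Those sites are
genuine breed discriminants, indistinguishable in kind from planted ones, so
"recover exactly the planted set" is only a well-posed question against an
exchangeable background where planted markers are the sole systematic
focal-vs-rest signal. The sweep-recovery fixture keeps fst = 0.1, where the
planted signal (fixation) is qualitatively distinct from background
divergence.

### What the generator does not emulate

Linkage disequilibrium between background sites (frequencies are drawn
independently per site), mutation-model realism (ref/alt bases are
arbitrary), depth heterogeneity along the genome, alignment and calling
artifacts, indel/SV read evidence, and sex chromosomes. Consequently,
passing recovery tests demonstrate that the statistics and selection rules
behave as specified under their own assumptions -- they do not certify
performance on real resequencing data, where LD, batch structure and calling
error move thresholds.

## Numerical and degenerate-input conventions

Coordinates are 1-based closed everywhere internally; BED export converts to
0-based half-open. ZHp uses the sample SD; standardisation is checked to
1e−9. `zhp_standardize()` refuses constant input (sd = 0) rather than
returning NaN. Window construction refuses unsorted positions. Hp requires a
positive pooled total. Single-window regions and single-score summaries
report SD as absent rather than 0. The DB index refuses coincident
centroids; degenerate (all-equal) proximities refuse to embed. Interval
merging treats abutting closed intervals (`next start = stop + 1`) as one
region. Mode reporting rounds to 2 decimals first and breaks ties toward
the smallest value.

## Worked example

```{r example, eval = FALSE}
fx <- default_fixture(seed = 1)
filt <- apply_site_filters(fx$table, filter_criteria())
scan <- sweep_scan(filt$sites, fx$panel, "NAA")
glance(scan)
merge_sweep_regions(scan)
half_set_check(filt$sites, fx$panel, "NAA", seed = 1) |> tidy()
autoplot(scan)
```

Problem sizes throughout the test-suite and the acceptance script are the
fixture defaults above (20k-site scans, 5k-site forests at 3,000 trees,
16.5k-window depth grids), chosen so a complete run stays in the minutes
range on a laptop while every stochastic recovery property is measured over
20–50 seeds.

## Known limitations

The scan reports no significance beyond the fixed ZHp thresholds (the
method's convention); no LD-aware null is attempted. Proximity-based MDS is
sensitive to forest size at small n. The CNV p-value is an approximation
that ignores overdispersion of real sequencing depth. The candidate-marker
rule is a hard pattern filter: one genotyping error in the focal group
removes a true marker, which is faithful to the rule but fragile on real
data.
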