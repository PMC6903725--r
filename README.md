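# sweepkit

Selective-sweep scanning and breed-discriminant variant analysis for
multi-sample genotype data, built around the comparative-genomics workflow
used to dissect the North American Araucana (NAA) chicken — a breed kept for
blue eggshells, ear-tufts, a pea comb and rumplessness — against reference
breeds from a jointly called SNP set.

## Who this is for

Population / livestock geneticists with a filtered multi-sample VCF (plus a
sample-to-group panel and gene annotations) who want to locate regions under
artificial selection, rank SNPs that discriminate one group from the rest,
and confirm candidate trait variants from structural-variant tables and
read-depth windows — all from tidy data frames in R.

## What it computes

**Creeping-window pooled heterozygosity (ZHp).** Windows grow SNP-by-SNP
(span ≤ 40 kb, inter-SNP gaps < 10 kb, ≥ 50 SNPs). Per window, allele
observations are pooled across the group's samples (read-count AD pooling by
default) and

&nbsp;&nbsp;&nbsp;&nbsp;H<sub>p</sub> = 2 Σn<sub>MAJ</sub> Σn<sub>MIN</sub> / (Σn<sub>MAJ</sub> + Σn<sub>MIN</sub>)²,
&nbsp;&nbsp;&nbsp;&nbsp;ZH<sub>p</sub> = (H<sub>p</sub> − μ̂) / σ̂ (genome-wide),

with ZHp ≤ −6 classified as strong selection and ZHp ≤ −4 as suggestive.
Strong windows merge into sweep regions with per-region summaries, and a
phenotype-balanced half-set rerun checks robustness to group size.

**Random-forest discriminant markers.** Focal-vs-rest random forest on the
dosage matrix; SNPs ranked by mean decrease in accuracy; cluster separation
shown by classical MDS of the forest proximity matrix and tested by a
Monte-Carlo permutation of the Davies-Bouldin index
(p = (1 + #{DB<sub>perm</sub> ≤ DB<sub>obs</sub>}) / (n<sub>perm</sub> + 1)).
Candidate markers follow the published genic-context + genotype-pattern
rule, with nearest-gene reports within ±40 kb (the LD scale in chicken).

**Trait confirmation.** Two-SNP rumplessness genotype classes and
phenotype-concordance tables; tufted-specific and all-tufted-heterozygous
deletion filters over structural-variant tables; CNV-style depth-window
log2 ratios with Poisson-approximation p-values, significant-segment calls
(≥ 4 consecutive windows, p ≤ 0.001, |log2| ≥ 0.6) and region medians.

**Synthetic data.** A Balding-Nichols group-divergence simulator with
planted sweeps, discriminant markers, deletions and duplications (plus truth
tables), so the whole pipeline is testable offline; fixtures round-trip
byte-identically through VCF/GFF3/TSV/JSON writers.

## Worked example

```r
library(sweepkit)
library(dplyr)

fx   <- default_fixture(seed = 1)          # 15 samples, 4 groups, ~20k SNPs,
                                           # one planted 100 kb sweep in NAA
filt <- apply_site_filters(fx$table, filter_criteria())
scan <- sweep_scan(filt$sites, fx$panel, "NAA")
glance(scan)
#> # A tibble: 1 × 7
#>   group n_windows hp_mean  hp_sd min_zhp n_suggestive n_strong
#>   <chr>     <int>   <dbl>  <dbl>   <dbl>        <int>    <int>
#> 1 NAA       19902   0.335 0.0507   -6.61          102      337

merge_sweep_regions(scan)
#> # A tibble: 1 × 7
#>   chrom  start    stop n_windows mean_zhp sd_zhp genes
#>   <chr>  <int>   <int>     <int>    <dbl>  <dbl> <chr>
#> 1 1     997195 1102233       337    -6.59 0.0872 ""
```

The 337 windows with ZHp ≤ −6 merge into a single strong-selection region
that recovers the planted 1.00–1.10 Mb sweep (window extension reaches a few
kb beyond the planted boundaries by construction). The half-set check reruns
the scan on a phenotype-balanced half of the group; the region's subset mean
ZHp (−4.37 here) staying at or below −4 is reported as a pass:

```r
half_set_check(filt$sites, fx$panel, "NAA", seed = 1) |> tidy() |>
  select(chrom, start, stop, sub_n_windows, sub_mean_zhp, pass)
#> # A tibble: 1 × 6
#>   chrom  start    stop sub_n_windows sub_mean_zhp pass
#>   <chr>  <int>   <int>         <int>        <dbl> <lgl>
#> 1 1     997195 1102233           715        -4.37 TRUE
```

The shipped study tables work the same way:

```r
del <- araucana_deletions()                 # 21 chr15 deletion records
tufted_specific_deletions(del, araucana_panel()) |> distinct(start, stop)  # 7 records
candidate_tuft_deletion(del, araucana_panel()) |> distinct(start, stop, gene)
#> 1019583 1027972 TXNRD2                     # the 8,389 bp ear-tuft candidate

tabulate_rp(rp_genotyping_records())
#> Rp genotype x phenotype table ( 142 birds ) ...
```

`autoplot()` methods draw the Manhattan-style ZHp panel, PCA and MDS plots;
`tidy()`/`glance()` return tibbles from every fitted object.

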