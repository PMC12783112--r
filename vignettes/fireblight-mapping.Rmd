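---
title: "Methods: tGBS genotype calling and F1 fire-blight association mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tGBS genotype calling and F1 fire-blight association mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbsmap)
library(dplyr)
```

## The problem

Reduced-representation sequencing (tunable genotyping-by-sequencing,
tGBS) genotypes large biparental populations cheaply: each sample yields
a pileup of base observations at restriction-site-adjacent loci, and
SNP genotypes are called from per-allele read support. In an F1 cross
between two heterozygous apple parents, markers segregate 1:1 (one
parent heterozygous) or 1:2:1 (both heterozygous), and a quantitative
disease phenotype — here percent lesion length (PLL) after fire blight
inoculation, necrotic shoot length divided by total shoot length —
can be mapped by comparing phenotype distributions between progeny
allele groups at every SNP.

`gbsmap` implements that chain as composable, data-frame-first
functions: read-support genotype calling with explicit depth/fraction
thresholds, per-site segregation filters, PLL aggregation, a per-SNP
Wilcoxon rank-sum scan with a Bonferroni genome-wide threshold, plus
gene-annotation summaries used to sanity-check an assembly. A synthetic
F1 generator supplies data with the statistical structure the analysis
assumes, so the whole pipeline runs — and is tested — without any
external data.

## Genotype calling

Calling proceeds in two steps on filtered base observations. A base
observation is ignored when the variant sits in the first or last 3 bp
of its read (`edge_mask_bp`, alignment artefacts concentrate at read
edges) or has PHRED quality below 20 (`min_phred`, a 1% error bound).

**Step 1 (discovery)** makes a provisional call per sample:
homozygous when the unique top allele has ≥ 5 reads making up ≥ 80% of
reads at the site; heterozygous when the top two alleles each have
≥ 5 reads and ≥ 30%. A site is polymorphic when at least two distinct
alleles occur across all provisional calls. The thresholds are applied
per sample; whether discovery should instead pool reads across samples
is not determined by the calling rules themselves, so the per-sample
interpretation is the default and the configuration object keeps it
explicit.

**Step 2 (classification)** calls each sample at each polymorphic
site: homozygous if ≥ 5 reads support the major allele covering ≥ 90%
of reads; otherwise heterozygous if the two most frequent alleles have
≥ 2 reads each, each strictly > 20% of reads, and combined ≥ 5 reads
covering ≥ 90%; otherwise missing. The strict `>` is used only for the
20% condition, `≥` everywhere else, mirroring the rule statement. The
two conditions cannot both hold (a minor allele above 20% caps the
major below 80%), which the test suite verifies by exhaustive
enumeration of all count vectors over three alleles up to depth 15,
against an independent straight-line transcription of the rules.

Two tie policies make the caller deterministic and order-independent:
a tied top pair becomes the heterozygous candidate pair (the
homozygous condition cannot fire on a tie at its default fractions),
and a tie extending to a third allele makes the pair ambiguous, hence
missing. "Reads" are distinct observation records; the package has no
alignment layer, so no duplicate collapsing by mapping coordinates is
attempted.

Fraction comparisons use a 10^-9 tolerance so that printed boundary
cases (9/10 = 90%) are decided exactly rather than by floating-point
rounding.

## Site filtering

Per site, summaries are computed from called genotypes (two allele
draws per called sample, parents excluded by default — the filters
describe progeny segregation): call rate, observed alleles, allele
frequencies *p* and *q*, genotype classes, MAF and heterozygosity
rate. A site is kept when call rate ≥ 50%, exactly 2 alleles, ≥ 2
genotype classes, MAF ≥ 10% and heterozygosity rate within
[0, 2pq + 0.20] — a Hardy–Weinberg expectation plus slack. Genotype-level
(not read-level) frequencies feed the bound, since the bound compares
against a genotype-derived heterozygosity rate. The filters are
conjunctive; evaluation order matters only for the reported reason
code, fixed as call_rate, allele_number, genotype_classes, maf,
het_range. For a fully-typed 1:1 marker the expected heterozygosity is
0.5 with p = 0.75, so the bound 2(0.75)(0.25) + 0.2 = 0.575 admits it
comfortably.

Residual missing genotypes would, in the study pipeline, be imputed by
an external phasing-based imputer before downstream use;
`impute_genotypes()` is a deliberate pass-through marking that slot.

## Phenotype aggregation

PLL is averaged per genotype and year over replicate shoots, then over
years. Mean-of-year-means (rather than pooling shoots) is the default
so unequal replicate counts cannot weight one year; a pooled mode is
available. Genotypes measured in a single year use that year's mean.
How the original trials handled missing replicates is not stated
anywhere authoritative, so these defaults are documented package
choices, not reconstructions. Between-year agreement is summarised by
Pearson correlation over genotypes with both years (Spearman
available).

## Association scan

At each SNP with MAF ≥ 0.05 among the tested progeny, the susceptible
parent anchors the grouping: the non-reference allele is the allele
the susceptible parent does not carry homozygously; group 1 holds
carriers of at least one non-reference allele, group 2 the remaining
called progeny. SNPs where the susceptible parent is heterozygous or
missing are skipped with a reason code — with a heterozygous reference
the susceptible allele is unidentifiable without phase, and silently
guessing would bias the scan.

Groups are compared with a Wilcoxon rank-sum test: midranks for ties;
an exact two-sided p (full null distribution of the rank sum,
equivalent to enumerating all C(n1+n2, n1) assignments, computed by
dynamic programming) when both groups have ≤ 25 observations and no
ties; otherwise a normal approximation with tie-corrected variance and
continuity correction. The switch mirrors common statistical practice;
25 keeps the exact path exact wherever it is affordable. With roughly
60/60 progeny per group the scan therefore runs on the approximation,
which agrees with the exact tail within 0.01 for tie-free groups of
10–20 (verified on a grid).

The genome-wide threshold is −log10(α/N) with α = 0.01 and N the
number of SNPs actually tested — after the MAF filter and skips — not
the number submitted. Bonferroni is the only correction offered,
matching the procedure the package reproduces; FDR is deliberately not
added. Results tidy into a tibble (`tidy()`), summarise into one row
(`glance()`), and plot as a Manhattan panel with the dashed threshold
(`autoplot()`).

## The synthetic generator

`sim_config()` fixes the study conditions the validation runs under:

* **Population**: 119 progeny plus the two parents; up to five
  replicate shoots per genotype in each of 2024 and 2025, 10% of
  shoots missing.
* **Genome**: 17 chromosomes of 35 Mb; marker positions uniform;
  genetic positions from a linear 4 cM/Mb conversion — no published
  genetic map is assumed, and a single linkage knob keeps the model
  inspectable. Crossovers follow Haldane's mapping function
  r = (1 − e^(−2d/100))/2 (no interference).
* **Markers**: biallelic; 40% heterozygous in parent 1 only, 40% in
  parent 2 only, 20% in both. Only the parent-2-heterozygous class is
  informative for the susceptible-parent grouping, so roughly 40% of
  simulated markers enter the scan.
* **QTL**: a single marker at the top of chromosome 3, heterozygous in
  the resistant parent, homozygous in the susceptible one. Carriers of
  the resistance allele draw per-shoot PLL from N(25, 15²), non-carriers
  from N(60, 15²), truncated to [0, 100] by rejection resampling —
  truncation by clamping would pile probability mass at the bounds and
  distort rank statistics. A single QTL is the default because the
  validation locus is single; the QTL marker is configurable.
* **Reads**: per sample × site depth from a negative binomial with
  mean 20 and size 5 (GBS depth is overdispersed relative to Poisson;
  size = Inf recovers Poisson), uniform read offsets over a 75 bp read,
  0.2% uniform base-error rate, 5% of bases below Q20.

The generator emulates what the calling and scanning rules consume:
segregating biallelic pileups with depth, error, read-position and
quality structure, and a replicated single-QTL phenotype. It does not
emulate restriction-site selection, alignment artefacts beyond the
read-edge effect, PCR duplicates, allele-specific bias, population
structure, or polygenic backgrounds — so green tests certify the
implemented rules and their statistical behaviour under the assumed
model, not performance on any real dataset.

All randomness flows from one seed (`random_seed`);
`simulate_f1_dataset()` and `run_pipeline()` seed once and draw in a
fixed order, making outputs bit-identical across runs, and
`write_fixtures()` emits byte-stable plain-text interchange files.

## Annotation summaries

`summarize_annotation()` reports gene/exon/CDS counts and lengths
(1-based inclusive) with the single-transcript identities
introns = exons − genes and intron length = gene − exon length; for
multi-transcript GFF3 input the longest transcript represents each
gene. `windowed_density()` tiles chromosomes with 50 kb half-open
windows (trailing partial window kept) and assigns features by start
coordinate. `interval_length()` returns end − start: that
exclusive-style convention — not the inclusive length — is what
reproduces the quoted 4,164 bp span of the FB_Mr5 homolog between
positions 598,337 and 602,501, and the discrepancy with inclusive GFF3
lengths is intentional and documented.

## Verification sizes and numerical choices

The test suite validates calibration and power on noiseless
truth-derived genotype calls (via `genotypes_from_truth()`), which
isolates the scan's statistical behaviour from read noise — read-level
calling fidelity has its own error-free-reads test. Sizes used: 20
replicates of 119 progeny × ~2,000 markers (17 × 118) for both the
null calibration (no QTL: at most one replicate in twenty may show any
SNP above the threshold) and QTL recovery (best-p SNP within 2 Mb of
the QTL and above the threshold in ≥ 18/20 replicates); the read-level
pipeline demonstration uses 510 markers at mean depth 20 for ~1.2
million base observations. Exhaustive caller checks run over all 816
count vectors of depth ≤ 15 over three alleles.

## Known limitations

* No alignment, imputation or phasing; inputs begin at the pileup
  table.
* The scan offers no kinship or structure correction — appropriate for
  a single biparental family, wrong for diversity panels.
* Susceptible-parent-heterozygous markers are skipped rather than
  rescued via the resistant parent, discarding some informative sites.
* Effect sizes are not estimated; the scan reports group sizes, the
  rank-sum statistic and p-values only.
* Multi-allelic sites are excluded by the allele-number filter and the
  scan's biallelic grouping.
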