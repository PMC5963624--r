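---
title: "Cohort contrasts by recurrence-free survival: models, thresholds and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cohort contrasts by recurrence-free survival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rfscontrast)
```

## Setting

The package compares cohorts of IDH1 wild-type glioblastoma grouped by
recurrence-free survival (RFS): short (S, under 6 months), medium (M,
16–23 months) and long (L, over 25 months). Exome-level analyses contrast
S against L over the exome-sequenced samples only (the `wes` flag in the
manifest); transcriptome analyses use all samples (`wts`). All operations
consume tidy tibbles produced by the package readers, so any upstream
variant caller or expression quantifier can feed the pipeline through the
documented TSV dialects or VCF.

## Counting conventions

Two distinct counting conventions coexist, deliberately:

* **Occurrence counts** (`summarize_burden()`): each record — one variant
  observed in one sample — counts once. A variant carried by four samples
  contributes four. These are the right units for "total molecular
  alterations per group", and the coding/deleterious sub-totals nest
  (`deleterious ⊆ coding ⊆ total`) because the deleterious flag is defined
  only for coding variants.
* **Distinct-key counts** (`gene_burden()`): within a gene, variants are
  identified by `(chrom, pos, ref, alt)` — sample- and
  annotation-independent — and counted once per sample and once per group
  however many samples share them. This makes a per-gene group count a
  property of the gene rather than of cohort size, and it is the only
  convention under which "the same variant shared by every sample" is one
  countable event. Hypermutation flagging and the recurrent-gene rule use
  distinct keys.

Variant identity excludes the gene symbol on purpose: identity should not
change if annotation sources disagree about gene boundaries.

## Thresholds

| Parameter | Default | Meaning |
|---|---|---|
| `hyper_threshold` | 50 | gene is hypermutated in a group iff distinct variants **>** 50 (strict) |
| `min_variants` | 4 | recurrent group-private gene: distinct variants **>** 4, every group sample mutated, other group wild type |
| `alpha_fdr` | 0.05 | BH FDR level defining significant DEGs |
| `cnv_cutoff_tumor_normal` | 1.0 | central log2-ratio call threshold, tumor vs normal |
| `cnv_cutoff_groups` | 0.8 | central log2-ratio call threshold, group vs group |
| `sd_band` | 0.5 | half-width of the call band and within-segment SD ceiling |
| `min_bins` | 5 | minimum consecutive bins for a non-neutral segment |
| `pseudocount` | 0.5 | added on the normalized coverage scale before the log ratio |

The strict inequalities ("more than 50", "more than 4") are kept verbatim:
a gene with exactly 50 group variants is not hypermutated, and the
recurrent rule effectively demands at least 5.

## Contingency tests

Between-group count comparisons are laid out as 2×2 tables (count,
margin − count per group) and tested with the Pearson chi-square statistic
without continuity correction (df = 1) by default. The choice is
deliberate: on the hypermutation table of the package's reference scale
(35 of 12714 versus 9 of 11126), the uncorrected statistic gives
p = 0.00049 — 0.0005 at one significant figure — whereas the
Yates-corrected value (0.00085) rounds differently. Both corrections and
Fisher's exact test are exposed through `contingency_test(method = ...)`;
the exact test's two-sided p is the usual sum of hypergeometric
probabilities not exceeding the observed table's. No multiple-testing
correction is applied across the three burden tests; they are reported as
raw p-values. A table with a zero margin is refused as degenerate (the
pipeline records the skip reason instead of failing).

## Differential expression

The transcript-level engine behind the original FPKM matrices is out of
scope; the package's contribution is the partition and integration logic,
which is engine-agnostic. The built-in test is Welch's t on
`log2(FPKM + 1)` for pairwise comparisons (and a one-way F screen across
all groups in `anova_screen()`), with BH q-values and significance at
`q < alpha_fdr`. A `DegTable` from any external engine can be supplied
instead, as long as it carries `gene` and `significant` columns.

Two modeling choices deserve note:

* **Degenerate variance.** When both sides of a comparison have zero
  sample variance the t statistic is undefined; the test then reduces to
  exact mean comparison (p = 1 when the means agree, p = 0 otherwise).
  Real FPKM data never hits this branch, but the noise-free synthetic
  preset exercises it by design (see below), and the convention is the
  natural continuous limit.
* **M versus rest.** The medium group's screen is modeled as M against the
  pooled S+L samples (one Welch comparison), with the two separate
  pairwise comparisons also available. The intersection of its significant
  set with the S-vs-L set (`common_degs()`) identifies genes that both
  single out M and separate the survival extremes.

The Venn partition assigns every gene in the union of the three pairwise
significant sets to one of 7 regions; region counts always sum to the
union size, and the partition is invariant under row reordering of the
inputs.

Expression tiers in the integrated report are tertiles of
`log2(mean FPKM + 1)` computed over the report's genes — a relative color
scale, not an absolute expression calibration.

## Copy number

Coverage enters as windowed read counts (BED-convention half-open bins).
Each track is scaled to a fixed library size (10^6) before anything else,
which makes every downstream quantity exactly invariant to rescaling any
single track; group sides are then averaged bin-wise and the per-bin
statistic is `log2((test + pc) / (control + pc))` with the pseudocount
guarding empty bins on the normalized scale (normalized bin values are
around `1e6 / n_bins`, so `pc = 0.5` is negligible except at zero).

Segment calling reads the "cut-off ± SD" convention as a band: bins enter
a candidate run when `|log2 ratio| ≥ cutoff − sd_band`; a run of at least
`min_bins` bins is called amplified or deleted when its mean stays beyond
the band edge and its within-run SD is at most `sd_band` (the stability
filter). This reading was chosen over a literal per-bin threshold at the
central cutoff because a true 2× amplification has mean log2 ratio exactly
1.0: under any finite depth roughly half its bins fall below 1.0, so a
per-bin rule at the central value can never recover the event — whereas
the band rule recovers it with near-certainty while a flat background
(mean 0, SD well under the band edge) produces no runs. Everything not
called is emitted as neutral segments, so segments tile the binned
territory per chromosome.

One caveat the group contrast inherits from its definition: a region
amplified in both groups cancels in the ratio, and a region amplified in
both but more weakly in one group shows up as an apparent loss in the
other — interpreting a contrast segment requires looking back at the
per-group tumor/normal tracks, which is why `run_pipeline()` always emits
both.

Total-count normalization also means a large planted amplification shifts
the background slightly negative (the amplified bins inflate the library
size). The band rule absorbs this at realistic amplified fractions (a few
percent of bins); the tests use such fractions on purpose.

## The synthetic cohort

The generator (`cohort_config()` / `generate_cohort()`) is the package's
stand-in for patient data, and its design goal is *exact recoverability*:
every set-valued structure it plants must come back verbatim from the
pipeline, so that a failed test indicts the pipeline, not sampling noise.
Three mechanisms control emergence:

* Background variant keys occupy disjoint position offsets per group
  (even/odd), so cross-group identical keys exist only where planted
  (exclusive-shared and universal keys get a reserved offset).
* Background carriers per variant are one anchored sample plus
  Bernoulli(`p_share`) others, capped below the full group — only planted
  keys can be universally shared within a group.
* Group-private background genes cap their distinct count at the group
  size, so only planted recurrent genes can pass the
  ">4 variants in every sample" rule.

Burden totals are the one stochastic quantity: per-gene distinct counts
are `1 + Poisson(λ)` with λ calibrated by root finding so the expected
per-group occurrence totals hit the preset's targets (76170/53319/39609
for S and 45903/33050/24328 for L at paper scale; realized totals land
within about 1%).

The `paper_scale_config()` preset plants the reference-scale structures:
mutated-gene sets of 12714 (S) and 11126 (L) sharing 9800 genes, 35 vs 9
hypermutated genes (top gene 105/75 distinct variants), 46 vs 5 recurrent
group-private genes, 17 vs 2 group-exclusive universally shared keys and
5 cohort-universal keys. Two of the printed reference counts cannot be
planted simultaneously with the rest because they are mutually
inconsistent as set algebra: with |S| = 12714, |L| = 11126 and 2914
S-private genes, the L-private count and the union are forced to 1326 and
14040 (not 1426 and 15610). The preset prioritizes the group set sizes and
the S-private count; the implied complements are what the pipeline
reports.

Expression in the preset is noise-free: within-group values are
deterministic, so significance reduces to exact mean (in)equality and the
planted Venn regions (112 S-vs-L-only, 33 in both M comparisons, 13 in all
three; union 158) are recovered exactly, as is the 13-gene intersection of
the M-vs-rest and S-vs-L screens. Single-pair regions are made
non-significant in the other two comparisons by giving the third group a
deterministic within-group spread (`m_spread`, log2 SD 4 about the
midpoint), which pins those Welch p-values near 0.5. One consequence of
this construction: a three-pairwise Venn with union 158 and the above
regions cannot also produce an M-vs-rest significant set of 60 — any gene
whose M mean differs from a homogeneous rest is necessarily significant in
both M pairwise comparisons, so the M-vs-rest set is 46 here. The
generator documents this as a structural property of the partition logic
rather than forcing an inconsistent planting.

What the preset does **not** emulate — and therefore what passing tests do
not show about real data: FPKM sampling noise and mean–variance coupling,
read-level artifacts, annotation errors, germline contamination, LOH,
subclonal allele fractions, and correlated hypermutation processes. The
noisy configurations used in the statistical property tests
(`noise_sd > 0`) restore sampling variability for sensitivity/FDR and
type-I checks, but they remain idealized log-normal models.

Problem sizes: the paper-scale genome is 3 chromosomes × 30 Mb with 100 kb
bins and 15000 genes tiled at 6 kb (4 kb footprints); the cohort is
6 S + 3 M + 4 L samples with 8 exomes and roughly 120 000 variant records.
The default small configuration (450 genes, 1 Mb chromosomes, 50 kb bins,
depth 400) keeps unit tests fast; coverage depth is higher there because a
six-bin planted event at depth 100 can lose a boundary bin to Poisson noise,
which is a property of the event size, not of the caller.

## Known limitations

* The deleterious flag is consumed, never computed; pathogenicity
  prediction is an upstream concern.
* Exome-level "every sample" rules quantify over sequenced samples only;
  unsequenced members of a group are invisible to the variant-level
  algebra.
* The CNV caller is a thresholding contract, not a change-point model; it
  will not resolve adjacent events closer than `min_bins` or events whose
  mean sits inside the band.
* The DE stand-in tests one gene at a time; no shrinkage or
  mean–variance modeling is attempted, which is conservative at n ≤ 6 per
  group.
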