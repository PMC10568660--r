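---
title: "popscan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{popscan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popscan)
```

## What popscan does

RNA-seq experiments are usually mined only for expression, but the aligned
reads also carry genotypes. popscan is the population-genetics layer for
that second use: starting from a multi-sample VCF called on RNA-seq
alignments (plus per-sample pileup counts, a GFF3, a sample sheet and small
marker panels), it computes selection scans (Hudson's F\_ST, PBS),
diversity summaries (π, Watterson's θ, F\_IS), population structure (LD
pruning + PCA), expressed allele balance at variants of interest, pooled
inversion karyotypes from tag SNPs, AIM-based ancestry fractions, SNP
feature/effect summaries and hypergeometric enrichment. A seeded synthetic
generator makes every estimator testable without any sequencing data.

Treatment groups in the sample sheet are the "populations" of every
statistic. Pooled libraries are handled throughout as single samples of
ploidy 2 × pool size.

## Variant filters

Sites are retained when they are single-nucleotide (all REF/ALT alleles of
length 1), have QUAL ≥ `qual_min` (default 30, *inclusive* — "a quality
score of 30" is read as a minimum), and have at most `max_missing_fraction`
of samples missing (default 0: a call must be present in every sample,
i.e. call-rate 1). Each filter is assessed on the input independently so
the removal report is attributable; the filters commute and the composite
is idempotent.

Multiallelic SNPs are *retained* for the diversity statistics, which are
defined on full allele counts, but *reduced* to reference vs the
globally-most-frequent alternate for F\_ST, PBS, LD pruning and PCA, whose
estimators are biallelic. The reduction drops the minor alternates from
both the count and the sample size and the number of reduced sites is
recorded (`biallelic_counts()` attribute `n_reduced`). Whether the source
workflow excludes such sites is unknown; retention-plus-reduction keeps
the diversity statistics exact and the biallelic statistics well-defined.

A sample counts as missing at a site when *any* of its haplotype calls is
absent, which covers partial calls such as `./1`; allele counting is
haplotype-level, so the called haplotypes of a partial call still
contribute to n.

## Estimators

**Hudson's F\_ST.** Per site, with alternate frequencies $p_1, p_2$
estimated from $n_1, n_2$ haplotypes,

$$\hat N = (p_1-p_2)^2 - \frac{p_1(1-p_1)}{n_1-1} - \frac{p_2(1-p_2)}{n_2-1},
\qquad \hat D = p_1(1-p_2) + p_2(1-p_1).$$

Windows and genes aggregate as a **ratio of averages**
$\sum \hat N / \sum \hat D$, the standard and stable form for this
estimator (the alternative, a mean of per-site ratios, explodes at low-D
sites). Negative per-site numerators are kept in the sums; truncating them
would bias the estimator upward. Sites with fewer than 2 haplotypes in
either group are masked. Windows tile each chromosome from position 1 with
span `window_size_bp` (default 20 kb) and step equal to the span
(nonoverlapping) unless a smaller step is requested — published RNA-seq
popgen summaries use both nonoverlapping and overlapping 20-kb windows,
so the default is nonoverlapping and the step is a parameter.

**PBS.** Pairwise F\_ST is converted to branch lengths
$T = -\log(1-F_{ST})$ and the focal branch is
$(T_{AB}+T_{AC}-T_{BC})/2$. F\_ST is clipped to $[0, 1-10^{-6}]$ first so
fixed differences give finite branches; clipped windows are flagged.

**Diversity.** Per window, π sums the per-site mean pairwise difference
$\sum_{j<k} c_j c_k / \binom{n}{2}$ and divides by the *full window span*;
θ\_W is $S/(a_{n-1}L)$ with $a_{n-1}$ the harmonic number. The window span
is not corrected for RNA-seq coverage gaps — a VCF-only implementation
cannot know them — so absolute levels are depressed relative to
whole-genome sequencing and are comparable only within an experiment.
Genome-wide means carry a seeded percentile bootstrap over windows (10,000
resamples by default; no particular CI construction is standard for these
summaries, so the choice is documented here). Groups can be
down-sampled to a common replicate count (seeded) before counting, as one
does when comparing groups of unequal size.

**Inbreeding.** $F_{IS} = 1 - \overline{H_{obs}}/\overline{H_{exp}}$ over
sites polymorphic in the group, with $H_{obs}$ the fraction of non-missing
samples carrying ≥ 2 distinct alleles and $H_{exp} = 1-\sum_a p_a^2$
(no small-sample correction). The estimator is not specified by the source
material; this is the simplest multiallelic-safe choice and is anchored in
tests at the exact values −1 (all heterozygotes at p = 0.5) and +1 (no
heterozygotes), and ≈ 0 under simulated Hardy–Weinberg genotypes.

**Gene-level F\_ST and flagging.** Genes with ≥ 1 variant are ranked by
percentile 100(r−1)/(n−1) (100 when a single gene is ranked); genes at or
above 100 − `fst_top_percentile` are flagged. This definition is the only
one consistent with both boundary cases exercised in the tests (a lone top
gene must rank 100; exactly 5 of 100 distinct genes flag at 5%).

## Structure

LD pruning slides windows of 500 SNPs (step 250) and removes the *later*
site of any pair with dosage $r^2 > 0.01$ (strict inequality), repeating
passes until a sweep removes nothing, so the result is a fixed point.
Correlations are Rogers–Huff style on unphased dosages — RNA-seq genotypes
are unphased and pools make phasing meaningless. Zero-variance sites have
no defined correlation and are retained (logged). Note the procedure is
window-local: a duplicated site's twin can be removed by a nearby
correlate before the duplicate pair is compared, in which case the
duplicate legitimately survives.

PCA mean-imputes missing dosages per site (count logged), centres per
site, and decomposes by SVD; each component's sign is fixed by making its
largest-magnitude loading positive, so output is fully deterministic.

## Pileup-based statistics

**Expressed allele balance** is computed from read pileups, not genotype
calls, so a pooled library's 10% allele is not rounded away by a caller.
Per replicate, f = alternate reads / depth; only the panel's stated
alternate base counts toward f, third alleles are tallied separately. A
covered locus with zero alternate reads is NOT\_DETECTED; depth 0 is
NO\_COVERAGE. Group summaries are *unweighted means over covered
replicates* (replicates are the biological unit; a depth-weighted pooled
variant is available) with a seeded 2,000-resample percentile bootstrap
CI. Covered replicates where the allele was not detected enter the mean as
f = 0. Default BAM read filters are the conventional pileup defaults (base
quality ≥ 13, mapping quality ≥ 1).

**Inversion karyotypes** generalize tag-SNP voting to pooled fractions:
the estimate is the unweighted mean over covered tag SNPs of the
inverted-allele read fraction, so 0 means no inverted alleles at any tag
and 1 means nothing else. Whether the original per-site concordance
weighting survives in pooled mode is undocumented; the plain mean is used
and a depth-weighted option provided. Group contrasts use two-sided
Mann–Whitney U (exact at small n without ties; midranks and the normal
approximation with continuity correction under ties; p = 1 when all
values tie) with Benjamini–Hochberg adjustment across all
contrasts × inversions — BH is the adjustment everywhere this package
emits an "adjusted p".

**AIM ancestry** tallies allele observations matching each species'
diagnostic allele; observations matching neither are "uninformative" and
never attributed (imported panels may not be diagnostic outside their
source population). Fractions, not per-locus majority votes, are reported
because pools are mixtures by construction; a diploid heterozygote
half-counts to each species. The genotype source is the filtered VCF by
default, with a pileup mode for loci lost to the missingness filter.

## Annotation layer

Feature classification is a three-way partition with precedence
exon > intron > intergenic, isoform exons merged; the genome's own
composition under the same partition is computed from the GFF3 alone
(lengths from `##sequence-region` pragmas) so ascertainment is visible.
Effect tallies parse upstream ANN annotations only (no re-annotation) with
severity nonsense > missense > synonymous > other. Sweep overlap is
half-open on both sides and labelled exploratory in its output. Enrichment
is the upper-tail hypergeometric test; the recommended universe is the
expressed genes, not the whole genome, because RNA-seq variant discovery
is itself expression-biased. Gene families order by average-linkage
clustering of correlation distance (1 − r) on normalized counts, a
conventional pair for expression heatmaps. Differential-expression inputs are
consumed from external tables; no DE model is re-implemented.

## The synthetic world

`simulate_populations()` draws, per site, an ancestral frequency
p ~ U(0.05, 0.95) and per-population frequencies from the Balding–Nichols
Beta(p(1−F)/F, (1−p)(1−F)/F); at F = 0 the population frequency *is* p.
Genotypes are Binomial(ploidy, q). Under this model the expected Hudson
ratio-of-averages F\_ST equals F, giving an analytic recovery anchor
(within ±0.02 at L = 20,000 sites, 50 diploids per population, in the
acceptance suite). Pileups are Binomial reads at Poisson depth with error
rate folded as q′ = q(1−e) + (1−q)e/3 and error reads scattered to
off-target bases. Defaults state the emulated world once: two populations
of six replicates (the motivating experiment's replicate count), one 20-Mb
chromosomal arm with 10,000 SNPs, diploid samples, mean depth 30, error
rate 0.001, a 46% genic toy genome. One global seed fans out to
per-component streams via a fixed hash, so identical seeds give
byte-identical artifacts and components can be regenerated independently.

What the generator does **not** emulate: linkage (sites are independent,
so LD-pruning behaviour on real data is only structurally tested),
coverage that tracks expression, allele-specific expression, batch
effects, or realistic RNA-seq dispersion in the expression-like table. A
green recovery test therefore establishes estimator correctness under the
stated sampling model, not robustness to those real-data features.

## Numerical and degenerate-input choices

- QUAL threshold inclusive; r² threshold strict; interval overlap
  half-open; external coordinates 1-based inclusive everywhere.
- F\_ST clipping margin 1e−6 before −log for PBS.
- Windows with no variants or zero summed denominator report NA, never 0.
- Contig names are taken verbatim; a contig mismatch between positions and
  annotation is an error, never a silent empty join.
- A group that is monomorphic everywhere yields F\_IS = NA with a warning;
  a sample with zero covered tag SNPs yields a missing karyotype with a
  warning; a contrast with < 2 replicates is skipped with a warning.
- Test-time scale-downs: unit tests use reduced bootstrap resamples and a
  4,000-site monotonicity grid; the full acceptance grid (20,000 sites,
  four F levels) runs in the dedicated acceptance tests.

## Known limitations

- Window spans ignore RNA-seq coverage gaps (documented above), so π/θ are
  experiment-internal quantities.
- The pooled karyotype mean ignores per-tag concordance weights.
- PBS on windows assumes the three pairwise scans share identical window
  grids; misalignment is an error rather than a join.
- The CLI emits plots as convenience PDFs only; every figure has a TSV
  twin and nothing downstream parses images.
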