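---
title: "dioseq methods: models, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dioseq methods: models, parameters and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dioseq)
```

This vignette documents the statistical machinery of dioseq: the models
and their assumptions, the tunable parameters and why their defaults are
what they are, what the synthetic-data generator does and does not
emulate, and the numerical conventions used throughout.

## The setting

Dioecious species carry males and females as separate individuals, and
sex-linked loci sit in genomic regions where recombination between the
sex-determining haplotypes is suppressed. In a species with no reference
genome, a practical route to such loci is comparative transcriptomics: a
few individuals of each sex are RNA-sequenced, reads are assembled de
novo into unigenes (oriented transcript contigs), and two signals are
mined from the same data — expression differences between the sexes and
SNP sites whose alleles segregate perfectly with sex. dioseq implements
the downstream analysis of that design; read cleaning, assembly,
expression quantification and variant calling are consumed as inputs
(count matrix, FASTA, VCF), not reimplemented.

## Sex-biased expression

### Normalization

`compute_size_factors()` uses median-of-ratios normalization: sample
$s$'s factor is the median over genes $g$ (restricted to genes with
positive counts in every sample) of $k_{gs}/(\prod_t k_{gt})^{1/n}$.
This removes library-depth differences without being driven by a few
highly expressed genes. If no gene is positive everywhere — common in
very sparse designs — the `pseudo_reference = TRUE` fallback computes
each gene's geometric mean over its positive counts only, using genes
expressed in at least two samples.

FPKM (`compute_fpkm()`) follows the textbook formula
$10^9 \cdot k_{gs} / (L_g \, N_s)$ with $L_g$ the unigene length in bp
and $N_s$ the library size, defaulting to the column sum of the count
matrix (the true mapped-fragment totals are not recoverable downstream
of assembly). FPKM is used only for the sex-specific expression floor
and for clustering; all testing happens on counts.

### The negative-binomial Wald test

`test_differential()` models normalized counts with variance
$\mu + \alpha \mu^2$. For each gene the two sex means $\bar q_M,
\bar q_F$ are compared through
$$ z = \frac{\log_2 (\bar q_M / \bar q_F)}
            {\sqrt{\left(\frac{1/\bar q_M + \alpha}{n_M} +
                         \frac{1/\bar q_F + \alpha}{n_F}\right)} / \ln 2 },$$
the delta-method standard error of a log ratio of NB means, referred to
the standard normal.

The dispersion $\alpha$ deserves comment. With three replicates per sex
a per-gene moment estimator ($\hat\alpha = (s^2 - \bar q)/\bar q^2$ from
within-sex residuals pooled across the sexes) is so noisy that the test
built on it cannot be simultaneously calibrated and powered: with a
normal reference the null rejection rate at 0.05 is about 0.11, and
switching to a $t_4$ reference restores calibration but loses strong
planted effects to the fat tails. The standard solution in this field is
to share dispersion information across genes, and dioseq does the
simplest defensible version of it: raw moment estimates from all genes
are pooled into a mean–dispersion trend
$\alpha(\mu) = a_0 + a_1/\mu$ (least squares, genes with $\mu > 1$),
and each gene is tested with its trend value, floored at $10^{-8}$.
Under this design the measured null rejection rate at 3v3,
$\mu = 100$, $\alpha = 0.05$ is 0.050–0.055 and planted 32-fold
effects are recovered essentially completely (see the test suite, which
asserts both). Per-gene dispersion outliers are not re-examined — a
deliberate simplification relative to shrinkage estimators, listed under
limitations.

When one sex's mean is zero the log ratio is infinite; a pseudo-count of
0.5 is added to both group means for the fold change and its error. Any
finite pseudo-count convention breaks exact invariance of `log2fc` under
rescaling one library for exactly these genes (the ratio-based estimate
is invariant for all genes with positive means); the sign and the
$|\log_2 FC| \ge 1$ call are unaffected. Genes with all-zero counts get
$p = 1$ and `log2fc` 0.

### Calling rules

`classify_deg()` calls a gene male-biased iff $p_{adj} < 0.05$ (strict)
and $\log_2 FC \ge 1$ (inclusive), female-biased symmetrically —
the operator sharpness follows the printed convention of such criteria.
$p_{adj}$ is Benjamini–Hochberg (`adjust_bh()`, a validated wrapper over
`stats::p.adjust`). `classify_sex_specific()` then looks *within the
DEGs* for genes with zero counts in every replicate of one sex and mean
FPKM above 0.03 in the other; the floor may instead be applied to every
replicate (`floor_mode = "all"`), since whether such a floor should bind
the mean or each replicate is ambiguous in common usage — the mean is
the default.

`cluster_samples()` clusters samples on $\log_2(\text{FPKM}+1)$ of the
DEGs with $1 - r$ (Pearson) distance and average linkage and cuts the
tree in two. Heat-map tools used for such figures typically default to
hierarchical clustering even when described as K-means; hierarchical
clustering is implemented here because its two-group cut is
deterministic and order-invariant.

## The sex-segregation SNP filter

`find_sex_segregating()` implements three criteria on per-individual
genotype calls: (1) depth at least `min_depth` (default 5, boundary
inclusive) in *every* individual — `filter_min_depth()`; (2) the site
polymorphic across the individuals; (3) one allele fixed in all females,
a different one fixed in all males. Criterion (3) implies (2), and the
filter evaluates it site by site; an optional stricter reading of (2) —
requiring the gene to be polymorphic anywhere irrespective of
segregation — would only remove genes whose single polymorphic site
already satisfies (3), so the nested form is used.

Conventions: positions are 1-based along the unigene from the 5′ end
(VCF `POS` used as-is). Heterozygous and missing genotypes are loaded as
no-calls, and a position with any no-call is ineligible, because the
criteria quantify over every individual; this is the `nocall` policy,
and `fail-site` is an explicit alias with the same effect. Depth is the
VCF `DP`, which counts unique reads when deduplication precedes calling.

With $n$ individuals a random unlinked biallelic site (all $2^n - 2$
polymorphic allele assignments equally likely) segregates by sex with
probability $2/(2^n - 2)$ — `segregation_null_rate()`; at 3+3 this is
$1/31$, which is why a handful of perfectly segregating sites across
tens of thousands of SNPs is meaningful but single sites in isolation
are not.

## SNP spectrum and sequence summaries

`classify_substitution()` types each unordered substitution pair
(purine–purine and pyrimidine–pyrimidine are transitions; the four mixed
pairs transversions); `tally_spectrum()` accepts either per-site records
or pre-tallied per-type counts (`n` column) and enforces the additivity
transitions + transversions = total. Densities divide by the total
assembled unigene length and are reported per kb, half-up rounded to two
decimals at the report layer only (`round_half_up()`; base `round()`
rounds half to even, which published tables generally do not).

`codon_position()` places a coding SNP at $1 + (pos - cds_{start})
\bmod 3$, forward frame only — unigenes are oriented transcripts, and
the CDS annotation (gene, 1-based inclusive start/end, length divisible
by 3) must be supplied explicitly. `classify_synonymy()` substitutes the
alternate base into the reference codon and translates both with the
standard genetic code (stop treated as its own residue, so stop
gain/loss is nonsynonymous). `calc_n50()` uses the descending
cumulative-sum definition. `read_qc()` computes Q20/Q30 as the percent
of bases at or above the threshold, GC over called A/C/G/T bases only
(N excluded from the denominator), and the error rate as
$\overline{10^{-Q/10}} \times 100$.

## Length-aware enrichment

Longer transcripts yield more reads and are easier to call DE, so a
category of long genes looks enriched to a plain hypergeometric test
even under the null. `build_pwf()` estimates each gene's DE probability
as a function of length by quantile binning (default 20 bins; weights
clipped to $(10^{-6}, 1 - 10^{-6})$). The classical approach fits a
monotone spline; binned proportions approximate it while being directly
unit-testable, and with `n_bins = 1` reduce to the global DE fraction.

`wallenius_test()` computes the upper tail of the Wallenius noncentral
hypergeometric — the biased-urn model in which each of the $m_1$
category genes is drawn with odds $\omega$ against the others — with
$\omega$ the mean weight inside the category over the mean weight
outside. The mass function is evaluated by the exact draw-by-draw
recursion (a dynamic program over draws, $O(n \cdot m_1)$) for universes
up to 2,000 genes; above that a normal approximation with the Wallenius
mean equation is used, adequate for tail screening but not for printed
precision. At $\omega = 1$ the recursion provably reduces to the central
hypergeometric, and the suite checks agreement with `phyper` to
$10^{-6}$. In a simulated null where DE probability rises with length
and categories are sampled proportionally to length, the measured
rejection rate at 0.05 over 2,000 category draws stays within
$0.05 \pm 0.015$ while the uncorrected hypergeometric rejects more
often (both asserted in the suite).

`enrich_all()` adjusts across categories with BH (reported as `q` — a
q-value in the BH sense), sorts by $p$, and reports each category's rich
factor (DE genes in category / universe genes annotated to it). Only
over-representation is tested. The universe defaults to annotated genes,
widenable to all genes. GO term ancestry propagation is out of scope:
the categories are taken as given.

## The synthetic study generator

`simulate_dataset()` writes a complete, internally consistent study from
one seed: unigene FASTA with CDS annotations, a replicated count matrix
with sample sheet, a multi-sample VCF (plus a flat genotype table),
per-sample FASTQ, and a truth manifest. The defaults encode the study
design this pipeline targets:

| parameter | default | rationale |
|---|---|---|
| replicates | 3 M + 3 F | the archetypal dioecious leaf-transcriptome design |
| `n_genes` | 2000 | scaled-down universe; large enough for BH and trend fitting, small enough that the full suite runs in minutes |
| `baseline_mean` | 100 | moderately expressed gene after normalization |
| `dispersion` | 0.05 | assumed moderate biological dispersion for full-sib replicates; an assumption, not an estimate from data |
| `planted_log2fc` | 5 | the strong effect regime: all planted biased genes differ 32-fold |
| biased M/F | 33 / 12 | with the sex-specific genes below, totals 73 male- and 43 female-biased (116 DEGs) |
| specific M/F | 40 / 31 | structural zeros in the silent sex |
| SNP sites | 60, of which 9 sex-segregating | the segregating sites cluster on ~5 genes, a Table-of-markers scale |
| `depth_mean`, `min_planted_depth` | 20, 5 | planted sites always pass the depth criterion; decoy "low depth" sites dip below it |
| reads | 400 × 100 bp per sample, GC 0.42, Q38 | enough for QC closed forms and GC checks |

Planted biased genes split the fold change symmetrically
($\mu \cdot 2^{\pm f/2}$) so library sizes stay balanced; sex-specific
genes are *structural* zeros (every replicate of the silent sex is
exactly 0, not a random draw), making the zero-count calling rule
exactly satisfiable — planting them as low-mean NB draws would make the
truth manifest probabilistically wrong. Variant decoys either violate
within-sex fixation (one flipped individual, or one heterozygote) or
segregate at sub-threshold depth; the truth manifest labels each site
`segregating` / `decoy` / `low_depth` so recovery tests can assert both
zero misses and zero leakage. The master seed fans out to fixed
per-stage substreams, so each stage can be regenerated independently and
identical configurations give byte-identical files.

What the generator deliberately does **not** emulate: mapping and
assembly artifacts (chimeric unigenes, multi-mapping inflation),
GC/length-dependent count bias, correlated genes, indels and
multi-allelic sites, base-composition-dependent sequencing error. A
pipeline that passes the recovery suite is therefore validated for its
*logic and calibration*, not certified against real-data artifacts — on
real data the segregation filter in particular inherits whatever
reference and calling errors the upstream produced.

## Numerical conventions and degenerate inputs

- Thresholds: $p_{adj} < \alpha$ strict, $|\log_2 FC| \ge$ threshold
  inclusive, FPKM floor strict ($> 0.03$), depth boundary inclusive
  ($\ge 5$).
- BH ties are resolved by `stats::p.adjust`'s stable step-up; ordering
  of tied categories after sorting is stabilized by category id.
- All-zero genes: $p = 1$, `log2fc` 0. Empty gene sets, empty call sets
  and empty categories return empty results or explicit errors naming
  the offending input, as documented per function.
- `run_pipeline()` validates the whole configuration first
  (`validate_config()` returns all problems at once) and fails before
  any stage runs if an input is missing; reruns with the same
  configuration and seed are byte-identical except for recorded paths.

## Problem sizes used by the validation suite

The suite exercises: a 10,000-gene all-null 3v3 simulation for test
calibration; the 2,000-gene default study for recovery, FDR and
clustering; all 64 biallelic six-individual assignments (exhaustive
oracle) plus 20 seeded cohorts for the segregation filter; 2,000
category draws at a 1,000-gene universe for enrichment calibration; all
576 single-base codon changes for synonymy. These sizes are the
package's chosen validation design: large enough for the stated
tolerances (e.g. a binomial SE of ~0.002 on the null rejection rate),
small enough to run routinely.

## Known limitations

- Two-group designs only; no covariates, batch terms, or shrinkage of
  fold changes; no exact NB tests. The trend-moderated Wald test is
  anti-conservative if dispersions are strongly gene-specific above the
  trend.
- The segregation filter is all-or-nothing: a single miscalled
  individual hides a true sex-linked site (no tolerance scoring), and
  heterozygous sites — expected for the heterogametic sex in an XY/ZW
  system — are treated as no-calls; the filter therefore targets
  hemizygous or fixed-difference markers.
- Wallenius evaluation above 2,000-gene universes is approximate.
- FPKM library sizes are count-matrix column sums, not mapped-fragment
  totals.
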