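---
title: "Methods: two-library digital gene expression analysis of staged yeast biofilms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-library digital gene expression analysis of staged yeast biofilms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biofilmDGE)
```

## The experimental design this package models

Immobilized ethanol fermentation lets *S. cerevisiae* form biofilms on
fiber surfaces. Cells are sampled at four conditions — free cells (FCP)
and three biofilm stages: attachment (AP, 3 h), sessile growth (SGP,
14 h) and maturation (BMP, 30 h) — and each condition yields **one**
pooled tag library (three samples pooled before sequencing, so there are
no biological replicates). Every statistic in this package is therefore
a *two-library* comparison: it models sampling (Poisson) variability of
tag counts, not biological variance between replicates. That is the
appropriate inference for this design and its central caveat: p-values
quantify counting noise only, and real biological variability between
cultures is invisible to them.

## Read quality control

Raw reads are filtered whole (no trimming) by three rules applied in a
fixed order, first failure winning:

1. **adapter** — the read contains a configured adapter sequence as an
   exact substring (adapters are caller-supplied; matching semantics are
   deliberately the simplest reproducible choice),
2. **unknown bases** — strictly more than 5% of bases are `N`,
3. **low quality** — strictly more than 30% of bases have Phred score
   ≤ 10 (inclusive cutoff).

The strict/inclusive reading of each boundary follows the filter's
stated definition; a 100-nt read with exactly 30 bases at Phred ≤ 10
passes, one with 31 fails. Phred+33 is the default encoding with a
Phred+64 switch, since HiSeq-2000-era data occurs in both.

## Expression and fold change

RPKM is `1e9 * C / (N * L)`. `N` is the library's total uniquely aligned
reads and is treated as a supplied constant — it need not equal the
column sum of the count table, because counts tables may be restricted
to a gene subset.

The log2 ratio between libraries is computed from library-size
normalized counts with a pseudocount (default `c = 1`):
`log2(((y + c)/N2) / ((x + c)/N1))`. Computing fold change from
pseudocounted normalized counts rather than from RPKM keeps zero-count
genes finite and makes the ratio independent of gene length, which
cancels anyway in a within-gene comparison. For large counts the two
definitions converge; the RPKM matrix is emitted alongside so either
ratio can be read off.

## The two-library exact test

For a gene with `x` tags at depth `N1` and `y` tags at depth `N2`, the
null law of `y` given `x` after marginalizing the unknown common Poisson
rate (improper uniform prior) is negative binomial with size `x + 1` and
success probability `N1/(N1 + N2)`:

$$p(y \mid x) = \left(\frac{N_2}{N_1}\right)^{y}
  \frac{(x+y)!}{x!\,y!}\left(1+\frac{N_2}{N_1}\right)^{-(x+y+1)}.$$

The pmf is evaluated in log space through `lgamma`, so counts up to 1e6
at depths up to 1e9 neither overflow nor lose the tail. The cumulative
sum $S = \sum_{i\le y} p(i\mid x)$ is evaluated through the regularized
incomplete beta identity for the negative-binomial CDF rather than by
term summation, for speed and tail stability.

**Two-sided rule.** The p-value is `2 * S` when `S <= 0.5` and
`2 * (1 - S + p(y|x))` otherwise, capped at 1. Keeping the observed
point's mass in the upper branch makes the two branches agree as `S`
crosses 0.5; without it the rule would be anti-conservative just above
the median. This is the standard construction for doubling a discrete
tail.

**Calibration and discreteness.** Under a null simulation at the study's
scale (20000 genes, both depths 1e7), the fraction of genes with
p ≤ 0.05 sits within 3 binomial standard errors of 0.05. The raw p-value
distribution, however, is *not* exactly uniform: a discrete doubled
statistic places an atom at p = 1 (about 3% of genes here — every gene
whose observed count sits at its conditional median), so a
Kolmogorov–Smirnov test on raw p-values at n = 20000 always rejects.
The test suite therefore checks uniformity on *randomized* p-values
(`P(Y < y) + U·p(y)`, the standard device for discrete tests, exactly
uniform under the null law) and checks decile flatness of the raw
p-values away from the atom. This is a property of all exact discrete
tests, not a defect of the implementation.

**DEG calling** uses inclusive thresholds: adjusted p ≤ 0.001 and
|log2 ratio| ≥ 1. The default FDR adjustment is Benjamini–Yekutieli,
matching the correction the analysis cites; Benjamini–Hochberg — what
most tag-DGE pipelines of that generation actually used — is available
by flag, and both are step-up procedures via `stats::p.adjust`. Whether
BY or BH was used originally is not decidable from the published record;
defaulting to the cited method is the conservative choice (BY ≥ BH
elementwise, so it can only reduce DEG counts).

## Category enrichment

Over-representation of a DEG set in a flat gene category is the
hypergeometric upper tail `P(X >= k)` with universe `N_univ` (all
annotated genes), category size `K`, and draw `n` = the number of DEGs
*that carry annotation* — not all DEGs, matching how the published
contingency table is laid out (e.g. 648 annotated DEGs against a
2143-gene universe for the attachment comparison). The tail is computed
by `stats::phyper` in log space; the six published pathway probabilities
(spanning 1.6e-3 down to 5.2e-53) are reproduced to their printed
precision, which confirms the hypergeometric upper tail as the
enrichment statistic in use, since it was not named. Only
over-representation is tested; depletion is out of scope. Q-values are
BH across exactly the categories tested in a run — the original total
tested-category count is unprinted, so published Q-values are
report-only and not exactly reproducible. Categories are flat sets: no
GO DAG propagation or term relationships.

## qPCR validation

Relative quantification is plain Livak 2^−ΔΔCT against a reference gene
(default 18S rRNA), with technical replicates averaged as arithmetic
mean Ct before differencing and no amplification-efficiency correction.
Concordance between sequencing and qPCR is Pearson correlation on
**log2** fold changes: raw fold changes spanning 6.8× to 555× would let
one or two extreme genes dominate r.

## The synthetic-data generator

The generator defines the study conditions under which everything is
tested:

* **Scale.** 6000 genes (yeast-genome scale), one library per stage at
  1e7 uniquely mapped tags (≈2 Gb of HiSeq-era sequencing per stage).
* **Transcript lengths** log-normal around 1.3 kb (sdlog 0.45, floor
  100 nt).
* **Baseline abundances** log-normal with sdlog 1.2 — a long-tailed law
  giving ≈3–4 decades of RPKM dynamic range, chosen once as realistic
  for a yeast transcriptome and exercising the numerical range of the
  test.
* **Counts** Poisson around length-weighted expected tags, with a
  gamma-mixed option (`dispersion` > 0, variance μ + φμ²) so robustness
  tests can deliberately violate the Poisson assumption.
* **Planted truth.** Nine sentinel genes carry the reported fold
  changes verbatim under their published names (Flo11 6.8/5.0/18.4-fold
  up across AP/SGP/BMP; Fbp1 239× and Pck1 555× up at AP; Hsp12
  181/49/13× up; Gut1 6.6/1.4/2.3× up; Bsc1 42/4/3× down; Mig1 26× down
  at AP; Tec1 2× up; Kss1 3× down). Effects are applied to expected
  counts without re-normalizing the library, so planted log2 fold
  changes are exact in expectation. Generic DE genes (log2 magnitudes
  uniform in 1.5–3.5) fill each comparison to the reported up/down
  totals (522/1576 at AP, 511/1045 at SGP, 472/455 at BMP), and the
  annotation universe holds exactly 2143 genes with a 32-gene category
  containing 26 planted DEGs and a 55-gene category containing 37,
  reproducing the published contingencies, with annotated AP DEGs
  totalling exactly 648.
* **FASTQ fixtures** plant exact per-class counts of adapter-bearing,
  N-rich (>5% N) and low-quality (>30% bases ≤ Phred 10) reads among
  clean reads that pass all filters by construction (clean reads are
  rejection-sampled to be adapter-free), so QC removal counts can be
  compared to planted labels exactly. Qualities are Phred+33 by default
  with a +64 switch.
* **Ct tables** set the test-condition target Ct to the control Ct
  minus the planted log2 fold change plus Gaussian noise, with a
  constant-up-to-noise reference gene, three technical replicates each;
  at zero noise the 2^−ΔΔCT recovery is exact.

Everything is reproducible bit-for-bit under a fixed seed.

**What the generator does not emulate:** biological replicate variance
(the design has none), sequence-content realism beyond what the QC
filters inspect, alignment ambiguity (counts are generated directly),
and composition effects between libraries. Passing tests therefore
demonstrate correctness of the statistics under the stated sampling
model, not robustness to the full messiness of real libraries.

## Numerical and design notes

* The published RPKM formula line is typographically corrupted; the
  implementation follows the cited Mortazavi definition `1e9·C/(N·L)`,
  which matches the printed definitions of C, N and L.
* The published two-sided rule's summation bound is likewise corrupt;
  the standard Audic–Claverie doubling construction above is the only
  coherent reading and is adopted.
* The headline DEG totals from the real libraries (2098/1556/927) are
  functions of unavailable raw data (no accession is given); they enter
  the package only as planted-truth targets and as arithmetic checks on
  the summary table (e.g. 1576 + 522 = 2098).
* Test problem sizes: the calibration and planted-recovery simulations
  run at the study scale (20000 genes for calibration, 6000 × 4
  libraries for the scenario) and complete in seconds; the pmf oracle
  sweep covers all x, y ≤ 50 at three depth ratios.
* Degenerate inputs: zero counts in both libraries give p = 1 and log2
  ratio 0; a category equal to the whole universe gives p = 1; fewer
  than 3 shared genes is an error for concordance rather than a
  meaningless correlation.
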