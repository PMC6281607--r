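---
title: "Gene-level rare-variant collapsing burden analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-level rare-variant collapsing burden analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geneburden)
```

## The statistical model

`geneburden` tests, per gene, whether cases are enriched for carriers of rare
predicted-damaging coding variants. The unit of analysis is the *carrier*: a
sample with at least one qualifying alternate allele in the gene, counted
once regardless of how many qualifying variants it carries. For a gene with
`a` carrier cases among `n1` and `c` carrier controls among `n2`, the test is
the exact conditional (Fisher) test on the 2x2 table with fixed margins. The
two-sided p-value follows the minimum-likelihood convention — the sum of
hypergeometric probabilities of all tables no more probable than the observed
one, with a `1 + 1e-7` relative tolerance on the comparison. This is the
convention of `stats::fisher.test`, and the package's own kernel
(`fisher_two_sided`) is cross-checked in the test suite both against
`fisher.test` and against a full-enumeration oracle on every table up to
total 60.

Two odds-ratio conventions circulate in published tables, so both are
reported: the cross-product estimate `a d / (b c)` (the `or` column; infinite
when controls have no carrier) and the conditional maximum-likelihood
estimate from the noncentral hypergeometric model (`or_cmle`, via
`fisher.test`), whose exact conditional 95% interval supplies `ci_low` /
`ci_high`.

Variants enter the test through four *embedded classes*:
PTV ⊂ PTV+Mis3 ⊂ PTV+Mis3+Mis2 ⊂ PTV+Mis3+Mis2+Mis1. A protein-truncating
variant (PTV) is one whose annotation flags it as loss-of-function; when the
flag is absent the fallback accepts nonsense, frameshift and canonical
splice-site effect terms not marked as terminal-exon (unknown status is
treated as non-terminal, with a warning, because terminal-exon rescue is the
rarer situation). Missense variants are graded Mis3/Mis2/Mis1/benign by the
number of "damaging" verdicts among three in-silico predictors. Nesting makes
carrier counts non-decreasing from the most to the least restrictive class,
which the suite asserts as an invariant.

Because the four class-wise tests per gene are nested and strongly
correlated, multiplicity is handled two ways: a Bonferroni flag at
`alpha / n_genes` with `n_genes = 20000` (the approximate human gene count,
so 2.5e-6 at `alpha = 0.05`), and a Benjamini-Hochberg FDR computed across
genes *within* each embedded class (`fdr_scope = "within_class"`; a global
scope is available but mixes nested tests of very different power). The
per-gene summary row is the class of minimal p, ties broken toward the most
restrictive class so that adding non-informative Mis1 variants never changes
a gene's headline class.

## Rarity

A variant qualifies when its minor allele frequency, computed on the
combined post-QC cases-plus-controls matrix with denominator twice the
number of non-missing calls, is strictly below 1%. Computing MAF on the
pooled cohort (rather than controls only) is deliberate: with ~10x more
controls than cases the pooled frequency is dominated by controls, and
pooling avoids excluding variants solely because they are frequent in cases
— which would erase the very signal under test in the opposite direction.

## The QC cascade

`run_qc` applies, in a fixed, documented order:

1. **Genotype masking** — calls with DP < 7 or GQ < 21 (i.e. retention
   requires depth > 6 *and* quality > 20) become missing. Masking precedes
   every missingness statistic, since an unreliable call should count as
   absent everywhere downstream.
2. **Sample missingness** — drop samples strictly above 15% missing calls.
3. **Relatedness** — pairwise pi-hat by method-of-moments IBD estimation
   from identity-by-state counts at common sites (within-matrix MAF >= 1%),
   with negative moment estimates clamped to zero before renormalization
   (the standard small-sample correction). For each pair above 0.15 the
   member with higher missingness is dropped (ties: the later sample-sheet
   entry). Fewer than 50 informative sites skips the step with a warning —
   rare-variant-only fixtures cannot support the estimator.
4. **Region masks** — exclusion of sites inside user-supplied BED masks
   (low-complexity, tandem repeats). BED is interpreted 0-based half-open;
   all internal positions are 1-based.
5. **Variant missingness** — exclude sites strictly above 5% missing.
6. **Hardy-Weinberg** — exact conditional test (heterozygote-count
   enumeration with parity constraint) in *controls only*, excluding at
   p < 1e-6. Controls-only avoids discarding genuine case-enrichment
   signals as HWE failures; the threshold mirrors the differential
   missingness one. Both choices are configurable.
7. **Differential missingness** — two-sided Fisher test of missing vs
   non-missing by phenotype, excluding at p < 1e-6, reusing the same exact
   kernel as the burden test.
8. **Allele balance** — per-variant *means*: the mean alternate-read
   fraction over heterozygous calls must lie in [0.25, 0.75] and the mean
   supporting-allele fraction over homozygous calls must reach 0.90.
   Per-variant averaging (rather than per-genotype filtering) is the chosen
   reading of an "average allele balance" rule; zero-depth calls are
   skipped, empty categories impose no constraint, and sites with no AD
   information pass with a warning.

Sample-level steps run before variant-level ones so that variant statistics
reflect the final cohort. Every exclusion is recorded with its rule in a
report whose counts reconcile exactly with the matrix size changes; the
cascade is monotone (it only removes), which the suite checks as a property.

VQSLOD is carried as an optional pass-through column with an off-by-default
numeric threshold; re-deriving VQSR sensitivity tranches would require the
recalibration model and is out of scope.

## Canonical variant representation

Multi-allelic records are split into one bi-allelic site per alternate
allele; a sample's dosage for allele *k* is the count of *k* in its
genotype, so splitting conserves the total alternate count per sample.
Alleles are then trimmed (shared suffix, then shared prefix, keeping one
base) and, when a reference window is available, indels are shifted left
while the edit remains sequence-equivalent. Normalization is idempotent and
is tested against a sequence-application oracle on random repeat-rich
windows. Genotypes with any missing allele are treated as fully missing —
the conservative choice for carrier counting.

## Reference consistency check

Individual-level genotypes for large reference panels are unavailable, so
the reference carrier proportion is approximated by TAC/ANmax: the summed
alternate-allele count of qualifying variants (reference MAF < 1%,
per-variant missingness < 20%) divided by the largest per-variant number of
individuals with allele information. The approximation treats every
reference allele as a distinct heterozygous carrier, valid when double
carriers are rare and coverage near-uniform; TAC therefore enters the 2x2
directly as the reference carrier count.

Two tests per gene and class — cases vs reference and controls vs reference
— feed a per-gene verdict pooled over all comparable classes:

* any class with control *excess* (OR > 1) at p < 1e-3: **not_analyzable**
  (the reference lacks variants for this gene);
* otherwise control *depletion* at p < 1e-3: **potential_false_positive**
  (the cohort's controls under-detect variants here, which inflates the
  case-control OR);
* otherwise depletion at p < 0.1: **questionable**;
* otherwise: **reinforced**.

The 1e-3 / 0.1 thresholds are package choices (both configurable): they
separate the severe control anomalies from mild ones on the fixture tables
while leaving unremarkable genes untouched. Pooling across classes matters:
a gene can look clean in its headline class yet show significant control
depletion only when Mis1 variants are included, and the verdict should
reflect that.

## The synthetic-cohort generator

`simulate_cohort` emulates the target study design. Defaults are the study
conditions: 92 cases and 1051 controls; rare heterozygous qualifying
variants; negative-binomial read depth (mean 50, size 10, matching deep
exome coverage); genotype quality ~ N(80, 15) clamped to [0, 99]; 1%
genotype missingness; heterozygous allele-balance ~ Beta with concentration
50 around 0.5. Carrier status is drawn per gene and damage class with the
configured control frequency `q`, and the case probability solves
`odds(p) = OR * odds(q)` — parameterizing enrichment on the odds scale makes
the input OR the estimand of the burden test, so parameter recovery is
well-defined. Carriers receive one qualifying variant drawn uniformly from
the gene's variant list (heterozygous by default, since MAF < 1% makes
homozygotes negligible; homozygous and multi-variant carriers are options
that exercise the union-counting semantics).

Violation knobs plant one QC defect each — uniform low depth, skewed
heterozygous allele balance, case-only extra missingness, masked-region
placement — and the suite asserts each is caught by exactly the intended
rule. The generator writes standard VCF/TSV/BED, is byte-identical under a
fixed seed (component substreams derive from the root seed), and emits a
truth table whose realized carrier counts the pipeline reproduces from the
emitted files.

What the generator does *not* emulate: linkage disequilibrium between
variants, read-level artifacts, ancestry structure, and batch effects.
Passing tests on synthetic cohorts therefore demonstrate the correctness of
the counting and testing machinery under the stated sampling model, not
robustness to the full messiness of real exome data.

A deterministic fixture (`study_fixtures`) encodes the published top-hit
tables of the 92/1051 bipolar-disorder design: thirteen 2x2 carrier tables,
the reference TAC values with an assumed ANmax of 33,370 (the panel size
that back-computes from the printed carrier percentages and odds ratios;
per-gene ANmax values are not published, so the reference comparison is
validated as a soft, label-level check rather than a hard numeric one), and
one additional *synthetic* Mis1-inclusive reference/cohort entry for LGR5,
which realizes the narrated Mis1-driven control depletion that the printed
tables omit. Each fixture gene's variants take the deepest damage class of
its published collapsing class, and carriers are spread over enough variants
(at most 20 carriers each, i.e. cohort MAF <= 0.00875) to keep every site
rare.

## Numerical choices and degenerate inputs

* Exact-test probabilities are computed on the log scale (`lchoose`,
  `lfactorial`) and renormalized, so tables with large margins (1143 vs
  33,370) lose no precision; tie comparison uses the `1 + 1e-7` relative
  tolerance.
* Zero margins return p = 1; a gene with no qualifying variant is reported
  untestable rather than p = 1, so it cannot dilute the FDR.
* OR = Inf (no control carriers) and OR = NA (no carriers at all) are
  preserved through the TSV writer/reader round trip.
* The burden scan orders results by (p, gene) and breaks per-gene class
  ties toward the most restrictive class; both make reruns bit-identical.
* pi-hat clamps each moment estimate to [0, 1] and renormalizes before
  computing P(IBD=1)/2 + P(IBD=2).

## Problem sizes in the shipped checks

The test suite and the acceptance script run at desk scale: exhaustive
oracle comparison of the Fisher kernel on all 2x2 tables to total 16 plus
2,000 random tables to total 60, and of the HWE kernel on all configurations
to 20 individuals plus 200 random ones to 30; a 2,000-gene null scan at the
92/1051 design for the empirical type-I error (Fisher's conservatism keeps
it near 3%, below the nominal 5%); and 500 count-level replicates for
recovery of a planted OR = 15 at control carrier frequency 0.004. These
sizes were chosen as the smallest that make the properties sharp.

## Known limitations

* The burden test is carrier-based collapsing only: no dosage weighting, no
  covariate adjustment, no SKAT-style variance-component test.
* The reference comparison is a consistency check, not a meta-analysis;
  without individual-level reference genotypes the TAC/ANmax approximation
  inherits coverage and stratification biases, and verdicts are only as
  good as the assumed ANmax.
* Gene models are annotation-tool territory: the package consumes effect
  terms and LOF flags and does not recompute positions against transcripts
  (the +/- 2 bp splice-site window is enforced upstream by the controlled
  effect-term vocabulary).
* The relatedness estimator needs a few hundred common sites; rare-variant-
  only panels skip the step with a warning.
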