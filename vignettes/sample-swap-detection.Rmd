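---
title: "Detecting sample swaps and mislabels from targeted NGS SNP fingerprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting sample swaps and mislabels from targeted NGS SNP fingerprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpswap)
library(dplyr)
```

## The problem

Clinical sequencing laboratories that process thousands of samples per year
inevitably face handling errors: two tubes interchanged (a *swap*), a sample
assigned to the wrong patient (a *mislabel*), or low-level cross-sample
contamination. Sequenced DNA can be traced back to its donor, so such
errors are detectable in silico — provided enough identity-informative
positions are covered. Targeted next-generation sequencing (tNGS) panels
cover only a few hundred kilobases, so the SNP lists shipped with
whole-genome tools are almost entirely uncovered and every tNGS assay needs
its own custom fingerprint panel.

`snpswap` implements the complete workflow:

1. **Panel selection**: derive an informative, linkage-pruned SNP panel
   from accumulated cohort variant data.
2. **Genotyping**: count reference/alternative reads at the panel loci
   directly from coordinate-sorted BAM files and discretise to genotypes.
3. **Concordance scan**: compare every pair of samples by the fraction of
   concordant genotype calls and the correlation of variant allele
   fractions (VAFs); verify that expected same-patient pairs really match.
4. **Synthetic cohorts**: simulate genotypes, read counts, planted
   handling errors and miniature BAM fixtures, so the whole pipeline is
   testable without patient data.

## The fingerprint model

A diploid germline SNP with population alternative-allele frequency $p$
has genotypes HOM\_REF, HET, HOM\_ALT with Hardy–Weinberg frequencies
$(1-p)^2,\; 2p(1-p),\; p^2$, and its VAF in a pure sample clusters near
0, 0.5 or 1. Two samples from the same person agree at essentially every
panel locus (up to copy-number effects and sampling noise); two unrelated
people agree at a locus only with probability $\sum_g f_g^2$, about
0.35–0.55 for informative SNPs. With $L$ independent loci the probability
that unrelated samples agree at $\ge 80\%$ of them decays geometrically
in $L$; 28 informative SNPs make chance matches negligible in cohorts of
thousands, which is why the bundled panel has 28 loci and why assays
should aim for at least ~25 usable independent SNPs.

A pair of samples is summarised by two statistics over the loci called in
*both* samples ("evaluable" loci):

* **fraction of concordant genotype calls** — robust to modest VAF noise,
  and
* **Pearson correlation of the VAF vectors** — retains the quantitative
  signal that discretisation discards.

Both must be high to flag a pair:

| status | condition (defaults) |
|---|---|
| `MATCH` | correlation ≥ 0.9 and fraction ≥ 0.8 |
| `BORDERLINE_MATCH` | correlation ≥ 0.9 and 0.7 ≤ fraction < 0.8 |
| `NO_MATCH` | otherwise |
| `UNEVALUABLE` | fewer than 10 jointly called loci |

The borderline band exists because same-patient tumour pairs can disagree
at a handful of loci for benign reasons: a clone with a chromosomal gain
or loss that changed between timepoints shifts heterozygous VAFs away
from 0.5 on that chromosome, and low coverage adds stochastic miscalls.
Such pairs show high VAF correlation with depressed concordance and
deserve manual review rather than a hard verdict; setting
`concordance_match = concordance_floor` collapses the rule to a single
threshold of 0.7. Pairs are *earmarked*, never silently reassigned —
resolving who is who requires orthogonal evidence (e.g. FISH or IGHV
status in a leukemia setting).

Expected same-patient pairs are derived from the sample names: by
convention the first run of digits is the patient identifier
(`CLL-<patient>-<run>-TP<k>`), overridable by any single-capture-group
regular expression or an explicit pairs table. An expected pair whose
scan status is `NO_MATCH` (verdict `DISCORDANT`) indicates a probable
handling error; a flagged pair whose patient identifiers differ is an
*unexpected match* — the signature of a swap or mislabel.

## Panel selection

Starting from a cohort variant matrix (all SNVs that a somatic pipeline
normally discards: intronic, synonymous and known non-pathogenic
variants, with their per-sample VAFs), `select_panel()` applies four
stages:

1. **Population AF window** (`[0.1, 0.9]`, inclusive): rare or near-fixed
   SNPs rarely differ between two random people. A candidate is kept if
   *either* the genome-derived or the exome-derived AF annotation falls
   in the window; the bounds are treated as inclusive since SNPs at
   exactly 0.1/0.9 are still informative.
2. **Artefact removal**: recurrent technical artefacts masquerade as
   variants with a *similar VAF in essentially all samples*, unlike a
   real SNP whose VAF segregates 0 / 0.5 / 1 across carriers. This is
   quantified as: present in ≥ 90% of samples *and* VAF standard
   deviation ≤ 0.05. Both knobs are configurable; the qualitative rule
   they quantify is a judgement call and the defaults are declared
   assumptions.
3. **Low-prevalence removal**: a SNP carried (VAF ≥ 0.1) by fewer than 5%
   of cohort samples contributes little discrimination. The 5% default
   is likewise a declared assumption, logged in the selection report.
4. **Linkage pruning**: SNPs in linkage disequilibrium are redundant.
   Linkage groups are an *input* (precomputed from pairwise r², e.g. with
   an external LD tool — computing LD from reference panels is out of
   scope); from each group the SNP with mean cohort VAF closest to 0.5 is
   kept, ties broken deterministically to the lowest genomic coordinate.

Every stage is a pure function of its inputs, so re-running the pipeline
on the same matrix, groups and thresholds reproduces the panel exactly.

Panels are BED-like on disk (0-based half-open, one line per SNP, columns
`chrom start end rsid ref alt [af]`) and 1-based internally. The bundled
28-SNP panel (`bundled_panel()`) carries published rsIDs for a chronic
lymphocytic leukemia tNGS assay, but its coordinates, alleles and allele
frequencies are synthetic stand-ins placed on short contigs so that the
package's simulations and BAM fixtures are self-contained — it is a
template and a test surface, not a resource for genotyping real
alignments.

## Genotyping from BAMs

`extract_readcounts()` pileup-counts each panel locus with standard
hygiene: duplicate, secondary, supplementary and unmapped reads are
excluded, reads need mapping quality ≥ 10 and bases quality ≥ 20
(defaults). Overlapping read pairs are counted per read, not per
fragment, which at worst doubles the weight of the overlapped bases;
this is documented, deterministic behaviour. The VAF denominator is
`ref + alt` only — other bases are reported (`other_count`) for QC but
excluded so the VAF stays interpretable as a biallelic allele fraction.

Discrete calls mirror the diploid VAF anchors: below 30 reads the locus
is `NO_CALL`; otherwise VAF < 0.1 → `HOM_REF`, 0.1–0.9 → `HET`,
> 0.9 → `HOM_ALT`. The het window deliberately matches the panel's
population-AF window and the 0/0.5/1 contamination anchors. All
thresholds are settings of `quality_config()`, because none of them is
canonical: depth 30 is a common tNGS minimum at which binomial noise
cannot carry a heterozygous VAF across either boundary with appreciable
probability, but assays with shallower coverage may need to loosen it.

## Numerical choices

* **Correlation** is computed on VAFs, not genotype codes: VAFs are what
  the read-count report stores, and they explain the borderline
  copy-number cases that motivate the three-valued status.
* **Degenerate correlation**: Pearson correlation is undefined when
  either VAF vector is constant (e.g. a sample homozygous-reference at
  every shared locus). The rule used everywhere is: 1 if the two vectors
  are elementwise within 0.1, else 0 — so comparing such a profile with
  itself is sane, and with a complementary profile is not a match.
* **Precision**: all statistics are kept at full precision internally and
  rounded to 3 decimals only in the CSV reports.
* **Zero discordance** is a normal outcome (identical profiles), not an
  error; a regression test pins this.
* **Sparse overlap**: pairs with < 10 jointly called loci are reported
  but labelled `UNEVALUABLE` instead of being classified on almost no
  evidence.
* The all-vs-all scan is vectorised over the full pair matrix (matrix
  products over the evaluable-locus masks), is exactly equivalent to the
  per-pair path (`compare_pair()`), and handles ~80,000 pairs in well
  under a second; it remains $O(n^2)$ by design, and the command-line
  front end warns beyond 5,000 samples.

## The synthetic cohort generator

`simulate_cohort()` emulates the structure of a longitudinal tNGS study:
`n_patients` patients, each sequenced at (by default) 2 timepoints.
Genotypes are drawn once per patient under Hardy–Weinberg from the
panel's population AFs; each sample then gets independent read noise:
depth ~ negative binomial (mean 100, dispersion parameter 100 — mildly
overdispersed, as targeted assays are; large dispersion approaches
Poisson), and alternative reads ~ binomial with expected allele fraction
$e$, 0.5 or $1-e$ for the three genotypes, with per-read error
$e = 0.001$. These defaults are the package's baseline study conditions:
typical tNGS fingerprint loci see hundreds of reads, and 100× is a
deliberately conservative floor at which genotype miscalls are already
negligible.

Planted errors come with exact truth bookkeeping. Swaps and mislabels
move *labels* only — the genotype matrix is untouched — and the implied
pair lists are recomputed generically from the final label↔patient map:
every label pair from different patients sharing a true genotype is an
expected *unexpected match*, every same-label pair with different true
genotypes is a *broken expected pair*. One swap between two patients'
timepoint-2 samples therefore implies exactly 2 unexpected and 2 broken
pairs; a mislabel onto another existing patient implies 1 unexpected and
(if that patient has two samples) 2 broken pairs. Contamination mixes
expected allele fractions at the given fraction and re-draws reads;
copy-number shifts add a VAF delta to the heterozygous loci of one
chromosome. `write_fixture_bams()` renders any synthetic cohort into
coordinate-sorted, indexed miniature BAMs (plus a synthetic reference
FASTA, one short contig per chromosome) whose pileup reproduces the
simulated counts read-for-read, closing the loop through the real
extraction code path.

What the generator does **not** emulate: read-level error profiles and
mapping ambiguity, indels, linkage between panel loci, population
stratification of allele frequencies, tumour clonal evolution beyond the
single-chromosome VAF shift, and library-level artefacts. Passing the
simulation-based tests therefore demonstrates the correctness of the
bookkeeping, thresholds and algebra under the stated noise model — not
the wet-lab performance of any particular assay.

## Contamination heuristic

Cross-individual contamination pulls VAFs off the 0/0.5/1 anchors.
`contamination_score()` reports the mean distance to the nearest anchor
over evaluable loci, lists loci deviating by more than 0.1, and flags
samples scoring above 0.05. At 10% contamination the expected shift at
discordant loci is only 0.05–0.1 and the *mean* over all loci is ≈ 0.04,
i.e. just below the default flag — the default is conservative, tuned to
avoid flagging copy-number noise; lower `flag_threshold` to ~0.03 to
chase milder contamination at high depth. This is a screening heuristic,
not a maximum-likelihood contamination estimator.

## Subset-size experiments

`subset_sensitivity()` re-runs the scan on random locus subsets
(deterministic per-(size, iteration) seeds derived from the master seed)
against a planted truth, reporting detected unexpected pairs, detected
broken expected pairs, and false positives — defined operationally as a
`MATCH` between samples that share no patient identifier and are not
planted duplicates. Under the baseline conditions sensitivity stays
complete down to 18 SNPs while false positives grow rapidly below ~20
SNPs; the per-size *means* over 10 iterations can wiggle at adjacent
sizes where false positives are near zero, so the tests assert the trend
rather than strict per-step monotonicity.

## A worked example

```{r example}
panel <- bundled_panel()
cohort <- simulate_cohort(panel, n_patients = 20, seed = 1)
tp2 <- cohort$samples$sample_id[cohort$samples$timepoint == 2]
cohort <- plant_errors(cohort, list(swap_error(tp2[1], tp2[2])))

scan <- scan_cohort(cohort$profiles, quiet = TRUE)
scan
scan$unexpected_matches
scan$expected %>% filter(verdict == "DISCORDANT")
```

The two unexpected matches and two discordant expected pairs are exactly
the pairs implied by the planted swap
(`cohort$truth$unexpected_pairs`, `cohort$truth$broken_expected`).
Reports are written by `swap_check()`
(`Pairwise_concordance_*.csv`, `SNP_readcounts_*.csv`,
`Expected_concordant_pairs_*.csv`, optional heatmap PNG); the timestamp
in every file name is injectable so runs are byte-reproducible.

## Problem sizes used by the test-suite

The packaged tests and the acceptance script use cohorts of up to 200
patients × 2 timepoints (79,800 pairwise comparisons), 10 replicate
seeds for the planted-error recovery property, 10 iterations per subset
size for the shrinking-panel experiment, 10,000 draws per allele
frequency for the Hardy–Weinberg checks, and 4-sample cohorts for the
BAM round trip — sizes chosen so that every stochastic property is
measured with comfortable margins while the whole suite stays quick on a
laptop.

## Limitations

* The fingerprint identifies *individuals*, not sample types: a swap
  between two samples of the same patient is invisible by construction.
* Cohorts sampled at a single timepoint can reveal duplicates under two
  names, but not plain swaps or mislabels (nothing is expected to match).
* 28 SNPs distinguish subjects within studies of thousands, not within
  the whole human population; forensic panels use 45+ independent SNPs.
* Verdicts point at *probable* errors; re-linking a sample to its true
  patient requires orthogonal evidence and is deliberately out of scope.
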