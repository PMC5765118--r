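---
title: "Quantifying activation-induced intron removal and its proteogenomic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying activation-induced intron removal and its proteogenomic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plateletIR)
```

## The biological question and the measurement model

Platelets are anucleate, yet they carry mRNAs, spliceosomal components and
— notably — partially spliced pre-mRNAs inherited from megakaryocytes.
Upon activation (e.g. by collagen, COLL, or thrombin-receptor activating
peptide, TRAP) some retained introns are excised in the cytoplasm and the
matured messages can be translated, so intron removal becomes a
post-transcriptional switch that reshapes the platelet proteome without
transcription. `plateletIR` implements the complete computational chain
needed to study this: per-intron retention quantification from RNA-seq
alignments, permutation-based differential testing, construction of a
proteogenomic junction-peptide database, peptide-to-junction mapping, and
the integrative join of all three data layers.

### The IR ratio

For an intron $i$ in sample $s$ the intron retention ratio is

$$
\mathrm{IR}_{is} \;=\;
\frac{a_{is}}{a_{is} + j_{is}},
$$

where $a_{is}$ is the *intronic abundance* — here, the median per-base read
depth over the intron's measurable region — and $j_{is}$ is the *exon splice
abundance* — the number of reads whose alignment gap (CIGAR `N` interval)
matches the intron's boundaries exactly. The ratio is 1 for a fully
retained intron, 0 for a fully spliced one, and missing when neither kind
of evidence exists ($a + j = 0$). Gapped reads whose gap only partially
overlaps the intron count for neither term: a junction read is evidence of
this precise splicing event only when both boundaries agree, and a
partially overlapping gap is evidence of a different isoform.

Upstream IR tools leave the abundance estimator partly unspecified; we use
the median of per-base depth because it is robust to residual overlap
artifacts at intron edges and is exactly testable against a brute-force
per-base pileup (the test suite does precisely that). The *measurable
region* excludes any position covered by an exon of any transcript or by a
small structured RNA (miRNA, snoRNA by default) nested inside the intron,
since coverage over such features reflects their own expression, not
retention of the host intron.

### Retention filter

An intron is called *retained* in a condition when, in at least 2 of the 3
biological replicates, its IR ratio is non-missing and strictly greater
than that sample's first quartile of the non-missing IR distribution. The
quantile (default 0.25) and the replicate rule (default 2 of 3) are
parameters of `ir_filter_params()`. "First quantile" admits more than one
reading; we take the first quartile, the most common one, and expose it as
a parameter rather than hard-coding the interpretation.

## Permutation statistics on a 3 + 3 design

Differential calls (introns: treated vs resting IR ratios; proteins:
treated vs resting log2 intensities; junction peptides: summed spanning
abundances) all use the same machinery, `permutation_test()`:

* the statistic is the two-sample pooled-variance t with a small
  stabilization constant $s_0$ added to the denominator,
  $t = (\bar{x}_2 - \bar{x}_1) / (\mathrm{SE} + s_0)$. By default $s_0$ is
  the median of the per-feature standard errors; this is the fudge-factor
  statistic of significance-analysis-of-microarrays lineage that
  proteomics permutation tests commonly use. Without it, features with
  accidentally tiny within-group variance dominate both tails of the null
  and the observed statistics; with it, the statistic is effectively an
  effect size once the variance falls below typical noise. Setting
  `s0 = 0` recovers the plain Student statistic (zero-variance features
  then get $t = 0$).
* the null distribution pools permuted statistics **across features**. A
  3 + 3 design admits only $\binom{6}{3} = 20$ distinct label assignments,
  so a per-feature null can never produce $p < 1/20$; pooling across
  features is the only way the stated significance levels (protein
  Bonferroni at $\alpha$ 0.01, intron BH-FDR 0.01) are attainable. The
  default 10000 permutations are drawn with replacement — realized
  efficiently as multinomial weights over the distinct assignments — and
  the observed labeling and its mirror are excluded from the null, since
  for features with genuine effects they would re-inject the full effect
  into the null distribution. p-values carry +1 smoothing in numerator and
  denominator.
* an `exact-per-feature` mode enumerates all 20 assignments per feature
  for auditing; its p-values are bounded below by 1/20 by construction.

Adjustment defaults follow the respective data layers: proteins use
Bonferroni at $\alpha$ 0.01 plus the linear fold-change cutoff
$|\mathrm{FC}| \ge 1.2$ (a ratio of group medians at or beyond 1.2 in
either direction); introns use BH-FDR at 0.01, with "removed" meaning
significant with negative IR change; transcripts use $|\mathrm{FC}| \ge 1.5$
at BH-FDR 0.05; junction peptides BH-FDR 0.05. All are `diff_config()`
fields.

## The junction-peptide database

For every intron retained in resting samples, the exon–exon junction of
the *matured* transcript is a validation target: once the intron is
removed and the message translated, peptides crossing that junction become
detectable by MS. `build_junction_db()` extracts up to 75 exonic
nucleotides on each side of the junction — the spliced context, not the
genomic window, because a genomic window would contain intron sequence and
could never yield a junction-spanning peptide — and translates the
concatenated window in all three reading frames. Exons shorter than the
flank are truncated, never extended into the next exon. On the minus
strand the flanks are taken in mRNA orientation and reverse-complemented.
Stop codons are kept as `*` in the database entries (preserving frame
bookkeeping); matching refuses any occurrence whose span would cross a
stop.

A match *spans the junction* when its coding nucleotide span has at least
one base on each side of the junction offset $L$ (strict inequalities):
the minimal evidence that the peptide crosses the splice boundary.
Isoleucine/leucine equivalence — the two are isobaric and indistinguishable
in spectral searches — is off by default (sequence-level matching can
afford to be stricter) and available as a flag. Junction-level
quantification sums the abundances of all spanning peptides of a junction
before computing fold-changes; there is no standard aggregation for
per-junction peptide changes, and summation is the simplest one that
respects detection sparsity.

## What the synthetic generator emulates

`simulate_study()` generates, deterministically from one root seed: a toy
genome and annotation (default 30 genes, 2–4 exons of 90–150 nt, introns
of 260–440 nt, every tenth gene carrying a snoRNA inside an intron to
exercise the exclusion mask); per-sample single-end stranded alignments in
SAM (dUTP protocol: reads align antisense to the transcript); log-normal
TMT-like protein intensities; and a peptide table whose junction peptides
are taken from the package's own three-frame translations.

Per intron and sample with true retention $\psi$ and evidence depth $D$
(default 60), the generator draws $\mathrm{Pois}((1-\psi)D)$
junction-spanning reads with CIGAR gaps matching the intron exactly, and
enough fully-intronic reads that expected interior coverage is $\psi D$ —
so the estimated IR ratio converges to $\psi$ as $D$ grows (a tested
property). Baseline retention is uniform on [0.35, 0.75]; planted removal
subtracts 0.4 from the treated-group truth for 25% of introns per
stimulus. Planted removal is drawn from introns in the upper part of the
baseline IR distribution (above its 0.4 quantile): the filter-then-test
design only ever evaluates removal for introns retained at rest, so a
removal event planted on a sub-threshold intron would be invisible to the
stated analysis by construction, not by failure. Of the genes with planted
removal, 80% also emit a stop-free junction-spanning peptide
(up-regulated 2.8-fold in the stimulated group where the removal is
planted) and an up-regulated protein — these are the "spliced and
translated" genes the integration stage should recover as `validated`.
A count-level twin, `simulate_ir_matrix()`, reproduces the same sampling
model without SAM I/O for statistical calibration experiments.

The generator deliberately omits: sequencing errors and quality modeling,
paired-end fragments, isoform-linked retention (each intron is
independent), library-size and composition effects, and peptide
detectability modeling. Passing tests therefore demonstrate correctness of
the measurement and inference chain under the stated sampling model — not
robustness to alignment artifacts or MS acquisition biases in real data.

## Numerical and design choices

* **Coordinates.** All internal intervals are 1-based closed
  (`IRanges`/`GRanges`), the native R genomics convention; GTF needs no
  conversion, and SAM `POS` is already 1-based. Output TSVs use the same
  convention.
* **Degenerate inputs.** IR ratio is missing (not 0) when both abundances
  are zero; differential IR drops introns with a missing ratio in any
  compared sample; `log2_median_summary()` refuses nonpositive
  intensities; empty junction databases and empty peptide sets round-trip
  as valid empty files.
* **Ties and determinism.** Permutation p-values use a $10^{-12}$ tolerance
  when comparing `|t*| >= |t|` so exact ties (e.g. the all-equal case)
  count as exceedances; every stochastic stage derives its own seed from
  the root seed, and `run_all()` reruns are byte-identical (md5-checked in
  the manifest and in the tests).
* **Problem sizes.** The default study (30 genes, ~60 introns, 9 samples,
  depth 60) and the calibration experiments (500–600 introns, 5–10
  replicate simulations) are sized so the entire suite runs on a laptop
  core in minutes while keeping the planted-effect recovery statistically
  meaningful.

## Known limitations

* The pooled permutation null assumes features are largely exchangeable;
  with very few features (say, fewer than ~20) the pooled ecdf is coarse
  and p-values degrade gracefully toward the per-feature bound.
* Transcript differential expression is a simple mean-FPKM log-ratio with
  the same permutation machinery — a deliberate stand-in at this scale,
  not a negative-binomial count model; it inherits FPKM's compositional
  sensitivity when a few transcripts dominate the library.
* Junction deduplication keys on genomic coordinates only; two genes
  sharing an identical intron (rare, overlapping loci) would share a
  junction entry.
* Peptide matching is substring-based against full frame translations; no
  in-silico tryptic digestion is performed, so enzyme-specific termini are
  not modeled.
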