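---
title: "Quantifying splicing restoration and ncRNA targeting of splice-event regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying splicing restoration and ncRNA targeting of splice-event regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dasetools)
```

## The analysis in one paragraph

`dasetools` analyzes *rescue experiments* at the level of alternative
splicing. Three conditions — control, a treatment that perturbs splicing, and
a rescue arm in which a candidate compound is applied before the treatment —
are compared through two ordered contrasts (treatment vs control, rescue vs
treatment). For each alternative-splicing event the package estimates PSI
(percent spliced in) from junction read counts, tests the contrast with a
binomial likelihood-ratio test, filters to differential alternative splicing
events (DASEs), and then asks the central question: for the events perturbed
in *both* contrasts, did the rescue move PSI back (opposite ΔPSI signs —
"restoration") and back *toward the control level* (absolute-PSI proximity)?
Downstream stages characterize the affected regions: premature stop codons in
retained introns, miRNA binding sites classified by seed rules, antisense
lncRNA overlap, and gene-set over-representation.

## PSI from junction counts

An event class determines how many distinct junctions support each isoform:
a skipped exon (SE) or retained intron (RI) has two inclusion-supporting
junctions and one skipping junction; mutually exclusive exons (MXE) have two
on either side; alternative 3'/5' splice sites (A3SS/A5SS) one each. With
inclusion reads $I$, skipping reads $S$, and multiplicities $L_I$, $L_S$:

$$\hat\psi = \frac{I/L_I}{I/L_I + S/L_S}.$$

The normalization removes the advantage the inclusion isoform gains from
being observable at more junctions. `estimate_psi(10, 10, "SE")` is therefore
$1/3$, not $1/2$. Events with $I = S = 0$ are not quantifiable and are
excluded with an explicit reason rather than silently assigned a value.

## The differential test

Replicate counts within a condition are modeled as
$I \sim \mathrm{Binomial}(I + S,\ \theta(\psi))$ with
$\theta(\psi) = \psi L_I / (\psi L_I + (1-\psi) L_S)$. The test compares a
null with one common $\psi$ across both groups against an alternative with
one $\psi$ per group; within a group the MLE pools replicate counts (the
pooled fraction is the sufficient statistic when replicates share a
$\psi$). Twice the log-likelihood ratio is referred to $\chi^2_1$.

This is a deliberate simplification: established junction-count tools model
between-replicate overdispersion with a paired hierarchical likelihood.
The pooled binomial LRT is the minimal test consistent with the counting
model, it is exactly calibrated to check (the suite verifies an empirical
false-positive rate of about 5% at $p \le 0.05$ on 10,000 null events at
coverage 100), and `read_rmats()` lets users import a tool's own statistics
and bypass the internal test entirely. With only two replicates per
condition, estimating a dispersion parameter per event would be noise
masquerading as rigor.

DASE filtering applies three closed thresholds, all exposed in
`pipeline_config()`: FDR $\le 0.05$ (Benjamini–Hochberg, computed within
each event class by default, mirroring per-class output files; switchable
with `fdr_by_class = FALSE`), $|\Delta\mathrm{PSI}| \ge 0.1$, and mean
coverage $\ge 5$. "Coverage" is not standardized across tools; here it is
the mean of $I + S$ over all replicates of both groups, and the definition
is recorded in the run manifest.

## Restoration

Events are matched across contrasts on a full identity key — class,
chromosome, strand, gene id, and every coordinate of the event — rather than
gene name, since one gene can host several events. An event is *restored*
when its two ΔPSI values are nonzero with strictly opposite signs; a zero
ΔPSI has no direction and counts as not restored. *Proximity* asks the
stronger question of levels, not just directions:
$|\psi_{ctr} - \psi_{rescue}| < |\psi_{ctr} - \psi_{trt}|$, with ties
counting as not proximal. Both choices are conservative: they can only
understate the rescue effect.

## Event regions and sequences

Region rules per class (all internal coordinates 0-based half-open,
BED-style; GTF input/output converts at the boundary): SE uses the cassette
exon; RI the intron between the flanking exons; MXE the first exon on the
plus strand and the second on the minus strand; A3SS/A5SS the long exon
minus its overlap with the short exon, which is contiguous because the two
share one boundary. Minus-strand sequences are reverse-complemented after
extraction, so every downstream consumer sees sense-strand 5'→3' sequence.
`N` bases are preserved and never pair in the duplex model.

## Stop-codon scanning

`scan_stop_codons()` reads non-overlapping codons from offset `frame - 1`
and counts TAG/TAA/TGA. Reading frames are *inputs*: in real data the frame
of an intron depends on the upstream coding context, which the package does
not reconstruct; a helper reports all three frames. The first premature stop
is reported in two units — the 1-based codon index and the 1-based
nucleotide position of the codon's first base. Curated retained-intron
reports conventionally print the nucleotide position (it is the unit
consistent with a position like 41 inside a 120-nt intron read in frame 2),
so Table-shaped outputs and the bundled example table use `first_stop_nt`.

## The duplex model and seed-rule classification

`duplex_mfe()` is a nearest-neighbor dynamic program over *intermolecular*
pairings only: Watson–Crick and G:U pairs, stacking energies for adjacent
pairs, size-dependent bulge and interior-loop penalties (capped at 15 nt per
strand, a typical duplex-tool default), and a duplex initiation cost. There
is no intramolecular structure and no target-accessibility term. Parameters
live in a TSV (`inst/extdata/duplex_energy_model.tsv`) so the model is data,
not code; the shipped values have Turner-magnitude stacking strengths
generated from a pair-strength formula and are calibrated to *rank and
sign* of duplex stability, not to reproduce any external tool's printed
energies. `rnaduplex_mfe()` shells out to ViennaRNA's RNAduplex, when
installed, as an independent sanity check. Ties between equal-energy sites
break deterministically: lowest target start, then most paired positions.
Only the best site per miRNA:target pair is reported.

Classification operates on the pairing trace, with miRNA positions 2–7 as
the seed and 13–16 as the post-seed region. Only Watson–Crick states count
as matches — a G:U wobble is a mismatch by construction, which matters
because the folding stage *does* allow wobble pairs; a duplex can be
energetically strong yet Unclassified. The four outcomes:

| seed 2–7            | post-seed 13–16      | class        |
|---------------------|----------------------|--------------|
| all WC              | zero WC              | Canonical    |
| all WC              | all four WC          | Strong       |
| ≥ 1 non-WC          | all four WC          | Compensatory |
| anything else       |                      | Unclassified |

Partial post-seed pairing (1–3 WC positions) is deliberately Unclassified in
all cases. The funnel applies two energy gates: a prediction-stage
prefilter at −20 kcal/mol and a final filter at −30 kcal/mol combined with
a non-Unclassified class. The A1 flag records an adenosine opposite miRNA
position 1 (a known determinant of Argonaute recognition); when position 1
is unpaired the opposite base is projected from the nearest pair, and a
position overhanging the target end yields `FALSE`.

## ncRNA annotation

The tissue-expression filter computes the 90th percentile (linear
interpolation between order statistics, `quantile(type = 7)`; both the
percentile and hence the definition's behavior are exposed) of the
expression values recorded for the tissue and keeps hybridizations whose
miRNA meets it; miRNAs without expression data are dropped but tallied, so
the funnel stays auditable. Antisense lncRNA mapping reports every
event-region/transcript pair with ≥ 1 bp genomic overlap on opposite
strands; whole transcript spans are used (block-aware overlap would require
exon structures, which many lncRNA annotations lack). Disease-association
annotation is a cardinality-preserving left join; absence of an association
is recorded as `"none"`, never used to drop a hybridization.

## Enrichment

`ora()` is a plain one-sided hypergeometric test with BH correction and fold
enrichment $(k/n)/(K/N)$. Gene sets and the background universe are user
inputs: no term database is bundled, so results are reproducible exactly
when the same annotation snapshot is supplied. Each event contributes its
gene once.

## What the generator emulates — and what it does not

`simulate_bundle()` produces a genome, annotation, junction counts, miRNA
pool, expression table, lncRNA intervals and gene sets with planted truth.
The counting model inverts the PSI estimator: totals
$N \sim \mathrm{Poisson}(\mu)$, inclusion reads
$I \sim \mathrm{Binomial}(N, \theta(\psi))$. Defaults encode the emulated
study design: 2 replicates per condition, three conditions, every event
restored (`frac_restored = 1`), planted $|\Delta\mathrm{PSI}| = 0.3$
(mid-range for reported rescue effects), control PSI uniform in
[0.25, 0.75], and mean coverage 100 — sequencing depth is a package choice,
as junction-level depth is rarely reported. One integer seed drives a single
pseudorandom stream; emitted files are bit-reproducible.

Planted signals are exact by construction: retained introns are built from
non-stop codons with stops written only at planned codons (so the scan truth
is unambiguous), and miRNA sites are exact reverse complements of the miRNA
with class-specific breaks — positions 13–16 broken for Canonical sites, one
seed position for Compensatory — using replacement bases that can neither
WC- nor wobble-pair.

The generator does **not** simulate: raw reads or alignment artifacts,
overdispersion between replicates (counts are exactly binomial at the
planted PSI), expression-level structure, splice-site sequence signals, or
genome repeat content. Passing tests on synthetic data therefore demonstrate
the pipeline's correctness under its own counting model, not robustness to
alignment noise or biological replicate variability — for real data the
`read_rmats()` adapter exists precisely so that a tool designed for those
problems can feed this package's downstream stages.

## Numerical choices and degenerate inputs

* LRT statistics are clamped at 0 and p-values to [0, 1]; `0·log 0 = 0`.
* BH ties keep the input order (stable).
* Events with an all-zero group are excluded with reason
  `"zero_counts_in_group"`; too-short sequences report zero stops plus a
  `too_short` flag; a zero-event simulation yields an empty bundle.
* Duplexes with best energy ≥ 0 are "no hybridization" results, not errors.
* Strandless interval records are excluded with a diagnostic, not treated
  as either strand.

## Problem sizes used by the test suite

The suite's property checks use 10,000 events for null calibration and sign
recovery at coverage 100; 100 seeded bundles of 12 events at coverage
10,000 for restoration recovery; 1,000 random sequences × 3 frames against
the translate-and-count oracle; exhaustive enumeration up to 8 nt against
the duplex DP; and all 2¹⁰ collapsed seed/post-seed patterns against the
classifier rule table. These sizes give the observed rates (e.g. a null
rejection rate near 0.05) standard errors comfortably inside the asserted
bands.

## Known limitations

* The internal energy model ranks duplexes sensibly but its absolute
  energies are not comparable to published duplex tools' values.
* Reading frames for retained introns must be supplied; the package does
  not reconstruct coding context from the annotation.
* The restoration analysis reports observed fractions; it does not test
  whether the restored fraction exceeds what chance intersection of two
  DASE lists would produce.
* lncRNA overlap uses transcript spans, not exon blocks.
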