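---
title: "Methods: deep-intronic variant discovery in HCM gene panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deep-intronic variant discovery in HCM gene panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deepintron)
```

## The problem

Hypertrophic cardiomyopathy (HCM) is a dominantly inherited sarcomeric
disease with a diagnostic yield of only ~50% from exon-restricted genetic
testing. Whole-gene sequencing of HCM panels exposes the introns, where
pathogenic variation can act by creating pseudo-exons, perturbing splicing
regulatory elements, or disrupting intronic transcription-factor binding
sites. A *deep-intronic* variant is conventionally one at least 100 nt from
the nearest canonical splice site. This package turns that analysis into a
reusable pipeline: multi-caller consensus on whole-gene panel data, in-silico
prioritization of noncoding variants, cohort-level allele-frequency
enrichment, and family-level co-segregation.

## Consensus model

Callers disagree both in which variants they emit and in how they spell
indels. We therefore (i) normalize every call — split multiallelic records,
trim shared trailing/leading bases, left-align against the reference
context — and (ii) apply a k-of-n vote: a variant is retained for a sample
iff at least `k` callers (default 2 of 4) report a non-reference genotype for
that sample. Matching is allele-exact on the normalized
`(chrom, pos, ref, alt)` tuple. Three gaps in the underlying protocol were
closed as package design choices:

* *Depth.* "Read depth ≥ 20" is evaluated as the **minimum** depth among
  supporting callers — the strictest deterministic reading; a missing
  FORMAT/DP loads as depth 0, so an undocumented call can never pass.
* *Genotype disagreement.* Majority vote among supporting callers, ties
  resolved toward het (the weaker claim).
* *"Independently called"* means a non-reference genotype for that sample,
  not site-level presence, since the downstream analysis is per-proband.

Under independent per-caller sensitivity $s$, consensus sensitivity is the
binomial tail $\sum_{j \ge k} \binom{n}{j} s^j (1-s)^{n-j}$ (= 0.9963 at
$s = 0.9$, $k = 2$, $n = 4$). The test suite checks the simulated pipeline
against this closed form within 3 Monte-Carlo standard errors, checks that
consensus precision is never below the best single caller under independent
false positives, and that the retained set is monotone non-increasing in
`k`. The published real-data operating point (~97% sensitivity / ~98%
precision against a reference sample) requires the real read data and the
four real callers and is **not** reproduced at desk scale; the closed-form
property is the substitute, and a green test establishes the consensus
machinery, not the callers.

## Prioritization model

Four precomputed scores are consumed, never computed: CADD (PHRED-scaled
deleteriousness), GWAVA (0–1 region score), Genomiser (0–1 noncoding
pathogenicity), SPIDEX (dPSI splicing impact). Thresholds, with deliberate
comparison directions:

| tool | default | comparison | rationale |
|---|---|---|---|
| CADD | 15 | `>` | "greater than 15" convention for panel screens |
| GWAVA | 0.5 | `>=` | the published table places score-0.5 variants in GWAVA groups, so ≥ is the only table-consistent reading |
| Genomiser | 0.6 | `>` | low end of the tool's published 0.6–0.9 range; the packaged table never scores between 0.56 and 0.82, so the table cannot disambiguate further |
| SPIDEX | 5 | `abs() >` | splicing disruption is directionless; all passing table values happen to be positive |

An absent (NA) score never passes. A variant's *tool set* is the exact subset
of passing tools; tier 1 requires {CADD, GWAVA, Genomiser}, tier 2 any other
≥2-tool set, tier 3 a singleton. On the packaged 26-variant table the
recomputed tool sets reproduce the published grouping row-for-row, and the
triple intersection has exactly 6 members — the strongest fixture property in
the test suite.

## Region and TFBS annotation

Splice distance is the unsigned distance to the nearest exon–intron boundary
of the gene containing the variant (strand-agnostic; the HGVS sign is
display-level). Classes partition gene-span positions: exonic; intronic
distance 1–2 = canonical splice site; 3–99 = proximal intronic; ≥ 100 = deep
intronic; outside all gene spans = intergenic. TFBS annotation is a point
overlap of the variant position with ChIP-seq peak intervals (BED half-open).
Coordinates follow format standards exactly — VCF 1-based, BED 0-based
half-open — so a 1-based position equal to a BED `end` value is the last
covered base and is *inside* the interval.

## Cohort enrichment

Allele frequency counts het = 1, hom = 2, hemi = 1 alt allele over called
alleles; X-linked variants treat males as hemizygous (1 allele), so the
denominator in an 8M/8F cohort is 24, not 32. The published proband
frequencies for X-linked LAMP2 variants are n/32 fractions — i.e. computed
with a diploid denominator; we follow the ploidy-aware convention instead,
which changes those (and only those) fixture frequencies (1/24 ≈ 0.042 vs a
printed 0.03125). All six tier-1 candidates are autosomal and unaffected.
Enrichment defaults to fold ≥ 3 against the 1000G EUR MAF, matching the
"3-fold more frequent" language and reproducing the count of two enriched
variants among the six tier-1 candidates; a zero reference MAF with carriers
present is flagged infinite rather than clamped. No statistical test is
attached (the source protocol applies none); the design leaves an exact test
as future work rather than silently adding inference.

## Compound heterozygosity and segregation

The compound-het screen pairs, per sample, a carried
pathogenic/likely-pathogenic variant from the exonic/splice-site screen with
a carried tier-1 intronic candidate. Selection on the exonic side is by
clinical class, not by region class, because the canonical example — MYBPC3
c.1227-13G>A — sits 13 nt into an intron yet is the established exonic-screen
mutation. Segregation summaries bin family members into carrier classes
(both / first-only / second-only / neither, or carrier / non-carrier for one
variant) against phenotype, excluding members untyped for any tracked
variant. Flags, computed over known phenotypes only: *monogenic-consistent* —
every carrier of the first variant affected, every non-carrier unaffected;
*digenic-consistent* — every dual carrier affected, everyone else unaffected.
With no informative member the flags are NA (indeterminate), never FALSE.

## Synthetic-data generator: the stated world

The generator emulates the structure of a 16-proband whole-gene HCM screen,
with each stream seeded from
one master seed (same seed ⇒ byte-identical files):

* **Cohort**: 16 probands, half male, default caller count 4.
* **Depth**: NegBin(mean 180, size 10), matching reported per-gene averages
  of 130–200+; P(DP < 20) is negligible, so the depth filter bites only on
  deliberately degraded configurations.
* **Caller errors**: default per-caller sensitivities (0.97, 0.95, 0.96,
  0.94) — modern callers on high-depth data; the closed-form consensus check
  sets all four to 0.9 explicitly in its own configuration. False positives
  are independent across callers (a correlation structure is not modelled —
  a documented limitation, as correlated errors would lower consensus
  precision gains). Indel-representation jitter re-spells a true indel
  (right-shift within a repeat run, else pad with the shared following
  base); normalization on load must undo it.
* **Scores**: pathogenic-like variants clear each of CADD/GWAVA/Genomiser
  independently with probability 0.995 (draws above the cutoff), benign-like
  with 0.02; SPIDEX is NA at rate 0.8, mirroring how sparsely deep-intronic
  sites are scored. The tier-1 recall of planted pathogenic variants is the
  product of the three pass probabilities, which the suite verifies.
* **Planted candidate**: allele frequency 0.19 against a reference MAF of
  0.06 (fold ≈ 3.17, deliberately just above the enrichment cutoff). Its
  alt-allele count is placed **exactly** (round(2n·AF) = 6 het carriers)
  rather than binomially: the end-to-end recovery property (≥ 95% of 100
  replicates) tests the pipeline, and binomial sampling of a frequency that
  sits 4% above the cutoff would make the test measure sampling noise
  (P(realized AF ≥ 0.18) ≈ 0.55), not the pipeline. Background variants
  *are* sampled binomially, and their mean realized AF is tested against the
  planted value.
* **Pedigree**: a nuclear family under full-penetrance digenic (affected iff
  both tracked variants carried) or monogenic rules.

What a green synthetic test does *not* establish: realistic linkage
structure, correlated caller errors, mutation-rate heterogeneity, read-level
artefacts, or the behaviour of the real scoring tools.

## Numerical and degenerate-input choices

* Precision of an empty callset is NA (undefined), never 0.
* Zero called alleles for a variant is an error, not AF 0.
* Fold enrichment with both frequencies 0 returns 1 flagged degenerate.
* Normalization is a fixed point (idempotent) and is context-bounded: a
  repeat run reaching the supplied context edge stops there, which the
  exhaustive-equivalence oracle in the tests mirrors.
* Duplicate conflicting score-table rows for one key are an error naming the
  key; fully identical duplicates are tolerated.
* Venn group labels use the fixed tool order CADD, GWAVA, GENOMISER, SPIDEX;
  output is independent of input order.

## Packaged fixtures

`inst/extdata` holds the example data — a published 16-proband, 26-gene HCM
whole-gene screen — as plain TSV/BED: the 26-row
prioritized-intronic score table and the classified exonic/splice-site
table (scores, MAFs and classes as published; *genomic coordinates are
synthetic stand-ins*, constructed on toy 10-exon gene models so that each
variant's distance to the nearest splice boundary equals its HGVS intronic
offset — files carrying such stand-ins are suffixed `_synthetic`), the
16-proband genotype matrix encoding the minimal genotype configuration
consistent with each published frequency and stated carrier count, TF peak
intervals reproducing the published FOS/JUN/EP300 overlaps, and the two
family pedigrees. Tests assert published-value equality only where the
published quantity is coordinate-free.

## Known limitations

* Variant matching is allele-exact; position-only matching (which some
  ensemble protocols use) is not offered.
* X/Y PAR regions, chrY and mitochondria have no special ploidy handling
  beyond the X-male rule.
* The benchmark is allele-level, not genotype-level.
* GFF3 support covers `exon` features keyed by `gene=`/`Parent=`
  attributes; full GFF3 feature hierarchies are out of scope.
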