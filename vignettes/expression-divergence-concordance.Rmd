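---
title: "Lineage polarity, ortholog concordance, and the 2x2 analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lineage polarity, ortholog concordance, and the 2x2 analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degconcord)
```

## The question and the model

Domestication is accompanied by regulatory rather than structural genetic
change, and by recurrent reproductive impairment of the domesticated form.
This package operationalizes one concrete, testable reading of that
observation: among animal genes differentially expressed between a
domestic animal and its wild congener, are the domestic lineage's
expression changes preferentially *codirected* with human ortholog
expression changes annotated as decreasing human reproductive potential,
while the wild lineage's changes are not?

The analysis has four layers.

**MRCA polarity.** A domestic-vs-wild log2 fold change is a single contrast
between two extant lineages. We read it as two oppositely directed,
equivalent changes since their unobserved most recent common ancestor: a
positive value means the domestic lineage went up and the wild lineage
down, a negative value the reverse. This is an assumption, not an
inference — the ancestor's expression is unobserved, and any asymmetric
split of the divergence between the lineages would change per-lineage
attributions. A zero fold change carries no polarity; by default such
records are excluded (`zero_policy = "EXCLUDE"`), and a strict mode errors
instead. No magnitude threshold or p-value filter is applied: significance
calls are inherited from the source studies and only the sign is used.

**Ortholog matching.** Animal symbols are matched to the curated human list
by normalization only — whitespace stripped, one trailing `_TOKEN` species
decoration removed, uppercased. Matches that case-folding cannot produce
(the avian and canine hemoglobin subunits onto human `HBB`/`HBD`) must be
declared in an explicit synonym table; we deliberately rule out fuzzy
matching because a silent approximate match cannot be audited or tested.
Unmatched DEGs are excluded and logged, never an error.

**Correspondence scoring.** Each human gene is annotated per direction:
`effect_under` and `effect_over` give the consequence of under- and
overexpression for reproductive potential (`DECREASE`, `INCREASE`, or
`UNKNOWN`). For each matched DEG and each lineage, the lineage's direction
selects the codirected slot (UP reads `effect_over`, DOWN `effect_under`),
and a correspondence record is emitted only when that slot is annotated. A
matched DEG therefore contributes 0, 1 or 2 records. The counting unit is
the record, not the distinct gene: the same gene observed in two species or
tissues counts each time, which is what makes the worked example's repeated
genes (two Cyp17a1 contrasts, five hemoglobin subunit rows) sum to 20 per
lineage. Only the reproductive-potential axis is scored; reproductive-health
annotations, where present, travel in the evidence text.

**The 2×2 table and its tests.** Records are tallied lineage × effect and
tested three ways, all implemented from first principles in this package:

- *Fisher exact, two-sided.* Conditional on the margins the first cell is
  hypergeometric; the p-value sums the point probabilities of every table
  in the support whose probability is at most the observed one. The
  comparison uses a relative tolerance of 1e-7 so that ties in point
  probability are not broken by floating-point noise. Point probabilities
  come from log binomial coefficients (`lchoose`), summed over the full
  support — at these table sizes that is exact to well below 1e-12, which
  the test suite verifies against an independent enumeration oracle on
  every 2×2 table with total at most 30.
- *Pearson χ².* The closed form `N(ad−bc)²/(r₁r₂c₁c₂)`, with the Yates
  variant reducing `|ad−bc|` by `N/2` (floored at zero) before squaring.
  The 1-df upper tail is evaluated through the complementary error
  function identity `p = erfc(√(x/2)) = 2Φ(−√x)`, checked against numeric
  integration of the density to 1e-10. Both conventions are reported side
  by side: on the worked-example table the uncorrected statistic (5.23,
  p = 0.022) clears the 0.05 level decisively while the Yates-corrected one
  (3.84, p = 0.050) sits exactly at it, and hiding either would misstate
  the strength of the evidence.
- *Exact binomial tails.* Per lineage, `P(X ≥ k)` for the majority cell
  over the lineage total at p₀ = 0.5, summed from exact binomial
  coefficients. The directional (one-sided) form is the scientifically
  meaningful one here: the claim under test is that domestication pushes
  expression specifically toward the potential-decreasing side.

A zero margin makes all three tests undefined; the pipeline then reports an
explicit `"undefined margins"` status rather than a number.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `zero_policy` | `"EXCLUDE"` | zero log2FC rows dropped vs. error |
| `alpha` | 0.05 | reporting level quoted in exports (gates nothing) |
| `n_degs` | 40 | generator: DEG records per corpus |
| `match_rate` | 0.7 | generator: P(symbol has an annotated ortholog) |
| `theta_dom`, `theta_wild` | 0.8, 0.45 | generator: P(lineage record is DECREASE) |
| `annot_missing` | 0.1 | generator: P(a direction slot is UNKNOWN) |
| `lfc_scale` | 1.5 | generator: mean of exponential \|log2FC\| (log2 units) |

The generator defaults mirror the structure of the worked example: a corpus
of a few dozen records, a domestic lineage strongly tilted toward
potential-decreasing correspondences (16/20 = 0.8) and a wild lineage near
an even split (9/20 = 0.45). They are study conditions, not tuning knobs.

## What the synthetic generator emulates — and what it does not

`generate_synthetic_bundle()` works backwards from the estimand: it samples
each matched gene's (lineage, effect) assignment directly, then constructs
a signed fold change and a per-direction annotation that force the real
pipeline to recover exactly that assignment. That gives machine-checkable
ground truth (`truth$expected_table`) for every seed, and makes parameter
recovery a sharp test: with no missingness and full matching, the recovered
domestic-DECREASE fraction at n = 2000 lands within Monte-Carlo error of
`theta_dom`.

What it does **not** emulate: real ortholog ambiguity (one synthetic animal
symbol maps to at most one human gene), correlated effects within gene
families, repeated observations of one gene across tissues or species,
source-study heterogeneity in differential-expression calling, and any
biological link between fold-change magnitude and annotation. Passing the
synthetic tests therefore validates the bookkeeping and the statistics, not
the biological curation — the fixture bundle, which is a transcription of a
published curated comparison, is the check on the latter, and its
`note` column marks the rows whose transcription involved judgment.

Magnitudes are drawn from an exponential law purely for cosmetic realism;
only the sign enters the analysis. A small offset keeps sampled magnitudes
bounded away from zero so polarity is always defined. Seeding is a single
master seed; calibration replicates derive per-replicate seeds by unit
increments, so a calibration table is reproducible from one integer.

## Numerical and design choices

- Probability comparisons in the Fisher rule use relative tolerance 1e-7;
  all tail sums run over the full support (no early truncation).
- Contingency cells are held as integers but converted to doubles before
  the χ² closed form, whose cross-products overflow 32-bit integers at
  corpus scale.
- Duplicate DEG records (same gene, species pair, tissue and source) are
  rejected at ingest; genuinely repeated observations must differ in at
  least one key field. Records the source studies report in opposite
  directions for the same gene are kept as-is and contribute
  independently — the published narrative itself describes such
  co-existing directions, and reconciling them silently would be a
  curation decision this package refuses to make for its user.
- Annotation entries with both directions `UNKNOWN` load (keeping a curated
  list complete) but are flagged `usable = FALSE`; they can match DEGs yet
  never produce a correspondence record.
- The type-I calibration counts replicates with undefined margins as
  non-rejections and reports their number separately; at the default
  calibration configuration they do not occur.

## Problem sizes used in validation

The oracle-equivalence sweep enumerates all 44,515 positive-margin 2×2
tables with total at most 30. Parameter recovery uses one corpus of 2000
DEGs plus three smaller corpora (n = 80) across seeds for exact
ground-truth equality. The null calibration runs 2000 replicates of a
40-DEG corpus at `theta = 0.5`; with the exact test's conservatism the
observed rejection rate at nominal 0.05 stays below the nominal level plus
two Monte-Carlo standard errors (observed ≈ 0.036 at the seeds exercised by
the analysis scripts).

## Known limitations

- The MRCA polarity convention attributes divergence symmetrically to both
  lineages; expression data from an outgroup would be needed to do better.
- The curated annotation transcribed in the fixture covers the genes whose
  directions are stated in the published body text; directions are never
  invented for the remainder, so the fixture is a subset of the full
  curated set (the printed marginals are nevertheless reproduced exactly).
- Correspondence records are treated as independent by all three tests;
  records sharing a gene (hemoglobin subunits, repeated Cyp17a1) are
  plainly not, so p-values are anti-conservative to an unquantified degree.
  This is a property of the 2×2 design itself, reported as published.
- No multiple-testing correction across genes is applied anywhere;
  significance is assessed only on the final table.
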