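---
title: "Guilt-by-association biomarker mining: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guilt-by-association biomarker mining: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markermine)
library(dplyr)
```

## The model

`markermine` formalizes a guilt-by-association argument: genes that share
transcriptional regulators with, belong to the same functional pathways as,
and are co-expressed or physically interacting with established disease
marker genes are themselves likely disease-associated. The procedure treats
these three relations as *orthogonal evidence axes* and demands agreement of
all three, on the reasoning that each individual knowledge base is both
incomplete and noisy: union *within* an axis compensates for incompleteness
of any single source, while intersection *across* axes suppresses the noise
each axis carries alone.

Two asymmetries in the combination rule are deliberate and worth stating
explicitly.

* **Binary membership.** A gene found by one source or by all of them, once
  or many times, enters a pool with identical weight. Knowledge bases are
  biased toward well-studied genes; counting repeat sightings would
  reinforce that bias rather than add information. Consequently no candidate
  ranking is produced — the output is a set.
* **Sign-blindness.** Regulatory edges count regardless of activation,
  repression or unknown mode. Regulatory databases frequently cannot
  resolve the sign, and a marker may be informative in either direction;
  direction is instead established later, empirically, by the expression
  validation stage.

Each subtype panel is expanded in a fully independent run. This is a
modelling commitment, not an implementation convenience: subtype-specific
markers are the goal, and cross-subtype overlap is reported afterwards as a
seven-region Venn partition rather than pooled away.

Seeds are *not* excluded from their own candidate sets. A seed that
re-surfaces through all three axes and survives the secretome filter is a
legitimate prediction, and its reappearance is a useful internal consistency
signal.

## Evidence-axis semantics

**Transcription factors.** For each seed, `expand_tf()` collects the TFs
that regulate it, all targets of those TFs, and — when the seed is itself a
TF — the seed's own targets. TF edges from all source extracts are pooled
*before* expansion: a regulator identified in one database contributes its
target list from every database, maximizing coverage of co-regulated genes.
The exported `combine_sources()` provides the complementary pool-level union
for sources that must stay separate until after expansion.

**Pathways.** `expand_pathway()` unions the members of every
molecular-function, biological-process or pathway set containing a seed.
Cellular-component sets are excluded: co-localization says little about
functional association, and the compartment question is answered separately
(and more specifically) by the topology filter. Standard GMT has no
namespace field, so the package adopts a `ns=<value>` token at the start of
the description field, defaulting to `biological_process`.

**Co-expression and interaction.** `expand_coexpression()` applies three
cut-offs, all exposed in `expansion_params()` and all defaulting to the
pipeline's canonical settings: mutual rank ≤ 2000 (the full ranked list a
co-expression resource returns; MR = 1 is the strongest partner), an
interaction-score floor of 0.150 (the conventional low-confidence
threshold, chosen permissive because the three-way intersection provides
the specificity), and a cap of 100 interaction partners per seed (the
first-shell limit). The rank cut-off is interpreted against the
`mutual_rank` *value*, not the file row order, matching MR semantics. At
the partner cap, ties in score are broken lexicographically by partner
symbol so runs are deterministic; the choice is arbitrary but fixed.

## Identifier discipline

All symbols are trimmed and upper-cased on ingest; mixed-case symbols in
public extracts otherwise cause silent set mismatches. `harmonize()` maps
raw identifiers (UniProt accessions, aliases) many-to-one onto gene symbols
and treats already-harmonized symbols as fixed points, making it idempotent.
Unmapped identifiers are excluded with a report rather than raising: no
source is assumed complete, and a hard failure on the first unknown
accession would make real extracts unusable. Ambiguous (many-to-many)
mappings keep the first entry and warn — the ambiguity is surfaced, not
silently resolved.

## The secretome filter

Membrane topology comes from Phobius short-format output (or the synthetic
generator's writer of the same format); the HMM itself is out of scope and
the TM count is trusted as given, since the tool already excludes the
signal-peptide hydrophobic core from its TM count. Four exhaustive,
mutually exclusive classes are derived: `secreted` (signal peptide, zero TM
segments), `sp_and_tm`, `tm_only`, `neither`. Only `secreted` passes the
filter — a signal peptide without any membrane anchor implies export to
extracellular space, the compartment accessible to minimally invasive
assays. Candidates lacking an annotation are excluded and listed in the run
report, mirroring the incomplete-source tolerance above.

## Expression validation

The validation stage tests each predicted gene's within-pair
log2(tumor) − log2(normal) differences against zero with a two-sided paired
*t*-test. The test is not dictated by the data format alone; it is the
natural choice for a matched-biopsy design with ten pairs and symmetric
confidence intervals, and the package commits to it explicitly:

* **No multiple-testing correction** in the default report; significance is
  raw `p < 0.05`. This is a deliberate fidelity choice for the screening
  character of the stage (an optional Benjamini–Hochberg column is available
  in the enrichment report via `adjust = TRUE`).
* **Multi-probe genes** are represented by the probe with the smallest
  p-value. Some deterministic rule is required for arrays where several
  probe sets map to one gene; minimum-p is declared and tested.
* **Direction calls**: `up` iff `p < α` and the mean difference is positive,
  `down` for negative, `ns` otherwise. Degenerate inputs are reported, not
  hidden: zero-variance nonzero differences yield `p = 0` with a
  `degenerate` flag; identical pairs yield `p = 1`, `ns`.
* **Confidence intervals** are mean ± *t*(1 − α/2, n − 1) × SE, with
  `level` the two-sided significance level (0.05 ⇒ 95% interval).
* Matrices are assumed log2-scale; `read_expression_matrix(assume_log2 =
  FALSE)` applies `log2(x + 1)`, the offset being unstated territory where
  a convention had to be fixed.

Tallies count a multi-subtype gene once per subtype (it is a prediction of
each run) and once in the deduplicated grand total (it is one transcript).
Genes without expression data are tallied as `missing`, never silently
dropped, so per-subtype class counts always sum to the number of
predictions.

## Over-representation

`over_representation()` computes, per annotation term, observed count,
expectation `|query| × |term| / |universe|`, fold enrichment
observed/expected, and an upper-tail hypergeometric p-value
`P(X ≥ observed)` — equivalent to a one-sided Fisher test. The
hypergeometric choice is the standard ORA test; the fold/expected framing
is computed independently of it, so the ranking (fold descending, ties by
p then term id) is meaningful under any test. No GO-graph ancestor
propagation is performed: annotations are used as given. The enrichment
query is an explicit argument (`dysregulated` — both directions — by
default, or `upregulated` only), because both readings of "validated genes"
are defensible and users should choose consciously.

## The synthetic study generator

`synth_config()` fixes the study conditions the generator emulates: seed
panels of 8/13/2 genes, planted expression effects of ±2 log2 units,
measurement noise of sd 0.5, ten tumor/normal pairs with probe-level
log2 intensities, and a pair-level offset of sd 0.3 inducing the
within-pair correlation a paired test exploits. Structural defaults —
150 genes, 12 mediating TFs, 12 planted markers — keep a single run small
enough that property suites can afford hundreds of replicates while every
pipeline stage still has non-trivial input.

Construction guarantees, per planted marker, a same-subtype seed link on
every axis, with each link placed entirely within one randomly chosen
source extract of its axis, so recovering the full planted set requires the
union-within-axis semantics. Decoys are disconnected from each axis
independently with probability `decoy_axis_dropout` (default 1.0).
Background noise — decoy-only regulators and gene sets, beyond-cutoff
co-expression ranks, below-threshold interaction scores, and
cellular-component sets mixing seeds and decoys — is confined so that it
can never link a decoy to a seed within an axis's admissible evidence.
With full dropout, end-to-end recovery of exactly the planted set is
therefore a by-construction oracle: any deviation is an implementation
defect, not generator noise. With `decoy_axis_dropout = 0` decoys satisfy
all axes and recovery is deliberately a superset.

A single integer seed governs all randomness (sub-generators derive fixed
small offsets from it), every emitted file embeds the seed in a comment
header, and identical configurations produce byte-identical bundles.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: realistic GO term-size distributions, probe-level
artifacts and normalization effects, correlated gene-gene expression beyond
the planted structure, many-to-many identifier pathologies, and the sheer
scale and redundancy of real knowledge bases. Recovery results on synthetic
bundles certify the pipeline's logic, not the biological yield of any
particular database snapshot.

## Numerical and testing choices

Simulation sizes are chosen to make the statistical checks sharp but
affordable: calibration and power use 200 replicate matrices of 40 genes
(8,000 null tests give a standard error on the type-I rate of about 0.002),
recovery uses ten independent studies of 150 genes, and oracle-equivalence
suites enumerate per-gene predicates on random knowledge bases of at most
50 genes and exhaustive hypergeometric draws on universes of at most 25.
Statistical routines are dual-routed in the tests: the paired test is
checked against a hand-computed t statistic and CDF, the confidence
interval against `t.test()`'s interval, and the hypergeometric p against
exhaustive enumeration — implementation and oracle never share a code path.

## Known limitations

* The pipeline's biological yield is bounded by its knowledge-base
  extracts; it discovers nothing outside them, and the packaged formats are
  frozen dialects, not live database clients.
* Binary membership forfeits any ranking among predictions; downstream
  prioritization must come from the validation statistics.
* The paired *t*-test assumes approximate normality of within-pair log2
  differences; with n = 10 it has limited robustness to heavy tails, and no
  moderated-variance (shrinkage) alternative is provided.
* Topology classification is only as good as the upstream predictor's
  short-format output; one canonical sequence per gene is assumed.
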