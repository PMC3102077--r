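---
title: "Consensus orthology: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus orthology: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthomeld)
```

## The problem and the model

Orthologs — genes in two species descended from a single gene in their last
common ancestor through speciation — are the best sequence-level predictor of
shared function, together with in-paralogs (co-orthologs), the copies arising
from duplications *after* speciation. Genome-wide ortholog detection between
distant genomes such as worm and human is hard: reciprocal-best-hit (RBH)
searches report only the single best counterpart and can carry false-negative
rates of tens of percent, while graph- and tree-based programs each make
different systematic errors. `orthomeld` implements the meta-analytic
response: run several programs, take the **union** of their query-species
predictions, and attach to each gene the exact set of sources supporting it.

The union is a deliberate sensitivity-over-specificity choice. Restricting to
genes found by all programs would discard many functionally validated
orthologs found by a single method; when the list's purpose is candidate
pre-filtering for RNAi screens, false negatives (conserved genes never
screened) cost more than false positives (a few extra clones injected).
The per-gene support set preserves the information a stricter user needs:
`support_share()` and `venn_partition()` let you re-restrict to any support
level after the fact.

## Identifier harmonization

All set arithmetic presupposes one namespace of gene identifiers. Sources mix
protein (isoform) names with gene-level sequence names and lag behind the
reference annotation, so `orthomeld` normalizes before comparing:

* `normalize_id()` strips one trailing lowercase isoform letter from
  cosmid-style sequence names (`F53B8.1a` → `F53B8.1`) and upper-cases such
  names (`t01c1.3` → `T01C1.3`). Both behaviours are policy switches; the
  default is on because mixed protein/gene naming is the common case in
  source downloads. Conventional lowercase locus symbols (`nhr-48`) are never
  touched. The function is idempotent by construction.
* `resolve_alias()` / `update_gene_set()` apply a release's gene-model
  updates: `removed` and `pseudogene` entries are dropped (and logged),
  `merged` entries are followed to a fixed point. A merge whose target is
  already a member of the set being updated is logged as a *duplicate merge*
  and dropped — the merged pair were really one gene; a merge onto an absent
  target renames and keeps. These two cases follow how published hit-list
  curations treat them. The conservation identity
  `|input| = |kept| + |removed| + |duplicate merges|` is asserted on every
  call.

Merge chains are followed with cycle detection and a depth limit of 100;
reference annotations never ship cycles, so a cycle is treated as data
corruption and raised as an error naming the chain. Identifiers a mapping
service cannot resolve are surfaced (flagged `unresolved` in
`membership_coverage()`), never silently guessed.

## Source dialects

The four file grammars (`pairwise_cluster`, `group_line`, `homology_group`,
`ortholog_pair`) are defined by this package, bit-exactly, rather than
chasing historical database formats: the original downloads are frozen to
specific 2008–2010 releases and cannot be re-fetched, so byte-faithful
emulation of any one of them is untestable. Each dialect instead captures the
*shape* of one program family's output: seed-ortholog clusters with
in-paralog confidences, one-group-per-line membership lists, long-format
homology groups keyed by numeric taxon, and per-pair homology-type calls.
Two rules are uniform across dialects: a query gene is asserted only when its
cluster/group/pair links it to at least one subject-species gene, and any
member with positive confidence counts (in-paralogs are included). Unknown
homology-type strings are kept but conservatively mapped to `many2many`, with
a warning.

## Family extraction and gold-standard evaluation

`extract_family()` implements annotation-rule extraction: genes carrying at
least one include term (InterPro domain or GO term identifier), minus an
exclusion ledger, plus an inclusion ledger. The ledgers model the manual
curation step that any annotation-driven family definition needs — genes
wearing a family-typical domain annotation that are not family members, and
members the annotation missed. They are explicit inputs with mandatory
reason text, never hidden constants, so every correction is auditable; a
ledger naming a gene absent from the annotated universe is an error, not a
no-op. The shipped kinase scenario uses `IPR000719` + `GO:0004672` as its
include terms — a documented stand-in, since the exact term list behind any
given published kinase query is rarely printed.

`evaluate_against_gold()` reports *putative* false-negative
(`gold_only / |gold|`) and false-positive (`extracted_only / |extracted|`)
rates. "Putative" matters: a gold compendium is itself a prediction, and
apparent errors are often reclassified on deeper (tree-based) inspection.
Rates are computed on exact counts; rounding happens only at presentation.

## Screen coverage and reclassification

Published RNAi screens carry their own homology calls, made years earlier
with weaker methods. `reclassify()` applies an auditable gain/lose ledger to
those calls (`conserved = prior + gains − losses`, asserted per run) with
strict consistency checks — a `gain` on a hit already called conserved, or a
duplicate ledger entry, is an error naming the gene. The adjudications
themselves (RBH re-searches, tree-database lookups) are *not* computed: they
depend on live external services and would break desk-scale reproducibility;
they enter only as the evidence text of ledger entries.

`coverage_summary()` then reports what fraction of the conserved hits the
consensus contains, and the screening-effort fraction. Because published
effort figures are ambiguous about their denominator (the original number of
clones targeted vs. the currently targetable set), both fractions are
emitted when both denominators are supplied.

## The simulator

`simulate_orthology()` generates the statistical structure the pipeline is
built for: `n_families` ancestral families, each conserved, query-specific or
subject-specific; conserved families may duplicate post-speciation on either
side (in-paralogs). Each source misses a conserved query gene independently
with probability $f_i$ and spuriously calls a non-conserved gene with
probability $g_i$; spurious calls are drawn only from genuinely
non-conserved genes so that sensitivity and precision keep clean
definitions. One pseudo-random stream per run, seeded mandatorily.

Default parameters, chosen once as a plausible worm/human-scale caricature:
35% query-specific and 25% subject-specific families (leaving ~40% conserved,
matching the ~38%-of-genome scale of real consensus lists); duplication
probabilities 0.15 (query) / 0.20 (subject); and a roster whose miss/spurious
rates (0.20/0.005 for the homology-group source down to 0.05/0.06 for the
ortholog-pair source) reproduce the qualitative ordering seen among real
programs — the most conservative source is smallest but most congruent, the
most sensitive source contributes the most unique calls. The closed forms the
tests check: a conserved gene escapes the union with probability
$\prod_i f_i$ (0.0016 at four sources with $f_i = 0.2$), and union
sensitivity is $1 - \prod_i f_i$.

What the simulator does **not** emulate: sequence evolution, correlated
errors between programs (real methods share BLAST inputs and fail together
on fast-evolving families), out-paralog confusion, and historical database
quirks. Passing tests therefore demonstrate the pipeline's arithmetic and
bookkeeping, not that any real program mixture achieves these error rates.

The scenario fixtures (`paper_scenario()`) are the complementary device:
seedless, fully hard-coded instances whose *marginal counts* equal published
contingency tables from the *C. elegans*–human meta-analysis (661 → 652
surviving hits; 575 + 14 − 17 = 572 conserved; 17 extracted NHRs vs 16 gold
with overlap 15; 3,386 of 7,663 found by all four; and so on). Only the
margins are pinned; individual identifiers are synthetic except the handful
of genes the published curations name explicitly. Tests derive every
statistic by running the pipeline on these inputs — no published total is
stored as an expected object inside a fixture.

## Numerical and formatting choices

* **Percent rounding**: nearest integer with ties away from zero
  (`round_half_away()`), the convention under which 44.18 prints as 44 and
  98.78 as 99; one-decimal values are always emitted alongside, so a
  coverage of 99.5 is representable without overstating it as 100.
* **Ordering**: all outputs sort identifiers in C-locale (radix) order, and
  re-running a pipeline on identical inputs is byte-identical (asserted in
  the test suite via MD5 manifests).
* **Degenerate inputs**: fractions with empty denominators (empty source,
  empty extracted set) are reported `NA`, never 0; empty gold compendia and
  empty conserved sets are errors, since their rates are undefined rather
  than missing.
* **Problem sizes in tests**: property suites run 20–100 random instances of
  ≤ 50 genes against brute-force oracles, and the stochastic recovery checks
  use 2,000 families (for the closed-form miss-rate comparison) and 20 seeds
  of 100–120 families (for dominance properties) — sizes at which binomial
  standard errors are tight enough to be meaningful while the whole suite
  stays fast.

## Orchestration

`run_pipeline()` chains the stages (ingest → consensus → venn / congruence /
annotate → pivot / family-eval / pathway- / screen- / library-coverage) from
a YAML config, validating it first (`validate_config()` collects all
findings rather than stopping at the first). Stages run in dependency order;
a requested stage whose upstream product is neither requested nor already on
disk raises a dependency error. Reports are emitted as TSV and JSON, with an
MD5 manifest. There is no shell entry point: the package's users drive it
from R, and `scripts/acceptance.R` shows the scripted pattern.

## Known limitations

* The consensus is unweighted: a gene found by one permissive program counts
  as much toward membership as one found by all four. The support set is
  exposed precisely so users can apply their own weighting.
* Identifier harmonization handles cosmid-style names and explicit alias
  maps; it does not consult any live mapping service, so unmapped historical
  names remain unresolved (by design, but users must supply a current alias
  map for old hit lists).
* GO terms are matched literally; there is no ancestor-closure over the
  ontology graph, so include-term lists must enumerate the specific terms
  their annotation source uses.
* The simulator's independence assumptions (per-source misses, per-gene
  spurious calls) are optimistic; real inter-program congruence is inflated
  by shared inputs, so simulated congruence statistics should not be read as
  forecasts for real databases.
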