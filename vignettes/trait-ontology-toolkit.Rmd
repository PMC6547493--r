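---
title: "From association signals to trait-ontology annotations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From association signals to trait-ontology annotations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traitlink)
library(dplyr)
```

Association-mapping studies in crops report marker loci significantly
associated with phenotypes, but those results stay scattered across
papers, each with its own trait wording and genome coordinates.
`traitlink` turns such summary statistics into structured
gene-to-trait-ontology annotation tables and provides the analyses that
make such tables useful: ontology-aware enrichment, semantic similarity
between phenotype descriptions, false-positive-rate simulation, and
co-expression module detection. This vignette explains each model, its
assumptions, the tunable parameters, and the design decisions where the
method description left genuine freedom.

## The trait ontology and its levels

A trait ontology is a DAG of trait terms connected by `is_a` links,
organized under a handful of root trait groups (nine for the plant trait
ontology layout this package emulates) and layered into levels from the
top (level 1 = roots) downward. `read_obo()` parses the OBO subset that
carries this structure — `[Term]` stanzas with `id`, `name`, `is_a`,
`is_obsolete` — and validates it hard at load time: cycles and dangling
`is_a` targets are structural errors, obsolete terms are dropped, and
non-`is_a` relationships (e.g. `part_of`) are ignored because the
layered hierarchy uses only parent links.

A term with several parents could sit on several layers; `term_level()`
defines its level as one plus the *shortest* parent path to any root.
That choice is deterministic, stable under stanza reordering, and
matches the intuitive reading of a layered hierarchy — a term is as
shallow as its shallowest placement. The maximum depth is data-driven
(the classic plant layout uses 6, some level tables print 7); nothing is
hard-coded.

## Information content and phenotype similarity

Phenotypes are described under the entity–quality (EQ) convention: an
entity (organism, species, trait term set) plus a quality (how the trait
varies). For similarity only the trait term set Cl(·) matters. Given
per-term annotation frequencies, the information content of a term is

$$I(t) = -\ln P(X = t), \qquad P(X = t) = \frac{\text{count}(t)}{\text{total}}$$

in nats (the log base was an open choice; natural log is used and
documented everywhere). IC is 0 exactly for a term carried by every
entity and undefined for a term never observed — `information_content()`
refuses count-0 terms rather than silently smoothing, leaving the
smoothing policy to the caller.

Two phenotype profiles P and R are compared by the IC-weighted
set-overlap score

$$\mathrm{sim}(P, R) =
  \frac{\sum_{x \in Cl(P) \cap Cl(R)} I(x)}
       {\sum_{y \in Cl(P) \cup Cl(R)} I(y)} \in [0, 1],$$

which is symmetric, equals 1 for identical class sets, 0 for disjoint
ones, and rewards sharing *rare* terms more than sharing common ones.
The counting basis for the frequencies (phenotype descriptions vs genes)
is deliberately left to the caller — `term_frequency()` accepts either.

`map_trait_to_terms()` uses this machinery to resolve free-text trait
labels: exact normalized-label hits return the curated mapping; unseen
labels are matched by name-token overlap (the query profile is the set
of terms whose names share a token with the label; each candidate's
profile is itself plus its ancestors) and the best candidate is
suggested only above a similarity threshold (default 0.4), always
flagged `similarity-suggested`, never silently mixed with curated
entries. An empty result is a logged outcome, not an error: unresolvable
labels must stay visible.

## From markers to genes: LD flanking windows

Mapping resolution in association studies is set by linkage
disequilibrium decay, which differs between species and populations
(roughly 10–25 kb in maize, 25–50 kb in rice at r² = 0.1). A
significant marker is therefore assigned to every gene whose body,
extended by the LD distance d on both sides, covers the marker
position:

* window `[start − d, end + d]`, closed on both sides, clamped at
  coordinate 1;
* strand is ignored (no strand rule exists for LD windows);
* a marker may link to several genes — all are kept, because restricting
  to the nearest gene would presume exactly the resolution LD denies;
* coordinates are 1-based inclusive end to end, the GFF3/IRanges
  convention native to R genomics; no internal coordinate shift is
  performed, so there is a single convention to reason about.

Records enter this step only if they pass a significance gate (default
p ≤ 1e-5, overridable per study, since each study applies its own
cutoff); the gate used is recorded in the run's provenance output.
Tables are built at several LD levels at once (default {10, 25} kb;
{25, 50} kb for slow-decay genomes), and because a larger window can
only add links, distinct genes and distinct (gene, term) relationships
are provably non-decreasing in d — a property the test suite asserts on
every generated fixture.

`top_fraction_filter()` implements the "most significant fraction"
operation used when narrowing a trait's gene list: it keeps the
`ceiling(f·n)` smallest p-values per study and retains all ties at the
cutoff, so no record is dropped while an equally significant one stays.

## Hypergeometric enrichment

Whether a query gene list is over-represented for a term is tested by
sampling without replacement: with N background genes, n of which carry
the term, and M query genes inside the background, the probability of
observing exactly k annotated query genes is

$$p(X = k) = \frac{\binom{M}{k}\binom{N-M}{n-k}}{\binom{N}{n}},$$

and the reported p-value is the upper tail P(X ≥ k), computed as the
complement of the lower sum. The implementation evaluates binomials in
log space so genome-scale backgrounds (N ≈ 40&nbsp;000) cannot overflow,
and sums the smaller side of the support; it is checked against
exhaustive enumeration of all C(N, n) draws for every configuration
with N ≤ 12 and against the stable distribution functions in `stats`.

Conventions, each chosen to match standard enrichment-tool behaviour:
the flag is raw p < α (default α = 0.05); Benjamini–Hochberg q-values
are always reported alongside but drive the flag only on request; terms
with n = 0 in the background are skipped, not reported at p = 1; the
background defaults to the annotation source's own gene universe, and a
user-supplied background (e.g. expressed genes) is intersected in. A
query with no gene in the background is an error naming the first
offenders — the alternative, silently testing nothing, hides unit
mismatches between gene-id conventions.

`cross_compare()` aligns results from several sources (trait terms, GO,
pathways, co-expression modules) into one table keyed by (source, term).
P-values are never combined across sources; the value of the comparison
is seeing the same query through independent vocabularies.

## False-positive-rate simulation

To measure how often enrichment flags terms for meaningless input,
`simulate_fpr()` draws gene sets uniformly without replacement from the
background, runs the full enrichment, and summarizes significance rates
per set size over many replicates (the classic grid is
20–1000 genes, 1000 replicates). "Rate" is ambiguous between two
readings, so both are implemented and tagged in the output: the
per-replicate fraction of tested terms with p < α (default), and the
share of replicates with at least one hit. Neither is asserted against
any published curve — absolute rates depend on the annotation table used
— but the per-term rate of a discrete upper-tail test can never exceed α
in expectation, and the suite asserts that conservativeness at three
standard errors.

Reproducibility: one master seed drives the whole grid; per-size
substreams are drawn deterministically from it, so adding a size never
perturbs another size's draws.

## Co-expression networks and Markov clustering

Pairwise Pearson correlations across samples (≥ 3 required; genes with
missing or constant values are dropped with a report) are Fisher
z-transformed, \(Z = \tfrac12 \ln\frac{1+r}{1-r}\), and edges are kept
by a threshold rule. The rule was an open choice: the default keeps
|r| ≥ 0.7, a conventional "strong correlation" cutoff at which the
planted-module generator below produces essentially block-diagonal
graphs at realistic sample counts; a top-k-neighbours alternative is
provided. |r| = 1 pairs are clipped to 1 − 1e-12 before the transform,
with a warning.

The graph is clustered with the Markov cluster algorithm: from the
column-stochastic transition matrix M (absolute-correlation weights,
self-loops of weight 1 added before normalization — the standard guard
against period-2 oscillation), alternate *expansion* (M ← M·M) and
*inflation*

$$(\Gamma_r M)_{pq} = \frac{(M_{pq})^r}{\sum_{i=1}^{k} (M_{iq})^r}$$

until the matrix stops changing. Inflation with r = 1 is the identity
on stochastic matrices, so it cannot form clusters; the default power
here is 2.0, with r exposed (including r = 1 for reproducing the
identity behaviour). Entries below 1e-5 are pruned each round and
columns renormalized; convergence is declared when the largest entry
change falls below 1e-6, capped at 100 iterations (non-convergence
returns the reached partition with a warning flag). Modules are read off
as connected components of the converged flow's non-zero pattern —
expansion never connects disconnected components, so modules can only
refine components, a property the suite checks against an independent
graph library. All four numerical knobs are exported arguments; the
defaults were picked for determinism at desk scale and behave
identically across platforms because every step is dense arithmetic.

`module_overlap()` maps a gene set onto the modules and reuses the
hypergeometric engine with modules as terms, reporting query genes
outside the network in an `unassigned` attribute rather than dropping
them.

## The synthetic-data generator

Real curated corpora and expression compendia cannot ship with a
package, so every analysis here is exercised on generated fixtures with
known ground truth. The generator is first-class, tested code, and each
part is a pure function of `(fixture_spec, seed)` — same spec, same
bytes.

* **Ontology**: rooted DAG with 9 roots, depth 6, branching 2 by
  default (mirroring the emulated layout's nine trait groups and six
  levels); ~10% of non-root terms receive a second parent drawn from
  the same upper level, so DAG handling is exercised while levels stay
  unambiguous.
* **Genome**: 60 genes of 2–5 kb over three 1 Mb chromosomes — a gene
  density (one per 50 kb) at which 25 kb windows regularly cover
  several genes, so multi-linking and LD monotonicity are genuinely
  exercised.
* **Association studies**: 3 traits × 2 studies, 40 null markers per
  study with uniform(0, 1) p-values, plus one effect marker inside each
  causal gene at a point mass of 1e-8 (a Beta alternative exists for
  power-style experiments). The point mass/uniform split makes the
  1e-5 gate's behaviour exactly predictable. Five causal genes (2+2+1)
  are planted per fixture, *at least two maximal LD windows apart*, so
  no gene can sit inside the windows of two different traits' causal
  markers — without that separation a trait's causal genes can
  legitimately inherit a second trait's term and the "planted term is
  the top enrichment" ground truth would not be a property of the
  construction. The truth table is computed by an independent,
  deliberately naive exhaustive scan over all emitted markers, so
  incidental recoveries (an effect marker inside a neighbouring
  non-causal gene's window) are part of the truth, exactly as they are
  part of the pipeline output.
* **Expression**: 4 modules × 25 genes over 40 samples; each gene is
  `sqrt(w)·latent + sqrt(1−w)·noise` with unit variances, so the
  expected within-module correlation is exactly w (default 0.8) and 0
  across modules.

What the generator does **not** emulate — and what passing tests
therefore do not show about real data: LD structure and allele
frequencies (only summary tables are simulated), genuinely skewed
annotation-size distributions, correlated traits across studies,
batch/tissue structure in expression, and the scale of real corpora
(tens of thousands of genes). The generator validates the machinery,
not the biology.

## Problem sizes and runtime

The shipped tests and the acceptance script run everything at desk
scale, chosen so the full pipeline stays interactive on a single core:
exhaustive enrichment enumeration up to N = 12 (≈ 3100 configurations),
FPR grids of 500 replicates at sizes {20, 100} over a 100-gene/10-term
source, fixtures of 60 genes / 250 markers, and 100-gene expression
matrices. All scale linearly (or, for the dense MCL, cubically in gene
count) if users raise them.

## Known limitations

* The OBO reader covers exactly the layered subset described above; OBO
  1.4 logical definitions, cross-products and ontology editing are out
  of scope.
* Enrichment is upper-tail only; depletion and ranked (GSEA-style)
  tests are not provided.
* No lift-over: records and gene models must share a genome build, and
  a mix is a hard error.
* MCL is dense; networks beyond a few thousand genes need a sparse
  implementation.
* Similarity suggestion for unseen trait labels is a token-overlap
  heuristic intended to *propose* curation candidates, never to replace
  curation; its provenance flag must be respected downstream.
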