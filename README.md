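# traitlink

Association-mapping studies in crops such as maize and rice report
marker loci significantly associated with phenotypic variation, but the
results stay scattered across publications, each with its own trait
wording, significance convention and genome build. `traitlink` is an R
toolkit for people who curate and analyse such results. It

* builds **gene-to-trait-ontology annotation tables** from
  marker–trait summary statistics, by assigning each significant marker
  to every gene whose body extended by a linkage-disequilibrium (LD)
  flanking window `[start − d, end + d]` covers it (typical d: 10/25 kb
  for maize-like LD decay, 25/50 kb for rice-like),
* resolves free-text trait labels to ontology terms through a curated
  dictionary, with an information-content **semantic similarity**
  fallback
  `sim(P, R) = Σ_{x∈Cl(P)∩Cl(R)} I(x) / Σ_{y∈Cl(P)∪Cl(R)} I(y)`,
  `I(t) = −ln P(X = t)`,
* tests gene lists for **hypergeometric enrichment** against any
  annotation source (trait terms, GO, pathways, co-expression modules):
  `p = P(X ≥ k)` with `p(X = k) = C(M,k)·C(N−M,n−k)/C(N,n)` computed in
  log space,
* estimates enrichment **false-positive rates** by simulation with
  random gene sets, and
* partitions co-expression networks (Pearson r → Fisher Z → threshold)
  into modules with the **Markov cluster algorithm**
  (`(Γ_r M)_pq = (M_pq)^r / Σ_i (M_iq)^r`, alternated with expansion
  `M ← M·M`).

A synthetic-data generator emits every input dialect the readers
consume (OBO ontologies, GFF3 gene models, TSV association tables,
expression matrices) with known planted ground truth, so the full
pipeline is testable end to end without external databases.

## Worked example

```r
library(traitlink)
library(dplyr)

spec  <- fixture_spec(seed = 1)          # 3 traits, 5 planted causal genes
onto  <- generate_ontology(spec)
onto
#> <trait_ontology> 567 terms, 9 roots, 613 is_a edges, depth 6

genes <- generate_gene_models(spec)
dict  <- generate_trait_dictionary(spec, onto)
study <- generate_association_study(spec, genes, dict)

tab <- build_gene_to_term_table(study$records, genes, dict, onto,
                                ld_levels = c(10, 25))
tas_counts(tab)
#> # A tibble: 2 × 3
#>   ld_level_kb n_genes n_pairs
#>         <dbl>   <int>   <int>
#> 1          10       5       5
#> 2          25       8       8
```

Widening the LD window from 10 to 25 kb grows the table from 5 to 8
distinct genes and gene-to-term relationships — counts can only grow
with the window, mirroring how curated corpora roughly double between
their LD levels. Enriching one planted trait's causal genes against the
25 kb table:

```r
ann <- annotation_set(distinct_gene_terms(tab) |> filter(ld_level_kb == 25),
                      source = "TO")
cg  <- study$causal_genes |> filter(trait_label == trait_label[[1]])
enrich(cg$gene_id, ann) |> head(3)
#> # A tibble: 3 × 8
#>   term_id         k     M     n     N p_value q_value enriched
#>   <chr>       <int> <int> <int> <int>   <dbl>   <dbl> <lgl>
#> 1 SYN:0000349     2     2     5     8   0.357       1 FALSE
#> 2 SYN:0000427     0     2     1     8   1           1 FALSE
#> 3 SYN:0000546     0     2     2     8   1           1 FALSE
```

The planted term (`SYN:0000349`) ranks first: both query genes (k = 2 of
M = 2) carry it. Its p-value of 0.357 is honest, not a defect — with
n = 5 of the N = 8 background genes annotated to the term, drawing 2
hits in 2 tries is unsurprising, which is exactly what the
hypergeometric tail says. Significance requires backgrounds where the
term is rare; on genome-scale annotation tables the same overlap is
highly significant.

Co-expression, on the planted 4-module expression fixture:

```r
ex  <- generate_expression(spec)
net <- build_coexpression_network(ex$expr, min_abs_r = 0.7) |>
  mcl_cluster(inflation = 2)
net
#> <coexpression_network> 100 genes, 1165 edges, 4 modules
table(net$modules$module_id, ex$labels$module)   # perfect recovery
```

## Command line

The same pipeline is scriptable via the installed `exec/traitlink`
entry point:

```sh
traitlink make-fixtures --seed 1 --out fx/
traitlink build --obo fx/ontology.obo --gff fx/genes.gff3 \
  --assoc fx/associations.tsv --dict fx/trait_dict.tsv \
  --ld 10,25 --pcut 1e-5 --out out/
traitlink enrich --genes genes.txt --ann out/gene_to_term_ld10.tsv --out e/
traitlink simulate-fpr --ann out/gene_to_term_ld10.tsv --sizes 20,100 \
  --reps 1000 --alpha 0.05 --seed 1 --out s/
traitlink coexpress --expr fx/expression.tsv --min-abs-r 0.7 \
  --inflation 2.0 --out c/
```

Each run writes a `provenance.json` recording version, parameters and a
config hash; identical config + seed reproduces byte-identical TSVs.

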