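# gogo

Semantic similarity between Gene Ontology (GO) terms from DAG topology,
with edge weights that account for how many children an ancestor term
has — plus gene-level functional similarity, affinity-propagation gene
clustering, and an MCC-based protocol for evaluating clusterings against
reference pathways.

## The problem and the measure

Quantifying how functionally similar two genes are usually starts from the
semantic similarity of their annotated GO terms. Information-content (IC)
methods (Resnik, Lin) capture term specificity well but need a large
annotation corpus, and their values shift whenever the corpus does.
Topological methods (Wang et al.) need only the ontology, but give every
`is_a` edge the same fixed weight, so they cannot tell a broad hub ancestor
from a narrow one.

The measure implemented here (GOGO) keeps the corpus-free topological
recursion but makes the weight of an edge into ancestor *t* depend on
*t*'s number of direct children `nc(t)`:

```
w_e = 1 / (c + nc(t)) + d
```

with `d` = 0.4 / 0.3 / 0.2 for `is_a` / `part_of` / `regulates` and
`c ≥ 0.67` (default 0.67) so that `0 < w_e ≤ 1`. Terms with many children
are, empirically, terms with low information content — so down-weighting
their contribution mimics IC without computing it.

For a term A with ancestor graph `DAG_A = (A, T_A, E_A)`, each ancestor
gets an S-value

```
S_A(A) = 1
S_A(t) = max { w_e · S_A(t') : t' ∈ children(t) ∩ T_A }
```

and two terms are compared through their common ancestors:

```
S_GO(A, B) = Σ_{t ∈ T_A ∩ T_B} (S_A(t) + S_B(t)) / (SV(A) + SV(B)),
SV(X) = Σ_{t ∈ T_X} S_X(t)
```

Gene-level similarity mixes the term-pair values with one of five
strategies (`ABM` — the default pooled best-match average — `BMA`, `BMM`,
`Avg`, `Max`); genes are clustered with affinity propagation
(500 iterations, convits 50, damping 0.95, median preference), and
clusterings are scored per gene against a reference pathway with the
Matthews correlation coefficient over pairwise co-membership, optionally
after injecting randomly selected or EC-matched noise genes.

The package also reads OBO 1.2 ontologies and GAF 2.x / TSV annotations,
computes corpus IC with Resnik and Lin baselines, analyses the
children-count/IC relationship, and generates seeded synthetic ontologies
and clustered annotation sets so the whole pipeline is testable offline.

## A worked example

```r
library(gogo)

spec <- fixture_spec(n_genes = 12, n_clusters = 3, seed = 1)
ont  <- simulate_ontology(spec)            # synthetic single-root GO DAG
sim  <- simulate_clustered_genes(spec, ont)

m  <- gene_sim_matrix(ont, sim$annotations, sim$reference$gene,
                      "BPO", strategy = "ABM")
round(m[1:4, 1:4], 3)
#>         GENE001 GENE002 GENE003 GENE004
#> GENE001   1.000   0.877   0.896   0.871
#> GENE002   0.877   1.000   0.811   0.878
#> GENE003   0.896   0.811   1.000   0.904
#> GENE004   0.871   0.878   0.904   1.000

cl <- affinity_propagation(m)
cl
#> Affinity-propagation clustering: 12 genes, 3 cluster(s) (converged in 132 iterations)
#>   [GENE004] GENE001, GENE002, GENE003, GENE004
#>   [GENE007] GENE005, GENE006, GENE007, GENE008
#>   [GENE012] GENE009, GENE010, GENE011, GENE012

evaluate_clustering(cl, sim$reference)
#> MCC evaluation over 12 genes, 3 reference cluster(s)
#>   C1           n= 4  avg MCC = 1.000
#>   C2           n= 4  avg MCC = 1.000
#>   C3           n= 4  avg MCC = 1.000
#>   overall avg MCC = 1.000
```

The similarity matrix shows the planted block structure (within-cluster
ABM similarities near 0.9, between-cluster far lower); affinity
propagation recovers the three planted clusters exactly, and every
per-gene MCC is 1.

On a real release, term-level similarity works the same way:

```r
ont <- parse_obo("go-20160910.obo", relations = c("is_a", "part_of"))
term_similarity(ont, "GO:0005975", "GO:1901135")   # carbohydrate vs derivative metabolism
```

## Command line

A thin CLI over the same functions lives at `inst/scripts/gogo.R`:

```sh
Rscript inst/scripts/gogo.R simulate --n-terms 60 --n-genes 12 --seed 1 --out-dir out/
Rscript inst/scripts/gogo.R term-sim --obo out/ontology.obo --pairs pairs.txt
Rscript inst/scripts/gogo.R cluster  --obo out/ontology.obo \
    --annotations out/genes.tsv --reference out/pathway.tsv --out-dir out/
```

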