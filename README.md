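# cardigan

Disease-gene prioritization by network propagation of
phenotype-similarity seeds — including for **uncharted** diseases, i.e.
diseases with *no* known associated gene.

## The problem

Network-medicine methods find new disease genes by "guilt by
association": genes close to known disease genes on the protein–protein
interaction (PPI) network are promising candidates. That strategy needs
seeds, so it is silent for the large fraction of diseases that have no
molecularly characterized gene at all. But such diseases still have a
*phenotype*, and diseases with similar phenotypes tend to have disease
modules that sit close together on the interactome. This package turns
that observation into a predictor: the known genes of phenotypically
similar diseases are used as soft seeds that "triangulate" the location
of the query's module.

## The method

For a query disease *q* over a network of *n* genes:

1. **Seed vector (Query Weight Set).** Each gene *g* receives

   - *Y<sub>g</sub>* = 1 if *g* is a known gene of *q*;
   - *Y<sub>g</sub>* = *h* / (1 + e<sup>−a(s−b)</sup>) otherwise, where
     *s* = max over the other diseases of *g* of their phenotype
     similarity to *q*, and 0 < *h* < 1 dampens the sigmoid so no
     foreign gene can outweigh the query's own genes;
   - *Y<sub>g</sub>* = 0 if *g* has no disease association.

   Phenotype similarity is Resnik-family semantic similarity: the
   information content −log *p(t)* of the most informative common
   ancestor *t* of the two diseases' annotation term sets in an
   ontology, with annotation counts up-propagated to ancestors.

2. **Diffusion.** *Y* is propagated with the label-consistency method:
   *F* = β (I − αS)<sup>−1</sup> *Y*, where
   *S* = D<sup>−1/2</sup> W D<sup>−1/2</sup> is the degree-normalized
   adjacency, α = 1/(1+μ), β = μ/(1+μ). *F* minimizes the quadratic
   cost ½ Σ<sub>ij</sub> W<sub>ij</sub>(F<sub>i</sub>/√D<sub>ii</sub> −
   F<sub>j</sub>/√D<sub>jj</sub>)² + μ‖F − Y‖², which balances
   smoothness of scores over edges against fidelity to the seeds.

3. **Ranking.** Genes sorted by decreasing *F* (deterministic
   lexicographic tie-break) are the prediction; the top of the list can
   be read as the predicted disease module.

Because step 1 works from phenotype alone, uncharted diseases are first
class queries. The package also implements the standard evaluation
protocols for this problem — leave-one-out, time-lapse (predict with an
earlier association snapshot, test on later gains), disease-module
reconstruction — with recall@k, the truncated normalized ROC AUC (area
up to a fixed false-positive budget), seeded random baselines, and a
planted-partition synthetic-benchmark generator so everything is
testable without external databases.

## Worked example

```r
library(cardigan)

world <- make_world(m = 4, s = 10, p_in = 0.4, p_out = 0.02,
                    diseases_per_module = 3, genes_per_disease = 4,
                    n_background = 60, seed = 42)
world
#> synthetic_world: 4 modules x 10 genes + 60 background (seed 42)
#>   edges: 69 within-module, 94 between
#>   diseases: 12 charted at t1, 4 hidden at t0

# an uncharted query: phenotype annotations from module 2, zero genes
uq <- make_uncharted_query(world, module = 2)
ranking <- predict_genes(uq$query, world$assoc_t1, uq$world$sim, world$net)
head(data.frame(rank = 1:6, gene = head(ranking$genes, 6),
                score = signif(head(ranking$scores, 6), 3)))
#>   rank      gene score
#> 1    1 M02_G0013 0.145
#> 2    2 M02_G0018 0.135
#> 3    3 M02_G0020 0.127
#> 4    4 M02_G0011 0.126
#> 5    5 M02_G0016 0.125
#> 6    6 M03_G0023 0.123

mean(uq$true_genes %in% head(ranking$genes, 10))
#> [1] 0.7
```

Seven of the ten genes of the query's hidden module appear in the top
10 of 100 candidates, although the query contributed no seed gene — all
signal came from the phenotype similarity to the module's charted
diseases. The standard leave-one-out protocol on the same world:

```r
evaluate_loo(world$assoc_t1, world$net, world$sim, mode = "charted")
#> evaluation_result [loo-charted]: 48 case(s)
#>   recall@1 = 0.104, recall@10 = 0.812, recall@100 = 1, recall@200 = 1
```

## Command line

A thin wrapper over the same functions is installed at
`inst/cli/cardigan.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/cardigan.R", package="cardigan"))')" \
  predict --config run.yaml --outdir out/
```

Subcommands: `predict`, `evaluate <loo|timelapse|module>`, `fit-params`,
`make-fixtures`, `similarity`. All inputs are plain TSV (edge list,
`disease<TAB>gene` associations, `term<TAB>parent` ontology,
`disease<TAB>term` annotations, similarity matrix); every run writes a
self-describing JSON manifest with parameters and input checksums.

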