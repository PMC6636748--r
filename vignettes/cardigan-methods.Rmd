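---
title: "Phenotype-seeded network propagation: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotype-seeded network propagation: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardigan)
```

## The model

A disease is represented twice: molecularly, by its set of associated
genes on a protein–protein interaction (PPI) network, and
phenotypically, by a set of ontology terms. The method's premise is that
diseases with similar phenotypes have disease modules that lie close
together on the interactome, so the known genes of phenotypically
similar diseases carry information about where an uncharacterized
disease's module should be.

### Seed construction

For a query disease $q$ the seed vector $Y \in [0,1]^n$ (the *query
weight set*) over the $n$ network genes is:

$$
Y_g = \begin{cases}
1 & g \text{ is a known gene of } q\\[2pt]
\dfrac{h}{1 + e^{-a\,(s_g - b)}} & g \text{ belongs to other diseases},
  \; s_g = \max_{d \ni g,\, d \neq q} \mathrm{sim}(q, d)\\[2pt]
0 & \text{otherwise.}
\end{cases}
$$

Taking the *maximum* similarity when a gene serves several diseases
keeps the strongest phenotype link; the dampening factor $0 < h < 1$
guarantees a strict hierarchy — own genes (weight 1) always dominate
similarity-derived seeds (at most $h$). The phenotype similarity is
Resnik-family semantic similarity: annotation counts are up-propagated
to ontology ancestors, the information content of a term is
$\mathrm{ic}(t) = -\log(\text{count}(t)/N)$ in nats, and
$\mathrm{sim}(d_1, d_2)$ is the highest information content among
common ancestors of the two diseases' term sets. By default the
"best pairwise" reading is used (the most informative term shared by
the ancestral closures of the two sets); the stricter "common ancestor
of *all* terms" variant is available via `set_mode = "union"` but
collapses towards the root for multi-topic diseases. Counts are taken
at the disease level (one disease, one count), not at the level of
individual publications; with publication-level corpora only the scale
of the similarity changes, which the trainable sigmoid midpoint
absorbs.

### Diffusion

$Y$ is propagated with the label-consistency scheme over the
degree-normalized adjacency $S = D^{-1/2} W D^{-1/2}$:

$$
F = \beta\,(I - \alpha S)^{-1} Y,\qquad
\alpha = \tfrac{1}{1+\mu},\;\; \beta = \tfrac{\mu}{1+\mu}.
$$

$F$ is the unique minimizer of the quadratic objective

$$
C(F) = \tfrac12 \sum_{i,j} W_{ij}
  \Big(\tfrac{F_i}{\sqrt{D_{ii}}} - \tfrac{F_j}{\sqrt{D_{jj}}}\Big)^2
  + \mu \, \lVert F - Y \rVert^2 ,
$$

whose gradient is $2\,[(I-S)F + \mu(F - Y)]$. A normalization note: the
smoothness sum runs over both orientations of every edge and the
leading $\tfrac12$ cancels exactly that double count, while the
fidelity term enters unhalved. Distributing the $\tfrac12$ over both
terms instead would shift the minimizer to the same closed form at a
regularization of $\mu/2$ — a pure reparameterization of the same
one-parameter family, but under that convention the stated closed form
is not the exact stationary point. The package fixes the convention
above so that `propagation_cost()` and `propagate()` are exactly
consistent, which the test suite verifies against an independent
quadratic-minimization oracle.

Since the spectrum of $S$ lies in $[-1, 1]$ and $\alpha < 1$, the
system is uniformly invertible and the Neumann series converges, which
gives the two interchangeable solvers: a direct sparse solve, and the
fixed-point iteration $F \leftarrow \alpha S F + \beta Y$ (a
contraction with rate $\alpha$). The iterative route stops when the
contraction bound on the sup-norm distance to the exact solution drops
below `tol * (1 + max|F|)` and reports its iteration count; `solver =
"auto"` uses the direct solve up to 20\,000 nodes and the iteration
above that. Both satisfy the same accuracy contract, so the choice is
invisible to callers. Seed matrices (one query per column) are solved
in a single multi-right-hand-side factorization, which is how the
evaluation protocols batch hundreds of queries cheaply.

## Tunable parameters

| parameter | meaning | default | rationale |
|---|---|---|---|
| $\alpha$ (or $\mu$) | diffusion strength; $\alpha = 1/(1+\mu)$ | 0.9 | standard for label-consistency propagation on PPI networks; can be tuned jointly by `fit_sigmoid_params()` |
| $h$ | dampening: supremum of foreign-gene seed weights | 0.5 | artifact default (the reference training procedure for these constants is not part of this package); keeps a 2× margin between own and foreign seeds |
| $a$ | sigmoid slope (per similarity nat) | 1 | neutral slope on the natural-log information-content scale |
| $b$ | sigmoid midpoint (similarity units) | median of the query's nonzero similarities | adapts the operating point to the corpus-dependent similarity scale; a fixed global $b$ can be supplied instead |
| `tol` | iterative-solver accuracy (sup-norm, relative) | 1e-10 | far below any score gap that affects rankings |
| `fp_cap` | false-positive budget of the truncated AUC | 200 | matches typical curated disease-module sizes |

`fit_sigmoid_params()` selects $(h, a, b, \alpha)$ by exhaustive grid
search maximizing mean leave-one-out recall@100 on a training set of
charted diseases; it is deterministic given grid and data, and ties go
to the lexicographically smallest tuple. Whether one or two shape
parameters are trained, and whether $b$ is global or per disease, are
left as configuration; the defaults above are one-shape-parameter,
per-query-$b$.

## Input conventions and degenerate cases

* Networks are undirected TSV edge lists; duplicate/reversed edges
  collapse (conflicting weights: maximum wins, with a warning);
  self-loops are dropped since the diffusion assumes $W_{ii}=0$.
* Isolated genes stay in the ranking universe with zero rows in $S$;
  their score is exactly $\beta Y_i$ (seed retention). This is a
  convention, not a consequence of the edge-sum cost — the cost is
  blind to isolated coordinates, and keeping them avoids silently
  shrinking the candidate list. For the same reason the network is
  *not* restricted to its largest connected component (`?load_network`
  keeps whatever the file contains).
* Associated genes missing from the network are dropped from the seed
  with a warning; a query with neither known genes nor a similarity row
  is an error ("cannot seed").
* Rankings break score ties lexicographically by gene id, so every
  protocol is exactly reproducible.
* Diseases without annotations error by default in the similarity
  computation; `missing = "zero"` opts into treating them as
  phenotypically unrelated.

## Evaluation protocols

*Leave-one-out* removes one association at a time, reseeds, and records
the rank of the held-out gene, excluding the query's remaining known
genes from the candidate list (disable with `exclude_known = FALSE`);
charted mode uses diseases with $\ge 2$ genes, uncharted mode
single-gene diseases (removal yields a synthetic uncharted disease).
*Time-lapse* predicts strictly from an earlier snapshot and tests on
associations gained later, stratified by whether the disease was
uncharted at the earlier time; gains outside the network are counted
rather than silently dropped, and recall is reported both per
disease–gene case and per disease, since the two denominators differ
when one disease gains several genes. *Module reconstruction* keeps a
random fraction $f$ of a curated module ($\lceil f \cdot |M| \rceil$
genes, so any $f > 0$ keeps at least one; $f = 0$ keeps none and seeds
purely from phenotype) and scores the hidden genes by the truncated
normalized AUC: the area under TPR versus false-positive count up to
`fp_cap` false positives, divided by `fp_cap`, so a perfect ranking
scores 1 and a ranking with no positive before `fp_cap` negatives
scores 0. Under a uniformly random ranking its expectation is
$\approx \tfrac{\text{fp\_cap}}{2(n - P)}$, which `random_baseline()`
verifies by Monte Carlo. All sampling (kept-gene selections, baseline
orderings) flows from one user-supplied seed, drawn up front in a fixed
order so results are independent of how the propagation work is
batched.

## The synthetic benchmark

`make_world()` generates the statistical structure the method assumes,
so every claim is testable without external databases:

* a planted-partition interactome — $m = 8$ modules of $s = 25$ genes,
  within-module edge probability $p_\text{in} = 0.3$, everything else
  $p_\text{out} = 0.01$ — plus 800 background genes in no module. The
  background matters: real interactomes have on the order of $10^4$
  genes of which only a minority carry disease annotations, and without
  it a top-100 cutoff on a 200-gene universe would be half the network
  and no baseline comparison would be meaningful. With the default
  1\,000 genes, random recall@100 is 0.1.
* three charted diseases per module, each with 8 genes sampled from its
  home module;
* a small poly-hierarchy ontology (one branch per module, four specific
  terms per branch, one term with two parents, three broad "general"
  terms) and annotations that give same-module disease pairs deeper —
  more informative — common ancestors than cross-module pairs; 20% of
  diseases also carry one foreign-branch noise term;
* a $t_0 \subseteq t_1$ snapshot pair: one disease per module is fully
  hidden at $t_0$ (uncharted then, charted later) and 30% of the
  remaining associations are hidden at random;
* `make_uncharted_query()` adds a disease with home-branch annotations
  and zero genes — the recovery target is its module.

The weighted variant draws within-module weights from a higher-mean
distribution (uniform on $[0.6, 1]$ versus $[0.1, 0.5]$), exercising
the weighted code path. The defaults were fixed once, as above, and all
experiment sizes below use them.

What passing these benchmarks shows — and does not. The generator
produces exactly the regime the method is designed for: modular
networks and a phenotype similarity genuinely correlated with module
proximity. Success here demonstrates the machinery is correct and the
inference works when its premise holds. It does not demonstrate
performance on real interactomes, whose degree distributions are
heavy-tailed (planted partitions are not degree-corrected), whose
annotation corpora are far sparser and noisier, and whose ascertainment
biases (well-studied genes are both better connected and better
annotated) have no synthetic counterpart here.

## Experiment sizes

The shipped experiments use: 20 random fixtures of up to 30 nodes for
solver-equivalence checks; 10 independent default worlds (1\,000 genes
each) for uncharted recovery; one default world for leave-one-out
(192 cases), time-lapse, and module reconstruction (24 modules × 4
kept fractions × 10 repetitions, batched into one linear solve); and
2\,000 Monte-Carlo permutations at $n = 10^4$, $P = 50$ for the
random-AUC expectation. These sizes give standard errors well below the
effects being demonstrated.

## Known limitations

* The similarity is unbounded (nats); only its ordering and the
  sigmoid operating point matter, but users supplying precomputed
  matrices on other scales should refit $b$ (or pass `b` explicitly).
* `fit_sigmoid_params()` optimizes leave-one-out recall of *charted*
  diseases; if the intended use is purely uncharted queries, a grid
  scored on the time-lapse uncharted stratum may be preferable.
* The ontology reader accepts the package's two-column
  `term<TAB>parent` TSV dialect, not OBO.
* Scores are reported raw; they are rank statistics, not calibrated
  probabilities.
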