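#' Generate a synthetic disease-gene world
#'
#' Builds a planted-partition interactome with `m` disease modules of `s`
#' genes each (within-module edge probability `p_in`, everything else
#' `p_out`) plus `n_background` background genes that belong to no module
#' -- emulating the bulk of a real interactome, where most genes carry no
#' disease annotation. Each module hosts `diseases_per_module` charted
#' diseases whose gene sets are sampled from the module. A small random
#' poly-hierarchy ontology is built with one branch per module; diseases
#' are annotated with terms from their home branch (plus occasional noise
#' terms from other branches and broad general terms), so that the
#' semantic similarity of same-module disease pairs is, in expectation,
#' higher than that of cross-module pairs. A `t0` association snapshot is
#' derived from the full `t1` snapshot by fully hiding
#' `uncharted_per_module` diseases per module (uncharted at t0, charted
#' at t1) and additionally hiding a random `hide_fraction` of the
#' remaining associations.
#'
#' @param m number of modules.
#' @param s module size (genes per module).
#' @param p_in,p_out within/between edge probabilities, `p_out < p_in`.
#' @param diseases_per_module charted diseases planted per module.
#' @param genes_per_disease genes sampled from the module per disease.
#' @param n_background module-free background genes.
#' @param hide_fraction fraction of charted-disease associations hidden
#'   from the t0 snapshot (beyond the fully hidden diseases).
#' @param uncharted_per_module diseases per module fully hidden at t0.
#' @param weighted if TRUE, within-module edges draw weights from a
#'   higher-mean distribution (uniform on \[0.6, 1\]) than cross edges
#'   (uniform on \[0.1, 0.5\]), exercising the weighted code path.
#' @param noise_term_prob probability that a disease also carries one
#'   annotation term from a foreign module branch.
#' @param seed RNG seed; the world is fully reproducible from it.
#' @return object of class `synthetic_world`: list with `net`
#'   ([interactome]), `assoc_t1`/`assoc_t0` ([disease_gene_map]s),
#'   `onto` ([ontology]), `corpus` ([annotation_corpus]), `sim`
#'   ([similarity_source]), `modules` (disease -> full home-module gene
#'   set), `module_genes` (per-module gene lists), `module_of_disease`,
#'   `edge_counts` (realized within/between counts), `params`.
#' @export
make_world <- function(m = 8L, s = 25L, p_in = 0.3, p_out = 0.01,
                       diseases_per_module = 3L, genes_per_disease = 8L,
                       n_background = 800L, hide_fraction = 0.3,
                       uncharted_per_module = 1L, weighted = FALSE,
                       noise_term_prob = 0.2, seed = 1L) {
  stopifnot(p_out >= 0, p_out < p_in, p_in <= 1,
            m >= 1, s >= 2, genes_per_disease <= s,
            hide_fraction >= 0, hide_fraction <= 1,
            uncharted_per_module < diseases_per_module ||
              uncharted_per_module == 0)
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  set.seed(as.integer(seed))

  n_mod <- m * s
  n <- n_mod + n_background
  genes <- c(sprintf("M%02d_G%04d", rep(seq_len(m), each = s), seq_len(n_mod)),
             if (n_background > 0) sprintf("Z_G%04d", seq_len(n_background)))
  module_of_gene <- c(rep(seq_len(m), each = s), rep(0L, n_background))

  # planted-partition edges over the upper triangle
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  same <- module_of_gene[ut[, 1]] == module_of_gene[ut[, 2]] &
    module_of_gene[ut[, 1]] > 0L
  keep <- stats::runif(nrow(ut)) < ifelse(same, p_in, p_out)
  ei <- ut[keep, 1]; ej <- ut[keep, 2]
  w <- if (weighted) {
    ifelse(same[keep], stats::runif(sum(keep), 0.6, 1.0),
           stats::runif(sum(keep), 0.1, 0.5))
  } else rep(1, sum(keep))
  edge_counts <- c(within = sum(same[keep]), between = sum(!same[keep]))
  net <- interactome(data.frame(gene_a = genes[ei], gene_b = genes[ej],
                                weight = w),
                     genes = genes)

  module_genes <- lapply(seq_len(m), function(k) genes[module_of_gene == k])

  # charted diseases: gene sets sampled from the home module
  disease_ids <- character(0); assoc_d <- character(0); assoc_g <- character(0)
  module_of_disease <- integer(0)
  for (k in seq_len(m)) {
    for (j in seq_len(diseases_per_module)) {
      d <- sprintf("D_M%02d_%02d", k, j)
      gs <- sort(sample(module_genes[[k]], genes_per_disease))
      disease_ids <- c(disease_ids, d)
      module_of_disease <- c(module_of_disease, k)
      assoc_d <- c(assoc_d, rep(d, length(gs)))
      assoc_g <- c(assoc_g, gs)
    }
  }
  names(module_of_disease) <- disease_ids
  assoc_t1 <- disease_gene_map(assoc_d, assoc_g, snapshot = "t1")

  # ontology: root -> general terms + one branch per module -> specifics;
  # the first specific of each branch gets a second (general) parent so
  # the DAG is a genuine poly-hierarchy
  n_specific <- 4L
  term <- character(0); parent <- character(0)
  for (l in 1:3) { term <- c(term, sprintf("T_gen%d", l))
                   parent <- c(parent, "T_root") }
  for (k in seq_len(m)) {
    br <- sprintf("T_M%02d", k)
    term <- c(term, br); parent <- c(parent, "T_root")
    for (l in seq_len(n_specific)) {
      sp <- sprintf("T_M%02d_S%d", k, l)
      term <- c(term, sp); parent <- c(parent, br)
      if (l == 1) { term <- c(term, sp); parent <- c(parent, "T_gen1") }
    }
  }
  onto <- ontology(term, parent)

  ann_d <- character(0); ann_t <- character(0)
  for (i in seq_along(disease_ids)) {
    d <- disease_ids[i]; k <- module_of_disease[i]
    n_terms <- sample(2:3, 1)
    ts <- sample(sprintf("T_M%02d_S%d", k, seq_len(n_specific)), n_terms)
    if (stats::runif(1) < noise_term_prob && m > 1) {
      other <- sample(setdiff(seq_len(m), k), 1)
      ts <- c(ts, sample(sprintf("T_M%02d_S%d", other,
                                 seq_len(n_specific)), 1))
    }
    if (stats::runif(1) < 0.5) ts <- c(ts, sprintf("T_gen%d", sample(3, 1)))
    ann_d <- c(ann_d, rep(d, length(ts))); ann_t <- c(ann_t, ts)
  }
  corpus <- annotation_corpus(ann_d, ann_t, onto)
  sim <- similarity_matrix(onto, corpus)

  # t0 snapshot: fully hide some diseases, then a fraction of the rest
  hidden_diseases <- unlist(lapply(seq_len(m), function(k) {
    ds <- disease_ids[module_of_disease == k]
    if (uncharted_per_module > 0) sample(ds, uncharted_per_module)
    else character(0)
  }))
  keep_pair <- !(assoc_d %in% hidden_diseases)
  partial <- keep_pair & (stats::runif(length(assoc_d)) < 1 - hide_fraction)
  # never let a kept disease lose *all* genes to partial hiding
  for (d in setdiff(disease_ids, hidden_diseases)) {
    idx <- which(assoc_d == d)
    if (!any(partial[idx])) partial[idx[1]] <- TRUE
  }
  assoc_t0 <- disease_gene_map(assoc_d[partial], assoc_g[partial],
                               snapshot = "t0")

  modules <- stats::setNames(
    lapply(module_of_disease, function(k) module_genes[[k]]), disease_ids)

  structure(list(net = net, assoc_t1 = assoc_t1, assoc_t0 = assoc_t0,
                 onto = onto, corpus = corpus, sim = sim,
                 annotations = data.frame(disease = ann_d, term = ann_t),
                 modules = modules, module_genes = module_genes,
                 module_of_disease = module_of_disease,
                 hidden_diseases = sort(hidden_diseases),
                 edge_counts = edge_counts,
                 params = list(m = m, s = s, p_in = p_in, p_out = p_out,
                               diseases_per_module = diseases_per_module,
                               genes_per_disease = genes_per_disease,
                               n_background = n_background,
                               hide_fraction = hide_fraction,
                               weighted = weighted,
                               noise_term_prob = noise_term_prob,
                               seed = as.integer(seed))),
            class = "synthetic_world")
}

#' Add an uncharted query disease to a synthetic world
#'
#' Creates a disease with phenotype annotations drawn from the given
#' module's ontology branch but *no* gene associations, then rebuilds the
#' annotation corpus and similarity matrix so the query has a similarity
#' row. This is the synthetic analogue of a molecularly uncharacterized
#' disease whose module location must be inferred from phenotype alone.
#'
#' @param world a `synthetic_world`.
#' @param module module index in `1..m` the query phenotypically belongs
#'   to (its hidden "true" genes are that module's genes).
#' @param n_terms number of home-branch terms to annotate the query with.
#' @return list with `world` (updated), `query` (the new disease id), and
#'   `true_genes` (the home module's genes, the recovery target).
#' @export
make_uncharted_query <- function(world, module, n_terms = 3L) {
  stopifnot(inherits(world, "synthetic_world"),
            module >= 1, module <= world$params$m)
  set.seed(world$params$seed + 31L * as.integer(module) + 1000003L)
  query <- sprintf("D_M%02d_query", module)
  n_specific <- 4L
  ts <- sample(sprintf("T_M%02d_S%d", module, seq_len(n_specific)),
               min(n_terms, n_specific))
  ann <- rbind(world$annotations,
               data.frame(disease = rep(query, length(ts)), term = ts))
  world$annotations <- ann
  world$corpus <- annotation_corpus(ann$disease, ann$term, world$onto)
  world$sim <- similarity_matrix(world$onto, world$corpus)
  list(world = world, query = query,
       true_genes = world$module_genes[[module]])
}

#' Write all world fixtures in the package's file dialects
#'
#' Emits `network.tsv` (edge list), `associations_t1.tsv` /
#' `associations_t0.tsv`, `ontology.tsv` (term/parent pairs),
#' `annotations.tsv`, `modules.tsv` and `similarity.tsv` under `dir`.
#' Output is byte-identical for identical worlds.
#'
#' @param world a `synthetic_world`.
#' @param dir output directory (created if absent).
#' @return named character vector of the paths written.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "synthetic_world"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(network = file.path(dir, "network.tsv"),
             assoc_t1 = file.path(dir, "associations_t1.tsv"),
             assoc_t0 = file.path(dir, "associations_t0.tsv"),
             ontology = file.path(dir, "ontology.tsv"),
             annotations = file.path(dir, "annotations.tsv"),
             modules = file.path(dir, "modules.tsv"),
             similarity = file.path(dir, "similarity.tsv"))

  Wt <- methods::as(methods::as(Matrix::triu(world$net$W), "generalMatrix"),
                    "TsparseMatrix")
  edges <- data.frame(a = world$net$genes[Wt@i + 1L],
                      b = world$net$genes[Wt@j + 1L], w = Wt@x)
  edges <- edges[order(edges$a, edges$b), ]
  utils::write.table(edges, paths[["network"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  write_associations(world$assoc_t1, paths[["assoc_t1"]])
  write_associations(world$assoc_t0, paths[["assoc_t0"]])

  pr <- world$onto$parents
  ot <- data.frame(term = rep(names(pr), lengths(pr)),
                   parent = unlist(pr, use.names = FALSE))
  ot <- ot[order(ot$term, ot$parent), ]
  utils::write.table(ot, paths[["ontology"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  ann <- world$annotations[order(world$annotations$disease,
                                 world$annotations$term), ]
  utils::write.table(ann, paths[["annotations"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  md <- data.frame(disease = rep(names(world$modules),
                                 lengths(world$modules)),
                   gene = unlist(world$modules, use.names = FALSE))
  utils::write.table(md, paths[["modules"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  write_similarity(world$sim, paths[["similarity"]])
  paths
}

#' @export
print.synthetic_world <- function(x, ...) {
  p <- x$params
  cat("synthetic_world: ", p$m, " modules x ", p$s, " genes + ",
      p$n_background, " background (seed ", p$seed, ")\n", sep = "")
  cat("  edges: ", x$edge_counts[["within"]], " within-module, ",
      x$edge_counts[["between"]], " between\n", sep = "")
  cat("  diseases: ", length(x$module_of_disease), " charted at t1, ",
      length(x$hidden_diseases), " hidden at t0\n", sep = "")
  invisible(x)
}
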