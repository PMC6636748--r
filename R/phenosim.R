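#' Information content of an ontology term
#'
#' `ic(t) = -log(count(t) / N)` in nats, where `count(t)` is the number of
#' annotated diseases whose ancestrally closed term set contains `t` and
#' `N` is the number of annotated diseases. A term covering the whole
#' corpus (any root reached by every disease) has `ic = 0`; rarer, deeper
#' terms have higher content, and `ic` is anti-monotone along ontology
#' edges because counts are up-propagated.
#'
#' @param term term id.
#' @param corpus an [annotation_corpus].
#' @param onto the [ontology] (used only to give a precise error for terms
#'   outside the ontology); optional.
#' @return non-negative information content in nats.
#' @export
information_content <- function(term, corpus, onto = NULL) {
  stopifnot(inherits(corpus, "annotation_corpus"))
  if (!is.null(onto) && !(term %in% onto$terms))
    stop("term not in ontology: ", term)
  cnt <- corpus$counts[[term]]
  if (is.null(cnt) || is.na(cnt))
    stop("term never used (directly or via descendants) in corpus: ", term)
  -log(as.numeric(cnt) / corpus$n_diseases)
}

#' Semantic phenotype similarity between two diseases
#'
#' Resnik-family similarity over the disease's term sets: the information
#' content of the most informative common ancestor across the two sets.
#' With `set_mode = "pairwise"` (default) the similarity is
#' `max_{a in terms(d1), b in terms(d2)} max{ ic(t) : t in anc(a) n anc(b) }`,
#' which equals the highest-IC term shared by the ancestral closures of the
#' two sets. `set_mode = "union"` instead takes common ancestors of *every*
#' term of both diseases (the LCA of the union), a stricter variant that
#' collapses towards the root for multi-topic diseases.
#'
#' @param d1,d2 disease ids.
#' @param onto an [ontology].
#' @param corpus an [annotation_corpus] over `onto`.
#' @param set_mode `"pairwise"` (best pairwise common ancestor) or
#'   `"union"` (common ancestor of all terms).
#' @param missing `"error"` (default) or `"zero"`: what to do when a
#'   disease carries no annotation.
#' @return non-negative similarity (nats); symmetric in `d1`, `d2`.
#' @export
caniza_similarity <- function(d1, d2, onto, corpus,
                              set_mode = c("pairwise", "union"),
                              missing = c("error", "zero")) {
  set_mode <- match.arg(set_mode)
  missing <- match.arg(missing)
  stopifnot(inherits(onto, "ontology"), inherits(corpus, "annotation_corpus"))
  for (d in c(d1, d2)) {
    if (is.null(corpus$terms[[d]])) {
      if (missing == "zero") return(0)
      stop("disease has no annotations: ", d)
    }
  }
  common <- if (set_mode == "pairwise") {
    intersect(corpus$closed[[d1]], corpus$closed[[d2]])
  } else {
    closures <- onto$ancestors[c(corpus$terms[[d1]], corpus$terms[[d2]])]
    Reduce(intersect, closures)
  }
  common <- intersect(common, names(corpus$counts))
  if (length(common) == 0) return(0)
  max(vapply(common, information_content, numeric(1), corpus = corpus))
}

#' Pairwise disease similarity matrix
#'
#' Computes all pairwise [caniza_similarity] values for a set of diseases.
#'
#' @param diseases character vector of disease ids; defaults to every
#'   annotated disease in the corpus.
#' @inheritParams caniza_similarity
#' @return a [similarity_source] backed by a dense symmetric matrix.
#' @export
similarity_matrix <- function(onto, corpus, diseases = NULL,
                              set_mode = c("pairwise", "union"),
                              missing = c("error", "zero")) {
  set_mode <- match.arg(set_mode)
  missing <- match.arg(missing)
  if (is.null(diseases)) diseases <- sort(names(corpus$terms))
  diseases <- as.character(diseases)
  n <- length(diseases)
  M <- matrix(0, n, n, dimnames = list(diseases, diseases))
  for (i in seq_len(n)) {
    for (j in i:n) {
      M[i, j] <- M[j, i] <- caniza_similarity(
        diseases[i], diseases[j], onto, corpus,
        set_mode = set_mode, missing = missing)
    }
  }
  similarity_source(M)
}

#' Wrap a symmetric disease-similarity matrix as a similarity source
#'
#' A similarity source answers `sim_lookup(src, d1, d2)` queries; values
#' are non-negative and symmetric.
#'
#' @param M numeric matrix with identical row and column disease ids.
#' @param tol asymmetry tolerance; `max|M - t(M)|` beyond it is rejected.
#' @return object of class `similarity_source`.
#' @export
similarity_source <- function(M, tol = 1e-9) {
  M <- as.matrix(M)
  if (is.null(rownames(M)) || is.null(colnames(M)) ||
      !identical(rownames(M), colnames(M)))
    stop("similarity matrix needs identical row and column disease ids")
  if (max(abs(M - t(M))) > tol)
    stop("similarity matrix asymmetric beyond tolerance ", tol)
  if (any(M < 0)) stop("similarity values must be non-negative")
  M <- (M + t(M)) / 2
  structure(list(matrix = M, diseases = rownames(M)),
            class = "similarity_source")
}

#' Query a similarity source
#'
#' @param src a [similarity_source].
#' @param d1,d2 disease ids.
#' @param default value returned when either disease is unknown to the
#'   source (`NA` by default; pass 0 to treat unknown diseases as
#'   phenotypically unrelated).
#' @return scalar similarity.
#' @export
sim_lookup <- function(src, d1, d2, default = NA_real_) {
  stopifnot(inherits(src, "similarity_source"))
  if (!(d1 %in% src$diseases) || !(d2 %in% src$diseases)) return(default)
  src$matrix[d1, d2]
}

#' Full similarity row for one disease
#'
#' Repeated queries for the same disease return identical values (the
#' backing matrix is immutable).
#'
#' @param src a [similarity_source].
#' @param d disease id.
#' @return named numeric vector over the source's diseases, or `NULL` when
#'   `d` is unknown.
#' @export
sim_row <- function(src, d) {
  stopifnot(inherits(src, "similarity_source"))
  if (!(d %in% src$diseases)) return(NULL)
  src$matrix[d, ]
}

#' Write a similarity source as TSV (disease ids as first row and column)
#' @param src a [similarity_source].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_similarity <- function(src, path) {
  stopifnot(inherits(src, "similarity_source"))
  utils::write.table(
    format(src$matrix, digits = 17, trim = TRUE, scientific = FALSE),
    path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Read a similarity matrix TSV written by [write_similarity]
#' @param path TSV path: header row of disease ids, first column likewise.
#' @param tol asymmetry tolerance (see [similarity_source]).
#' @return a [similarity_source].
#' @export
load_similarity <- function(path, tol = 1e-9) {
  M <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   row.names = 1, check.names = FALSE,
                                   quote = ""))
  similarity_source(M, tol = tol)
}

#' @export
print.similarity_source <- function(x, ...) {
  cat("similarity source: ", length(x$diseases), " diseases\n", sep = "")
  invisible(x)
}
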