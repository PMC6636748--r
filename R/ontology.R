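#' Construct an ontology from term--parent pairs
#'
#' Represents a rooted DAG (poly-hierarchies such as MeSH are allowed:
#' a term may have several parents, and several roots may coexist).
#' Transitive ancestor sets -- each term's ancestors include the term
#' itself -- are precomputed once, since every similarity query needs them.
#'
#' @param term character vector of child term ids.
#' @param parent character vector of parent term ids (same length). Terms
#'   that never appear as a child are roots.
#' @return object of class `ontology`: list with `terms` (character),
#'   `parents` (named list), `ancestors` (named list, self-inclusive),
#'   `roots` (character).
#' @export
ontology <- function(term, parent) {
  stopifnot(length(term) == length(parent))
  term <- as.character(term); parent <- as.character(parent)
  keep <- !duplicated(paste(term, parent))
  term <- term[keep]; parent <- parent[keep]
  terms <- sort(unique(c(term, parent)))
  parents <- lapply(stats::setNames(terms, terms), function(t)
    unique(parent[term == t]))

  # Kahn topological order doubles as the acyclicity check
  n_unresolved <- lengths(parents)
  order <- character(0)
  frontier <- terms[n_unresolved == 0]
  children <- split(term, parent)
  remaining <- stats::setNames(n_unresolved, terms)
  while (length(frontier) > 0) {
    order <- c(order, frontier)
    next_frontier <- character(0)
    for (p in frontier) {
      for (ch in children[[p]]) {
        remaining[ch] <- remaining[ch] - 1L
        if (remaining[ch] == 0L) next_frontier <- c(next_frontier, ch)
      }
    }
    frontier <- unique(next_frontier)
  }
  if (length(order) < length(terms))
    stop("ontology contains a cycle involving: ",
         paste(utils::head(setdiff(terms, order), 5), collapse = ", "))

  ancestors <- vector("list", length(terms))
  names(ancestors) <- terms
  for (t in order) {  # parents come before children in `order`
    anc <- t
    for (p in parents[[t]]) anc <- c(anc, ancestors[[p]])
    ancestors[[t]] <- unique(anc)
  }
  structure(list(terms = terms, parents = parents, ancestors = ancestors,
                 roots = terms[lengths(parents) == 0]),
            class = "ontology")
}

#' Read an ontology from a 2-column TSV of `term<TAB>parent` pairs
#'
#' A term with multiple parents occupies multiple lines. Lines starting
#' with `#` are comments.
#'
#' @param path TSV file path.
#' @return an [ontology].
#' @export
load_ontology <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                           colClasses = "character", quote = "")
  if (ncol(tab) < 2) stop("ontology file needs 2 columns: term, parent")
  ontology(tab[[1]], tab[[2]])
}

#' Ancestor set of a term (self-inclusive)
#' @param onto an [ontology].
#' @param term term id.
#' @return character vector of ancestor term ids, including `term`.
#' @export
term_ancestors <- function(onto, term) {
  stopifnot(inherits(onto, "ontology"))
  anc <- onto$ancestors[[term]]
  if (is.null(anc)) stop("term not in ontology: ", term)
  anc
}

#' Build an annotation corpus from disease--term assignments
#'
#' Annotation counts are up-propagated: a term's count is the number of
#' annotated diseases whose term set, closed under ancestry, contains it.
#' This is the standard Resnik corpus treatment and guarantees
#' `count(ancestor) >= count(descendant)`.
#'
#' @param disease character vector of disease ids.
#' @param term character vector of term ids (same length).
#' @param onto the [ontology] the terms live in.
#' @return object of class `annotation_corpus`: list with `terms` (named
#'   list disease -> direct term set), `closed` (disease -> ancestral
#'   closure of its term set), `counts` (named integer per term),
#'   `n_diseases` (number of annotated diseases).
#' @export
annotation_corpus <- function(disease, term, onto) {
  stopifnot(length(disease) == length(term), inherits(onto, "ontology"))
  disease <- as.character(disease); term <- as.character(term)
  unknown <- setdiff(unique(term), onto$terms)
  if (length(unknown) > 0)
    stop("annotation term(s) not in ontology: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  terms_by_disease <- lapply(split(term, disease), unique)
  closed <- lapply(terms_by_disease, function(ts)
    unique(unlist(onto$ancestors[ts], use.names = FALSE)))
  counts <- table(unlist(closed, use.names = FALSE))
  counts <- stats::setNames(as.integer(counts), names(counts))
  structure(list(terms = terms_by_disease, closed = closed, counts = counts,
                 n_diseases = length(terms_by_disease)),
            class = "annotation_corpus")
}

#' Read disease--term annotations from TSV (`disease_id<TAB>term_id`)
#' @param path TSV file path.
#' @param onto the [ontology] the terms belong to.
#' @return an [annotation_corpus].
#' @export
load_annotations <- function(path, onto) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                           colClasses = "character", quote = "")
  if (ncol(tab) < 2) stop("annotation file needs 2 columns: disease, term")
  annotation_corpus(tab[[1]], tab[[2]], onto)
}

#' @export
print.ontology <- function(x, ...) {
  cat("ontology: ", length(x$terms), " terms, ",
      length(x$roots), " root(s)\n", sep = "")
  invisible(x)
}

#' @export
print.annotation_corpus <- function(x, ...) {
  cat("annotation corpus: ", x$n_diseases, " diseases, ",
      length(x$counts), " used terms\n", sep = "")
  invisible(x)
}
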