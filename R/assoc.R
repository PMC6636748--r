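#' Disease--gene association map
#'
#' One snapshot of a disease--gene association database: a mapping from
#' disease id to its set of associated genes. Diseases with at least one
#' gene are "charted"; a disease may be carried with an empty set to
#' represent an uncharted disease known only by phenotype.
#'
#' @param disease character vector of disease ids.
#' @param gene character vector of gene ids (same length).
#' @param snapshot free-text snapshot label (e.g. `"2013"`).
#' @return object of class `disease_gene_map`: list with `genes` (named
#'   list disease -> character vector) and `snapshot`.
#' @export
disease_gene_map <- function(disease, gene, snapshot = NA_character_) {
  stopifnot(length(disease) == length(gene))
  genes <- lapply(split(as.character(gene), as.character(disease)),
                  function(g) sort(unique(g)))
  structure(list(genes = genes, snapshot = snapshot),
            class = "disease_gene_map")
}

as_disease_gene_map <- function(x) {
  if (inherits(x, "disease_gene_map")) return(x)
  if (is.data.frame(x) && ncol(x) >= 2)
    return(disease_gene_map(x[[1]], x[[2]]))
  if (is.list(x))
    return(structure(list(genes = lapply(x, function(g) sort(unique(
      as.character(g)))), snapshot = NA_character_),
      class = "disease_gene_map"))
  stop("cannot interpret object as a disease_gene_map")
}

#' Read associations from TSV (`disease_id<TAB>gene_id`)
#' @param path TSV path; `#` lines are comments.
#' @param snapshot snapshot label stored on the result.
#' @return a [disease_gene_map].
#' @export
load_associations <- function(path, snapshot = NA_character_) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                           colClasses = "character", quote = "")
  if (ncol(tab) < 2) stop("association file needs 2 columns: disease, gene")
  disease_gene_map(tab[[1]], tab[[2]], snapshot = snapshot)
}

#' Write associations as TSV
#' @param assoc a [disease_gene_map].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_associations <- function(assoc, path) {
  assoc <- as_disease_gene_map(assoc)
  d <- rep(names(assoc$genes), lengths(assoc$genes))
  g <- unlist(assoc$genes, use.names = FALSE)
  utils::write.table(data.frame(disease_id = d, gene_id = g), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Remove one disease--gene association (for leave-one-out protocols)
#' @param assoc a [disease_gene_map].
#' @param disease,gene the association to drop.
#' @param drop_empty drop the disease entirely if its set becomes empty
#'   (`FALSE` keeps it as an uncharted disease).
#' @return a new [disease_gene_map].
#' @export
drop_association <- function(assoc, disease, gene, drop_empty = FALSE) {
  assoc <- as_disease_gene_map(assoc)
  assoc$genes[[disease]] <- setdiff(assoc$genes[[disease]], gene)
  if (drop_empty && length(assoc$genes[[disease]]) == 0)
    assoc$genes[[disease]] <- NULL
  assoc
}

#' @export
print.disease_gene_map <- function(x, ...) {
  sizes <- lengths(x$genes)
  cat("disease_gene_map: ", length(sizes), " diseases (",
      sum(sizes > 0), " charted), ", sum(sizes), " associations",
      if (!is.na(x$snapshot)) paste0(" [snapshot ", x$snapshot, "]"),
      "\n", sep = "")
  invisible(x)
}
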