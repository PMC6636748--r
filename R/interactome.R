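#' Construct an interactome from an edge table
#'
#' Builds the symmetric adjacency `W`, the degree vector `D` and the
#' degree-normalized adjacency `S = D^{-1/2} W D^{-1/2}` used by the
#' diffusion. Self-loops are dropped (with a warning) and duplicate edges
#' with conflicting weights are collapsed to the maximum weight.
#'
#' @param edges data.frame with columns `gene_a`, `gene_b` and optionally
#'   `weight` (finite, non-negative; defaults to 1 for binary networks).
#' @param genes optional character vector of additional gene identifiers to
#'   keep in the universe even if they carry no edge (isolated nodes).
#'
#' @return An object of class `interactome`: a list with
#'   \describe{
#'     \item{genes}{lexicographically ordered gene identifiers (length n)}
#'     \item{W}{n x n symmetric sparse adjacency (`Matrix::dgCMatrix`)}
#'     \item{degree}{named degree vector, `D_ii = sum_k W_ik`}
#'     \item{S}{normalized adjacency; rows/columns of isolated nodes are zero}
#'   }
#' @export
interactome <- function(edges, genes = NULL) {
  stopifnot(is.data.frame(edges), ncol(edges) >= 2)
  a <- as.character(edges[[1]])
  b <- as.character(edges[[2]])
  w <- if (ncol(edges) >= 3) as.numeric(edges[[3]]) else rep(1, length(a))
  if (anyNA(w) || any(!is.finite(w))) {
    bad <- which(!is.finite(w) | is.na(w))[1]
    stop("non-numeric or non-finite edge weight at input row ", bad)
  }
  if (any(w < 0)) {
    bad <- which(w < 0)[1]
    stop("negative edge weight at input row ", bad, " (", a[bad], " -- ",
         b[bad], ": ", w[bad], ")")
  }

  loop <- a == b
  if (any(loop)) {
    warning(sum(loop), " self-loop(s) dropped (e.g. ", a[which(loop)[1]], ")")
    a <- a[!loop]; b <- b[!loop]; w <- w[!loop]
  }
  if (length(a) == 0 && is.null(genes)) stop("no edges left: empty network")

  gene_universe <- sort(unique(c(a, b, as.character(genes))))
  n <- length(gene_universe)
  ia <- match(a, gene_universe)
  ib <- match(b, gene_universe)

  # canonical orientation so "A B" and "B A" collapse to one edge
  lo <- pmin(ia, ib); hi <- pmax(ia, ib)
  key <- paste(lo, hi)
  if (anyDuplicated(key)) {
    agg <- tapply(w, key, max)
    n_conflict <- sum(vapply(split(w, key), function(x)
      length(unique(x)) > 1, logical(1)))
    if (n_conflict > 0)
      warning(n_conflict, " duplicate edge(s) with conflicting weights; ",
              "kept the maximum")
    keys <- strsplit(names(agg), " ", fixed = TRUE)
    lo <- vapply(keys, function(k) as.integer(k[1]), integer(1))
    hi <- vapply(keys, function(k) as.integer(k[2]), integer(1))
    w <- as.numeric(agg)
  }

  W <- Matrix::sparseMatrix(i = c(lo, hi), j = c(hi, lo), x = c(w, w),
                            dims = c(n, n),
                            dimnames = list(gene_universe, gene_universe))
  W <- methods::as(Matrix::drop0(W), "CsparseMatrix")
  structure(
    list(genes = gene_universe, W = W,
         degree = stats::setNames(Matrix::rowSums(W), gene_universe),
         S = normalize_adjacency(W)),
    class = "interactome")
}

#' Degree-normalize an adjacency matrix
#'
#' Computes `S = D^{-1/2} W D^{-1/2}` with `D_ii = sum_k W_ik`. Rows and
#' columns of isolated nodes (zero degree) are left identically zero, so
#' such nodes retain only their seed weight under diffusion.
#'
#' @param W symmetric non-negative (sparse) adjacency matrix.
#' @return sparse symmetric matrix `S` with spectrum in `[-1, 1]`.
#' @export
normalize_adjacency <- function(W) {
  d <- Matrix::rowSums(W)
  inv_sqrt <- ifelse(d > 0, 1 / sqrt(d), 0)
  Dm <- Matrix::Diagonal(x = inv_sqrt)
  S <- Dm %*% W %*% Dm
  dimnames(S) <- dimnames(W)
  methods::as(S, "CsparseMatrix")
}

#' Read a PPI network from a tab-separated edge list
#'
#' Expected format: `gene_a<TAB>gene_b[<TAB>weight]`, one interaction per
#' line; lines starting with `#` are comments. A missing third column (or
#' `weighted = FALSE`) yields a binary network with unit weights.
#'
#' @param path path to the edge-list file.
#' @param weighted if `FALSE`, any third column is ignored and all weights
#'   are set to 1.
#' @param keep_isolated optional character vector of gene ids to retain as
#'   isolated nodes.
#' @return an [interactome] object.
#' @export
load_network <- function(path, weighted = TRUE, keep_isolated = NULL) {
  if (!file.exists(path)) stop("network file not found: ", path)
  lns <- readLines(path, warn = FALSE)
  if (!any(nzchar(lns) & !startsWith(lns, "#")))
    stop("empty network file: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                           colClasses = "character", fill = FALSE,
                           quote = "", stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("edge list needs at least 2 tab-separated columns")
  if (ncol(tab) >= 3 && weighted) {
    suppressWarnings(w <- as.numeric(tab[[3]]))
    if (anyNA(w)) {
      bad <- which(is.na(w))[1]
      stop("non-numeric weight '", tab[[3]][bad], "' at line ", bad,
           " of ", path)
    }
    if (any(!is.finite(w)))
      stop("non-finite weight at line ", which(!is.finite(w))[1], " of ", path)
    if (any(w < 0))
      stop("negative weight at line ", which(w < 0)[1], " of ", path)
    tab <- data.frame(gene_a = tab[[1]], gene_b = tab[[2]], weight = w)
  } else {
    tab <- data.frame(gene_a = tab[[1]], gene_b = tab[[2]], weight = 1)
  }
  interactome(tab, genes = keep_isolated)
}

#' Export an interactome adjacency in MatrixMarket coordinate format
#'
#' Writes the upper triangle of `W` as an `%%MatrixMarket matrix coordinate
#' real symmetric` file, plus a sidecar `<path>.genes` file with the row
#' ordering, for interoperability with sparse-matrix tooling.
#'
#' @param net an [interactome].
#' @param path output `.mtx` path.
#' @return `path`, invisibly.
#' @export
write_network_mtx <- function(net, path) {
  stopifnot(inherits(net, "interactome"))
  Matrix::writeMM(methods::as(methods::as(Matrix::triu(net$W),
                                          "generalMatrix"),
                              "TsparseMatrix"), path)
  writeLines(net$genes, paste0(path, ".genes"))
  invisible(path)
}

#' @export
print.interactome <- function(x, ...) {
  nnz <- Matrix::nnzero(x$W) / 2
  cat("interactome: ", length(x$genes), " genes, ", nnz, " interactions\n",
      sep = "")
  cat("  weighted: ", !all(x$W@x %in% c(0, 1)),
      "; isolated nodes: ", sum(x$degree == 0), "\n", sep = "")
  invisible(x)
}
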