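#' Sigmoid seed-weight parameters
#'
#' The phenotype similarity `s` between the query and another disease is
#' rescaled into a seed weight `w(s) = h / (1 + exp(-a * (s - b)))`: a
#' logistic in `s`, dampened by the multiplicative factor `0 < h < 1` so
#' that genes of *other* diseases can never compete with the query's own
#' genes (which get weight exactly 1 > h).
#'
#' @param h dampening factor in (0, 1); the supremum of foreign-gene
#'   weights.
#' @param a logistic slope, > 0 (per similarity nat).
#' @param b logistic midpoint, in similarity units; `NA` means "use the
#'   median of the query's non-zero similarities", resolved per query at
#'   seed-building time.
#' @return object of class `sigmoid_params`.
#' @export
sigmoid_params <- function(h = 0.5, a = 1, b = NA_real_) {
  stopifnot(is.numeric(h), h > 0, h < 1, is.numeric(a), a > 0)
  structure(list(h = h, a = a, b = as.numeric(b)), class = "sigmoid_params")
}

#' Dampened sigmoid rescaling of a phenotype similarity
#'
#' @param s similarity value(s), >= 0.
#' @param params a [sigmoid_params]; `b` must be resolved (non-NA) here.
#' @return weight(s) in `(0, h)`, strictly increasing in `s`.
#' @export
sigmoid_weight <- function(s, params) {
  stopifnot(inherits(params, "sigmoid_params"))
  if (is.na(params$b))
    stop("sigmoid midpoint b unresolved; supply b or build via build_qws()")
  params$h / (1 + exp(-params$a * (s - params$b)))
}

#' Build the Query Weight Set (seed vector) for a disease
#'
#' For each gene of the network: weight 1 if the gene is a known gene of
#' the query disease; otherwise, if the gene is associated with other
#' diseases, the sigmoid-rescaled *highest* phenotype similarity between
#' the query and those diseases; otherwise 0. Associated genes missing
#' from the network are dropped with a warning. An uncharted query (no
#' known genes) is seeded purely from similarity.
#'
#' @param query query disease id.
#' @param assoc a [disease_gene_map].
#' @param sim a [similarity_source] (or `NULL` for a pure own-gene seed).
#' @param net an [interactome].
#' @param params a [sigmoid_params].
#' @return object of class `qws`: list with `Y` (named numeric over
#'   `net$genes`, values in \[0, 1\]), `query`, `provenance` (factor per
#'   gene: `own-gene`, `similarity`, `zero`), `params` (with `b`
#'   resolved), `own_genes` (query genes present in the network).
#' @export
build_qws <- function(query, assoc, sim, net, params = sigmoid_params()) {
  stopifnot(inherits(net, "interactome"), inherits(params, "sigmoid_params"))
  assoc <- as_disease_gene_map(assoc)
  own <- assoc$genes[[query]]
  if (is.null(own)) own <- character(0)

  sims <- if (!is.null(sim)) sim_row(sim, query) else NULL
  if (length(own) == 0 && is.null(sims))
    stop("cannot seed query '", query,
         "': no known genes and no similarity data")

  genes <- net$genes
  Y <- stats::setNames(numeric(length(genes)), genes)
  provenance <- rep("zero", length(genes))

  # similarity-derived background: per gene, the highest similarity over
  # the other diseases it is associated with
  if (!is.null(sims)) {
    others <- setdiff(intersect(names(assoc$genes), names(sims)), query)
    if (length(others) > 0) {
      d_of_pair <- rep(others, lengths(assoc$genes[others]))
      g_of_pair <- unlist(assoc$genes[others], use.names = FALSE)
      s_of_pair <- sims[d_of_pair]
      best <- tapply(s_of_pair, g_of_pair, max)
      missing_genes <- setdiff(names(best), genes)
      if (length(missing_genes) > 0) {
        warning(length(missing_genes), " associated gene(s) absent from the ",
                "network dropped (e.g. ", missing_genes[1], ")")
        best <- best[setdiff(names(best), missing_genes)]
      }
      if (length(best) > 0) {
        if (is.na(params$b)) {
          nz <- sims[sims > 0 & names(sims) != query]
          params$b <- if (length(nz) > 0) stats::median(nz) else 0
        }
        Y[names(best)] <- sigmoid_weight(as.numeric(best), params)
        provenance[match(names(best), genes)] <- "similarity"
      }
    }
  }
  if (is.na(params$b)) params$b <- 0  # no background: midpoint irrelevant

  own_in <- intersect(own, genes)
  if (length(own_in) < length(own))
    warning(length(own) - length(own_in), " known gene(s) of '", query,
            "' absent from the network dropped (e.g. ",
            setdiff(own, own_in)[1], ")")
  Y[own_in] <- 1
  provenance[match(own_in, genes)] <- "own-gene"

  structure(list(Y = Y, query = query,
                 provenance = factor(provenance,
                                     levels = c("own-gene", "similarity",
                                                "zero")),
                 params = params, own_genes = own_in),
            class = "qws")
}

#' Export a QWS as TSV (`gene_id<TAB>weight<TAB>provenance`)
#' @param q a [qws].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qws <- function(q, path) {
  stopifnot(inherits(q, "qws"))
  utils::write.table(
    data.frame(gene_id = names(q$Y), weight = q$Y,
               provenance = as.character(q$provenance)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Fit seed and diffusion parameters by grid search
#'
#' Deterministic grid search over `(h, a, b, alpha)` maximizing the mean
#' leave-one-out recall@`k` on a training set of charted diseases. Ties
#' are broken towards the lexicographically smallest `(h, a, b, alpha)`
#' tuple, so the result is reproducible for any grid ordering.
#'
#' @param train a [disease_gene_map] of training diseases (>= 2 charted).
#' @param sim a [similarity_source].
#' @param net an [interactome].
#' @param grid data.frame with columns `h`, `a`, `b`, `alpha`, one row per
#'   candidate point.
#' @param k recall cutoff used as the objective (default 100).
#' @return list with `params` ([sigmoid_params]), `alpha`, and `scores`
#'   (the grid with an extra `score` column).
#' @export
fit_sigmoid_params <- function(train, sim, net, grid, k = 100) {
  train <- as_disease_gene_map(train)
  if (is.null(grid) || nrow(grid) == 0) stop("empty parameter grid")
  stopifnot(all(c("h", "a", "b", "alpha") %in% names(grid)))
  n_charted <- sum(lengths(train$genes) >= 2)
  if (n_charted < 1)
    stop("training set has no disease with >= 2 genes; cannot run LOO")

  scores <- vapply(seq_len(nrow(grid)), function(i) {
    res <- evaluate_loo(train, net, sim,
                        params = sigmoid_params(grid$h[i], grid$a[i],
                                                grid$b[i]),
                        diffusion = diffusion_params(alpha = grid$alpha[i]),
                        mode = "charted")
    mean(res$cases$rank <= k, na.rm = TRUE)
  }, numeric(1))

  grid$score <- scores
  ord <- order(-grid$score, grid$h, grid$a, grid$b, grid$alpha)
  best <- grid[ord[1], ]
  list(params = sigmoid_params(best$h, best$a, best$b),
       alpha = best$alpha, scores = grid)
}

#' @export
print.qws <- function(x, ...) {
  tab <- table(x$provenance)
  cat("QWS for '", x$query, "': ", length(x$Y), " genes (",
      tab[["own-gene"]], " own, ", tab[["similarity"]],
      " similarity-derived)\n", sep = "")
  cat("  sigmoid: h=", x$params$h, " a=", x$params$a,
      " b=", signif(x$params$b, 4), "\n", sep = "")
  invisible(x)
}

#' @export
print.sigmoid_params <- function(x, ...) {
  cat("sigmoid_params: h=", x$h, " a=", x$a, " b=", x$b, "\n", sep = "")
  invisible(x)
}
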