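#' Diffusion parameters for the label-consistency propagation
#'
#' The propagation minimizes
#' `C(F) = 1/2 * ( sum_ij W_ij (F_i/sqrt(D_ii) - F_j/sqrt(D_jj))^2
#'                 + mu * sum_i (F_i - Y_i)^2 )`,
#' whose minimizer is `F = beta * (I - alpha * S)^{-1} Y` with
#' `alpha = 1/(1+mu)` and `beta = mu/(1+mu)` (so `alpha + beta = 1`).
#' Either `mu` or `alpha` may be given; the other is derived.
#'
#' @param mu regularization weight of the seed-fidelity term, > 0.
#' @param alpha diffusion strength in (0, 1); `alpha = 1/(1+mu)`.
#' @param solver `"auto"` picks a direct sparse solve for networks up to
#'   `direct_max_n` nodes and the fixed-point iteration above that;
#'   `"closed_form"` / `"iterative"` force one route. Both satisfy the
#'   same accuracy contract, so the choice is invisible to callers.
#' @param tol convergence tolerance of the iterative scheme (sup-norm
#'   distance to the exact minimizer, relative to `1 + max|F|`).
#' @param max_iter iteration cap for the iterative scheme.
#' @param direct_max_n size threshold for the `"auto"` solver choice.
#' @return object of class `diffusion_params` with fields `mu`, `alpha`,
#'   `beta`, `solver`, `tol`, `max_iter`, `direct_max_n`.
#' @export
diffusion_params <- function(mu = NULL, alpha = NULL,
                             solver = c("auto", "closed_form", "iterative"),
                             tol = 1e-10, max_iter = 10000L,
                             direct_max_n = 20000L) {
  solver <- match.arg(solver)
  if (is.null(mu) && is.null(alpha)) alpha <- 0.9
  if (is.null(alpha)) {
    stopifnot(mu > 0)
    alpha <- 1 / (1 + mu)
  } else {
    stopifnot(alpha > 0, alpha < 1)
    mu <- 1 / alpha - 1
  }
  beta <- mu / (1 + mu)
  stopifnot(abs(alpha * (1 + mu) - 1) < 1e-12,
            abs(beta * (1 + mu) - mu) < 1e-12,
            abs(alpha + beta - 1) < 1e-12)
  structure(list(mu = mu, alpha = alpha, beta = beta, solver = solver,
                 tol = tol, max_iter = as.integer(max_iter),
                 direct_max_n = as.integer(direct_max_n)),
            class = "diffusion_params")
}

#' Evaluate the label-consistency cost function
#'
#' Exact evaluation of
#' `C(F) = 1/2 * sum_ij W_ij (F_i/sqrt(D_ii) - F_j/sqrt(D_jj))^2
#'         + mu * sum_i (F_i - Y_i)^2`,
#' where the smoothness sum runs over both orientations of every edge and
#' the leading 1/2 cancels that double count. With this normalization the
#' closed form `F = beta*(I - alpha*S)^{-1} Y` is the exact (unique)
#' minimizer: the gradient is `2*((I - S)F + mu*(F - Y))`. Isolated nodes
#' contribute only through the fidelity term.
#'
#' @param F numeric label vector, length n.
#' @param net an [interactome].
#' @param Y seed vector (numeric length n, or a [qws]).
#' @param mu regularization parameter, > 0.
#' @return the non-negative scalar cost.
#' @export
propagation_cost <- function(F, net, Y, mu) {
  stopifnot(inherits(net, "interactome"))
  if (inherits(Y, "qws")) Y <- Y$Y
  n <- length(net$genes)
  if (length(F) != n || length(Y) != n)
    stop("F and Y must have length n = ", n)
  d <- net$degree
  Fn <- ifelse(d > 0, F / sqrt(d), 0)
  Wt <- methods::as(net$W, "TsparseMatrix")
  smooth <- sum(Wt@x * (Fn[Wt@i + 1L] - Fn[Wt@j + 1L])^2)
  0.5 * smooth + mu * sum((F - Y)^2)
}

#' Propagate a seed vector over the network
#'
#' Computes the minimizer `F = beta * (I - alpha*S)^{-1} Y` of the
#' label-consistency cost, by a direct sparse solve or by the fixed-point
#' iteration `F <- alpha*S*F + beta*Y` (a contraction since
#' `||alpha*S|| <= alpha < 1`). `Y` may be a matrix with one seed vector
#' per column; the linear system is then solved once with multiple
#' right-hand sides, which is how the evaluation protocols batch their
#' queries.
#'
#' @param net an [interactome].
#' @param Y a [qws], a numeric vector aligned to `net$genes`, or a matrix
#'   with n rows (one query per column).
#' @param params a [diffusion_params].
#' @return for vector input, a named numeric vector `F`; for matrix input
#'   a matrix of the same shape. The iterative route attaches an
#'   `"iterations"` attribute.
#' @export
propagate <- function(net, Y, params = diffusion_params()) {
  stopifnot(inherits(net, "interactome"), inherits(params, "diffusion_params"))
  vec_in <- !is.matrix(Y)
  if (inherits(Y, "qws")) Y <- Y$Y
  n <- length(net$genes)
  Ym <- if (vec_in) matrix(as.numeric(Y), ncol = 1) else as.matrix(Y)
  if (nrow(Ym) != n) stop("Y must have length (or row count) n = ", n)

  solver <- params$solver
  if (solver == "auto")
    solver <- if (n <= params$direct_max_n) "closed_form" else "iterative"

  if (solver == "closed_form") {
    A <- Matrix::Diagonal(n) - params$alpha * net$S
    Fm <- as.matrix(Matrix::solve(A, params$beta * Ym))
    iters <- NA_integer_
  } else {
    Fm <- params$beta * Ym  # F_0 = beta*Y: first Neumann term
    bY <- params$beta * Ym
    iters <- 0L
    bound <- Inf
    repeat {
      iters <- iters + 1L
      if (iters > params$max_iter) {
        stop(errorCondition(
          paste0("no convergence after ", params$max_iter,
                 " iterations (error bound ", signif(bound, 3), ")"),
          last = Fm, residual = bound,
          class = "propagation_no_convergence"))
      }
      Fnew <- as.matrix(params$alpha * (net$S %*% Fm) + bY)
      resid <- max(abs(Fnew - Fm))
      Fm <- Fnew
      # contraction bound: ||F_t - F*||_inf <= resid * alpha/(1 - alpha)
      bound <- resid * params$alpha / (1 - params$alpha)
      if (bound <= params$tol * (1 + max(abs(Fm)))) break
    }
  }
  dimnames(Fm) <- list(net$genes, colnames(Ym))
  if (vec_in) {
    out <- stats::setNames(as.numeric(Fm), net$genes)
    if (!is.na(iters)) attr(out, "iterations") <- iters
    out
  } else {
    if (!is.na(iters)) attr(Fm, "iterations") <- iters
    Fm
  }
}

#' Rank genes by diffusion score
#'
#' Sorts genes by decreasing score; ties are broken lexicographically by
#' gene id so rankings are deterministic. Genes in `exclude` (typically
#' the query's remaining known genes during leave-one-out) are removed
#' before ranking.
#'
#' @param F named numeric score vector (output of [propagate]).
#' @param exclude character vector of gene ids to remove from the
#'   candidate list.
#' @param query optional query disease id carried along for bookkeeping.
#' @return object of class `gene_ranking`: list with `genes` (ordered
#'   character), `scores` (numeric, same order), `query`.
#' @export
rank_genes <- function(F, exclude = character(0), query = NA_character_) {
  stopifnot(!is.null(names(F)))
  if (any(!is.finite(F))) stop("non-finite diffusion scores")
  keep <- !(names(F) %in% exclude)
  F <- F[keep]
  ord <- order(-F, names(F), method = "radix")
  structure(list(genes = names(F)[ord], scores = as.numeric(F)[ord],
                 query = query),
            class = "gene_ranking")
}

#' Position of genes within a ranking
#' @param ranking a [gene_ranking].
#' @param genes gene ids.
#' @return integer ranks (1-based); `NA` for genes not in the ranking.
#' @export
gene_rank <- function(ranking, genes) {
  stopifnot(inherits(ranking, "gene_ranking"))
  match(genes, ranking$genes)
}

#' Export a ranking as TSV (`rank<TAB>gene_id<TAB>score`)
#' @param ranking a [gene_ranking].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  stopifnot(inherits(ranking, "gene_ranking"))
  utils::write.table(
    data.frame(rank = seq_along(ranking$genes), gene_id = ranking$genes,
               score = ranking$scores),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' One-call prediction for a query disease
#'
#' Convenience wrapper: build the QWS, propagate, rank.
#'
#' @inheritParams build_qws
#' @param diffusion a [diffusion_params].
#' @param exclude genes removed from the candidate list before ranking
#'   (the query's own seed genes are *kept* unless listed here).
#' @return a [gene_ranking].
#' @export
predict_genes <- function(query, assoc, sim, net,
                          params = sigmoid_params(),
                          diffusion = diffusion_params(),
                          exclude = character(0)) {
  q <- build_qws(query, assoc, sim, net, params)
  F <- propagate(net, q, diffusion)
  rank_genes(F, exclude = exclude, query = query)
}

#' @export
print.diffusion_params <- function(x, ...) {
  cat("diffusion_params: mu=", signif(x$mu, 4), " alpha=", x$alpha,
      " beta=", signif(x$beta, 4), " solver=", x$solver, "\n", sep = "")
  invisible(x)
}

#' @export
print.gene_ranking <- function(x, ...) {
  cat("gene_ranking", if (!is.na(x$query)) paste0(" for '", x$query, "'"),
      ": ", length(x$genes), " candidates; top 5: ",
      paste(utils::head(x$genes, 5), collapse = ", "), "\n", sep = "")
  invisible(x)
}
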