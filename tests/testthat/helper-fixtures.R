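# Shared fixtures, built in code at test time.

# K2: two genes, one unit edge
k2_net <- function() interactome(data.frame(a = "A", b = "B"))

# path A - B - C with unit weights
path3_net <- function() interactome(data.frame(a = c("A", "B"),
                                               b = c("B", "C")))

# Erdos-Renyi fixture plus a ring, so no node is isolated (the edge-sum
# cost is blind to isolated nodes, which follow the seed-retention
# convention instead)
random_net <- function(n, p = 0.25, weighted = FALSE) {
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(ut)) < p
  genes <- sprintf("g%03d", seq_len(n))
  i <- c(ut[keep, 1], seq_len(n))
  j <- c(ut[keep, 2], c(seq_len(n - 1) + 1L, 1L))
  w <- if (weighted) stats::runif(length(i), 0.1, 1) else rep(1, length(i))
  suppressWarnings(  # ER edge may duplicate a ring edge; max-collapse is fine
    interactome(data.frame(a = genes[i], b = genes[j], w = w)))
}

# 6-term toy ontology used by the brute-force similarity oracle:
#        root
#        /  \
#       u    v
#      / \  / \
#     a   b    c      (b has parents u and v: poly-hierarchy)
toy_ontology <- function() {
  ontology(term   = c("u", "v", "a", "b", "b", "c"),
           parent = c("root", "root", "u", "u", "v", "v"))
}

toy_corpus <- function(onto = toy_ontology()) {
  annotation_corpus(
    disease = c("d1", "d1", "d2", "d2", "d3", "d4"),
    term    = c("a",  "b",  "b",  "c",  "c",  "u"),
    onto)
}

# independent brute-force oracle for the most-informative-common-ancestor
# similarity: naive recursive ancestor walk + direct counting, sharing no
# code with the package implementation
oracle_ancestors <- function(term, parent, t) {
  out <- t
  for (p in parent[term == t]) out <- c(out, oracle_ancestors(term, parent, p))
  unique(out)
}

oracle_similarity <- function(term, parent, annotations, d1, d2) {
  diseases <- unique(annotations$disease)
  closures <- lapply(split(annotations$term, annotations$disease),
                     function(ts) unique(unlist(
                       lapply(ts, oracle_ancestors, term = term,
                              parent = parent))))
  cnt <- function(t) sum(vapply(closures, function(cl) t %in% cl, logical(1)))
  ic <- function(t) -log(cnt(t) / length(diseases))
  best <- 0
  for (a in annotations$term[annotations$disease == d1]) {
    for (b in annotations$term[annotations$disease == d2]) {
      common <- intersect(oracle_ancestors(term, parent, a),
                          oracle_ancestors(term, parent, b))
      common <- common[vapply(common, cnt, numeric(1)) > 0]
      if (length(common) > 0) best <- max(best, max(vapply(common, ic,
                                                           numeric(1))))
    }
  }
  best
}

# small planted-module world for protocol tests (kept cheap)
small_world <- function(seed = 42) {
  make_world(m = 4, s = 10, p_in = 0.4, p_out = 0.02,
             diseases_per_module = 3, genes_per_disease = 4,
             n_background = 60, seed = seed)
}

# quadratic-minimization oracle for the propagation: reconstructs the
# Hessian and gradient of the cost purely from cost() evaluations
# (second differences of a quadratic are exact) and solves the normal
# equations -- independent of the propagation code path
oracle_minimize_cost <- function(net, Y, mu, h = 1e-3) {
  n <- length(net$genes)
  C0 <- propagation_cost(numeric(n), net, Y, mu)
  e <- function(i) { v <- numeric(n); v[i] <- h; v }
  Cp <- vapply(seq_len(n), function(i)
    propagation_cost(e(i), net, Y, mu), numeric(1))
  Cm <- vapply(seq_len(n), function(i)
    propagation_cost(-e(i), net, Y, mu), numeric(1))
  g <- (Cp - Cm) / (2 * h)
  H <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in i:n) {
      Cij <- propagation_cost(e(i) + e(j), net, Y, mu)
      H[i, j] <- H[j, i] <- (Cij - Cp[i] - Cp[j] + C0) / h^2
    }
  }
  diag(H) <- (Cp + Cm - 2 * C0) / h^2
  solve(H, -g)
}
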