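test_that("sigmoid weight has the right midpoint, bound and monotonicity", {
  p <- sigmoid_params(h = 0.5, a = 2, b = 1)
  expect_equal(sigmoid_weight(1, p), 0.25)            # s = b -> h/2
  expect_lt(sigmoid_weight(5, p), 0.5)                # sup = h
  expect_lte(sigmoid_weight(1e6, p), 0.5)             # saturates at h < 1
  expect_lt(sigmoid_weight(1e6, p), 1)
  expect_equal(sigmoid_weight(1e3, p), 0.5, tolerance = 1e-12)
  s <- seq(0, 5, by = 0.25)
  expect_true(all(diff(sigmoid_weight(s, p)) > 0))    # strictly increasing
  expect_error(sigmoid_params(h = 1.2), "h")
  expect_error(sigmoid_params(a = -1), "a")
})

qws_fixture <- function() {
  net <- interactome(data.frame(a = c("g1", "g2", "g3", "g4"),
                                b = c("g2", "g3", "g4", "g1")))
  assoc <- disease_gene_map(
    disease = c("q", "d1", "d2", "d2"),
    gene = c("g1", "g2", "g2", "g3"))
  M <- matrix(c(0, 0.2, 0.8,
                0.2, 0, 0.1,
                0.8, 0.1, 0), 3,
              dimnames = list(c("q", "d1", "d2"), c("q", "d1", "d2")))
  list(net = net, assoc = assoc, sim = similarity_source(M))
}

test_that("seed vector follows own-gene / best-similarity / zero rules", {
  fx <- qws_fixture()
  p <- sigmoid_params(h = 0.5, a = 1, b = 0.5)
  q <- build_qws("q", fx$assoc, fx$sim, fx$net, p)
  expect_equal(unname(q$Y["g1"]), 1)                       # own gene
  # g2 belongs to d1 (sim 0.2) and d2 (sim 0.8): highest similarity wins
  expect_equal(unname(q$Y["g2"]), sigmoid_weight(0.8, p))
  expect_equal(unname(q$Y["g3"]), sigmoid_weight(0.8, p))  # d2 only
  expect_equal(unname(q$Y["g4"]), 0)                       # unassociated
  expect_equal(as.character(q$provenance),
               c("own-gene", "similarity", "similarity", "zero"))
})

test_that("own-disease label dominates shared genes and the hierarchy
           1 > h >= foreign weights holds", {
  fx <- qws_fixture()
  # g1 is also a gene of d2 now; own-disease weight must stay 1
  assoc2 <- disease_gene_map(disease = c("q", "d2", "d2"),
                             gene = c("g1", "g1", "g3"))
  p <- sigmoid_params(h = 0.5, a = 1, b = 0.1)
  q <- build_qws("q", assoc2, fx$sim, fx$net, p)
  expect_equal(unname(q$Y["g1"]), 1)
  foreign <- q$Y[q$provenance == "similarity"]
  expect_true(all(foreign <= p$h))
  expect_true(all(foreign < 1))
})

test_that("similarity ordering is preserved in seed weights", {
  fx <- qws_fixture()
  p <- sigmoid_params(h = 0.5, a = 1, b = 0.5)
  q <- build_qws("q", fx$assoc, fx$sim, fx$net, p)
  # d2 (sim .8) gene g3 must outweigh a d1-only (sim .2) gene; rebuild with
  # disjoint single associations to isolate the ordering
  assoc <- disease_gene_map(disease = c("d1", "d2"), gene = c("g2", "g3"))
  q2 <- build_qws("q", assoc, fx$sim, fx$net, p)
  expect_gt(q2$Y[["g3"]], q2$Y[["g2"]])
})

test_that("association file order does not change the seed vector", {
  fx <- qws_fixture()
  p <- sigmoid_params(h = 0.5, a = 1, b = 0.5)
  fwd <- build_qws("q", data.frame(d = c("q", "d1", "d2", "d2"),
                                   g = c("g1", "g2", "g2", "g3")),
                   fx$sim, fx$net, p)
  rev <- build_qws("q", data.frame(d = c("d2", "d2", "d1", "q"),
                                   g = c("g3", "g2", "g2", "g1")),
                   fx$sim, fx$net, p)
  expect_identical(fwd$Y, rev$Y)
})

test_that("uncharted queries seed from similarity; unseedable ones error", {
  fx <- qws_fixture()
  assoc <- disease_gene_map(disease = c("d1", "d2", "d2"),
                            gene = c("g2", "g2", "g3"))
  q <- build_qws("q", assoc, fx$sim, fx$net,
                 sigmoid_params(h = 0.5, a = 1, b = 0.5))
  expect_length(q$own_genes, 0)
  expect_gt(max(q$Y), 0)
  expect_error(build_qws("q", assoc, NULL, fx$net), "cannot seed")
})

test_that("genes absent from the network are dropped with a warning", {
  fx <- qws_fixture()
  assoc <- disease_gene_map(disease = c("q", "d2"),
                            gene = c("ghost1", "ghost2"))
  # both the foreign and the own ghost gene raise their own warning
  expect_warning(expect_warning(
    q <- build_qws("q", assoc, fx$sim, fx$net,
                   sigmoid_params(b = 0.5)),
    "absent from the network"), "absent from the network")
  expect_equal(sum(q$Y), 0)
})

test_that("unresolved midpoint defaults to the median nonzero similarity", {
  fx <- qws_fixture()
  q <- build_qws("q", fx$assoc, fx$sim, fx$net, sigmoid_params())
  expect_equal(q$params$b, stats::median(c(0.2, 0.8)))
})

test_that("QWS export round-trips through TSV", {
  fx <- qws_fixture()
  q <- build_qws("q", fx$assoc, fx$sim, fx$net, sigmoid_params(b = 0.5))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_qws(q, p)
  back <- utils::read.table(p, header = TRUE, sep = "\t")
  expect_equal(setNames(back$weight, back$gene_id), q$Y)
  expect_equal(back$provenance, as.character(q$provenance))
})

test_that("parameter fitting returns the single grid point degenerately
           and breaks score ties lexicographically", {
  w <- small_world(seed = 21)
  grid1 <- data.frame(h = 0.4, a = 1, b = 1, alpha = 0.8)
  fit <- fit_sigmoid_params(w$assoc_t1, w$sim, w$net, grid1)
  expect_equal(fit$params$h, 0.4)
  expect_equal(fit$alpha, 0.8)
  expect_equal(fit$scores$score, fit$scores$score[1])
  # two identical points tie; the lexicographically smaller tuple wins
  grid2 <- rbind(data.frame(h = 0.6, a = 1, b = 1, alpha = 0.8),
                 data.frame(h = 0.4, a = 1, b = 1, alpha = 0.8))
  # force equal scores by using the same (a, b, alpha) and checking h order
  fit2 <- fit_sigmoid_params(w$assoc_t1, w$sim, w$net, grid2)
  if (fit2$scores$score[1] == fit2$scores$score[2]) {
    expect_equal(fit2$params$h, 0.4)
  } else {
    expect_equal(fit2$params$h,
                 grid2$h[which.max(fit2$scores$score)])
  }
  expect_error(fit_sigmoid_params(w$assoc_t1, w$sim, w$net,
                                  grid1[0, ]), "empty")
})

test_that("fitting rewards a dampening factor above the grid minimum when
           similarity is informative", {
  # two disjoint cliques; the query disease has one anchor gene in the big
  # clique and its other gene hidden in the small clique, where a highly
  # similar disease lives. Only the phenotype background can point the
  # diffusion at the right clique, so larger h must win the grid.
  big <- sprintf("a%02d", 1:15)
  small <- sprintf("b%d", 1:5)
  clique <- function(g) t(combn(g, 2))
  edges <- rbind(clique(big), clique(small))
  net <- interactome(data.frame(a = edges[, 1], b = edges[, 2]))
  assoc <- disease_gene_map(disease = c("q", "q", "d", "d"),
                            gene = c("a01", "b1", "b2", "b3"))
  M <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("q", "d"), c("q", "d")))
  sim <- similarity_source(M)
  grid <- expand.grid(h = c(0.05, 0.9), a = 1, b = 1, alpha = 0.9)
  fit <- fit_sigmoid_params(assoc, sim, net, grid, k = 10)
  expect_gt(fit$params$h, min(grid$h))
  expect_gt(fit$scores$score[fit$scores$h == 0.9],
            fit$scores$score[fit$scores$h == 0.05])
})
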