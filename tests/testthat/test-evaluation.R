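test_that("recall@k treats missing ranks as misses and is monotone", {
  r <- recall_at(c(1L, 5L, 150L, NA))
  expect_equal(unname(r), c(0.25, 0.5, 0.5, 0.75))
  expect_true(all(diff(r) >= 0))
})

test_that("normalized AUC anchors at 1 and 0", {
  genes <- sprintf("g%04d", 1:500)
  pos <- genes[1:10]
  expect_equal(normalized_auc(genes, pos), 1.0)             # positives first
  late <- c(genes[11:500], genes[1:10])                     # after 490 > 200
  expect_equal(normalized_auc(late, pos), 0.0)
  expect_error(normalized_auc(genes, character(0)), "positives")
  # positives absent from the ranking count in the denominator
  expect_equal(normalized_auc(genes[1:5], genes[1:10], fp_cap = 10), 0.5)
})

test_that("rank-based AUC shortcut agrees with the explicit walk", {
  set.seed(5)
  for (rep in 1:10) {
    n <- 400; P <- sample(3:30, 1)
    ord <- sample(sprintf("g%03d", 1:n))
    pos <- sample(sprintf("g%03d", 1:n), P)
    walk <- normalized_auc(ord, pos, fp_cap = 50)
    shortcut <- cardigan:::auc_from_positive_ranks(match(pos, ord), P,
                                                   fp_cap = 50)
    expect_equal(shortcut, walk, tolerance = 1e-12)
  }
})

test_that("random baseline matches its closed-form expectations", {
  base <- random_baseline(2000L, 40L, ks = c(1, 10, 100, 200),
                          fp_cap = 200, reps = 400, seed = 9)
  # E[recall@k] = k / n per positive
  for (k in c(10, 100, 200)) {
    x <- base$cases[[paste0("recall@", k)]]
    se <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - k / 2000), 3 * se + 1e-9)
  }
  # E[auc] ~ (fp_cap/(n - P)) / 2
  se <- base$summary$stderr
  expect_lt(abs(base$summary$mean_auc - (200 / (2000 - 40)) / 2),
            3 * se + 1e-9)
  # bit-identical reruns under a fixed seed
  again <- random_baseline(2000L, 40L, ks = c(1, 10, 100, 200),
                           fp_cap = 200, reps = 400, seed = 9)
  expect_identical(base$cases, again$cases)
  # k = n recovers everything
  full <- random_baseline(50L, 5L, ks = 50, reps = 5, seed = 1)
  expect_equal(unname(full$recall), 1)
})

test_that("leave-one-out recovers planted clique genes and never leaks
           the held-out gene into its own seeds", {
  # 2-gene disease inside a tight module; LOO must rank the held-out gene
  # near the top
  w <- small_world(seed = 4)
  res <- evaluate_loo(w$assoc_t1, w$net, w$sim, mode = "charted")
  expect_true(all(diff(recall_at(res$cases$rank)) >= 0))
  for (i in seq_len(nrow(res$cases))) {
    expect_false(res$cases$gene[i] %in% res$details$seed_genes[[i]])
  }
  # held-out genes of dense modules come back quickly
  expect_gt(res$recall[["recall@10"]], 0.5)
})

test_that("loo eligibility rules split charted from uncharted", {
  net <- small_world(seed = 4)$net
  g <- net$genes
  assoc <- disease_gene_map(
    disease = c("two", "two", "one"),
    gene = c(g[1], g[2], g[3]))
  M <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("two", "one"),
                                                c("two", "one")))
  sim <- similarity_source(M)
  ch <- evaluate_loo(assoc, net, sim, mode = "charted")
  expect_setequal(unique(ch$cases$disease), "two")
  un <- evaluate_loo(assoc, net, sim, mode = "uncharted")
  expect_setequal(unique(un$cases$disease), "one")   # 2-gene disease skipped
  expect_error(evaluate_loo(disease_gene_map("d", g[1]), net, sim,
                            mode = "charted"), "no eligible")
})

test_that("remaining known genes are excluded from loo candidates", {
  w <- small_world(seed = 4)
  res <- evaluate_loo(w$assoc_t1, w$net, w$sim, mode = "charted")
  expect_true(all(res$cases$n_candidates ==
                    length(w$net$genes) -
                    lengths(res$details$seed_genes)))
  res2 <- evaluate_loo(w$assoc_t1, w$net, w$sim, mode = "charted",
                       exclude_known = FALSE)
  expect_true(all(res2$cases$n_candidates == length(w$net$genes)))
})

test_that("time-lapse predicts strictly from the earlier snapshot", {
  w <- small_world(seed = 6)
  res <- evaluate_timelapse(w$assoc_t0, w$assoc_t1, w$net, w$sim)
  expect_setequal(unique(res$cases$stratum), c("uncharted", "charted"))
  # purity: the associations visible at prediction time are exactly t0
  t0_pairs <- sort(paste(rep(names(w$assoc_t0$genes),
                             lengths(w$assoc_t0$genes)),
                         unlist(w$assoc_t0$genes), sep = "\t"))
  expect_identical(res$details$seed_assoc, t0_pairs)
  gained <- setdiff(sort(paste(rep(names(w$assoc_t1$genes),
                                   lengths(w$assoc_t1$genes)),
                               unlist(w$assoc_t1$genes), sep = "\t")),
                    t0_pairs)
  expect_false(any(res$details$seed_assoc %in% gained))
  # per-disease and per-case denominators are both reported
  expect_true(all(c("by_case", "by_disease") %in%
                    names(res$summary$uncharted)))
})

test_that("time-lapse bookkeeping: empty test sets, single gains and
           out-of-network genes", {
  w <- small_world(seed = 6)
  expect_error(evaluate_timelapse(w$assoc_t1, w$assoc_t1, w$net, w$sim),
               "empty time-lapse test set")
  # one uncharted disease gaining one in-network gene = one test case
  net <- w$net
  t0 <- disease_gene_map("other", net$genes[1])
  t1 <- disease_gene_map(c("other", "newbie"),
                         c(net$genes[1], net$genes[2]))
  M <- matrix(c(0, 1, 1, 0), 2,
              dimnames = list(c("other", "newbie"), c("other", "newbie")))
  res <- evaluate_timelapse(t0, t1, net, similarity_source(M))
  expect_equal(nrow(res$cases), 1)
  expect_equal(res$cases$stratum, "uncharted")
  # a gained gene outside the network is excluded and counted
  t1b <- disease_gene_map(c("other", "newbie", "newbie"),
                          c(net$genes[1], net$genes[2], "ghost"))
  res2 <- evaluate_timelapse(t0, t1b, net, similarity_source(M))
  expect_equal(nrow(res2$cases), 1)
  expect_equal(res2$details$exclusions[["not_in_network"]], 1L)
  # t0 associations missing from t1 are reported, not dropped
  t0x <- disease_gene_map(c("other", "other"),
                          c(net$genes[1], net$genes[5]))
  expect_warning(res3 <- evaluate_timelapse(t0x, t1, net,
                                            similarity_source(M)),
                 "missing from t1")
  expect_length(res3$details$t0_not_in_t1, 1)
})

test_that("module reconstruction skips degenerate cases and seeds purely
           from phenotype at fraction zero", {
  w <- small_world(seed = 12)
  res <- evaluate_module_reconstruction(
    w$modules, w$assoc_t1, w$net, w$sim,
    kept_fractions = c(0, 0.5, 1), reps = 2, fp_cap = 50, seed = 3)
  # f = 1 keeps everything: nothing to recover, no cases
  expect_false(any(res$cases$fraction == 1))
  # f = 0: pure phenotype seeding still produces predictions
  f0 <- res$cases[res$cases$fraction == 0, ]
  expect_equal(unique(f0$n_kept), 0L)
  expect_true(all(is.finite(f0$auc)))
  expect_true(all(res$cases$auc >= 0 & res$cases$auc <= 1))
  # a module entirely outside the network is skipped with a warning
  mods <- c(w$modules[1], list(offgrid = c("nope1", "nope2")))
  expect_warning(
    evaluate_module_reconstruction(mods, w$assoc_t1, w$net, w$sim,
                                   kept_fractions = 0.5, reps = 1,
                                   seed = 3),
    "outside the network")
})

test_that("module reconstruction is reproducible from its seed and keeps
           ceil(f * size) genes", {
  w <- small_world(seed = 12)
  r1 <- evaluate_module_reconstruction(w$modules[1:3], w$assoc_t1, w$net,
                                       w$sim, kept_fractions = c(0.05, 0.5),
                                       reps = 3, seed = 8)
  r2 <- evaluate_module_reconstruction(w$modules[1:3], w$assoc_t1, w$net,
                                       w$sim, kept_fractions = c(0.05, 0.5),
                                       reps = 3, seed = 8)
  expect_identical(r1$cases, r2$cases)
  sz <- lengths(w$modules[1:3])[r1$cases$disease]
  expect_equal(r1$cases$n_kept,
               as.integer(ceiling(r1$cases$fraction * sz)))
})

test_that("per-case records reproduce the aggregate recall when
           re-read from the exported file", {
  w <- small_world(seed = 4)
  res <- evaluate_loo(w$assoc_t1, w$net, w$sim, mode = "charted")
  p <- withr::local_tempfile(fileext = ".tsv")
  write_evaluation_cases(res, p)
  back <- utils::read.table(p, header = TRUE, sep = "\t")
  expect_equal(recall_at(back$rank), res$recall)
})
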