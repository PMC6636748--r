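DEFAULT_KS <- c(1L, 10L, 100L, 200L)

#' Recall at k from a vector of test-case ranks
#'
#' Fraction of test cases whose recovered gene sits within the top `k`
#' of its ranking; `NA` ranks (gene never ranked) count as misses, so
#' recall is non-decreasing in `k`.
#'
#' @param ranks integer ranks, one per test case (`NA` = not found).
#' @param ks cutoffs (default 1, 10, 100, 200).
#' @return named numeric vector `recall@k`.
#' @export
recall_at <- function(ranks, ks = DEFAULT_KS) {
  stats::setNames(vapply(ks, function(k)
    mean(!is.na(ranks) & ranks <= k), numeric(1)),
    paste0("recall@", ks))
}

new_evaluation_result <- function(protocol, cases, recall = NULL,
                                  summary = NULL, details = list()) {
  structure(list(protocol = protocol, cases = cases, recall = recall,
                 summary = summary, details = details),
            class = "evaluation_result")
}

#' Leave-one-out evaluation of disease-gene recovery
#'
#' Removes one disease--gene association at a time, rebuilds the seed
#' vector without it, propagates, and records the rank at which the
#' held-out gene is recovered. `mode = "charted"` uses diseases with >= 2
#' known genes (the query keeps its remaining genes as weight-1 seeds);
#' `mode = "uncharted"` uses single-gene diseases, whose removal yields a
#' synthetic uncharted disease seeded purely by phenotype similarity.
#' In charted mode the query's remaining known genes are excluded from
#' the candidate list before ranking (configurable).
#'
#' @param assoc a [disease_gene_map].
#' @param net an [interactome].
#' @param sim a [similarity_source].
#' @param params a [sigmoid_params].
#' @param diffusion a [diffusion_params].
#' @param mode `"charted"` or `"uncharted"`.
#' @param exclude_known exclude the query's remaining known genes from
#'   the candidates (default TRUE).
#' @param diseases optional subset of query diseases.
#' @return an `evaluation_result` with per-case records (`disease`,
#'   `gene`, `rank`, `n_candidates`), aggregate `recall`, and in
#'   `details$seed_genes` the own-gene seed set actually used per case
#'   (for leakage auditing).
#' @export
evaluate_loo <- function(assoc, net, sim, params = sigmoid_params(),
                         diffusion = diffusion_params(),
                         mode = c("charted", "uncharted"),
                         exclude_known = TRUE, diseases = NULL) {
  mode <- match.arg(mode)
  assoc <- as_disease_gene_map(assoc)
  stopifnot(inherits(net, "interactome"))

  sizes <- lengths(assoc$genes)
  eligible <- if (mode == "charted") names(sizes)[sizes >= 2]
              else names(sizes)[sizes == 1]
  if (!is.null(diseases)) eligible <- intersect(eligible, diseases)

  cases <- list()
  for (d in eligible) {
    for (g in assoc$genes[[d]]) {
      if (!(g %in% net$genes)) next   # held-out gene must be rankable
      cases[[length(cases) + 1]] <- list(disease = d, gene = g)
    }
  }
  if (length(cases) == 0)
    stop("no eligible leave-one-out cases (mode = ", mode, ")")

  # batch: one QWS column per case, a single multi-RHS linear solve
  Ys <- matrix(0, length(net$genes), length(cases))
  seed_genes <- vector("list", length(cases))
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    assoc_i <- drop_association(assoc, cs$disease, cs$gene)
    q <- suppressWarnings(
      build_qws(cs$disease, assoc_i, sim, net, params))
    Ys[, i] <- q$Y
    seed_genes[[i]] <- q$own_genes
  }
  Fm <- propagate(net, Ys, diffusion)

  rec <- data.frame(disease = character(0), gene = character(0),
                    rank = integer(0), n_candidates = integer(0))
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    excl <- if (exclude_known) seed_genes[[i]] else character(0)
    rk <- rank_genes(stats::setNames(Fm[, i], net$genes),
                     exclude = excl, query = cs$disease)
    rec <- rbind(rec, data.frame(
      disease = cs$disease, gene = cs$gene,
      rank = gene_rank(rk, cs$gene), n_candidates = length(rk$genes)))
  }
  new_evaluation_result(
    protocol = paste0("loo-", mode), cases = rec,
    recall = recall_at(rec$rank),
    details = list(seed_genes = seed_genes, mode = mode))
}

#' Time-lapse evaluation: predict later-discovered associations
#'
#' Predictions use only the earlier snapshot `assoc_t0`; test genes are
#' the associations gained by `assoc_t1`, restricted to network genes
#' (out-of-network gains are counted, not silently dropped). Diseases are
#' stratified by their t0 status: `uncharted` (no t0 genes) versus
#' `charted` (gained further genes). Recall is reported both per
#' disease--gene case and per disease (a disease's recall at k is the
#' fraction of its gained genes in the top k).
#'
#' @param assoc_t0,assoc_t1 earlier/later [disease_gene_map] snapshots;
#'   t0 associations are expected to be a subset of t1 (violations are
#'   reported in `details$t0_not_in_t1`, and such genes are never tested).
#' @inheritParams evaluate_loo
#' @return an `evaluation_result`; `cases` has a `stratum` column,
#'   `recall` is computed per case, `summary` holds per-stratum case- and
#'   disease-level recall, `details$exclusions` counts why candidate test
#'   genes were dropped, and `details$seed_assoc` records the exact
#'   association pairs available at prediction time.
#' @export
evaluate_timelapse <- function(assoc_t0, assoc_t1, net, sim,
                               params = sigmoid_params(),
                               diffusion = diffusion_params(),
                               exclude_known = TRUE) {
  assoc_t0 <- as_disease_gene_map(assoc_t0)
  assoc_t1 <- as_disease_gene_map(assoc_t1)
  stopifnot(inherits(net, "interactome"))

  pairs <- function(a) {
    d <- rep(names(a$genes), lengths(a$genes))
    g <- unlist(a$genes, use.names = FALSE)
    paste(d, g, sep = "\t")
  }
  p0 <- pairs(assoc_t0); p1 <- pairs(assoc_t1)
  t0_not_in_t1 <- setdiff(p0, p1)
  if (length(t0_not_in_t1) > 0)
    warning(length(t0_not_in_t1),
            " t0 association(s) missing from t1 (reported, not dropped)")

  excl <- c(not_in_network = 0L, disease_not_similar = 0L)
  cases <- list()
  for (d in names(assoc_t1$genes)) {
    g0 <- assoc_t0$genes[[d]]; if (is.null(g0)) g0 <- character(0)
    gained <- setdiff(assoc_t1$genes[[d]], g0)
    if (length(gained) == 0) next
    stratum <- if (length(g0) == 0) "uncharted" else "charted"
    if (stratum == "uncharted" &&
        (is.null(sim) || !(d %in% sim$diseases))) {
      # no seed of any kind possible at t0
      excl[["disease_not_similar"]] <- excl[["disease_not_similar"]] +
        length(gained)
      next
    }
    for (g in gained) {
      if (!(g %in% net$genes)) {
        excl[["not_in_network"]] <- excl[["not_in_network"]] + 1L
        next
      }
      cases[[length(cases) + 1]] <-
        list(disease = d, gene = g, stratum = stratum)
    }
  }
  if (length(cases) == 0)
    stop("empty time-lapse test set; exclusions: ",
         paste(names(excl), excl, sep = "=", collapse = ", "))

  # one QWS per test disease (the t0 map is shared by its cases)
  qdis <- unique(vapply(cases, `[[`, character(1), "disease"))
  Ys <- matrix(0, length(net$genes), length(qdis),
               dimnames = list(net$genes, qdis))
  own0 <- stats::setNames(vector("list", length(qdis)), qdis)
  for (d in qdis) {
    q <- suppressWarnings(build_qws(d, assoc_t0, sim, net, params))
    Ys[, d] <- q$Y
    own0[[d]] <- q$own_genes
  }
  Fm <- propagate(net, Ys, diffusion)

  rec <- do.call(rbind, lapply(cases, function(cs) {
    ex <- if (exclude_known) own0[[cs$disease]] else character(0)
    rk <- rank_genes(stats::setNames(Fm[, cs$disease], net$genes),
                     exclude = ex, query = cs$disease)
    data.frame(disease = cs$disease, gene = cs$gene, stratum = cs$stratum,
               rank = gene_rank(rk, cs$gene),
               n_candidates = length(rk$genes))
  }))

  per_stratum <- lapply(split(rec, rec$stratum), function(sub) {
    by_disease <- vapply(DEFAULT_KS, function(k) {
      mean(vapply(split(sub, sub$disease), function(dd)
        mean(!is.na(dd$rank) & dd$rank <= k), numeric(1)))
    }, numeric(1))
    list(by_case = recall_at(sub$rank),
         by_disease = stats::setNames(by_disease,
                                      paste0("recall@", DEFAULT_KS)),
         n_cases = nrow(sub), n_diseases = length(unique(sub$disease)))
  })

  new_evaluation_result(
    protocol = "timelapse", cases = rec, recall = recall_at(rec$rank),
    summary = per_stratum,
    details = list(exclusions = excl, t0_not_in_t1 = t0_not_in_t1,
                   seed_assoc = sort(p0), seed_genes = own0))
}

#' Truncated normalized ROC AUC
#'
#' Walks the ranking from the top, tracking the true positive rate
#' (fraction of `positives` recovered) against the count of false
#' positives, stops after `fp_cap` false positives, and reports the area
#' under that step curve divided by `fp_cap`. A perfect ranking (all
#' positives before any negative) scores 1; a ranking whose positives all
#' fall after `fp_cap` negatives scores 0. Positives missing from the
#' ranking count in the denominator but are never recovered.
#'
#' @param ranking a [gene_ranking] (or character vector of ordered
#'   gene ids).
#' @param positives non-empty character vector of true genes.
#' @param fp_cap false-positive truncation point (>= 1), default 200.
#' @return AUC in \[0, 1\].
#' @export
normalized_auc <- function(ranking, positives, fp_cap = 200L) {
  genes <- if (inherits(ranking, "gene_ranking")) ranking$genes else ranking
  stopifnot(fp_cap >= 1)
  positives <- unique(as.character(positives))
  if (length(positives) == 0) stop("no positives supplied")
  is_pos <- genes %in% positives
  P <- length(positives)
  tp <- 0; fp <- 0; area <- 0
  for (flag in is_pos) {
    if (flag) {
      tp <- tp + 1
    } else {
      fp <- fp + 1
      area <- area + tp / P
      if (fp >= fp_cap) break
    }
  }
  if (fp < fp_cap) area <- area + (fp_cap - fp) * tp / P  # curve plateau
  area / fp_cap
}

# closed-form equivalent from positive ranks alone; used for fast
# baselines (rank_i sorted ascending; fp before i-th positive = r_i - i)
auc_from_positive_ranks <- function(pos_ranks, n_positives, fp_cap = 200L) {
  r <- sort(pos_ranks[!is.na(pos_ranks)])
  if (length(r) == 0) return(0)
  fp <- r - seq_along(r)
  sum(pmax(0, fp_cap - fp)) / (n_positives * fp_cap)
}

#' Disease-module reconstruction experiment
#'
#' For each disease module, keeps a random fraction `f` of its genes as
#' known genes of the query (the rest are hidden), predicts with the usual
#' seed-and-propagate procedure (phenotype-similarity background
#' included), and scores the hidden genes with [normalized_auc]. Each
#' (disease, fraction) cell is repeated `reps` times with fresh random
#' kept-gene selections; `f = 0` keeps nothing and seeds purely from
#' phenotype similarity. Kept counts use `ceiling(f * |module|)` so any
#' `f > 0` keeps at least one gene.
#'
#' @param modules named list `disease_id -> character vector` of module
#'   genes (or a 2-column data.frame `disease_id`, `gene_id`). Module ids
#'   must be present in the similarity source to receive a phenotype
#'   background; unmapped modules run without one, with a warning.
#' @param assoc a [disease_gene_map] providing the other diseases'
#'   associations (the query's own entry is replaced by the kept genes).
#' @inheritParams evaluate_loo
#' @param kept_fractions fractions of the module to keep, in \[0, 1\].
#' @param reps random kept-gene selections per (disease, fraction).
#' @param fp_cap truncation for [normalized_auc].
#' @param seed RNG seed; all sampling is reproducible from it.
#' @return an `evaluation_result`: `cases` has one row per
#'   (disease, fraction, rep) with its AUC; `summary` is a data.frame of
#'   per-fraction mean AUC and standard error over all diseases x reps.
#' @export
evaluate_module_reconstruction <- function(modules, assoc, net, sim,
                                           params = sigmoid_params(),
                                           diffusion = diffusion_params(),
                                           kept_fractions = c(0, 0.05, 0.5,
                                                              0.95),
                                           reps = 10L, fp_cap = 200L,
                                           seed = 1L) {
  if (is.data.frame(modules))
    modules <- lapply(split(as.character(modules[[2]]),
                            as.character(modules[[1]])), unique)
  stopifnot(length(modules) > 0, all(kept_fractions >= 0),
            all(kept_fractions <= 1))
  assoc <- as_disease_gene_map(assoc)

  usable <- list()
  for (d in names(modules)) {
    mg <- intersect(modules[[d]], net$genes)
    if (length(mg) == 0) {
      warning("module '", d, "' entirely outside the network; skipped")
      next
    }
    if (!is.null(sim) && !(d %in% sim$diseases))
      warning("module '", d, "' absent from the similarity source; ",
              "running without phenotype background")
    usable[[d]] <- sort(mg)
  }
  if (length(usable) == 0) stop("no module overlaps the network")

  # draw every kept-set up front in a fixed order, so results do not
  # depend on how the propagation work is batched
  set.seed(seed)
  plan <- list()
  for (d in names(usable)) {
    for (f in kept_fractions) {
      n_keep <- if (f == 0) 0L else as.integer(ceiling(f * length(usable[[d]])))
      for (r in seq_len(reps)) {
        kept <- sort(sample(usable[[d]], n_keep))
        hidden <- setdiff(usable[[d]], kept)
        if (length(hidden) == 0) next   # f = 1: nothing to recover
        plan[[length(plan) + 1]] <-
          list(disease = d, fraction = f, rep = r,
               kept = kept, hidden = hidden)
      }
    }
  }
  if (length(plan) == 0) stop("no reconstruction case has hidden genes")

  Ys <- matrix(0, length(net$genes), length(plan))
  for (i in seq_along(plan)) {
    pl <- plan[[i]]
    assoc_i <- assoc
    assoc_i$genes[[pl$disease]] <- pl$kept
    q <- suppressWarnings(
      build_qws(pl$disease, assoc_i, sim, net, params))
    Ys[, i] <- q$Y
  }
  Fm <- propagate(net, Ys, diffusion)

  rec <- do.call(rbind, lapply(seq_along(plan), function(i) {
    pl <- plan[[i]]
    rk <- rank_genes(stats::setNames(Fm[, i], net$genes),
                     exclude = pl$kept, query = pl$disease)
    data.frame(disease = pl$disease, fraction = pl$fraction, rep = pl$rep,
               n_kept = length(pl$kept), n_hidden = length(pl$hidden),
               auc = normalized_auc(rk, pl$hidden, fp_cap = fp_cap))
  }))

  summ <- do.call(rbind, lapply(split(rec, rec$fraction), function(sub)
    data.frame(fraction = sub$fraction[1], n = nrow(sub),
               mean_auc = mean(sub$auc),
               stderr = stats::sd(sub$auc) / sqrt(nrow(sub)))))
  summ <- summ[order(summ$fraction), ]
  rownames(summ) <- NULL

  new_evaluation_result(protocol = "module-reconstruction", cases = rec,
                        summary = summ,
                        details = list(fp_cap = fp_cap, reps = reps,
                                       seed = seed))
}

#' Random-ranking baseline
#'
#' Scores uniformly random gene orderings with the same metrics as the
#' method: recall at k for a set of true genes, and truncated normalized
#' AUC. Seeded and reproducible.
#'
#' @param net an [interactome] (its gene universe is the candidate set),
#'   or directly an integer number of candidates.
#' @param positives character vector of true genes (or an integer count,
#'   in which case positions are sampled abstractly).
#' @param ks recall cutoffs.
#' @param fp_cap truncation for the AUC.
#' @param reps number of random orderings.
#' @param seed RNG seed.
#' @return an `evaluation_result`: `cases` holds per-rep recall@k and
#'   AUC; `recall` the mean recall; `summary` mean/stderr of the AUC.
#' @export
random_baseline <- function(net, positives, ks = DEFAULT_KS, fp_cap = 200L,
                            reps = 100L, seed = 1L) {
  n <- if (inherits(net, "interactome")) length(net$genes) else as.integer(net)
  P <- if (is.character(positives)) length(unique(positives))
       else as.integer(positives)
  stopifnot(reps >= 1, P >= 1, P <= n)
  set.seed(seed)
  per_rep <- matrix(0, reps, length(ks) + 1,
                    dimnames = list(NULL, c(paste0("recall@", ks), "auc")))
  for (r in seq_len(reps)) {
    pos_ranks <- sort(sample.int(n, P))  # positions of positives in a
    # uniformly random ordering
    per_rep[r, seq_along(ks)] <- vapply(ks, function(k)
      mean(pos_ranks <= k), numeric(1))
    per_rep[r, length(ks) + 1] <-
      auc_from_positive_ranks(pos_ranks, P, fp_cap)
  }
  cases <- as.data.frame(per_rep)
  cases$rep <- seq_len(reps)
  new_evaluation_result(
    protocol = "random-baseline", cases = cases,
    recall = stats::setNames(colMeans(per_rep)[seq_along(ks)],
                             paste0("recall@", ks)),
    summary = data.frame(mean_auc = mean(per_rep[, "auc"]),
                         stderr = stats::sd(per_rep[, "auc"]) / sqrt(reps)),
    details = list(n = n, n_positives = P, seed = seed, fp_cap = fp_cap))
}

#' Export per-case evaluation records as TSV
#' @param result an `evaluation_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_evaluation_cases <- function(result, path) {
  stopifnot(inherits(result, "evaluation_result"))
  utils::write.table(result$cases, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat("evaluation_result [", x$protocol, "]: ", nrow(x$cases),
      " case(s)\n", sep = "")
  if (!is.null(x$recall)) {
    cat("  ", paste(names(x$recall), signif(x$recall, 3),
                    sep = " = ", collapse = ", "), "\n", sep = "")
  }
  if (is.data.frame(x$summary)) {
    print(x$summary)
  }
  invisible(x)
}
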