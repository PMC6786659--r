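# Ranking evaluation: the consistency error CE = #N * (1 - AUC), repeated
# k-fold cross-validation with inner regularization tuning, the four
# cancer-type-specific training regimes, and network diagnostics.

#' Cross-validation configuration
#'
#' @param k Number of outer folds (default 5 pan-cancer; use 2 per disease).
#' @param repeats Number of repeated fold assignments (default 2).
#' @param seed RNG seed for fold assignment.
#' @param c_grid Candidate regularization values; default the 11 half-powers
#'   of two from 2^-2.5 to 2^2.5.
#' @param inner_k Folds for the inner tuning loop (default 5, reduced
#'   automatically when the training set is too small).
#' @param tune Whether to tune C at all; when `FALSE` the smallest grid
#'   value is used everywhere.
#' @return List of class `cv_config`.
#' @export
cv_config <- function(k = 5, repeats = 2, seed = 1,
                      c_grid = 2^((-5:5) / 2), inner_k = 5, tune = TRUE) {
  if (k < 2) stop("k must be at least 2")
  structure(list(k = k, repeats = repeats, seed = seed,
                 c_grid = sort(c_grid), inner_k = inner_k, tune = tune),
            class = "cv_config")
}

#' Seeded partition of items into k folds
#'
#' Items are shuffled under the seed and dealt into `k` folds whose sizes
#' differ by at most one.
#'
#' @param items Character vector to partition.
#' @param k Number of folds.
#' @param seed RNG seed.
#' @return List of `k` character vectors partitioning `items`.
#' @export
split_folds <- function(items, k, seed) {
  if (length(items) < k) stop("fewer items (", length(items),
                              ") than folds (", k, "); use a smaller k")
  shuffled <- with_seed(seed, sample(items))
  fold <- rep(seq_len(k), length.out = length(items))
  unname(split(shuffled, fold))
}

#' ROC/AUC/consistency-error evaluation of a ranking
#'
#' AUC is computed by Mann-Whitney pair counting with ties credited 1/2; the
#' consistency error is `CE = #N * (1 - AUC)`, the mean number of negative
#' (non-driver) genes ranked above the positives.  A perfect ranking has
#' CE = 0 and a random one CE near #N/2.
#'
#' @param ranking A [ranked_genes()] data frame covering all positives and
#'   negatives.
#' @param positives,negatives Disjoint, non-empty gene sets.
#' @return List of class `eval_result` with `auc`, `ce`, `n_negatives`, and
#'   `roc_points` (data frame of fpr/tpr, ties grouped).
#' @export
rank_metrics <- function(ranking, positives, negatives) {
  if (length(positives) == 0 || length(negatives) == 0) {
    stop("positives and negatives must both be non-empty")
  }
  if (length(intersect(positives, negatives)) > 0) {
    stop("positives and negatives must be disjoint")
  }
  scores <- stats::setNames(ranking$score, ranking$gene)
  missing <- setdiff(c(positives, negatives), names(scores))
  if (length(missing) > 0) {
    stop("gene(s) absent from the ranking: ",
         paste(utils::head(missing, 10), collapse = ", "))
  }
  sp <- scores[positives]; sn <- scores[negatives]
  nP <- length(sp); nN <- length(sn)
  r <- rank(c(sp, sn))  # ties averaged -> 1/2 credit in the U statistic
  auc <- (sum(r[seq_len(nP)]) - nP * (nP + 1) / 2) / (nP * nN)
  # ROC points with tied scores grouped
  all_scores <- c(sp, sn)
  is_pos <- c(rep(TRUE, nP), rep(FALSE, nN))
  ord <- order(-all_scores)
  s_ord <- all_scores[ord]
  gid <- cumsum(c(TRUE, s_ord[-1] != s_ord[-length(s_ord)]))
  tp <- cumsum(rowsum(as.numeric(is_pos[ord]), gid)[, 1])
  fp <- cumsum(rowsum(as.numeric(!is_pos[ord]), gid)[, 1])
  roc <- data.frame(fpr = c(0, unname(fp) / nN), tpr = c(0, unname(tp) / nP))
  structure(list(auc = auc, ce = nN * (1 - auc), n_negatives = nN,
                 roc_points = roc),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("AUC = %.4f, CE = %.2f (#N = %d)\n", x$auc, x$ce, x$n_negatives))
  invisible(x)
}

# Fit on the training genes and rank the candidates (by default all
# non-training genes; a candidate that is itself a training gene receives
# its in-kernel score).
.fit_rank <- function(gold_train, kernel, universe, C, candidates = NULL) {
  model <- ocsvm_fit(kernel[gold_train, gold_train, drop = FALSE], C)
  if (is.null(candidates)) candidates <- setdiff(universe, gold_train)
  ocsvm_score(model, kernel[candidates, gold_train, drop = FALSE])
}

#' Inner-loop tuning of the regularization parameter C
#'
#' Splits the training gold standard into inner folds; for every grid value,
#' trains on the inner-train genes and measures the CE of the held-out genes
#' against `universe` minus the full gold set.  Returns the grid member with
#' the smallest mean CE (ties and the degenerate all-equal case resolve to
#' the smallest C).
#'
#' @param gold_train Training driver genes.
#' @param kernel Gene kernel over the universe.
#' @param universe All scoreable genes.
#' @param cfg A [cv_config()]; `inner_k` is reduced to `length(gold_train)`
#'   when necessary.
#' @param negatives Optional explicit negative set; defaults to
#'   `universe` minus `gold_train`.
#' @return Best C (scalar from the grid).
#' @export
tune_C <- function(gold_train, kernel, universe, cfg, negatives = NULL) {
  k <- min(cfg$inner_k, length(gold_train))
  if (k < 2) return(min(cfg$c_grid))
  if (is.null(negatives)) negatives <- setdiff(universe, gold_train)
  folds <- split_folds(gold_train, k, child_seed(cfg$seed, 999L))
  mean_ce <- vapply(cfg$c_grid, function(C) {
    ces <- vapply(seq_len(k), function(f) {
      tr <- setdiff(gold_train, folds[[f]])
      ranking <- .fit_rank(tr, kernel, universe, C)
      neg <- setdiff(negatives, folds[[f]])
      rank_metrics(ranking, folds[[f]], neg)$ce
    }, numeric(1))
    mean(ces)
  }, numeric(1))
  cfg$c_grid[which.min(mean_ce)]  # which.min takes the first (smallest C) tie
}

#' Repeated k-fold cross-validation of pan-cancer driver ranking
#'
#' The gold standard is split into `k` folds (`repeats` times).  Each fold
#' is held out in turn; the model is trained on the remaining gold genes
#' (with inner C tuning), all non-training genes are scored, and the CE of
#' the held-out drivers is measured against the negatives — the universe
#' minus the *entire* gold set, so known drivers never count as negatives.
#'
#' @param gold Gold-standard driver genes (subset of `universe`).
#' @param kernel Gene kernel matrix over `universe`.
#' @param universe All scoreable genes.
#' @param cfg A [cv_config()].
#' @return List of class `cv_result` with `mean_ce`, `mean_auc`,
#'   `n_negatives`, and per-fold data frame `folds`.
#' @export
cross_validate <- function(gold, kernel, universe, cfg = cv_config()) {
  gold <- intersect(universe, gold)
  if (length(gold) < cfg$k) {
    stop("gold standard (", length(gold), ") smaller than k (", cfg$k,
         "); use a smaller k")
  }
  negatives <- setdiff(universe, gold)
  rows <- list()
  for (rep_i in seq_len(cfg$repeats)) {
    folds <- split_folds(gold, cfg$k, child_seed(cfg$seed, rep_i))
    for (f in seq_len(cfg$k)) {
      test_genes <- folds[[f]]
      train_genes <- setdiff(gold, test_genes)
      C <- if (cfg$tune) tune_C(train_genes, kernel, universe, cfg,
                                negatives = negatives)
           else min(cfg$c_grid)
      ranking <- .fit_rank(train_genes, kernel, universe, C)
      m <- rank_metrics(ranking, test_genes, negatives)
      rows[[length(rows) + 1]] <- data.frame(
        rep = rep_i, fold = f, C = C, auc = m$auc, ce = m$ce,
        n_negatives = m$n_negatives)
    }
  }
  folds_df <- do.call(rbind, rows)
  structure(list(mean_ce = mean(folds_df$ce), mean_auc = mean(folds_df$auc),
                 n_negatives = length(negatives), folds = folds_df,
                 cfg = cfg),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cross-validation: mean CE = %.2f, mean AUC = %.4f over %d folds (#N = %d)\n",
              x$mean_ce, x$mean_auc, nrow(x$folds), x$n_negatives))
  invisible(x)
}

# Train one disease fold under a given regime and rank the candidates.
# variant-specific training sets:
#   single_task : the disease's own training drivers, disease-restricted
#                 mutation features
#   aggregation : all other diseases' drivers + the disease's training
#                 drivers, full-table features
#   multitask   : pair kernel with the standard multitask disease kernel
#   multitask2  : pair kernel with the descriptor-based cancer kernel
.disease_fit_rank <- function(variant, d, train_d, test_d, pairs, kernels,
                              dk, C, universe) {
  if (variant %in% c("single_task", "aggregation")) {
    # held-out genes may drive other diseases too; they must stay scoreable,
    # so the aggregation regime drops them from its pooled training set.
    # Candidates exclude only the disease's own training drivers: pooled
    # training genes from other diseases are still scored (in-kernel) and
    # count against the model when they outrank the held-out drivers.
    train_genes <- if (variant == "single_task") train_d else
      setdiff(unique(c(pairs$gene[pairs$disease != d], train_d)), test_d)
    .fit_rank(train_genes, kernels[[variant]], universe, C,
              candidates = setdiff(universe, train_d))
  } else {
    keep <- pairs$disease != d | pairs$gene %in% train_d
    tp <- pairs[keep, , drop = FALSE]
    candidates <- setdiff(universe, train_d)
    fit_score_multitask(kernels$full, dk, tp, d, candidates, C)
  }
}

#' Per-disease cross-validated CE under four training regimes
#'
#' Compares ways of training a disease-specific ranker: `single_task` (only
#' the disease's own drivers and mutation data), `aggregation` (all other
#' diseases' drivers plus half of the disease's own, full mutation data),
#' `multitask` (pair kernel with the standard multitask disease kernel) and
#' `multitask2` (pair kernel with the descriptor-based cancer kernel).  Each
#' disease with at least `min_drivers` known drivers is evaluated by
#' repeated `cfg$k`-fold cross-validation over its drivers; positives are
#' the held-out drivers and negatives all genes outside the disease's own
#' gold list — drivers known only for other diseases count as negatives,
#' so a regime that promotes unrelated diseases' drivers pays for it.
#'
#' @param variants Subset of the four regime names (default all).
#' @param pairs Gold (gene, disease) pairs, columns `gene` and `disease`.
#' @param table A [mutation_table()] with disease labels.
#' @param net A [ppi_network()].
#' @param descriptors Descriptor matrix (needed for `multitask2`).
#' @param cfg A [cv_config()] (use `k = 2` as in the reference protocol).
#' @param mode `"OG"` or `"TSG"` feature mode.
#' @param kernel_choice Gene kernel choice for [build_gene_kernel()].
#' @param min_drivers Minimum drivers for a disease to be evaluated
#'   (default 4).
#' @return Data frame (disease, variant, n_drivers, mean_ce); skipped
#'   diseases are reported in attribute `skipped`.
#' @export
disease_cv <- function(variants = c("single_task", "aggregation",
                                    "multitask", "multitask2"),
                       pairs, table, net, descriptors = NULL,
                       cfg = cv_config(k = 2), mode = c("OG", "TSG"),
                       kernel_choice = "mutation+ppi", min_drivers = 4) {
  mode <- match.arg(mode)
  variants <- match.arg(variants, several.ok = TRUE)
  if (any(pairs$disease == "") || any(table$records$disease == "")) {
    stop("multitask operations require disease labels on every record")
  }
  pairs <- unique(pairs[, c("gene", "disease")])
  universe <- table$universe
  all_gold <- unique(pairs$gene)
  diseases <- sort(unique(pairs$disease))
  counts <- table(pairs$disease)
  eligible <- diseases[counts[diseases] >= min_drivers]
  skipped <- setdiff(diseases, eligible)
  if (length(skipped) > 0) {
    message("skipping disease(s) with fewer than ", min_drivers,
            " drivers: ", paste(skipped, collapse = ", "))
  }
  full_kernel <- build_gene_kernel(table, net, mode, kernel_choice)
  kernels_base <- list(aggregation = full_kernel, full = full_kernel)
  gold_by_disease <- lapply(stats::setNames(diseases, diseases),
                            function(dd) pairs$gene[pairs$disease == dd])
  dks <- list(multitask = disease_kernel("multitask"),
              multitask2 = if ("multitask2" %in% variants)
                disease_kernel("cancer", descriptors) else NULL)
  rows <- list()
  for (d in eligible) {
    gold_d <- sort(pairs$gene[pairs$disease == d])
    kernels <- kernels_base
    if ("single_task" %in% variants) {
      kernels$single_task <- build_gene_kernel(table, net, mode,
                                               kernel_choice,
                                               restrict_to_disease = d)
    }
    # the gold standard of the disease-d task is d's own driver list, so
    # drivers known only for other diseases count as negatives
    negatives <- setdiff(universe, gold_d)
    for (variant in variants) {
      dk <- dks[[variant]]
      ces <- c()
      for (rep_i in seq_len(cfg$repeats)) {
        folds <- split_folds(gold_d, cfg$k,
                             child_seed(cfg$seed, rep_i * 101L))
        for (f in seq_len(cfg$k)) {
          test_d <- folds[[f]]
          train_d <- setdiff(gold_d, test_d)
          C <- if (!cfg$tune) {
            min(cfg$c_grid)
          } else if (variant %in% c("multitask", "multitask2")) {
            # the multitask model's training set is the full pair list
            tp <- pairs[pairs$disease != d | pairs$gene %in% train_d, ,
                        drop = FALSE]
            .tune_C_pairs(tp, dk, kernels$full, universe, gold_by_disease,
                          cfg)
          } else {
            inner_k <- min(cfg$inner_k, length(train_d))
            if (inner_k < 2) min(cfg$c_grid) else {
              inner_folds <- split_folds(train_d, inner_k,
                                         child_seed(cfg$seed, 777L))
              mean_ce <- vapply(cfg$c_grid, function(Cc) {
                mean(vapply(seq_len(inner_k), function(g) {
                  itr <- setdiff(train_d, inner_folds[[g]])
                  if (length(itr) == 0) return(NA_real_)
                  r <- .disease_fit_rank(variant, d, itr, inner_folds[[g]],
                                         pairs, kernels, dk, Cc, universe)
                  rank_metrics(r, inner_folds[[g]], negatives)$ce
                }, numeric(1)), na.rm = TRUE)
              }, numeric(1))
              cfg$c_grid[which.min(mean_ce)]
            }
          }
          ranking <- .disease_fit_rank(variant, d, train_d, test_d, pairs,
                                       kernels, dk, C, universe)
          ces <- c(ces, rank_metrics(ranking, test_d, negatives)$ce)
        }
      }
      rows[[length(rows) + 1]] <- data.frame(
        disease = d, variant = variant, n_drivers = length(gold_d),
        mean_ce = mean(ces), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "skipped") <- skipped
  out
}

# Inner C tuning for a multitask model: 5-fold CV over the *pairs* of the
# training set (the model's actual training items).  For every fold the
# model is retrained without the held-out pairs and the CE of each held-out
# pair's gene is measured for its own disease; C minimizing the mean CE
# wins (ties -> smallest C).
.tune_C_pairs <- function(tp, dk, K_gene, universe, gold_by_disease, cfg) {
  n <- nrow(tp)
  k <- min(cfg$inner_k, n)
  if (k < 2) return(min(cfg$c_grid))
  fold_of <- rep(seq_len(k), length.out = n)
  fold_of <- with_seed(child_seed(cfg$seed, 778L), sample(fold_of))
  ce_by_c <- matrix(NA_real_, length(cfg$c_grid), k)
  for (f in seq_len(k)) {
    held <- tp[fold_of == f, , drop = FALSE]
    train <- tp[fold_of != f, , drop = FALSE]
    if (nrow(train) == 0) next
    K_train <- pair_kernel(K_gene, dk, train)
    for (ci in seq_along(cfg$c_grid)) {
      model <- ocsvm_fit(K_train, cfg$c_grid[ci])
      ces <- c()
      for (dq in unique(held$disease)) {
        pos <- held$gene[held$disease == dq]
        neg <- setdiff(universe, gold_by_disease[[dq]])
        own_train <- train$gene[train$disease == dq]
        cand <- setdiff(universe, own_train)
        Kg <- K_gene[cand, train$gene, drop = FALSE]
        Kd <- disease_kernel_matrix(dk, dq, train$disease)
        scores <- as.vector(Kg %*% (model$alpha * as.vector(Kd)))
        names(scores) <- cand
        ces <- c(ces, rank_metrics(ranked_genes(scores),
                                   intersect(pos, cand), neg)$ce)
      }
      ce_by_c[ci, f] <- mean(ces)
    }
  }
  cfg$c_grid[which.min(rowMeans(ce_by_c, na.rm = TRUE))]
}

#' Spearman correlation between network degree and ranking position
#'
#' For each value `t` in `top_removed`, drops the `t` best-ranked genes and
#' reports the Spearman rank correlation between PPI degree and rank among
#' the remaining network genes.  A slowly decaying correlation indicates
#' that the ranking tracks degree globally, not just for a few top genes.
#'
#' @param ranking A [ranked_genes()] data frame covering the network genes.
#' @param net A [ppi_network()].
#' @param top_removed Integer vector of removal counts.
#' @return Data frame (top_removed, rho).
#' @export
degree_rank_correlation <- function(ranking, net, top_removed = 0) {
  missing <- setdiff(net$nodes, ranking$gene)
  if (length(missing) > 0) {
    stop("ranking does not cover network gene(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  rho <- vapply(top_removed, function(t) {
    if (t >= nrow(ranking)) stop("t = ", t, " >= number of ranked genes")
    rest <- ranking[ranking$rank > t, , drop = FALSE]
    rest <- rest[rest$gene %in% net$nodes, , drop = FALSE]
    stats::cor(net$degree[rest$gene], rest$rank, method = "spearman")
  }, numeric(1))
  data.frame(top_removed = top_removed, rho = rho)
}

#' Degree-binned shuffle benchmark of the network signal
#'
#' Cross-validates the diffusion-kernel ranker on the true network, then on
#' `n_shuffles` degree-binned relabelings of it (the diffusion kernel is
#' permuted, not recomputed).  The returned fraction of shuffles with a
#' worse (larger) CE than the true network measures how much of the network
#' signal exceeds what degree alone explains.
#'
#' @param gold Gold-standard driver genes.
#' @param table A [mutation_table()] (defines the gene universe).
#' @param net A [ppi_network()].
#' @param n_shuffles Number of shuffles (default 100).
#' @param cfg A [cv_config()].
#' @param n_bins Degree bins for the shuffle (default 20).
#' @return List with `true_ce`, numeric vector `shuffle_ce`, and `fraction`.
#' @export
shuffle_benchmark <- function(gold, table, net, n_shuffles = 100,
                              cfg = cv_config(), n_bins = 20) {
  universe <- table$universe
  K_true <- align_items(diffusion_kernel(normalized_laplacian(net)),
                        universe, fill_diag = 1)
  true_ce <- cross_validate(gold, K_true, universe, cfg)$mean_ce
  shuffle_ce <- vapply(seq_len(n_shuffles), function(s) {
    perm <- degree_binned_shuffle(net, n_bins,
                                  seed = child_seed(cfg$seed, s))
    cross_validate(gold, relabel_kernel(K_true, perm), universe,
                   cfg)$mean_ce
  }, numeric(1))
  list(true_ce = true_ce, shuffle_ce = shuffle_ce,
       fraction = if (n_shuffles > 0) mean(shuffle_ce > true_ce)
                  else NA_real_)
}
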