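test_that("consistency error tracks the AUC identity", {
  # perfect separation
  r <- ranked_genes(c(p1 = 3, p2 = 2.5, n1 = 2, n2 = 1, n3 = 0))
  m <- rank_metrics(r, c("p1", "p2"), c("n1", "n2", "n3"))
  expect_equal(m$auc, 1)
  expect_equal(m$ce, 0)

  # fully inverted
  m <- rank_metrics(r, c("n2", "n3"), c("p1", "p2", "n1"))
  expect_equal(m$auc, 0)
  expect_equal(m$ce, m$n_negatives)

  # all-tied scores: half credit
  r <- ranked_genes(c(a = 1, b = 1, c = 1, d = 1))
  m <- rank_metrics(r, c("a", "b"), c("c", "d"))
  expect_equal(m$auc, 0.5)

  expect_error(rank_metrics(r, character(0), "c"), "non-empty")
  expect_error(rank_metrics(r, c("a", "c"), c("c", "d")), "disjoint")
  expect_error(rank_metrics(r, "zz", "c"), "absent")
})

test_that("pair-counting AUC equals trapezoidal ROC area (two oracles)", {
  set.seed(88)
  for (i in 1:20) {
    n <- 30
    scores <- sample(round(rnorm(n), 1))  # deliberate ties
    names(scores) <- sprintf("g%02d", 1:n)
    pos <- sample(names(scores), 8)
    neg <- setdiff(names(scores), pos)
    m <- rank_metrics(ranked_genes(scores), pos, neg)
    trap <- with(m$roc_points,
                 sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2))
    expect_equal(m$auc, trap, tolerance = 1e-9)
    expect_equal(m$ce, m$n_negatives * (1 - m$auc), tolerance = 1e-9)
    expect_true(all(diff(m$roc_points$fpr) >= 0))
    expect_true(all(diff(m$roc_points$tpr) >= 0))
    expect_true(m$ce >= 0 && m$ce <= m$n_negatives)
  }
})

test_that("random rankings give CE near #N / 2", {
  set.seed(11)
  ces <- replicate(40, {
    scores <- rnorm(120)
    names(scores) <- sprintf("g%03d", 1:120)
    pos <- sample(names(scores), 20)
    rank_metrics(ranked_genes(scores), pos, setdiff(names(scores), pos))$ce
  })
  expect_lt(abs(mean(ces) - 50), 2 * sd(ces) / sqrt(length(ces)) + 3)
})

test_that("fold splitting partitions with near-equal sizes, seeded", {
  items <- sprintf("g%02d", 1:13)
  folds <- split_folds(items, 5, seed = 3)
  expect_setequal(unlist(folds), items)
  expect_equal(sum(lengths(folds)), 13)
  expect_lte(diff(range(lengths(folds))), 1)
  expect_identical(folds, split_folds(items, 5, seed = 3))
  expect_false(identical(folds, split_folds(items, 5, seed = 4)))
  expect_error(split_folds(items, 20, seed = 1), "smaller k")
})

test_that("cv_config exposes the 11-value half-power C grid", {
  cfg <- cv_config()
  expect_length(cfg$c_grid, 11)
  expect_equal(min(cfg$c_grid), 2^(-2.5))
  expect_equal(max(cfg$c_grid), 2^(2.5))
  expect_error(cv_config(k = 1), "at least 2")
})

test_that("tune_C returns a grid member, smallest on degenerate ties", {
  # identity kernel: candidates score 0 for every C, all CE equal
  genes <- sprintf("g%02d", 1:30)
  K <- diag(30); dimnames(K) <- list(genes, genes)
  cfg <- cv_config(seed = 1)
  best <- tune_C(genes[1:10], K, genes, cfg)
  expect_true(best %in% cfg$c_grid)
  expect_equal(best, min(cfg$c_grid))
})

test_that("cross_validate separates an oracle kernel perfectly", {
  genes <- sprintf("g%02d", 1:30)
  gold <- genes[1:10]
  # block kernel: gold genes mutually similar, everything else dissimilar
  K <- diag(30) * 0.5
  dimnames(K) <- list(genes, genes)
  K[gold, gold] <- K[gold, gold] + 1
  res <- cross_validate(gold, K, genes, cv_config(k = 5, repeats = 2,
                                                  seed = 1))
  expect_equal(res$mean_ce, 0)
  expect_equal(res$mean_auc, 1)
  expect_identical(nrow(res$folds), 10L)
  # leave-one-out when k = |gold|
  res_loo <- cross_validate(gold, K, genes,
                            cv_config(k = 10, repeats = 1, seed = 1,
                                      tune = FALSE))
  expect_identical(nrow(res_loo$folds), 10L)
  expect_error(cross_validate(gold[1:3], K, genes, cv_config(k = 5)),
               "smaller k")
})

test_that("cross_validate is reproducible and seed-sensitive", {
  set.seed(2)
  genes <- sprintf("g%02d", 1:40)
  K <- random_psd_kernel(40, seed = 19)
  dimnames(K) <- list(genes, genes)
  gold <- genes[1:12]
  cfg <- cv_config(k = 4, repeats = 2, seed = 5, tune = FALSE)
  r1 <- cross_validate(gold, K, genes, cfg)
  r2 <- cross_validate(gold, K, genes, cfg)
  expect_identical(r1, r2)
  r3 <- cross_validate(gold, K, genes,
                       cv_config(k = 4, repeats = 2, seed = 6, tune = FALSE))
  expect_false(identical(r1$folds$ce, r3$folds$ce))
})

test_that("degree-rank correlation matches a rank-then-Pearson oracle", {
  net <- random_network(25, p = 0.25, seed = 6)
  set.seed(10)
  scores <- rnorm(25)
  names(scores) <- net$nodes
  ranking <- ranked_genes(scores)
  res <- degree_rank_correlation(ranking, net, top_removed = c(0, 3, 7))
  for (i in seq_len(nrow(res))) {
    t <- res$top_removed[i]
    rest <- ranking[ranking$rank > t, ]
    oracle <- stats::cor(rank(net$degree[rest$gene]), rank(rest$rank))
    expect_equal(res$rho[i], oracle, tolerance = 1e-9)
  }
  # ranking identical to the degree ordering: |rho| near 1 (degree ties
  # are broken arbitrarily by the jitter, so exact 1 is not attainable)
  by_deg <- ranked_genes(net$degree + stats::runif(25, 0, 1e-4))
  res1 <- degree_rank_correlation(by_deg, net, 0)
  expect_gt(abs(res1$rho), 0.95)
  expect_error(degree_rank_correlation(ranking, net, 25), ">=")
})

test_that("shuffle benchmark with zero shuffles returns an empty result", {
  sim <- synth_generate(synth_config(n_genes = 60, n_samples = 30,
                                     n_drivers = 8, seed = 2))
  res <- shuffle_benchmark(sim$truth$tsg_all, sim$table, sim$net,
                           n_shuffles = 0,
                           cfg = cv_config(k = 4, repeats = 1, seed = 2,
                                           tune = FALSE))
  expect_length(res$shuffle_ce, 0)
  expect_true(is.na(res$fraction))
  expect_true(is.finite(res$true_ce))
})

test_that("one-disease input: multitask equals single_task fold for fold", {
  sim <- synth_generate(synth_config(n_genes = 80, n_samples = 40,
                                     n_drivers = 8, seed = 5))
  pairs <- data.frame(gene = sim$truth$tsg_all, disease = "PAN",
                      stringsAsFactors = FALSE)
  cfg <- cv_config(k = 2, repeats = 1, seed = 3, tune = FALSE)
  res <- disease_cv(c("single_task", "multitask"), pairs, sim$table,
                    sim$net, cfg = cfg, mode = "TSG")
  ce <- res$mean_ce[match(c("single_task", "multitask"), res$variant)]
  expect_equal(ce[1], ce[2], tolerance = 1e-9)
})

test_that("disease_cv skips diseases below the driver minimum", {
  sim <- synth_generate(synth_config(n_genes = 100, n_samples = 60,
                                     n_drivers = 10, n_diseases = 2,
                                     drivers_per_disease = 4, seed = 9))
  # force D02 below the minimum by keeping only 2 of its pairs
  pairs <- sim$pairs$tsg
  keep_d2 <- utils::head(which(pairs$disease == "D02"), 2)
  pairs <- pairs[pairs$disease == "D01" |
                   seq_len(nrow(pairs)) %in% keep_d2, ]
  cfg <- cv_config(k = 2, repeats = 1, seed = 1, tune = FALSE)
  expect_message(
    res <- disease_cv("aggregation", pairs, sim$table, sim$net,
                      cfg = cfg, mode = "TSG"),
    "skipping")
  expect_identical(unique(res$disease), "D01")
  expect_identical(attr(res, "skipped"), "D02")
})
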