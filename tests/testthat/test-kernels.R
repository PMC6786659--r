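test_that("mutation kernel is the feature inner product", {
  f <- structure(data.frame(gene = c("g1", "g2"),
                            a = c(1, 0), b = c(2, 1), c = c(0, 1)),
                 class = c("gene_features", "data.frame"))
  K <- mutation_kernel(f, standardize = FALSE)
  expect_equal(K["g1", "g2"], 2)
  expect_equal(K["g1", "g1"], 5)
  # identical feature vectors give identical entries
  f2 <- f; f2[2, -1] <- f2[1, -1]
  K2 <- mutation_kernel(f2, standardize = FALSE)
  expect_equal(K2["g1", "g2"], K2["g1", "g1"])
  expect_equal(K2["g2", "g2"], K2["g1", "g1"])
})

test_that("mutation kernel rank is at most 3 and PSD", {
  set.seed(21)
  f <- structure(data.frame(gene = sprintf("g%02d", 1:12),
                            a = rpois(12, 3), b = rpois(12, 1),
                            c = runif(12)),
                 class = c("gene_features", "data.frame"))
  for (std in c(TRUE, FALSE)) {
    K <- mutation_kernel(f, standardize = std)
    expect_lte(qr(K)$rank, 3)
    expect_gte(min_rel_eigen(K), -1e-8)
  }
})

test_that("zero-variance feature columns are centered with a warning", {
  f <- structure(data.frame(gene = c("a", "b"), x = c(1, 2), y = c(3, 3),
                            z = c(0, 1)),
                 class = c("gene_features", "data.frame"))
  expect_warning(K <- mutation_kernel(f, standardize = TRUE), "y")
  expect_gte(min_rel_eigen(K), -1e-8)
})

test_that("normalized Laplacian matches the textbook cases", {
  net <- ppi_network(rbind(c("A", "B")))
  L <- normalized_laplacian(net)
  expect_equal(unname(L), rbind(c(1, -1), c(-1, 1)))

  # isolated node convention: all-zero row and column
  net <- ppi_network(rbind(c("A", "B")), nodes = "C")
  L <- normalized_laplacian(net)
  expect_equal(unname(L["C", ]), c(0, 0, 0))
  expect_equal(unname(L[, "C"]), c(0, 0, 0))

  net <- ppi_network(rbind(c("A", "B"), c("B", "C")))
  L <- normalized_laplacian(net)
  expect_equal(L["A", "B"], -1 / sqrt(2))
  ev <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev >= -1e-12 & ev <= 2 + 1e-12))
})

test_that("diffusion kernel matches closed form and series oracle", {
  # two-node closed form: eigenvalues 0 and 2
  K <- diffusion_kernel(normalized_laplacian(ppi_network(rbind(c("A", "B")))))
  expect_equal(K["A", "A"], (1 + exp(-2)) / 2, tolerance = 1e-12)
  expect_equal(K["A", "B"], (1 - exp(-2)) / 2, tolerance = 1e-12)

  # empty graph: exp(0) = I
  K0 <- diffusion_kernel(normalized_laplacian(
    ppi_network(matrix(character(0), ncol = 2), nodes = c("x", "y", "z"))))
  expect_equal(unname(K0), diag(3))

  # truncated-series oracle on random graphs
  for (s in 1:5) {
    net <- random_network(sample(5:20, 1), p = 0.25, seed = s)
    L <- normalized_laplacian(net)
    expect_equal(diffusion_kernel(L), series_expm_neg(L), tolerance = 1e-8)
  }
})

test_that("diffusion kernel structure: components, isolated nodes, PSD", {
  # two components + an isolated node
  net <- ppi_network(rbind(c("A", "B"), c("B", "C"), c("X", "Y")),
                     nodes = "Z")
  K <- diffusion_kernel(normalized_laplacian(net))
  expect_gte(min_rel_eigen(K), -1e-8)
  expect_true(all(K[c("A", "B", "C"), c("A", "B", "C")] > 0))
  expect_lt(max(abs(K[c("A", "B", "C"), c("X", "Y", "Z")])), 1e-12)
  expect_equal(K["Z", "Z"], 1)

  # permutation equivariance: relabeling commutes with the kernel
  perm <- c(A = "C", B = "A", C = "B", X = "X", Y = "Y", Z = "Z")
  net2 <- ppi_network(cbind(perm[net$edges[, 1]], perm[net$edges[, 2]]),
                      nodes = "Z")
  K2 <- diffusion_kernel(normalized_laplacian(net2))
  for (u in names(perm)) for (v in names(perm)) {
    expect_equal(K2[perm[[u]], perm[[v]]], K[u, v], tolerance = 1e-12)
  }
})

test_that("degree kernel is the rank-one degree outer product", {
  net <- ppi_network(rbind(c("A", "B"), c("B", "C")))
  K <- degree_kernel(net)
  expect_equal(unname(K), rbind(c(1, 2, 1), c(2, 4, 2), c(1, 2, 1)))
  net <- ppi_network(rbind(c("A", "B")), nodes = "C")
  K <- degree_kernel(net)
  expect_equal(unname(K["C", ]), c(0, 0, 0))
  # all 2x2 minors vanish
  K <- degree_kernel(random_network(8, p = 0.4, seed = 3))
  idx <- t(combn(nrow(K), 2))
  for (r in sample(nrow(idx), 10)) {
    i <- idx[r, 1]; j <- idx[r, 2]
    expect_equal(K[i, i] * K[j, j] - K[i, j] * K[j, i], 0)
  }
})

test_that("integrated kernel averages entrywise and preserves PSD", {
  K <- random_psd_kernel(4, seed = 5)
  expect_equal(integrated_kernel(K, K), K)
  I4 <- diag(4); dimnames(I4) <- dimnames(K)
  Z <- 0 * K
  expect_equal(unname(integrated_kernel(I4, Z)), diag(4) / 2)
  K2 <- random_psd_kernel(4, seed = 6)
  expect_gte(min_rel_eigen(integrated_kernel(K, K2)), -1e-8)
  K3 <- random_psd_kernel(3, seed = 7)
  expect_error(integrated_kernel(K, K3), "d")  # names the missing item
})

test_that("align_items extends kernels with the isolated convention", {
  net <- ppi_network(rbind(c("A", "B")))
  K <- diffusion_kernel(normalized_laplacian(net))
  Ka <- align_items(K, c("A", "B", "C"), fill_diag = 1)
  expect_equal(unname(Ka["C", ]), c(0, 0, 1))
  expect_equal(Ka[c("A", "B"), c("A", "B")], K)
  # idempotent and PSD-preserving
  expect_identical(align_items(Ka, c("A", "B", "C"), fill_diag = 1), Ka)
  expect_gte(min_rel_eigen(Ka), -1e-8)
  expect_error(align_items(Ka, c("A", "B"), fill_diag = 1), "outside")
})

test_that("degree-binned shuffle preserves bin degrees and is seeded", {
  net <- random_network(30, p = 0.15, seed = 9)
  perm <- degree_binned_shuffle(net, n_bins = 5, seed = 42)
  expect_setequal(names(perm), net$nodes)
  expect_setequal(unname(perm), net$nodes)
  # within-bin permutation: every node keeps (approximately) its own degree
  # bin, so the multiset of degrees in each bin is unchanged
  ord <- order(-net$degree[net$nodes], net$nodes)
  sorted <- net$nodes[ord]
  bins <- split(sorted, rep(1:5, each = 6))
  for (b in bins) {
    expect_setequal(unname(perm[b]), b)
  }
  # identity when every bin is a singleton
  id_perm <- degree_binned_shuffle(net, n_bins = 30, seed = 1)
  expect_identical(unname(id_perm[net$nodes]), net$nodes)
  # seeded reproducibility
  expect_identical(perm, degree_binned_shuffle(net, n_bins = 5, seed = 42))
  expect_false(identical(perm, degree_binned_shuffle(net, 5, seed = 43)))
  expect_error(degree_binned_shuffle(net, n_bins = 31), "exceeds")
})

test_that("relabel_kernel reproduces the kernel of the relabeled graph", {
  net <- random_network(12, p = 0.3, seed = 13)
  K <- diffusion_kernel(normalized_laplacian(net))
  perm <- degree_binned_shuffle(net, n_bins = 3, seed = 8)
  K_perm <- relabel_kernel(K, perm)
  net2 <- ppi_network(cbind(unname(perm[net$edges[, 1]]),
                            unname(perm[net$edges[, 2]])),
                      nodes = net$nodes)
  K2 <- diffusion_kernel(normalized_laplacian(net2))
  expect_equal(K_perm, K2, tolerance = 1e-10)
})

test_that("build_gene_kernel covers all kernel choices over the universe", {
  recs <- mk_records(c("A", "B", "C"), c("missense", "frameshift", "silent"),
                     position = c(1, NA, NA), polyphen = c(0.9, NA, NA))
  tab <- mutation_table(recs, universe = c("A", "B", "C", "D"))
  net <- ppi_network(rbind(c("A", "B")))
  for (choice in c("mutation", "ppi", "degree", "mutation+ppi",
                   "mutation+degree")) {
    K <- suppressWarnings(build_gene_kernel(tab, net, "TSG", choice))
    expect_identical(rownames(K), tab$universe)
    expect_gte(min_rel_eigen(K), -1e-8)
  }
  expect_error(build_gene_kernel(tab, net, "TSG", "rbf"), "unknown kernel")
  expect_error(build_gene_kernel(tab, NULL, "TSG", "ppi"), "requires")
})
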