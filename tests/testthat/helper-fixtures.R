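# Shared fixtures and independent oracles for the test suite.

# Build a mutation record data frame from compact arguments.
mk_records <- function(gene, category, sample = NULL, disease = "",
                       position = NA_real_, polyphen = NA_real_) {
  n <- max(length(gene), length(category), length(sample),
           length(disease), length(position), length(polyphen))
  data.frame(
    gene = rep_len(gene, n),
    sample = rep_len(if (is.null(sample)) sprintf("S%02d", seq_len(n))
                     else sample, n),
    disease = rep_len(disease, n),
    category = rep_len(category, n),
    protein_position = rep_len(position, n),
    polyphen2 = rep_len(polyphen, n),
    stringsAsFactors = FALSE
  )
}

# Write a MAF-dialect TSV for read_mutation_table tests.
write_maf_fixture <- function(path, classification, gene = "TP53",
                              sample = "S01", disease = "", position = "",
                              polyphen = "") {
  n <- length(classification)
  df <- data.frame(
    Hugo_Symbol = rep_len(gene, n),
    Tumor_Sample_Barcode = rep_len(sample, n),
    Disease = rep_len(disease, n),
    Variant_Classification = classification,
    Protein_position = rep_len(position, n),
    PolyPhen2 = rep_len(polyphen, n),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Independent oracle: truncated-series matrix exponential of -L.
series_expm_neg <- function(L, terms = 30) {
  n <- nrow(L)
  acc <- diag(n)
  term <- diag(n)
  for (k in seq_len(terms)) {
    term <- term %*% (-L) / k
    acc <- acc + term
  }
  dimnames(acc) <- dimnames(L)
  acc
}

# Independent oracle: brute-force grid search of the one-class SVM dual
#   min 1/2 a' K a  s.t. sum(a) = 1, 0 <= a_i <= U
# Full grid for n <= 3; coarse-to-fine refinement for n = 4, 5 (a full
# 1e-3 grid over a 4-simplex is not enumerable).
oracle_qp_objective <- function(K, U, step = 1e-3) {
  n <- nrow(K)
  obj <- function(a) 0.5 * sum(a * (K %*% a))
  grid_axes <- function(lo, hi, by) {
    lapply(seq_len(n - 1), function(i) {
      lo_i <- max(0, lo[i]); hi_i <- min(U, hi[i])
      # include the box corner exactly (U may not be a grid multiple)
      unique(c(seq(lo_i, hi_i, by = by), hi_i))
    })
  }
  best_over <- function(axes) {
    pts <- as.matrix(expand.grid(axes))
    last <- 1 - rowSums(pts)
    ok <- last >= -1e-12 & last <= U + 1e-12
    pts <- pts[ok, , drop = FALSE]
    last <- pmin(pmax(last[ok], 0), U)
    A <- cbind(pts, last)
    vals <- 0.5 * rowSums((A %*% K) * A)
    list(obj = min(vals), a = A[which.min(vals), ])
  }
  best <- if (n <= 3) {
    best_over(grid_axes(rep(0, n - 1), rep(U, n - 1), step))
  } else {
    coarse <- best_over(grid_axes(rep(0, n - 1), rep(U, n - 1), 0.02))
    a0 <- coarse$a[seq_len(n - 1)]
    fine <- best_over(grid_axes(a0 - 0.025, a0 + 0.025, step))
    if (fine$obj < coarse$obj) fine else coarse
  }
  # local polish at 10x resolution so the oracle's own discretization error
  # sits well below the comparison tolerance
  a1 <- best$a[seq_len(n - 1)]
  polish <- best_over(grid_axes(a1 - 2 * step, a1 + 2 * step, step / 10))
  min(best$obj, polish$obj)
}

# Random PSD kernel with dimnames.
random_psd_kernel <- function(n, seed) {
  set.seed(seed)
  M <- matrix(rnorm(n * n), n)
  K <- crossprod(M)
  dimnames(K) <- list(letters[seq_len(n)], letters[seq_len(n)])
  K
}

# Random connected-ish undirected graph as a ppi_network.
random_network <- function(n, p = 0.2, seed = 1) {
  set.seed(seed)
  nodes <- sprintf("N%02d", seq_len(n))
  pairs <- t(combn(nodes, 2))
  keep <- runif(nrow(pairs)) < p
  ppi_network(pairs[keep, , drop = FALSE], nodes = nodes)
}

min_rel_eigen <- function(K) {
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  min(ev) / max(abs(ev), 1)
}
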