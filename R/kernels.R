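# Gene kernels: mutation inner-product kernel, diffusion kernel over the PPI
# network, degree kernel, and their combination.  All constructors return
# symmetric numerically-PSD matrices with item dimnames.

#' Validate a kernel matrix
#'
#' Checks symmetry (to 1e-10, relative) and, optionally, positive
#' semidefiniteness (minimum eigenvalue above a small negative tolerance
#' scaled by the largest absolute eigenvalue).
#'
#' @param K Numeric matrix with identical row/column dimnames.
#' @param check_psd Whether to run the (O(n^3)) eigenvalue check.
#' @return `K`, invisibly, on success.
#' @export
check_kernel <- function(K, check_psd = TRUE) {
  if (!is.matrix(K) || nrow(K) != ncol(K)) stop("kernel must be square")
  if (is.null(rownames(K)) || !identical(rownames(K), colnames(K))) {
    stop("kernel must carry identical row/column item names")
  }
  if (anyDuplicated(rownames(K))) stop("kernel items must be unique")
  scale <- max(abs(K), 1)
  if (max(abs(K - t(K))) > 1e-10 * scale) stop("kernel is not symmetric")
  if (check_psd) {
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev), 1)) {
      stop("kernel is not positive semidefinite (min eigenvalue ",
           format(min(ev)), ")")
    }
  }
  invisible(K)
}

#' Mutation kernel: inner product of per-gene feature vectors
#'
#' With `standardize = TRUE` (the default) each feature column is z-scored
#' across the gene universe before the inner product, so that raw counts,
#' which span orders of magnitude, do not dominate when kernels are averaged.
#' A zero-variance column is centered only (with a warning).
#'
#' @param features A `gene_features` table from [og_features()] /
#'   [tsg_features()].
#' @param standardize Z-score feature columns before the inner product.
#' @return Symmetric PSD matrix of rank at most 3, genes as dimnames.
#' @export
mutation_kernel <- function(features, standardize = TRUE) {
  genes <- features$gene
  if (length(genes) < 1) stop("need at least one gene")
  phi <- as.matrix(features[, -1, drop = FALSE])
  rownames(phi) <- genes
  if (standardize) {
    mu <- colMeans(phi)
    sdv <- apply(phi, 2, stats::sd)
    zero_var <- sdv == 0 | is.na(sdv)
    if (any(zero_var)) {
      warning("zero-variance feature column(s) centered only: ",
              paste(colnames(phi)[zero_var], collapse = ", "))
      sdv[zero_var] <- 1
    }
    phi <- sweep(sweep(phi, 2, mu), 2, sdv, "/")
  }
  K <- tcrossprod(phi)
  (K + t(K)) / 2
}

#' Normalized graph Laplacian L = I - D^{-1/2} A D^{-1/2}
#'
#' Isolated nodes get all-zero rows and columns (including the diagonal), so
#' that the diffusion kernel assigns them self-similarity 1 and zero
#' similarity to every other node.
#'
#' @param net A [ppi_network()].
#' @return Symmetric matrix with eigenvalues in `[0, 2]`, nodes as dimnames.
#' @export
normalized_laplacian <- function(net) {
  A <- adjacency_matrix(net)
  d <- rowSums(A)
  inv_sqrt <- ifelse(d > 0, 1 / sqrt(d), 0)
  L <- diag(as.numeric(d > 0), nrow = length(d)) - outer(inv_sqrt, inv_sqrt) * A
  dimnames(L) <- dimnames(A)
  L
}

#' Diffusion kernel: matrix exponential of the negative normalized Laplacian
#'
#' Computed through the symmetric eigendecomposition of L (exact for
#' symmetric matrices): K = V exp(-lambda) V'.  Two genes are similar when
#' they are connected through many short paths in the network.
#'
#' @param L Normalized Laplacian from [normalized_laplacian()].
#' @return Symmetric PSD matrix; isolated nodes have unit diagonal and zero
#'   off-diagonal entries.
#' @export
diffusion_kernel <- function(L) {
  eig <- eigen(L, symmetric = TRUE)
  K <- eig$vectors %*% (exp(-eig$values) * t(eig$vectors))
  K <- (K + t(K)) / 2
  dimnames(K) <- dimnames(L)
  K
}

#' Degree kernel: rank-one outer product of network degrees
#'
#' Control kernel capturing only the number of interaction partners of each
#' gene; used to test whether network performance is explained by degree
#' alone.
#'
#' @param net A [ppi_network()].
#' @return Rank-1 symmetric PSD matrix `K[i, j] = d_i * d_j`.
#' @export
degree_kernel <- function(net) {
  d <- as.numeric(net$degree)
  K <- outer(d, d)
  dimnames(K) <- list(net$nodes, net$nodes)
  K
}

#' Integrated kernel: entrywise average of two kernels
#'
#' @param K1,K2 Kernel matrices over identical item lists (same order).
#' @return `(K1 + K2) / 2`.
#' @export
integrated_kernel <- function(K1, K2) {
  if (!identical(rownames(K1), rownames(K2))) {
    diff <- c(setdiff(rownames(K1), rownames(K2)),
              setdiff(rownames(K2), rownames(K1)))
    if (length(diff) > 0) {
      stop("kernels have mismatched items: ",
           paste(utils::head(diff, 10), collapse = ", "))
    }
    stop("kernel items are ordered differently")
  }
  (K1 + K2) / 2
}

#' Extend a kernel to a larger item universe
#'
#' Items absent from the kernel are added following the isolated-node
#' convention: `fill_diag` on the diagonal (1 for diffusion-type kernels, 0
#' for the degree kernel) and 0 everywhere else.  The result is reordered to
#' `universe` and remains PSD whenever the input is (block-diagonal
#' extension).  Idempotent.
#'
#' @param K Kernel matrix.
#' @param universe Ordered item names; must be a superset of `rownames(K)`.
#' @param fill_diag Diagonal value for the added items.
#' @return Kernel over `universe`.
#' @export
align_items <- function(K, universe, fill_diag = 1) {
  extra <- setdiff(rownames(K), universe)
  if (length(extra) > 0) {
    stop("kernel items outside the universe: ",
         paste(utils::head(extra, 10), collapse = ", "))
  }
  missing <- setdiff(universe, rownames(K))
  n <- length(universe)
  out <- matrix(0, n, n, dimnames = list(universe, universe))
  out[rownames(K), colnames(K)] <- K
  if (length(missing) > 0) {
    out[cbind(missing, missing)] <- fill_diag
  }
  out
}

#' Degree-binned node shuffle of a network
#'
#' Nodes are sorted by decreasing degree (ties broken lexicographically for
#' determinism), cut into `n_bins` contiguous groups whose sizes differ by at
#' most one, and randomly permuted within each group.  The returned
#' relabeling approximately preserves every gene's degree while destroying
#' its neighborhood, which is the null model used to test whether network
#' performance exceeds what degree alone explains.
#'
#' @param net A [ppi_network()].
#' @param n_bins Number of degree bins (default 20).
#' @param seed RNG seed for reproducibility.
#' @return Named character vector mapping each node to its replacement.
#' @export
degree_binned_shuffle <- function(net, n_bins = 20, seed = 1) {
  nodes <- net$nodes
  if (n_bins > length(nodes)) stop("n_bins exceeds the number of nodes")
  ord <- order(-net$degree[nodes], nodes)
  sorted <- nodes[ord]
  sizes <- rep(length(nodes) %/% n_bins, n_bins)
  rem <- length(nodes) %% n_bins
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1
  bin <- rep(seq_len(n_bins), times = sizes)
  perm <- sorted
  with_seed(seed, {
    for (b in seq_len(n_bins)) {
      i <- which(bin == b)
      perm[i] <- sorted[i][sample.int(length(i))]
    }
  })
  names(perm) <- sorted
  perm[nodes]
}

#' Apply a node relabeling to a kernel matrix
#'
#' Returns the kernel of the relabeled graph without recomputing it:
#' `K'[perm[u], perm[v]] = K[u, v]`.  Items not named in `perm` are left in
#' place.
#'
#' @param K Kernel matrix.
#' @param perm Named character vector (old name -> new name), as returned by
#'   [degree_binned_shuffle()].
#' @return Kernel over the same items in the same order.
#' @export
relabel_kernel <- function(K, perm) {
  items <- rownames(K)
  full <- stats::setNames(items, items)
  full[names(perm)] <- perm
  if (anyDuplicated(full)) stop("relabeling is not a permutation")
  new_names <- unname(full[items])
  out <- K
  dimnames(out) <- list(new_names, new_names)
  out[items, items]
}

#' Build a gene kernel from mutation data and a PPI network
#'
#' Convenience constructor covering the kernel choices used throughout:
#' `"mutation"`, `"ppi"`, `"degree"`, `"mutation+ppi"` (the default
#' integrated kernel) and `"mutation+degree"`.  Network kernels are extended
#' to the mutation gene universe with the isolated-node convention.
#'
#' @param table A [mutation_table()].
#' @param net A [ppi_network()] (may be `NULL` for `choice = "mutation"`).
#' @param mode `"OG"` or `"TSG"` feature mode.
#' @param choice Kernel choice string.
#' @param restrict_to_disease Optional disease restriction for the mutation
#'   features.
#' @param standardize Passed to [mutation_kernel()].
#' @return Kernel matrix over the mutation table's gene universe.
#' @export
build_gene_kernel <- function(table, net = NULL, mode = c("OG", "TSG"),
                              choice = "mutation+ppi",
                              restrict_to_disease = NULL,
                              standardize = TRUE) {
  mode <- match.arg(mode)
  choices <- c("mutation", "ppi", "degree", "mutation+ppi", "mutation+degree")
  if (!choice %in% choices) {
    stop("unknown kernel choice '", choice, "'; expected one of: ",
         paste(choices, collapse = ", "))
  }
  universe <- table$universe
  need_net <- choice != "mutation"
  if (need_net && is.null(net)) stop("kernel choice '", choice,
                                     "' requires a PPI network")
  Kmut <- NULL
  if (choice %in% c("mutation", "mutation+ppi", "mutation+degree")) {
    feats <- gene_features(table, mode, restrict_to_disease)
    Kmut <- mutation_kernel(feats, standardize = standardize)
  }
  # network proteins outside the mutation universe are not scoreable;
  # restrict (principal submatrix, PSD-preserving) before aligning
  restrict_align <- function(K, fill_diag) {
    keep <- intersect(rownames(K), universe)
    align_items(K[keep, keep, drop = FALSE], universe, fill_diag)
  }
  Knet <- NULL
  if (choice %in% c("ppi", "mutation+ppi")) {
    Knet <- restrict_align(diffusion_kernel(normalized_laplacian(net)),
                           fill_diag = 1)
  } else if (choice %in% c("degree", "mutation+degree")) {
    Knet <- restrict_align(degree_kernel(net), fill_diag = 0)
  }
  if (is.null(Knet)) return(Kmut)
  if (is.null(Kmut)) return(Knet)
  integrated_kernel(Kmut, Knet)
}
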