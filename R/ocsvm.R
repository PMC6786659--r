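# One-class SVM on a precomputed kernel.  Training solves the dual
#
#     min  1/2 a' K a   s.t.  sum(a) = 1,  0 <= a_i <= U(C),
#
# with U(C) = max(C, 1) / N: for C <= 1 the box forces the fully uniform
# solution a_i = 1/N, and larger C progressively relaxes the box so that
# weight can concentrate on the most mutually-similar training items.  Only
# the ranking of the scoring function f(g) = sum_i a_i K(g_i, g) is ever
# used, so no offset term is needed.  The QP is solved by a deterministic
# SMO-style pairwise coordinate descent (the equality constraint is
# maintained by moving weight between the most violating pair).

#' Train a one-class SVM on a precomputed kernel
#'
#' @param K_train Symmetric PSD kernel matrix restricted to the training
#'   items (dimnames required).
#' @param C Positive regularization value; the box bound is
#'   `max(C, 1) / N`.
#' @param tol KKT violation tolerance, relative to the kernel scale.
#' @param max_iter Iteration cap for the pairwise descent.
#' @return An object of class `ocsvm_model` with elements `items`, `alpha`,
#'   `C`, `kernel_id`, and `objective`.
#' @export
ocsvm_fit <- function(K_train, C, tol = 1e-8, max_iter = NULL) {
  check_kernel(K_train, check_psd = TRUE)
  if (C <= 0) stop("C must be positive")
  n <- nrow(K_train)
  U <- max(C, 1) / n
  alpha <- rep(1 / n, n)
  if (U > 1 / n + 1e-15 && n > 1) {
    K <- unname(K_train)
    if (is.null(max_iter)) max_iter <- 200L * n * n
    scale <- max(abs(diag(K)), 1)
    eps_b <- 1e-12  # slack for box-boundary membership
    grad <- as.vector(K %*% alpha)
    for (it in seq_len(max_iter)) {
      up <- alpha < U - eps_b        # can receive weight
      dn <- alpha > eps_b            # can give weight
      i <- which(up)[which.min(grad[up])]
      j <- which(dn)[which.max(grad[dn])]
      if (length(i) == 0 || length(j) == 0) break
      if (grad[j] - grad[i] <= tol * scale) break
      denom <- K[i, i] + K[j, j] - 2 * K[i, j]
      step <- if (denom > 1e-14 * scale) (grad[j] - grad[i]) / denom else Inf
      step <- min(step, U - alpha[i], alpha[j])
      alpha[i] <- alpha[i] + step
      alpha[j] <- alpha[j] - step
      grad <- grad + step * (K[, i] - K[, j])
    }
  }
  structure(list(items = rownames(K_train), alpha = alpha, C = C,
                 kernel_id = attr(K_train, "kernel_id"),
                 objective = 0.5 * sum(alpha * (K_train %*% alpha))),
            class = "ocsvm_model")
}

#' @export
print.ocsvm_model <- function(x, ...) {
  cat("ocsvm_model:", length(x$items), "training items, C =", x$C,
      ", support vectors:", sum(x$alpha > 1e-10), "\n")
  invisible(x)
}

#' Ranked item list from a named score vector
#'
#' Items are sorted by decreasing score with ties broken by identifier
#' (ascending), giving a fully deterministic order; ranks are consecutive
#' from 1.
#'
#' @param scores Named numeric vector of scores.
#' @return Data frame of class `ranked_genes` with columns `rank`, `gene`,
#'   `score`.
#' @export
ranked_genes <- function(scores) {
  ord <- order(-scores, names(scores), method = "radix")
  structure(data.frame(rank = seq_along(scores),
                       gene = names(scores)[ord],
                       score = unname(scores[ord]),
                       stringsAsFactors = FALSE),
            class = c("ranked_genes", "data.frame"))
}

#' Score candidates with a trained one-class SVM
#'
#' `f(g) = sum_i alpha_i K(g_i, g)`.
#'
#' @param model An [ocsvm_fit()] result.
#' @param K_cross Kernel rows between candidates (rows) and the model's
#'   training items (columns, in training order).
#' @return A [ranked_genes()] data frame over the candidates.
#' @export
ocsvm_score <- function(model, K_cross) {
  if (!identical(colnames(K_cross), model$items)) {
    stop("columns of K_cross must match the model's training items in order")
  }
  scores <- as.vector(K_cross %*% model$alpha)
  names(scores) <- rownames(K_cross)
  ranked_genes(scores)
}

#' Train and score a multitask one-class SVM
#'
#' Trains on the pair kernel over the training (gene, disease) pairs and
#' scores candidate genes for one query disease:
#' `f(g, q) = sum_i alpha_i K_gene(g_i, g) K_disease(d_i, q)`.
#'
#' @param K_gene Gene kernel covering training and candidate genes.
#' @param dk A [disease_kernel()].
#' @param training_pairs Data frame with columns `gene`, `disease`.
#' @param query_disease Disease label to score for.
#' @param candidate_genes Character vector of genes to rank.
#' @param C Regularization value.
#' @return A [ranked_genes()] data frame over `candidate_genes`.
#' @export
fit_score_multitask <- function(K_gene, dk, training_pairs, query_disease,
                                candidate_genes, C) {
  K_train <- pair_kernel(K_gene, dk, training_pairs)
  model <- ocsvm_fit(K_train, C)
  missing <- setdiff(candidate_genes, rownames(K_gene))
  if (length(missing) > 0) {
    stop("candidate gene(s) outside the gene kernel: ",
         paste(utils::head(missing, 10), collapse = ", "))
  }
  Kg <- K_gene[candidate_genes, training_pairs$gene, drop = FALSE]
  Kd <- disease_kernel_matrix(dk, query_disease, training_pairs$disease)
  scores <- as.vector(Kg %*% (model$alpha * as.vector(Kd)))
  names(scores) <- candidate_genes
  ranked_genes(scores)
}

#' Serialize a trained model to a flat text file
#' @param path Output path.
#' @param model An `ocsvm_model`.
#' @export
write_model <- function(path, model) {
  header <- c(paste0("#C\t", sprintf("%.12g", model$C)),
              paste0("#kernel_id\t", if (is.null(model$kernel_id)) ""
                     else model$kernel_id))
  body <- paste(model$items, sprintf("%.15g", model$alpha), sep = "\t")
  writeLines(c(header, "item\talpha", body), path)
  invisible(path)
}

#' Read a model written by [write_model()]
#' @param path Path to the model file.
#' @return An `ocsvm_model`.
#' @export
read_model <- function(path) {
  lines <- readLines(path)
  meta <- lines[grepl("^#", lines)]
  getv <- function(key) sub(paste0("^#", key, "\t"), "", meta[grepl(
    paste0("^#", key, "\t"), meta)])
  body <- utils::read.delim(text = lines[!grepl("^#", lines)],
                            colClasses = c("character", "numeric"))
  kid <- getv("kernel_id")
  structure(list(items = body$item, alpha = body$alpha,
                 C = as.numeric(getv("C")),
                 kernel_id = if (identical(kid, "")) NULL else kid,
                 objective = NA_real_),
            class = "ocsvm_model")
}
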