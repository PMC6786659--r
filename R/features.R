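# Per-gene 3-dimensional mutation feature vectors.  Oncogenes are
# characterized by gain-of-function signals (damaging missense mutations,
# positional clustering), tumor suppressors by loss-of-function signals
# (frameshift, nonsense, splice-site mutations).

# PolyPhen2 threshold above which a missense mutation counts as damaging.
# Strict inequality: a score of exactly 0.447 is not damaging.
.polyphen_damaging <- 0.447

#' Shannon entropy of a multiset of protein positions
#'
#' Natural-log Shannon entropy of the empirical distribution over distinct
#' positions.  Missing positions are excluded from the distribution; an empty
#' or single-support multiset has entropy 0.
#'
#' @param positions Numeric vector of protein positions (NAs allowed).
#' @return Non-negative entropy in nats.
#' @export
positional_entropy <- function(positions) {
  positions <- positions[!is.na(positions)]
  if (length(positions) == 0) return(0)
  p <- as.numeric(table(positions)) / length(positions)
  -sum(p * log(p))
}

.restrict_records <- function(table, restrict_to_disease) {
  r <- table$records
  if (is.null(restrict_to_disease)) return(r)
  known <- setdiff(unique(r$disease), "")
  if (!restrict_to_disease %in% known) {
    stop("unknown disease '", restrict_to_disease, "'; known labels: ",
         paste(sort(known), collapse = ", "))
  }
  r[r$disease == restrict_to_disease, , drop = FALSE]
}

.feature_table <- function(genes, phi, mode) {
  df <- data.frame(gene = genes, phi, stringsAsFactors = FALSE,
                   row.names = NULL)
  structure(df, mode = mode, scaled = FALSE,
            class = c("gene_features", "data.frame"))
}

#' Oncogene-mode feature vectors
#'
#' For every gene in the universe: the number of damaging missense mutations
#' (PolyPhen2 score strictly greater than 0.447; missing scores count as
#' non-damaging), the total number of missense mutations, and the positional
#' entropy of the missense mutations (mutations with missing position are
#' counted in the total but excluded from the entropy distribution).
#'
#' @param table A [mutation_table()].
#' @param restrict_to_disease Optional disease label; only that disease's
#'   records are used.
#' @return A `gene_features` data frame (gene, n_damaging, n_missense,
#'   entropy) with attributes `mode = "OG"` and `scaled = FALSE`.
#' @export
og_features <- function(table, restrict_to_disease = NULL) {
  r <- .restrict_records(table, restrict_to_disease)
  r <- r[r$category == "missense", , drop = FALSE]
  genes <- table$universe
  idx <- split(seq_len(nrow(r)), factor(r$gene, levels = genes))
  phi <- t(vapply(idx, function(i) {
    c(n_damaging = sum(!is.na(r$polyphen2[i]) &
                         r$polyphen2[i] > .polyphen_damaging),
      n_missense = length(i),
      entropy = positional_entropy(r$protein_position[i]))
  }, numeric(3)))
  .feature_table(genes, phi, "OG")
}

#' Tumor-suppressor-mode feature vectors
#'
#' For every gene in the universe: the number of frameshift mutations, the
#' number of loss-of-function mutations (nonsense plus frameshift), and the
#' number of splice-site mutations.
#'
#' @inheritParams og_features
#' @return A `gene_features` data frame (gene, n_frameshift, n_lof,
#'   n_splice_site) with attribute `mode = "TSG"`.
#' @export
tsg_features <- function(table, restrict_to_disease = NULL) {
  r <- .restrict_records(table, restrict_to_disease)
  genes <- table$universe
  cat_count <- function(category) {
    tab <- table(factor(r$gene[r$category == category], levels = genes))
    as.numeric(tab)
  }
  n_fs <- cat_count("frameshift")
  n_ns <- cat_count("nonsense")
  n_sp <- cat_count("splice_site")
  phi <- cbind(n_frameshift = n_fs, n_lof = n_ns + n_fs, n_splice_site = n_sp)
  .feature_table(genes, phi, "TSG")
}

#' Compute OG- or TSG-mode features
#' @param table A [mutation_table()].
#' @param mode `"OG"` or `"TSG"`.
#' @param restrict_to_disease Optional disease label.
#' @return A `gene_features` data frame.
#' @export
gene_features <- function(table, mode = c("OG", "TSG"),
                          restrict_to_disease = NULL) {
  mode <- match.arg(mode)
  if (mode == "OG") og_features(table, restrict_to_disease)
  else tsg_features(table, restrict_to_disease)
}
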