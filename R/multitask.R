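# Disease descriptors and disease/pair kernels for the multitask setting.
# A disease is encoded as a 43-bit vector: 12 histological tumor-type bits
# plus 31 anatomical localization bits.  Disease kernels control how driver
# information is shared across cancer types.

.type_vocab <- c(
  "adenocarcinoma", "adenoma", "blastoma", "carcinoma", "glioma", "leukemia",
  "lymphoma", "medulloblastoma", "melanoma", "myeloma", "rhabdomyosarcoma",
  "sarcoma"
)

.localization_vocab <- c(
  "adrenal glands", "astrocytes", "B-cell", "bladder", "bone", "breast",
  "cervix", "central nervous system", "colon", "ducts", "endometrium", "eye",
  "head and neck", "heart", "kidney", "liver", "lung", "lymphocytes",
  "mucosa", "muscle", "nerve", "oesophagus", "ovary", "pancreas", "prostate",
  "salivary glands", "skin", "soft tissue", "stomach", "T-cell", "thyroid"
)

#' Disease descriptor vocabulary
#'
#' @return List with elements `types` (12 tumor-type characteristics) and
#'   `localizations` (31 anatomical localizations); their concatenation names
#'   the 43 descriptor bits.
#' @export
disease_vocabulary <- function() {
  list(types = .type_vocab, localizations = .localization_vocab)
}

.match_vocab <- function(names, vocab, what) {
  idx <- match(tolower(trimws(names)), tolower(vocab))
  if (anyNA(idx)) {
    bad <- names[is.na(idx)][1]
    dist <- utils::adist(tolower(bad), tolower(vocab))
    closest <- vocab[order(dist)][1:3]
    stop("unknown ", what, " '", bad, "'; closest vocabulary entries: ",
         paste(closest, collapse = ", "))
  }
  idx
}

#' Build a 43-bit disease descriptor
#'
#' Sets a bit for every named tumor-type and localization characteristic
#' (case-insensitive matching against the fixed vocabulary).  At least one
#' bit must be set.
#'
#' @param types Character vector of tumor-type characteristics.
#' @param localizations Character vector of localization characteristics.
#' @return Named 0/1 integer vector of length 43.
#' @export
build_descriptor <- function(types = character(0),
                             localizations = character(0)) {
  psi <- stats::setNames(integer(43), c(.type_vocab, .localization_vocab))
  if (length(types) > 0) {
    psi[.match_vocab(types, .type_vocab, "tumor type")] <- 1L
  }
  if (length(localizations) > 0) {
    psi[12L + .match_vocab(localizations, .localization_vocab,
                           "localization")] <- 1L
  }
  if (sum(psi) == 0) stop("descriptor must have at least one nonzero bit")
  psi
}

.check_descriptors <- function(descriptors) {
  if (!is.matrix(descriptors) || ncol(descriptors) != 43) {
    stop("descriptors must be a matrix with 43 columns")
  }
  expected <- c(.type_vocab, .localization_vocab)
  if (!identical(colnames(descriptors), expected)) {
    stop("descriptor columns must be the fixed 12+31 vocabulary in order")
  }
  if (!all(descriptors %in% c(0, 1))) stop("descriptor entries must be 0/1")
  if (any(rowSums(descriptors) == 0)) {
    stop("descriptor rows must have at least one nonzero bit: ",
         paste(rownames(descriptors)[rowSums(descriptors) == 0], collapse = ", "))
  }
  invisible(descriptors)
}

#' Read a disease descriptor CSV
#'
#' First column `disease`, then 43 binary columns named exactly by the fixed
#' vocabulary (12 tumor types, then 31 localizations).
#'
#' @param path Path to the CSV.
#' @return Numeric 0/1 matrix, diseases as row names.
#' @export
read_descriptors <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "disease") stop("first column must be 'disease'")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$disease
  storage.mode(m) <- "numeric"
  .check_descriptors(m)
  m
}

#' Write a disease descriptor CSV
#' @param path Output path.
#' @param descriptors 0/1 matrix with disease row names and the 43-name
#'   vocabulary as columns.
#' @export
write_descriptors <- function(path, descriptors) {
  .check_descriptors(descriptors)
  df <- data.frame(disease = rownames(descriptors), descriptors,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Construct a disease kernel
#'
#' Four kernels over cancer types are supported:
#' \describe{
#'   \item{uniform}{`K(d, d') = 1`: all diseases pooled (pan-cancer).}
#'   \item{dirac}{`K(d, d') = [d = d']`: no sharing (single-task).}
#'   \item{multitask}{`(uniform + dirac) / 2`: a disease's own drivers get
#'     twice the weight of any other disease's.}
#'   \item{cancer}{`(Psi(d)' Psi(d') + uniform + dirac) / 3`: sharing
#'     proportional to descriptor similarity; requires `descriptors`.}
#' }
#'
#' @param type One of `"uniform"`, `"dirac"`, `"multitask"`, `"cancer"`.
#' @param descriptors 0/1 descriptor matrix (rows = diseases), required for
#'   `type = "cancer"`.
#' @return An object of class `disease_kernel`; evaluate it over disease
#'   label vectors with [disease_kernel_matrix()].
#' @export
disease_kernel <- function(type = c("uniform", "dirac", "multitask", "cancer"),
                           descriptors = NULL) {
  type <- match.arg(type)
  if (type == "cancer") {
    if (is.null(descriptors)) stop("type 'cancer' requires descriptors")
    .check_descriptors(descriptors)
  }
  structure(list(type = type, descriptors = descriptors),
            class = "disease_kernel")
}

#' Materialize a disease kernel over label vectors
#'
#' @param dk A [disease_kernel()].
#' @param d_row,d_col Character vectors of disease labels.
#' @return Matrix of kernel values, `length(d_row)` by `length(d_col)`.
#' @export
disease_kernel_matrix <- function(dk, d_row, d_col = d_row) {
  nr <- length(d_row); nc <- length(d_col)
  dirac <- outer(d_row, d_col, "==") * 1
  switch(dk$type,
    uniform = matrix(1, nr, nc),
    dirac = dirac,
    multitask = (1 + dirac) / 2,
    cancer = {
      all_d <- unique(c(d_row, d_col))
      missing <- setdiff(all_d, rownames(dk$descriptors))
      if (length(missing) > 0) {
        stop("no descriptor for disease(s): ", paste(missing, collapse = ", "))
      }
      inner <- tcrossprod(dk$descriptors[d_row, , drop = FALSE],
                          dk$descriptors[d_col, , drop = FALSE])
      unname((inner + 1 + dirac) / 3)
    }
  )
}

.pair_ids <- function(pairs) paste(pairs$gene, pairs$disease, sep = "|")

#' Kernel between (gene, disease) pairs
#'
#' `K_pair((g, d), (g', d')) = K_gene(g, g') * K_disease(d, d')`.  The
#' product of two PSD kernels is PSD (Schur product of their liftings), so a
#' one-class SVM can be trained directly on the pair kernel.
#'
#' @param K_gene Gene kernel matrix covering all genes in the pairs.
#' @param dk A [disease_kernel()].
#' @param pairs_row,pairs_col Data frames with columns `gene` and `disease`.
#' @return Matrix with rows/columns named `gene|disease`.
#' @export
pair_kernel <- function(K_gene, dk, pairs_row, pairs_col = pairs_row) {
  for (p in list(pairs_row, pairs_col)) {
    missing <- setdiff(p$gene, rownames(K_gene))
    if (length(missing) > 0) {
      stop("gene(s) outside the gene kernel: ",
           paste(utils::head(missing, 10), collapse = ", "))
    }
  }
  Kg <- K_gene[pairs_row$gene, pairs_col$gene, drop = FALSE]
  Kd <- disease_kernel_matrix(dk, pairs_row$disease, pairs_col$disease)
  K <- Kg * Kd
  dimnames(K) <- list(.pair_ids(pairs_row), .pair_ids(pairs_col))
  K
}
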