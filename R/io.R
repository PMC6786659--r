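# File readers/writers and the core in-memory containers.  All vocabularies
# are normalized here so downstream modules only ever see clean typed tables.

#' Closed vocabulary of mutation categories
#'
#' @return Character vector of the six recognized mutation categories.
#' @export
mutation_categories <- function() {
  c("missense", "nonsense", "frameshift", "splice_site", "silent", "other")
}

# MAF-style variant classification -> category.  Anything not listed maps to
# "other" (never dropped).
.maf_dialect <- c(
  Missense_Mutation = "missense",
  Nonsense_Mutation = "nonsense",
  Frame_Shift_Del   = "frameshift",
  Frame_Shift_Ins   = "frameshift",
  Splice_Site       = "splice_site",
  Silent            = "silent"
)

#' Construct a mutation table
#'
#' A mutation table is a long-format record of somatic mutations plus an
#' ordered gene universe.  The universe is always a lexicographically sorted
#' superset of the genes appearing in the records; genes supplied via
#' `universe` that carry no mutations stay in the universe (they are scoreable
#' candidates with all-zero features).
#'
#' @param records Data frame with columns `gene`, `sample`, `disease`,
#'   `category`, `protein_position`, `polyphen2`.
#' @param universe Optional character vector of additional gene symbols.
#' @return An object of class `mutation_table` with elements `records` and
#'   `universe`.
#' @export
mutation_table <- function(records, universe = NULL) {
  required <- c("gene", "sample", "disease", "category",
                "protein_position", "polyphen2")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    stop("records lack required columns: ", paste(missing_cols, collapse = ", "))
  }
  bad <- setdiff(unique(records$category), mutation_categories())
  if (length(bad) > 0) {
    stop("unknown mutation categories: ", paste(bad, collapse = ", "))
  }
  pos <- records$protein_position
  if (any(!is.na(pos) & pos < 1)) stop("protein_position must be >= 1")
  pp <- records$polyphen2
  if (any(!is.na(pp) & (pp < 0 | pp > 1))) stop("polyphen2 must lie in [0, 1]")
  universe <- sort(unique(c(as.character(records$gene), universe)))
  structure(list(records = records, universe = universe),
            class = "mutation_table")
}

#' @export
print.mutation_table <- function(x, ...) {
  cat("mutation_table:", nrow(x$records), "records,",
      length(x$universe), "genes in universe,",
      length(setdiff(unique(x$records$disease), "")), "disease labels\n")
  invisible(x)
}

#' Read a MAF-like somatic mutation TSV
#'
#' Expected columns (MAF dialect): `Hugo_Symbol`, `Tumor_Sample_Barcode`,
#' `Variant_Classification`, and optionally `Disease`, `Protein_position`,
#' `PolyPhen2`.  Variant classifications are mapped into the closed category
#' vocabulary; unmapped strings become `"other"` and are reported through a
#' single summarizing warning.
#'
#' @param path Path to a tab-separated file with a header line.
#' @param dialect Name of the classification dialect (only `"maf"` is built
#'   in) or a named character vector mapping raw classifications to
#'   categories.
#' @return A [mutation_table()].
#' @export
read_mutation_table <- function(path, dialect = "maf") {
  if (!file.exists(path)) stop("file not found: ", path)
  map <- if (is.character(dialect) && length(dialect) == 1) {
    if (dialect != "maf") stop("unknown dialect: ", dialect)
    .maf_dialect
  } else dialect
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, na.strings = NULL)
  mandatory <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification")
  for (col in mandatory) {
    if (!col %in% names(raw)) stop("missing mandatory column: ", col)
  }
  n <- nrow(raw)
  get_opt <- function(col) if (col %in% names(raw)) raw[[col]] else rep("", n)
  parse_num <- function(x, what) {
    x[x %in% c("", "NA", ".")] <- NA_character_
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad) > 0) {
      stop("unparseable ", what, " at line ", bad[1] + 1L, ": '", x[bad[1]], "'")
    }
    out
  }
  category <- unname(map[raw$Variant_Classification])
  unmapped <- is.na(category)
  category[unmapped] <- "other"
  if (any(unmapped)) {
    tab <- table(raw$Variant_Classification[unmapped])
    warning(sum(unmapped), " record(s) with unmapped classification(s) (",
            paste(names(tab), collapse = ", "), ") coerced to 'other'")
  }
  pos <- parse_num(get_opt("Protein_position"), "Protein_position")
  pp <- parse_num(get_opt("PolyPhen2"), "PolyPhen2")
  records <- data.frame(
    gene = raw$Hugo_Symbol,
    sample = raw$Tumor_Sample_Barcode,
    disease = get_opt("Disease"),
    category = category,
    protein_position = pos,
    polyphen2 = pp,
    stringsAsFactors = FALSE
  )
  tab <- mutation_table(records)
  attr(tab, "n_unmapped") <- sum(unmapped)
  tab
}

#' Write a mutation table as a MAF-dialect TSV
#'
#' Categories are rendered back to representative MAF classification strings,
#' so a write/read cycle preserves the category of every record (the
#' frameshift insertion/deletion distinction is not retained).
#'
#' @param path Output path.
#' @param table A [mutation_table()].
#' @export
write_mutation_table <- function(path, table) {
  rev_map <- c(missense = "Missense_Mutation", nonsense = "Nonsense_Mutation",
               frameshift = "Frame_Shift_Del", splice_site = "Splice_Site",
               silent = "Silent", other = "Other")
  r <- table$records
  out <- data.frame(
    Hugo_Symbol = r$gene,
    Tumor_Sample_Barcode = r$sample,
    Disease = r$disease,
    Variant_Classification = unname(rev_map[r$category]),
    Protein_position = ifelse(is.na(r$protein_position), "",
                              format(r$protein_position, trim = TRUE)),
    PolyPhen2 = ifelse(is.na(r$polyphen2), "",
                       sprintf("%.12g", r$polyphen2)),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct an undirected PPI network
#'
#' Self-loops are dropped (with a warning) and duplicate edges collapsed.
#' Node order is lexicographic, covering both edge endpoints and any extra
#' nodes supplied through `nodes` (isolated proteins).
#'
#' @param edges Two-column character matrix or data frame of interacting gene
#'   pairs.
#' @param nodes Optional additional node names.
#' @return An object of class `ppi_network` with elements `nodes`, `edges`
#'   (two-column matrix, each row sorted), and `degree` (named integer).
#' @export
ppi_network <- function(edges, nodes = NULL) {
  edges <- as.matrix(edges)
  if (length(edges) == 0) {
    edges <- matrix(character(0), ncol = 2)
  }
  if (ncol(edges) != 2) stop("edges must have exactly two columns")
  storage.mode(edges) <- "character"
  loops <- edges[, 1] == edges[, 2]
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped")
    edges <- edges[!loops, , drop = FALSE]
  }
  # canonical order within each pair, then dedup
  swap <- edges[, 1] > edges[, 2]
  edges[swap, ] <- edges[swap, c(2, 1), drop = FALSE]
  edges <- unique(edges)
  node_set <- sort(unique(c(as.character(edges), nodes)))
  deg <- integer(length(node_set))
  names(deg) <- node_set
  if (nrow(edges) > 0) {
    tab <- table(factor(as.character(edges), levels = node_set))
    deg[names(tab)] <- as.integer(tab)
  }
  structure(list(nodes = node_set, edges = edges, degree = deg),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat("ppi_network:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Adjacency matrix of a PPI network
#'
#' @param net A [ppi_network()].
#' @return Symmetric 0/1 matrix with zero diagonal, nodes in network order.
#' @export
adjacency_matrix <- function(net) {
  n <- length(net$nodes)
  A <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
  if (nrow(net$edges) > 0) {
    i <- match(net$edges[, 1], net$nodes)
    j <- match(net$edges[, 2], net$nodes)
    A[cbind(i, j)] <- 1
    A[cbind(j, i)] <- 1
  }
  A
}

#' Read a PPI network from a two-column edge list
#'
#' Lines starting with `#` are comments; fields are separated by any
#' whitespace.  Duplicate edges are collapsed and self-loops dropped.
#'
#' @param path Path to the edge-list file.
#' @return A [ppi_network()].
#' @export
read_ppi_edgelist <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0) return(ppi_network(matrix(character(0), ncol = 2)))
  toks <- strsplit(trimws(lines[idx]), "\\s+")
  nt <- lengths(toks)
  if (any(nt != 2)) {
    bad <- idx[which(nt != 2)[1]]
    stop("expected 2 tokens at line ", bad, ", found ", nt[which(nt != 2)[1]])
  }
  ppi_network(do.call(rbind, toks))
}

#' Write a PPI network as an edge list
#' @param path Output path.
#' @param net A [ppi_network()].
#' @export
write_ppi_edgelist <- function(path, net) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gold-standard gene list (one symbol per line)
#'
#' Duplicates are collapsed with a warning; input order of first occurrence is
#' preserved.
#'
#' @param path Path to the list file.
#' @return Character vector of unique gene symbols.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  genes <- trimws(readLines(path))
  genes <- genes[genes != "" & !grepl("^#", genes)]
  dup <- duplicated(genes)
  if (any(dup)) warning(sum(dup), " duplicate gene(s) collapsed")
  genes[!dup]
}

#' Read a (gene, disease) pair list
#'
#' Tab-separated, two columns `gene` and `disease`, one known driver
#' association per line.  The same gene may appear with several diseases and
#' vice versa.
#'
#' @param path Path to the pair file (with header).
#' @return Data frame with columns `gene` and `disease`.
#' @export
read_pair_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  if (!all(c("gene", "disease") %in% names(df))) {
    stop("pair file must have columns 'gene' and 'disease'")
  }
  df[, c("gene", "disease")]
}

#' Write a (gene, disease) pair list
#' @param path Output path.
#' @param pairs Data frame with columns `gene` and `disease`.
#' @export
write_pair_list <- function(path, pairs) {
  utils::write.table(pairs[, c("gene", "disease")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a ranked gene list
#'
#' Output is tab-separated with header `rank<TAB>gene<TAB>score`; scores carry
#' 12 significant digits so that write/read round-trips are lossless at that
#' precision.
#'
#' @param path Output path.
#' @param ranking A [ranked_genes()] object.
#' @export
write_ranking <- function(path, ranking) {
  out <- data.frame(rank = ranking$rank, gene = ranking$gene,
                    score = sprintf("%.12g", ranking$score),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a ranked gene list written by [write_ranking()]
#' @param path Path to the ranking TSV.
#' @return A `ranked_genes` data frame.
#' @export
read_ranking <- function(path) {
  df <- utils::read.delim(path, colClasses = c("integer", "character", "numeric"))
  structure(df, class = c("ranked_genes", "data.frame"))
}

#' Write a kernel matrix as TSV (item header row + row names)
#' @param path Output path.
#' @param K Kernel matrix with dimnames.
#' @export
write_kernel_tsv <- function(path, K) {
  df <- data.frame(item = rownames(K), K, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a kernel matrix written by [write_kernel_tsv()]
#' @param path Path to the kernel TSV.
#' @return Symmetric numeric matrix with dimnames.
#' @export
read_kernel_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  items <- as.character(df[[1]])
  K <- as.matrix(df[, -1, drop = FALSE])
  dimnames(K) <- list(items, items)
  K
}
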