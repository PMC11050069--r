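#' Construct an expression dataset
#'
#' Container for one cohort: a genes x samples matrix with per-sample ploidy
#' group labels, a platform kind and a species label.
#'
#' @param matrix Numeric genes x samples matrix with unique rownames (gene
#'   ids) and colnames (sample ids). Counts platforms must be non-negative.
#' @param sample_groups Character vector, one of `"diploid"`/`"polyploid"`
#'   per column of `matrix`, named by sample id or in column order.
#' @param platform `"counts"` (sequencing) or `"intensity"` (array scale).
#' @param species Free-text species label (e.g. `"human"`, `"mouse"`).
#' @return An object of class `ExpressionDataset`.
#' @export
expression_dataset <- function(matrix, sample_groups,
                               platform = c("counts", "intensity"),
                               species = "human") {
  platform <- match.arg(platform)
  assert_that(is.matrix(matrix) && is.numeric(matrix),
              "expression matrix must be a numeric matrix")
  assert_that(nrow(matrix) == 0 || !is.null(rownames(matrix)),
              "expression matrix needs gene ids as rownames")
  dup <- rownames(matrix)[duplicated(rownames(matrix))]
  assert_that(length(dup) == 0,
              paste0("duplicate gene id(s): ", paste(unique(dup), collapse = ", ")),
              class = "ploidysig_format_error")
  assert_that(all(is.finite(matrix)), "expression matrix contains non-finite values",
              class = "ploidysig_format_error")
  if (!is.null(names(sample_groups)) && !is.null(colnames(matrix))) {
    missing <- setdiff(colnames(matrix), names(sample_groups))
    assert_that(length(missing) == 0,
                paste0("sample(s) missing from metadata: ",
                       paste(missing, collapse = ", ")),
                class = "ploidysig_format_error")
    sample_groups <- sample_groups[colnames(matrix)]
  }
  assert_that(length(sample_groups) == ncol(matrix),
              "one group label per sample is required",
              class = "ploidysig_format_error")
  assert_that(all(sample_groups %in% c("diploid", "polyploid")),
              "sample groups must be 'diploid' or 'polyploid'",
              class = "ploidysig_format_error")
  if (platform == "counts") {
    assert_that(all(matrix >= 0), "counts platform requires non-negative values",
                class = "ploidysig_format_error")
  }
  structure(
    list(matrix = matrix,
         sample_groups = as.character(sample_groups),
         platform = platform,
         species = species),
    class = "ExpressionDataset"
  )
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset: %d genes x %d samples (%s, %s); %d diploid / %d polyploid\n",
              nrow(x$matrix), ncol(x$matrix), x$platform, x$species,
              sum(x$sample_groups == "diploid"),
              sum(x$sample_groups == "polyploid")))
  invisible(x)
}

#' Read a cohort expression matrix and its sample metadata
#'
#' The expression TSV has a `gene_id` first column and one column per sample;
#' the metadata TSV has columns `sample` and `group` (diploid/polyploid).
#'
#' @param path Expression TSV path.
#' @param metadata_path Sample metadata TSV path.
#' @inheritParams expression_dataset
#' @return An [expression_dataset()].
#' @export
read_expression <- function(path, metadata_path,
                            platform = c("counts", "intensity"),
                            species = "human") {
  platform <- match.arg(platform)
  assert_that(file.exists(path), paste0("expression file not found: ", path),
              class = "ploidysig_format_error")
  assert_that(file.exists(metadata_path),
              paste0("metadata file not found: ", metadata_path),
              class = "ploidysig_format_error")
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  assert_that(ncol(tab) >= 2 && colnames(tab)[1] == "gene_id",
              "expression TSV must start with a 'gene_id' column",
              class = "ploidysig_format_error")
  meta <- read.delim(metadata_path, stringsAsFactors = FALSE)
  assert_that(all(c("sample", "group") %in% colnames(meta)),
              "metadata TSV must have 'sample' and 'group' columns",
              class = "ploidysig_format_error")
  m <- as.matrix(tab[, -1, drop = FALSE])
  assert_that(is.numeric(m), "expression values must be numeric",
              class = "ploidysig_format_error")
  rownames(m) <- tab$gene_id
  groups <- setNames(meta$group, meta$sample)
  expression_dataset(m, groups, platform = platform, species = species)
}

#' Write a cohort expression matrix and sample metadata
#'
#' @param dataset An [expression_dataset()].
#' @param path,metadata_path Output TSV paths.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(dataset, path, metadata_path) {
  tab <- data.frame(gene_id = rownames(dataset$matrix),
                    dataset$matrix, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(sample = colnames(dataset$matrix),
                     group = dataset$sample_groups,
                     stringsAsFactors = FALSE)
  write.table(meta, metadata_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-signature collection
#'
#' One set per line: name, description, then tab-separated member genes.
#'
#' @param path GMT file path.
#' @return A named list of character vectors with a `description` attribute
#'   (named character vector), class `SignatureCollection`.
#' @export
read_gmt <- function(path) {
  assert_that(file.exists(path), paste0("GMT file not found: ", path),
              class = "ploidysig_format_error")
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(fields, function(f) length(f) < 3, logical(1))
  assert_that(!any(bad),
              paste0("GMT line(s) with no members: ",
                     paste(which(bad), collapse = ", ")),
              class = "ploidysig_format_error")
  nm <- vapply(fields, `[[`, character(1), 1)
  assert_that(!anyDuplicated(nm),
              paste0("duplicate signature name(s): ",
                     paste(unique(nm[duplicated(nm)]), collapse = ", ")),
              class = "ploidysig_format_error")
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  desc <- vapply(fields, `[[`, character(1), 2)
  signature_collection(setNames(sets, nm), setNames(desc, nm))
}

#' Construct a signature collection
#'
#' @param sets Named list of character vectors (unique set names, non-empty
#'   members).
#' @param descriptions Optional named character vector of descriptions.
#' @return A `SignatureCollection`.
#' @export
signature_collection <- function(sets, descriptions = NULL) {
  assert_that(is.list(sets) && !is.null(names(sets)) && !anyDuplicated(names(sets)),
              "signature sets must be a uniquely named list")
  empty <- names(sets)[lengths(sets) == 0]
  assert_that(length(empty) == 0,
              paste0("empty signature(s): ", paste(empty, collapse = ", ")),
              class = "ploidysig_format_error")
  if (is.null(descriptions)) descriptions <- setNames(rep("", length(sets)), names(sets))
  structure(sets, description = descriptions[names(sets)],
            class = "SignatureCollection")
}

#' Write a signature collection to GMT
#'
#' @param collection A `SignatureCollection` (or plain named list).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(collection, path) {
  desc <- attr(collection, "description") %||%
    setNames(rep("", length(collection)), names(collection))
  lines <- vapply(names(collection), function(nm) {
    paste(c(nm, desc[[nm]], collection[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an interaction network from a TSV edge list
#'
#' Columns: `gene_a`, `gene_b` and optionally `score`. Self loops are dropped
#' with a warning, duplicate edges collapsed. When `min_score` is given, only
#' edges with score strictly greater than the threshold are kept (mirroring
#' the "physical score > 0.4" convention of STRING-derived networks).
#'
#' @param path Edge-list TSV path.
#' @param min_score Optional strict lower bound on the edge score.
#' @return An undirected simple [igraph::graph] over gene identifiers.
#' @export
read_edge_list <- function(path, min_score = NULL) {
  assert_that(file.exists(path), paste0("edge list not found: ", path),
              class = "ploidysig_format_error")
  tab <- read.delim(path, stringsAsFactors = FALSE)
  assert_that(ncol(tab) >= 2, "edge list needs at least two columns",
              class = "ploidysig_format_error")
  a <- as.character(tab[[1]])
  b <- as.character(tab[[2]])
  if (!is.null(min_score)) {
    assert_that(ncol(tab) >= 3, "min_score given but edge list has no score column",
                class = "ploidysig_format_error")
    keep <- tab[[3]] > min_score
    a <- a[keep]; b <- b[keep]
  }
  loops <- a == b
  if (any(loops)) {
    warning(sprintf("dropping %d self-loop edge(s)", sum(loops)))
    a <- a[!loops]; b <- b[!loops]
  }
  g <- igraph::graph_from_data_frame(data.frame(a, b, stringsAsFactors = FALSE),
                                     directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Write an interaction network as a TSV edge list
#'
#' @param network An igraph graph.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_edge_list <- function(network, path) {
  el <- igraph::as_edgelist(network)
  # canonical order for byte-stable output
  swap <- el[, 1] > el[, 2]
  el[swap, ] <- el[swap, c(2, 1)]
  el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  tab <- data.frame(gene_a = el[, 1], gene_b = el[, 2], stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an ortholog map
#'
#' Two-column TSV pairing gene identifiers of two species; pairs must be
#' unique. Column names carry the species labels.
#'
#' @param path TSV path.
#' @return A two-column data frame of class `OrthologMap`.
#' @export
read_ortholog_map <- function(path) {
  assert_that(file.exists(path), paste0("ortholog map not found: ", path),
              class = "ploidysig_format_error")
  tab <- read.delim(path, stringsAsFactors = FALSE)
  assert_that(ncol(tab) == 2, "ortholog map must have exactly two columns",
              class = "ploidysig_format_error")
  ortholog_map(tab)
}

#' @rdname read_ortholog_map
#' @param pairs Two-column data frame of gene-id pairs.
#' @export
ortholog_map <- function(pairs) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  assert_that(ncol(pairs) == 2, "ortholog map must have exactly two columns")
  dup <- duplicated(pairs)
  assert_that(!any(dup), "ortholog map contains duplicate pairs",
              class = "ploidysig_format_error")
  class(pairs) <- c("OrthologMap", "data.frame")
  pairs
}

#' Write an ortholog map
#' @param map An `OrthologMap`.
#' @param path Output path.
#' @export
write_ortholog_map <- function(map, path) {
  write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Translate a dataset's gene identifiers through an ortholog map
#'
#' Only one-to-one ortholog pairs are used: any gene participating in a
#' one-to-many or many-to-many relation is dropped, so the translated
#' identifiers remain unique and downstream cross-cohort intersection is
#' well defined.
#'
#' @param dataset An [expression_dataset()].
#' @param map An `OrthologMap`; one column must match `dataset$species`, the
#'   other `target_species` (by column name).
#' @param target_species Species label to translate into.
#' @return A new [expression_dataset()] in the target namespace, with at most
#'   as many rows as the input.
#' @export
apply_orthologs <- function(dataset, map, target_species) {
  if (identical(dataset$species, target_species)) return(dataset)
  cols <- colnames(map)
  assert_that(dataset$species %in% cols,
              paste0("ortholog map has no column for species '", dataset$species, "'"))
  assert_that(target_species %in% cols,
              paste0("ortholog map has no column for species '", target_species, "'"))
  from <- as.character(map[[dataset$species]])
  to <- as.character(map[[target_species]])
  # strict 1:1 restriction on both sides
  keep <- !(from %in% from[duplicated(from)]) & !(to %in% to[duplicated(to)])
  from <- from[keep]; to <- to[keep]
  idx <- match(rownames(dataset$matrix), from)
  rows <- which(!is.na(idx))
  if (length(rows) == 0) {
    warning("no gene mapped 1:1 through the ortholog map; empty dataset returned")
  }
  m <- dataset$matrix[rows, , drop = FALSE]
  rownames(m) <- to[idx[rows]]
  expression_dataset(m, setNames(dataset$sample_groups, colnames(m)),
                     platform = dataset$platform, species = target_species)
}

#' Read / write a one-column gene list
#'
#' @param path TSV path with a single `gene_id` column (header required).
#' @return Character vector of gene ids.
#' @export
read_gene_set <- function(path) {
  assert_that(file.exists(path), paste0("gene list not found: ", path),
              class = "ploidysig_format_error")
  tab <- read.delim(path, stringsAsFactors = FALSE)
  as.character(tab[[1]])
}

#' @rdname read_gene_set
#' @param genes Character vector of gene ids.
#' @export
write_gene_set <- function(genes, path) {
  write.table(data.frame(gene_id = genes, stringsAsFactors = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
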