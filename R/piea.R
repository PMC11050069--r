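#' One-step interactome neighborhood of a gene
#'
#' @param network Undirected igraph over gene identifiers.
#' @param gene Gene id (must be a node, otherwise the empty set is returned).
#' @return Character vector of direct interactants, excluding the gene
#'   itself.
#' @export
neighborhood <- function(network, gene) {
  if (!gene %in% igraph::V(network)$name) return(character())
  nb <- igraph::neighbors(network, gene)$name
  setdiff(unique(nb), gene)
}

#' Protein-interaction enrichment analysis (PIEA) scan
#'
#' Treats each sufficiently connected gene's one-step interactome
#' neighborhood as a gene signature and tests its over-representation in a
#' DEG set by the cumulative hypergeometric upper tail, against a fixed
#' background universe. Only genes with strictly more than `min_degree`
#' interactants (within the background) are tested; FDR values are
#' Benjamini-Hochberg adjusted across the tested genes.
#'
#' @param network Undirected igraph; nodes outside `background` are ignored.
#' @param deg_set Character vector of DEGs; must lie within `background`.
#' @param background Character vector: the testable-gene universe.
#' @param min_degree Strict lower bound on neighborhood size (default 5,
#'   i.e. genes with more than 5 interactants are tested).
#' @param direction Optional label (`"up"`/`"down"`) recorded per row.
#' @return Data frame sorted by p: `gene_id`, `K_nb` (neighborhood size),
#'   `k_nb` (neighbors in the DEG set), `n_set`, `N_bg`, `p`, `fdr`,
#'   `direction`.
#' @export
piea_scan <- function(network, deg_set, background, min_degree = 5,
                      direction = NA_character_) {
  background <- unique(background)
  deg_set <- unique(deg_set)
  outside <- setdiff(deg_set, background)
  assert_that(length(outside) == 0,
              paste0("DEG set gene(s) not in background: ",
                     paste(head(outside, 10), collapse = ", "),
                     if (length(outside) > 10) ", ..." else ""),
              class = "ploidysig_domain_error")
  nodes <- intersect(igraph::V(network)$name, background)
  sub <- igraph::induced_subgraph(network, nodes)
  adj <- igraph::as_adj_list(sub)
  node_names <- igraph::V(sub)$name
  N <- length(background)
  n_set <- length(deg_set)
  is_deg <- node_names %in% deg_set
  rows <- lapply(seq_along(node_names), function(i) {
    nb <- setdiff(node_names[as.integer(adj[[i]])], node_names[i])
    K <- length(nb)
    if (K <= min_degree) return(NULL)
    k <- sum(nb %in% deg_set)
    data.frame(gene_id = node_names[i], K_nb = K, k_nb = k,
               n_set = n_set, N_bg = N,
               p = hypergeom_upper_tail(N, K, n_set, k),
               direction = direction, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) {
    tab <- data.frame(gene_id = character(), K_nb = integer(),
                      k_nb = integer(), n_set = integer(), N_bg = integer(),
                      p = numeric(), direction = character(),
                      stringsAsFactors = FALSE)
  }
  tab$fdr <- p.adjust(tab$p, method = "BH")
  tab <- tab[order(tab$p, tab$gene_id), , drop = FALSE]
  rownames(tab) <- NULL
  tab[, c("gene_id", "K_nb", "k_nb", "n_set", "N_bg", "p", "fdr", "direction")]
}

#' Select master regulators from PIEA scans
#'
#' A master regulator is a gene whose neighborhood is significantly enriched
#' in the consensus up (down) set at the given FDR cut AND which itself
#' belongs to that consensus set, i.e. demonstrates consistent
#' ploidy-dependent expression.
#'
#' @param records PIEA records with a `direction` column (`"up"`/`"down"`),
#'   e.g. `rbind` of two [piea_scan()] runs.
#' @param consensus A `ConsensusSet`.
#' @param fdr_cut Strict FDR threshold (default 0.05).
#' @return List with character vectors `up` and `down` (disjoint).
#' @export
select_master_regulators <- function(records, consensus, fdr_cut = 0.05) {
  pick <- function(dir, members) {
    r <- records[records$direction == dir & records$fdr < fdr_cut, , drop = FALSE]
    intersect(r$gene_id, members)
  }
  list(up = pick("up", consensus$up), down = pick("down", consensus$down))
}

#' PIEA master-regulator detection against a consensus set
#'
#' Runs [piea_scan()] for the consensus up and down sets and applies
#' [select_master_regulators()].
#'
#' @inheritParams piea_scan
#' @param consensus A `ConsensusSet`.
#' @inheritParams select_master_regulators
#' @return List: `up`, `down` (regulator gene vectors) and `records` (the
#'   combined scan table).
#' @export
piea_master_regulators <- function(network, consensus, background,
                                   min_degree = 5, fdr_cut = 0.05) {
  rec <- rbind(
    piea_scan(network, intersect(consensus$up, background), background,
              min_degree = min_degree, direction = "up"),
    piea_scan(network, intersect(consensus$down, background), background,
              min_degree = min_degree, direction = "down")
  )
  sel <- select_master_regulators(rec, consensus, fdr_cut = fdr_cut)
  list(up = sel$up, down = sel$down, records = rec)
}
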