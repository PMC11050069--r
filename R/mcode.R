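#' Induced subgraph on a gene list
#'
#' @param network Undirected igraph.
#' @param genes Character vector; genes absent from the network are ignored.
#' @return The induced igraph subgraph.
#' @export
induced_subgraph_genes <- function(network, genes) {
  igraph::induced_subgraph(network, intersect(igraph::V(network)$name,
                                              unique(genes)))
}

# Density of an undirected simple graph; 0 for fewer than 2 nodes.
graph_density <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2) return(0)
  igraph::ecount(g) / (n * (n - 1) / 2)
}

# MCODE vertex weight: k-core number of the highest k-core of the closed
# neighborhood of v, times that core's density (the core-clustering
# coefficient).
mcode_vertex_weights <- function(g) {
  adj <- igraph::as_adj_list(g)
  nms <- igraph::V(g)$name
  vapply(seq_along(nms), function(i) {
    nb_idx <- unique(c(i, as.integer(adj[[i]])))
    if (length(nb_idx) < 2) return(0)
    sub <- igraph::induced_subgraph(g, nb_idx)
    core <- igraph::coreness(sub)
    kmax <- max(core)
    if (kmax == 0) return(0)
    top <- igraph::induced_subgraph(sub, which(core == kmax))
    kmax * graph_density(top)
  }, numeric(1))
}

#' MCODE molecular-complex detection
#'
#' Extracts densely connected complexes from a simple undirected graph:
#' vertices are weighted by the core-clustering coefficient of their closed
#' neighborhood (density of its highest k-core times the core number),
#' complexes are grown greedily from the highest-weight unused seed by
#' admitting neighbors whose weight exceeds `(1 - vwp)` of the seed weight,
#' and (with `haircut`) trimmed to their 2-core. Nodes are never reused
#' across complexes. Equal-weight seed ties break lexicographically on gene
#' id, making the output deterministic.
#'
#' @param network Simple undirected igraph.
#' @param vwp Vertex weight percentage (default 0.2).
#' @param haircut Trim each complex to its 2-core (default `TRUE`).
#' @param fluff Unsupported flag kept for interface parity; must be `FALSE`.
#' @param min_size Minimum complex size after trimming (default 3).
#' @return List of complexes sorted by score descending, each a list with
#'   `members` (sorted gene ids), `seed` and `score` (density x size).
#' @export
mcode <- function(network, vwp = 0.2, haircut = TRUE, fluff = FALSE,
                  min_size = 3) {
  assert_that(isFALSE(fluff), "fluff expansion is not supported")
  assert_that(vwp >= 0 && vwp < 1, "vwp must lie in [0, 1)")
  if (igraph::vcount(network) == 0) return(list())
  w <- mcode_vertex_weights(network)
  nms <- igraph::V(network)$name
  adj <- igraph::as_adj_list(network)
  names(adj) <- nms
  ord <- order(-w, nms)
  used <- setNames(rep(FALSE, length(nms)), nms)
  complexes <- list()
  for (i in ord) {
    seed <- nms[i]
    if (used[seed]) next
    thr <- w[i] * (1 - vwp)
    members <- seed
    frontier <- seed
    used[seed] <- TRUE
    while (length(frontier) > 0) {
      nxt <- character()
      for (v in frontier) {
        vi <- match(v, nms)
        for (u_idx in as.integer(adj[[vi]])) {
          u <- nms[u_idx]
          if (!used[u] && w[u_idx] > thr) {
            used[u] <- TRUE
            members <- c(members, u)
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- nxt
    }
    sub <- igraph::induced_subgraph(network, members)
    if (haircut) {
      core <- igraph::coreness(sub)
      keep <- igraph::V(sub)$name[core >= 2]
      if (!seed %in% keep) next
      sub <- igraph::induced_subgraph(sub, keep)
      # keep the connected piece containing the seed
      comp <- igraph::components(sub)
      keep <- igraph::V(sub)$name[comp$membership ==
                                    comp$membership[match(seed, igraph::V(sub)$name)]]
      sub <- igraph::induced_subgraph(sub, keep)
    }
    if (igraph::vcount(sub) < min_size) next
    complexes[[length(complexes) + 1]] <- list(
      members = sort(igraph::V(sub)$name),
      seed = seed,
      score = graph_density(sub) * igraph::vcount(sub)
    )
  }
  ord2 <- order(-vapply(complexes, `[[`, numeric(1), "score"),
                vapply(complexes, `[[`, character(1), "seed"))
  complexes[ord2]
}

#' Write MCODE complexes as a TSV
#'
#' Columns: `complex_id`, `score`, `seed`, `members` (comma-separated).
#'
#' @param complexes Output of [mcode()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_mcode_report <- function(complexes, path) {
  tab <- data.frame(
    complex_id = seq_along(complexes),
    score = vapply(complexes, function(x) sprintf("%.4f", x$score), character(1)),
    seed = vapply(complexes, `[[`, character(1), "seed"),
    members = vapply(complexes, function(x) paste(x$members, collapse = ","),
                     character(1)),
    stringsAsFactors = FALSE
  )
  if (length(complexes) == 0) {
    tab <- data.frame(complex_id = integer(), score = character(),
                      seed = character(), members = character(),
                      stringsAsFactors = FALSE)
  }
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
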