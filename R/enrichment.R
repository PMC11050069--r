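#' Upper tail of the hypergeometric distribution
#'
#' `P(X >= k)` where `X` counts members of a size-`K` class drawn in a sample
#' of `n` from a background of `N`. Computed via the log-space stable
#' cumulative routine, so it is accurate for backgrounds well beyond 1e5.
#'
#' @param N Background size.
#' @param K Class (signature) size within the background.
#' @param n Sample (query) size.
#' @param k Observed overlap.
#' @return Probability in \\[0, 1].
#' @export
hypergeom_upper_tail <- function(N, K, n, k) {
  assert_that(all(c(N, K, n, k) >= 0), "hypergeometric parameters must be non-negative",
              class = "ploidysig_domain_error")
  assert_that(K <= N && n <= N, "K and n cannot exceed the background size N",
              class = "ploidysig_domain_error")
  assert_that(k <= min(K, n), "overlap k cannot exceed min(K, n)",
              class = "ploidysig_domain_error")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Signature over-representation in a query gene set
#'
#' For each signature the overlap with the query is scored by the cumulative
#' hypergeometric upper tail against a fixed background universe; the
#' observed/expected (O/E) ratio is the overlap divided by the expected count
#' `n * K / N` under random draws. FDR values come from Benjamini-Hochberg
#' adjustment across all tested signatures. The reporting filter keeps
#' records with FDR strictly below `fdr_cut` and O/E strictly above `oe_cut`.
#'
#' Signature members absent from the background are dropped before sizing;
#' signatures left empty are not tested.
#'
#' @param query Character vector of query genes (must lie in `background`).
#' @param collection A `SignatureCollection` (named list of gene sets).
#' @param background Character vector: the background universe.
#' @param fdr_cut,oe_cut Strict reporting thresholds (defaults FDR < 0.01,
#'   O/E > 1.5).
#' @return Data frame sorted by FDR with one row per tested signature:
#'   `signature`, `k` (observed), `K` (signature size in background), `n`
#'   (query size), `N` (background size), `expected`, `oe_ratio`, `p`,
#'   `fdr`, `selected` (passes both filters), `member_genes`
#'   (comma-separated overlap).
#' @export
enrich <- function(query, collection, background,
                   fdr_cut = 0.01, oe_cut = 1.5) {
  background <- unique(background)
  query <- unique(query)
  outside <- setdiff(query, background)
  assert_that(length(outside) == 0,
              paste0("query gene(s) not in background: ",
                     paste(head(outside, 10), collapse = ", "),
                     if (length(outside) > 10) ", ..." else ""),
              class = "ploidysig_domain_error")
  N <- length(background)
  n <- length(query)
  sets <- lapply(collection, intersect, background)
  sets <- sets[lengths(sets) > 0]
  rows <- lapply(names(sets), function(nm) {
    s <- sets[[nm]]
    ov <- intersect(query, s)
    K <- length(s)
    k <- length(ov)
    e <- n * K / N
    data.frame(signature = nm, k = k, K = K, n = n, N = N,
               expected = e,
               oe_ratio = if (e > 0) k / e else NA_real_,
               p = hypergeom_upper_tail(N, K, n, k),
               member_genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) {
    tab <- data.frame(signature = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), expected = numeric(),
                      oe_ratio = numeric(), p = numeric(),
                      member_genes = character(), stringsAsFactors = FALSE)
  }
  tab$fdr <- p.adjust(tab$p, method = "BH")
  tab$selected <- tab$fdr < fdr_cut & !is.na(tab$oe_ratio) & tab$oe_ratio > oe_cut
  tab <- tab[order(tab$fdr, tab$p, tab$signature), , drop = FALSE]
  rownames(tab) <- NULL
  tab[, c("signature", "k", "K", "n", "N", "expected", "oe_ratio",
          "p", "fdr", "selected", "member_genes")]
}

#' Write an enrichment report TSV
#'
#' Columns `signature`, `gene_number`, `oe_ratio` (2 decimals), `fdr`
#' (scientific notation) and `member_genes`, matching the usual layout of
#' published over-representation tables.
#'
#' @param records Output of [enrich()].
#' @param path Output TSV path.
#' @param filtered Write only rows passing the reporting filter
#'   (default `TRUE`).
#' @return Invisibly, `path`.
#' @export
write_enrichment_report <- function(records, path, filtered = TRUE) {
  if (filtered) records <- records[records$selected, , drop = FALSE]
  out <- data.frame(signature = records$signature,
                    gene_number = records$k,
                    oe_ratio = sprintf("%.2f", records$oe_ratio),
                    fdr = sprintf("%.2E", records$fdr),
                    member_genes = records$member_genes,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
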