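#' Build the per-cohort direction matrix
#'
#' Rows are the genes testable in every cohort (the shared universe) in a
#' common namespace; entries are each cohort's call: `up`, `down` or `none`.
#' A gene absent from any one cohort cannot be consistently regulated in all
#' comparisons and is excluded from the universe.
#'
#' @param per_cohort_results List of [moderated_t_test()] data frames, all in
#'   the same gene namespace (translate mouse cohorts with
#'   [apply_orthologs()] before testing, or map their result gene ids).
#' @param p_cut,fdr_cut Strict significance thresholds used per cohort.
#' @return Character matrix genes x cohorts with entries in
#'   `c("up", "down", "none")`, class `DirectionMatrix`.
#' @export
build_direction_matrix <- function(per_cohort_results,
                                   p_cut = 0.05, fdr_cut = 0.1) {
  assert_that(length(per_cohort_results) >= 1, "at least one cohort is required")
  gene_lists <- lapply(per_cohort_results, `[[`, "gene_id")
  universe <- Reduce(intersect, gene_lists)
  assert_that(length(universe) > 0,
              paste("no gene is testable in every cohort;",
                    "check ortholog coverage and gene-id namespaces"))
  nm <- names(per_cohort_results) %||%
    paste0("cohort", seq_along(per_cohort_results))
  mat <- matrix("none", nrow = length(universe), ncol = length(per_cohort_results),
                dimnames = list(universe, nm))
  for (j in seq_along(per_cohort_results)) {
    res <- per_cohort_results[[j]]
    degs <- select_degs(res, p_cut = p_cut, fdr_cut = fdr_cut)
    mat[intersect(universe, degs$up), j] <- "up"
    mat[intersect(universe, degs$down), j] <- "down"
  }
  class(mat) <- c("DirectionMatrix", class(mat))
  mat
}

#' Call consensus up/down gene sets
#'
#' A consensus gene is up (down) when it is called up (down) in every cohort
#' of the direction matrix; any `none` entry or sign conflict excludes it.
#'
#' @param mat A `DirectionMatrix` from [build_direction_matrix()].
#' @return List of class `ConsensusSet`: `up`, `down` (character vectors),
#'   `n_cohorts`, and the provenance `matrix`.
#' @export
call_consensus <- function(mat) {
  up <- rownames(mat)[rowSums(mat == "up") == ncol(mat)]
  down <- rownames(mat)[rowSums(mat == "down") == ncol(mat)]
  structure(list(up = up, down = down, n_cohorts = ncol(mat), matrix = mat),
            class = "ConsensusSet")
}

#' @export
print.ConsensusSet <- function(x, ...) {
  cat(sprintf("ConsensusSet over %d cohorts: %d up, %d down (universe %d genes)\n",
              x$n_cohorts, length(x$up), length(x$down), nrow(x$matrix)))
  invisible(x)
}
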