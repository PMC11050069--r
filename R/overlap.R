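#' Match a consensus ploidy signature against an external cohort
#'
#' Intersects the consensus up (down) set with an external cohort's up
#' (down) DEG list — only direction-concordant matches count — and scores
#' each overlap by the hypergeometric upper tail on the shared tested
#' universe. Discordant overlaps (consensus up vs external down and vice
#' versa) are reported informationally.
#'
#' @param consensus A `ConsensusSet`.
#' @param external_up,external_down Character vectors: the external cohort's
#'   up- and downregulated genes.
#' @param universe Character vector: the shared tested universe; must be
#'   non-empty. All sets are restricted to it before counting.
#' @return List of class `OverlapResult`: `matched_up`, `matched_down`
#'   (gene vectors), `n_matched_up`, `n_matched_down`, `p_up`, `p_down`,
#'   `discordant_up_down`, `discordant_down_up`, `n_universe`.
#' @export
match_signature <- function(consensus, external_up, external_down, universe) {
  universe <- unique(universe)
  assert_that(length(universe) > 0, "overlap universe is empty",
              class = "ploidysig_domain_error")
  cu <- intersect(consensus$up, universe)
  cd <- intersect(consensus$down, universe)
  eu <- intersect(unique(external_up), universe)
  ed <- intersect(unique(external_down), universe)
  mu <- intersect(cu, eu)
  md <- intersect(cd, ed)
  N <- length(universe)
  structure(list(
    matched_up = sort(mu),
    matched_down = sort(md),
    n_matched_up = length(mu),
    n_matched_down = length(md),
    p_up = hypergeom_upper_tail(N, length(cu), length(eu), length(mu)),
    p_down = hypergeom_upper_tail(N, length(cd), length(ed), length(md)),
    discordant_up_down = sort(intersect(cu, ed)),
    discordant_down_up = sort(intersect(cd, eu)),
    n_universe = N
  ), class = "OverlapResult")
}

#' @export
print.OverlapResult <- function(x, ...) {
  cat(sprintf(paste0("OverlapResult (universe %d genes):\n",
                     "  matched up:   %d (p = %.3g)\n",
                     "  matched down: %d (p = %.3g)\n",
                     "  discordant:   %d up/down, %d down/up\n"),
              x$n_universe, x$n_matched_up, x$p_up,
              x$n_matched_down, x$p_down,
              length(x$discordant_up_down), length(x$discordant_down_up)))
  invisible(x)
}
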