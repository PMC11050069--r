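#' Quantile-normalize an expression matrix
#'
#' Forces every column to the same empirical distribution: the vector of
#' row-rank means. Ties within a column receive the mean of the reference
#' values at the tied ranks. For tie-free input every column ends up with
#' exactly the same value multiset and the operation is idempotent; tied
#' entries (common in low counts) are averaged, so their columns agree with
#' the reference distribution only up to the tie resolution.
#'
#' @param m Numeric matrix with at least two columns and finite values.
#' @return Matrix of the same shape with identical per-column value multisets.
#' @export
quantile_normalize <- function(m) {
  assert_that(is.matrix(m) && is.numeric(m), "input must be a numeric matrix")
  assert_that(ncol(m) >= 2, "quantile normalization needs at least 2 columns")
  assert_that(all(is.finite(m)), "matrix contains non-finite values")
  ref <- rowMeans(matrix(apply(m, 2, sort), nrow = nrow(m)))
  out <- apply(m, 2, function(col) {
    r <- rank(col, ties.method = "average")
    lo <- ref[floor(r)]
    hi <- ref[ceiling(r)]
    (lo + hi) / 2
  })
  dimnames(out) <- dimnames(m)
  out
}

#' Prepare a cohort matrix for differential testing
#'
#' Counts platforms are shifted-log transformed (`log2(x + 0.5)`); intensity
#' platforms are log2-scaled only when values look unlogged (matrix maximum
#' above 30, the usual ceiling for log-scale array data). Both then go
#' through [quantile_normalize()], so all cohorts enter testing on one scale.
#'
#' @param dataset An [expression_dataset()].
#' @return Normalized log2-scale matrix.
#' @export
prepare_matrix <- function(dataset) {
  m <- dataset$matrix
  if (dataset$platform == "counts") {
    m <- log2(m + 0.5)
  } else if (max(m) > 30) {
    m <- log2(m + 1)
  }
  quantile_normalize(m)
}

# Solve trigamma(y) = x by Newton iteration on 1/y (limma-style), used by the
# moment fit of the variance prior.
trigamma_inverse <- function(x) {
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-10) break
  }
  y
}

# Fit the scaled-F prior (d0, s0^2) for gene-wise variances s2 with d
# residual df by matching moments of log(s2). Degenerate spread (all
# variances equal) yields d0 = Inf, i.e. a fully pooled variance.
fit_variance_prior <- function(s2, d) {
  z <- log(pmax(s2, 1e-300))
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- var(e) - trigamma(d / 2)
  if (!is.finite(evar) || evar <= 0) {
    message("variance spread is degenerate; using a fully pooled variance (d0 = Inf)")
    return(list(d0 = Inf, s02 = exp(emean)))
  }
  d0 <- 2 * trigamma_inverse(evar)
  s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02)
}

#' Empirical-Bayes moderated t-test between ploidy groups
#'
#' Per gene: the log2 fold change is mean(polyploid) - mean(diploid); the
#' pooled residual variance is shrunk towards a prior fitted across genes by
#' matching moments of the scaled-F distribution of the gene variances; the
#' moderated t uses the posterior variance and gains the prior degrees of
#' freedom. Benjamini-Hochberg adjustment is applied across all genes.
#'
#' @param m Normalized log2-scale matrix (genes x samples).
#' @param groups Character vector per column, `"diploid"`/`"polyploid"`;
#'   at least two samples per group.
#' @param d0 Optional prior degrees of freedom override; `d0 = 0` gives the
#'   ordinary pooled two-sample t, `d0 = Inf` a fully pooled variance.
#' @param p_cut,fdr_cut Thresholds used for the `direction` column (strict
#'   inequalities, defaults p < 0.05 and FDR < 0.1).
#' @return Data frame with columns `gene_id`, `lfc`, `t`, `p`, `fdr`,
#'   `direction` (`up`/`down`/`none`).
#' @export
moderated_t_test <- function(m, groups, d0 = NULL,
                             p_cut = 0.05, fdr_cut = 0.1) {
  assert_that(is.matrix(m) && is.numeric(m), "input must be a numeric matrix")
  assert_that(length(groups) == ncol(m), "one group label per sample is required")
  i1 <- which(groups == "polyploid")
  i2 <- which(groups == "diploid")
  assert_that(length(i1) >= 2 && length(i2) >= 2,
              "each group needs at least 2 samples")
  n1 <- length(i1); n2 <- length(i2)
  m1 <- rowMeans(m[, i1, drop = FALSE])
  m2 <- rowMeans(m[, i2, drop = FALSE])
  lfc <- m1 - m2
  ss1 <- rowSums((m[, i1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((m[, i2, drop = FALSE] - m2)^2)
  d <- n1 + n2 - 2
  s2 <- (ss1 + ss2) / d
  if (is.null(d0)) {
    prior <- fit_variance_prior(s2, d)
    d0 <- prior$d0; s02 <- prior$s02
  } else if (is.infinite(d0)) {
    s02 <- mean(s2)
  } else {
    s02 <- if (d0 > 0) fit_variance_prior(s2, d)$s02 else 0
  }
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2)) else
    (d0 * s02 + d * s2) / (d0 + d)
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t <- ifelse(se > 0, lfc / se, ifelse(lfc == 0, 0, sign(lfc) * Inf))
  df_total <- d0 + d
  p <- 2 * pt(-abs(t), df = df_total)
  p[se == 0 & lfc == 0] <- 1  # flat gene: no evidence either way
  fdr <- p.adjust(p, method = "BH")
  res <- data.frame(gene_id = rownames(m), lfc = lfc, t = t, p = p, fdr = fdr,
                    stringsAsFactors = FALSE, row.names = NULL)
  res$direction <- ifelse(res$p < p_cut & res$fdr < fdr_cut & res$lfc > 0, "up",
                   ifelse(res$p < p_cut & res$fdr < fdr_cut & res$lfc < 0, "down",
                          "none"))
  attr(res, "d0") <- d0
  attr(res, "s02") <- s02
  res
}

#' Differential expression for one cohort
#'
#' Convenience wrapper: [prepare_matrix()] then [moderated_t_test()].
#'
#' @inheritParams prepare_matrix
#' @inheritParams moderated_t_test
#' @return See [moderated_t_test()].
#' @export
cohort_differential <- function(dataset, d0 = NULL,
                                p_cut = 0.05, fdr_cut = 0.1) {
  moderated_t_test(prepare_matrix(dataset), dataset$sample_groups, d0 = d0,
                   p_cut = p_cut, fdr_cut = fdr_cut)
}

#' Select differentially expressed genes
#'
#' A gene is called up when p < `p_cut`, FDR < `fdr_cut` (both strict) and
#' the log2 fold change is positive; down analogously. Genes with zero fold
#' change are never selected.
#'
#' @param results Output of [moderated_t_test()].
#' @inheritParams moderated_t_test
#' @return List with character vectors `up` and `down`.
#' @export
select_degs <- function(results, p_cut = 0.05, fdr_cut = 0.1) {
  sig <- results$p < p_cut & results$fdr < fdr_cut
  list(up = results$gene_id[sig & results$lfc > 0],
       down = results$gene_id[sig & results$lfc < 0])
}
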