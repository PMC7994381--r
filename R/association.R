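# Pearson-correlation criteria: expression vs gene copy number and
# expression vs MYCN expression.  Expression enters on the
# log2(normalised count + 1) scale; p-values are Bonferroni-adjusted over
# the tested family and genes pass with adjusted p < alpha and r > 0.

#' Two-sided Pearson correlation test
#'
#' Sample Pearson r with a two-sided p-value from
#' `t = r * sqrt((N - 2) / (1 - r^2))` on `N - 2` degrees of freedom,
#' after pairwise removal of missing values.  Undefined cases (fewer than
#' 3 complete pairs, or zero variance in either argument) are flagged with
#' missing `r` and `p` so callers can exclude them from the family.
#'
#' @param x,y Numeric vectors of equal length.
#' @return A list with elements `r`, `p`, and `n` (complete pairs used).
#' @export
pearson_test <- function(x, y) {
  if (length(x) != length(y))
    .stop_fmt("pearson_test: x and y must have equal length")
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || var(x) == 0 || var(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n))
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Correlation filter over a gene family
#'
#' Correlates every row of an expression matrix against a per-sample
#' target vector (gene copy number, or MYCN expression), adjusts the
#' p-values with Bonferroni over the tested family, and passes genes with
#' adjusted p < `alpha` and r > 0.
#'
#' @param expr Numeric matrix (genes x samples), typically
#'   `log2(normalised count + 1)`.
#' @param target Either a numeric per-sample vector shared by all genes
#'   (e.g. MYCN expression), or a numeric matrix of the same shape as
#'   `expr` giving a per-gene target (e.g. each gene's own copy number).
#' @param alpha Adjusted-p significance threshold (default 0.05).
#' @return A `data.frame` with columns `gene_id`, `r`, `p`, `p_adj`,
#'   `passes`.  Undefined correlations have missing `r`/`p` and fail.
#' @export
correlation_filter <- function(expr, target, alpha = 0.05) {
  per_gene <- is.matrix(target)
  if (per_gene && !all(dim(target) == dim(expr)))
    .stop_fmt("correlation_filter: per-gene target must match expr shape")
  if (!per_gene && length(target) != ncol(expr))
    .stop_fmt("correlation_filter: target length != number of samples")
  res <- t(vapply(seq_len(nrow(expr)), function(i) {
    tg <- if (per_gene) target[i, ] else target
    pt <- pearson_test(expr[i, ], tg)
    c(pt$r, pt$p)
  }, numeric(2)))
  out <- data.frame(gene_id = rownames(expr), r = res[, 1], p = res[, 2],
                    stringsAsFactors = FALSE, row.names = NULL)
  out$p_adj <- adjust_pvalues(out$p, method = "bonferroni")
  out$passes <- !is.na(out$p_adj) & out$p_adj < alpha &
    !is.na(out$r) & out$r > 0
  out
}

#' Normalised log2 expression
#'
#' `log2(count / size_factor + 1)`, the scale used for the correlation and
#' survival criteria.
#'
#' @param counts Integer matrix, genes x samples.
#' @param sf Optional size factors; computed with [size_factors()] when
#'   missing.
#' @return Numeric matrix of the same shape as `counts`.
#' @export
log_expression <- function(counts, sf = NULL) {
  if (is.null(sf)) sf <- size_factors(counts)
  log2(sweep(counts, 2, sf, "/") + 1)
}
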