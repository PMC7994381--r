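# Two-group differential expression on counts: negative-binomial
# log-linear model per gene with method-of-moments dispersion, Wald
# chi-squared test, Benjamini-Hochberg / Bonferroni adjustment, and the
# data-dependent log2 fold-change threshold (lower quartile of the
# positive significant fold-changes).

#' Median-of-ratios size factors
#'
#' For each sample, the median over genes (expressed in all samples) of the
#' ratio of its count to the gene's geometric mean across samples, rescaled
#' so the size factors have geometric mean 1.
#'
#' @param counts Integer matrix, genes x samples.
#' @return Named numeric vector of size factors, one per sample.
#' @export
size_factors <- function(counts) {
  if (ncol(counts) == 1) return(setNames(1, colnames(counts)))
  lg <- rowMeans(log(counts))
  ok <- is.finite(lg)
  if (!any(ok))
    .stop_fmt(paste("size_factors: no gene has nonzero counts in all",
                    "samples; consider a pseudo-reference fallback"))
  s <- apply(counts[ok, , drop = FALSE], 2, function(col)
    median(col / exp(lg[ok])))
  s <- s / exp(mean(log(s)))
  setNames(s, colnames(counts))
}

# Method-of-moments NB dispersion on normalised counts, pooled within
# groups so a real group difference does not inflate it.  Floored at 1e-8.
.mom_dispersion <- function(q, groups) {
  ests <- vapply(unique(groups), function(g) {
    x <- q[groups == g]
    if (length(x) < 2) return(NA_real_)
    m <- mean(x)
    if (m <= 0) return(NA_real_)
    (var(x) - m) / m^2
  }, numeric(1))
  a <- mean(ests, na.rm = TRUE)
  if (!is.finite(a)) a <- 1e-8
  max(a, 1e-8)
}

#' Negative-binomial Wald test per gene
#'
#' Fits, for every gene, the log-linear model
#' `mean_i = s_i * exp(b0 + b1 * group_i)` with a per-gene NB dispersion
#' estimated by method of moments on normalised counts (floored at 1e-8),
#' and tests `b1 = 0` with a two-sided Wald chi-squared test on 1 degree of
#' freedom.  `log2fc = b1 / ln 2` is the log2 fold-change of group 2 over
#' group 1.  Genes with all-zero counts in both groups are flagged
#' untestable (`p` missing) and are excluded from multiplicity adjustment.
#'
#' @param counts Integer matrix, genes x samples.
#' @param groups Binary vector (0/1, logical, or two-level factor), one
#'   entry per sample.
#' @param sf Optional size factors; computed with [size_factors()] when
#'   missing.
#' @return A `data.frame` with columns `gene_id`, `log2fc`, `se` (standard
#'   error of `log2fc`), `p`.
#' @export
nb_wald_test <- function(counts, groups, sf = NULL) {
  if (is.factor(groups) || is.character(groups))
    groups <- as.integer(factor(groups)) - 1L
  groups <- as.integer(as.logical(groups))
  if (length(groups) != ncol(counts))
    .stop_fmt("nb_wald_test: groups length != number of samples")
  if (length(unique(groups)) != 2)
    .stop_fmt("nb_wald_test: both groups must be non-empty")
  if (is.null(sf)) sf <- size_factors(counts)
  lsf <- log(sf)
  res <- t(vapply(seq_len(nrow(counts)), function(i) {
    k <- counts[i, ]
    if (all(k == 0)) return(c(NA_real_, NA_real_, NA_real_))
    a <- .mom_dispersion(k / sf, groups)
    fit <- try(suppressWarnings(
      glm(k ~ groups + offset(lsf),
          family = MASS::negative.binomial(theta = 1 / a),
          control = glm.control(maxit = 50))), silent = TRUE)
    if (inherits(fit, "try-error")) return(c(NA_real_, NA_real_, NA_real_))
    co <- summary(fit)$coefficients
    if (nrow(co) < 2 || !is.finite(co[2, 2]))
      return(c(NA_real_, NA_real_, NA_real_))
    b1 <- co[2, 1]; se <- co[2, 2]
    c(b1 / log(2), se / log(2), pchisq((b1 / se)^2, df = 1,
                                       lower.tail = FALSE))
  }, numeric(3)))
  data.frame(gene_id = rownames(counts), log2fc = res[, 1], se = res[, 2],
             p = res[, 3], stringsAsFactors = FALSE, row.names = NULL)
}

#' Adjust p-values for multiple testing
#'
#' Benjamini-Hochberg step-up or Bonferroni `min(1, m * p)`; `NA` entries
#' (untestable genes) are excluded from the family and stay `NA`.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param method `"BH"` or `"bonferroni"`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE))
    .stop_fmt("adjust_pvalues: p-values outside [0, 1]")
  p.adjust(p, method = method)
}

#' Data-dependent log2 fold-change threshold
#'
#' The lower quartile (25th percentile, linear-interpolation convention) of
#' all positive log2 fold-changes passing the adjusted-p threshold.
#' Missing when no gene qualifies, in which case [de_filter()] passes no
#' gene.
#'
#' @param results `data.frame` with columns `log2fc` and `p_adj`.
#' @param alpha Adjusted-p significance threshold (default 0.05).
#' @return The threshold, or `NA` if the qualifying set is empty.
#' @export
lfc_threshold <- function(results, alpha = 0.05) {
  x <- results$log2fc[!is.na(results$p_adj) & results$p_adj < alpha &
                        !is.na(results$log2fc) & results$log2fc > 0]
  if (length(x) == 0) return(NA_real_)
  unname(quantile(x, 0.25, type = 7))
}

#' Differential-expression filter
#'
#' A gene passes when its adjusted p-value is below `alpha` and its log2
#' fold-change is at or above the data-dependent threshold (inclusive).
#'
#' @param results `data.frame` with columns `log2fc` and `p_adj`.
#' @param threshold Log2 fold-change threshold; computed with
#'   [lfc_threshold()] when missing.
#' @param alpha Adjusted-p significance threshold (default 0.05).
#' @return Logical vector of passes aligned to `results` rows (`FALSE` for
#'   untestable genes).
#' @export
de_filter <- function(results, threshold = NULL, alpha = 0.05) {
  if (is.null(threshold)) threshold <- lfc_threshold(results, alpha)
  if (is.na(threshold)) return(rep(FALSE, nrow(results)))
  out <- !is.na(results$p_adj) & results$p_adj < alpha &
    !is.na(results$log2fc) & results$log2fc >= threshold
  out
}

#' Two-group differential-expression screen
#'
#' Convenience wrapper running [nb_wald_test()], [adjust_pvalues()],
#' [lfc_threshold()] and [de_filter()] in sequence.
#'
#' @inheritParams nb_wald_test
#' @param method Multiplicity adjustment, `"BH"` (default) or
#'   `"bonferroni"`.
#' @param alpha Adjusted-p significance threshold.
#' @return A `data.frame` with columns `gene_id`, `log2fc`, `se`, `p`,
#'   `p_adj`, `passes`, with the fold-change threshold in attribute
#'   `lfc_threshold`.
#' @export
de_screen <- function(counts, groups, sf = NULL, method = "BH",
                      alpha = 0.05) {
  res <- nb_wald_test(counts, groups, sf = sf)
  res$p_adj <- adjust_pvalues(res$p, method = method)
  thr <- lfc_threshold(res, alpha)
  res$passes <- de_filter(res, threshold = thr, alpha = alpha)
  attr(res, "lfc_threshold") <- thr
  res
}
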