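# The five-criterion cohort screen: per-gene criterion flags, score 0-5
# and deterministic ranking over the genes of the recurrently gained
# region.  Criteria: (1) DE in region-gain vs diploid samples, (2) DE in
# MYCN-amplified vs non-amplified samples, (3) expression/copy-number
# correlation, (4) expression/MYCN-expression correlation, (5) poor-
# outcome association (median-dichotomised survival filter).

#' Five-criterion cohort screen
#'
#' Runs the full screen over the genes of the configured region:
#' criteria 1 and 2 via [de_screen()] on their own stratifications (each
#' with its own data-dependent fold-change threshold; the DE family is
#' all genes in the count matrix), criterion 3 via [correlation_filter()]
#' against each gene's own copy number, criterion 4 against the MYCN
#' expression vector, criterion 5 via [survival_filter()].  Only
#' up-regulation can pass the DE criteria.  Samples with missing region
#' status are dropped from criterion 1 only.
#'
#' @param x An `nb_cohort` from [simulate_cohort()], or `NULL` if the
#'   tables are given individually.
#' @param segments,counts,clinical,genes Individual input tables (see the
#'   `read_*` functions); ignored when `x` is an `nb_cohort`.
#' @param region Region of interest, a list with `chrom`, `start`, `end`
#'   (see [parse_region()]); defaults to the cohort's region.
#' @param mycn_gene Identifier of the MYCN gene in the count matrix
#'   (default `"MYCN"`).
#' @param endpoint Survival endpoint for criterion 5, `"os"` (default) or
#'   `"efs"`.
#' @param alpha Significance threshold used by every criterion
#'   (default 0.05).
#' @return An object of class `nb_screen`: a `data.frame` with one row
#'   per region gene -- criterion flags `c1_de_gain` .. `c5_survival`,
#'   `score`, `rank`, and the per-criterion evidence (fold changes,
#'   correlations, HR, p-values).  Attributes carry the two fold-change
#'   thresholds and the stratum sizes.
#' @export
five_criteria_screen <- function(x = NULL, segments = NULL, counts = NULL,
                                 clinical = NULL, genes = NULL,
                                 region = NULL, mycn_gene = "MYCN",
                                 endpoint = "os", alpha = 0.05) {
  if (inherits(x, "nb_cohort")) {
    segments <- x$segments; counts <- x$counts; clinical <- x$clinical
    genes <- x$genes
    if (is.null(region)) region <- x$region
  }
  if (is.null(segments) || is.null(counts) || is.null(clinical) ||
      is.null(genes) || is.null(region))
    .stop_fmt("five_criteria_screen: need segments, counts, clinical, genes and region")
  if (!mycn_gene %in% rownames(counts))
    .stop_fmt("five_criteria_screen: MYCN gene '%s' not in count matrix",
              mycn_gene)
  samples <- colnames(counts)
  clinical <- clinical[match(samples, clinical$sample), ]
  if (anyNA(clinical$sample))
    .stop_fmt("five_criteria_screen: clinical table missing samples")

  region_genes <- genes[genes$chrom == region$chrom &
                          genes$start < region$end &
                          genes$end > region$start &
                          genes$gene_id != mycn_gene, , drop = FALSE]
  region_genes <- region_genes[region_genes$gene_id %in% rownames(counts), ,
                               drop = FALSE]
  if (nrow(region_genes) == 0)
    .stop_fmt("five_criteria_screen: no region genes found in counts")

  sf <- size_factors(counts)
  expr <- log_expression(counts, sf)
  rcounts <- counts[rownames(counts) %in% region_genes$gene_id, ,
                    drop = FALSE]

  # criterion 1: DE, region gain vs diploid (samples with missing region
  # status or a loss call are excluded from this criterion only).  All
  # five criteria share one gene universe -- the region transcripts -- so
  # the DE families and quartile thresholds are computed over that
  # universe; size factors come from the full count matrix.
  rs <- suppressWarnings(region_status(segments, region, samples = samples))
  keep1 <- !is.na(rs$call) & rs$call %in% c("gain", "diploid")
  if (sum(rs$call[keep1] == "gain") < 2 ||
      sum(rs$call[keep1] == "diploid") < 2)
    .stop_fmt("five_criteria_screen: fewer than 2 samples in the %s stratum",
              if (sum(rs$call[keep1] == "gain") < 2) "gain" else "diploid")
  de1 <- de_screen(rcounts[, keep1, drop = FALSE],
                   rs$call[keep1] == "gain", sf = sf[keep1],
                   method = "BH", alpha = alpha)

  # criterion 2: DE, MYCN-amplified vs non-amplified
  amp <- clinical$mycn_amplified
  if (sum(amp == 1) < 2 || sum(amp == 0) < 2)
    .stop_fmt("five_criteria_screen: fewer than 2 samples in the %s stratum",
              if (sum(amp == 1) < 2) "amplified" else "non-amplified")
  de2 <- de_screen(rcounts, amp == 1, sf = sf, method = "BH",
                   alpha = alpha)

  ridx <- match(region_genes$gene_id, rownames(counts))
  rexpr <- expr[ridx, , drop = FALSE]

  # criterion 3: correlation with each gene's own copy number
  cn <- t(vapply(seq_len(nrow(region_genes)), function(i) {
    vapply(samples, function(sm) {
      gene_copy_number(segments[segments$sample == sm, , drop = FALSE],
                       region_genes[i, ])
    }, numeric(1))
  }, numeric(length(samples))))
  rownames(cn) <- region_genes$gene_id
  c3 <- correlation_filter(rexpr, cn, alpha = alpha)

  # criterion 4: correlation with MYCN expression
  c4 <- correlation_filter(rexpr, expr[mycn_gene, ], alpha = alpha)

  # criterion 5: survival association
  c5 <- survival_filter(rexpr, clinical, endpoint = endpoint,
                        alpha = alpha)

  i1 <- match(region_genes$gene_id, de1$gene_id)
  i2 <- match(region_genes$gene_id, de2$gene_id)
  out <- data.frame(
    gene_id = region_genes$gene_id,
    c1_de_gain = de1$passes[i1],
    c2_de_amp = de2$passes[i2],
    c3_cn_corr = c3$passes,
    c4_mycn_corr = c4$passes,
    c5_survival = c5$passes,
    log2fc_gain = de1$log2fc[i1], padj_gain = de1$p_adj[i1],
    log2fc_amp = de2$log2fc[i2], padj_amp = de2$p_adj[i2],
    r_cn = c3$r, padj_cn = c3$p_adj,
    r_mycn = c4$r, padj_mycn = c4$p_adj,
    hr = c5$hr, logrank_p = c5$logrank_p,
    stringsAsFactors = FALSE, row.names = NULL)
  flags <- as.matrix(out[, c("c1_de_gain", "c2_de_amp", "c3_cn_corr",
                             "c4_mycn_corr", "c5_survival")])
  out$score <- as.integer(rowSums(flags, na.rm = TRUE))
  out <- rank_genes(out)
  attr(out, "lfc_threshold_gain") <- attr(de1, "lfc_threshold")
  attr(out, "lfc_threshold_amp") <- attr(de2, "lfc_threshold")
  attr(out, "n_gain") <- sum(rs$call[keep1] == "gain")
  attr(out, "n_diploid") <- sum(rs$call[keep1] == "diploid")
  attr(out, "n_amp") <- sum(amp == 1)
  attr(out, "region") <- region
  class(out) <- c("nb_screen", "data.frame")
  out
}

#' Rank screened genes
#'
#' Deterministic ordering: descending score, ties broken by survival HR
#' (descending), then the gain-stratification DE adjusted p (ascending),
#' then gene id (lexical).  The result is invariant to the input row
#' order.
#'
#' @param results A screen result `data.frame` with columns `score`,
#'   `hr`, `padj_gain`, `gene_id`.
#' @return The same `data.frame`, ordered, with a `rank` column.
#' @export
rank_genes <- function(results) {
  hr <- ifelse(is.na(results$hr), -Inf, results$hr)
  pa <- ifelse(is.na(results$padj_gain), Inf, results$padj_gain)
  o <- order(-results$score, -hr, pa, results$gene_id)
  out <- results[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' @export
print.nb_screen <- function(x, n = 10, ...) {
  reg <- attr(x, "region")
  if (!is.null(reg))
    cat(sprintf("Five-criterion screen over %d genes in %s:%d-%d\n",
                nrow(x), reg$chrom, reg$start, reg$end))
  if (!is.null(attr(x, "n_gain")))
    cat(sprintf("  strata: %d gain / %d diploid; %d amplified\n",
                attr(x, "n_gain"), attr(x, "n_diploid"), attr(x, "n_amp")))
  if (!is.null(attr(x, "lfc_threshold_gain")))
    cat(sprintf("  log2FC thresholds: gain %.3f, amplified %.3f\n",
                attr(x, "lfc_threshold_gain"), attr(x, "lfc_threshold_amp")))
  s5 <- x$gene_id[x$score == 5]
  cat(sprintf("  genes passing all five criteria: %s\n",
              if (length(s5)) paste(s5, collapse = ", ") else "none"))
  cols <- intersect(c("rank", "gene_id", "score", "c1_de_gain",
                      "c2_de_amp", "c3_cn_corr", "c4_mycn_corr",
                      "c5_survival"), names(x))
  print(head(as.data.frame(x)[cols], n), row.names = FALSE, ...)
  invisible(x)
}

#' @export
summary.nb_screen <- function(object, ...) {
  flags <- as.matrix(object[, c("c1_de_gain", "c2_de_amp", "c3_cn_corr",
                                "c4_mycn_corr", "c5_survival")])
  structure(list(n_genes = nrow(object),
                 criterion_pass = colSums(flags, na.rm = TRUE),
                 score_table = table(factor(object$score, levels = 0:5)),
                 top = object$gene_id[object$score == 5]),
            class = "summary.nb_screen")
}

#' @export
print.summary.nb_screen <- function(x, ...) {
  cat(sprintf("Screen over %d genes\n", x$n_genes))
  cat("Per-criterion pass counts:\n")
  print(x$criterion_pass)
  cat("Score distribution:\n")
  print(x$score_table)
  cat(sprintf("Score-5 genes: %s\n",
              if (length(x$top)) paste(x$top, collapse = ", ") else "none"))
  invisible(x)
}

#' Plot screen scores by genomic position
#'
#' @param x An `nb_screen` object.
#' @param genes Optional gene-model `data.frame` providing positions.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.nb_screen <- function(x, genes = NULL, ...) {
  if (!is.null(genes)) {
    pos <- genes$start[match(x$gene_id, genes$gene_id)] / 1e6
    graphics::plot(pos, x$score, pch = 16, ylim = c(0, 5),
                   xlab = "gene position (Mb)", ylab = "criteria passed",
                   ...)
  } else {
    graphics::plot(x$rank, x$score, pch = 16, ylim = c(0, 5),
                   xlab = "rank", ylab = "criteria passed", ...)
  }
  invisible(x)
}
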