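# The ChIP-seq coactivator-target screen: promoter windows, peak-to-
# promoter assignment, mark co-occupancy, the fold-enrichment filter and
# ranking, E-box motif scanning, and the five-criterion target screen.

.chip_marks <- c("alyref", "mycn", "polii", "h3k27ac", "h3k4me3")

#' Strand-aware promoter windows
#'
#' The promoter is the interval from 1000 bases upstream to 100 bases
#' downstream of the transcription start site, in transcription
#' orientation (width 1100), clipped at the chromosome start.
#'
#' @param genes Gene-model `data.frame` (see [read_gene_models()]).
#' @return A `data.frame` with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (0-based half-open windows).
#' @export
promoter_windows <- function(genes) {
  minus <- genes$strand == "-"
  start <- ifelse(minus, genes$tss - 100, genes$tss - 1000)
  end <- ifelse(minus, genes$tss + 1000, genes$tss + 100)
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             start = pmax(0, start), end = end, strand = genes$strand,
             stringsAsFactors = FALSE)
}

#' Assign peaks to promoter windows
#'
#' A peak is assigned to a gene when it overlaps the gene's promoter
#' window by at least one base; one peak may be assigned to several
#' genes.  Peak and window chromosome names must share at least one name,
#' otherwise an error lists the offending sets.
#'
#' @param peaks Peak `data.frame` (see [read_narrowpeak()]).
#' @param windows Promoter windows from [promoter_windows()].
#' @return A `data.frame` with columns `gene_id`, `peak_name`,
#'   `fold_enrichment`, one row per (gene, peak) assignment.
#' @export
assign_peaks <- function(peaks, windows) {
  if (nrow(peaks) > 0 &&
      length(intersect(unique(peaks$chrom), unique(windows$chrom))) == 0)
    .stop_fmt("assign_peaks: no shared chromosome names (peaks: %s; windows: %s)",
              paste(unique(peaks$chrom), collapse = ","),
              paste(unique(windows$chrom), collapse = ","))
  if (nrow(peaks) == 0)
    return(data.frame(gene_id = character(), peak_name = character(),
                      fold_enrichment = numeric(),
                      stringsAsFactors = FALSE))
  pg <- GenomicRanges::GRanges(peaks$chrom,
                               IRanges::IRanges(peaks$start + 1L,
                                                peaks$end))
  wg <- GenomicRanges::GRanges(windows$chrom,
                               IRanges::IRanges(windows$start + 1L,
                                                windows$end))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(wg, pg))
  data.frame(gene_id = windows$gene_id[S4Vectors::queryHits(hits)],
             peak_name = peaks$name[S4Vectors::subjectHits(hits)],
             fold_enrichment =
               peaks$fold_enrichment[S4Vectors::subjectHits(hits)],
             stringsAsFactors = FALSE)
}

#' Promoter co-occupancy matrix
#'
#' Combines per-mark peak assignments into a genes x marks boolean
#' occupancy matrix; `alyref_fe` is the maximum fold enrichment over the
#' ALYREF peaks assigned to a gene (`NA` when the gene has none).
#'
#' @param assignments Named list of assignment `data.frame`s from
#'   [assign_peaks()], with entries for the marks `alyref`, `mycn`,
#'   `polii`, `h3k27ac`, `h3k4me3`.
#' @param gene_ids Gene universe; defaults to all genes appearing in any
#'   assignment.
#' @return An object of class `occupancy_matrix`: a `data.frame` with
#'   `gene_id`, one logical column per mark, `cooccupied` (all five marks
#'   present) and `alyref_fe`.
#' @export
occupancy_matrix <- function(assignments, gene_ids = NULL) {
  missing <- setdiff(.chip_marks, names(assignments))
  if (length(missing))
    .stop_fmt("occupancy_matrix: missing mark(s): %s",
              paste(missing, collapse = ", "))
  if (is.null(gene_ids))
    gene_ids <- sort(unique(unlist(lapply(assignments[.chip_marks],
                                          function(a) a$gene_id))))
  out <- data.frame(gene_id = gene_ids, stringsAsFactors = FALSE)
  for (mk in .chip_marks)
    out[[mk]] <- gene_ids %in% assignments[[mk]]$gene_id
  aly <- assignments$alyref
  fe <- rep(NA_real_, length(gene_ids))
  if (nrow(aly) > 0) {
    mx <- tapply(aly$fold_enrichment, aly$gene_id, max)
    fe[match(names(mx), gene_ids)] <- as.numeric(mx)
  }
  out$cooccupied <- Reduce(`&`, lapply(.chip_marks, function(m) out[[m]]))
  out$alyref_fe <- fe
  class(out) <- c("occupancy_matrix", "data.frame")
  out
}

#' Fold-enrichment filter and ranking
#'
#' Genes pass with ALYREF fold enrichment strictly greater than the
#' threshold ("more than 5"); passing genes are ranked by descending fold
#' enrichment, ties broken by gene id.
#'
#' @param occupancy An `occupancy_matrix`.
#' @param threshold Fold-enrichment cut-off (default 5, strict).
#' @return A `data.frame` of passing genes with columns `gene_id`,
#'   `alyref_fe`, `fe_rank`, ordered by rank.
#' @export
fe_filter <- function(occupancy, threshold = 5) {
  keep <- !is.na(occupancy$alyref_fe) & occupancy$alyref_fe > threshold
  out <- data.frame(gene_id = occupancy$gene_id[keep],
                    alyref_fe = occupancy$alyref_fe[keep],
                    stringsAsFactors = FALSE)
  o <- order(-out$alyref_fe, out$gene_id)
  out <- out[o, , drop = FALSE]
  out$fe_rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Scan a sequence for E-box motifs
#'
#' Reports every 6-mer window matching CANNTG (N = any base); windows
#' equal to the canonical motif CACGTG are labelled `canonical`, all
#' other matches `non-canonical`.  Windows containing the letter N in the
#' sequence never match.  Both motif classes are reverse-complement
#' palindromic as patterns, so a single-strand scan suffices.
#'
#' @param sequence DNA string over the alphabet A, C, G, T, N
#'   (case-insensitive).
#' @return A `data.frame` with columns `position` (0-based offset),
#'   `kind` (`"canonical"` or `"non-canonical"`), `seq` (the matched
#'   6-mer).
#' @examples
#' ebox_scan("CACGTGAACAGCTG")
#' @export
ebox_scan <- function(sequence) {
  s <- toupper(sequence)
  if (grepl("[^ACGTN]", s))
    .stop_fmt("ebox_scan: invalid character in sequence")
  m <- gregexpr("(?=CA[ACGT][ACGT]TG)", s, perl = TRUE)[[1]]
  if (m[1] == -1)
    return(data.frame(position = integer(), kind = character(),
                      seq = character(), stringsAsFactors = FALSE))
  pos <- as.integer(m)
  hits <- substring(s, pos, pos + 5)
  data.frame(position = pos - 1L,
             kind = ifelse(hits == "CACGTG", "canonical", "non-canonical"),
             seq = hits, stringsAsFactors = FALSE)
}

#' Five-criterion ChIP coactivator-target screen
#'
#' Flags, for every gene of the occupancy universe: (1) promoter
#' co-occupancy of all five marks (ALYREF, MYCN, RNA Pol II, H3K27ac,
#' H3K4me3); (2) ALYREF fold enrichment strictly above the threshold;
#' (3) survival association ([survival_filter()]: HR > 1 and log-rank
#' p < 0.05 on the median-dichotomised expression); (4) positive
#' Bonferroni-significant correlation with MYCN expression; (5)
#' membership in a user-supplied gene set (e.g. ubiquitination-related
#' genes).  The final list holds genes passing all five, ordered by
#' fold-enrichment rank.
#'
#' @param occupancy An `occupancy_matrix`, or a named list of peak
#'   `data.frame`s (marks `alyref`, `mycn`, `polii`, `h3k27ac`,
#'   `h3k4me3`), in which case `genes` must be supplied to build promoter
#'   windows.
#' @param counts Count matrix including the screened genes and
#'   `mycn_gene`.
#' @param clinical Clinical table aligned to the count-matrix samples.
#' @param gene_set Character vector of gene ids for criterion 5 (an empty
#'   set yields an empty final list, with a warning).
#' @param genes Gene models, required when `occupancy` is a peak list.
#' @param fe_threshold Fold-enrichment cut-off (default 5).
#' @param mycn_gene MYCN identifier in `counts` (default `"MYCN"`).
#' @param endpoint Survival endpoint (default `"os"`).
#' @param alpha Significance threshold (default 0.05).
#' @return An object of class `chip_screen`: a `data.frame` with one row
#'   per gene -- the five criterion flags, `alyref_fe`, `fe_rank` (among
#'   FE-passing genes), `hr`, `logrank_p`, `r_mycn`, `padj_mycn`, and
#'   `final_pass`; ordered with the final list first by `fe_rank`.
#' @export
chip_target_screen <- function(occupancy, counts, clinical, gene_set,
                               genes = NULL, fe_threshold = 5,
                               mycn_gene = "MYCN", endpoint = "os",
                               alpha = 0.05) {
  if (!inherits(occupancy, "occupancy_matrix")) {
    if (is.null(genes))
      .stop_fmt("chip_target_screen: genes required to build promoter windows")
    win <- promoter_windows(genes)
    assignments <- lapply(occupancy, assign_peaks, windows = win)
    occupancy <- occupancy_matrix(assignments, gene_ids = genes$gene_id)
  }
  if (length(gene_set) == 0)
    warning("chip_target_screen: empty gene set; final list is empty",
            call. = FALSE)
  if (!mycn_gene %in% rownames(counts))
    .stop_fmt("chip_target_screen: MYCN gene '%s' not in count matrix",
              mycn_gene)
  ids <- occupancy$gene_id
  expr <- log_expression(counts)
  in_expr <- ids %in% rownames(expr)
  eidx <- match(ids[in_expr], rownames(expr))

  c3 <- data.frame(gene_id = ids, hr = NA_real_, logrank_p = NA_real_,
                   passes = FALSE, stringsAsFactors = FALSE)
  c4 <- data.frame(gene_id = ids, r = NA_real_, p_adj = NA_real_,
                   passes = FALSE, stringsAsFactors = FALSE)
  if (any(in_expr)) {
    sub <- expr[eidx, , drop = FALSE]
    sf3 <- survival_filter(sub, clinical, endpoint = endpoint,
                           alpha = alpha)
    cf4 <- correlation_filter(sub, expr[mycn_gene, ], alpha = alpha)
    c3[in_expr, c("hr", "logrank_p", "passes")] <-
      sf3[, c("hr", "logrank_p", "passes")]
    c4[in_expr, c("r", "p_adj", "passes")] <- cf4[, c("r", "p_adj", "passes")]
  }

  fe_pass <- fe_filter(occupancy, threshold = fe_threshold)
  out <- data.frame(
    gene_id = ids,
    cooccupied = occupancy$cooccupied,
    fe_pass = ids %in% fe_pass$gene_id,
    survival_pass = c3$passes,
    mycn_corr_pass = c4$passes,
    in_gene_set = ids %in% gene_set,
    alyref_fe = occupancy$alyref_fe,
    fe_rank = fe_pass$fe_rank[match(ids, fe_pass$gene_id)],
    hr = c3$hr, logrank_p = c3$logrank_p,
    r_mycn = c4$r, padj_mycn = c4$p_adj,
    stringsAsFactors = FALSE)
  out$final_pass <- out$cooccupied & out$fe_pass & out$survival_pass &
    out$mycn_corr_pass & out$in_gene_set
  o <- order(!out$final_pass, ifelse(is.na(out$fe_rank), Inf, out$fe_rank),
             out$gene_id)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "fe_threshold") <- fe_threshold
  attr(out, "n_fe_passing") <- nrow(fe_pass)
  class(out) <- c("chip_screen", "data.frame")
  out
}

#' @export
print.chip_screen <- function(x, n = 10, ...) {
  if (!is.null(attr(x, "fe_threshold")))
    cat(sprintf("ChIP target screen over %d genes (FE threshold %g, %d FE-passing)\n",
                nrow(x), attr(x, "fe_threshold"), attr(x, "n_fe_passing")))
  fin <- x$gene_id[x$final_pass]
  cat(sprintf("  final targets (all five criteria): %s\n",
              if (length(fin)) paste(fin, collapse = ", ") else "none"))
  cols <- intersect(c("gene_id", "cooccupied", "fe_pass", "survival_pass",
                      "mycn_corr_pass", "in_gene_set", "alyref_fe",
                      "fe_rank", "final_pass"), names(x))
  print(head(as.data.frame(x)[cols], n), row.names = FALSE, ...)
  invisible(x)
}
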