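#' @importFrom stats median quantile var coef pchisq pnorm rbinom rexp rlnorm
#'   rnbinom rnorm runif setNames uniroot complete.cases cor p.adjust glm
#'   glm.control offset
#' @importFrom utils read.delim write.table head
NULL

# All internal coordinates are 0-based half-open [start, end).  GTF input is
# 1-based closed and is converted exactly once at the boundary (read/write).

.stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

.check_interval_frame <- function(df, what, line_offset = 1L) {
  bad <- which(!is.finite(df$start) | !is.finite(df$end))
  if (length(bad))
    .stop_fmt("%s: non-numeric coordinates at line %d", what, bad[1] + line_offset)
  bad <- which(df$start < 0)
  if (length(bad))
    .stop_fmt("%s: negative start at line %d", what, bad[1] + line_offset)
  bad <- which(df$end <= df$start)
  if (length(bad))
    .stop_fmt("%s: end <= start at line %d", what, bad[1] + line_offset)
  invisible(df)
}

#' Read a segmental copy-number table
#'
#' Reads a tab-separated table of per-sample copy-number segments with
#' columns `sample`, `chrom`, `start`, `end`, `ploidy`.  Coordinates are
#' 0-based half-open.  `ploidy` is the segment's average copy number
#' (real-valued, >= 0).  Segments of one sample on one chromosome must not
#' overlap.
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` with columns `sample`, `chrom`, `start`, `end`,
#'   `ploidy`, one row per segment.
#' @seealso [write_segments()], [average_ploidy()]
#' @export
read_segments <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "chrom", "start", "end", "ploidy")
  if (!all(need %in% names(df)))
    .stop_fmt("segment file %s: header must contain %s", path,
              paste(need, collapse = ", "))
  df <- df[need]
  df$start <- suppressWarnings(as.numeric(df$start))
  df$end <- suppressWarnings(as.numeric(df$end))
  df$ploidy <- suppressWarnings(as.numeric(df$ploidy))
  .check_interval_frame(df, sprintf("segment file %s", path))
  bad <- which(!is.finite(df$ploidy) | df$ploidy < 0)
  if (length(bad))
    .stop_fmt("segment file %s: missing or negative ploidy at line %d",
              path, bad[1] + 1L)
  validate_segments(df)
}

#' Validate a segment table
#'
#' Checks column presence, interval sanity and the per-sample
#' per-chromosome non-overlap invariant.
#'
#' @param segments A segment `data.frame` as returned by [read_segments()].
#' @return The validated `data.frame`, invisibly usable downstream.
#' @export
validate_segments <- function(segments) {
  stopifnot(is.data.frame(segments),
            all(c("sample", "chrom", "start", "end", "ploidy") %in%
                  names(segments)))
  if (nrow(segments) == 0) return(segments)
  if (any(segments$end <= segments$start))
    .stop_fmt("segments: empty or inverted interval present")
  if (any(segments$ploidy < 0)) .stop_fmt("segments: negative ploidy")
  key <- paste(segments$sample, segments$chrom, sep = "\r")
  for (k in unique(key)) {
    s <- segments[key == k, ]
    o <- order(s$start)
    if (any(s$start[o][-1] < s$end[o][-nrow(s)])) {
      parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
      .stop_fmt("segments: overlapping segments for sample %s on %s",
                parts[1], parts[2])
    }
  }
  segments
}

#' Write a segmental copy-number table
#'
#' @param segments Segment `data.frame` (see [read_segments()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path) {
  validate_segments(segments)
  write.table(segments, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.empty_peaks <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             name = character(), score = numeric(), strand = character(),
             fold_enrichment = numeric(), pvalue = numeric(),
             qvalue = numeric(), summit_offset = numeric(),
             stringsAsFactors = FALSE)
}

#' Read an ENCODE narrowPeak file
#'
#' narrowPeak is BED6+4: chrom, start, end, name, score, strand,
#' signalValue, pValue, qValue, peak (summit offset).  Column 7
#' (signalValue) is interpreted as the peak-caller's fold enrichment (FE)
#' over genomic input.  Coordinates are 0-based half-open.
#'
#' @param path Path to a narrowPeak file (no header line).
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`, `fold_enrichment`, `pvalue`, `qvalue`,
#'   `summit_offset`.
#' @export
read_narrowpeak <- function(path) {
  cols <- names(.empty_peaks())
  if (file.size(path) == 0) return(.empty_peaks())
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 10)
    .stop_fmt("narrowPeak file %s: expected >= 10 columns, found %d",
              path, ncol(df))
  df <- df[, 1:10]
  names(df) <- cols
  for (nm in c("start", "end", "fold_enrichment")) {
    v <- suppressWarnings(as.numeric(df[[nm]]))
    if (anyNA(v))
      .stop_fmt("narrowPeak file %s: non-numeric %s at line %d", path, nm,
                which(is.na(v))[1])
    df[[nm]] <- v
  }
  .check_interval_frame(df, sprintf("narrowPeak file %s", path),
                        line_offset = 0L)
  if (any(df$fold_enrichment < 0))
    .stop_fmt("narrowPeak file %s: negative fold enrichment", path)
  df
}

#' Write an ENCODE narrowPeak file
#'
#' @param peaks Peak `data.frame` (see [read_narrowpeak()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  need <- c("chrom", "start", "end", "name", "score", "strand",
            "fold_enrichment", "pvalue", "qvalue", "summit_offset")
  stopifnot(all(need %in% names(peaks)))
  write.table(peaks[need], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from a GTF file
#'
#' Imports records with feature type `gene` and converts the 1-based closed
#' GTF intervals to the package's 0-based half-open convention.  The
#' transcription start site (TSS) is the first transcribed base: `start`
#' for `+`-strand genes and `end - 1` (half-open) for `-`-strand genes.
#'
#' @param path Path to a GTF file.
#' @return A `data.frame` with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `tss` (all coordinates 0-based half-open).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
  ids <- gr$gene_id
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    .stop_fmt("GTF file %s: records with missing gene_id attribute", path)
  if (anyDuplicated(ids))
    .stop_fmt("GTF file %s: duplicated gene_id '%s'", path,
              ids[duplicated(ids)][1])
  df <- data.frame(
    gene_id = as.character(ids),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
  df$strand[df$strand == "*"] <- "+"
  df$tss <- ifelse(df$strand == "-", df$end - 1L, df$start)
  df
}

#' Write gene models to a GTF file
#'
#' Converts internal 0-based half-open intervals back to GTF 1-based closed
#' coordinates.
#'
#' @param genes Gene-model `data.frame` (see [read_gene_models()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand") %in%
                  names(genes)))
  gr <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(genes$start + 1L, genes$end),
    strand = genes$strand)
  gr$source <- "nbscreen"
  gr$type <- "gene"
  gr$gene_id <- genes$gene_id
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read a gene-level count matrix
#'
#' First column `gene_id`, remaining columns one per sample; counts must be
#' non-negative integers.
#'
#' @param path Path to the TSV file.
#' @return An integer matrix, genes in rows (rownames = gene ids), samples
#'   in columns.
#' @export
read_counts <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "gene_id")
    .stop_fmt("count file %s: first column must be gene_id", path)
  if (anyDuplicated(df$gene_id))
    .stop_fmt("count file %s: duplicated gene ids", path)
  if (anyDuplicated(names(df)[-1]))
    .stop_fmt("count file %s: duplicated sample ids", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "numeric"
  if (anyNA(m) || any(m < 0) || any(m != round(m)))
    .stop_fmt("count file %s: counts must be non-negative integers", path)
  storage.mode(m) <- "integer"
  rownames(m) <- df$gene_id
  m
}

#' Write a gene-level count matrix
#'
#' @param counts Integer matrix, genes x samples.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.clinical_cols <- c("sample", "os_time", "os_event", "efs_time",
                    "efs_event", "stage_advanced", "age_over_18m",
                    "mycn_amplified")

#' Read a clinical annotation table
#'
#' One row per sample with overall/event-free survival times (days), event
#' indicators, and binary prognostic covariates: advanced stage (INSS 3/4),
#' age at diagnosis over 18 months, and MYCN-amplification status.
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` with columns `sample`, `os_time`, `os_event`,
#'   `efs_time`, `efs_event`, `stage_advanced`, `age_over_18m`,
#'   `mycn_amplified`.
#' @export
read_clinical <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(.clinical_cols %in% names(df)))
    .stop_fmt("clinical file %s: header must contain %s", path,
              paste(.clinical_cols, collapse = ", "))
  df <- df[.clinical_cols]
  validate_clinical(df)
}

#' Validate a clinical table
#'
#' @param clinical Clinical `data.frame` (see [read_clinical()]).
#' @return The validated `data.frame`.
#' @export
validate_clinical <- function(clinical) {
  stopifnot(all(.clinical_cols %in% names(clinical)))
  if (anyDuplicated(clinical$sample))
    .stop_fmt("clinical table: duplicated sample ids")
  for (nm in c("os_time", "efs_time"))
    if (any(clinical[[nm]] <= 0))
      .stop_fmt("clinical table: non-positive %s", nm)
  for (nm in c("os_event", "efs_event", "stage_advanced", "age_over_18m",
               "mycn_amplified"))
    if (!all(clinical[[nm]] %in% c(0L, 1L)))
      .stop_fmt("clinical table: %s must be 0/1", nm)
  clinical
}

#' Write a clinical annotation table
#'
#' @param clinical Clinical `data.frame` (see [read_clinical()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clinical, path) {
  validate_clinical(clinical)
  write.table(clinical[.clinical_cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Parse a region string
#'
#' Parses `"chr17:5000000-8000000"` into its chromosome, start and end
#' (0-based half-open).
#'
#' @param x A string `chrom:start-end`.
#' @return A list with elements `chrom`, `start`, `end`.
#' @export
parse_region <- function(x) {
  m <- regmatches(x, regexec("^([^:]+):([0-9]+)-([0-9]+)$", x))[[1]]
  if (length(m) != 4)
    .stop_fmt("cannot parse region '%s' (expected chrom:start-end)", x)
  out <- list(chrom = m[2], start = as.numeric(m[3]), end = as.numeric(m[4]))
  if (out$end <= out$start) .stop_fmt("region '%s': end <= start", x)
  out
}
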