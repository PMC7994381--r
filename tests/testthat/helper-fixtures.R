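# Shared fixtures, built in code.

# small, fast cohort configuration for unit tests (acceptance tests use
# the full default configuration)
small_config <- function(seed = 1, ...) {
  sim_config(n_samples = 80, n_genes = 80, n_region_genes = 16,
             seed = seed, ...)
}

# four-sample hand-built segment fixture on a 30-kb toy chromosome:
# sample A diploid everywhere; B gained in bin 2; C lost in bin 1,
# boundary value n = 3 in bin 3; D boundary value n = 1 in bin 1
hand_segments <- function() {
  rbind(
    data.frame(sample = "A", chrom = "chrT", start = 0, end = 30000,
               ploidy = 2),
    data.frame(sample = "B", chrom = "chrT", start = c(0, 10000, 20000),
               end = c(10000, 20000, 30000), ploidy = c(2, 3.5, 2)),
    data.frame(sample = "C", chrom = "chrT", start = c(0, 10000, 20000),
               end = c(10000, 20000, 30000), ploidy = c(0.5, 2, 3)),
    data.frame(sample = "D", chrom = "chrT", start = c(0, 10000),
               end = c(10000, 30000), ploidy = c(1, 2)))
}

# deterministic random peak/window fixture for overlap oracle checks
random_intervals <- function(n, chrom = "chrZ", max_pos = 1e5,
                             max_len = 500) {
  start <- sample.int(max_pos, n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  data.frame(chrom = chrom, start = start, end = start + len,
             stringsAsFactors = FALSE)
}

# brute-force all-pairs interval overlap (oracle for assign_peaks)
brute_overlap_pairs <- function(windows, peaks) {
  out <- NULL
  for (i in seq_len(nrow(windows))) for (j in seq_len(nrow(peaks))) {
    if (windows$chrom[i] == peaks$chrom[j] &&
        windows$start[i] < peaks$end[j] &&
        windows$end[i] > peaks$start[j])
      out <- rbind(out, data.frame(gene_id = windows$gene_id[i],
                                   peak_name = peaks$name[j],
                                   stringsAsFactors = FALSE))
  }
  if (is.null(out))
    out <- data.frame(gene_id = character(), peak_name = character())
  out[order(out$gene_id, out$peak_name), , drop = FALSE]
}

# brute-force E-box enumeration over all 6-mer windows (oracle)
brute_ebox <- function(s) {
  s <- toupper(s)
  n <- nchar(s) - 5
  if (n < 1) return(data.frame(position = integer(), kind = character()))
  hits <- lapply(seq_len(n), function(i) {
    w <- substr(s, i, i + 5)
    if (grepl("N", w)) return(NULL)
    if (substr(w, 1, 2) == "CA" && substr(w, 5, 6) == "TG")
      data.frame(position = i - 1L,
                 kind = if (w == "CACGTG") "canonical" else "non-canonical")
    else NULL
  })
  do.call(rbind, hits)
}

# brute-force Benjamini-Hochberg step-up and Bonferroni (oracles)
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(1, adj)
  out
}
brute_bonferroni <- function(p) pmin(1, p * length(p))

# narrowPeak data.frame builder
mk_peaks <- function(chrom, start, end, fe,
                     name = sprintf("p%d", seq_along(start))) {
  data.frame(chrom = chrom, start = start, end = end, name = name,
             score = 0, strand = ".", fold_enrichment = fe, pvalue = 1,
             qvalue = 1, summit_offset = 0, stringsAsFactors = FALSE)
}
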