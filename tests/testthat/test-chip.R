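test_that("promoter windows are strand-aware and clipped", {
  genes <- data.frame(gene_id = c("plus", "minus", "edge"),
                      chrom = "chrZ", start = c(5000, 4000, 300),
                      end = c(7000, 6000, 1300),
                      strand = c("+", "-", "+"),
                      stringsAsFactors = FALSE)
  genes$tss <- c(5000, 5999, 300)
  win <- promoter_windows(genes)
  expect_equal(unlist(win[win$gene_id == "plus", c("start", "end")]),
               c(start = 4000, end = 5100))
  expect_equal(win$end - win$start,
               c(1100, 1100, 400))  # edge gene clipped at chromosome start
  # minus strand: -1000 upstream is to the right of the TSS
  mw <- win[win$gene_id == "minus", ]
  expect_equal(c(mw$start, mw$end), c(5899, 6999))

  g2 <- data.frame(gene_id = "m", chrom = "chrZ", start = 4000,
                   end = 5001, strand = "-", tss = 5000)
  w2 <- promoter_windows(g2)
  expect_equal(c(w2$start, w2$end), c(4900, 6000))
})

test_that("peak assignment is >= 1-base overlap with half-open boundaries", {
  win <- data.frame(gene_id = c("a", "b", "c"), chrom = "chrZ",
                    start = c(4000, 5100, 9000),
                    end = c(5100, 6200, 10100), strand = "+",
                    stringsAsFactors = FALSE)
  pk <- mk_peaks("chrZ", c(4500, 5100, 5050, 20000),
                 c(4600, 5200, 5150, 20100), c(5, 6, 7, 8))
  asn <- assign_peaks(pk, win)
  expect_true(any(asn$gene_id == "a" & asn$peak_name == "p1"))
  # half-open abutment: peak [5100,5200) does not touch window [4000,5100)
  expect_false(any(asn$gene_id == "a" & asn$peak_name == "p2"))
  expect_true(any(asn$gene_id == "b" & asn$peak_name == "p2"))
  # a peak spanning two adjacent promoters is assigned to both
  expect_equal(sort(asn$gene_id[asn$peak_name == "p3"]), c("a", "b"))

  expect_error(assign_peaks(mk_peaks("chrQ", 1, 100, 2), win),
               "no shared chromosome")
})

test_that("peak assignment equals brute-force all-pairs overlap", {
  set.seed(51)
  win <- random_intervals(200)
  win$gene_id <- sprintf("g%03d", seq_len(nrow(win)))
  pk <- cbind(random_intervals(200),
              mk_peaks("chrZ", 1, 2, runif(200))[rep(1, 200),
                                                 c("name", "score",
                                                   "strand",
                                                   "fold_enrichment",
                                                   "pvalue", "qvalue",
                                                   "summit_offset")])
  pk$chrom <- "chrZ"
  pk$name <- sprintf("p%03d", seq_len(nrow(pk)))
  got <- assign_peaks(pk, win)[, c("gene_id", "peak_name")]
  got <- got[order(got$gene_id, got$peak_name), , drop = FALSE]
  want <- brute_overlap_pairs(win, pk)
  expect_equal(unname(as.matrix(got)), unname(as.matrix(want)))
})

test_that("the occupancy matrix combines marks and takes the max ALYREF FE", {
  win <- promoter_windows(data.frame(
    gene_id = c("full", "nohk4", "dual"), chrom = "chrZ",
    start = c(5000, 15000, 25000), end = c(7000, 17000, 27000),
    strand = "+", tss = c(5000, 15000, 25000)))
  at <- function(genes, fe = 2) {
    i <- match(genes, win$gene_id)
    mk_peaks("chrZ", win$start[i], win$end[i], fe)
  }
  asn <- list(
    alyref = assign_peaks(rbind(at("full", 3), at("full", 7),
                                at(c("nohk4", "dual"), 4)), win),
    mycn = assign_peaks(at(c("full", "nohk4", "dual")), win),
    polii = assign_peaks(at(c("full", "nohk4", "dual")), win),
    h3k27ac = assign_peaks(at(c("full", "nohk4", "dual")), win),
    h3k4me3 = assign_peaks(at(c("full", "dual")), win))
  occ <- occupancy_matrix(asn, gene_ids = win$gene_id)
  expect_true(occ$cooccupied[occ$gene_id == "full"])
  expect_false(occ$cooccupied[occ$gene_id == "nohk4"])
  # two ALYREF peaks FE 3 and 7 at one promoter -> max taken
  expect_equal(occ$alyref_fe[occ$gene_id == "full"], 7)

  expect_error(occupancy_matrix(asn[-1]), "missing mark.*alyref")
})

test_that("the FE filter is strict at the threshold and ranks by descending FE", {
  occ <- data.frame(
    gene_id = c("at5", "usp3like", "top", "second", "third", "fourth",
                "fifth", "below"),
    alyref_fe = c(5.0, 6.15987, 9, 8, 7, 6.2, 6.16, 3),
    stringsAsFactors = FALSE)
  occ$alyref <- TRUE; occ$mycn <- TRUE; occ$polii <- TRUE
  occ$h3k27ac <- TRUE; occ$h3k4me3 <- TRUE; occ$cooccupied <- TRUE
  class(occ) <- c("occupancy_matrix", "data.frame")
  res <- fe_filter(occ, threshold = 5)
  expect_false("at5" %in% res$gene_id)       # strictly more than 5
  expect_false("below" %in% res$gene_id)
  expect_equal(res$fe_rank[res$gene_id == "usp3like"], 6)
  expect_equal(res$gene_id[1], "top")
  # inserting a lower-FE gene does not disturb existing relative order
  occ2 <- rbind(occ, data.frame(gene_id = "lowest", alyref_fe = 5.5,
                                alyref = TRUE, mycn = TRUE, polii = TRUE,
                                h3k27ac = TRUE, h3k4me3 = TRUE,
                                cooccupied = TRUE))
  class(occ2) <- c("occupancy_matrix", "data.frame")
  res2 <- fe_filter(occ2, threshold = 5)
  expect_equal(res2$gene_id[seq_len(6)], res$gene_id[seq_len(6)])
})

test_that("E-box scanning matches exhaustive window enumeration", {
  one <- ebox_scan("CACGTG")
  expect_equal(one$position, 0L)
  expect_equal(one$kind, "canonical")

  nc <- ebox_scan("CAGCTG")
  expect_equal(nc$kind, "non-canonical")
  expect_equal(ebox_scan("CACCTG")$kind, "non-canonical")

  # constructed 60-mer with 2 canonical and 3 other E-box words
  s <- paste0("AAAA", "CACGTG", "TTTT", "CAGCTG", "GGGG", "CACCTG",
              "AAAA", "CACGTG", "TTTT", "CATATG", "ACGTACGTAC")
  hits <- ebox_scan(s)
  expect_equal(sum(hits$kind == "canonical"), 2)
  expect_equal(sum(hits$kind == "non-canonical"), 3)
  want <- brute_ebox(s)
  expect_equal(hits$position, want$position)
  expect_equal(hits$kind, want$kind)

  # N in the sequence never matches; invalid characters error
  expect_equal(nrow(ebox_scan("CANNTG")), 0)
  expect_error(ebox_scan("CACGTX"), "invalid character")

  set.seed(52)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), 200, replace = TRUE,
                      prob = c(.24, .24, .24, .24, .04)), collapse = "")
    got <- ebox_scan(s)
    want <- brute_ebox(s)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got$position, want$position)
      expect_equal(got$kind, want$kind)
    }
  }
})

test_that("the ChIP target screen enforces all five criteria", {
  fx <- simulate_chip_fixture(small_config(seed = 53))
  res <- chip_target_screen(fx$peaks, fx$cohort$counts,
                            fx$cohort$clinical, fx$gene_set,
                            genes = fx$genes)
  target <- fx$truth$target_gene
  row <- res[res$gene_id == target, ]
  expect_true(row$final_pass)
  expect_equal(row$fe_rank, 1)

  # removing the target from the gene set breaks exactly that criterion
  res2 <- chip_target_screen(fx$peaks, fx$cohort$counts,
                             fx$cohort$clinical,
                             setdiff(fx$gene_set, target),
                             genes = fx$genes)
  row2 <- res2[res2$gene_id == target, ]
  expect_false(row2$in_gene_set)
  expect_false(row2$final_pass)
  expect_true(row2$cooccupied && row2$fe_pass)

  # empty gene set: warning and an empty final list
  expect_warning(
    res3 <- chip_target_screen(fx$peaks, fx$cohort$counts,
                               fx$cohort$clinical, character(0),
                               genes = fx$genes),
    "empty gene set")
  expect_false(any(res3$final_pass))
})
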