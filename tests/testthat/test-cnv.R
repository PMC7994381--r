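test_that("bin grids tile the chromosome with a final partial bin", {
  b <- make_bins("chr17", 30000, 10000)
  expect_equal(nrow(b), 3)
  expect_equal(b$end, c(10000, 20000, 30000))

  b <- make_bins("chr17", 25000, 10000)
  expect_equal(nrow(b), 3)
  expect_equal(b$start[3], 20000)
  expect_equal(b$end[3], 25000)

  expect_equal(nrow(make_bins("chr17", 5000, 10000)), 1)
  expect_error(make_bins("chr17", 0, 10000), "positive")
})

test_that("average ploidy is the length-weighted mean over covered bases", {
  seg <- data.frame(chrom = "chrT", start = c(0, 5000),
                    end = c(5000, 10000), ploidy = c(2, 4))
  expect_equal(average_ploidy(seg, "chrT", 0, 10000), 3)

  one <- data.frame(chrom = "chrT", start = 0, end = 10000, ploidy = 3)
  expect_equal(average_ploidy(one, "chrT", 2000, 8000), 3)

  expect_true(is.na(average_ploidy(one, "chrT", 20000, 30000)))

  # uncovered bases excluded from the weighting unless imputed diploid
  part <- data.frame(chrom = "chrT", start = 0, end = 5000, ploidy = 4)
  expect_equal(average_ploidy(part, "chrT", 0, 10000), 4)
  expect_equal(average_ploidy(part, "chrT", 0, 10000,
                              impute_diploid = TRUE), 3)
})

test_that("average ploidy is invariant to splitting segments", {
  set.seed(11)
  for (i in 1:20) {
    bks <- sort(sample(1000:9000, 3))
    pl <- runif(4, 0, 5)
    seg <- data.frame(chrom = "chrT", start = c(0, bks),
                      end = c(bks, 10000), ploidy = pl)
    # split every segment at its midpoint, same ploidy
    mid <- floor((seg$start + seg$end) / 2)
    split <- rbind(
      data.frame(chrom = "chrT", start = seg$start, end = mid, ploidy = pl),
      data.frame(chrom = "chrT", start = mid, end = seg$end, ploidy = pl))
    q <- sort(sample(0:10000, 2))
    if (q[1] == q[2]) next
    expect_equal(average_ploidy(seg, "chrT", q[1], q[2]),
                 average_ploidy(split, "chrT", q[1], q[2]),
                 tolerance = 1e-12)
  }
})

test_that("ploidy classification partitions [0, Inf) with gain-first boundaries", {
  expect_equal(classify_ploidy(c(0, 0.5, 1, 1.5, 2, 2.999, 3, 4.2)),
               c("loss", "loss", "loss", "diploid", "diploid", "diploid",
                 "gain", "gain"))
  expect_error(classify_ploidy(-0.1), "negative")
  expect_true(is.na(classify_ploidy(NA_real_)))
  # total over a dense grid: every value classified
  expect_false(anyNA(classify_ploidy(seq(0, 10, by = 0.01))))
})

test_that("region status classifies the region average per sample", {
  seg <- hand_segments()
  region <- list(chrom = "chrT", start = 0, end = 30000)
  rs <- region_status(seg, region)
  expect_equal(rs$call[rs$sample == "A"], "diploid")

  # half ploidy 2, half ploidy 4 -> n = 3 -> gain (boundary rule)
  half <- data.frame(sample = "H", chrom = "chrT", start = c(0, 15000),
                     end = c(15000, 30000), ploidy = c(2, 4))
  rs <- region_status(half, region)
  expect_equal(rs$n, 3)
  expect_equal(rs$call, "gain")

  # uniform 3.5 -> gain
  g <- data.frame(sample = "G", chrom = "chrT", start = 0, end = 30000,
                  ploidy = 3.5)
  expect_equal(region_status(g, region)$call, "gain")

  # zero coverage -> NA with warning
  expect_warning(
    rs <- region_status(g, list(chrom = "chrX", start = 0, end = 1000)),
    "no coverage")
  expect_true(is.na(rs$call))
})

test_that("cohort frequency profile reproduces hand-computed fractions", {
  seg <- hand_segments()
  grid <- make_bins("chrT", 30000, 10000)
  prof <- cohort_frequency_profile(seg, grid)

  # bin 1 [0,10000): A=2 dip, B=2 dip, C=0.5 loss, D=1 loss (boundary)
  expect_equal(prof$f_loss[1], 0.5)
  expect_equal(prof$f_diploid[1], 0.5)
  expect_equal(prof$f_gain[1], 0)
  # bin 2 [10000,20000): B=3.5 gain among 4 covered
  expect_equal(prof$f_gain[2], 0.25)
  # bin 3 [20000,30000): C=3 gain (boundary n=3)
  expect_equal(prof$f_gain[3], 0.25)
  expect_equal(prof$f_diploid[3], 0.75)
  # fractions sum to 1 in every covered bin
  expect_equal(prof$f_loss + prof$f_diploid + prof$f_gain, rep(1, 3))

  # all-diploid cohort
  dd <- data.frame(sample = rep(c("X", "Y"), each = 1), chrom = "chrT",
                   start = 0, end = 30000, ploidy = 2)
  pd <- cohort_frequency_profile(dd, grid)
  expect_equal(pd$f_diploid, rep(1, 3))

  # masked bin emitted with missing frequencies
  pm <- cohort_frequency_profile(seg, grid,
                                 mask = data.frame(chrom = "chrT",
                                                   start = 10000,
                                                   end = 20000))
  expect_true(is.na(pm$f_gain[2]))
  expect_false(is.na(pm$f_gain[1]))
  expect_equal(nrow(pm), 3)
})

test_that("gene copy number averages ploidy over the gene interval", {
  seg <- data.frame(chrom = "chrT", start = c(0, 5000),
                    end = c(5000, 10000), ploidy = c(2, 4))
  gene_in <- list(chrom = "chrT", start = 1000, end = 3000)
  expect_equal(gene_copy_number(
    data.frame(chrom = "chrT", start = 0, end = 10000, ploidy = 3),
    gene_in), 3)
  # gene spanning the 2/4 breakpoint at its midpoint
  expect_equal(gene_copy_number(seg, list(chrom = "chrT", start = 4000,
                                          end = 6000)), 3)
  expect_true(is.na(gene_copy_number(seg, list(chrom = "chrT",
                                               start = 50000,
                                               end = 60000))))
})
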