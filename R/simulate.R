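# Synthetic-cohort and ChIP-fixture generators with planted ground truth.
#
# The generator emulates the statistical structure the screens assume:
# segmental ploidy profiles with a recurrent distal arm gain, NB counts
# with copy-number dosage and amplification effects, right-censored
# survival with expression-linked hazard, and multi-mark promoter peak
# sets with one planted co-occupied target.  Everything is deterministic
# given (config, seed).

#' Simulation configuration
#'
#' Defaults encode the cohort structure the screens assume: a recurrent
#' distal gain at 50% prevalence (within the 38-65% range reported for
#' 17q gain in neuroblastoma), MYCN amplification at 25% prevalence with a
#' 4-fold odds link to the gain, multiplicative copy-number dosage on NB
#' count means, one planted driver gene inside the gained region with an
#' amplification-linked expression boost (log2FC 1.5) and a planted
#' hazard ratio of 2.5 for driver-high patients.
#'
#' @param n_samples Cohort size (default 200).
#' @param n_genes Total genes simulated (default 400).
#' @param n_region_genes Genes inside the gained region (default 60).
#' @param p_gain Marginal prevalence of the region gain (default 0.5).
#' @param p_amp Marginal prevalence of MYCN amplification (default 0.25).
#' @param gain_amp_odds Odds multiplier linking amplification to gain
#'   (default 4; the marginal prevalences are preserved).
#' @param dosage_exponent Exponent `d` of the multiplicative dosage effect
#'   `(ploidy / 2)^d` on count means (default 1).
#' @param driver_amp_log2fc Planted amplification effect on the driver
#'   gene, in log2 units (default 1.5).
#' @param driver_hr Planted hazard ratio for driver-high patients
#'   (default 2.5).
#' @param dispersion NB dispersion alpha (default 0.1).
#' @param baseline_hazard Baseline hazard in events/day (default 1/1500).
#' @param censor_time Administrative censoring horizon in days
#'   (default 3000).
#' @param seed Integer seed; every generator call is deterministic given
#'   the config (default 1).
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_samples = 200, n_genes = 400, n_region_genes = 60,
                       p_gain = 0.5, p_amp = 0.25, gain_amp_odds = 4,
                       dosage_exponent = 1, driver_amp_log2fc = 1.5,
                       driver_hr = 2.5, dispersion = 0.1,
                       baseline_hazard = 1 / 1500, censor_time = 3000,
                       seed = 1L) {
  cfg <- list(n_samples = n_samples, n_genes = n_genes,
              n_region_genes = n_region_genes, p_gain = p_gain,
              p_amp = p_amp, gain_amp_odds = gain_amp_odds,
              dosage_exponent = dosage_exponent,
              driver_amp_log2fc = driver_amp_log2fc,
              driver_hr = driver_hr, dispersion = dispersion,
              baseline_hazard = baseline_hazard,
              censor_time = censor_time, seed = as.integer(seed))
  for (nm in c("p_gain", "p_amp"))
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1)
      .stop_fmt("sim_config: %s must be in [0, 1]", nm)
  for (nm in c("n_samples", "n_genes", "n_region_genes"))
    if (cfg[[nm]] < 1) .stop_fmt("sim_config: %s must be positive", nm)
  if (cfg$n_region_genes >= cfg$n_genes)
    .stop_fmt("sim_config: n_region_genes must be < n_genes")
  if (cfg$dispersion <= 0) .stop_fmt("sim_config: dispersion must be > 0")
  for (nm in c("gain_amp_odds", "driver_hr", "baseline_hazard",
               "censor_time"))
    if (cfg[[nm]] <= 0) .stop_fmt("sim_config: %s must be > 0", nm)
  class(cfg) <- "sim_config"
  cfg
}

# Toy genome used by the cohort generator: one 8-Mb chromosome named
# "chr17" whose distal 3 Mb is the recurrently gained region, plus a
# second chromosome "chr2" carrying the MYCN gene (focally amplified in
# amplified samples).  Scaled down from genome size for speed; the 10-kb
# binning convention is unchanged.
.sim_genome <- function() {
  list(chrom = "chr17", chrom_length = 8e6,
       region = list(chrom = "chr17", start = 5e6, end = 8e6),
       mycn_chrom = "chr2", mycn_chrom_length = 1e6,
       mycn_start = 4e5, mycn_end = 4.06e5)
}

# Gene models for the cohort: genes 2 kb wide, evenly spaced, alternating
# strand; region genes tile the gained region, the rest tile the proximal
# part; MYCN sits on chr2.
.sim_genes <- function(cfg) {
  g <- .sim_genome()
  n_out <- cfg$n_genes - cfg$n_region_genes
  gene_w <- 2000
  sp_out <- floor((g$region$start - gene_w) / max(n_out, 1))
  sp_in <- floor((g$region$end - g$region$start - gene_w) /
                   max(cfg$n_region_genes, 1))
  starts <- c(seq_len(n_out) - 1, rep(0, cfg$n_region_genes))
  starts[seq_len(n_out)] <- (seq_len(n_out) - 1) * sp_out
  inr <- seq_len(cfg$n_region_genes)
  starts[n_out + inr] <- g$region$start + (inr - 1) * sp_in
  ids <- sprintf("G%03d", seq_len(cfg$n_genes))
  strand <- rep(c("+", "-"), length.out = cfg$n_genes)
  df <- data.frame(gene_id = ids, chrom = g$chrom, start = starts,
                   end = starts + gene_w, strand = strand,
                   stringsAsFactors = FALSE)
  df <- rbind(df, data.frame(gene_id = "MYCN", chrom = g$mycn_chrom,
                             start = g$mycn_start, end = g$mycn_end,
                             strand = "+", stringsAsFactors = FALSE))
  df$tss <- ifelse(df$strand == "-", df$end - 1, df$start)
  df
}

# Joint gain/amplification labels: amplification is Bernoulli(p_amp); the
# gain odds are multiplied by gain_amp_odds in amplified samples, with the
# baseline odds solved so the marginal gain prevalence stays p_gain.
.sim_labels <- function(cfg) {
  amp <- rbinom(cfg$n_samples, 1, cfg$p_amp)
  if (cfg$p_gain == 0) return(list(amp = amp, gain = rep(0L, cfg$n_samples)))
  if (cfg$p_gain == 1) return(list(amp = amp, gain = rep(1L, cfg$n_samples)))
  if (cfg$gain_amp_odds == 1 || cfg$p_amp %in% c(0, 1)) {
    gain <- rbinom(cfg$n_samples, 1, cfg$p_gain)
  } else {
    f <- function(o0) {
      o1 <- cfg$gain_amp_odds * o0
      cfg$p_amp * o1 / (1 + o1) + (1 - cfg$p_amp) * o0 / (1 + o0) -
        cfg$p_gain
    }
    o0 <- uniroot(f, c(1e-9, 1e9))$root
    p <- ifelse(amp == 1,
                cfg$gain_amp_odds * o0 / (1 + cfg$gain_amp_odds * o0),
                o0 / (1 + o0))
    gain <- rbinom(cfg$n_samples, 1, p)
  }
  list(amp = amp, gain = as.integer(gain))
}

#' Simulate a synthetic neuroblastoma-like cohort
#'
#' Generates, deterministically for a given config (including its seed):
#' (i) joint region-gain / MYCN-amplification labels linked through
#' `gain_amp_odds`; (ii) per-sample segment profiles on a toy chromosome
#' -- diploid baseline ploidy ~ Normal(2, 0.1) truncated at 0, with the
#' distal region at Uniform(3, 4) in gained samples, and a focal
#' high-level MYCN segment in amplified samples; (iii) NB counts with mean
#' `s_i * mu_g * (ploidy_gi / 2)^d`, gene means `mu_g` ~ logNormal(log 100, 1),
#' size factors `s_i` ~ logNormal(0, 0.25); the MYCN gene mean is
#' multiplied by 2^2 in amplified samples and the driver gene additionally
#' by `2^driver_amp_log2fc`; (iv) exponential survival with hazard
#' `baseline_hazard * driver_hr^[driver expression above cohort median]`,
#' censored at `min(censor_time, Uniform(0, 2 * censor_time))`.
#'
#' @param config A [sim_config()].
#' @return An object of class `nb_cohort`: a list with elements
#'   `segments`, `counts`, `clinical`, `genes`, `region`, and `truth`
#'   (driver gene, planted labels and effect sizes).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  g <- .sim_genome()
  genes <- .sim_genes(config)
  n <- config$n_samples
  samples <- sprintf("S%03d", seq_len(n))
  lab <- .sim_labels(config)

  base_pl <- pmax(rnorm(n, 2, 0.1), 0)
  gain_pl <- runif(n, 3, 4)
  seg <- lapply(seq_len(n), function(i) {
    if (lab$gain[i] == 1) {
      s17 <- data.frame(sample = samples[i], chrom = g$chrom,
                        start = c(0, g$region$start),
                        end = c(g$region$start, g$chrom_length),
                        ploidy = c(base_pl[i], gain_pl[i]))
    } else {
      s17 <- data.frame(sample = samples[i], chrom = g$chrom, start = 0,
                        end = g$chrom_length, ploidy = base_pl[i])
    }
    if (lab$amp[i] == 1) {
      s2 <- data.frame(sample = samples[i], chrom = g$mycn_chrom,
                       start = c(0, g$mycn_start - 1e4,
                                 g$mycn_end + 1e4),
                       end = c(g$mycn_start - 1e4, g$mycn_end + 1e4,
                               g$mycn_chrom_length),
                       ploidy = c(base_pl[i], 30, base_pl[i]))
    } else {
      s2 <- data.frame(sample = samples[i], chrom = g$mycn_chrom,
                       start = 0, end = g$mycn_chrom_length,
                       ploidy = base_pl[i])
    }
    rbind(s17, s2)
  })
  segments <- do.call(rbind, seg)
  rownames(segments) <- NULL

  G <- config$n_genes
  region_gene <- genes$chrom == g$chrom & genes$start >= g$region$start
  driver_idx <- which(region_gene)[ceiling(sum(region_gene) / 2)]
  driver_gene <- genes$gene_id[driver_idx]

  # per-gene per-sample ploidy for the dosage effect (chr17 genes only;
  # MYCN expression effect is imposed directly below)
  pl <- matrix(rep(base_pl, each = G), G, n)
  if (any(lab$gain == 1))
    pl[region_gene[seq_len(G)], lab$gain == 1] <-
      matrix(rep(gain_pl[lab$gain == 1], each = sum(region_gene)),
             sum(region_gene), sum(lab$gain))

  mu_g <- rlnorm(G, log(100), 1)
  s_i <- rlnorm(n, 0, 0.25)
  s_i <- s_i / exp(mean(log(s_i)))
  M <- outer(mu_g, s_i) * (pl / 2)^config$dosage_exponent
  M[driver_idx, ] <- M[driver_idx, ] *
    2^(config$driver_amp_log2fc * lab$amp)
  mycn_mu <- 200 * s_i * 2^(2 * lab$amp)
  counts <- matrix(rnbinom(G * n, mu = M, size = 1 / config$dispersion),
                   G, n)
  counts <- rbind(counts,
                  rnbinom(n, mu = mycn_mu, size = 1 / config$dispersion))
  rownames(counts) <- genes$gene_id
  colnames(counts) <- samples
  storage.mode(counts) <- "integer"

  expr <- log_expression(counts)
  drv_high <- dichotomize_by_median(expr[driver_idx, ])
  hazard <- config$baseline_hazard * config$driver_hr^drv_high
  t_event <- rexp(n, hazard)
  t_cens <- pmin(config$censor_time, runif(n, 0, 2 * config$censor_time))
  os_time <- pmax(pmin(t_event, t_cens), 1)
  os_event <- as.integer(t_event <= t_cens)
  # event-free survival: the same event process observed with an earlier
  # progression fraction
  t_efs <- t_event * runif(n, 0.5, 1)
  efs_time <- pmax(pmin(t_efs, t_cens), 1)
  efs_event <- as.integer(t_efs <= t_cens)

  clinical <- data.frame(
    sample = samples, os_time = os_time, os_event = os_event,
    efs_time = efs_time, efs_event = efs_event,
    stage_advanced = rbinom(n, 1, pmin(0.9, 0.3 + 0.4 * lab$amp)),
    age_over_18m = rbinom(n, 1, 0.5),
    mycn_amplified = lab$amp, stringsAsFactors = FALSE)

  out <- list(segments = segments, counts = counts, clinical = clinical,
              genes = genes, region = g$region,
              truth = list(driver_gene = driver_gene, gain = lab$gain,
                           amp = lab$amp,
                           driver_amp_log2fc = config$driver_amp_log2fc,
                           driver_hr = config$driver_hr,
                           driver_high = drv_high,
                           region_genes = genes$gene_id[region_gene]),
              config = config)
  class(out) <- "nb_cohort"
  out
}

#' @export
print.nb_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d samples, %d genes (%d in %s:%d-%d), driver %s\n",
              ncol(x$counts), nrow(x$counts),
              length(x$truth$region_genes), x$region$chrom,
              x$region$start, x$region$end, x$truth$driver_gene))
  cat(sprintf("  region gain: %d samples; MYCN-amplified: %d samples\n",
              sum(x$truth$gain), sum(x$truth$amp)))
  invisible(x)
}

#' Write a synthetic cohort to a directory
#'
#' Writes `segments.tsv`, `counts.tsv`, `clinical.tsv`, `genes.gtf` and
#' `truth.json` in the package's file dialects.
#'
#' @param cohort An `nb_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_segments(cohort$segments, file.path(dir, "segments.tsv"))
  write_counts(cohort$counts, file.path(dir, "counts.tsv"))
  write_clinical(cohort$clinical, file.path(dir, "clinical.tsv"))
  write_gene_models(cohort$genes, file.path(dir, "genes.gtf"))
  truth <- cohort$truth
  truth$region <- cohort$region
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Simulate a ChIP-seq promoter-occupancy fixture
#'
#' Builds a toy chromosome with `n_genes` gene models and per-mark
#' narrowPeak-style peak sets for ALYREF, MYCN, RNA polymerase II, H3K27ac
#' and H3K4me3.  One planted target gene receives a peak from every mark
#' overlapping its promoter window (TSS -1000/+100) with ALYREF fold
#' enrichment drawn Uniform(5.5, 10); decoy genes receive either the full
#' mark set with ALYREF FE drawn Uniform(1, 5) or an incomplete mark
#' combination.  A matched expression/survival cohort is generated in
#' which the planted target plays the driver role (so it passes the
#' survival and MYCN-correlation criteria), and the gene-set file contains
#' the target plus random decoys.
#'
#' @param config A [sim_config()]; `n_genes`, `n_samples`, the driver
#'   effect sizes and the NB parameters are reused.
#' @return A list with elements `peaks` (named list of peak `data.frame`s
#'   for marks `alyref`, `mycn`, `polii`, `h3k27ac`, `h3k4me3`), `genes`,
#'   `gene_set`, `cohort` (an `nb_cohort`-like expression/clinical
#'   bundle), and `truth` (planted target, per-gene mark completeness and
#'   FE).
#' @export
simulate_chip_fixture <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1000003L)
  G <- config$n_genes
  gene_w <- 2000; spacing <- 10000
  starts <- (seq_len(G) - 1) * spacing + 5000
  genes <- data.frame(gene_id = sprintf("T%03d", seq_len(G)),
                      chrom = "chrS", start = starts,
                      end = starts + gene_w,
                      strand = rep(c("+", "-"), length.out = G),
                      stringsAsFactors = FALSE)
  genes$tss <- ifelse(genes$strand == "-", genes$end - 1, genes$start)

  target_idx <- ceiling(G / 2)
  target <- genes$gene_id[target_idx]
  marks <- c("alyref", "mycn", "polii", "h3k27ac", "h3k4me3")

  # decoy classes: full marks with sub-threshold ALYREF FE, or an
  # incomplete mark combination
  full_marks <- rep(FALSE, G)
  full_marks[target_idx] <- TRUE
  decoys <- setdiff(seq_len(G), target_idx)
  complete_decoys <- sample(decoys, floor(length(decoys) / 2))
  full_marks[complete_decoys] <- TRUE
  fe <- rep(NA_real_, G)
  fe[target_idx] <- runif(1, 5.5, 10)
  fe[decoys] <- runif(length(decoys), 1, 5)

  win <- promoter_windows(genes)
  peak_at <- function(i, fe_val, mark, j) {
    centre <- floor((win$start[i] + win$end[i]) / 2)
    data.frame(chrom = "chrS", start = centre - 150, end = centre + 150,
               name = sprintf("%s_p%d", mark, j), score = 0,
               strand = ".", fold_enrichment = fe_val,
               pvalue = 5, qvalue = 4, summit_offset = 150,
               stringsAsFactors = FALSE)
  }
  present <- matrix(FALSE, G, length(marks),
                    dimnames = list(genes$gene_id, marks))
  present[target_idx, ] <- TRUE
  present[complete_decoys, ] <- TRUE
  incomplete <- setdiff(decoys, complete_decoys)
  for (i in incomplete) {
    keep <- sample(marks, sample(0:4, 1))
    present[i, keep] <- TRUE
  }
  peaks <- lapply(marks, function(mk) {
    idx <- which(present[, mk])
    if (length(idx) == 0) return(.empty_peaks())
    do.call(rbind, lapply(seq_along(idx), function(j) {
      i <- idx[j]
      fv <- if (mk == "alyref") fe[i] else runif(1, 2, 20)
      peak_at(i, fv, mk, j)
    }))
  })
  names(peaks) <- marks

  # matched expression/survival cohort in which the planted target is the
  # prognostic, amplification-linked gene
  n <- config$n_samples
  samples <- sprintf("S%03d", seq_len(n))
  amp <- rbinom(n, 1, config$p_amp)
  mu_g <- rlnorm(G, log(100), 1)
  s_i <- rlnorm(n, 0, 0.25)
  s_i <- s_i / exp(mean(log(s_i)))
  M <- outer(mu_g, s_i)
  M[target_idx, ] <- M[target_idx, ] * 2^(config$driver_amp_log2fc * amp)
  counts <- matrix(rnbinom(G * n, mu = M, size = 1 / config$dispersion),
                   G, n)
  counts <- rbind(counts, rnbinom(n, mu = 200 * s_i * 2^(2 * amp),
                                  size = 1 / config$dispersion))
  rownames(counts) <- c(genes$gene_id, "MYCN")
  colnames(counts) <- samples
  storage.mode(counts) <- "integer"
  expr <- log_expression(counts)
  hi <- dichotomize_by_median(expr[target_idx, ])
  t_event <- rexp(n, config$baseline_hazard * config$driver_hr^hi)
  t_cens <- pmin(config$censor_time, runif(n, 0, 2 * config$censor_time))
  t_efs <- t_event * runif(n, 0.5, 1)
  clinical <- data.frame(
    sample = samples,
    os_time = pmax(pmin(t_event, t_cens), 1),
    os_event = as.integer(t_event <= t_cens),
    efs_time = pmax(pmin(t_efs, t_cens), 1),
    efs_event = as.integer(t_efs <= t_cens),
    stage_advanced = rbinom(n, 1, 0.5),
    age_over_18m = rbinom(n, 1, 0.5),
    mycn_amplified = amp, stringsAsFactors = FALSE)

  gene_set <- c(target, sample(genes$gene_id[-target_idx], 20))

  list(peaks = peaks, genes = genes, gene_set = sort(gene_set),
       cohort = list(counts = counts, clinical = clinical),
       truth = list(target_gene = target, target_fe = fe[target_idx],
                    marks_present = present, alyref_fe = fe))
}

#' Write a ChIP fixture to a directory
#'
#' Writes one narrowPeak file per mark, `genes.gtf`, `gene_set.txt`,
#' `counts.tsv`, `clinical.tsv` and `truth.json`.
#'
#' @param fixture Result of [simulate_chip_fixture()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_chip_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (mk in names(fixture$peaks))
    write_narrowpeak(fixture$peaks[[mk]],
                     file.path(dir, sprintf("%s.narrowPeak", mk)))
  write_gene_models(fixture$genes, file.path(dir, "genes.gtf"))
  writeLines(fixture$gene_set, file.path(dir, "gene_set.txt"))
  write_counts(fixture$cohort$counts, file.path(dir, "counts.tsv"))
  write_clinical(fixture$cohort$clinical, file.path(dir, "clinical.tsv"))
  truth <- fixture$truth
  truth$marks_present <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
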