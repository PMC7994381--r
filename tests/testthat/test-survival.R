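# independent oracle: log-rank by direct tabulation at each event time
brute_logrank <- function(times, events, groups) {
  g <- as.integer(groups)
  ts <- sort(unique(times[events == 1]))
  OmE <- 0; V <- 0
  for (t in ts) {
    at <- times >= t
    n <- sum(at); n1 <- sum(at & g == 1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & g == 1)
    OmE <- OmE + d1 - d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  OmE^2 / V
}

test_that("the product-limit estimator matches hand computation", {
  # no events -> S = 1 everywhere
  km <- km_estimate(c(3, 5, 8), c(0, 0, 0))
  expect_equal(km$survival, rep(1, 3))

  # one death among four at t = 5 -> S(5) = 3/4
  km <- km_estimate(c(5, 6, 7, 8), c(1, 0, 0, 0))
  expect_equal(km_survival_at(km, 5), 0.75)

  # hand product-limit: times (2,4,6,8), events (1,1,0,1)
  km <- km_estimate(c(2, 4, 6, 8), c(1, 1, 0, 1))
  expect_equal(km_survival_at(km, c(2, 4, 6, 8)), c(0.75, 0.5, 0.5, 0))
  expect_equal(km_survival_at(km, 1), 1)

  expect_error(km_estimate(numeric(0), numeric(0)), "empty")
})

test_that("without censoring the KM curve equals the empirical survival fraction", {
  set.seed(41)
  for (i in 1:10) {
    t <- rexp(sample(10:80, 1), 1 / 100)
    km <- km_estimate(t, rep(1, length(t)))
    qs <- sort(t)
    emp <- vapply(qs, function(q) mean(t > q), numeric(1))
    expect_equal(km_survival_at(km, qs), emp, tolerance = 1e-12)
  }
})

test_that("the log-rank test matches the observed-minus-expected tabulation", {
  # identical groups -> statistic 0, p = 1
  t <- c(1, 2, 3, 1, 2, 3); e <- c(1, 1, 0, 1, 1, 0)
  g <- c(0, 0, 0, 1, 1, 1)
  lr <- logrank_test(t, e, g)
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1, tolerance = 1e-12)

  # label swap leaves the test invariant
  t2 <- c(2, 4, 5, 7, 9, 12); e2 <- c(1, 1, 0, 1, 1, 1)
  g2 <- c(0, 1, 0, 1, 0, 1)
  a <- logrank_test(t2, e2, g2)
  b <- logrank_test(t2, e2, 1 - g2)
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)

  # six-subject fixture against the hand tabulation
  expect_equal(a$statistic, brute_logrank(t2, e2, g2), tolerance = 1e-10)

  set.seed(42)
  for (i in 1:10) {
    n <- sample(8:40, 1)
    t <- round(rexp(n, 1 / 50)) + 1
    e <- rbinom(n, 1, 0.7)
    g <- rbinom(n, 1, 0.5)
    if (length(unique(g)) < 2 || sum(e) == 0) next
    expect_equal(logrank_test(t, e, g)$statistic, brute_logrank(t, e, g),
                 tolerance = 1e-10)
  }

  expect_error(logrank_test(t2, e2, rep(0, 6)), "non-empty")
})

test_that("Cox fits recover planted hazard ratios and respect rank invariance", {
  set.seed(43)
  n <- 500
  x <- rbinom(n, 1, 0.5)
  t <- rexp(n, (1 / 100) * 2^x)
  cens <- runif(n, 0, 300)
  time <- pmin(t, cens); ev <- as.integer(t <= cens)
  fit <- cox_fit(x, time, ev)
  expect_true(fit$converged)
  expect_gt(unname(fit$hr[1]), 1.7)
  expect_lt(unname(fit$hr[1]), 2.35)

  # null covariate: beta within 3 SE of 0
  z <- rnorm(n)
  fit0 <- cox_fit(z, time, ev)
  expect_lt(abs(unname(fit0$coefficients[1])),
            3 * unname(fit0$se[1]))

  # rescaling time leaves the partial likelihood (and beta) unchanged
  fit2 <- cox_fit(x, time * 37.5, ev)
  expect_equal(unname(fit$coefficients), unname(fit2$coefficients),
               tolerance = 1e-8)

  expect_error(cox_fit(rep(1, n), time, ev), "constant")
})

test_that("the log-rank statistic equals the Cox score test for a binary covariate", {
  set.seed(44)
  n <- 80
  x <- rbinom(n, 1, 0.5)
  t <- rexp(n, (1 / 50) * 1.8^x)
  ev <- rbinom(n, 1, 0.8)
  lr <- logrank_test(t, ev, x)
  cf <- cox_fit(x, t, ev)
  expect_equal(lr$p, cf$logrank_p, tolerance = 1e-6)
})

test_that("median dichotomisation assigns ties to the low group", {
  expect_equal(dichotomize_by_median(c(1, 2, 3, 4)), c(0, 0, 1, 1))
  expect_equal(dichotomize_by_median(c(1, 2, 3)), c(0, 0, 1))  # median -> low
  expect_equal(dichotomize_by_median(rep(2, 5)), rep(0, 5))
  expect_error(dichotomize_by_median(1), "at least 2")
})

test_that("the survival filter requires HR > 1 and log-rank significance", {
  set.seed(45)
  n <- 300
  risk <- rnorm(n)
  harmful <- risk + rnorm(n, sd = 0.3)
  protective <- -risk + rnorm(n, sd = 0.3)
  t <- rexp(n, (1 / 100) * 2.5^(risk > median(risk)))
  cens <- runif(n, 0, 300)
  clinical <- data.frame(sample = sprintf("s%03d", 1:n),
                         os_time = pmin(t, cens) + 0.001,
                         os_event = as.integer(t <= cens),
                         efs_time = pmin(t, cens) + 0.001,
                         efs_event = as.integer(t <= cens),
                         stage_advanced = 0L, age_over_18m = 0L,
                         mycn_amplified = 0L)
  expr <- rbind(harmful = harmful, protective = protective,
                flat = rep(1, n))
  colnames(expr) <- clinical$sample
  expect_warning(res <- survival_filter(expr, clinical), "degenerate")
  expect_true(res$passes[res$gene_id == "harmful"])
  # protective: small p but HR < 1 -> fails
  expect_lt(res$logrank_p[res$gene_id == "protective"], 0.05)
  expect_false(res$passes[res$gene_id == "protective"])
  expect_false(res$passes[res$gene_id == "flat"])
  expect_true(is.na(res$hr[res$gene_id == "flat"]))
})

test_that("multivariate and additive Cox models behave as designed", {
  set.seed(46)
  n <- 400
  conf <- rbinom(n, 1, 0.5)              # mediating covariate
  gene <- as.integer(runif(n) < 0.15 + 0.7 * conf)
  t <- rexp(n, (1 / 100) * 3^conf)       # hazard acts through conf only
  cens <- runif(n, 0, 400)
  clinical <- data.frame(sample = sprintf("s%03d", 1:n),
                         os_time = pmin(t, cens) + 0.001,
                         os_event = as.integer(t <= cens),
                         efs_time = pmin(t, cens) + 0.001,
                         efs_event = as.integer(t <= cens),
                         stage_advanced = conf,
                         age_over_18m = rbinom(n, 1, 0.5),
                         mycn_amplified = rbinom(n, 1, 0.25))

  # empty covariate set reduces to the univariate fit
  uni <- cox_fit(cbind(gene = gene), clinical$os_time, clinical$os_event)
  mv0 <- multivariate_cox(gene, clinical, covariates = character(0))
  expect_equal(unname(coef(uni$fit)), unname(mv0$coefficients["gene"]),
               tolerance = 1e-10)

  # gene effect mediated by stage: gene HR attenuates toward 1
  mv <- multivariate_cox(gene, clinical, covariates = "stage_advanced")
  expect_lt(unname(mv$hr["gene"]), unname(uni$hr["gene"]))

  att <- additive_cox_attenuation(gene, clinical)
  expect_equal(nrow(att), 3)
  expect_equal(sort(att$covariate),
               sort(c("stage_advanced", "age_over_18m", "mycn_amplified")))
  # the planted confounder has the greatest |delta HR|
  expect_equal(att$covariate[att$rank == 1], "stage_advanced")

  # independent covariates leave the gene HR essentially unchanged
  set.seed(47)
  gene2 <- rbinom(n, 1, 0.5)
  t2 <- rexp(n, (1 / 100) * 2^gene2)
  clinical2 <- clinical
  clinical2$os_time <- pmin(t2, cens) + 0.001
  clinical2$os_event <- as.integer(t2 <= cens)
  clinical2$stage_advanced <- rbinom(n, 1, 0.5)
  att2 <- additive_cox_attenuation(gene2, clinical2)
  expect_lt(max(abs(att2$delta_hr)), 0.25)
})
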