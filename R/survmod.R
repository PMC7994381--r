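# Survival machinery: Kaplan-Meier estimation, log-rank testing, Cox
# proportional-hazards fitting (Breslow ties), median dichotomisation, the
# univariate HR/log-rank gene filter, and multivariate/additive models.
# Model fitting is delegated to the survival package; this module fixes
# the conventions (ties, endpoints, tie rule at the median) and the filter
# logic.

#' @importFrom survival Surv coxph survfit survdiff coxph.control
NULL

.endpoint_cols <- function(endpoint = c("os", "efs")) {
  endpoint <- match.arg(endpoint)
  if (endpoint == "os") c("os_time", "os_event") else c("efs_time", "efs_event")
}

#' Kaplan-Meier estimate
#'
#' Product-limit estimator of the survival function under right censoring.
#'
#' @param times Positive follow-up times.
#' @param events Event indicators (1 = event, 0 = censored).
#' @return An object of class `km_curve`: a `data.frame` with columns
#'   `time`, `n_risk`, `n_event`, `n_censor`, `survival` at every distinct
#'   observed time.
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0) .stop_fmt("km_estimate: empty input")
  if (any(times <= 0)) .stop_fmt("km_estimate: times must be positive")
  fit <- survfit(Surv(times, events) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    survival = fit$surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' Right-continuous step-function evaluation; S(t) = 1 before the first
#' event.
#'
#' @param curve A `km_curve` from [km_estimate()].
#' @param times Times at which to evaluate the curve.
#' @return Numeric vector of survival probabilities.
#' @export
km_survival_at <- function(curve, times) {
  vapply(times, function(t) {
    i <- which(curve$time <= t)
    if (length(i) == 0) 1 else curve$survival[max(i)]
  }, numeric(1))
}

#' Plot a Kaplan-Meier curve
#'
#' @param x A `km_curve` object.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.km_curve <- function(x, ...) {
  graphics::plot(c(0, x$time), c(1, x$survival), type = "s",
                 ylim = c(0, 1), xlab = "time (days)",
                 ylab = "survival probability", ...)
  invisible(x)
}

#' Two-group log-rank test
#'
#' Observed-minus-expected chi-squared statistic on 1 degree of freedom
#' with a two-sided p-value.
#'
#' @param times Positive follow-up times.
#' @param events Event indicators (1 = event, 0 = censored).
#' @param groups Binary group labels.
#' @return A list with elements `statistic` and `p`.
#' @export
logrank_test <- function(times, events, groups) {
  g <- as.integer(as.factor(groups))
  if (length(unique(g)) != 2)
    .stop_fmt("logrank_test: both groups must be non-empty")
  sd <- survdiff(Surv(times, events) ~ g)
  list(statistic = unname(sd$chisq),
       p = pchisq(unname(sd$chisq), df = 1, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Maximises the Breslow partial likelihood (Newton-Raphson, convergence
#' tolerance 1e-9, at most 25 iterations) and reports per-covariate
#' coefficients, standard errors from the observed information, hazard
#' ratios and two-sided Wald p-values, plus the model score (log-rank)
#' test p-value.  Non-convergent or degenerate fits (e.g. monotone
#' likelihood under complete separation) are flagged `converged = FALSE`
#' with a warning so callers can exclude them.
#'
#' @param covariates Numeric vector or matrix (samples x covariates).
#' @param times Positive follow-up times.
#' @param events Event indicators.
#' @return An object of class `cox_fit`: a list with `coefficients`, `se`,
#'   `hr`, `wald_p`, `logrank_p`, `converged`, `iterations`, and the
#'   underlying `coxph` fit in `$fit`.
#' @export
cox_fit <- function(covariates, times, events) {
  x <- as.matrix(covariates)
  if (is.null(colnames(x)))
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  const <- apply(x, 2, function(v) length(unique(v)) < 2)
  if (any(const))
    .stop_fmt("cox_fit: covariate(s) constant across subjects: %s",
              paste(colnames(x)[const], collapse = ", "))
  dat <- data.frame(.time = times, .event = events, x, check.names = FALSE)
  fml <- stats::as.formula(paste("Surv(.time, .event) ~",
                                 paste(sprintf("`%s`", colnames(x)),
                                       collapse = " + ")))
  warned <- FALSE
  fit <- withCallingHandlers(
    coxph(fml, data = dat, ties = "breslow",
          control = coxph.control(eps = 1e-9, iter.max = 25)),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)
  beta <- coef(fit)
  se <- sqrt(diag(fit$var))
  converged <- !warned && all(is.finite(beta)) && all(is.finite(se)) &&
    all(abs(beta) < 20)
  if (!converged)
    warning("cox_fit: fit flagged non-convergent or degenerate",
            call. = FALSE)
  out <- list(coefficients = beta, se = setNames(se, names(beta)),
              hr = exp(beta),
              wald_p = pchisq((beta / se)^2, df = 1, lower.tail = FALSE),
              logrank_p = unname(sm$sctest["pvalue"]),
              converged = converged, iterations = fit$iter, fit = fit)
  class(out) <- "cox_fit"
  out
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox proportional-hazards fit (Breslow ties, %d iteration%s%s)\n",
              x$iterations, if (x$iterations == 1) "" else "s",
              if (x$converged) "" else "; NOT converged"))
  tab <- data.frame(coef = x$coefficients, se = x$se, HR = x$hr,
                    wald_p = x$wald_p)
  print(tab, ...)
  cat(sprintf("Score (log-rank) test p = %.4g\n", x$logrank_p))
  invisible(x)
}

#' Dichotomise expression at the cohort median
#'
#' High = value strictly above the median; values equal to the median
#' (ties) are assigned to the low group.
#'
#' @param x Numeric per-sample values (at least 2).
#' @return Integer vector, 1 = high, 0 = low.
#' @export
dichotomize_by_median <- function(x) {
  if (length(x) < 2)
    .stop_fmt("dichotomize_by_median: need at least 2 samples")
  as.integer(x > median(x))
}

#' Univariate survival filter over genes
#'
#' For each gene: dichotomise expression at the median, fit a univariate
#' Cox model on the high/low label and run a two-group log-rank test.  A
#' gene passes with hazard ratio > 1 and log-rank p < 0.05.  Genes with a
#' degenerate dichotomisation (all samples in one group) are skipped with
#' a warning.
#'
#' @param expr Numeric matrix (genes x samples) of expression values,
#'   typically `log2(normalised count + 1)`.
#' @param clinical Clinical `data.frame` aligned to the columns of `expr`
#'   (matched by the `sample` column).
#' @param endpoint `"os"` (overall survival, default) or `"efs"`
#'   (event-free survival).
#' @param alpha Log-rank significance threshold (default 0.05).
#' @return A `data.frame` with columns `gene_id`, `hr`, `logrank_p`,
#'   `wald_p`, `passes` (`NA` evidence for skipped genes, which fail).
#' @export
survival_filter <- function(expr, clinical, endpoint = "os", alpha = 0.05) {
  idx <- match(colnames(expr), clinical$sample)
  if (anyNA(idx))
    .stop_fmt("survival_filter: samples missing from clinical table: %s",
              paste(colnames(expr)[is.na(idx)][1:3], collapse = ", "))
  cl <- clinical[idx, ]
  ec <- .endpoint_cols(endpoint)
  times <- cl[[ec[1]]]; events <- cl[[ec[2]]]
  res <- lapply(seq_len(nrow(expr)), function(i) {
    hi <- dichotomize_by_median(expr[i, ])
    if (length(unique(hi)) < 2)
      return(c(NA_real_, NA_real_, NA_real_))
    cf <- suppressWarnings(cox_fit(hi, times, events))
    lr <- logrank_test(times, events, hi)
    c(unname(cf$hr[1]), lr$p, unname(cf$wald_p[1]))
  })
  res <- do.call(rbind, res)
  skipped <- is.na(res[, 1])
  if (any(skipped))
    warning(sprintf("survival_filter: %d gene(s) with degenerate median split skipped",
                    sum(skipped)), call. = FALSE)
  data.frame(gene_id = rownames(expr), hr = res[, 1], logrank_p = res[, 2],
             wald_p = res[, 3],
             passes = !is.na(res[, 1]) & res[, 1] > 1 &
               !is.na(res[, 2]) & res[, 2] < alpha,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Multivariate Cox model for a gene label plus clinical covariates
#'
#' Joint fit of the gene high/low label and any subset of the prognostic
#' covariates (advanced stage, age over 18 months, MYCN amplification);
#' with an empty covariate set this reduces to the univariate fit.  The
#' attribute `gene_significant` records whether the gene term retains
#' Wald p < 0.05 (independent prognostic significance).
#'
#' @param gene_label Binary per-sample label (e.g. from
#'   [dichotomize_by_median()]), aligned to `clinical` rows.
#' @param clinical Clinical `data.frame`.
#' @param covariates Character subset of `c("stage_advanced",
#'   "age_over_18m", "mycn_amplified")`.
#' @param endpoint `"os"` or `"efs"`.
#' @return A `cox_fit` with the gene term named `gene`, plus attribute
#'   `gene_significant`.
#' @export
multivariate_cox <- function(gene_label, clinical,
                             covariates = c("stage_advanced",
                                            "age_over_18m",
                                            "mycn_amplified"),
                             endpoint = "os") {
  covariates <- intersect(covariates,
                          c("stage_advanced", "age_over_18m",
                            "mycn_amplified"))
  ec <- .endpoint_cols(endpoint)
  x <- cbind(gene = gene_label)
  for (cv in covariates) x <- cbind(x, clinical[[cv]])
  colnames(x) <- c("gene", covariates)
  fit <- cox_fit(x, clinical[[ec[1]]], clinical[[ec[2]]])
  attr(fit, "gene_significant") <- unname(fit$wald_p["gene"] < 0.05)
  fit
}

#' Additive Cox attenuation analysis
#'
#' For each clinical covariate, fits the two-covariate model
#' (gene + covariate) and reports the gene hazard ratio, its Wald p-value,
#' and the change in gene HR relative to the univariate model.  Covariates
#' are ranked by |delta HR|: the top-ranked covariates are those with the
#' greatest impact on the gene's prognostic significance.
#'
#' @inheritParams multivariate_cox
#' @return A `data.frame` with one row per covariate: `covariate`,
#'   `gene_hr`, `gene_p`, `delta_hr`, `rank`, ordered by rank; the
#'   univariate gene HR is in attribute `univariate_hr`.
#' @export
additive_cox_attenuation <- function(gene_label, clinical,
                                     covariates = c("stage_advanced",
                                                    "age_over_18m",
                                                    "mycn_amplified"),
                                     endpoint = "os") {
  ec <- .endpoint_cols(endpoint)
  uni <- cox_fit(cbind(gene = gene_label), clinical[[ec[1]]],
                 clinical[[ec[2]]])
  uni_hr <- unname(uni$hr["gene"])
  rows <- lapply(covariates, function(cv) {
    fit <- multivariate_cox(gene_label, clinical, covariates = cv,
                            endpoint = endpoint)
    data.frame(covariate = cv, gene_hr = unname(fit$hr["gene"]),
               gene_p = unname(fit$wald_p["gene"]),
               delta_hr = unname(fit$hr["gene"]) - uni_hr,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$rank <- rank(-abs(out$delta_hr), ties.method = "first")
  out <- out[order(out$rank), ]
  rownames(out) <- NULL
  attr(out, "univariate_hr") <- uni_hr
  out
}
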