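#' @include stability.R
#' @importFrom survival Surv coxph survfit survdiff ridge
NULL

#' Survival validation of a gene signature by risk stratification
#'
#' External check of a selected signature against follow-up data: a Cox
#' proportional-hazards model is fitted on the signature genes over the
#' tumor samples (Breslow tie handling; an optional small ridge penalty
#' stabilizes wide or collinear signatures), samples are dichotomized at
#' the median of the fitted relative risk `exp(X beta)` (the exact-median
#' sample goes to the low-risk group), Kaplan-Meier curves are estimated
#' per group, and the two-group log-rank test is computed against the
#' chi-squared(1) reference.
#'
#' @param x tumor-only [ExpressionDataset-class] (normal samples, if
#'   present, are dropped with a message).
#' @param surv a [SurvivalTable-class] covering the tumor samples.
#' @param signature character vector of gene ids, all present in `x`.
#' @param ridgeEps ridge penalty on the Cox fit (default 1e-4; 0 forces
#'   the unpenalized fit).
#' @return a [RiskStratification-class].
#' @export
stratifyAndTest <- function(x, surv, signature, ridgeEps = 1e-4) {
  stopifnot(is(x, "ExpressionDataset"), is(surv, "SurvivalTable"),
            ridgeEps >= 0)
  if (!length(signature)) stop("empty signature")
  missing <- setdiff(signature, geneIds(x))
  if (length(missing))
    stop("signature genes absent from dataset: ",
         paste(missing, collapse = ", "))
  lab <- sampleLabels(x)
  if (any(lab == 0L)) {
    message("dropping ", sum(lab == 0L), " normal sample(s)")
    x <- new("ExpressionDataset", x[, lab == 1L])
  }
  ids <- intersect(sampleIds(x), sampleIds(surv))
  if (length(ids) < 4) stop("fewer than 4 samples with survival data")
  time <- survTime(surv)[ids]
  event <- survEvent(surv)[ids]
  if (sum(event) < 2) stop("need at least 2 observed events")
  X <- designMatrix(x)[ids, signature, drop = FALSE]

  fit <- if (ridgeEps > 0) {
    survival::coxph(survival::Surv(time, event) ~
                      survival::ridge(X, theta = ridgeEps, scale = FALSE),
                    ties = "breslow")
  } else {
    survival::coxph(survival::Surv(time, event) ~ X, ties = "breslow")
  }
  beta <- stats::setNames(as.numeric(stats::coef(fit)), signature)
  lp <- drop(X %*% beta)
  rr <- exp(lp)
  group <- ifelse(rr > stats::median(rr), "high", "low") # median ties to low
  if (length(unique(group)) < 2)
    stop("risk scores are constant; cannot form two groups")

  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  stat <- sd$chisq
  pval <- stats::pchisq(stat, df = 1, lower.tail = FALSE)

  sf <- survival::survfit(survival::Surv(time, event) ~ group)
  strata <- rep(sub("^group=", "", names(sf$strata)), sf$strata)
  km <- data.frame(group = strata, time = sf$time, survival = sf$surv,
                   n_at_risk = sf$n.risk)

  new("RiskStratification",
      riskTable = data.frame(sample_id = ids, relative_risk = rr,
                             group = group, row.names = NULL),
      kmCurves = km, logrankStat = stat, logrankP = pval,
      coxCoefficients = beta)
}

#' @describeIn stratifyAndTest risk table accessor.
#' @param x a [RiskStratification-class].
#' @export
riskTable <- function(x) { stopifnot(is(x, "RiskStratification")); x@riskTable }

#' @describeIn stratifyAndTest Kaplan-Meier curves accessor.
#' @export
kmCurves <- function(x) { stopifnot(is(x, "RiskStratification")); x@kmCurves }

#' @describeIn stratifyAndTest log-rank chi-squared statistic and p-value.
#' @export
logrankTest <- function(x) {
  stopifnot(is(x, "RiskStratification"))
  c(statistic = x@logrankStat, df = 1, p = x@logrankP)
}

setMethod("show", "RiskStratification", function(object) {
  tab <- table(object@riskTable$group)
  cat("RiskStratification: ", nrow(object@riskTable), " samples (",
      tab[["high"]], " high / ", tab[["low"]], " low risk); log-rank chisq=",
      signif(object@logrankStat, 4), ", p=", signif(object@logrankP, 4),
      "\n", sep = "")
})

#' Write a RiskStratification to a directory
#'
#' Emits `risk.tsv` (sample, relative risk, group), `km.tsv` (per-group
#' survival curves) and `logrank.txt` (statistic, df, p).
#'
#' @param x a [RiskStratification-class].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
writeRiskStratification <- function(x, dir) {
  stopifnot(is(x, "RiskStratification"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(x@riskTable, file.path(dir, "risk.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(x@kmCurves, file.path(dir, "km.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(sprintf("statistic\t%.10g\ndf\t1\np\t%.10g",
                     x@logrankStat, x@logrankP),
             file.path(dir, "logrank.txt"))
  invisible(dir)
}
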