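#' @include correlation.R
#' @useDynLib twiner, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Construct a PenaltySpec
#'
#' @param alpha lasso-ridge mix in \[0, 1\] (default 0.9, mostly lasso).
#' @param lambda positive shrinkage parameter; a single value, a
#'   descending path, or empty to be chosen by [cvLambda()].
#' @param weights per-gene penalty factors (ideally named by gene id);
#'   empty means unit weights, i.e. the plain elastic net.
#' @return a [PenaltySpec-class].
#' @export
PenaltySpec <- function(alpha = 0.9, lambda = numeric(0),
                        weights = numeric(0)) {
  new("PenaltySpec", alpha = as.numeric(alpha), lambda = as.numeric(lambda),
      weights = if (is(weights, "TwinerWeights")) weightVector(weights)
                else as.numeric(stats::setNames(weights, names(weights))))
}

setMethod("show", "PenaltySpec", function(object) {
  cat("PenaltySpec: alpha=", object@alpha, ", ",
      if (length(object@lambda) == 0) "lambda unset"
      else if (length(object@lambda) == 1)
        paste0("lambda=", signif(object@lambda, 4))
      else paste0("lambda path of ", length(object@lambda)),
      ", ", if (length(object@weights)) "per-gene weights" else "unit weights",
      "\n", sep = "")
})

# align penalty weights to the dataset's genes; empty weights = unit
.align_weights <- function(penalty, gene_ids) {
  w <- penalty@weights
  if (!length(w)) return(rep(1, length(gene_ids)))
  if (!is.null(names(w))) {
    if (!all(gene_ids %in% names(w)))
      stop("penalty weights lack genes: ",
           paste(utils::head(setdiff(gene_ids, names(w)), 5L), collapse = ", "))
    w <- w[gene_ids]
  } else if (length(w) != length(gene_ids)) {
    stop("unnamed penalty weights must match the number of genes")
  }
  unname(w)
}

.design_and_labels <- function(x) {
  X <- designMatrix(x)
  y <- as.numeric(sampleLabels(x))
  if (length(unique(y)) < 2) stop("both classes must be present")
  list(X = X, y = y)
}

#' Smallest lambda shrinking every penalized coefficient to zero
#'
#' Computed from the Karush-Kuhn-Tucker threshold at the null model
#' (intercept = logit of the prevalence): `max_j |g_j| / (alpha * w_j)`
#' over genes with positive weight, where g_j is the per-sample score of
#' gene j.
#'
#' @param x an [ExpressionDataset-class] with standardized features.
#' @param penalty a [PenaltySpec-class] with `alpha > 0`.
#' @return positive scalar lambda_max.
#' @export
lambdaMax <- function(x, penalty) {
  stopifnot(is(penalty, "PenaltySpec"))
  if (penalty@alpha <= 0)
    stop("the lambda path requires alpha > 0 (some lasso component)")
  dl <- .design_and_labels(x)
  w <- .align_weights(penalty, geneIds(x))
  g <- as.numeric(crossprod(dl$X, dl$y - mean(dl$y))) / nrow(dl$X)
  pos <- w > 0
  if (!any(pos)) stop("all penalty weights are zero; no finite lambda_max")
  max(abs(g[pos]) / (penalty@alpha * w[pos]))
}

#' Log-spaced descending lambda path
#'
#' @param lambda_max largest lambda (typically from [lambdaMax()]).
#' @param nlambda number of values (default 100).
#' @param lambdaMinRatio smallest lambda as a fraction of `lambda_max`
#'   (default 1e-3).
#' @return descending numeric vector of length `nlambda`.
#' @export
lambdaPath <- function(lambda_max, nlambda = 100, lambdaMinRatio = 1e-3) {
  stopifnot(lambda_max > 0, nlambda >= 1, lambdaMinRatio > 0,
            lambdaMinRatio < 1)
  exp(seq(log(lambda_max), log(lambda_max * lambdaMinRatio),
          length.out = nlambda))
}

# low-level path solver; lambdas must be descending
.solve_path <- function(X, y, w, alpha, lambdas, tol, maxIter) {
  .cd_logistic_path_cpp(X, y, w, alpha, lambdas, tol, 10 * tol,
                        as.integer(maxIter))
}

#' Fit weighted elastic-net sparse logistic regression
#'
#' Minimizes the penalized negative log-likelihood
#' `-(1/n) l(b0, beta) + lambda * (alpha * ||w o beta||_1 +
#' (1 - alpha) * ||w o beta||_2^2)` by cyclic coordinate descent on the
#' iteratively reweighted least-squares quadratic, with the exact
#' Karush-Kuhn-Tucker conditions checked at return.  The intercept is
#' never penalized; a gene with `w_j = 0` is unpenalized.
#'
#' `method = "rescale"` solves the same problem through the exact
#' reparameterization `x_j -> x_j / w_j`, `beta_j -> w_j * beta_j` (for
#' `w_j > 0`), which reduces the weighted penalty to the standard elastic
#' net; both routes agree at the optimum and exist mainly to cross-check
#' each other.
#'
#' @param x an [ExpressionDataset-class]; features should be standardized
#'   (see [preprocessExpression()]).
#' @param penalty a [PenaltySpec-class] with a single `lambda`.
#' @param tol convergence tolerance on coefficient change (default 1e-7);
#'   the KKT residual bound is `10 * tol`.
#' @param maxIter maximum coordinate sweeps (default 1e5).
#' @param method `"direct"` (penalty factors in the solver) or
#'   `"rescale"` (reparameterization).
#' @return a [PenalizedFit-class].
#' @export
fitWeightedEnet <- function(x, penalty, tol = 1e-7, maxIter = 1e5,
                            method = c("direct", "rescale")) {
  method <- match.arg(method)
  stopifnot(is(penalty, "PenaltySpec"))
  if (length(penalty@lambda) != 1L)
    stop("fitWeightedEnet needs a single lambda; see cvLambda()")
  dl <- .design_and_labels(x)
  w <- .align_weights(penalty, geneIds(x))
  if (method == "direct") {
    sol <- .solve_path(dl$X, dl$y, w, penalty@alpha, penalty@lambda,
                       tol, maxIter)
    beta <- sol$beta[, 1L]
  } else {
    pos <- w > 0
    Xs <- dl$X
    Xs[, pos] <- sweep(dl$X[, pos, drop = FALSE], 2L, w[pos], "/")
    wt <- as.numeric(pos)               # rescaled genes get unit weight
    sol <- .solve_path(Xs, dl$y, wt, penalty@alpha, penalty@lambda,
                       tol, maxIter)
    beta <- sol$beta[, 1L]
    beta[pos] <- beta[pos] / w[pos]
  }
  names(beta) <- geneIds(x)
  pen <- PenaltySpec(penalty@alpha, penalty@lambda,
                     stats::setNames(w, geneIds(x)))
  obj <- .objective(dl$X, dl$y, sol$intercept[1L], beta, pen)
  fit <- new("PenalizedFit", intercept = sol$intercept[1L],
             coefficients = beta, penalty = pen, objectiveValue = obj,
             converged = sol$converged[1L],
             nIterations = sol$n_sweeps[1L], kktMax = sol$kkt_max[1L])
  if (!fit@converged)
    warning("coordinate descent did not reach the KKT tolerance in ",
            maxIter, " sweeps (max residual ", signif(fit@kktMax, 3), ")")
  fit
}

#' @describeIn fitWeightedEnet coefficients of a fit, intercept first.
#' @param object a [PenalizedFit-class].
#' @param ... ignored.
#' @export
setMethod("coef", "PenalizedFit", function(object, ...) {
  c("(Intercept)" = object@intercept, object@coefficients)
})

#' @describeIn fitWeightedEnet gene ids with nonzero coefficient.
#' @export
setMethod("selectedGenes", "PenalizedFit", function(x) {
  names(x@coefficients)[x@coefficients != 0]
})

setMethod("show", "PenalizedFit", function(object) {
  cat("PenalizedFit: ", length(selectedGenes(object)), "/",
      length(object@coefficients), " genes selected; lambda=",
      signif(object@penalty@lambda, 4), ", alpha=", object@penalty@alpha,
      "; objective=", signif(object@objectiveValue, 6),
      if (!object@converged) " (NOT converged)", "\n", sep = "")
})

.objective <- function(X, y, intercept, beta, penalty) {
  eta <- drop(X %*% beta) + intercept
  ll <- sum(y * stats::plogis(eta, log.p = TRUE) +
            (1 - y) * stats::plogis(-eta, log.p = TRUE))
  w <- if (length(penalty@weights)) unname(penalty@weights) else
    rep(1, length(beta))
  lam <- if (length(penalty@lambda)) penalty@lambda[1L] else 0
  -ll / nrow(X) +
    lam * (penalty@alpha * sum(w * abs(beta)) +
           (1 - penalty@alpha) * sum((w * beta)^2))
}

#' Penalized negative log-likelihood of a fit on a dataset
#'
#' Evaluates `-(1/n) * l(b0, beta) + lambda * (alpha * ||w o beta||_1 +
#' (1 - alpha) * ||w o beta||_2^2)`, the objective minimized by
#' [fitWeightedEnet()].  The log-likelihood term is computed
#' overflow-safely; the intercept is unpenalized.
#'
#' @param x an [ExpressionDataset-class].
#' @param fit a [PenalizedFit-class] over the dataset's genes.
#' @param penalty penalty to evaluate under; defaults to the fit's own.
#' @return scalar objective value.
#' @export
negPenalizedLogLik <- function(x, fit, penalty = fit@penalty) {
  stopifnot(is(fit, "PenalizedFit"), is(penalty, "PenaltySpec"))
  if (any(!is.finite(fit@coefficients)) || !is.finite(fit@intercept))
    stop("non-finite coefficients")
  dl <- .design_and_labels(x)
  beta <- fit@coefficients[geneIds(x)]
  if (anyNA(beta)) stop("fit does not cover the dataset's genes")
  eta <- drop(dl$X %*% beta) + fit@intercept
  # log P(y=1) = plogis(eta, log=TRUE); log P(y=0) = plogis(-eta, log=TRUE)
  ll <- sum(dl$y * stats::plogis(eta, log.p = TRUE) +
            (1 - dl$y) * stats::plogis(-eta, log.p = TRUE))
  w <- .align_weights(penalty, geneIds(x))
  lam <- if (length(penalty@lambda)) penalty@lambda[1L] else 0
  -ll / nrow(dl$X) +
    lam * (penalty@alpha * sum(w * abs(beta)) +
           (1 - penalty@alpha) * sum((w * beta)^2))
}

#' Karush-Kuhn-Tucker residuals of a fit
#'
#' Exact stationarity/subgradient violations at the fit, one per gene plus
#' one for the intercept.  At a true optimum all residuals vanish; the
#' solver guarantees `max < 10 * tol` when converged.
#'
#' @param x the [ExpressionDataset-class] the fit was computed on.
#' @param fit a [PenalizedFit-class].
#' @return named numeric vector (genes, then `"(Intercept)"`).
#' @export
kktResiduals <- function(x, fit) {
  stopifnot(is(fit, "PenalizedFit"))
  dl <- .design_and_labels(x)
  beta <- unname(fit@coefficients[geneIds(x)])
  w <- .align_weights(fit@penalty, geneIds(x))
  r <- .kkt_residuals_cpp(dl$X, dl$y, fit@intercept, beta, w,
                          fit@penalty@alpha, fit@penalty@lambda[1L])
  stats::setNames(r, c(geneIds(x), "(Intercept)"))
}

#' Predicted tumor probabilities
#'
#' `P(Y = 1 | X) = 1 / (1 + exp(-(X beta + b0)))`, computed
#' overflow-safely and clamped to the open interval (0, 1).
#'
#' @param fit a [PenalizedFit-class].
#' @param x an [ExpressionDataset-class] covering the fit's genes.
#' @return named numeric vector of probabilities, one per sample.
#' @export
predictProb <- function(fit, x) {
  stopifnot(is(fit, "PenalizedFit"), is(x, "ExpressionDataset"))
  if (!setequal(names(fit@coefficients), geneIds(x)))
    stop("gene sets of fit and dataset are misaligned")
  beta <- fit@coefficients[geneIds(x)]
  eta <- drop(designMatrix(x) %*% beta) + fit@intercept
  p <- stats::plogis(eta)
  eps <- 1e-12
  stats::setNames(pmin(pmax(p, eps), 1 - eps), sampleIds(x))
}

#' Choose lambda by stratified k-fold cross-validation
#'
#' Builds a descending log-spaced lambda path from the weighted KKT
#' threshold `lambda_max` down to `lambdaMinRatio * lambda_max`, fits the
#' warm-started path on each training fold and scores the held-out fold,
#' and returns the lambda minimizing the mean cross-validated metric
#' (largest such lambda on ties).  Folds are stratified by class.
#'
#' @param x an [ExpressionDataset-class].
#' @param penalty a [PenaltySpec-class]; its `lambda` slot is ignored.
#' @param k number of folds (default 10).
#' @param metric `"mse"` (Brier score, default) or `"deviance"`.
#' @param seed integer seed controlling fold assignment.
#' @param nlambda,lambdaMinRatio path geometry (defaults 100 and 1e-3).
#' @param tol,maxIter solver controls as in [fitWeightedEnet()].
#' @return list with `lambda_opt`, `cv_table` (data.frame: lambda,
#'   cv_mean, cv_se, nonzero), and `path` (the lambda path).
#' @export
cvLambda <- function(x, penalty, k = 10, metric = c("mse", "deviance"),
                     seed = 1L, nlambda = 100, lambdaMinRatio = 1e-3,
                     tol = 1e-7, maxIter = 1e5) {
  metric <- match.arg(metric)
  stopifnot(k >= 2)
  dl <- .design_and_labels(x)
  n <- nrow(dl$X)
  if (k > n) stop("more folds than samples")
  w <- .align_weights(penalty, geneIds(x))
  lmax <- lambdaMax(x, penalty)
  path <- lambdaPath(lmax, nlambda, lambdaMinRatio)

  # stratified folds; fold numbers cycle across classes so that no fold is
  # left empty even when a class has fewer members than k
  folds <- integer(n)
  .with_seed(seed, {
    start <- 0L
    for (cl in unique(dl$y)) {
      idx <- which(dl$y == cl)
      labs <- ((start + seq_along(idx) - 1L) %% k) + 1L
      folds[idx] <- sample(labs)
      start <- start + length(idx)
    }
  })
  loss <- matrix(NA_real_, k, length(path))
  for (f in seq_len(k)) {
    tr <- folds != f
    if (all(tr)) next                    # empty held-out fold
    if (length(unique(dl$y[tr])) < 2)
      stop("training fold ", f, " contains a single class")
    sol <- .solve_path(dl$X[tr, , drop = FALSE], dl$y[tr], w,
                       penalty@alpha, path, tol, maxIter)
    eta <- sweep(dl$X[!tr, , drop = FALSE] %*% sol$beta, 2L,
                 sol$intercept, "+")
    pr <- stats::plogis(eta)
    yv <- dl$y[!tr]
    loss[f, ] <- if (metric == "mse") colMeans((pr - yv)^2)
    else {
      pr <- pmin(pmax(pr, 1e-12), 1 - 1e-12)
      colMeans(-2 * (yv * log(pr) + (1 - yv) * log(1 - pr)))
    }
  }
  cv_mean <- colMeans(loss, na.rm = TRUE)
  cv_se <- apply(loss, 2L, stats::sd, na.rm = TRUE) / sqrt(sum(!is.na(loss[, 1L])))
  best <- which(cv_mean <= min(cv_mean) + 1e-15)[1L]  # largest lambda on ties
  full <- .solve_path(dl$X, dl$y, w, penalty@alpha, path, tol, maxIter)
  list(lambda_opt = path[best],
       cv_table = data.frame(lambda = path, cv_mean = cv_mean,
                             cv_se = cv_se,
                             nonzero = colSums(full$beta != 0)),
       path = path)
}

#' Serialize a fit as TSV plus a metadata sidecar
#'
#' Writes `gene_id`/`coefficient` pairs to `path` and lambda, alpha,
#' intercept, objective and convergence to `metadataPath`.
#'
#' @param fit a [PenalizedFit-class].
#' @param path coefficient TSV path.
#' @param metadataPath sidecar path (default `paste0(path, ".meta")`).
#' @return `path`, invisibly.
#' @export
writePenalizedFit <- function(fit, path, metadataPath = paste0(path, ".meta")) {
  stopifnot(is(fit, "PenalizedFit"))
  utils::write.table(
    data.frame(gene_id = names(fit@coefficients),
               coefficient = sprintf("%.17g", fit@coefficients)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c(paste0("lambda\t", sprintf("%.17g", fit@penalty@lambda)),
               paste0("alpha\t", fit@penalty@alpha),
               paste0("intercept\t", sprintf("%.17g", fit@intercept)),
               paste0("objective\t", sprintf("%.17g", fit@objectiveValue)),
               paste0("converged\t", fit@converged),
               paste0("n_iterations\t", fit@nIterations)),
             metadataPath)
  invisible(path)
}

# evaluate expr under a temporary RNG state seeded with `seed`
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}
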