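# independent objective evaluation used as the oracle throughout
naive_objective <- function(X, y, b0, beta, lambda, alpha, w) {
  eta <- drop(X %*% beta) + b0
  p <- 1 / (1 + exp(-eta))
  ll <- sum(y * log(p) + (1 - y) * log(1 - p))
  -ll / nrow(X) +
    lambda * (alpha * sum(w * abs(beta)) + (1 - alpha) * sum((w * beta)^2))
}

test_that("the penalized objective matches a naive summation oracle", {
  ds <- random_dataset(n = 30, p = 5, seed = 10)
  X <- designMatrix(ds)
  y <- unname(sampleLabels(ds))
  set.seed(2)
  beta <- rnorm(5, sd = 0.5)
  names(beta) <- geneIds(ds)
  w <- runif(5, 0.1, 1)
  names(w) <- geneIds(ds)
  pen <- PenaltySpec(0.7, 0.08, w)
  fit <- new("PenalizedFit", intercept = 0.3, coefficients = beta,
             penalty = pen, objectiveValue = 0, converged = FALSE,
             nIterations = 0L, kktMax = Inf)
  expect_equal(negPenalizedLogLik(ds, fit),
               naive_objective(X, y, 0.3, beta, 0.08, 0.7, unname(w)),
               tolerance = 1e-10)
})

test_that("null and unpenalized limits of the objective are exact", {
  ds <- random_dataset(n = 25, p = 4, seed = 12)
  y <- unname(sampleLabels(ds))
  ybar <- mean(y)
  zero <- setNames(rep(0, 4), geneIds(ds))
  fit0 <- new("PenalizedFit", intercept = qlogis(ybar), coefficients = zero,
              penalty = PenaltySpec(0.9, 0.5), objectiveValue = 0,
              converged = FALSE, nIterations = 0L, kktMax = Inf)
  # zero coefficients: penalty vanishes and the value is the per-sample
  # Bernoulli null deviance over 2
  expect_equal(negPenalizedLogLik(ds, fit0),
               -mean(y * log(ybar) + (1 - y) * log(1 - ybar)),
               tolerance = 1e-12)
  # all-zero weights: objective equals the bare negative log-likelihood
  set.seed(3)
  beta <- setNames(rnorm(4), geneIds(ds))
  w0 <- setNames(rep(0, 4), geneIds(ds))
  fitw <- new("PenalizedFit", intercept = -0.2, coefficients = beta,
              penalty = PenaltySpec(0.9, 3, w0), objectiveValue = 0,
              converged = FALSE, nIterations = 0L, kktMax = Inf)
  expect_equal(negPenalizedLogLik(ds, fitw),
               naive_objective(designMatrix(ds), y, -0.2, beta, 0, 0.9,
                               rep(1, 4)),
               tolerance = 1e-12)
  bad <- fitw
  bad@coefficients[1] <- Inf
  expect_error(negPenalizedLogLik(ds, bad), "non-finite")
})

test_that("huge lambda gives the fully shrunk null model", {
  ds <- random_dataset(n = 40, p = 8, seed = 20)
  fit <- fitWeightedEnet(ds, PenaltySpec(0.9, 1e6))
  expect_true(all(fit@coefficients == 0))
  expect_equal(fit@intercept, qlogis(mean(sampleLabels(ds))),
               tolerance = 1e-7)
})

test_that("unit weights reproduce the standard elastic-net fit", {
  skip_if_not_installed("glmnet")
  for (seed in c(1, 7, 23)) {
    ds <- random_dataset(n = 60, p = 12, seed = seed,
                         signal = c(1.2, -1, 0.5))
    X <- designMatrix(ds)
    y <- unname(sampleLabels(ds))
    alpha <- 0.9
    lam <- 0.04
    fit <- fitWeightedEnet(ds, PenaltySpec(alpha, lam), tol = 1e-10)
    # this package's ridge term is (1 - alpha) * ||beta||_2^2 while the
    # reference solver halves it, hence the exact (lambda, alpha) remap
    g <- glmnet::glmnet(X, y, family = "binomial",
                        alpha = alpha / (2 - alpha),
                        lambda = lam * (2 - alpha),
                        standardize = FALSE, thresh = 1e-16, maxit = 1e6)
    expect_lt(max(abs(as.numeric(coef(g))[-1] - fit@coefficients)), 1e-6)
    expect_lt(abs(as.numeric(coef(g))[1] - fit@intercept), 1e-6)
  }
})

test_that("direct and reparameterized weighted fits agree", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(30:60, 1)
    p <- sample(4:12, 1)
    ds <- random_dataset(n = n, p = p, seed = seed)
    w <- setNames(runif(p, 0.05, 1), geneIds(ds))
    if (seed %% 4 == 0) w[1] <- 0      # exercise the unpenalized case
    pen <- PenaltySpec(0.9, 0.05, w)
    f1 <- fitWeightedEnet(ds, pen, tol = 1e-9)
    f2 <- fitWeightedEnet(ds, pen, tol = 1e-9, method = "rescale")
    expect_lt(max(abs(f1@coefficients - f2@coefficients)), 1e-5)
    expect_lt(abs(f1@objectiveValue - f2@objectiveValue), 1e-8)
  }
})

test_that("returned fits satisfy the KKT conditions", {
  for (seed in c(2, 9)) {
    ds <- random_dataset(n = 50, p = 10, seed = seed)
    w <- setNames(runif(10, 0.1, 1), geneIds(ds))
    fit <- fitWeightedEnet(ds, PenaltySpec(0.85, 0.03, w), tol = 1e-8)
    expect_true(fit@converged)
    expect_lt(max(kktResiduals(ds, fit)), 1e-7)
  }
})

test_that("lambda_max is tight", {
  for (seed in c(3, 14)) {
    ds <- random_dataset(n = 45, p = 8, seed = seed)
    pen <- PenaltySpec(0.9)
    lmax <- lambdaMax(ds, pen)
    hi <- fitWeightedEnet(ds, PenaltySpec(0.9, lmax))
    lo <- fitWeightedEnet(ds, PenaltySpec(0.9, lmax * 0.999))
    expect_true(all(hi@coefficients == 0))
    expect_gt(sum(lo@coefficients != 0), 0)
  }
})

test_that("raising one gene's weight never grows its coefficient", {
  for (seed in 1:6) {
    ds <- random_dataset(n = 40, p = 5, seed = seed + 40)
    j <- (seed %% 5) + 1
    prev <- Inf
    for (wj in c(0.2, 0.5, 1, 2)) {
      w <- setNames(rep(0.6, 5), geneIds(ds))
      w[j] <- wj
      fit <- fitWeightedEnet(ds, PenaltySpec(0.9, 0.03, w), tol = 1e-9)
      bj <- abs(fit@coefficients[j])
      expect_lte(bj, prev + 1e-8)
      prev <- bj
    }
  }
})

test_that("the returned optimum beats random perturbations", {
  ds <- random_dataset(n = 40, p = 6, seed = 50)
  X <- designMatrix(ds)
  y <- unname(sampleLabels(ds))
  w <- setNames(runif(6, 0.2, 1), geneIds(ds))
  fit <- fitWeightedEnet(ds, PenaltySpec(0.9, 0.04, w), tol = 1e-9)
  set.seed(99)
  for (i in 1:100) {
    beta2 <- fit@coefficients + rnorm(6, sd = 0.05)
    b02 <- fit@intercept + rnorm(1, sd = 0.05)
    expect_gte(naive_objective(X, y, b02, beta2, 0.04, 0.9, unname(w)),
               fit@objectiveValue - 1e-10)
  }
})

test_that("probability predictions are exact and overflow-safe", {
  ds <- random_dataset(n = 15, p = 4, seed = 60)
  zero <- setNames(rep(0, 4), geneIds(ds))
  f0 <- new("PenalizedFit", intercept = 0, coefficients = zero,
            penalty = PenaltySpec(0.9, 1), objectiveValue = 0,
            converged = TRUE, nIterations = 1L, kktMax = 0)
  expect_equal(unname(predictProb(f0, ds)), rep(0.5, 15))
  fbig <- f0
  fbig@intercept <- 1e4
  pr <- predictProb(fbig, ds)
  expect_true(all(pr < 1) && all(is.finite(pr)))
  set.seed(5)
  beta <- setNames(rnorm(4), geneIds(ds))
  fr <- f0
  fr@coefficients <- beta
  fr@intercept <- 0.7
  eta <- drop(designMatrix(ds) %*% beta) + 0.7
  expect_equal(unname(predictProb(fr, ds)),
               unname(exp(eta) / (1 + exp(eta))), tolerance = 1e-12)
  dsx <- random_dataset(n = 10, p = 3, seed = 61)
  expect_error(predictProb(f0, subsetGenes(dsx, "g1")), "misaligned")
})

test_that("cross-validation tracks signal strength", {
  # pure noise: the chosen lambda sits high on the path
  ds <- random_dataset(n = 60, p = 10, seed = 70, signal = numeric(0))
  cv <- cvLambda(ds, PenaltySpec(0.9), seed = 7)
  expect_lte(which(cv$path == cv$lambda_opt),
             ceiling(length(cv$path) / 4))
  # a single strong feature is selected at lambda_opt in almost every rep
  hits <- 0
  for (seed in 1:20) {
    set.seed(seed + 500)
    X <- scale(matrix(rnorm(60 * 5), 60, 5))
    dimnames(X) <- list(paste0("s", 1:60), paste0("g", 1:5))
    y <- rbinom(60, 1, plogis(2.5 * X[, 3]))
    if (length(unique(y)) < 2) next
    dss <- ExpressionDataset(X, labels = y)
    cvs <- cvLambda(dss, PenaltySpec(0.9), seed = seed)
    fit <- fitWeightedEnet(dss, PenaltySpec(0.9, cvs$lambda_opt))
    hits <- hits + ("g3" %in% selectedGenes(fit))
  }
  expect_gte(hits, 19)
})

test_that("leave-one-out cross-validation runs on a 10-sample instance", {
  set.seed(81)
  X <- scale(matrix(rnorm(10 * 3), 10, 3))
  dimnames(X) <- list(paste0("s", 1:10), paste0("g", 1:3))
  ds <- ExpressionDataset(X, labels = rep(c(0L, 1L), 5))
  cv <- cvLambda(ds, PenaltySpec(0.9), k = 10, seed = 2)
  expect_true(is.finite(cv$lambda_opt))
  expect_true(all(is.finite(cv$cv_table$cv_mean)))
})

test_that("fits serialize to text with full precision", {
  ds <- random_dataset(n = 30, p = 4, seed = 90)
  fit <- fitWeightedEnet(ds, PenaltySpec(0.9, 0.05))
  f <- tempfile()
  writePenalizedFit(fit, f)
  tab <- read.table(f, header = TRUE, sep = "\t")
  expect_identical(tab$gene_id, geneIds(ds))
  expect_equal(tab$coefficient, unname(fit@coefficients), tolerance = 1e-16)
  expect_true(file.exists(paste0(f, ".meta")))
})
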