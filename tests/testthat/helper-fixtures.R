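# Shared fixtures, all generated in code.

# standardized random dataset with a weak 2-gene signal
random_dataset <- function(n = 40, p = 6, seed = 1, signal = c(1, -0.8)) {
  set.seed(seed)
  X <- matrix(scale(matrix(rnorm(n * p), n, p)), n, p)
  dimnames(X) <- list(paste0("s", seq_len(n)), paste0("g", seq_len(p)))
  eta <- X[, seq_along(signal), drop = FALSE] %*% signal
  y <- rbinom(n, 1, plogis(eta))
  # guarantee both classes
  if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
  ExpressionDataset(X, labels = y)
}

# CorrelationProfile from an explicit symmetric matrix
profile_from_matrix <- function(m, genes = NULL, cohort = "A") {
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(m)))
  dimnames(m) <- list(genes, genes)
  new("CorrelationProfile", correlations = m, cohort = cohort,
      sampleFilter = "all")
}

# valid random correlation matrix (sampled data guarantees PSD)
random_profile <- function(p = 6, n = 25, seed = 1, cohort = "A") {
  set.seed(seed)
  m <- cor(matrix(rnorm(n * p), n, p))
  profile_from_matrix(m, cohort = cohort)
}

# brute-force per-gene angle between profile columns, degrees
oracle_angles <- function(A, B, include_self = FALSE) {
  p <- nrow(A)
  out <- numeric(p)
  for (j in seq_len(p)) {
    va <- A[, j]
    vb <- B[, j]
    if (!include_self) {
      va <- va[-j]
      vb <- vb[-j]
    }
    cs <- sum(va * vb) / (sqrt(sum(va^2)) * sqrt(sum(vb^2)))
    out[j] <- acos(max(-1, min(1, cs))) * 180 / pi
  }
  out
}

# small twin scenario for fast protocol tests
mini_scenario <- function() {
  twinScenario(nA = 60, nB = 60, p = 60, twinSize = 10, specificSize = 10,
               nSpecificBlocks = 2, nSignal = 3)
}
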