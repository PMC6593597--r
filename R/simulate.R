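#' @include survival.R
NULL

#' Construct a TwinScenario
#'
#' Builds the population description for the two-cohort generator: a twin
#' block whose correlation structure is identical in both cohorts, one
#' disease-specific correlated block per cohort (same gene indices, but
#' cohort B's loading signs are flipped for half the genes and the block
#' order is permuted, so the correlation vectors differ strongly), and
#' independent noise genes.  The first `nSignal` twin genes drive the
#' tumor/normal outcome through a logistic model.
#'
#' The defaults describe the scenario used throughout the package's tests:
#' 300 genes (30 twin, 30 specific, 240 noise), 150 samples per cohort,
#' 5 signal genes with unit log-odds effects, within-block correlation
#' 0.7 and target tumor prevalence 0.7.
#'
#' @param nA,nB samples per cohort (default 150 each).
#' @param p total genes (default 300).
#' @param twinSize twin-block size (default 30).
#' @param specificSize size of each disease-specific block (default 30).
#' @param nSpecificBlocks number of disease-specific blocks (default 2).
#' @param nSignal number of outcome-driving twin genes (default 5).
#' @param effectSize log-odds per unit expression (default 1).
#' @param rhoTwin,rhoSpecific within-block correlations (default 0.7).
#' @param tumorFraction target marginal tumor prevalence (default 0.7).
#' @return a [TwinScenario-class].
#' @export
twinScenario <- function(nA = 150, nB = 150, p = 300, twinSize = 30,
                         specificSize = 30, nSpecificBlocks = 2,
                         nSignal = 5, effectSize = 1,
                         rhoTwin = 0.7, rhoSpecific = 0.7,
                         tumorFraction = 0.7) {
  if (twinSize + nSpecificBlocks * specificSize > p)
    stop("blocks exceed the total number of genes")
  twin <- seq_len(twinSize)
  specific <- twinSize + seq_len(nSpecificBlocks * specificSize)
  noise <- setdiff(seq_len(p), c(twin, specific))
  new("TwinScenario", nA = as.integer(nA), nB = as.integer(nB),
      p = as.integer(p), twinBlock = as.integer(twin),
      specificBlock = as.integer(specific),
      specificBlockSize = as.integer(specificSize),
      noiseGenes = as.integer(noise),
      signalGenes = as.integer(twin[seq_len(nSignal)]),
      effectSize = as.numeric(effectSize), rhoTwin = as.numeric(rhoTwin),
      rhoSpecific = as.numeric(rhoSpecific),
      tumorFraction = as.numeric(tumorFraction))
}

setMethod("show", "TwinScenario", function(object) {
  cat("TwinScenario: p=", object@p, " (twin ", length(object@twinBlock),
      ", specific ", length(object@specificBlock), ", noise ",
      length(object@noiseGenes), "); n=", object@nA, "+", object@nB,
      "; ", length(object@signalGenes), " signal genes, effect ",
      object@effectSize, "\n", sep = "")
})

# equicorrelated block sample: m genes at correlation rho, n draws.
# one-factor construction: x = sqrt(rho)*z + sqrt(1-rho)*e
.equicorr_block <- function(n, m, rho) {
  z <- stats::rnorm(n)
  sqrt(rho) * matrix(z, n, m) + sqrt(1 - rho) * matrix(stats::rnorm(n * m), n, m)
}

# signed one-factor block: corr(i, j) = s_i * s_j * rho
.signed_block <- function(n, m, rho, signs) {
  z <- stats::rnorm(n)
  t(t(sqrt(rho) * matrix(z, n, m)) * signs) +
    sqrt(1 - rho) * matrix(stats::rnorm(n * m), n, m)
}

#' Generate a two-cohort dataset with a planted twin block
#'
#' Draws both cohorts from multivariate normal distributions at the
#' post-preprocessing scale (standard normal margins): the twin block is
#' equicorrelated at `rhoTwin` identically in both cohorts; the specific
#' block is a signed one-factor block whose signs and within-block gene
#' order differ between the cohorts; noise genes are independent.  Labels
#' follow `P(Y = 1 | x) = plogis(b0 + effectSize * sum(signal genes))`
#' with `b0 = qlogis(tumorFraction)`.
#'
#' With `mode = "fpkm"` the Gaussian values are pushed through a lognormal
#' map (`exp(mu_g + x)`, gene-specific baselines), producing non-negative
#' FPKM-like values that exercise [preprocessExpression()].
#'
#' @param scenario a [TwinScenario-class].
#' @param seed integer seed; identical seeds give bit-identical output.
#' @param mode `"gaussian"` (default, ready-to-model z-scores) or
#'   `"fpkm"` (lognormal pre-image, needs preprocessing).
#' @return list with [ExpressionDataset-class] elements `a` and `b`, and
#'   `ground_truth`: a data.frame with gene_id, block
#'   (`twin`/`specific`/`noise`) and is_signal.
#' @export
generateTwinData <- function(scenario, seed = 1L,
                             mode = c("gaussian", "fpkm")) {
  stopifnot(is(scenario, "TwinScenario"))
  mode <- match.arg(mode)
  s <- scenario
  genes <- sprintf("g%03d", seq_len(s@p))
  .with_seed(seed, {
    m_spec <- s@specificBlockSize
    n_blocks <- length(s@specificBlock) %/% m_spec
    chunks <- split(s@specificBlock,
                    rep(seq_len(n_blocks), each = m_spec))
    signsA <- rep(1, m_spec)
    signsB <- rep(c(1, -1), length.out = m_spec)
    permsB <- lapply(seq_len(n_blocks), function(i) sample(m_spec))
    baselines <- stats::runif(s@p, 1, 6)   # lognormal means for fpkm mode

    make_cohort <- function(n, tag, specific_signs, specific_perms) {
      X <- matrix(stats::rnorm(n * s@p), n, s@p)
      X[, s@twinBlock] <- .equicorr_block(n, length(s@twinBlock), s@rhoTwin)
      for (bi in seq_len(n_blocks)) {
        blk <- .signed_block(n, m_spec, s@rhoSpecific, specific_signs)
        X[, chunks[[bi]]] <- blk[, specific_perms[[bi]], drop = FALSE]
      }
      colnames(X) <- genes
      rownames(X) <- paste0(tag, "_s", seq_len(n))
      eta <- stats::qlogis(s@tumorFraction) +
        s@effectSize * rowSums(X[, s@signalGenes, drop = FALSE])
      y <- stats::rbinom(n, 1L, stats::plogis(eta))
      if (mode == "fpkm") X <- exp(sweep(X, 2L, baselines, "+"))
      ExpressionDataset(X, labels = y, cohort = tag)
    }
    a <- make_cohort(s@nA, "A", signsA,
                     rep(list(seq_len(m_spec)), n_blocks))
    b <- make_cohort(s@nB, "B", signsB, permsB)
  })
  block <- rep("noise", s@p)
  block[s@twinBlock] <- "twin"
  block[s@specificBlock] <- "specific"
  list(a = a, b = b,
       ground_truth = data.frame(gene_id = genes, block = block,
                                 is_signal = seq_len(s@p) %in% s@signalGenes))
}

#' Generate exponential survival times driven by a gene signature
#'
#' Event times are exponential with rate
#' `baselineRate * exp(sum(hazardCoefs * x))`; censoring times are
#' independent exponential with rate `censorRate`; the observed time is
#' the minimum and the event indicator marks whether the event came first.
#'
#' @param x an [ExpressionDataset-class].
#' @param signature gene ids the hazard depends on.
#' @param hazardCoefs log hazard ratios, one per signature gene (recycled
#'   if scalar).
#' @param baselineRate baseline event rate (> 0, default 0.1).
#' @param censorRate censoring rate (> 0, default 0.05).
#' @param seed integer seed.
#' @return a [SurvivalTable-class] over the dataset's samples.
#' @export
generateSurvival <- function(x, signature, hazardCoefs, baselineRate = 0.1,
                             censorRate = 0.05, seed = 1L) {
  stopifnot(is(x, "ExpressionDataset"), baselineRate > 0, censorRate > 0)
  missing <- setdiff(signature, geneIds(x))
  if (length(missing))
    stop("signature genes absent: ", paste(missing, collapse = ", "))
  coefs <- rep_len(hazardCoefs, length(signature))
  lp <- drop(designMatrix(x)[, signature, drop = FALSE] %*% coefs)
  n <- length(lp)
  .with_seed(seed, {
    t_event <- stats::rexp(n, rate = baselineRate * exp(lp))
    t_cens <- stats::rexp(n, rate = censorRate)
  })
  SurvivalTable(sampleIds(x), pmin(t_event, t_cens),
                as.integer(t_event <= t_cens))
}

#' Write a generated scenario to a directory of delimited text files
#'
#' Emits `A.tsv`, `B.tsv` (genes in columns), `labels_A.tsv`,
#' `labels_B.tsv`, `ground_truth.tsv` and optionally `survival.tsv`
#' (survival over cohort A's tumor samples, hazard on the signal genes).
#'
#' @param sim output of [generateTwinData()].
#' @param dir output directory (created if absent).
#' @param survival also write a survival table (default FALSE).
#' @param seed seed for survival generation.
#' @return `dir`, invisibly.
#' @export
writeTwinData <- function(sim, dir, survival = FALSE, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeExpression(sim$a, file.path(dir, "A.tsv"),
                  labelsPath = file.path(dir, "labels_A.tsv"))
  writeExpression(sim$b, file.path(dir, "B.tsv"),
                  labelsPath = file.path(dir, "labels_B.tsv"))
  utils::write.table(sim$ground_truth, file.path(dir, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (survival) {
    sig <- sim$ground_truth$gene_id[sim$ground_truth$is_signal]
    surv <- generateSurvival(sim$a, sig, 0.5, seed = seed)
    utils::write.table(
      data.frame(sample_id = sampleIds(surv), time = survTime(surv),
                 event = survEvent(surv)),
      file.path(dir, "survival.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  invisible(dir)
}
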