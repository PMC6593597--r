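#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata
NULL

#' ExpressionDataset: labeled expression matrix for two-disease modeling
#'
#' Container for one cohort (or a merged pair of cohorts) of expression
#' data, extending [SummarizedExperiment::SummarizedExperiment].  Genes are
#' rows, samples are columns (the Bioconductor convention); the binary
#' outcome (1 = tumor, 0 = normal) lives in `colData(x)$label`, and a free
#' cohort tag (e.g. `"A"`, `"B"`, `"merged"`) in the metadata.
#'
#' Validity requires a numeric assay named `"exprs"` with no missing or
#' non-finite values, unique gene and sample identifiers, and labels in
#' \{0, 1\}.
#'
#' @seealso [ExpressionDataset()] for construction from a samples-by-genes
#'   matrix, [readExpression()] for delimited text input.
#' @export
setClass("ExpressionDataset", contains = "SummarizedExperiment")

setValidity("ExpressionDataset", function(object) {
  msg <- character()
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'exprs' is required")
  else {
    m <- SummarizedExperiment::assay(object, "exprs")
    if (!is.numeric(m)) msg <- c(msg, "assay 'exprs' must be numeric")
    else if (anyNA(m) || any(!is.finite(m)))
      msg <- c(msg, "assay 'exprs' contains missing or non-finite values")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "gene identifiers (rownames) must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample identifiers (colnames) must be present and unique")
  if (!"label" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData column 'label' is required")
  else {
    lab <- SummarizedExperiment::colData(object)$label
    if (anyNA(lab) || !all(lab %in% c(0L, 1L)))
      msg <- c(msg, "labels must be 0 (normal) or 1 (tumor), no NA")
  }
  if (length(msg)) msg else TRUE
})

#' CorrelationProfile: per-disease gene-gene Pearson correlation matrix
#'
#' Holds the p-by-p Pearson correlation matrix of one disease (Sigma_A or
#' Sigma_B), whose column j is gene j's correlation vector with all genes.
#' Validity enforces symmetry (within 1e-10), unit diagonal and entries in
#' \[-1, 1\].
#'
#' @slot correlations p-by-p numeric matrix with gene ids as dimnames.
#' @slot cohort single string tagging the source cohort.
#' @slot sampleFilter which samples the correlations were computed on
#'   (`"all"`, `"tumor_only"` or `"normal_only"`).
#' @export
setClass("CorrelationProfile",
  representation(correlations = "matrix", cohort = "character",
                 sampleFilter = "character"))

setValidity("CorrelationProfile", function(object) {
  m <- object@correlations
  msg <- character()
  if (nrow(m) != ncol(m)) msg <- c(msg, "correlation matrix must be square")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    msg <- c(msg, "gene ids (dimnames) must be present and unique")
  else if (!identical(rownames(m), colnames(m)))
    msg <- c(msg, "row and column gene ids must agree")
  if (max(abs(m - t(m))) > 1e-10) msg <- c(msg, "matrix not symmetric within 1e-10")
  if (max(abs(diag(m) - 1)) > 1e-10) msg <- c(msg, "diagonal must be 1")
  if (any(m < -1 - 1e-10) || any(m > 1 + 1e-10))
    msg <- c(msg, "entries must lie in [-1, 1]")
  if (length(object@cohort) != 1L) msg <- c(msg, "cohort must be a single string")
  if (length(msg)) msg else TRUE
})

#' TwinerWeights: per-gene angular distances and penalty factors
#'
#' For each gene, the angular distance (degrees, in \[0, 180\]) between its
#' correlation vectors in diseases A and B, and the derived elastic-net
#' penalty factor w_j = d_j / max_k d_k in \[0, 1\].  Genes with twin-like
#' correlation structure across the diseases get small weights, hence small
#' penalties.
#'
#' @slot geneIds character vector of gene identifiers.
#' @slot distanceDeg numeric angular distances in degrees.
#' @slot weight numeric penalty factors in \[0, 1\].
#' @export
setClass("TwinerWeights",
  representation(geneIds = "character", distanceDeg = "numeric",
                 weight = "numeric"))

setValidity("TwinerWeights", function(object) {
  msg <- character()
  p <- length(object@geneIds)
  if (length(object@distanceDeg) != p || length(object@weight) != p)
    msg <- c(msg, "geneIds, distanceDeg and weight must have equal length")
  if (anyDuplicated(object@geneIds)) msg <- c(msg, "gene ids must be unique")
  if (p > 0) {
    if (any(object@distanceDeg < -1e-10) || any(object@distanceDeg > 180 + 1e-10))
      msg <- c(msg, "distances must lie in [0, 180] degrees")
    # max(weight) == 1 holds at construction via twinerWeights() but may be
    # broken on purpose by the angular pre-filter (no renormalization), so
    # validity only bounds the range
    if (any(object@weight < -1e-12) || any(object@weight > 1 + 1e-12))
      msg <- c(msg, "weights must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' PenaltySpec: weighted elastic-net penalty parameters
#'
#' The penalty lambda * (alpha * ||w o beta||_1 + (1 - alpha) * ||w o beta||_2^2),
#' where `o` is the elementwise product.  `alpha` mixes lasso (1) and ridge
#' (0); `lambda` may be a single value, a descending path, or empty (to be
#' chosen by cross-validation); `weights` of length 0 means unit penalty
#' factors (plain elastic net).
#'
#' @slot alpha numeric(1) in \[0, 1\].
#' @slot lambda numeric, positive, non-increasing if a path; may be empty.
#' @slot weights numeric penalty factors >= 0, possibly named; empty = unit.
#' @export
setClass("PenaltySpec",
  representation(alpha = "numeric", lambda = "numeric", weights = "numeric"))

setValidity("PenaltySpec", function(object) {
  msg <- character()
  if (length(object@alpha) != 1L || is.na(object@alpha) ||
      object@alpha < 0 || object@alpha > 1)
    msg <- c(msg, "alpha must be a single value in [0, 1]")
  if (length(object@lambda) && (anyNA(object@lambda) || any(object@lambda <= 0)))
    msg <- c(msg, "all lambda values must be positive")
  if (length(object@lambda) > 1 && is.unsorted(rev(object@lambda)))
    msg <- c(msg, "a lambda path must be non-increasing")
  if (length(object@weights) && (anyNA(object@weights) || any(object@weights < 0)))
    msg <- c(msg, "weights must be non-negative")
  if (length(msg)) msg else TRUE
})

#' PenalizedFit: a fitted weighted elastic-net logistic model
#'
#' @slot intercept numeric(1), unpenalized intercept.
#' @slot coefficients named numeric vector of gene coefficients (dense
#'   storage, mostly zero).
#' @slot penalty the [PenaltySpec-class] the fit was computed under
#'   (single lambda).
#' @slot objectiveValue value of the penalized negative log-likelihood at
#'   the optimum.
#' @slot converged logical(1); FALSE if the iteration cap was hit.
#' @slot nIterations integer(1), coordinate sweeps used.
#' @slot kktMax numeric(1), largest Karush-Kuhn-Tucker residual at return.
#' @export
setClass("PenalizedFit",
  representation(intercept = "numeric", coefficients = "numeric",
                 penalty = "PenaltySpec", objectiveValue = "numeric",
                 converged = "logical", nIterations = "integer",
                 kktMax = "numeric"))

setValidity("PenalizedFit", function(object) {
  msg <- character()
  if (length(object@intercept) != 1L || !is.finite(object@intercept))
    msg <- c(msg, "intercept must be a single finite value")
  if (is.null(names(object@coefficients)))
    msg <- c(msg, "coefficients must be named by gene id")
  if (object@converged && !is.finite(object@objectiveValue))
    msg <- c(msg, "objective must be finite when converged")
  if (length(msg)) msg else TRUE
})

#' StabilityResult: resampling protocol output
#'
#' Aggregates the repeated train/test resampling runs of
#' [runStability()]: one record per run and method with its metrics and
#' selected genes, per-gene selection frequencies, the consensus signatures
#' (genes selected in more than `freqThreshold` of runs), per-method metric
#' medians, and the Venn decomposition of the two consensus sets.
#'
#' @slot records data.frame, one row per (run, method).
#' @slot selectionFrequency data.frame with columns gene_id, en, twiner.
#' @slot consensus named list of character vectors (`en`, `twiner`).
#' @slot medians data.frame of per-method metric medians.
#' @slot venn named list: `en_only`, `twiner_only`, `shared`.
#' @slot freqThreshold numeric(1), consensus frequency cutoff (strict >).
#' @slot params list echoing the protocol parameters.
#' @export
setClass("StabilityResult",
  representation(records = "data.frame", selectionFrequency = "data.frame",
                 consensus = "list", medians = "data.frame", venn = "list",
                 freqThreshold = "numeric", params = "list"))

#' RiskStratification: survival validation of a gene signature
#'
#' Output of [stratifyAndTest()]: Cox relative risks, the median-split
#' high/low risk groups, Kaplan-Meier curves per group, and the two-group
#' log-rank test.
#'
#' @slot riskTable data.frame: sample_id, relative_risk, group.
#' @slot kmCurves data.frame: group, time, survival, n_at_risk.
#' @slot logrankStat numeric(1) chi-squared statistic (1 df).
#' @slot logrankP numeric(1) p-value.
#' @slot coxCoefficients named numeric vector of fitted log hazard ratios.
#' @export
setClass("RiskStratification",
  representation(riskTable = "data.frame", kmCurves = "data.frame",
                 logrankStat = "numeric", logrankP = "numeric",
                 coxCoefficients = "numeric"))

setValidity("RiskStratification", function(object) {
  msg <- character()
  tab <- table(object@riskTable$group)
  if (length(tab) == 2 && abs(tab[["high"]] - tab[["low"]]) > 1)
    msg <- c(msg, "high and low risk groups must differ by at most 1 sample")
  if (length(object@logrankP) != 1L || object@logrankP < 0 || object@logrankP > 1)
    msg <- c(msg, "log-rank p-value must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' TwinScenario: population description for the two-cohort generator
#'
#' Describes two synthetic disease cohorts sharing a "twin" gene block with
#' identical correlation structure, plus per-cohort disease-specific
#' correlated blocks (whose structure differs between cohorts by
#' construction) and independent noise genes.  A subset of the twin block
#' drives the binary tumor/normal outcome through a logistic model.
#'
#' Genes are laid out as: twin block first, then the specific block, then
#' noise genes.  The specific block is correlated in both cohorts, but in
#' cohort B its loading signs are flipped for half the genes and the gene
#' order within the block is permuted, so its correlation vectors differ
#' strongly between cohorts.
#'
#' @slot nA,nB samples per cohort.
#' @slot p total number of genes.
#' @slot twinBlock,specificBlock,noiseGenes integer index vectors (disjoint).
#' @slot signalGenes integer indices (subset of the twin block) driving the
#'   outcome.
#' @slot effectSize log-odds increment per unit expression of each signal
#'   gene.
#' @slot rhoTwin,rhoSpecific within-block correlations, in (-1, 1).
#' @slot tumorFraction target marginal tumor prevalence per cohort.
#' @export
setClass("TwinScenario",
  representation(nA = "integer", nB = "integer", p = "integer",
                 twinBlock = "integer", specificBlock = "integer",
                 specificBlockSize = "integer",
                 noiseGenes = "integer", signalGenes = "integer",
                 effectSize = "numeric", rhoTwin = "numeric",
                 rhoSpecific = "numeric", tumorFraction = "numeric"))

setValidity("TwinScenario", function(object) {
  msg <- character()
  blocks <- c(object@twinBlock, object@specificBlock, object@noiseGenes)
  if (anyDuplicated(blocks)) msg <- c(msg, "gene blocks must be disjoint")
  if (!setequal(blocks, seq_len(object@p)))
    msg <- c(msg, "blocks must partition 1..p")
  if (!all(object@signalGenes %in% object@twinBlock))
    msg <- c(msg, "signal genes must lie in the twin block")
  for (rho in c(object@rhoTwin, object@rhoSpecific))
    if (rho <= -1 || rho >= 1) msg <- c(msg, "rho must lie in (-1, 1)")
  if (object@rhoTwin < 0)
    msg <- c(msg, "rhoTwin must be non-negative (equicorrelated twin block)")
  if (object@tumorFraction <= 0 || object@tumorFraction >= 1)
    msg <- c(msg, "tumorFraction must lie in (0, 1)")
  if (min(object@nA, object@nB) < 4) msg <- c(msg, "need at least 4 samples per cohort")
  if (length(msg)) msg else TRUE
})
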