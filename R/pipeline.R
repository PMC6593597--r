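#' @include simulate.R
NULL

#' End-to-end twiner analysis of two cohorts
#'
#' Convenience wrapper chaining the full method: per-cohort Pearson
#' correlation profiles (tumor samples by default), per-gene angular
#' distances and penalty weights, cohort merging over the shared genes,
#' the angular pre-filter, and the resampling stability protocol
#' comparing the plain elastic net with the twiner penalty.
#'
#' @param a,b per-disease [ExpressionDataset-class] objects.  Both are
#'   aligned to their shared genes first.
#' @param preprocess apply [preprocessExpression()] to each cohort first
#'   (set TRUE for raw FPKM-like input; default FALSE, data already
#'   log/z-scored).
#' @param sampleFilter samples used for the correlation matrices
#'   (default `"tumor_only"`).
#' @param includeSelf keep the self-correlation entry in the angular
#'   distance (default FALSE).
#' @param angleThreshold pre-filter threshold in degrees (default 75).
#' @param alpha,nRuns,cvFolds,trainFraction,freqThreshold,baseSeed
#'   protocol parameters passed to [runStability()].
#' @param ... further arguments to [runStability()].
#' @return list with `weights` (full [TwinerWeights-class]), `filtered`
#'   (output of [prefilterByAngle()]), and `stability`
#'   ([StabilityResult-class]).
#' @export
twinerAnalysis <- function(a, b, preprocess = FALSE,
                           sampleFilter = "tumor_only", includeSelf = FALSE,
                           angleThreshold = 75, alpha = 0.9, nRuns = 100,
                           cvFolds = 10, trainFraction = 0.75,
                           freqThreshold = 0.75, baseSeed = 1L, ...) {
  if (preprocess) {
    a <- preprocessExpression(a)
    b <- preprocessExpression(b)
  }
  shared <- intersect(geneIds(a), geneIds(b))
  if (length(shared) < 2) stop("cohorts share fewer than 2 genes")
  a <- subsetGenes(a, shared)
  b <- subsetGenes(b, shared)
  d <- angularDistance(correlationProfile(a, sampleFilter),
                       correlationProfile(b, sampleFilter),
                       includeSelf = includeSelf)
  w <- twinerWeights(d)
  merged <- mergeCohorts(a, b)
  filtered <- prefilterByAngle(merged, w, angleThreshold)
  stab <- runStability(filtered$dataset, filtered$weights, nRuns = nRuns,
                       alpha = alpha, cvFolds = cvFolds,
                       trainFraction = trainFraction,
                       freqThreshold = freqThreshold, baseSeed = baseSeed,
                       ...)
  list(weights = w, filtered = filtered, stability = stab)
}
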