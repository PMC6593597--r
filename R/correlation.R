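#' @include data-io.R
NULL

#' Pearson correlation profile of a cohort
#'
#' Computes the gene-by-gene Pearson correlation matrix of one disease
#' cohort; column j is gene j's correlation vector with every gene.  By
#' default only tumor samples are used, since the method targets the
#' disease's co-expression structure.
#'
#' @param x an [ExpressionDataset-class].
#' @param sampleFilter which samples enter the correlations:
#'   `"tumor_only"` (default), `"normal_only"` or `"all"`.
#' @return a [CorrelationProfile-class].
#' @export
correlationProfile <- function(x, sampleFilter = c("tumor_only", "all",
                                                   "normal_only")) {
  stopifnot(is(x, "ExpressionDataset"))
  sampleFilter <- match.arg(sampleFilter)
  lab <- sampleLabels(x)
  keep <- switch(sampleFilter,
                 all = rep(TRUE, length(lab)),
                 tumor_only = lab == 1L,
                 normal_only = lab == 0L)
  if (sum(keep) < 3)
    stop("need at least 3 samples after '", sampleFilter, "' filtering")
  m <- designMatrix(x)[keep, , drop = FALSE]
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance gene(s) after filtering: ",
         paste(utils::head(colnames(m)[sds == 0], 5L), collapse = ", "))
  cc <- stats::cor(m)
  cc[cc > 1] <- 1
  cc[cc < -1] <- -1
  cc <- (cc + t(cc)) / 2
  diag(cc) <- 1
  new("CorrelationProfile", correlations = cc,
      cohort = as.character(cohortTag(x)), sampleFilter = sampleFilter)
}

#' @describeIn correlationProfile gene identifiers of a profile.
#' @export
setMethod("geneIds", "CorrelationProfile", function(x) rownames(x@correlations))

#' @describeIn correlationProfile cohort tag of a profile.
#' @export
setMethod("cohortTag", "CorrelationProfile", function(x) x@cohort)

#' Correlation matrix of a CorrelationProfile
#' @param x a [CorrelationProfile-class].
#' @return the p-by-p numeric correlation matrix.
#' @export
correlationMatrix <- function(x) {
  stopifnot(is(x, "CorrelationProfile"))
  x@correlations
}

setMethod("show", "CorrelationProfile", function(object) {
  cat("CorrelationProfile (cohort ", object@cohort, ", ",
      object@sampleFilter, "): ", nrow(object@correlations),
      " genes\n", sep = "")
})

#' Per-gene angular distance between two correlation profiles
#'
#' For each gene j, the angle (in degrees) between its correlation vectors
#' in diseases A and B:
#' `d_j = arccos( <s_j^A, s_j^B> / (||s_j^A|| * ||s_j^B||) )`.
#' The angle depends only on the proportionality of the vectors, not their
#' magnitude, so similarly correlated genes get small distances.  With
#' `includeSelf = FALSE` (default) the self-correlation entry, which is 1
#' in both diseases and would uniformly deflate all angles, is removed
#' from each column first.
#'
#' The cosine is clamped to \[-1, 1\]; overshoot beyond 1e-12 raises an
#' error.
#'
#' @param a,b [CorrelationProfile-class] objects over identical gene sets
#'   in identical order.
#' @param includeSelf keep the self-correlation entry in each column.
#' @return named numeric vector of angular distances in degrees, in
#'   \[0, 180\].
#' @export
angularDistance <- function(a, b, includeSelf = FALSE) {
  stopifnot(is(a, "CorrelationProfile"), is(b, "CorrelationProfile"))
  if (!identical(geneIds(a), geneIds(b)))
    stop("profiles must cover identical gene sets in identical order")
  A <- a@correlations
  B <- b@correlations
  dot <- colSums(A * B)
  na2 <- colSums(A * A)
  nb2 <- colSums(B * B)
  if (!includeSelf) {
    # remove the diagonal entry (1 in both) from each column
    dot <- dot - 1
    na2 <- na2 - 1
    nb2 <- nb2 - 1
  }
  if (any(na2 <= 0) || any(nb2 <= 0))
    stop("zero-norm correlation column for gene(s): ",
         paste(utils::head(geneIds(a)[na2 <= 0 | nb2 <= 0], 5L),
               collapse = ", "))
  cosang <- dot / sqrt(na2 * nb2)
  if (any(abs(cosang) > 1 + 1e-12))
    stop("cosine overshoot beyond tolerance: ", max(abs(cosang)) - 1)
  cosang[cosang > 1] <- 1
  cosang[cosang < -1] <- -1
  stats::setNames(acos(cosang) * 180 / pi, geneIds(a))
}

#' Twiner penalty weights from angular distances
#'
#' Normalizes per-gene angular distances by their maximum to produce
#' elastic-net penalty factors `w_j = d_j / max_k d_k` in \[0, 1\]: twin
#' genes (small distance) are penalized less.  If every distance is 0 the
#' weights are all set to 0 (every gene unpenalized) with a warning, the
#' only consistent limit of "smaller distances, smaller penalties".
#'
#' @param distances named non-negative numeric vector of angular distances
#'   in degrees, as from [angularDistance()] (any unit works; the weights
#'   are unit-invariant).
#' @return a [TwinerWeights-class].
#' @export
twinerWeights <- function(distances) {
  if (anyNA(distances) || any(distances < 0))
    stop("distances must be non-negative and finite")
  if (is.null(names(distances)))
    names(distances) <- paste0("g", seq_along(distances))
  dmax <- max(distances)
  if (dmax == 0) {
    warning("all angular distances are zero; every gene is unpenalized")
    w <- rep(0, length(distances))
  } else {
    w <- as.numeric(distances) / dmax
  }
  new("TwinerWeights", geneIds = names(distances),
      distanceDeg = as.numeric(distances), weight = w)
}

#' @describeIn twinerWeights gene identifiers.
#' @param x a `TwinerWeights` object.
#' @export
setMethod("geneIds", "TwinerWeights", function(x) x@geneIds)

#' @describeIn twinerWeights angular distances (degrees), named by gene.
#' @export
setMethod("distanceDeg", "TwinerWeights", function(x)
  stats::setNames(x@distanceDeg, x@geneIds))

#' @describeIn twinerWeights penalty factors, named by gene.
#' @export
setMethod("weightVector", "TwinerWeights", function(x)
  stats::setNames(x@weight, x@geneIds))

setMethod("show", "TwinerWeights", function(object) {
  cat("TwinerWeights: ", length(object@geneIds), " genes; distance ",
      sprintf("%.1f-%.1f", min(object@distanceDeg), max(object@distanceDeg)),
      " deg\n", sep = "")
})

#' Angular-distance pre-filter
#'
#' Drops every gene whose angular distance is `thresholdDeg` or larger
#' (strictly-less-than rule: a gene at exactly the threshold is dropped)
#' from both the merged dataset and the weights.  Weights are not
#' renormalized afterwards: normalization by the maximum distance precedes
#' filtering.
#'
#' @param x merged [ExpressionDataset-class].
#' @param weights [TwinerWeights-class] covering the dataset's genes.
#' @param thresholdDeg angular threshold in degrees, in (0, 180\]
#'   (default 75).
#' @return list with elements `dataset`, `weights` (both restricted) and
#'   `dropped` (character vector of removed gene ids).
#' @export
prefilterByAngle <- function(x, weights, thresholdDeg = 75) {
  stopifnot(is(x, "ExpressionDataset"), is(weights, "TwinerWeights"),
            thresholdDeg > 0, thresholdDeg <= 180)
  d <- distanceDeg(weights)
  if (!all(geneIds(x) %in% names(d)))
    stop("weights lack some dataset genes")
  d <- d[geneIds(x)]
  keep <- names(d)[d < thresholdDeg]
  if (!length(keep)) stop("angular pre-filter removed every gene")
  dropped <- setdiff(geneIds(x), keep)
  sel <- match(keep, weights@geneIds)
  # weights are intentionally NOT renormalized: the division by the
  # maximum distance happens before filtering
  w <- new("TwinerWeights", geneIds = weights@geneIds[sel],
           distanceDeg = weights@distanceDeg[sel],
           weight = weights@weight[sel])
  ds <- new("ExpressionDataset", x[keep, ])
  list(dataset = ds, weights = w, dropped = dropped)
}

#' Write weights/distances as a three-column TSV
#'
#' Columns: `gene_id`, `distance_deg`, `weight`.
#'
#' @param x a [TwinerWeights-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeTwinerWeights <- function(x, path) {
  stopifnot(is(x, "TwinerWeights"))
  utils::write.table(
    data.frame(gene_id = x@geneIds, distance_deg = x@distanceDeg,
               weight = x@weight),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a correlation matrix as square TSV with header row and column
#'
#' @param x a [CorrelationProfile-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeCorrelationProfile <- function(x, path) {
  stopifnot(is(x, "CorrelationProfile"))
  m <- x@correlations
  out <- cbind(gene_id = rownames(m),
               matrix(sprintf("%.17g", m), nrow(m), ncol(m),
                      dimnames = dimnames(m)))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
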