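#' @include AllClasses.R
NULL

#' Gene identifiers of an object
#' @param x an object carrying gene ids.
#' @return character vector of gene identifiers.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' Sample identifiers of an object
#' @param x an object carrying sample ids.
#' @return character vector of sample identifiers.
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' Binary outcome labels (1 = tumor, 0 = normal)
#' @param x an [ExpressionDataset-class].
#' @return named integer vector, one entry per sample.
#' @export
setGeneric("sampleLabels", function(x) standardGeneric("sampleLabels"))

#' Cohort tag of an object
#' @param x an object carrying a cohort tag.
#' @return single character string (possibly `NA`).
#' @export
setGeneric("cohortTag", function(x) standardGeneric("cohortTag"))

#' Per-gene angular distances in degrees
#' @param x a [TwinerWeights-class].
#' @return named numeric vector of distances in \[0, 180\].
#' @export
setGeneric("distanceDeg", function(x) standardGeneric("distanceDeg"))

#' Per-gene elastic-net penalty factors
#' @param x a [TwinerWeights-class] (or a [PenaltySpec-class]).
#' @return named numeric vector of weights.
#' @export
setGeneric("weightVector", function(x) standardGeneric("weightVector"))

#' Genes with nonzero coefficient in a fit
#' @param x a [PenalizedFit-class].
#' @return character vector of gene ids.
#' @export
setGeneric("selectedGenes", function(x) standardGeneric("selectedGenes"))

#' Per-gene selection frequencies across resampling runs
#' @param x a [StabilityResult-class].
#' @return data.frame with columns gene_id, en, twiner.
#' @export
setGeneric("selectionFrequency", function(x) standardGeneric("selectionFrequency"))

#' Consensus gene signatures (selected in more than the threshold fraction
#' of runs)
#' @param x a [StabilityResult-class].
#' @param method `"en"`, `"twiner"`, or `NULL` for both.
#' @return character vector, or named list when `method` is `NULL`.
#' @export
setGeneric("consensusGenes", function(x, method = NULL) standardGeneric("consensusGenes"))

#' Per-run records of a stability analysis
#' @param x a [StabilityResult-class].
#' @return data.frame, one row per (run, method).
#' @export
setGeneric("runRecords", function(x) standardGeneric("runRecords"))
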