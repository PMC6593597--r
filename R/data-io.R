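#' @include AllGenerics.R
NULL

#' Construct an ExpressionDataset
#'
#' @param values numeric matrix of expression values with unique dimnames.
#'   Orientation is declared by `orientation`; internally genes are stored
#'   as rows (the Bioconductor convention).
#' @param labels binary outcome vector (1 = tumor, 0 = normal), one entry
#'   per sample, in sample order.
#' @param cohort optional single string tagging the cohort.
#' @param orientation `"samples_by_genes"` (default) or `"genes_by_samples"`,
#'   describing `values`.
#' @return an [ExpressionDataset-class].
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("s", 1:3), paste0("g", 1:4)))
#' ExpressionDataset(m, labels = c(1, 1, 0), cohort = "A")
#' @export
ExpressionDataset <- function(values, labels, cohort = NA_character_,
                              orientation = c("samples_by_genes",
                                              "genes_by_samples")) {
  orientation <- match.arg(orientation)
  if (orientation == "samples_by_genes") values <- t(values)
  storage.mode(values) <- "double"
  labels <- as.integer(labels)
  if (length(labels) != ncol(values))
    stop("'labels' must have one entry per sample (", ncol(values), ")")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values),
    colData = S4Vectors::DataFrame(label = labels, row.names = colnames(values)))
  S4Vectors::metadata(se)$cohort <- cohort
  new("ExpressionDataset", se)
}

#' @describeIn ExpressionDataset gene identifiers.
#' @param x an `ExpressionDataset`.
#' @export
setMethod("geneIds", "ExpressionDataset", function(x) rownames(x))

#' @describeIn ExpressionDataset sample identifiers.
#' @export
setMethod("sampleIds", "ExpressionDataset", function(x) colnames(x))

#' @describeIn ExpressionDataset binary outcome labels, named by sample.
#' @export
setMethod("sampleLabels", "ExpressionDataset", function(x) {
  lab <- SummarizedExperiment::colData(x)$label
  names(lab) <- colnames(x)
  lab
})

#' @describeIn ExpressionDataset cohort tag.
#' @export
setMethod("cohortTag", "ExpressionDataset", function(x) {
  tag <- S4Vectors::metadata(x)$cohort
  if (is.null(tag)) NA_character_ else tag
})

#' Design matrix (samples by genes) of an ExpressionDataset
#'
#' @param x an [ExpressionDataset-class].
#' @return numeric matrix, samples in rows, genes in columns.
#' @export
designMatrix <- function(x) {
  stopifnot(is(x, "ExpressionDataset"))
  t(SummarizedExperiment::assay(x, "exprs"))
}

setMethod("show", "ExpressionDataset", function(object) {
  lab <- sampleLabels(object)
  cat("ExpressionDataset (cohort ", cohortTag(object), "): ",
      nrow(object), " genes x ", ncol(object), " samples; ",
      sum(lab == 1L), " tumor / ", sum(lab == 0L), " normal\n", sep = "")
})

.parse_labels <- function(labels, sample_ids) {
  if (is.character(labels) && length(labels) == 1L && file.exists(labels)) {
    tab <- utils::read.table(labels, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    if (ncol(tab) == 1L) return(as.integer(tab[[1L]]))
    lab <- tab[[2L]]
    names(lab) <- tab[[1L]]
    missing <- setdiff(sample_ids, names(lab))
    if (length(missing))
      stop("label file lacks samples: ", paste(missing, collapse = ", "))
    return(as.integer(lab[sample_ids]))
  }
  as.integer(labels)
}

#' Read an expression matrix from delimited text
#'
#' Reads a delimited text matrix with a header and identifiers in the first
#' column, normalizing the declared orientation to the internal genes-by-
#' samples layout.  Duplicate gene identifiers are rejected.
#'
#' @param path file path of the delimited matrix.
#' @param orientation `"genes_in_columns"` (rows are samples) or
#'   `"genes_in_rows"` (rows are genes).
#' @param labels binary label vector in sample order, or the path of a
#'   label file (TSV: `sample_id<TAB>label`, or a single label column).
#' @param delimiter field separator (default tab).
#' @param cohort optional cohort tag.
#' @return an [ExpressionDataset-class].
#' @export
readExpression <- function(path, orientation = c("genes_in_columns",
                                                 "genes_in_rows"),
                           labels, delimiter = "\t",
                           cohort = NA_character_) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = delimiter,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           fill = FALSE, quote = "")
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate identifiers in first column: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  hdr <- colnames(tab)[-1L]
  if (anyDuplicated(hdr))   # checked pre-subset: data.frame `[` mangles dups
    stop("duplicate identifiers in header: ",
         paste(unique(hdr[duplicated(hdr)]), collapse = ", "))
  m <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric values in ", path)
  rownames(m) <- ids
  colnames(m) <- hdr
  if (orientation == "genes_in_columns") {
    ds_vals <- m                      # samples x genes
    ExpressionDataset(ds_vals, labels = .parse_labels(labels, rownames(m)),
                      cohort = cohort, orientation = "samples_by_genes")
  } else {
    ExpressionDataset(m, labels = .parse_labels(labels, colnames(m)),
                      cohort = cohort, orientation = "genes_by_samples")
  }
}

#' Write an expression matrix (and labels) as delimited text
#'
#' Values are written with 17 significant digits so that
#' `readExpression()` round-trips them exactly.
#'
#' @param x an [ExpressionDataset-class].
#' @param path output file path for the matrix.
#' @param orientation layout of the written matrix.
#' @param delimiter field separator.
#' @param labelsPath optional path for a two-column `sample_id`, `label`
#'   file.
#' @return `path`, invisibly.
#' @export
writeExpression <- function(x, path, orientation = c("genes_in_columns",
                                                     "genes_in_rows"),
                            delimiter = "\t", labelsPath = NULL) {
  orientation <- match.arg(orientation)
  m <- designMatrix(x)                # samples x genes
  if (orientation == "genes_in_rows") m <- t(m)
  fm <- matrix(sprintf("%.17g", m), nrow(m), ncol(m))
  out <- cbind(rownames(m), fm)
  colnames(out) <- c(if (orientation == "genes_in_columns") "sample_id"
                     else "gene_id", colnames(m))
  utils::write.table(out, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  if (!is.null(labelsPath)) {
    lab <- sampleLabels(x)
    utils::write.table(data.frame(sample_id = names(lab), label = lab),
                       labelsPath, sep = delimiter, quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  invisible(path)
}

#' Log-transform and Z-score normalize expression values
#'
#' Applies the standard RNA-Seq preprocessing for FPKM-like input: each
#' value becomes `log(value + logOffset)` (natural log) and each gene is
#' then standardized to mean 0, sd 1 across samples (sample sd, n - 1
#' denominator).  Genes with zero variance after the log transform are
#' dropped from the returned dataset and listed in
#' `metadata(x)$dropped_zero_variance`.
#'
#' @param x an [ExpressionDataset-class] with non-negative values.
#' @param logOffset positive pseudo-count added before the log (default 1).
#' @return a preprocessed [ExpressionDataset-class].
#' @export
preprocessExpression <- function(x, logOffset = 1) {
  stopifnot(is(x, "ExpressionDataset"), logOffset > 0)
  m <- SummarizedExperiment::assay(x, "exprs")
  if (any(m < 0))
    stop("negative expression values: input must be FPKM-like (>= 0)")
  m <- log(m + logOffset)
  sds <- apply(m, 1L, stats::sd)
  dropped <- rownames(m)[sds == 0]
  if (length(dropped)) {
    message("dropping ", length(dropped), " zero-variance gene(s): ",
            paste(utils::head(dropped, 5L), collapse = ", "),
            if (length(dropped) > 5L) ", ...")
    m <- m[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (!nrow(m)) stop("all genes have zero variance")
  m <- (m - rowMeans(m)) / sds
  out <- ExpressionDataset(m, labels = sampleLabels(x),
                           cohort = cohortTag(x),
                           orientation = "genes_by_samples")
  S4Vectors::metadata(out)$dropped_zero_variance <- dropped
  out
}

#' Restrict a dataset to a gene list
#'
#' Keeps the intersection of the dataset's genes with `keep`, preserving
#' the dataset's original gene order (the typical use is subsetting to a
#' protein-coding gene list).
#'
#' @param x an [ExpressionDataset-class].
#' @param keep character vector of gene ids to retain.
#' @return the restricted [ExpressionDataset-class]; the number of `keep`
#'   ids not present is stored in `metadata(x)$n_keep_missing`.
#' @export
subsetGenes <- function(x, keep) {
  stopifnot(is(x, "ExpressionDataset"))
  if (!length(keep)) stop("'keep' must be non-empty")
  sel <- geneIds(x) %in% keep
  if (!any(sel)) stop("no genes of the dataset appear in 'keep'")
  out <- x[sel, ]
  out <- new("ExpressionDataset", out)
  S4Vectors::metadata(out)$n_keep_missing <- sum(!(keep %in% geneIds(x)))
  out
}

#' Merge two cohorts into a single two-disease dataset
#'
#' Aligns the cohorts on their shared genes (in `a`'s gene order) and
#' concatenates samples, `a`'s samples first.  Labels are carried through,
#' so tumors of either disease form the positive class.
#'
#' @param a,b [ExpressionDataset-class] objects with disjoint sample ids.
#' @return merged [ExpressionDataset-class] with cohort tag `"merged"`.
#' @export
mergeCohorts <- function(a, b) {
  stopifnot(is(a, "ExpressionDataset"), is(b, "ExpressionDataset"))
  shared <- intersect(geneIds(a), geneIds(b))
  if (!length(shared)) stop("cohorts share no genes")
  if (length(common <- intersect(sampleIds(a), sampleIds(b))))
    stop("duplicate sample ids across cohorts: ",
         paste(utils::head(common, 5L), collapse = ", "))
  ma <- SummarizedExperiment::assay(a, "exprs")[shared, , drop = FALSE]
  mb <- SummarizedExperiment::assay(b, "exprs")[shared, , drop = FALSE]
  ExpressionDataset(cbind(ma, mb),
                    labels = c(sampleLabels(a), sampleLabels(b)),
                    cohort = "merged", orientation = "genes_by_samples")
}

#' Read a plain-text gene list (one identifier per line)
#'
#' @param path file path; blank lines are ignored.
#' @return character vector of gene ids.
#' @export
readGeneList <- function(path) {
  ids <- trimws(readLines(path))
  ids[nzchar(ids)]
}

#' SurvivalTable: follow-up times and event status
#'
#' Right-censored survival data aligned to an expression dataset's
#' samples.
#'
#' @slot samples character sample identifiers.
#' @slot time non-negative follow-up times.
#' @slot event integer event indicator (1 = event observed, 0 = censored).
#' @export
setClass("SurvivalTable",
  representation(samples = "character", time = "numeric", event = "integer"))

setValidity("SurvivalTable", function(object) {
  msg <- character()
  n <- length(object@samples)
  if (length(object@time) != n || length(object@event) != n)
    msg <- c(msg, "samples, time and event must have equal length")
  if (anyDuplicated(object@samples)) msg <- c(msg, "sample ids must be unique")
  if (any(object@time < 0) || anyNA(object@time))
    msg <- c(msg, "times must be non-negative")
  if (anyNA(object@event) || !all(object@event %in% c(0L, 1L)))
    msg <- c(msg, "event must be 0 (censored) or 1 (event)")
  if (length(msg)) msg else TRUE
})

#' @describeIn SurvivalTable constructor.
#' @param samples character sample ids.
#' @param time non-negative follow-up times.
#' @param event binary event indicators.
#' @export
SurvivalTable <- function(samples, time, event) {
  new("SurvivalTable", samples = as.character(samples),
      time = as.numeric(time), event = as.integer(event))
}

#' @describeIn SurvivalTable sample identifiers.
#' @param x a `SurvivalTable`.
#' @export
setMethod("sampleIds", "SurvivalTable", function(x) x@samples)

#' Follow-up times of a SurvivalTable
#' @param x a [SurvivalTable-class].
#' @return numeric vector named by sample.
#' @export
survTime <- function(x) { stats::setNames(x@time, x@samples) }

#' Event indicators of a SurvivalTable
#' @param x a [SurvivalTable-class].
#' @return integer vector named by sample (1 = event, 0 = censored).
#' @export
survEvent <- function(x) { stats::setNames(x@event, x@samples) }

setMethod("show", "SurvivalTable", function(object) {
  cat("SurvivalTable: ", length(object@samples), " samples, ",
      sum(object@event), " events\n", sep = "")
})

#' Read a survival table from delimited text
#'
#' Expects columns `sample_id`, `time`, `event`.
#'
#' @param path file path.
#' @param delimiter field separator.
#' @return a [SurvivalTable-class].
#' @export
readSurvivalTable <- function(path, delimiter = "\t") {
  tab <- utils::read.table(path, header = TRUE, sep = delimiter,
                           stringsAsFactors = FALSE)
  need <- c("sample_id", "time", "event")
  if (!all(need %in% colnames(tab)))
    stop("survival table needs columns: ", paste(need, collapse = ", "))
  SurvivalTable(tab$sample_id, tab$time, tab$event)
}
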