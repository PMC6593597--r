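#' @include metrics.R
NULL

#' Stratified train/test split
#'
#' Randomly partitions the samples into disjoint, exhaustive train and
#' test sets.  With `stratified = TRUE` (default) the split is drawn
#' within each class, preserving the class mix up to rounding.
#'
#' @param x an [ExpressionDataset-class].
#' @param trainFraction fraction of samples assigned to training
#'   (default 0.75).
#' @param seed integer seed; identical seeds give identical splits.
#' @param stratified preserve class proportions (default TRUE).
#' @return list with [ExpressionDataset-class] elements `train` and
#'   `test`.
#' @export
splitTrainTest <- function(x, trainFraction = 0.75, seed = 1L,
                           stratified = TRUE) {
  stopifnot(is(x, "ExpressionDataset"),
            trainFraction > 0, trainFraction < 1)
  lab <- sampleLabels(x)
  n <- length(lab)
  idx <- .with_seed(seed, {
    if (stratified) {
      unlist(lapply(unique(lab), function(cl) {
        cls <- which(lab == cl)
        sample(cls, round(length(cls) * trainFraction))
      }), use.names = FALSE)
    } else {
      sample(n, round(n * trainFraction))
    }
  })
  idx <- sort(idx)
  if (length(idx) == 0L || length(idx) == n)
    stop("degenerate split: empty train or test set")
  train <- new("ExpressionDataset", x[, idx])
  test <- new("ExpressionDataset", x[, -idx])
  for (part in list(train, test))
    if (length(unique(sampleLabels(part))) < 2)
      stop("a class is absent from the ",
           if (identical(part, train)) "training" else "test", " set")
  list(train = train, test = test)
}

.metric_row <- function(fit, train, test, cutoff = 0.5) {
  ptr <- predictProb(fit, train)
  pte <- predictProb(fit, test)
  ytr <- sampleLabels(train)
  yte <- sampleLabels(test)
  data.frame(
    train_mse = mseClassification(ptr, ytr),
    test_mse = mseClassification(pte, yte),
    train_auc_pr = aucPrecisionRecall(ptr, ytr),
    test_auc_pr = aucPrecisionRecall(pte, yte),
    train_miscl = misclassificationCount(ptr, ytr, cutoff),
    test_miscl = misclassificationCount(pte, yte, cutoff),
    n_selected = length(selectedGenes(fit)))
}

#' Resampling stability protocol comparing plain and twiner elastic nets
#'
#' Runs the full experimental protocol: `nRuns` random stratified
#' train/test splits; on each training set, for both methods -- `en`
#' (unit penalty factors) and `twiner` (angular-distance penalty factors)
#' -- lambda is chosen by stratified k-fold cross-validation and the model
#' refit at the optimum; Brier MSE, precision-recall AUC and
#' misclassification counts are recorded on train and test sets along
#' with the selected genes.  Both methods share each run's split, so the
#' comparison is paired.  Aggregates per-gene selection frequencies, the
#' consensus signatures (genes selected in strictly more than
#' `freqThreshold` of runs), per-method metric medians, and the Venn
#' decomposition of the two consensus sets.
#'
#' Run r uses seed `baseSeed + r` for its split and fold assignment, so
#' any single run can be reproduced in isolation.
#'
#' @param x merged [ExpressionDataset-class] (typically after
#'   [prefilterByAngle()]).
#' @param weights [TwinerWeights-class] aligned to the dataset's genes.
#' @param nRuns number of resampling runs (default 100).
#' @param alpha elastic-net mix (default 0.9).
#' @param cvFolds cross-validation folds (default 10).
#' @param trainFraction training fraction per split (default 0.75).
#' @param freqThreshold consensus frequency cutoff, strict `>` (default
#'   0.75).
#' @param baseSeed integer base seed (default 1).
#' @param metric cross-validation metric, `"mse"` or `"deviance"`.
#' @param nlambda,lambdaMinRatio,tol,maxIter solver/path controls, see
#'   [cvLambda()].
#' @param verbose print per-run progress.
#' @return a [StabilityResult-class].
#' @export
runStability <- function(x, weights, nRuns = 100, alpha = 0.9,
                         cvFolds = 10, trainFraction = 0.75,
                         freqThreshold = 0.75, baseSeed = 1L,
                         metric = "mse", nlambda = 100,
                         lambdaMinRatio = 1e-3, tol = 1e-7, maxIter = 1e5,
                         verbose = FALSE) {
  stopifnot(is(x, "ExpressionDataset"), is(weights, "TwinerWeights"),
            nRuns >= 1)
  wt <- weightVector(weights)
  if (!all(geneIds(x) %in% names(wt)))
    stop("weights lack some dataset genes")
  wt <- wt[geneIds(x)]
  specs <- list(en = PenaltySpec(alpha),
                twiner = PenaltySpec(alpha, weights = wt))
  genes <- geneIds(x)
  sel_count <- list(en = stats::setNames(numeric(length(genes)), genes),
                    twiner = stats::setNames(numeric(length(genes)), genes))
  rows <- vector("list", 2L * nRuns)

  for (r in seq_len(nRuns)) {
    seed <- as.integer(baseSeed + r)
    split <- tryCatch(
      splitTrainTest(x, trainFraction, seed = seed, stratified = TRUE),
      error = function(e) stop("run ", r, " (seed ", seed, ") failed: ",
                               conditionMessage(e)))
    for (m in names(specs)) {
      cv <- cvLambda(split$train, specs[[m]], k = cvFolds, metric = metric,
                     seed = seed, nlambda = nlambda,
                     lambdaMinRatio = lambdaMinRatio, tol = tol,
                     maxIter = maxIter)
      fit <- fitWeightedEnet(split$train,
                             PenaltySpec(alpha, cv$lambda_opt,
                                         specs[[m]]@weights),
                             tol = tol, maxIter = maxIter)
      sel <- selectedGenes(fit)
      sel_count[[m]][sel] <- sel_count[[m]][sel] + 1
      rows[[2L * (r - 1L) + match(m, names(specs))]] <- cbind(
        data.frame(run_id = r, method = m, seed = seed,
                   lambda_opt = cv$lambda_opt),
        .metric_row(fit, split$train, split$test),
        data.frame(selected_genes = paste(sel, collapse = ";")))
    }
    if (verbose)
      message("run ", r, "/", nRuns, " done (seed ", seed, ")")
  }

  records <- do.call(rbind, rows)
  freq <- data.frame(gene_id = genes,
                     en = unname(sel_count$en / nRuns),
                     twiner = unname(sel_count$twiner / nRuns))
  consensus <- lapply(sel_count, function(cnt)
    genes[cnt / nRuns > freqThreshold])
  metric_cols <- c("lambda_opt", "train_mse", "test_mse", "train_auc_pr",
                   "test_auc_pr", "train_miscl", "test_miscl", "n_selected")
  medians <- do.call(rbind, lapply(names(specs), function(m) {
    sub <- records[records$method == m, metric_cols, drop = FALSE]
    cbind(data.frame(method = m),
          as.data.frame(lapply(sub, stats::median)))
  }))
  venn <- list(en_only = setdiff(consensus$en, consensus$twiner),
               twiner_only = setdiff(consensus$twiner, consensus$en),
               shared = intersect(consensus$en, consensus$twiner))
  new("StabilityResult", records = records, selectionFrequency = freq,
      consensus = consensus, medians = medians, venn = venn,
      freqThreshold = freqThreshold,
      params = list(nRuns = nRuns, alpha = alpha, cvFolds = cvFolds,
                    trainFraction = trainFraction, baseSeed = baseSeed,
                    metric = metric, nlambda = nlambda,
                    lambdaMinRatio = lambdaMinRatio))
}

#' @describeIn runStability per-run records.
#' @export
setMethod("runRecords", "StabilityResult", function(x) x@records)

#' @describeIn runStability selection frequencies per gene and method.
#' @export
setMethod("selectionFrequency", "StabilityResult", function(x)
  x@selectionFrequency)

#' @describeIn runStability consensus signature(s).
#' @param method `"en"`, `"twiner"` or `NULL` for both.
#' @export
setMethod("consensusGenes", "StabilityResult", function(x, method = NULL) {
  if (is.null(method)) x@consensus
  else x@consensus[[match.arg(method, c("en", "twiner"))]]
})

setMethod("show", "StabilityResult", function(object) {
  cat("StabilityResult: ", object@params$nRuns, " runs, alpha=",
      object@params$alpha, "\n  consensus (freq > ",
      object@freqThreshold, "): en=", length(object@consensus$en),
      ", twiner=", length(object@consensus$twiner), " genes (",
      length(object@venn$shared), " shared)\n", sep = "")
})

#' Correlation network among selected genes
#'
#' All-pairs Pearson correlations among a gene signature, computed on the
#' requested sample subset, as a signed weighted edge list (one row per
#' unordered pair) suitable for network rendering: positive edges are the
#' usual "green", negative "red", and `abs_r` the display thickness.
#'
#' @param x an [ExpressionDataset-class].
#' @param genes character vector of at least 2 gene ids, all present in
#'   `x`.
#' @param sampleFilter `"tumor_only"`, `"normal_only"` or `"all"`.
#' @param minAbsCor optional floor on `|r|`; weaker edges are dropped
#'   (default 0, keep all).
#' @return data.frame with columns `gene_i`, `gene_j`, `r`, `sign`,
#'   `abs_r`.
#' @export
exportSelectedGeneNetwork <- function(x, genes,
                                      sampleFilter = c("tumor_only",
                                                       "normal_only", "all"),
                                      minAbsCor = 0) {
  sampleFilter <- match.arg(sampleFilter)
  stopifnot(is(x, "ExpressionDataset"))
  if (length(genes) < 2) stop("need at least 2 genes")
  missing <- setdiff(genes, geneIds(x))
  if (length(missing))
    stop("genes absent from dataset: ", paste(missing, collapse = ", "))
  prof <- correlationProfile(subsetGenes(x, genes), sampleFilter)
  m <- correlationMatrix(prof)
  ut <- which(upper.tri(m), arr.ind = TRUE)
  edges <- data.frame(gene_i = rownames(m)[ut[, 1L]],
                      gene_j = colnames(m)[ut[, 2L]],
                      r = m[ut])
  edges$sign <- ifelse(edges$r >= 0, "positive", "negative")
  edges$abs_r <- abs(edges$r)
  edges[edges$abs_r >= minAbsCor, , drop = FALSE]
}

#' Write a StabilityResult to a directory of delimited text files
#'
#' Emits `runs.tsv`, `frequency.tsv`, `medians.tsv`, `consensus_en.txt`,
#' `consensus_twiner.txt` and `venn.tsv`.
#'
#' @param x a [StabilityResult-class].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
writeStabilityResult <- function(x, dir) {
  stopifnot(is(x, "StabilityResult"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(obj, f) utils::write.table(
    obj, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(x@records, "runs.tsv")
  wt(x@selectionFrequency, "frequency.tsv")
  wt(x@medians, "medians.tsv")
  writeLines(x@consensus$en, file.path(dir, "consensus_en.txt"))
  writeLines(x@consensus$twiner, file.path(dir, "consensus_twiner.txt"))
  venn <- do.call(rbind, lapply(names(x@venn), function(nm)
    if (length(x@venn[[nm]]))
      data.frame(set = nm, gene_id = x@venn[[nm]]) else NULL))
  if (is.null(venn)) venn <- data.frame(set = character(), gene_id = character())
  wt(venn, "venn.tsv")
  invisible(dir)
}
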