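test_that("reading normalizes either orientation to the same dataset", {
  m <- matrix(c(1.5, 2, 0, 3.25, 4, 5), nrow = 3,
              dimnames = list(c("s1", "s2", "s3"), c("G1", "G2")))
  f1 <- tempfile(fileext = ".tsv")
  f2 <- tempfile(fileext = ".tsv")
  write.table(cbind(sample_id = rownames(m), m), f1, sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(cbind(gene_id = colnames(m), t(m)), f2, sep = "\t",
              quote = FALSE, row.names = FALSE)
  d1 <- readExpression(f1, "genes_in_columns", labels = c(1, 0, 1))
  d2 <- readExpression(f2, "genes_in_rows", labels = c(1, 0, 1))
  expect_equal(designMatrix(d1), m)
  expect_identical(designMatrix(d1), designMatrix(d2))
  expect_identical(sampleLabels(d1), sampleLabels(d2))
  expect_identical(geneIds(d1), c("G1", "G2"))
})

test_that("duplicate gene identifiers are rejected at read time", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "G1\t1\t2", "G1\t3\t4"), f)
  expect_error(readExpression(f, "genes_in_rows", labels = c(1, 0)),
               "duplicate")
  f2 <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tG1\tG1", "s1\t1\t2", "s2\t3\t4"), f2)
  expect_error(readExpression(f2, "genes_in_columns", labels = c(1, 0)),
               "duplicate")
})

test_that("write/read round-trips values exactly", {
  ds <- random_dataset(n = 7, p = 4, seed = 3)
  f <- tempfile(fileext = ".tsv")
  lf <- tempfile(fileext = ".tsv")
  writeExpression(ds, f, labelsPath = lf)
  back <- readExpression(f, "genes_in_columns", labels = lf)
  expect_identical(designMatrix(back), designMatrix(ds))
  expect_identical(unname(sampleLabels(back)), unname(sampleLabels(ds)))
})

test_that("preprocessing log-transforms, standardizes and drops flat genes", {
  vals <- cbind(G1 = c(0, 0, 0),                   # zero variance -> dropped
                G2 = c(1, exp(1) - 1, 3),
                G3 = c(0.5, 2, 7))
  rownames(vals) <- paste0("s", 1:3)
  ds <- ExpressionDataset(vals, labels = c(1, 0, 1))
  expect_message(out <- preprocessExpression(ds), "zero-variance")
  expect_identical(geneIds(out), c("G2", "G3"))
  expect_identical(S4Vectors::metadata(out)$dropped_zero_variance, "G1")
  # hand-computed: log(value + 1), then (x - mean) / sd with n - 1 denominator
  lg <- log(vals[, "G2"] + 1)
  expect_equal(unname(designMatrix(out)[, "G2"]),
               unname((lg - mean(lg)) / sd(lg)), tolerance = 1e-14)
  # every kept gene ends up exactly standardized
  m <- designMatrix(out)
  expect_lt(max(abs(colMeans(m))), 1e-12)
  expect_lt(max(abs(apply(m, 2, sd) - 1)), 1e-12)
})

test_that("preprocessing rejects negative (non-FPKM-like) input", {
  vals <- matrix(c(-1, 2, 3, 4), 2,
                 dimnames = list(c("s1", "s2"), c("G1", "G2")))
  ds <- ExpressionDataset(vals, labels = c(0, 1))
  expect_error(preprocessExpression(ds), "negative")
})

test_that("gene subsetting keeps order and errors on empty intersection", {
  ds <- random_dataset(n = 5, p = 3)
  expect_identical(geneIds(subsetGenes(ds, geneIds(ds))), geneIds(ds))
  one <- subsetGenes(ds, "g2")
  expect_identical(geneIds(one), "g2")
  expect_equal(designMatrix(one)[, 1], designMatrix(ds)[, "g2"])
  expect_error(subsetGenes(ds, c("nope1", "nope2")), "no genes")
  expect_error(subsetGenes(ds, character(0)), "non-empty")
})

test_that("cohort merging aligns shared genes to the first cohort's order", {
  set.seed(9)
  a <- random_dataset(n = 4, p = 4, seed = 9)
  mb <- matrix(rnorm(3 * 3), 3,
               dimnames = list(paste0("t", 1:3), c("g3", "g1", "g4")))
  b <- ExpressionDataset(mb, labels = c(1, 1, 0), cohort = "B")
  merged <- mergeCohorts(a, b)
  expect_identical(geneIds(merged), c("g1", "g3", "g4"))
  expect_equal(nrow(designMatrix(merged)), 7)
  # values of cohort B were permuted into cohort A's gene order
  expect_equal(designMatrix(merged)["t2", "g1"], mb["t2", "g1"])
  expect_equal(designMatrix(merged)["t2", "g3"], mb["t2", "g3"])
  expect_identical(unname(sampleLabels(merged)),
                   c(unname(sampleLabels(a)), 1L, 1L, 0L))
  # merge is symmetric up to row order
  m2 <- mergeCohorts(b, a)
  expect_setequal(sampleIds(m2), sampleIds(merged))
  expect_equal(designMatrix(m2)[sampleIds(merged), geneIds(merged)],
               designMatrix(merged))
})

test_that("cohort merging rejects duplicate samples and disjoint genes", {
  a <- random_dataset(n = 4, p = 3, seed = 2)
  expect_error(mergeCohorts(a, a), "duplicate sample")
  mb <- matrix(1:4, 2, dimnames = list(c("x1", "x2"), c("h1", "h2")))
  b <- ExpressionDataset(mb, labels = c(0, 1))
  expect_error(mergeCohorts(a, b), "share no genes")
})

test_that("survival tables validate and round-trip through text", {
  st <- SurvivalTable(c("s1", "s2"), c(5, 2.5), c(1, 0))
  expect_identical(unname(survEvent(st)), c(1L, 0L))
  expect_error(SurvivalTable("s1", -1, 1), "non-negative")
  expect_error(SurvivalTable(c("s1", "s1"), c(1, 2), c(1, 0)), "unique")
  f <- tempfile()
  write.table(data.frame(sample_id = c("a", "b"), time = c(1, 2),
                         event = c(0, 1)),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- readSurvivalTable(f)
  expect_identical(sampleIds(back), c("a", "b"))
})
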