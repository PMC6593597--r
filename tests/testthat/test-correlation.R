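test_that("correlation profiles match a brute-force Pearson loop", {
  set.seed(4)
  ds <- random_dataset(n = 20, p = 5, seed = 4)
  prof <- correlationProfile(ds, "all")
  m <- designMatrix(ds)
  for (i in 1:5) for (j in 1:5) {
    expect_equal(correlationMatrix(prof)[i, j],
                 cor(m[, i], m[, j]), tolerance = 1e-12)
  }
  expect_identical(geneIds(prof), geneIds(ds))
})

test_that("collinear and anti-collinear genes hit the correlation bounds", {
  x <- c(-1.2, 0.3, 1.1, 2.0)
  vals <- cbind(g1 = x, g2 = 2 * x + 3, g3 = -x)
  rownames(vals) <- paste0("s", 1:4)
  ds <- ExpressionDataset(vals, labels = c(1, 0, 1, 0))
  cc <- correlationMatrix(correlationProfile(ds, "all"))
  expect_equal(cc["g1", "g2"], 1)
  expect_equal(cc["g1", "g3"], -1)
})

test_that("sample filters and degenerate inputs are handled", {
  ds <- random_dataset(n = 12, p = 3, seed = 5)
  lab <- sampleLabels(ds)
  tum <- correlationProfile(ds, "tumor_only")
  m <- designMatrix(ds)[lab == 1, ]
  expect_equal(correlationMatrix(tum)[1, 2], cor(m[, 1], m[, 2]),
               tolerance = 1e-12)
  tiny <- new("ExpressionDataset", ds[, 1:2])
  expect_error(correlationProfile(tiny, "all"), "at least 3")
  flat <- designMatrix(ds)
  flat[, 2] <- 1
  dsf <- ExpressionDataset(flat, labels = lab)
  expect_error(correlationProfile(dsf, "all"), "zero-variance")
})

test_that("angular distance reproduces closed-form angles", {
  # identical profiles: all angles zero
  A <- random_profile(p = 5, seed = 11)
  expect_equal(unname(angularDistance(A, A)), rep(0, 5), tolerance = 1e-10)
  # orthogonal columns for gene 1: (1, 0) vs (0, 1) -> 90 degrees
  mA <- rbind(c(1, 1, 0), c(1, 1, 0.2), c(0, 0.2, 1))
  mB <- rbind(c(1, 0, 1), c(0, 1, 0.2), c(1, 0.2, 1))
  expect_equal(unname(angularDistance(profile_from_matrix(mA),
                                      profile_from_matrix(mB))[1]), 90)
  # (1, 1) vs (1, 0) -> 45 degrees
  mC <- matrix(1, 3, 3)
  expect_equal(unname(angularDistance(profile_from_matrix(mC),
                                      profile_from_matrix(mA))[1]), 45)
})

test_that("angular distance matches the brute-force oracle on random profiles", {
  for (seed in 1:5) {
    A <- random_profile(p = 6, seed = seed, cohort = "A")
    B <- random_profile(p = 6, seed = seed + 100, cohort = "B")
    for (self in c(FALSE, TRUE)) {
      got <- angularDistance(A, B, includeSelf = self)
      want <- oracle_angles(correlationMatrix(A), correlationMatrix(B),
                            include_self = self)
      expect_equal(unname(got), want, tolerance = 1e-10)
    }
  }
})

test_that("angular distance is symmetric and permutation-equivariant", {
  A <- random_profile(p = 6, seed = 21, cohort = "A")
  B <- random_profile(p = 6, seed = 22, cohort = "B")
  expect_identical(angularDistance(A, B), angularDistance(B, A))
  perm <- c(3, 1, 6, 2, 5, 4)
  pm <- function(P) profile_from_matrix(
    correlationMatrix(P)[perm, perm],
    genes = geneIds(P)[perm], cohort = cohortTag(P))
  expect_equal(angularDistance(pm(A), pm(B)),
               angularDistance(A, B)[perm], tolerance = 1e-12)
})

test_that("angular distance is invariant to column magnitude", {
  # the oracle applied to rescaled columns equals the package's distances:
  # the angle depends only on direction
  A <- random_profile(p = 6, seed = 31)
  B <- random_profile(p = 6, seed = 32, cohort = "B")
  got <- angularDistance(A, B)
  scaled <- correlationMatrix(A) %*% diag(c(2, 0.5, 7, 1, 3, 10))
  expect_equal(unname(got),
               oracle_angles(scaled, correlationMatrix(B)),
               tolerance = 1e-9)
})

test_that("angular distance rejects mismatched gene sets", {
  A <- random_profile(p = 4, seed = 1)
  B <- profile_from_matrix(correlationMatrix(random_profile(p = 4, seed = 2)),
                           genes = paste0("h", 1:4))
  expect_error(angularDistance(A, B), "identical gene sets")
})

test_that("weights normalize distances by their maximum", {
  w <- twinerWeights(c(a = 10, b = 20, c = 40))
  expect_equal(unname(weightVector(w)), c(0.25, 0.5, 1.0))
  expect_equal(max(weightVector(w)), 1)
  # equal distances reduce twiner to the plain elastic net
  expect_equal(unname(weightVector(twinerWeights(c(x = 30, y = 30)))),
               c(1, 1))
  # a zero-distance gene among others is unpenalized
  expect_equal(unname(weightVector(twinerWeights(c(x = 0, y = 10)))[1]), 0)
  expect_error(twinerWeights(c(-1, 2)), "non-negative")
  expect_warning(w0 <- twinerWeights(c(u = 0, v = 0)), "unpenalized")
  expect_equal(unname(weightVector(w0)), c(0, 0))
})

test_that("weights are invariant to the distance unit", {
  d <- c(g1 = 10, g2 = 25, g3 = 60)
  expect_equal(weightVector(twinerWeights(d)),
               weightVector(twinerWeights(d * pi / 180)))
})

test_that("the angular pre-filter applies a strict-less-than rule", {
  set.seed(6)
  ds <- random_dataset(n = 10, p = 3, seed = 6)
  w <- new("TwinerWeights", geneIds = geneIds(ds),
           distanceDeg = c(30, 80, 75), weight = c(30, 80, 75) / 80)
  out <- prefilterByAngle(ds, w, thresholdDeg = 75)
  # 80 and the boundary 75 are dropped; weights not renormalized
  expect_identical(geneIds(out$dataset), "g1")
  expect_setequal(out$dropped, c("g2", "g3"))
  expect_equal(unname(weightVector(out$weights)), 30 / 80)
  ident <- prefilterByAngle(ds, w, thresholdDeg = 180)
  expect_identical(geneIds(ident$dataset), geneIds(ds))
  wall <- new("TwinerWeights", geneIds = geneIds(ds),
              distanceDeg = c(90, 91, 92), weight = c(90, 91, 92) / 92)
  expect_error(prefilterByAngle(ds, wall, 75), "every gene")
})

test_that("twin-block genes survive the pre-filter preferentially", {
  sim <- generateTwinData(mini_scenario(), seed = 31)
  d <- angularDistance(correlationProfile(sim$a),
                       correlationProfile(sim$b))
  w <- twinerWeights(d)
  merged <- mergeCohorts(sim$a, sim$b)
  out <- prefilterByAngle(merged, w, 75)
  gt <- sim$ground_truth
  kept <- gt$gene_id %in% geneIds(out$dataset)
  frac_twin <- mean(kept[gt$block == "twin"])
  frac_spec <- mean(kept[gt$block == "specific"])
  expect_gt(frac_twin, frac_spec)
  expect_gt(frac_twin, 0.8)
})

test_that("twin/specific distance separation grows with sample size", {
  gap <- sapply(c(50, 200), function(n) {
    sc <- twinScenario(nA = n, nB = n, p = 60, twinSize = 10,
                       specificSize = 10, nSpecificBlocks = 2, nSignal = 3)
    sim <- generateTwinData(sc, seed = 77)
    d <- angularDistance(correlationProfile(sim$a, "all"),
                         correlationProfile(sim$b, "all"))
    gt <- sim$ground_truth
    median(d[gt$block == "specific"]) - median(d[gt$block == "twin"])
  })
  expect_gt(gap[1], 0)
  expect_gt(gap[2], gap[1])
})
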