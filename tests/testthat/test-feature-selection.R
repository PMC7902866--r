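test_that("fold coefficient averaging is the element-wise mean", {
  v <- c(1, -2, 3)
  expect_identical(averageFoldCoefficients(list(v, v)), v)
  expect_identical(averageFoldCoefficients(list(c(1, -1), c(-1, 1))), c(0, 0))
  set.seed(3)
  M <- matrix(rnorm(40), 8, 5)
  brute <- apply(M, 2, function(col) sum(col) / length(col))
  expect_equal(averageFoldCoefficients(M), brute, tolerance = 1e-12)
  expect_error(averageFoldCoefficients(list(1:3, 1:4)), "length")
})

test_that("features are ranked by |coefficient| with index tie-breaking", {
  expect_identical(as.integer(rankFeatures(c(0.1, -0.5, 0.3)))[1:3],
                   c(2L, 3L, 1L))
  expect_identical(as.integer(rankFeatures(c(0.2, 0.2)))[1:2], c(1L, 2L))
  set.seed(5)
  a <- rnorm(100)
  expect_identical(as.integer(rankFeatures(a)),
                   order(abs(a), decreasing = TRUE))  # no ties almost surely
  expect_error(rankFeatures(c(1, NaN)), "non-finite")
})

test_that("a unit-interval schedule reduces to exhaustive search", {
  err <- function(idx) abs(length(idx) - 13) + 1  # deterministic evaluator
  r <- coarseToFineSearch(1:20, schedule = 1L, evaluator = err)
  expect_equal(nrow(r$trace), 20)
  expect_equal(r$mStar, 13L)
  expect_identical(r$indices, 1:13)
})

test_that("coarse-to-fine equals exhaustive search on unimodal error curves", {
  # bracketing guarantee: for a unimodal curve the coarse best is within one
  # coarse interval of the global optimum, so the fine stage must find it
  for (m0 in c(1, 3, 17, 25, 38, 50)) {
    err <- function(idx) (length(idx) - m0)^2 + 0.5
    ex <- coarseToFineSearch(1:50, 1L, err)
    cf <- coarseToFineSearch(1:50, c(10L, 1L), err)
    expect_equal(cf$mStar, ex$mStar)
    expect_true(all(cf$trace$m >= 1 & cf$trace$m <= 50))
  }
  # asymmetric unimodal shape
  err <- function(idx) { m <- length(idx); ifelse(m < 23, 40 - m, 2 * m) }
  expect_equal(coarseToFineSearch(1:50, c(10L, 1L), err)$mStar,
               coarseToFineSearch(1:50, 1L, err)$mStar)
})

test_that("invalid schedules and empty candidate sets are rejected", {
  err <- function(idx) length(idx)
  expect_error(coarseToFineSearch(1:10, c(10, 100), err), "decreasing")
  expect_error(coarseToFineSearch(1:10, c(5, 2), err), "end at 1")
  expect_error(coarseToFineSearch(integer(0), 1L, err, K = 0), "empty")
})

test_that("group-level search recovers planted features among noise", {
  hits <- 0L
  for (seed in 1:10) {
    set.seed(seed)
    N <- 60; K <- 200
    X <- matrix(rnorm(N * K), N, K)
    y <- drop(X[, 1:5] %*% c(2, -2, 2, -2, 2)) + rnorm(N, 0, 1)
    sel <- selectFeatures(X, y, mode = "group_level", schedule = c(10L, 1L))
    if (all(1:5 %in% selectedFeatures(sel))) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("group-level selection on tiny problems is deterministic and exhaustive", {
  set.seed(2)
  X <- matrix(rnorm(30), 10, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  y <- drop(X %*% c(1, 0.2, 0)) + rnorm(10, 0, 0.1)
  s1 <- selectFeatures(X, y, mode = "group_level", schedule = 1L)
  s2 <- selectFeatures(X, y, mode = "group_level", schedule = 1L)
  expect_equal(nrow(searchTrace(s1)), 3)
  expect_identical(searchTrace(s1), searchTrace(s2))
  expect_identical(selectedFeatures(s1), selectedFeatures(s2))
  expect_true(s1@mStar %in% 1:3)
})

test_that("planted-set recall improves with planted effect size", {
  recallAt <- function(r2, seeds = 1:2) {
    mean(vapply(seeds, function(seed) {
      gen <- generateCohort(cohortSpec(
        nParticipants = 50, nRois = 12, nVoxels = 30,
        roiMeanBase = 0.55, roiSigmaBase = seq(0.08, 0.14, length.out = 12),
        subjectSd = 0.05, plantedEdges = cbind(c(1, 3, 5, 7), c(2, 4, 6, 8)),
        plantedWeights = c(1, -1, 1, -1), plantedR2 = r2, seed = seed))
      X <- gen$truth$trueMC   # closed-form features isolate selection quality
      y <- gen$phenotypes$laser_threshold_J
      sel <- selectFeatures(X, y, mode = "group_level", schedule = c(10L, 1L))
      mean(gen$truth$plantedFeatureIdx %in% selectedFeatures(sel))
    }, numeric(1)))
  }
  r <- c(recallAt(0.2), recallAt(0.6), recallAt(0.95))
  expect_true(all(diff(r) >= 0))
  expect_gt(r[3], r[1])
})

test_that("nested selection reports per-fold subsets and their consensus", {
  set.seed(9)
  N <- 24; K <- 15
  X <- matrix(rnorm(N * K), N, K)
  y <- drop(X[, 1:2] %*% c(3, -3)) + rnorm(N, 0, 0.5)
  sel <- selectFeatures(X, y, mode = "nested", schedule = 1L)
  expect_length(sel@perFold, N)
  expect_true(all(vapply(sel@perFold, function(ix) all(ix %in% 1:K),
                         logical(1))))
  expect_identical(selectedFeatures(sel), sel@consensus)
  expect_length(predictions(sel), N)
  expect_true(all(c(1L, 2L) %in% sel@consensus))
})
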