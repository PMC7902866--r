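test_that("Gaussian symmetrized KL matches closed forms and quadrature", {
  expect_identical(gaussianSymmetricKL(0, 1, 0, 1), 0)
  # equal SDs: (mu1 - mu2)^2 / sigma^2
  expect_equal(gaussianSymmetricKL(0, 1, 1, 1), 1.0, tolerance = 1e-12)
  # equal means: (sd1^2/sd2^2 + sd2^2/sd1^2)/2 - 1
  expect_equal(gaussianSymmetricKL(0, 1, 0, 2), 1.125, tolerance = 1e-12)

  # numerical-quadrature oracle on random parameter pairs
  quadSKL <- function(m1, s1, m2, s2) {
    f <- function(x) {
      p <- dnorm(x, m1, s1); q <- dnorm(x, m2, s2)
      (p - q) * (dnorm(x, m1, s1, log = TRUE) - dnorm(x, m2, s2, log = TRUE))
    }
    integrate(f, -Inf, Inf, rel.tol = 1e-10)$value
  }
  set.seed(7)
  for (i in 1:10) {
    m1 <- rnorm(1); m2 <- rnorm(1)
    s1 <- runif(1, 0.3, 2); s2 <- runif(1, 0.3, 2)
    v <- gaussianSymmetricKL(m1, s1, m2, s2)
    expect_equal(v, quadSKL(m1, s1, m2, s2), tolerance = 1e-6)
    expect_identical(v, gaussianSymmetricKL(m2, s2, m1, s1))
    expect_gte(v, 0)
  }
  expect_error(gaussianSymmetricKL(0, 0, 0, 1), "must be finite and > 0")
  expect_error(gaussianSymmetricKL(0, 1, 0, -2), "must be finite and > 0")
})

test_that("generateCohort is reproducible from its seed", {
  spec <- cohortSpec(nParticipants = 20, nRois = 6, nVoxels = 40, seed = 7)
  a <- generateCohort(spec)
  b <- generateCohort(spec)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$truth$trueMC, b$truth$trueMC)
  expect_identical(roiSamples(a$samples, "sub-003", "ROI_05_L"),
                   roiSamples(b$samples, "sub-003", "ROI_05_L"))
})

test_that("noise-free planting makes the laser threshold a perfect affine image of the predictor", {
  spec <- cohortSpec(nParticipants = 25, nRois = 6, nVoxels = 30,
                    noiseSd = c(0, 0), plantedR2 = NA, seed = 3)
  gen <- generateCohort(spec)
  expect_equal(cor(gen$truth$linPredLaser, gen$phenotypes$laser_threshold_J),
               1, tolerance = 1e-12)
})

test_that("generated thresholds respect the cohort calibration targets", {
  gen <- generateCohort(cohortSpec(nParticipants = 120, nRois = 8,
                                   nVoxels = 30, seed = 11))
  la <- gen$phenotypes$laser_threshold_J
  co <- gen$phenotypes$cold_threshold_s
  expect_true(all(la >= 1.75 & la <= 4.25))
  # cold thresholds are standardized onto the target mean/SD
  expect_equal(mean(co), 9.59, tolerance = 1e-8)
  expect_equal(sd(co), 0.38, tolerance = 1e-8)
})

test_that("cohort specs reject invalid planted edges and parameters", {
  expect_error(cohortSpec(nRois = 5, plantedEdges = cbind(1, 9)),
               "missing ROI")
  expect_error(cohortSpec(nRois = 5, plantedEdges = cbind(2, 2)),
               "distinct ROIs")
  expect_error(cohortSpec(nRois = 5,
                          plantedEdges = rbind(c(1, 2), c(2, 1))),
               "distinct unordered pairs")
  expect_error(cohortSpec(nRois = 2), "nRois")
  expect_error(cohortSpec(noiseSd = c(-1, 1), plantedR2 = NA), "noiseSd")
  expect_error(cohortSpec(laserRange = c(4, 2)), "laserRange")
})

test_that("ground-truth MC is symmetric in pair order and zero for identical parameters", {
  gen <- generateCohort(cohortSpec(nParticipants = 5, nRois = 5,
                                   nVoxels = 30, seed = 2))
  tru <- gen$truth$trueMC
  expect_true(all(tru >= 0))
  mu <- gen$truth$mu; sg <- gen$truth$sigma
  expect_identical(gaussianSymmetricKL(mu[1, 1], sg[1], mu[1, 2], sg[2]),
                   gaussianSymmetricKL(mu[1, 2], sg[2], mu[1, 1], sg[1]))
  expect_identical(gaussianSymmetricKL(mu[2, 3], sg[3], mu[2, 3], sg[3]), 0)
})

test_that("empirical MC from drawn voxels converges to the closed-form truth", {
  # mean-driven divergences (equal sigmas): per-edge plug-in KL estimates at
  # n = 5000 carry a few-percent Monte-Carlo dispersion, so the convergence
  # statistic is the cohort median; sigma-contrast pairs are excluded because
  # KDE tail under-coverage biases those upward (see the methods vignette)
  spec <- cohortSpec(nParticipants = 3, nRois = 6, nVoxels = 5000,
                     roiMeanBase = seq(0.45, 0.66, length.out = 6),
                     roiSigmaBase = 0.12, subjectSd = 0.03,
                     plantedEdges = cbind(1, 2), seed = 1)
  gen <- generateCohort(spec)
  emp <- mcFeatureMatrix(buildCohortMC(gen$samples))
  tru <- gen$truth$trueMC
  sel <- tru >= 0.5 & tru <= 2.5
  expect_gt(sum(sel), 10)
  rel <- abs(emp[sel] - tru[sel]) / tru[sel]
  expect_lt(median(rel), 0.05)
  expect_lt(max(rel), 0.20)
})
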