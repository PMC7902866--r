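makePhen <- function(laser, cold) {
  data.frame(participant_id = sprintf("p%02d", seq_along(laser)),
             laser_threshold_J = laser, cold_threshold_s = cold,
             stringsAsFactors = FALSE)
}

test_that("pain sensitivity scores are the mean of min-max-normalized thresholds", {
  ph <- makePhen(c(2.0, 2.5, 3.0, 4.0), c(8, 9, 10, 12))
  sc <- computePainScores(ph)
  expect_equal(sc$laser_norm, (ph$laser_threshold_J - 2) / 2, tolerance = 1e-12)
  expect_equal(sc$pain_sensitivity_score,
               (sc$laser_norm + sc$cold_norm) / 2, tolerance = 1e-12)
  # participant at the cohort max of both thresholds scores exactly 1
  expect_equal(sc$pain_sensitivity_score[4], 1)
  expect_true(all(sc$pain_sensitivity_score >= 0 &
                  sc$pain_sensitivity_score <= 1))
  # mixed normalized values average as expected
  expect_equal(mean(c(0.2, 0.8)), 0.5)
  expect_error(computePainScores(makePhen(rep(2, 4), c(8, 9, 10, 12))),
               "constant")
  expect_error(computePainScores(makePhen(c(2, -1, 3), c(8, 9, 10))),
               "> 0")
})

test_that("error metrics match their definitions", {
  expect_equal(as.numeric(mae(c(2, 3), c(2.5, 2.5))), 0.5)
  expect_equal(as.numeric(mrae(c(1.1, 1.8), c(1, 2))), 0.1, tolerance = 1e-12)
  y <- c(1.2, 3.4, 2.2)
  expect_equal(as.numeric(mae(y, y)), 0)
  expect_equal(as.numeric(mrae(y, y)), 0)
  expect_equal(pearsonR(y, y), 1)
  set.seed(4)
  yh <- rnorm(50, 5); yt <- rnorm(50, 5)
  expect_equal(as.numeric(mae(yh, yt)), sum(abs(yh - yt)) / 50,
               tolerance = 1e-12)
  expect_equal(as.numeric(mrae(yh, yt)), sum(abs((yh - yt) / yt)) / 50,
               tolerance = 1e-12)
  expect_equal(pearsonR(yh, yt),
               cov(yh, yt) / (sd(yh) * sd(yt)), tolerance = 1e-12)
  expect_error(mrae(c(1, 2), c(0, 2)), "zero true value")
  expect_error(mae(1:3, 1:4), "length mismatch")
})

test_that("evaluation reports assemble per-participant errors and summaries", {
  set.seed(5)
  y <- runif(20, 2, 4); yh <- y + rnorm(20, 0, 0.3)
  names(yh) <- sprintf("p%02d", 1:20)
  rep <- evaluatePrediction(yh, y, featureSet = "mc", thresholdType = "laser")
  expect_equal(rep$mae, mean(abs(yh - y)), tolerance = 1e-12)
  expect_equal(rep$n, 20)
  expect_equal(nrow(rep$per_participant), 20)
  expect_false(anyDuplicated(rep$per_participant$participant_id) > 0)
})

test_that("rank-sum comparison uses the normal approximation and matches enumeration", {
  e <- c(0.3, 0.5, 0.1, 0.9)
  r <- compareErrorSets(e, e)
  expect_gt(r$p, 1 - 1e-6)
  # U statistic vs brute-force enumeration over all C(6,3) rank assignments
  A <- c(1, 2, 3); B <- c(4, 5, 6)
  r2 <- compareErrorSets(A, B)
  U <- sum(outer(A, B, ">")) + 0.5 * sum(outer(A, B, "=="))
  expect_equal(unname(r2$statistic), U)
  allU <- apply(combn(6, 3), 2, function(ix) {
    a <- (1:6)[ix]; b <- setdiff(1:6, a)
    sum(outer(a, b, ">"))
  })
  expect_equal(mean(allU <= U) * 2, 0.1)  # exact two-sided p for this layout
  expect_lt(r2$p, 0.1)                    # approximation agrees in direction
  set.seed(10)
  a <- abs(rnorm(200)); b <- abs(rnorm(200)) + 0.5  # half-SD shifted errors
  expect_lt(compareErrorSets(a, b)$p, 0.01)
  expect_error(compareErrorSets(numeric(0), 1:3), "empty")
})

test_that("correlation comparison is exact under identical predictions", {
  set.seed(11)
  y <- rnorm(40); p <- y + rnorm(40)
  r <- compareCorrelations(p, p, y, B = 200, seed = 1)
  expect_equal(r$p, 1)
  expect_equal(r$statistic, 0)
  expect_error(compareCorrelations(p, p, y, B = 0), "B must be > 0")
  z <- compareCorrelations(p, rnorm(40), y, method = "ztest")
  expect_true(z$p >= 0 && z$p <= 1)
})

test_that("lobe-pair counts conserve the selected-edge total", {
  parc <- syntheticParcellation(32)   # two ROIs per hemisphere-lobe group
  lob <- lobeLabels(parc)
  ij <- painMC:::.lowerPairs(32)
  # build a planted selection concentrated in two lobe pairs
  pairKey <- ifelse(lob[ij[, 1]] <= lob[ij[, 2]],
                    paste(lob[ij[, 1]], lob[ij[, 2]]),
                    paste(lob[ij[, 2]], lob[ij[, 1]]))
  k1 <- names(sort(table(pairKey), decreasing = TRUE))[1]
  k2 <- names(sort(table(pairKey), decreasing = TRUE))[2]
  idx <- c(which(pairKey == k1)[1:3], which(pairKey == k2)[1:2])
  counts <- lobePairCounts(idx, parc, topK = 2)
  expect_equal(sum(counts$n), length(idx))
  expect_setequal(paste(counts$lobe_a, counts$lobe_b)[counts$top],
                  c(k1, k2))
  # single concentrated pair
  c1 <- lobePairCounts(which(pairKey == k1)[1:3], parc)
  expect_equal(nrow(c1), 1)
  expect_equal(c1$n, 3L)
  expect_error(lobePairCounts(10^6, parc), "feature range")
})

test_that("lobe-pair set algebra mirrors common/unique summaries", {
  a <- data.frame(lobe_a = c("Prefrontal_L", "Occipital_L"),
                  lobe_b = c("Prefrontal_R", "Occipital_R"),
                  n = c(5L, 3L), top = c(TRUE, TRUE))
  b <- data.frame(lobe_a = c("Prefrontal_L", "Temporal_L"),
                  lobe_b = c("Prefrontal_R", "Temporal_R"),
                  n = c(4L, 2L), top = c(TRUE, TRUE))
  ops <- lobePairSetOps(a, b)
  expect_equal(ops$common$lobe_a, "Prefrontal_L")
  expect_equal(ops$onlyA$lobe_a, "Occipital_L")
  expect_equal(ops$onlyB$lobe_a, "Temporal_L")
})

test_that("MC-GMV correlation flags duplicated features and respects permutations", {
  set.seed(12)
  n <- 40
  gmv <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("g", 1:4)))
  mcf <- cbind(gmv[, 2], matrix(rnorm(n * 3), n, 3))
  colnames(mcf) <- paste0("m", 1:4)
  r <- mcGmvCorrelation(mcf, gmv)
  expect_equal(r$r["m1", "g2"], 1, tolerance = 1e-12)
  expect_true(r$significant["m1", "g2"])
  perm <- sample(n)
  r2 <- mcGmvCorrelation(mcf[perm, ], gmv[perm, ])
  expect_equal(r$r, r2$r, tolerance = 1e-12)
  # constant feature flagged as NA, not an error
  mcf2 <- mcf; mcf2[, 2] <- 1
  r3 <- mcGmvCorrelation(mcf2, gmv)
  expect_true(all(is.na(r3$r["m2", ])))
})

test_that("independent noise features stay mostly non-significant under BH", {
  set.seed(13)
  n <- 100
  mcf <- matrix(rnorm(n * 30), n, 30)
  gmv <- matrix(rnorm(n * 5), n, 5)
  r <- mcGmvCorrelation(mcf, gmv)
  expect_lte(mean(r$significant), 0.07)
})
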