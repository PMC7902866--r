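# NIfTI fixtures are built in code: a 10x10x10 atlas with two labeled ROIs
# and per-participant gray-matter images on the same grid.
makeNiftiFixture <- function(dir, values = c(0.3, 0.7), jitter = 0) {
  atlas <- array(0L, dim = c(10, 10, 10))
  atlas[1:4, , ] <- 1L      # 400 voxels
  atlas[6:10, 1:5, ] <- 2L  # 250 voxels
  atlasPath <- file.path(dir, "atlas.nii.gz")
  RNifti::writeNifti(atlas, atlasPath)
  paths <- character(2)
  set.seed(99)
  for (i in 1:2) {
    img <- array(0, dim = c(10, 10, 10))
    img[atlas == 1L] <- values[1] + rnorm(400, 0, jitter)
    img[atlas == 2L] <- values[2] + rnorm(250, 0, jitter)
    paths[i] <- file.path(dir, sprintf("sub%02d.nii.gz", i))
    RNifti::writeNifti(img, paths[i])
  }
  names(paths) <- c("sub01", "sub02")
  list(atlas = atlasPath, gm = paths)
}

twoRoiParc <- Parcellation(data.frame(
  roi_id = 1:2, name = c("RegionA_L", "RegionB_R"),
  hemisphere = c("L", "R"), lobe = c("prefrontal", "occipital")))

test_that("ROI samples are extracted by atlas label with the right counts", {
  d <- withr::local_tempdir()
  fx <- makeNiftiFixture(d)
  ss <- extractROISamples(fx$gm, fx$atlas, twoRoiParc)
  expect_identical(participants(ss), c("sub01", "sub02"))
  a <- roiSamples(ss, "sub01", "RegionA_L")
  b <- roiSamples(ss, "sub01", "RegionB_R")
  expect_length(a, 400)  # label-1 voxel count by construction
  expect_length(b, 250)
  expect_true(all(a == 0.3) && all(b == 0.7))
})

test_that("extraction is keyed by participant id, not file order", {
  d <- withr::local_tempdir()
  fx <- makeNiftiFixture(d, jitter = 0.02)
  s1 <- extractROISamples(fx$gm, fx$atlas, twoRoiParc)
  s2 <- extractROISamples(rev(fx$gm), fx$atlas, twoRoiParc)
  expect_identical(participants(s1), participants(s2))
  expect_identical(roiSamples(s1, "sub02", "RegionA_L"),
                   roiSamples(s2, "sub02", "RegionA_L"))
})

test_that("extraction errors name missing ROIs, grid mismatches and NaNs", {
  d <- withr::local_tempdir()
  fx <- makeNiftiFixture(d)
  parc3 <- Parcellation(rbind(roiTable(twoRoiParc),
                              data.frame(roi_id = 3, name = "RegionC_L",
                                         hemisphere = "L", lobe = "insula")))
  expect_error(extractROISamples(fx$gm, fx$atlas, parc3), "3")
  small <- array(0.5, dim = c(8, 8, 8))
  sp <- file.path(d, "small.nii.gz")
  RNifti::writeNifti(small, sp)
  expect_error(extractROISamples(c(sub01 = sp), fx$atlas, twoRoiParc),
               "grid mismatch")
  bad <- RNifti::readNifti(fx$gm[1])
  bad[1, 1, 1] <- NaN
  bp <- file.path(d, "bad.nii.gz")
  RNifti::writeNifti(bad, bp)
  expect_error(extractROISamples(c(sub01 = bp), fx$atlas, twoRoiParc), "NaN")
})

test_that("GMV is the intensity sum times voxel volume, or the mean", {
  ss <- ROISampleSet(list(p1 = list(RegionA_L = c(0.5, 0.5),
                                    RegionB_R = c(0.2, 0.4, 0.6))),
                     twoRoiParc)
  g <- computeGMV(ss, voxelVolume = 1)
  expect_equal(g["p1", "RegionA_L"], 1.0)
  gm <- computeGMV(ss, mode = "mean")
  expect_equal(unname(gm["p1", ]), c(0.5, 0.4))
  g2 <- computeGMV(ss, voxelVolume = 1.5^3)
  expect_equal(g2["p1", "RegionA_L"], 1.0 * 1.5^3)
})

test_that("GMV tables follow the cohort and parcellation shape", {
  gen <- tinyCohort(seed = 5, nParticipants = 12, nRois = 8, nVoxels = 25)
  g <- computeGMV(gen$samples)
  expect_equal(dim(g), c(12, 8))
  expect_identical(colnames(g), roiNames(parcellation(gen$samples)))
  expect_true(all(is.finite(g)) && all(g >= 0))
})

test_that("long-format TSV round-trips a sample set", {
  gen <- tinyCohort(seed = 2, nParticipants = 4, nRois = 4, nVoxels = 15)
  f <- tempfile(fileext = ".tsv")
  writeROISamplesTSV(gen$samples, f)
  back <- readROISamplesTSV(f, parcellation(gen$samples))
  expect_identical(participants(back), participants(gen$samples))
  expect_equal(roiSamples(back, "sub-002", "ROI_03_L"),
               roiSamples(gen$samples, "sub-002", "ROI_03_L"),
               tolerance = 1e-12)
})

test_that("long tables with missing cells or too few voxels are rejected", {
  parc <- syntheticParcellation(3)
  df <- expand.grid(participant_id = "p1", roi_id = 1:2)
  df <- df[rep(seq_len(nrow(df)), each = 12), ]
  df$value <- rnorm(nrow(df), 0.5, 0.05)
  expect_error(roiSampleSetFromLong(df, parc), "missing ROI")
  df3 <- data.frame(participant_id = "p1",
                    roi_id = rep(1:3, times = c(12, 12, 3)),
                    value = rnorm(27, 0.5, 0.05))
  expect_error(roiSampleSetFromLong(df3, parc), "minVoxels")
})
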