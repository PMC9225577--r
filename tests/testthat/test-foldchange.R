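test_that("fold changes are the mean ratio minus one, gated at alpha", {
  phe <- makeToyTargeted()
  fc <- gatedFoldChanges(phe)
  m <- foldChanges(fc)
  ## ala: clear depletion; independent two-sample oracle confirms the
  ## difference is real at these values
  oracle <- t.test(c(45, 50, 55), c(100, 110, 90), var.equal = TRUE)
  expect_lt(oracle$p.value, 0.05)
  expect_equal(m["ala", "iso1"], 50 / 100 - 1)
  ## glc: within-noise difference is gated to exactly 0
  oracle2 <- t.test(c(95, 105, 100), c(100, 110, 90), var.equal = TRUE)
  expect_gt(oracle2$p.value, 0.05)
  expect_identical(m["glc", "iso1"], 0)
  ## suc: production shows as positive fold change
  expect_equal(m["suc", "iso1"], 300 / 100 - 1)
  ## urea: spent equals control replicate-for-replicate
  expect_identical(m["urea", "iso1"], 0)
  expect_true(validObject(fc))
})

test_that("perturbing a gated cell within noise leaves it at zero", {
  phe <- makeToyTargeted()
  h <- peakHeights(phe)
  for (delta in c(-2, 0, 2)) {
    h["glc", 1:3] <- c(95, 105, 100) + delta
    phe2 <- PeakHeightExperiment(h, as.data.frame(colData(phe)),
                                 "targeted")
    m <- foldChanges(gatedFoldChanges(phe2))
    expect_identical(m["glc", "iso1"], 0)
  }
})

test_that("lowering alpha can only shrink the significant support", {
  truth <- simulateTruth(nIsolates = 4, nMetabolites = 25, seed = 5,
                         crossFeeding = FALSE)
  mono <- simulateMonocultures(truth, cv = 0.15, seed = 6)
  loose <- foldChanges(gatedFoldChanges(mono$peaks, alpha = 0.05)) != 0
  strict <- foldChanges(gatedFoldChanges(mono$peaks, alpha = 0.005)) != 0
  expect_true(all(loose[strict]))      # strict support is a subset
  expect_lte(sum(strict), sum(loose))
})

test_that("a zero control mean with spent signal is flagged undefined", {
  phe <- makeToyTargeted()
  h <- peakHeights(phe)
  h["trp", 4:9] <- 0                   # control all-zero, spent nonzero
  phe2 <- PeakHeightExperiment(h, as.data.frame(colData(phe)), "targeted")
  fc <- gatedFoldChanges(phe2)
  expect_true(flagged(fc)["trp", "iso1"])
  expect_true(is.na(foldChanges(fc)["trp", "iso1"]))
})

test_that("missing heights follow the declared policy", {
  phe <- makeToyTargeted()
  h <- peakHeights(phe)
  h["ala", "iso1_r1"] <- NA
  phe2 <- PeakHeightExperiment(h, as.data.frame(colData(phe)), "targeted")
  dropped <- gatedFoldChanges(phe2, naPolicy = "drop")
  expect_true(is.na(foldChanges(dropped)["ala", "iso1"]))
  expect_true(flagged(dropped)["ala", "iso1"])
  imputed <- gatedFoldChanges(phe2, naPolicy = "halfmin")
  expect_false(is.na(foldChanges(imputed)["ala", "iso1"]))
})

test_that("utilization profiles keep depletion and drop production", {
  fcm <- new("FoldChangeMatrix",
             fc = matrix(c(-0.97, 0, 1.4, -0.5, -1, 0, 0, 0), 4, 2,
                         dimnames = list(paste0("m", 1:4), c("a", "b"))),
             pvalues = matrix(c(0.001, 0.9, 0.01, 0.02,
                                0.001, 0.8, 0.7, 0.6), 4, 2),
             alpha = 0.05,
             nReplicates = matrix(3L, 4, 2),
             flagged = matrix(FALSE, 4, 2))
  p <- utilizationProfiles(fcm)
  expect_equal(unname(p[, "a"]), c(0.97, 0, 0, 0.5))
  expect_equal(unname(p[, "b"]), c(1, 0, 0, 0))  # complete depletion -> 1
  expect_true(all(p >= 0 & p <= 1))
})
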