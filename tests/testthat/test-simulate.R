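test_that("generators are deterministic under a fixed seed", {
  t1 <- simulateTruth(nIsolates = 8, nMetabolites = 60, seed = 1)
  t2 <- simulateTruth(nIsolates = 8, nMetabolites = 60, seed = 1)
  expect_equal(t1, t2)
  m1 <- simulateMonocultures(t1, cv = 0.1, seed = 9)
  m2 <- simulateMonocultures(t2, cv = 0.1, seed = 9)
  expect_equal(peakHeights(m1$peaks), peakHeights(m2$peaks))
  expect_equal(m1$growth$od, m2$growth$od)
  s1 <- simulateSequential(t1, cv = 0.1, seed = 9, withPeaks = FALSE)
  s2 <- simulateSequential(t2, cv = 0.1, seed = 9, withPeaks = FALSE)
  expect_equal(s1$growth$od, s2$growth$od)
  expect_equal(s1$trueMIS, s2$trueMIS)
})

test_that("archetypes order support sizes and pure competition has no secretion", {
  truth <- simulateTruth(nIsolates = 8, nMetabolites = 60, seed = 3)
  C <- consumptionMatrix(truth)
  gen <- rowSums(C > 0)[truth@archetype == "generalist"]
  spec <- rowSums(C > 0)[truth@archetype == "specialist"]
  expect_gt(mean(gen), mean(spec))
  expect_true(all(apply(C, 1, max) > 0.97))  # near-complete depletion each
  pure <- simulateTruth(nIsolates = 4, nMetabolites = 20, seed = 3,
                        crossFeeding = FALSE)
  expect_equal(ncol(secretionMatrix(pure)), 0L)
  expect_equal(nrow(trueCrossFeeding(pure)), 0L)
  expect_true(all(simulateSequential(pure, cv = 0, seed = 1,
                                     withPeaks = FALSE)$trueMIS <= 0,
                  na.rm = TRUE))
})

test_that("monoculture tables have the design-forced dimensions", {
  truth <- simulateTruth(nIsolates = 6, nMetabolites = 30, seed = 4,
                         crossFeeding = FALSE)
  mono <- simulateMonocultures(truth, cv = 0.1, nReplicates = 3, seed = 4)
  expect_equal(dim(mono$peaks), c(30L, 6L * 3L + 2L * 3L))
  withSecr <- simulateTruth(nIsolates = 6, nMetabolites = 30, seed = 4,
                            nSecretedPer = 2)
  mono2 <- simulateMonocultures(withSecr, cv = 0.1, seed = 4)
  expect_equal(nrow(mono2$peaks), 30L + 6L * 2L)
})

test_that("noiseless peak expectations obey the mass-balance structure", {
  truth <- simulateTruth(nIsolates = 4, nMetabolites = 15, seed = 6,
                         crossFeeding = FALSE)
  mono <- simulateMonocultures(truth, cv = 0, seed = 6)
  h <- peakHeights(mono$peaks)
  cd <- as.data.frame(SummarizedExperiment::colData(mono$peaks))
  C <- consumptionMatrix(truth)
  for (i in rownames(C)) {
    sp <- h[, cd$isolate_id %in% i, drop = FALSE]
    g <- unique(cd$control_group[cd$isolate_id %in% i])
    ctl <- h[, !is.na(cd$role) & cd$role %in%
                c("medium_control_early", "medium_control_late") &
                cd$control_group == g, drop = FALSE]
    expect_equal(unname(sp[, 1] / rowMeans(ctl)), unname(1 - C[i, ]),
                 tolerance = 1e-10)
  }
  ## double-spent expectation: spent x (1 - recipient consumption)
  sq <- simulateSequential(truth, cv = 0, seed = 6)
  h2 <- peakHeights(sq$peaks)
  cd2 <- as.data.frame(SummarizedExperiment::colData(sq$peaks))
  spent_i <- h2[, which(cd2$role == "spent" & cd2$isolate_id == "iso1")[1]]
  doub <- h2[, which(cd2$role == "double_spent" &
                     cd2$influencer_id == "iso1" &
                     cd2$recipient_id == "iso2")[1]]
  expect_equal(unname(doub), unname(spent_i * (1 - C["iso2", ])),
               tolerance = 1e-10)
})

test_that("true interaction boundaries are forced by the configuration", {
  truth <- simulateTruth(nIsolates = 3, nMetabolites = 10, seed = 10,
                         crossFeeding = FALSE)
  ## influencer consuming everything the recipient uses -> true MIS = -1
  truth@consumption["iso1", ] <- 1
  sq <- simulateSequential(truth, cv = 0, seed = 1, withPeaks = FALSE)
  expect_equal(unname(sq$trueMIS["iso2", "iso1"]), -1)
  ## disjoint supports -> true MIS = 0
  t2 <- truth
  t2@consumption["iso1", ] <- c(rep(0.8, 5), rep(0, 5))
  t2@consumption["iso2", ] <- c(rep(0, 5), rep(0.8, 5))
  sq2 <- simulateSequential(t2, cv = 0, seed = 1, withPeaks = FALSE)
  expect_equal(unname(sq2$trueMIS["iso2", "iso1"]), 0)
})
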