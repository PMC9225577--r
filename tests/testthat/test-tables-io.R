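test_that("toy targeted table has the expected shape and roles", {
  phe <- makeToyTargeted()
  expect_s4_class(phe, "PeakHeightExperiment")
  expect_equal(dim(phe), c(5L, 9L))
  expect_equal(sort(unique(unname(sampleRoles(phe)))),
               c("medium_control_early", "medium_control_late", "spent"))
  expect_equal(tableKind(phe), "targeted")
})

test_that("peak tables round-trip through CSV, preserving order and NAs", {
  phe <- makeToyTargeted()
  h <- peakHeights(phe)
  h["glc", "iso1_r2"] <- NA            # explicit missing value
  phe <- PeakHeightExperiment(h, as.data.frame(colData(phe)), "targeted")
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  writePeakTable(phe, f1, f2)
  back <- readPeakTable(f1, f2, tableKind = "targeted")
  expect_identical(rownames(back), rownames(phe))
  expect_identical(colnames(back), colnames(phe))
  expect_equal(peakHeights(back), peakHeights(phe))
  expect_true(is.na(peakHeights(back)["glc", "iso1_r2"]))
})

test_that("validation rejects documented malformed inputs by name", {
  phe <- makeToyTargeted()
  md <- as.data.frame(colData(phe))
  h <- peakHeights(phe)
  expect_error(PeakHeightExperiment(h, md[-1, ], "targeted"), "iso1_r1")
  bad <- md; bad$role[1] <- "mystery"
  expect_error(validObject(PeakHeightExperiment(h, bad, "targeted")),
               "mystery")
  hneg <- h; hneg[1, 1] <- -5
  expect_error(validObject(PeakHeightExperiment(hneg, md, "targeted")),
               "negative")
  hdup <- rbind(h, h[1, , drop = FALSE])
  expect_error(validObject(PeakHeightExperiment(hdup, md, "targeted")),
               "duplicate analyte")
})

test_that("spent samples must resolve to at least two control samples", {
  phe <- makeToyTargeted()
  md <- as.data.frame(colData(phe))
  md$control_group[md$role == "medium_control_early"] <- "elsewhere"
  expect_error(validObject(PeakHeightExperiment(peakHeights(phe), md,
                                                "targeted")),
               "control_group")
})

test_that("growth tables sort series by time and reject bad values", {
  df <- expand.grid(replicate = 1:3, medium = c("SDM", "iso2"),
                    isolate = c("iso1", "none"),
                    time_h = seq(0, 4, by = 0.5),
                    stringsAsFactors = FALSE)
  df$od600 <- 0.02 + 0.01 * df$time_h
  df <- df[sample(nrow(df)), ]          # shuffle
  f <- tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  gt <- readGrowthTable(f)
  expect_s3_class(gt, "GrowthTable")
  one <- gt$od[gt$od$isolate == "iso1" & gt$od$medium == "SDM" &
               gt$od$replicate == 1, ]
  expect_false(is.unsorted(one$time_h, strictly = TRUE))
  df$od600[5] <- -0.01
  write.csv(df, f, row.names = FALSE)
  expect_error(readGrowthTable(f), "negative od600")
  df$od600[5] <- 0.05
  df <- rbind(df, df[1, ])              # duplicate time point
  write.csv(df, f, row.names = FALSE)
  expect_error(readGrowthTable(f), "duplicate time")
})

test_that("result matrices write deterministically with empty-cell NAs", {
  m <- matrix(c(NA, -0.5, 0.25, NA), 2, 2,
              dimnames = list(c("iso1", "iso2"), c("iso1", "iso2")))
  f1 <- tempfile(); f2 <- tempfile()
  writeMatrix(m, f1); writeMatrix(m, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_false(any(grepl("NA|nan", readLines(f1), ignore.case = TRUE)))
  expect_equal(readMatrix(f1), m)
  expect_equal(length(readLines(f1)), 3L)   # header + 2 rows
})
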