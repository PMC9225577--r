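test_that("richness, abundance and diversity follow their definitions", {
  p <- cbind(even = c(0.5, 0.5, 0), single = c(1, 0, 0),
             skew = c(0.9, 0.1, 0), empty = c(0, 0, 0))
  m <- substrateMetrics(p)
  expect_equal(m$richness, c(2L, 1L, 2L, 0L))
  expect_equal(m$abundance, c(100, 100, 100, 0))
  expect_equal(m$diversity[1:2], c(2, 1))
  expect_equal(m$diversity[3], 1 / (0.81 + 0.01), tolerance = 1e-12)
  expect_true(is.na(m$diversity[4]))
})

test_that("inverse Simpson matches the vegan oracle on random profiles", {
  skip_if_not_installed("vegan")
  set.seed(202)
  for (i in 1:10) {
    p <- runif(12) * rbinom(12, 1, 0.6)
    if (sum(p > 0) == 0) p[1] <- 0.5
    ours <- substrateMetrics(matrix(p, ncol = 1))$diversity
    ref <- unname(vegan::diversity(p[p > 0], index = "invsimpson"))
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})

test_that("diversity is scale-invariant and bounded by richness", {
  set.seed(77)
  for (i in 1:20) {
    p <- runif(15) * rbinom(15, 1, 0.5)
    if (sum(p > 0) < 2) next
    m1 <- substrateMetrics(matrix(p, ncol = 1))
    m2 <- substrateMetrics(matrix(p * 0.37, ncol = 1))
    expect_equal(m1$diversity, m2$diversity, tolerance = 1e-10)
    expect_gte(m1$diversity, 1)
    expect_lte(m1$diversity, m1$richness + 1e-10)
    expect_gte(m1$abundance / 100, max(p))
    expect_lte(m1$abundance / 100, m1$richness)
  }
})

test_that("moving mass from the scarcest to the dominant substrate lowers diversity", {
  set.seed(13)
  for (i in 1:10) {
    p <- runif(8, 0.05, 0.8)
    base <- substrateMetrics(matrix(p, ncol = 1))$diversity
    uniform <- substrateMetrics(matrix(rep(0.5, 8), ncol = 1))$diversity
    expect_lte(base, uniform + 1e-10)  # even use maximises diversity
    q <- p
    lo <- which.min(q); hi <- which.max(q)
    delta <- min(0.5 * q[lo], 1 - q[hi])
    q[lo] <- q[lo] - delta; q[hi] <- q[hi] + delta
    expect_lt(substrateMetrics(matrix(q, ncol = 1))$diversity, base)
  }
})
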