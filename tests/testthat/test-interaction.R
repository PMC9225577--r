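test_that("predicted interaction strengths match hand-evaluated overlap", {
  p <- cbind(r = c(0.8, 0.4, 0), i = c(0.5, 1.0, 0.9))
  s <- interactionStrengths(predictedInteractions(p))
  expect_equal(s["r", "i"], -(0.4 + 0.4) / (0.64 + 0.16),
               tolerance = 1e-12)                 # exactly -1
  expect_equal(s["i", "r"], -0.8 / 2.06, tolerance = 1e-12)  # ~ -0.3883
  expect_true(all(is.na(diag(s))))
})

test_that("identical profiles compete fully; disjoint profiles not at all", {
  ident <- cbind(a = c(0.3, 0.6, 0.1), b = c(0.3, 0.6, 0.1))
  s <- interactionStrengths(predictedInteractions(ident))
  expect_equal(s["a", "b"], -1, tolerance = 1e-12)
  expect_equal(s["b", "a"], -1, tolerance = 1e-12)
  disj <- cbind(a = c(0.9, 0.4, 0, 0), b = c(0, 0, 0.7, 0.2))
  s2 <- interactionStrengths(predictedInteractions(disj))
  expect_identical(unname(s2["a", "b"]), 0)
  expect_identical(unname(s2["b", "a"]), 0)
})

test_that("overlap scores are invariant to common profile rescaling", {
  set.seed(41)
  p <- matrix(runif(60) * rbinom(60, 1, 0.5), 15, 4,
              dimnames = list(NULL, paste0("iso", 1:4)))
  p[1, ] <- pmax(p[1, ], 0.2)          # no empty supports
  s1 <- interactionStrengths(predictedInteractions(p))
  s2 <- interactionStrengths(predictedInteractions(p * 100))  # percent scale
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("stronger influencer depletion strictly deepens the interaction", {
  p <- cbind(r = c(0.6, 0.3, 0), i = c(0.2, 0.5, 0.4))
  base <- interactionStrengths(predictedInteractions(p))["r", "i"]
  p2 <- p
  p2[1, "i"] <- 0.4                    # metabolite in r's support
  deeper <- interactionStrengths(predictedInteractions(p2))["r", "i"]
  expect_lt(deeper, base)
})

test_that("empty-support recipients are flagged undefined, not zero", {
  p <- cbind(a = c(0.5, 0.5), b = c(0, 0))
  pis <- predictedInteractions(p)
  expect_equal(undefinedRecipients(pis), "b")
  expect_true(all(is.na(interactionStrengths(pis)["b", ])))
  expect_warning(expect_error(competitiveRank(pis), "fewer than 2"),
                 "excluding")
})

test_that("competitive ranks are antisymmetric sums over partners", {
  p <- cbind(r = c(0.8, 0.4, 0), i = c(0.5, 1.0, 0.9))
  rk <- competitiveRank(predictedInteractions(p))
  expect_equal(rk$score[rk$isolate == "r"], -1 + 0.8 / 2.06,
               tolerance = 1e-10)      # ~ -0.6117
  expect_equal(rk$score[rk$isolate == "i"], +1 - 0.8 / 2.06,
               tolerance = 1e-10)
  expect_equal(sum(rk$score), 0, tolerance = 1e-12)
  expect_equal(rk$rank[rk$isolate == "i"], 1L)
  ## a symmetric overlap structure gives all-zero scores
  ident <- cbind(a = c(0.3, 0.6), b = c(0.3, 0.6), c = c(0.3, 0.6))
  rk2 <- competitiveRank(predictedInteractions(ident))
  expect_equal(rk2$score, rep(0, 3), tolerance = 1e-12)
})
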