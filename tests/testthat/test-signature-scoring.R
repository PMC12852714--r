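test_that("tier classification matches the printed rules on boundary cases", {
  expect_identical(classifyCorrelation(0.55, 0.001), "strong_pos")
  expect_identical(classifyCorrelation(0.28, 0.0005), "weak_pos")
  expect_identical(classifyCorrelation(0.28, 0.01), "none")   # the gap
  expect_identical(classifyCorrelation(-0.31, 0.02), "moderate_neg")
  expect_identical(classifyCorrelation(0.10, 0.9), "none")
  # inclusive r, strict p, exactly at the printed boundaries
  expect_identical(classifyCorrelation(0.50, 0.049), "strong_pos")
  expect_identical(classifyCorrelation(0.50, 0.05), "none")
  expect_identical(classifyCorrelation(0.26, 0.001), "none")
  expect_identical(classifyCorrelation(0.26, 0.0009), "weak_pos")
})

test_that("tier classification is odd in rho over a dense grid", {
  rhos <- c(0.1, 0.26, 0.29, 0.30, 0.49, 0.50, 0.9)
  ps <- c(1e-4, 1e-3, 0.01, 0.049, 0.05, 0.5)
  mirror <- c(strong_pos = "strong_neg", moderate_pos = "moderate_neg",
              weak_pos = "weak_neg", none = "none")
  for (r in rhos) for (p in ps) {
    pos <- classifyCorrelation(r, p)
    neg <- classifyCorrelation(-r, p)
    expect_identical(neg, unname(mirror[pos]))
  }
})

test_that("relaxed weak-p flag opens the documented gap region", {
  th <- TierThresholds(relaxWeakP = TRUE)
  expect_identical(classifyCorrelation(0.28, 0.01, th), "weak_pos")
  expect_identical(classifyCorrelation(0.28, 0.06, th), "none")
})

test_that("denominator adjustments follow the published rules", {
  sigs <- builtinSignatures()
  # two platform-missing genes in the 10-gene signature: divide by 8
  sim <- simulateExpression(nSamples = 60, plantedRho = 0.6, nPlanted = 5,
                            missingGenes = c("ITGB", "UMPS"),
                            backgroundGenes = 0, seed = 21)
  rs <- ratioScore(sim$expr, "CD24", sigs$high_risk, "positive")
  expect_identical(rs@denominator, 8L)
  expect_setequal(rs@missingGenes, c("ITGB", "UMPS"))

  # IDO1 missing from the M1 profile: divide by 11
  tam <- GeneSignature("tam", union(signatureGenes(sigs$M1),
                                    signatureGenes(sigs$M2)), "marker")
  sim2 <- simulateExpression(nSamples = 60, geneOfInterest = "SIGLEC10",
                             signature = tam, nPlanted = 0,
                             missingGenes = "IDO1", backgroundGenes = 0,
                             seed = 22)
  prof <- m1m2Profile(sim2$expr, "SIGLEC10")
  expect_identical(prof$M1@denominator, 11L)
  expect_identical(prof$M2@denominator, 12L)

  # TREM2 against the M2 profile that contains it: divide by 11
  sim3 <- simulateExpression(nSamples = 60, geneOfInterest = "TREM2",
                             signature = tam, nPlanted = 0,
                             backgroundGenes = 0, seed = 23)
  prof3 <- m1m2Profile(sim3$expr, "TREM2")
  expect_identical(prof3$M2@denominator, 11L)
  expect_true(prof3$M2@selfExcluded)
  expect_identical(prof3$M1@denominator, 12L)
})

test_that("planted correlations are recovered as k/10 ratios", {
  sim <- simulateExpression(nSamples = 200, plantedRho = 0.6, nPlanted = 7,
                            backgroundGenes = 0, seed = 24)
  rs <- ratioScore(sim$expr, "CD24", "high_risk", "positive")
  expect_identical(rs@numerator, 7L)
  expect_identical(rs@denominator, 10L)
  expect_equal(scoreRatio(rs), 0.7)
  # nothing counts in the negative direction
  neg <- ratioScore(sim$expr, "CD24", "high_risk", "negative")
  expect_identical(neg@numerator, 0L)
})

test_that("independent noise scores zero and saturated planting scores one", {
  simNull <- simulateExpression(nSamples = 200, plantedRho = 0,
                                backgroundGenes = 0, seed = 25)
  expect_equal(scoreRatio(ratioScore(simNull$expr, "CD24", "high_risk",
                                     "positive")), 0)
  simFull <- simulateExpression(nSamples = 100, plantedRho = 0.95,
                                nPlanted = 10, backgroundGenes = 0,
                                seed = 26)
  expect_equal(scoreRatio(ratioScore(simFull$expr, "CD24", "high_risk",
                                     "positive")), 1)
})

test_that("ratio is invariant under strictly increasing per-gene transforms", {
  sim <- simulateExpression(nSamples = 120, plantedRho = 0.6, nPlanted = 4,
                            backgroundGenes = 0, seed = 27)
  base <- ratioScore(sim$expr, "CD24", "high_risk", "positive")
  m <- exprValues(sim$expr)
  for (i in seq_len(nrow(m)))
    m[i, ] <- if (i %% 2) exp(m[i, ]) else m[i, ]^(1 / 3) + 7
  tr <- ratioScore(ExprMatrix(m), "CD24", "high_risk", "positive")
  expect_identical(tr@numerator, base@numerator)
  expect_identical(tr@denominator, base@denominator)
})

test_that("score panels enumerate combinations and flag tiny subgroups", {
  sim <- simulateExpression(nSamples = c(SHH = 30, Group3 = 30, Group4 = 3),
                            plantedRho = 0.6, nPlanted = 5,
                            backgroundGenes = 0, seed = 28)
  sigs <- builtinSignatures()[c("high_risk", "low_risk")]
  # low_risk genes are absent from this simulation: restrict to high_risk
  tab <- scorePanel(sim$expr, c("CD24", "FOXM1"),
                    signatures = sigs["high_risk"], perSubgroup = TRUE)
  expect_identical(nrow(tab), 6L)                   # 2 genes x 1 sig x 3 sub
  expect_identical(tab$gene, rep(c("CD24", "FOXM1"), each = 3L))
  flagged <- tab[tab$subgroup == "Group4", ]
  expect_true(all(!flagged$computable))
  expect_true(all(is.na(flagged$ratio)))
  expect_true(all(tab[tab$subgroup != "Group4", "computable"]))
})

test_that("tier tables mark planted, absent and undersized cells", {
  marker <- getSignature("marker")
  sim <- simulateExpression(nSamples = c(SHH = 60, WNT = 3),
                            geneOfInterest = "SIGLEC10", signature = marker,
                            plantedGenes = "TREM2", plantedRho = 0.9,
                            missingGenes = "P2RY12", backgroundGenes = 0,
                            seed = 29)
  tt <- tierTable(sim$expr, "SIGLEC10", perSubgroup = TRUE)
  expect_identical(tt["SHH", "TREM2"], "strong_pos")
  expect_identical(tt["SHH", "P2RY12"], "absent")
  expect_true(all(tt["WNT", ] == "insufficient_n"))
})

test_that("ratioScore input contracts hold", {
  sim <- simulateExpression(nSamples = 20, plantedRho = 0.5, nPlanted = 2,
                            backgroundGenes = 0, seed = 30)
  expect_error(ratioScore(sim$expr, "NOTAGENE", "high_risk", "positive"),
               "not present")
  m <- exprValues(sim$expr)[, 1:3]
  expect_error(ratioScore(ExprMatrix(m), "CD24", "high_risk", "positive"),
               "at least 4")
})
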