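test_that("generators are pure functions of their seed", {
  a <- simulateExpression(nSamples = 25, plantedRho = 0.5, nPlanted = 3,
                          seed = 91)
  b <- simulateExpression(nSamples = 25, plantedRho = 0.5, nPlanted = 3,
                          seed = 91)
  expect_identical(exprValues(a$expr), exprValues(b$expr))
  c <- simulateExpression(nSamples = 25, plantedRho = 0.5, nPlanted = 3,
                          seed = 92)
  expect_false(identical(exprValues(a$expr), exprValues(c$expr)))

  s1 <- simulateSurvival(c(A = 10, B = 10), c(A = 0.05, B = 0.02), seed = 93)
  s2 <- simulateSurvival(c(A = 10, B = 10), c(A = 0.05, B = 0.02), seed = 93)
  expect_identical(s1, s2)

  i1 <- simulateStainImage(nNuclei = 5, seed = 94)
  i2 <- simulateStainImage(nNuclei = 5, seed = 94)
  expect_identical(i1$image@marker, i2$image@marker)
  expect_identical(i1$truth, i2$truth)

  t1 <- simulateSubtypeSamples(nPerSubtype = 2, backgroundGenes = 200,
                               genesPerSignature = 20, seed = 95)
  t2 <- simulateSubtypeSamples(nPerSubtype = 2, backgroundGenes = 200,
                               genesPerSignature = 20, seed = 95)
  expect_identical(exprValues(t1$expr), exprValues(t2$expr))
})

test_that("generator runs do not disturb the caller's RNG stream", {
  set.seed(96)
  before <- .Random.seed
  invisible(simulateExpression(nSamples = 10, plantedRho = 0.3,
                               nPlanted = 2, seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("planted Spearman correlations hit their target at large n", {
  simNull <- simulateExpression(nSamples = 2000, plantedRho = 0,
                                backgroundGenes = 0, seed = 97)
  simHigh <- simulateExpression(nSamples = 2000, plantedRho = 0.99,
                                backgroundGenes = 0, seed = 98)
  x0 <- exprValues(simNull$expr)["CD24", ]
  xh <- exprValues(simHigh$expr)["CD24", ]
  for (g in simNull$truth$plantedGenes) {
    rhoNull <- stats::cor(x0, exprValues(simNull$expr)[g, ],
                          method = "spearman")
    expect_lt(abs(rhoNull), 0.05)
  }
  for (g in simHigh$truth$plantedGenes) {
    rhoHigh <- stats::cor(xh, exprValues(simHigh$expr)[g, ],
                          method = "spearman")
    expect_gte(rhoHigh, 0.97)
  }
})

test_that("the marginal transform leaves Spearman correlations unchanged", {
  ln <- simulateExpression(nSamples = 300, plantedRho = 0.6, nPlanted = 5,
                           marginal = "lognormal", seed = 99)
  nm <- simulateExpression(nSamples = 300, plantedRho = 0.6, nPlanted = 5,
                           marginal = "normal", seed = 99)
  g <- ln$truth$plantedGenes[1]
  expect_identical(
    stats::cor(exprValues(ln$expr)["CD24", ], exprValues(ln$expr)[g, ],
               method = "spearman"),
    stats::cor(exprValues(nm$expr)["CD24", ], exprValues(nm$expr)[g, ],
               method = "spearman"))
})

test_that("missing genes are dropped from the output matrix", {
  sim <- simulateExpression(nSamples = 10, plantedRho = 0.5, nPlanted = 2,
                            missingGenes = c("ITGB", "UMPS"), seed = 100)
  expect_false(any(c("ITGB", "UMPS") %in% geneIds(sim$expr)))
  expect_true("FOXM1" %in% geneIds(sim$expr))
})

test_that("survival simulation matches the closed-form event fraction", {
  rec <- simulateSurvival(c(g = 1000), c(g = 0.05),
                          censorHorizonDays = 100, seed = 101)
  expected <- 1 - exp(-0.05 * 100)            # 0.9933
  observed <- mean(rec$event)
  se <- sqrt(expected * (1 - expected) / 1000)
  expect_lt(abs(observed - expected), 4 * se)
  expect_true(all(rec$time_days <= 100))
  expect_error(simulateSurvival(c(g = 5), c(g = 0.05),
                                censorHorizonDays = 0, seed = 1),
               "censorHorizonDays")
  expect_error(simulateSurvival(c(g = 5), c(g = -1), seed = 1), "positive")
})

test_that("noiseless images reproduce extreme stained fractions exactly", {
  s0 <- simulateStainImage(tumorFraction = 0.3, stainedFraction = 0,
                           nNuclei = 0, noiseSd = 0, seed = 102)
  tm0 <- new("MaskResult", mask = s0$truth$tumorMask,
             areaPx = as.integer(s0$truth$tumorAreaPx),
             areaMm2 = 0, thresholdUsed = 0.5)
  expect_equal(stainedAreaRatio(s0$image@marker, tm0, 0.45), 0)
  s1 <- simulateStainImage(tumorFraction = 0.3, stainedFraction = 1,
                           nNuclei = 0, noiseSd = 0, seed = 103)
  tm1 <- new("MaskResult", mask = s1$truth$tumorMask,
             areaPx = as.integer(s1$truth$tumorAreaPx),
             areaMm2 = 0, thresholdUsed = 0.5)
  expect_equal(stainedAreaRatio(s1$image@marker, tm1, 0.45), 1)
})

test_that("infeasible nucleus packing and oversized blobs are rejected", {
  expect_error(simulateStainImage(shape = c(64L, 64L), tumorFraction = 0.1,
                                  nNuclei = 500, seed = 104),
               "packing")
  expect_error(simulateStainImage(tumorFraction = 0.9, nNuclei = 0,
                                  seed = 105), "too large")
})

test_that("subtype simulation shifts exactly the signature genes", {
  st <- simulateSubtypeSamples(nPerSubtype = 30, shiftSd = 2,
                               backgroundGenes = 300,
                               genesPerSignature = 30, seed = 106)
  m <- log(exprValues(st$expr))
  cl <- st$truth == "Classical"
  sigGenes <- signatureGenes(st$signatures$Classical)
  bgGenes <- setdiff(rownames(m), unlist(lapply(st$signatures,
                                                signatureGenes)))
  expect_equal(mean(m[sigGenes, cl]), 2, tolerance = 0.1)
  expect_equal(mean(m[bgGenes, cl]), 0, tolerance = 0.1)
  expect_identical(unname(sampleGroups(st$expr)), unname(st$truth))
})
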