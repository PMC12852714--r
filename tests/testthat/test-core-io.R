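test_that("expression reader validates shape, case and uniqueness", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2\ts3\ts4",
               "cd24\t1\t2\t3\t4",
               "FOXM1\t4\t3\t2\t1",
               "Siglec-10\t1\t1\t2\t2"), path)
  em <- readExpression(path)
  expect_s4_class(em, "ExprMatrix")
  expect_equal(dim(exprValues(em)), c(3L, 4L))
  expect_setequal(geneIds(em), c("CD24", "FOXM1", "SIGLEC10"))

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene,s1,s2", "FOXM1,1,2", "foxm1,3,4"), dup)
  expect_error(readExpression(dup), "duplicate")

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene,s1,s2", "CD24,1,x"), bad)
  expect_error(readExpression(bad), "non-numeric")
})

test_that("comma and tab dialects are both accepted, with group files", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene,a,b,c,d", "CD24,1,2,3,4", "MKI67,2,3,4,5"), path)
  gf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,group", "a,SHH", "b,SHH", "c,Group3", "d,Group3"), gf)
  em <- readExpression(path, groupFile = gf)
  expect_equal(unname(sampleGroups(em)), c("SHH", "SHH", "Group3", "Group3"))
})

test_that("built-in signatures match the curated lists character for character", {
  sigs <- builtinSignatures()
  expect_identical(signatureGenes(sigs$high_risk),
                   c("FOXM1", "NEK2", "CCT2", "ACTL6A", "CCND2", "ABL1",
                     "SYNCRIP", "ITGB", "ENAH", "UMPS"))
  expect_identical(signatureGenes(sigs$low_risk),
                   c("ADAM22", "AEBP1", "DHRS2", "RAC3", "SHANK1", "CYB5D2",
                     "IL27RA", "DNAH2", "ZPF3", "NRXN2"))
  expect_identical(signatureGenes(sigs$M1),
                   c("APOL3", "CCL19", "CCL5", "CCR7", "CD38", "CD40",
                     "CXCL10", "CXCL9", "EBI3", "IDO1", "LAMP3", "TNFAIP6"))
  expect_identical(signatureGenes(sigs$M2),
                   c("AIF1", "CCL13", "CCL18", "CD180", "CD209", "CD4",
                     "CLEC4A", "CLEC10A", "MS4A6A", "NPL", "SLC15A3",
                     "TREM2"))
  expect_length(signatureGenes(sigs$M1), 12L)
  expect_length(signatureGenes(sigs$M2), 12L)
  expect_identical(signatureGenes(sigs$high_risk)[c(1L, 10L)],
                   c("FOXM1", "UMPS"))
  expect_true("TREM2" %in% signatureGenes(sigs$M2))
  expect_true(all(c("CD24", "SIGLEC10", "MKI67") %in%
                    signatureGenes(sigs$marker)))
  expect_identical(signatureRole(sigs$M1), "M1")
})

test_that("survival reader parses records and rejects invalid rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,time_days,event,group",
               "m1,27.5,1,control", "m2,100,0,treated"), path)
  rec <- readSurvival(path)
  expect_equal(rec$time_days, c(27.5, 100))
  expect_equal(rec$event, c(TRUE, FALSE))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,time_days,event,group", "m1,-3,1,control"), bad)
  expect_error(readSurvival(bad), "positive")

  bad2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,time_days,event,group", "m1,3,2,control"), bad2)
  expect_error(readSurvival(bad2), "event")
})

test_that("score tables survive a write/read round trip exactly", {
  sim <- simulateExpression(nSamples = 30, plantedRho = 0.7, nPlanted = 5,
                            backgroundGenes = 0, seed = 11)
  tab <- scorePanel(sim$expr, "CD24",
                    signatures = builtinSignatures()["high_risk"])
  path <- withr::local_tempfile(fileext = ".tsv")
  writeScores(tab, path)
  back <- readScores(path)
  expect_identical(back$ratio, tab$ratio)
  expect_identical(back$numerator, tab$numerator)
  expect_identical(back$denominator, tab$denominator)
  expect_identical(back$gene, tab$gene)
})

test_that("GMT and YAML threshold readers work", {
  gmt <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("Classical\tsynthetic\tEGFR\tNES1\tAKT2",
               "Proneural\tsynthetic\tOLIG2\tSOX2"), gmt)
  sigs <- readGmt(gmt)
  expect_named(sigs, c("Classical", "Proneural"))
  expect_identical(signatureGenes(sigs$Classical), c("EGFR", "NES1", "AKT2"))
  expect_identical(signatureRole(sigs$Proneural), "subtype")

  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("weak_r: 0.2", "relax_weak_p: true"), yml)
  th <- readThresholds(yml)
  expect_equal(th@weakR, 0.2)
  expect_true(th@relaxWeakP)
  expect_equal(th@strongR, 0.5)  # untouched default
})

test_that("stain images round-trip through TIFF and flag absent markers", {
  sim <- simulateStainImage(shape = c(64L, 64L), tumorFraction = 0.2,
                            stainedFraction = 0.5, nNuclei = 3,
                            noiseSd = 0, seed = 12)
  path <- withr::local_tempfile(fileext = ".tif")
  writeStainImage(sim$image, path)
  back <- readStainImage(path, pixelSizeUm = 1)
  expect_equal(dim(back@nuclear), dim(sim$image@nuclear))
  expect_gt(length(back@marker), 0L)
  expect_equal(max(abs(back@marker - sim$image@marker)), 0, tolerance = 1e-2)

  gray <- withr::local_tempfile(fileext = ".png")
  nucOnly <- StainImage(NULL, sim$image@nuclear, 1)
  writeStainImage(nucOnly, gray)
  g <- readStainImage(gray, pixelSizeUm = 0.65)
  expect_identical(length(g@marker), 0L)
  expect_equal(g@pixelSizeUm, 0.65)
  sidecar <- paste0(gray, ".yaml")
  writeLines("pixel_size_um: 0.5", sidecar)
  withr::defer(unlink(sidecar))
  expect_equal(readStainImage(gray)@pixelSizeUm, 0.5)
})

test_that("ExprMatrix validity rejects malformed input", {
  m <- matrix(1:4, 2, 2, dimnames = list(c("A", "A"), c("s1", "s2")))
  expect_error(ExprMatrix(m), "duplicate")
  m2 <- matrix(c(1, NA, 3, 4), 2, 2,
               dimnames = list(c("A", "B"), c("s1", "s2")))
  expect_error(ExprMatrix(m2), "finite")
})
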