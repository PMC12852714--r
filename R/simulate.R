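## Seeded generators producing inputs with the statistical structure the
## analysis assumes, plus exact ground truth: Gaussian-copula expression
## with planted Spearman correlations, exponential survival with
## administrative censoring, two-channel stain images with known stained
## fraction and nucleus count, and subtype-shifted expression panels.
## Every generator is a pure function of its arguments and seed.

#' Simulate an expression matrix with planted Spearman correlations
#'
#' Gaussian-copula sampling: a latent standard-normal factor represents the
#' gene of interest, and each planted signature gene is given latent
#' (Pearson) correlation `r = 2 sin(pi * plantedRho / 6)` with it — the
#' exact conversion such that the observed Spearman correlation after any
#' monotone marginal transform is `plantedRho`. Planted genes are
#' conditionally independent given the factor (pairwise latent correlation
#' `r^2` among themselves); all other signature genes and the background
#' genes are independent. Marginals are lognormal (log-SD 1) by default,
#' mimicking the positivity and skew of normalized expression, or standard
#' normal.
#'
#' @param nSamples integer, or named integer vector giving samples per
#'   subgroup (labels become `sampleGroups`).
#' @param geneOfInterest gene symbol of the hub gene (default `"CD24"`).
#' @param signature a [GeneSignature-class] (default: built-in high-risk).
#' @param plantedRho target Spearman correlation, |rho| < 1.
#' @param nPlanted how many signature genes are planted (default: all).
#' @param plantedGenes optional explicit subset of signature genes to plant
#'   (overrides `nPlanted`).
#' @param backgroundGenes number of additional independent genes.
#' @param marginal `"lognormal"` or `"normal"`.
#' @param missingGenes genes to drop from the output matrix (emulating
#'   platform-missing genes).
#' @param seed RNG seed (mandatory).
#' @return list with `expr` (an [ExprMatrix-class]) and `truth`
#'   (planted genes, target Spearman rho, latent r).
#' @export
simulateExpression <- function(nSamples = 100L, geneOfInterest = "CD24",
                               signature = getSignature("high_risk"),
                               plantedRho = 0.6, nPlanted = NULL,
                               plantedGenes = NULL, backgroundGenes = 50L,
                               marginal = c("lognormal", "normal"),
                               missingGenes = character(), seed) {
  marginal <- match.arg(marginal)
  if (is.character(signature)) signature <- getSignature(signature)
  assertNumber(plantedRho, "plantedRho", lower = -1 + 1e-9,
               upper = 1 - 1e-9)
  geneOfInterest <- normalizeSymbols(geneOfInterest)
  sigGenes <- setdiff(signatureGenes(signature), geneOfInterest)
  if (is.null(plantedGenes)) {
    if (is.null(nPlanted)) nPlanted <- length(sigGenes)
    nPlanted <- assertCount(nPlanted, "nPlanted")
    if (nPlanted > length(sigGenes))
      stop("nPlanted exceeds the number of plantable signature genes")
    plantedGenes <- sigGenes[seq_len(nPlanted)]
  } else {
    plantedGenes <- normalizeSymbols(plantedGenes)
    if (!all(plantedGenes %in% sigGenes))
      stop("plantedGenes must be signature genes other than the gene of ",
           "interest")
  }
  latentR <- 2 * sin(pi * plantedRho / 6)
  if (latentR^2 >= 1)
    stop("implied latent correlation matrix is not positive definite")
  if (is.null(names(nSamples))) {
    groups <- NULL
    ns <- stats::setNames(as.integer(nSamples), "all")
  } else {
    ns <- vapply(nSamples, as.integer, 0L)
  }
  backgroundGenes <- assertCount(backgroundGenes, "backgroundGenes")
  bg <- if (backgroundGenes > 0L)
    sprintf("BG%04d", seq_len(backgroundGenes)) else character()
  allGenes <- c(geneOfInterest, sigGenes, bg)
  withSeed(seed, {
    cols <- list()
    groupLabels <- character()
    for (gname in names(ns)) {
      n <- ns[[gname]]
      z <- matrix(rnorm(length(allGenes) * n), length(allGenes), n,
                  dimnames = list(allGenes, NULL))
      z0 <- z[geneOfInterest, ]
      for (g in plantedGenes)
        z[g, ] <- latentR * z0 + sqrt(1 - latentR^2) * z[g, ]
      cols[[gname]] <- z
      groupLabels <- c(groupLabels, rep(gname, n))
    }
    z <- do.call(cbind, cols)
    colnames(z) <- sprintf("%s_s%03d", groupLabels,
                           unlist(lapply(ns, seq_len), use.names = FALSE))
    x <- if (marginal == "lognormal") exp(z) else z
    drop <- normalizeSymbols(missingGenes)
    x <- x[!rownames(x) %in% drop, , drop = FALSE]
    expr <- ExprMatrix(x, sampleGroups = if (is.null(names(nSamples)))
      NULL else groupLabels)
    list(expr = expr,
         truth = list(geneOfInterest = geneOfInterest,
                      plantedGenes = plantedGenes,
                      plantedRho = plantedRho, latentR = latentR,
                      missingGenes = drop))
  })
}

#' Simulate exponential survival with administrative censoring
#'
#' Event times are exponential with the group-specific hazard; subjects
#' whose latent time exceeds the horizon are censored there (the
#' fixed-length monitoring window of an animal survival study).
#'
#' @param nPerGroup named integer vector, subjects per group.
#' @param hazardPerDay named numeric vector of hazards (per day), same
#'   names.
#' @param censorHorizonDays administrative horizon, must be positive
#'   (default 100).
#' @param seed RNG seed.
#' @return survival data.frame (`subject_id`, `time_days`, `event`,
#'   `group`).
#' @export
simulateSurvival <- function(nPerGroup, hazardPerDay,
                             censorHorizonDays = 100, seed) {
  assertNumber(censorHorizonDays, "censorHorizonDays", lower = 1e-12)
  if (is.null(names(nPerGroup)) || is.null(names(hazardPerDay)) ||
      !setequal(names(nPerGroup), names(hazardPerDay)))
    stop("nPerGroup and hazardPerDay must be named consistently")
  if (any(hazardPerDay <= 0)) stop("hazards must be positive")
  withSeed(seed, {
    rows <- lapply(names(nPerGroup), function(g) {
      n <- as.integer(nPerGroup[[g]])
      t <- rexp(n, rate = hazardPerDay[[g]])
      ev <- t <= censorHorizonDays
      data.frame(subject_id = sprintf("%s_%03d", g, seq_len(n)),
                 time_days = pmin(t, censorHorizonDays), event = ev,
                 group = g, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

## Smooth random field over a grid: a small sum of low-frequency cosines.
.smoothField <- function(nr, nc, nWaves = 6L) {
  rr <- matrix(seq_len(nr) / nr, nr, nc)
  cc <- matrix(rep(seq_len(nc) / nc, each = nr), nr, nc)
  f <- matrix(0, nr, nc)
  for (i in seq_len(nWaves)) {
    u <- sample(-3:3, 1L); v <- sample(-3:3, 1L)
    phi <- runif(1L, 0, 2 * pi)
    f <- f + runif(1L, 0.5, 1) * cos(2 * pi * (u * rr + v * cc) + phi)
  }
  f
}

#' Simulate a two-channel stain image with known ground truth
#'
#' Builds a wobbly-disk tumor blob of approximately `tumorFraction` of the
#' image, marks exactly `round(stainedFraction * tumorArea)` tumor pixels
#' as stained (selected by a smooth random field, so the stained region is
#' blobby rather than salt-and-pepper), places `nNuclei` non-overlapping
#' nucleus disks inside the tumor, and adds Gaussian intensity noise.
#' Exact ground-truth masks and counts are returned alongside the image.
#'
#' Channel design: nuclear = 0.05 background + `nuclearBaseline` inside the
#' tumor (diffuse DAPI) + 0.95 nucleus disks; marker = 0.1 background, 0.8
#' on stained pixels.
#'
#' @param shape image shape (rows, cols), default 256 x 256.
#' @param tumorFraction target tumor fraction of the image (the blob model
#'   supports up to ~0.5).
#' @param stainedFraction fraction of tumor pixels that are
#'   marker-positive.
#' @param nNuclei nucleus count; an error is raised when that many
#'   non-overlapping disks cannot be packed.
#' @param noiseSd Gaussian intensity noise SD (default 0.02).
#' @param pixelSizeUm pixel edge length, micrometres.
#' @param nuclearBaseline diffuse nuclear-channel intensity inside the
#'   tumor (set 0 for cultured-cell images where only nuclei fluoresce).
#' @param nucleusRadiusPx nucleus disk radius (default 4 px).
#' @param minSeparationPx minimum centre-to-centre distance (default
#'   `2 * nucleusRadiusPx + 3`, i.e. well-separated).
#' @param seed RNG seed.
#' @return list with `image` (a [StainImage-class]) and `truth`
#'   (tumor/stained masks, exact fractions, nucleus centres and count).
#' @export
simulateStainImage <- function(shape = c(256L, 256L), tumorFraction = 0.3,
                               stainedFraction = 0.25, nNuclei = 50L,
                               noiseSd = 0.02, pixelSizeUm = 1,
                               nuclearBaseline = 0.5, nucleusRadiusPx = 4L,
                               minSeparationPx = NULL, seed) {
  assertNumber(tumorFraction, "tumorFraction", lower = 0, upper = 1)
  assertNumber(stainedFraction, "stainedFraction", lower = 0, upper = 1)
  assertNumber(noiseSd, "noiseSd", lower = 0)
  nNuclei <- assertCount(nNuclei, "nNuclei")
  nr <- as.integer(shape[1L]); nc <- as.integer(shape[2L])
  if (is.null(minSeparationPx)) minSeparationPx <- 2 * nucleusRadiusPx + 3
  r0 <- sqrt(tumorFraction * nr * nc / pi)
  if (tumorFraction > 0 && r0 * 1.2 > min(nr, nc) / 2 - 2)
    stop("tumorFraction too large for the blob model at this image size")
  withSeed(seed, {
    ## wobbly-disk tumor mask, exact by construction
    if (tumorFraction > 0) {
      amp <- runif(3L, 0, 0.05)
      phase <- runif(3L, 0, 2 * pi)
      cy <- nr / 2 + runif(1L, -nr * 0.02, nr * 0.02)
      cx <- nc / 2 + runif(1L, -nc * 0.02, nc * 0.02)
      dy <- matrix(seq_len(nr) - cy, nr, nc)
      dx <- matrix(rep(seq_len(nc) - cx, each = nr), nr, nc)
      rad <- sqrt(dy^2 + dx^2)
      theta <- atan2(dy, dx)
      edge <- r0 * (1 + amp[1L] * cos(2 * theta + phase[1L]) +
                      amp[2L] * cos(3 * theta + phase[2L]) +
                      amp[3L] * cos(5 * theta + phase[3L]))
      tumor <- rad <= edge
    } else {
      tumor <- matrix(FALSE, nr, nc)
    }
    tumorPx <- sum(tumor)
    ## stained subset: top-m tumor pixels of a smooth field
    stained <- matrix(FALSE, nr, nc)
    m <- round(stainedFraction * tumorPx)
    if (m > 0) {
      field <- .smoothField(nr, nc) + matrix(runif(nr * nc, 0, 1e-6), nr)
      idx <- which(tumor)
      stained[idx[order(field[idx], decreasing = TRUE)[seq_len(m)]]] <- TRUE
    }
    ## nucleus packing by rejection sampling
    centers <- matrix(numeric(0), 0L, 2L)
    if (nNuclei > 0L) {
      if (tumorPx == 0L) stop("cannot place nuclei without a tumor region")
      inside <- which(tumor)
      tries <- 0L
      while (nrow(centers) < nNuclei) {
        tries <- tries + 1L
        if (tries > 20000L)
          stop("infeasible packing: cannot place ", nNuclei,
               " nuclei at the requested separation")
        pick <- inside[sample.int(length(inside), 1L)]
        py <- (pick - 1L) %% nr + 1L
        px <- (pick - 1L) %/% nr + 1L
        if (py <= nucleusRadiusPx || px <= nucleusRadiusPx ||
            py > nr - nucleusRadiusPx || px > nc - nucleusRadiusPx) next
        if (nrow(centers) &&
            min(sqrt((centers[, 1L] - py)^2 + (centers[, 2L] - px)^2)) <
              minSeparationPx) next
        centers <- rbind(centers, c(py, px))
      }
    }
    nuclei <- matrix(FALSE, nr, nc)
    if (nrow(centers)) {
      for (i in seq_len(nrow(centers))) {
        ys <- (centers[i, 1L] - nucleusRadiusPx):(centers[i, 1L] +
                                                    nucleusRadiusPx)
        xs <- (centers[i, 2L] - nucleusRadiusPx):(centers[i, 2L] +
                                                    nucleusRadiusPx)
        dd <- outer((ys - centers[i, 1L])^2, (xs - centers[i, 2L])^2, "+")
        nuclei[ys, xs] <- nuclei[ys, xs] | (dd <= nucleusRadiusPx^2)
      }
    }
    nuclear <- 0.05 + nuclearBaseline * tumor
    nuclear[nuclei] <- 0.95
    marker <- matrix(0.1, nr, nc)
    marker[stained] <- 0.8
    if (noiseSd > 0) {
      nuclear <- nuclear + matrix(rnorm(nr * nc, 0, noiseSd), nr, nc)
      marker <- marker + matrix(rnorm(nr * nc, 0, noiseSd), nr, nc)
    }
    clamp <- function(m) pmin(pmax(m, 0), 1)
    img <- StainImage(marker = clamp(marker), nuclear = clamp(nuclear),
                      pixelSizeUm = pixelSizeUm)
    list(image = img,
         truth = list(tumorMask = tumor,
                      tumorFraction = tumorPx / (nr * nc),
                      tumorAreaPx = tumorPx,
                      stainedMask = stained,
                      stainedFraction = if (tumorPx > 0) m / tumorPx else 0,
                      nucleusCenters = centers, nNuclei = nrow(centers)))
  })
}

#' Simulate subtype-labelled samples with shifted signature genes
#'
#' Builds disjoint synthetic subtype signatures over a lognormal background
#' universe and, for each sample, up-shifts its true subtype's signature
#' genes by `shiftSd` standard deviations in log space. With `shiftSd = 0`
#' there is no signal and subtype recovery is at chance.
#'
#' @param nPerSubtype samples per subtype (default 20).
#' @param shiftSd signature up-shift in SD units (default 2).
#' @param backgroundGenes size of the gene universe (default 1000).
#' @param genesPerSignature genes per subtype signature (default 50).
#' @param subtypes subtype labels (default Classical, Proneural,
#'   Mesenchymal).
#' @param seed RNG seed.
#' @return list with `expr` (labelled [ExprMatrix-class]), `signatures`
#'   (named list of synthetic subtype [GeneSignature-class] objects) and
#'   `truth` (named character vector of true labels).
#' @export
simulateSubtypeSamples <- function(nPerSubtype = 20L, shiftSd = 2,
                                   backgroundGenes = 1000L,
                                   genesPerSignature = 50L,
                                   subtypes = c("Classical", "Proneural",
                                                "Mesenchymal"),
                                   seed) {
  nPerSubtype <- assertCount(nPerSubtype, "nPerSubtype", lower = 1L)
  assertNumber(shiftSd, "shiftSd", lower = 0)
  genesPerSignature <- assertCount(genesPerSignature, "genesPerSignature",
                                   lower = 1L)
  backgroundGenes <- assertCount(backgroundGenes, "backgroundGenes",
                                 lower = length(subtypes) * genesPerSignature)
  genes <- sprintf("G%05d", seq_len(backgroundGenes))
  sigs <- lapply(seq_along(subtypes), function(i) {
    GeneSignature(subtypes[i],
                  genes[((i - 1L) * genesPerSignature + 1L):
                          (i * genesPerSignature)],
                  role = "subtype")
  })
  names(sigs) <- subtypes
  withSeed(seed, {
    n <- nPerSubtype * length(subtypes)
    labels <- rep(subtypes, each = nPerSubtype)
    ids <- sprintf("%s_%02d", labels,
                   rep(seq_len(nPerSubtype), times = length(subtypes)))
    z <- matrix(rnorm(backgroundGenes * n), backgroundGenes, n,
                dimnames = list(genes, ids))
    for (j in seq_len(n))
      z[signatureGenes(sigs[[labels[j]]]), j] <-
        z[signatureGenes(sigs[[labels[j]]]), j] + shiftSd
    expr <- ExprMatrix(exp(z), sampleGroups = labels)
    list(expr = expr, signatures = sigs,
         truth = stats::setNames(labels, ids))
  })
}
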