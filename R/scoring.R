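## Tier classification of Spearman correlations and the signature
## correlation-ratio score, including the denominator-adjustment rules for
## platform-missing genes and for a gene of interest contained in its own
## signature.

#' Classify a correlation into the seven-level tier scale
#'
#' The strongest satisfied tier is returned. With the default thresholds:
#' strong when |rho| >= 0.50 and p < 0.05, else moderate when |rho| >= 0.30
#' and p < 0.05, else weak when |rho| >= 0.26 and p < 0.001, else `none`.
#' The sign of rho selects the positive or negative branch. R comparisons
#' are inclusive, p comparisons strict. Note the deliberate gap: |rho| in
#' \[0.26, 0.30) with p in \[0.001, 0.05) classifies as `none` unless
#' `relaxWeakP` is set in the thresholds.
#'
#' @param rho Spearman correlation(s) in \[-1, 1\] (vectorized).
#' @param p two-sided p-value(s) in \[0, 1\].
#' @param thresholds a [TierThresholds-class].
#' @return character vector of tiers: `strong_pos`, `moderate_pos`,
#'   `weak_pos`, `none`, `weak_neg`, `moderate_neg`, `strong_neg`.
#' @examples
#' classifyCorrelation(c(0.55, 0.28, 0.28), c(0.001, 0.0005, 0.01))
#' @export
classifyCorrelation <- function(rho, p, thresholds = TierThresholds()) {
  if (length(rho) != length(p)) stop("'rho' and 'p' must have equal length")
  if (any(!is.finite(rho)) || any(abs(rho) > 1 + 1e-12))
    stop("'rho' must lie in [-1, 1]")
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("'p' must lie in [0, 1]")
  th <- thresholds
  weakP <- if (th@relaxWeakP) th@moderateP else th@weakP
  a <- abs(rho)
  strength <- ifelse(a >= th@strongR & p < th@strongP, "strong",
              ifelse(a >= th@moderateR & p < th@moderateP, "moderate",
              ifelse(a >= th@weakR & p < weakP, "weak", "none")))
  out <- ifelse(strength == "none", "none",
                paste0(strength, ifelse(rho >= 0, "_pos", "_neg")))
  unname(out)
}

## Expression vector for one gene, optionally restricted to a subgroup.
.geneVector <- function(expr, gene, subgroup = NULL) {
  m <- exprValues(expr)
  gene <- normalizeSymbols(gene)
  if (!gene %in% rownames(m))
    stop("gene '", gene, "' is not present in the expression matrix")
  v <- m[gene, ]
  if (!is.null(subgroup)) {
    grp <- sampleGroups(expr)
    if (is.null(grp)) stop("expression matrix carries no subgroup labels")
    v <- v[names(grp)[grp == subgroup]]
  }
  v
}

#' Pairwise Spearman correlations against a gene of interest
#'
#' Computes Spearman rho, two-sided p and tier for the gene of interest
#' against each requested gene present in the matrix.
#'
#' @param expr an [ExprMatrix-class].
#' @param geneOfInterest gene symbol.
#' @param genes character vector of partner gene symbols.
#' @param thresholds a [TierThresholds-class].
#' @param subgroup optional subgroup label restricting the samples.
#' @return data.frame with columns `gene_a`, `gene_b`, `rho`, `p_two_sided`,
#'   `n`, `tier` (genes absent from the matrix get tier `"absent"` and NA
#'   statistics).
#' @export
correlateGenes <- function(expr, geneOfInterest, genes,
                           thresholds = TierThresholds(), subgroup = NULL) {
  geneOfInterest <- normalizeSymbols(geneOfInterest)
  genes <- normalizeSymbols(genes)
  x <- .geneVector(expr, geneOfInterest, subgroup)
  m <- exprValues(expr)
  rows <- lapply(genes, function(g) {
    if (!g %in% rownames(m))
      return(data.frame(gene_a = geneOfInterest, gene_b = g,
                        rho = NA_real_, p_two_sided = NA_real_,
                        n = length(x), tier = "absent",
                        stringsAsFactors = FALSE))
    y <- .geneVector(expr, g, subgroup)
    st <- spearmanTest(x, y)
    data.frame(gene_a = geneOfInterest, gene_b = g, rho = st$rho,
               p_two_sided = st$pTwoSided, n = st$n,
               tier = classifyCorrelation(st$rho, st$pTwoSided, thresholds),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Signature correlation-ratio score
#'
#' Correlates the gene of interest with every signature gene present in the
#' matrix (excluding the gene of interest itself when it belongs to the
#' signature), classifies each correlation, and counts the genes whose tier
#' sign matches `direction` at any strength (weak, moderate or strong). The
#' denominator is the signature size minus absent genes minus one for
#' self-exclusion — generalizing the published divide-by-8 (two genes
#' missing from a platform) and divide-by-11 (one gene missing, or TREM2
#' scored against the M2 profile that contains it) adjustments.
#'
#' @param expr an [ExprMatrix-class] with at least 4 samples in the selected
#'   subgroup.
#' @param geneOfInterest gene symbol present in `expr`.
#' @param signature a [GeneSignature-class] (or built-in signature name).
#' @param direction `"positive"` or `"negative"`; only sign-matched tiers
#'   count toward the numerator.
#' @param thresholds a [TierThresholds-class].
#' @param subgroup optional subgroup label.
#' @return a [RatioScore-class].
#' @examples
#' sim <- simulateExpression(nSamples = 50, plantedRho = 0.9,
#'                           nPlanted = 10, seed = 1)
#' ratioScore(sim$expr, "CD24", getSignature("high_risk"), "positive")
#' @export
ratioScore <- function(expr, geneOfInterest, signature,
                       direction = c("positive", "negative"),
                       thresholds = TierThresholds(), subgroup = NULL) {
  direction <- match.arg(direction)
  if (is.character(signature)) signature <- getSignature(signature)
  stopifnot(is(signature, "GeneSignature"))
  geneOfInterest <- normalizeSymbols(geneOfInterest)
  x <- .geneVector(expr, geneOfInterest, subgroup)
  if (length(x) < 4L)
    stop("need at least 4 samples in the selected subgroup")
  sigGenes <- signatureGenes(signature)
  selfExcluded <- geneOfInterest %in% sigGenes
  candidates <- setdiff(sigGenes, geneOfInterest)
  present <- candidates[candidates %in% geneIds(expr)]
  missing <- setdiff(candidates, present)
  denominator <- length(sigGenes) - length(missing) - as.integer(selfExcluded)
  if (denominator <= 0L)
    stop("denominator is zero: no evaluable signature genes")
  tiers <- correlateGenes(expr, geneOfInterest, present, thresholds,
                          subgroup)$tier
  wanted <- if (direction == "positive")
    c("weak_pos", "moderate_pos", "strong_pos")
  else c("weak_neg", "moderate_neg", "strong_neg")
  numerator <- sum(tiers %in% wanted)
  new("RatioScore", geneOfInterest = geneOfInterest,
      signatureName = signature@name, direction = direction,
      numerator = as.integer(numerator),
      denominator = as.integer(denominator),
      ratio = numerator / denominator,
      missingGenes = missing, selfExcluded = selfExcluded,
      subgroup = if (is.null(subgroup)) NA_character_ else subgroup,
      nSamples = length(x))
}

.scoreRow <- function(rs) {
  data.frame(gene = rs@geneOfInterest, signature = rs@signatureName,
             subgroup = rs@subgroup, direction = rs@direction,
             numerator = rs@numerator, denominator = rs@denominator,
             ratio = rs@ratio, n_samples = rs@nSamples,
             missing_genes = paste(rs@missingGenes, collapse = ";"),
             self_excluded = rs@selfExcluded, computable = TRUE,
             note = "", stringsAsFactors = FALSE)
}

.flaggedRow <- function(gene, sigName, subgroup, direction, n, note) {
  data.frame(gene = gene, signature = sigName, subgroup = subgroup,
             direction = direction, numerator = NA_integer_,
             denominator = NA_integer_, ratio = NA_real_, n_samples = n,
             missing_genes = "", self_excluded = NA, computable = FALSE,
             note = note, stringsAsFactors = FALSE)
}

#' Score a panel of genes against several signatures
#'
#' One [ratioScore()] per (gene of interest, signature, subgroup)
#' combination, returned as a long-format table in deterministic
#' lexicographic order (gene, then signature, then subgroup). Subgroups with
#' fewer than 4 samples yield a flagged, non-computable row rather than
#' being dropped.
#'
#' @param expr an [ExprMatrix-class].
#' @param genesOfInterest character vector of gene symbols.
#' @param signatures list of [GeneSignature-class] objects (default: the
#'   built-in high-risk and low-risk signatures).
#' @param direction `"positive"` or `"negative"` (applied to every score).
#' @param perSubgroup when TRUE, score each subgroup separately.
#' @param thresholds a [TierThresholds-class].
#' @return data.frame with columns gene, signature, subgroup, direction,
#'   numerator, denominator, ratio, n_samples, missing_genes,
#'   self_excluded, computable, note.
#' @export
scorePanel <- function(expr, genesOfInterest,
                       signatures = builtinSignatures()[c("high_risk",
                                                          "low_risk")],
                       direction = "positive", perSubgroup = FALSE,
                       thresholds = TierThresholds()) {
  genesOfInterest <- sort(normalizeSymbols(genesOfInterest))
  if (is(signatures, "GeneSignature")) signatures <- list(signatures)
  sigNames <- sort(vapply(signatures, function(s) s@name, ""))
  sigByName <- stats::setNames(signatures,
                               vapply(signatures, function(s) s@name, ""))
  if (perSubgroup) {
    grp <- sampleGroups(expr)
    if (is.null(grp))
      stop("perSubgroup = TRUE requires subgroup labels")
    subgroups <- sort(unique(grp))
  } else {
    subgroups <- NA_character_
  }
  rows <- list()
  for (g in genesOfInterest) for (sn in sigNames) for (sg in subgroups) {
    sub <- if (is.na(sg)) NULL else sg
    n <- if (is.na(sg)) ncol(expr) else sum(sampleGroups(expr) == sg)
    if (n < 4L) {
      rows[[length(rows) + 1L]] <-
        .flaggedRow(g, sn, sg, direction, n, "fewer than 4 samples")
      next
    }
    rs <- ratioScore(expr, g, sigByName[[sn]], direction, thresholds, sub)
    row <- .scoreRow(rs)
    row$subgroup <- sg
    rows[[length(rows) + 1L]] <- row
  }
  do.call(rbind, rows)
}

#' Tier table of a gene of interest against a marker panel
#'
#' The heatmap-style matrix behind subgroup-by-marker correlation figures:
#' rows are subgroups (or `"all"`), columns marker genes, cells the tier of
#' the Spearman correlation between the gene of interest and the marker in
#' that subgroup. Markers absent from the matrix give `"absent"`; subgroups
#' with fewer than 4 samples give `"insufficient_n"`.
#'
#' @param expr an [ExprMatrix-class].
#' @param geneOfInterest gene symbol.
#' @param markerGenes marker panel (default: the built-in marker signature).
#' @param perSubgroup when TRUE, one row per subgroup.
#' @param thresholds a [TierThresholds-class].
#' @return character matrix, subgroups x markers.
#' @export
tierTable <- function(expr, geneOfInterest,
                      markerGenes = signatureGenes(getSignature("marker")),
                      perSubgroup = FALSE,
                      thresholds = TierThresholds()) {
  markerGenes <- normalizeSymbols(markerGenes)
  if (perSubgroup) {
    grp <- sampleGroups(expr)
    if (is.null(grp)) stop("perSubgroup = TRUE requires subgroup labels")
    subgroups <- sort(unique(grp))
  } else {
    subgroups <- "all"
  }
  out <- matrix(NA_character_, length(subgroups), length(markerGenes),
                dimnames = list(subgroups, markerGenes))
  for (sg in subgroups) {
    sub <- if (identical(sg, "all")) NULL else sg
    n <- if (is.null(sub)) ncol(expr) else sum(sampleGroups(expr) == sub)
    if (n < 4L) {
      out[sg, ] <- "insufficient_n"
      next
    }
    out[sg, ] <- correlateGenes(expr, geneOfInterest, markerGenes,
                                thresholds, sub)$tier
  }
  out
}

#' M1/M2 macrophage-profile ratios
#'
#' Scores a gene of interest against the built-in 12-gene M1 (anti-tumoral)
#' and M2 (pro-tumoral) macrophage profiles with direction `"positive"`,
#' applying the self-exclusion rule (TREM2 scored against M2 uses
#' denominator 11) and the missing-gene rule (e.g. platforms lacking IDO1
#' score M1 over 11).
#'
#' @param expr an [ExprMatrix-class].
#' @param geneOfInterest gene symbol (e.g. SIGLEC10, TREM2, CD163, ITGA4).
#' @param thresholds a [TierThresholds-class].
#' @param subgroup optional subgroup label.
#' @return named list with [RatioScore-class] elements `M1` and `M2`.
#' @export
m1m2Profile <- function(expr, geneOfInterest,
                        thresholds = TierThresholds(), subgroup = NULL) {
  list(M1 = ratioScore(expr, geneOfInterest, getSignature("M1"),
                       "positive", thresholds, subgroup),
       M2 = ratioScore(expr, geneOfInterest, getSignature("M2"),
                       "positive", thresholds, subgroup))
}
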