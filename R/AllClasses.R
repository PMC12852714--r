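#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata
NULL

TIER_LEVELS <- c("strong_neg", "moderate_neg", "weak_neg", "none",
                 "weak_pos", "moderate_pos", "strong_pos")

SIGNATURE_ROLES <- c("high_risk", "low_risk", "M1", "M2", "subtype", "marker")

#' Expression matrix container
#'
#' Thin wrapper around [SummarizedExperiment::SummarizedExperiment] holding a
#' genes-by-samples matrix of normalized continuous expression values.
#' Row names are gene symbols (upper-cased, hyphen-stripped, unique); an
#' optional `group` column in `colData` carries molecular subgroup labels
#' (e.g. SHH, Group3, GBM_PN).
#'
#' @slot .Data inherited SummarizedExperiment slots; use the accessors.
#' @seealso [ExprMatrix()], [exprValues()], [sampleGroups()]
#' @export
setClass("ExprMatrix", contains = "SummarizedExperiment")

setValidity("ExprMatrix", function(object) {
  v <- assay(object)
  g <- rownames(v)
  if (is.null(g) || anyNA(g) || any(g == ""))
    return("all genes must have non-empty symbols")
  if (anyDuplicated(g))
    return(paste0("duplicate gene symbols: ",
                  paste(unique(g[duplicated(g)]), collapse = ", ")))
  if (!identical(g, normalizeSymbols(g)))
    return("gene symbols must be upper-case with hyphens stripped")
  if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
    return("sample identifiers must be present and unique")
  if (!is.numeric(v) || any(!is.finite(v)))
    return("expression values must be finite numbers")
  if ("group" %in% colnames(colData(object))) {
    grp <- colData(object)$group
    if (anyNA(grp)) return("subgroup labels must not contain NA")
  }
  TRUE
})

#' Construct an ExprMatrix
#'
#' @param values numeric matrix, genes in rows (rownames = symbols), samples
#'   in columns (colnames = sample ids).
#' @param sampleGroups optional character vector of subgroup labels, either
#'   unnamed in column order or named by sample id.
#' @return an [ExprMatrix-class] object.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(c("CD24", "FOXM1", "NEK2"), paste0("s", 1:4)))
#' em <- ExprMatrix(m, sampleGroups = rep(c("SHH", "Group3"), 2))
#' sampleGroups(em)
#' @export
ExprMatrix <- function(values, sampleGroups = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  rownames(values) <- normalizeSymbols(rownames(values))
  cd <- DataFrame(row.names = colnames(values))
  if (!is.null(sampleGroups)) {
    if (!is.null(names(sampleGroups))) {
      missing <- setdiff(colnames(values), names(sampleGroups))
      if (length(missing))
        stop("sampleGroups lacks labels for: ",
             paste(missing, collapse = ", "))
      sampleGroups <- sampleGroups[colnames(values)]
    } else if (length(sampleGroups) != ncol(values)) {
      stop("sampleGroups must have one label per sample")
    }
    cd$group <- as.character(sampleGroups)
  }
  se <- SummarizedExperiment(assays = list(expr = values), colData = cd)
  new("ExprMatrix", se)
}

#' Gene signature
#'
#' A named, ordered list of gene symbols with a role describing how the
#' signature is used: prognostic (`high_risk`, `low_risk`), macrophage
#' polarization profile (`M1`, `M2`), tumor `subtype` set, or a `marker`
#' panel.
#'
#' @slot name signature name.
#' @slot genes ordered character vector of gene symbols (unique, upper-case).
#' @slot role one of `high_risk`, `low_risk`, `M1`, `M2`, `subtype`, `marker`.
#' @export
setClass("GeneSignature",
         representation(name = "character", genes = "character",
                        role = "character"))

setValidity("GeneSignature", function(object) {
  if (length(object@name) != 1L || !nzchar(object@name))
    return("'name' must be a single non-empty string")
  if (length(object@genes) == 0L)
    return("'genes' must be non-empty")
  if (anyDuplicated(object@genes))
    return("'genes' must be unique within a signature")
  if (!identical(object@genes, normalizeSymbols(object@genes)))
    return("gene symbols must be normalized (upper-case, no hyphens)")
  if (length(object@role) != 1L || !object@role %in% SIGNATURE_ROLES)
    return(paste0("'role' must be one of: ",
                  paste(SIGNATURE_ROLES, collapse = ", ")))
  TRUE
})

#' @rdname GeneSignature-class
#' @param name signature name.
#' @param genes character vector of gene symbols (normalized on input).
#' @param role signature role.
#' @export
GeneSignature <- function(name, genes, role = "marker") {
  new("GeneSignature", name = as.character(name),
      genes = normalizeSymbols(genes), role = as.character(role))
}

#' Correlation-tier classification thresholds
#'
#' Holds the r-magnitude and p-value cutoffs of the three-tier correlation
#' scale. Defaults are the published rules: weak |r| >= 0.26 with p < 0.001,
#' moderate |r| >= 0.30 with p < 0.05, strong |r| >= 0.50 with p < 0.05
#' (mirrored for negative correlations). R comparisons are inclusive,
#' p comparisons strict. `relaxWeakP = TRUE` widens the weak tier's p cutoff
#' to `moderateP` for sensitivity analysis (off by default, so the r gap
#' \[0.26, 0.30) with p in \[0.001, 0.05) classifies as `none`).
#'
#' @slot weakR,weakP,moderateR,moderateP,strongR,strongP numeric cutoffs.
#' @slot relaxWeakP logical sensitivity-analysis flag.
#' @export
setClass("TierThresholds",
         representation(weakR = "numeric", weakP = "numeric",
                        moderateR = "numeric", moderateP = "numeric",
                        strongR = "numeric", strongP = "numeric",
                        relaxWeakP = "logical"))

setValidity("TierThresholds", function(object) {
  if (!(object@weakR > 0 && object@weakR < object@moderateR &&
        object@moderateR < object@strongR && object@strongR < 1))
    return("need 0 < weakR < moderateR < strongR < 1")
  if (!(object@weakP > 0 && object@weakP <= object@moderateP &&
        object@moderateP <= 1))
    return("need 0 < weakP <= moderateP <= 1")
  if (object@strongP <= 0 || object@strongP > 1)
    return("strongP must be in (0, 1]")
  TRUE
})

#' @rdname TierThresholds-class
#' @param weakR,weakP,moderateR,moderateP,strongR,strongP numeric cutoffs.
#' @param relaxWeakP logical; widen the weak tier's p cutoff to `moderateP`.
#' @export
TierThresholds <- function(weakR = 0.26, weakP = 0.001,
                           moderateR = 0.30, moderateP = 0.05,
                           strongR = 0.50, strongP = 0.05,
                           relaxWeakP = FALSE) {
  new("TierThresholds", weakR = weakR, weakP = weakP,
      moderateR = moderateR, moderateP = moderateP,
      strongR = strongR, strongP = strongP,
      relaxWeakP = assertFlag(relaxWeakP, "relaxWeakP"))
}

#' Signature correlation-ratio score
#'
#' The fraction of a signature's genes whose Spearman correlation with the
#' gene of interest reaches any tier of the requested sign. The denominator
#' is the signature size minus genes absent from the expression matrix and
#' minus one when the gene of interest is itself a signature member
#' (self-exclusion).
#'
#' @slot geneOfInterest gene symbol scored.
#' @slot signatureName name of the signature scored against.
#' @slot direction "positive" or "negative".
#' @slot numerator count of sign-matched correlated genes.
#' @slot denominator adjusted signature size.
#' @slot ratio numerator / denominator, in \[0, 1\].
#' @slot missingGenes signature genes absent from the matrix.
#' @slot selfExcluded TRUE when the gene of interest was removed from its own
#'   signature.
#' @slot subgroup subgroup label the score was computed in (NA when global).
#' @slot nSamples number of samples used.
#' @export
setClass("RatioScore",
         representation(geneOfInterest = "character",
                        signatureName = "character",
                        direction = "character",
                        numerator = "integer",
                        denominator = "integer",
                        ratio = "numeric",
                        missingGenes = "character",
                        selfExcluded = "logical",
                        subgroup = "character",
                        nSamples = "integer"))

setValidity("RatioScore", function(object) {
  if (!object@direction %in% c("positive", "negative"))
    return("direction must be 'positive' or 'negative'")
  if (object@denominator <= 0L) return("denominator must be positive")
  if (object@numerator < 0L || object@numerator > object@denominator)
    return("need 0 <= numerator <= denominator")
  if (abs(object@ratio - object@numerator / object@denominator) > 1e-12)
    return("ratio must equal numerator/denominator")
  TRUE
})

#' Two-sample test result
#'
#' @slot statistic test statistic (U for Mann-Whitney, chi-square for the
#'   log-rank Mantel-Cox test).
#' @slot pTwoSided two-sided p-value.
#' @slot n1,n2 group sizes.
#' @slot method computation tag: `exact`, `normal_approx`, `t_approx` or
#'   `chi_square`, recorded for reproducibility.
#' @export
setClass("TestResult",
         representation(statistic = "numeric", pTwoSided = "numeric",
                        n1 = "integer", n2 = "integer", method = "character"))

setValidity("TestResult", function(object) {
  if (object@pTwoSided < 0 || object@pTwoSided > 1)
    return("p-value must lie in [0, 1]")
  TRUE
})

#' Kaplan-Meier curve
#'
#' Product-limit survival estimate over the distinct event times of one
#' group. The median is the smallest event time at which the survival
#' function drops to 0.5 or below; `NA` when it never does.
#'
#' @slot times distinct event times, increasing.
#' @slot survival survival probabilities after each event time.
#' @slot atRisk number at risk just before each event time.
#' @slot nEvents events at each time.
#' @slot median median survival time or `NA`.
#' @slot n number of subjects.
#' @export
setClass("KMCurve",
         representation(times = "numeric", survival = "numeric",
                        atRisk = "integer", nEvents = "integer",
                        median = "numeric", n = "integer"))

setValidity("KMCurve", function(object) {
  s <- object@survival
  if (length(s) && (any(s < -1e-12) || any(s > 1 + 1e-12)))
    return("survival must lie in [0, 1]")
  if (length(s) > 1L && any(diff(s) > 1e-12))
    return("survival must be non-increasing")
  if (is.unsorted(object@times, strictly = TRUE))
    return("event times must be strictly increasing")
  TRUE
})

#' Two-channel stain image
#'
#' A marker channel and a nuclear (DAPI) channel of equal shape, with the
#' physical pixel size. The marker channel may be absent (0 x 0 matrix) for
#' nuclear-only images.
#'
#' @slot marker numeric intensity matrix (possibly 0 x 0 when absent).
#' @slot nuclear numeric intensity matrix.
#' @slot pixelSizeUm physical pixel edge length in micrometres.
#' @export
setClass("StainImage",
         representation(marker = "matrix", nuclear = "matrix",
                        pixelSizeUm = "numeric"))

setValidity("StainImage", function(object) {
  if (length(object@nuclear) == 0L) return("nuclear channel must be non-empty")
  if (any(!is.finite(object@nuclear)) ||
      (length(object@marker) && any(!is.finite(object@marker))))
    return("intensities must be finite")
  if (any(object@nuclear < 0) ||
      (length(object@marker) && any(object@marker < 0)))
    return("intensities must be non-negative")
  if (length(object@marker) &&
      !identical(dim(object@marker), dim(object@nuclear)))
    return("marker and nuclear channels must have the same shape")
  if (length(object@pixelSizeUm) != 1L || !is.finite(object@pixelSizeUm) ||
      object@pixelSizeUm <= 0)
    return("pixelSizeUm must be a single positive number")
  TRUE
})

#' @rdname StainImage-class
#' @param marker,nuclear numeric intensity matrices (same shape); pass
#'   `NULL` for a nuclear-only image.
#' @param pixelSizeUm physical pixel edge length, micrometres.
#' @export
StainImage <- function(marker = NULL, nuclear, pixelSizeUm) {
  if (is.null(marker)) marker <- matrix(numeric(0), 0L, 0L)
  new("StainImage", marker = marker, nuclear = nuclear,
      pixelSizeUm = pixelSizeUm)
}

#' Binary mask with calibrated area
#'
#' @slot mask logical matrix (TRUE = inside the region).
#' @slot areaPx number of TRUE pixels.
#' @slot areaMm2 area in square millimetres
#'   (`areaPx * (pixelSizeUm / 1000)^2`).
#' @slot thresholdUsed intensity threshold that produced the mask.
#' @export
setClass("MaskResult",
         representation(mask = "matrix", areaPx = "integer",
                        areaMm2 = "numeric", thresholdUsed = "numeric"))

setValidity("MaskResult", function(object) {
  if (!is.logical(object@mask)) return("mask must be logical")
  if (object@areaPx != sum(object@mask))
    return("areaPx must equal the count of TRUE pixels")
  TRUE
})

#' Ranked gene list for preranked enrichment
#'
#' Genes ordered by decreasing ranking metric; ties broken by gene symbol
#' ascending so the ordering is deterministic.
#'
#' @slot geneIds gene symbols in rank order.
#' @slot metric ranking metric values, same order (non-increasing).
#' @export
setClass("RankedList",
         representation(geneIds = "character", metric = "numeric"))

setValidity("RankedList", function(object) {
  if (length(object@geneIds) != length(object@metric))
    return("geneIds and metric must have equal length")
  if (anyDuplicated(object@geneIds)) return("duplicate genes in ranked list")
  if (is.unsorted(rev(object@metric))) return("metric must be non-increasing")
  TRUE
})

#' Subtype assignment by maximum NES
#'
#' @slot sampleId sample identifier.
#' @slot nes named numeric vector of normalized enrichment scores, one per
#'   subtype signature.
#' @slot pValues named numeric vector of permutation p-values.
#' @slot assigned subtype with the highest NES, or "ambiguous" on an exact
#'   tie.
#' @export
setClass("SubtypeCall",
         representation(sampleId = "character", nes = "numeric",
                        pValues = "numeric", assigned = "character"))
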