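#' @include AllClasses.R
NULL

#' Accessors for sigratio objects
#'
#' `exprValues` returns the genes-by-samples matrix, `geneIds` and
#' `sampleIds` its dimnames, and `sampleGroups` the subgroup labels (named
#' by sample, or `NULL` when none were supplied). `signatureGenes` and
#' `signatureRole` read a [GeneSignature-class]; `scoreRatio` the ratio of a
#' [RatioScore-class]; `medianSurvival` the median of a [KMCurve-class].
#'
#' @param x a sigratio object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname accessors
#' @export
setGeneric("signatureGenes", function(x) standardGeneric("signatureGenes"))

#' @rdname accessors
#' @export
setGeneric("signatureRole", function(x) standardGeneric("signatureRole"))

#' @rdname accessors
#' @export
setGeneric("scoreRatio", function(x) standardGeneric("scoreRatio"))

#' @rdname accessors
#' @export
setGeneric("medianSurvival", function(x) standardGeneric("medianSurvival"))

#' @rdname accessors
#' @export
setMethod("exprValues", "ExprMatrix", function(x) assay(x, "expr"))

#' @rdname accessors
#' @export
setMethod("geneIds", "ExprMatrix", function(x) rownames(x))

#' @rdname accessors
#' @export
setMethod("geneIds", "RankedList", function(x) x@geneIds)

#' @rdname accessors
#' @export
setMethod("sampleIds", "ExprMatrix", function(x) colnames(x))

#' @rdname accessors
#' @export
setMethod("sampleGroups", "ExprMatrix", function(x) {
  cd <- colData(x)
  if (!"group" %in% colnames(cd)) return(NULL)
  stats::setNames(as.character(cd$group), rownames(cd))
})

#' @rdname accessors
#' @export
setMethod("signatureGenes", "GeneSignature", function(x) x@genes)

#' @rdname accessors
#' @export
setMethod("signatureRole", "GeneSignature", function(x) x@role)

#' @rdname accessors
#' @export
setMethod("scoreRatio", "RatioScore", function(x) x@ratio)

#' @rdname accessors
#' @export
setMethod("medianSurvival", "KMCurve", function(x) x@median)

setMethod("show", "GeneSignature", function(object) {
  cat("GeneSignature '", object@name, "' (role: ", object@role, ", ",
      length(object@genes), " genes)\n", sep = "")
  cat(" ", paste(object@genes, collapse = ", "), "\n")
})

setMethod("show", "RatioScore", function(object) {
  cat("RatioScore: ", object@geneOfInterest, " vs ", object@signatureName,
      " (", object@direction, ")\n", sep = "")
  sub <- if (is.na(object@subgroup)) "all samples" else object@subgroup
  cat(sprintf("  ratio %d/%d = %.3f  [%s, n = %d]\n", object@numerator,
              object@denominator, object@ratio, sub, object@nSamples))
  if (length(object@missingGenes))
    cat("  missing from matrix:",
        paste(object@missingGenes, collapse = ", "), "\n")
  if (object@selfExcluded)
    cat("  gene of interest excluded from its own signature\n")
})

setMethod("show", "TestResult", function(object) {
  cat(sprintf("TestResult (%s): statistic = %.6g, two-sided p = %.4g, n = %d/%d\n",
              object@method, object@statistic, object@pTwoSided,
              object@n1, object@n2))
})

setMethod("show", "KMCurve", function(object) {
  med <- if (is.na(object@median)) "not reached" else
    format(object@median)
  cat(sprintf("KMCurve: %d subjects, %d event times, median survival %s\n",
              object@n, length(object@times), med))
})

setMethod("show", "SubtypeCall", function(object) {
  cat("SubtypeCall for sample '", object@sampleId, "': ", object@assigned,
      "\n", sep = "")
  for (nm in names(object@nes))
    cat(sprintf("  %-12s NES = %7.3f  p = %.4g\n", nm, object@nes[[nm]],
                object@pValues[[nm]]))
})

setMethod("show", "MaskResult", function(object) {
  cat(sprintf("MaskResult: %d px (%.4g mm^2), threshold %.4g, shape %d x %d\n",
              object@areaPx, object@areaMm2, object@thresholdUsed,
              nrow(object@mask), ncol(object@mask)))
})
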