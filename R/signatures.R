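## Built-in signature registry. Gene lists are transcribed verbatim from the
## curated sources, including "ITGB" (no unambiguous HGNC symbol; likely
## absent from any real platform) and "ZPF3" (possible typo for ZNF3). They
## are deliberately NOT corrected: scores must reflect the published lists,
## and absent genes are handled by the denominator-adjustment rules.

.SIGNATURE_REGISTRY <- list(
  high_risk = c("FOXM1", "NEK2", "CCT2", "ACTL6A", "CCND2", "ABL1",
                "SYNCRIP", "ITGB", "ENAH", "UMPS"),
  low_risk  = c("ADAM22", "AEBP1", "DHRS2", "RAC3", "SHANK1", "CYB5D2",
                "IL27RA", "DNAH2", "ZPF3", "NRXN2"),
  M1 = c("APOL3", "CCL19", "CCL5", "CCR7", "CD38", "CD40", "CXCL10",
         "CXCL9", "EBI3", "IDO1", "LAMP3", "TNFAIP6"),
  M2 = c("AIF1", "CCL13", "CCL18", "CD180", "CD209", "CD4", "CLEC4A",
         "CLEC10A", "MS4A6A", "NPL", "SLC15A3", "TREM2"),
  marker = c("MKI67", "CTNNB1", "SMO", "MYC", "CDK6", "CD24", "SIGLEC10",
             "TREM2", "CD163", "ITGA4", "P2RY12", "TMEM119", "AIF1", "PTPRC")
)

.SIGNATURE_ROLE_OF <- c(high_risk = "high_risk", low_risk = "low_risk",
                        M1 = "M1", M2 = "M2", marker = "marker")

#' Built-in gene signatures
#'
#' Returns the curated signature registry used throughout the package:
#'
#' * `high_risk` — 10-gene poor-prognosis signature (FOXM1 ... UMPS).
#' * `low_risk` — 10-gene favourable-prognosis signature (ADAM22 ... NRXN2).
#' * `M1` — 12-gene anti-tumoral macrophage profile (CIBERSORT-derived).
#' * `M2` — 12-gene pro-tumoral macrophage profile (contains TREM2).
#' * `marker` — tumor-cell, microglia and macrophage marker panel used for
#'   tier tables (MKI67, CD24, SIGLEC10, TREM2, ...).
#'
#' The lists are kept verbatim, including symbols with no current HGNC match
#' ("ITGB", "ZPF3"); platform-missing genes are accounted for by the
#' denominator rules of [ratioScore()].
#'
#' @return named list of [GeneSignature-class] objects.
#' @examples
#' sigs <- builtinSignatures()
#' signatureGenes(sigs$M2)
#' @export
builtinSignatures <- function() {
  lapply(stats::setNames(names(.SIGNATURE_REGISTRY),
                         names(.SIGNATURE_REGISTRY)),
         function(nm) GeneSignature(nm, .SIGNATURE_REGISTRY[[nm]],
                                    role = .SIGNATURE_ROLE_OF[[nm]]))
}

#' Fetch one built-in signature by name
#'
#' @param name one of `"high_risk"`, `"low_risk"`, `"M1"`, `"M2"`,
#'   `"marker"`.
#' @return a [GeneSignature-class].
#' @export
getSignature <- function(name) {
  name <- match.arg(name, names(.SIGNATURE_REGISTRY))
  builtinSignatures()[[name]]
}
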