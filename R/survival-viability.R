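## In vivo / in vitro pipeline stages: the two-group survival comparison
## with administrative censoring at a horizon, MTT viability normalization,
## and log-dose interpolation of the 50%-death crossing.

#' Compare survival between two groups
#'
#' Applies administrative censoring — any subject with a time beyond
#' `censorHorizonDays` is censored at the horizon, regardless of its event
#' flag — then runs the log-rank (Mantel-Cox) test and estimates a
#' Kaplan-Meier curve (with median) per group.
#'
#' @param records survival data.frame (`time_days`, `event`, `group`).
#' @param groupA,groupB the two group labels to compare.
#' @param censorHorizonDays administrative censoring horizon (default 100
#'   days).
#' @return list with `test` (a [TestResult-class]) and `curves` (named list
#'   of [KMCurve-class] for the two groups).
#' @export
compareSurvival <- function(records, groupA, groupB,
                            censorHorizonDays = 100) {
  assertNumber(censorHorizonDays, "censorHorizonDays", lower = 1e-9)
  records <- .checkSurvival(records)
  if (!"group" %in% names(records)) stop("records need a 'group' column")
  keep <- records$group %in% c(groupA, groupB)
  records <- records[keep, , drop = FALSE]
  if (!any(records$group == groupA) || !any(records$group == groupB))
    stop("both groups must be non-empty")
  over <- records$time_days > censorHorizonDays
  records$event[over] <- FALSE
  records$time_days[over] <- censorHorizonDays
  curves <- lapply(stats::setNames(c(groupA, groupB), c(groupA, groupB)),
                   function(g) kmEstimate(records[records$group == g, ]))
  list(test = logrankTest(records), curves = curves)
}

#' Normalize MTT viability readings to untreated controls
#'
#' The corrected optical density is the 540 nm reading minus the 650 nm
#' reference reading (standard MTT background handling). Within each
#' stratum — `timepoint_h`, crossed with `plate` when present — the
#' viability fraction of every well is its corrected OD divided by the mean
#' corrected OD of the untreated (`dose_uM == 0`) wells of that stratum.
#'
#' @param records viability data.frame with columns `label`, `dose_uM`,
#'   `timepoint_h`, `od540`, `od650` and optional `plate`.
#' @return the input with an added `viability_fraction` column.
#' @export
normalizeViability <- function(records) {
  need <- c("dose_uM", "timepoint_h", "od540", "od650")
  if (!all(need %in% names(records)))
    stop("viability records need columns: ", paste(need, collapse = ", "))
  corrected <- records$od540 - records$od650
  strata <- if ("plate" %in% names(records))
    interaction(records$timepoint_h, records$plate, drop = TRUE)
  else factor(records$timepoint_h)
  records$viability_fraction <- NA_real_
  for (s in levels(strata)) {
    idx <- strata == s
    untreated <- idx & records$dose_uM == 0
    if (!any(untreated))
      stop("stratum '", s, "' has no untreated (dose 0) wells")
    ref <- mean(corrected[untreated])
    if (ref <= 0)
      stop("untreated mean corrected OD is non-positive in stratum '",
           s, "'")
    records$viability_fraction[idx] <- corrected[idx] / ref
  }
  records
}

#' Dose at which viability first crosses a target fraction
#'
#' Finds the first downward crossing of the viability curve through
#' `fraction` and interpolates linearly in log10(dose). An exact hit on a
#' tested dose returns that dose. When the curve never drops to the target,
#' the dose is `NA` (`crossed = FALSE`). Non-monotonic curves still return
#' the first crossing but are flagged.
#'
#' @param dose strictly increasing positive doses.
#' @param viability viability fractions at those doses.
#' @param fraction target fraction (default 0.5, i.e. 50% cell death).
#' @return list with `dose`, `crossed`, `monotonic`.
#' @examples
#' doseAtFraction(c(1, 10), c(0.9, 0.1))$dose  # ~3.16
#' @export
doseAtFraction <- function(dose, viability, fraction = 0.5) {
  if (length(dose) != length(viability) || length(dose) < 1L)
    stop("dose and viability must be equal-length, non-empty")
  if (any(dose <= 0)) stop("doses must be positive for log interpolation")
  if (is.unsorted(dose, strictly = TRUE))
    stop("doses must be strictly increasing")
  assertNumber(fraction, "fraction", lower = 0, upper = 1)
  monotonic <- !is.unsorted(rev(viability))
  below <- viability <= fraction
  if (!any(below))
    return(list(dose = NA_real_, crossed = FALSE, monotonic = monotonic))
  i <- which(below)[1L]
  d <- if (i == 1L) {
    dose[1L]
  } else if (viability[i] == fraction) {
    dose[i]
  } else {
    ld <- log10(dose)
    frac <- (viability[i - 1L] - fraction) /
      (viability[i - 1L] - viability[i])
    10^(ld[i - 1L] + frac * (ld[i] - ld[i - 1L]))
  }
  list(dose = d, crossed = TRUE, monotonic = monotonic)
}
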