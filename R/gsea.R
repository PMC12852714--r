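## Preranked gene-set enrichment: classic weighted Kolmogorov-Smirnov
## running-sum enrichment score, gene-tag permutation null, NES, and
## subtype assignment by maximum NES. Probe-collapsing is out of scope:
## inputs are already symbol-keyed, so set membership is plain symbol
## matching.

#' Rank one sample's genes for preranked enrichment
#'
#' Genes are ordered by expression value descending; ties are broken by
#' gene symbol ascending, so the ranking is deterministic and independent
#' of the input row order. The ranking metric is the expression value
#' itself.
#'
#' @param expr an [ExprMatrix-class].
#' @param sampleId sample identifier.
#' @return a [RankedList-class].
#' @export
rankSample <- function(expr, sampleId) {
  if (!sampleId %in% sampleIds(expr))
    stop("sample '", sampleId, "' not found")
  v <- exprValues(expr)[, sampleId]
  o <- order(-v, names(v), method = "radix")
  new("RankedList", geneIds = names(v)[o], metric = unname(v[o]))
}

## ES from sorted hit positions. Running sum: hits increment by
## |metric|^p / sum(|metric_hits|^p), misses decrement by 1/(N - k).
## Extrema can only occur immediately before or after a hit, so only 2k
## candidate values need evaluating.
.esFromPositions <- function(metric, pos, weightP, N) {
  k <- length(pos)
  if (k == 0L) stop("gene set has no member in the ranked list")
  if (k >= N) stop("gene set covers the entire ranked list")
  pos <- sort(pos)
  w <- abs(metric[pos])^weightP
  W <- sum(w)
  if (W == 0) {                       # all hit metrics zero: equal weights
    w <- rep.int(1, k)
    W <- k
  }
  cw <- cumsum(w) / W
  missDec <- 1 / (N - k)
  after <- cw - (pos - seq_len(k)) * missDec
  before <- after - w / W
  cand <- c(after, before)
  esPos <- max(cand)
  esNeg <- min(cand)
  if (esPos >= -esNeg) esPos else esNeg
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Classic preranked enrichment: walking down the ranked list, members of
#' the gene set ("hits") increment a running sum by `|metric|^weightP`
#' normalized to the hit total, non-members decrement it by `1/(N - k)`.
#' The enrichment score is the signed maximal deviation of the running sum
#' from zero; `|ES| <= 1` always. With `weightP = 0` the score reduces to
#' the (signed) Kolmogorov-Smirnov statistic between hit and miss rank
#' distributions.
#'
#' @param ranked a [RankedList-class].
#' @param geneSet a [GeneSignature-class] (must share at least one gene
#'   with the list, at most `maxSetSize` genes).
#' @param weightP weighting exponent (default 1).
#' @param maxSetSize largest admissible gene-set size (default 1000).
#' @return signed enrichment score.
#' @export
enrichmentScore <- function(ranked, geneSet, weightP = 1,
                            maxSetSize = 1000L) {
  stopifnot(is(ranked, "RankedList"), is(geneSet, "GeneSignature"))
  if (length(signatureGenes(geneSet)) > maxSetSize)
    stop("gene set exceeds maxSetSize = ", maxSetSize)
  pos <- which(ranked@geneIds %in% signatureGenes(geneSet))
  .esFromPositions(ranked@metric, pos, weightP, length(ranked@geneIds))
}

#' Normalized enrichment score by gene-tag permutation
#'
#' The null distribution is built by drawing `nPerm` random gene sets of
#' the same size from the ranked list (gene-tag permutation, the standard
#' null for preranked mode). NES is the observed ES divided by the mean
#' |null ES| among null scores of the same sign; the p-value is the
#' one-sided empirical tail probability with add-one correction. When no
#' null score shares the observed sign, the NES falls back to normalizing
#' by the overall mean |null ES| and the p-value floors at
#' `1 / (nPerm + 1)`.
#'
#' @param ranked a [RankedList-class].
#' @param geneSet a [GeneSignature-class].
#' @param nPerm number of permutations, `>= 100`.
#' @param seed RNG seed (mandatory, for reproducibility).
#' @param weightP weighting exponent.
#' @return list with `es`, `nes`, `pValue`, `nPerm`.
#' @export
normalizedES <- function(ranked, geneSet, nPerm = 1000L, seed, weightP = 1) {
  nPerm <- assertCount(nPerm, "nPerm", lower = 100L)
  es <- enrichmentScore(ranked, geneSet, weightP)
  N <- length(ranked@geneIds)
  k <- sum(ranked@geneIds %in% signatureGenes(geneSet))
  nullEs <- withSeed(seed, vapply(seq_len(nPerm), function(b) {
    .esFromPositions(ranked@metric, sample.int(N, k), weightP, N)
  }, 0))
  sameSign <- nullEs[sign(nullEs) == sign(es) | nullEs == 0]
  if (length(sameSign) == 0L) {
    nes <- es / mean(abs(nullEs))
    p <- 1 / (nPerm + 1)
  } else {
    nes <- es / mean(abs(sameSign))
    p <- (1 + sum(abs(sameSign) >= abs(es))) / (nPerm + 1)
  }
  list(es = es, nes = nes, pValue = p, nPerm = nPerm)
}

## Argmax with the declared tie rule: an exact NES tie is "ambiguous".
.decideSubtype <- function(nes) {
  top <- which(nes == max(nes))
  if (length(top) > 1L) "ambiguous" else names(nes)[top]
}

#' Assign a subtype by maximum NES
#'
#' Ranks the sample, computes a NES per subtype signature, and assigns the
#' subtype with the highest NES; an exact NES tie yields `"ambiguous"`.
#' Each signature uses a deterministic substream derived from `seed`.
#'
#' @param expr an [ExprMatrix-class].
#' @param sampleId sample to classify.
#' @param signatures named list of at least two subtype
#'   [GeneSignature-class] objects.
#' @param nPerm permutations per signature.
#' @param seed RNG seed.
#' @param weightP weighting exponent.
#' @return a [SubtypeCall-class].
#' @export
assignSubtype <- function(expr, sampleId, signatures, nPerm = 500L,
                          seed = 1L, weightP = 1) {
  if (length(signatures) < 2L) stop("need at least two subtype signatures")
  nms <- vapply(signatures, function(s) s@name, "")
  ranked <- rankSample(expr, sampleId)
  res <- lapply(seq_along(signatures), function(i) {
    normalizedES(ranked, signatures[[i]], nPerm = nPerm,
                 seed = seed + i - 1L, weightP = weightP)
  })
  nes <- stats::setNames(vapply(res, `[[`, 0, "nes"), nms)
  pv <- stats::setNames(vapply(res, `[[`, 0, "pValue"), nms)
  new("SubtypeCall", sampleId = sampleId, nes = nes, pValues = pv,
      assigned = .decideSubtype(nes))
}

#' Assign subtypes for every sample
#'
#' @param expr an [ExprMatrix-class].
#' @param signatures named list of subtype signatures.
#' @param nPerm permutations per signature.
#' @param seed base seed; each sample uses a deterministic offset.
#' @param weightP weighting exponent.
#' @return data.frame with `sample_id`, `assigned` and one NES column per
#'   signature.
#' @export
assignSubtypes <- function(expr, signatures, nPerm = 500L, seed = 1L,
                           weightP = 1) {
  ids <- sampleIds(expr)
  calls <- lapply(seq_along(ids), function(i) {
    assignSubtype(expr, ids[i], signatures, nPerm = nPerm,
                  seed = seed + (i - 1L) * length(signatures),
                  weightP = weightP)
  })
  nes <- do.call(rbind, lapply(calls, function(cl) cl@nes))
  out <- data.frame(sample_id = ids,
                    assigned = vapply(calls, function(cl) cl@assigned, ""),
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(nes))
}
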