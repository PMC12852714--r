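## Rank-based statistics implemented from first principles: midranks,
## Spearman correlation with exact small-sample permutation p, Mann-Whitney
## U, Kaplan-Meier product-limit estimation and the log-rank (Mantel-Cox)
## test. Standard-library routines (cor.test, wilcox.test, survdiff) serve
## as independent oracles in the test suite, not as the implementation.

.permCache <- new.env(parent = emptyenv())

## All permutations of 1:n as an n! x n integer matrix (n <= 9), cached.
allPermutations <- function(n) {
  key <- as.character(n)
  if (!is.null(.permCache[[key]])) return(.permCache[[key]])
  build <- function(n) {
    if (n == 1L) return(matrix(1L, 1L, 1L))
    sub <- build(n - 1L)
    do.call(rbind, lapply(seq_len(n), function(i) {
      rest <- seq_len(n)[-i]
      cbind(rep.int(i, nrow(sub)),
            matrix(rest[sub], nrow(sub), n - 1L))
    }))
  }
  out <- build(as.integer(n))
  if (n <= 9L) .permCache[[key]] <- out
  out
}

#' Midranks
#'
#' Ranks with ties replaced by their average (midranks), the rank convention
#' under which Spearman's rho is the Pearson correlation of ranks.
#'
#' @param x numeric vector, finite, length >= 1.
#' @return numeric vector of midranks; their sum is always `n(n+1)/2`.
#' @examples
#' midranks(c(5, 5, 9))  # 1.5 1.5 3
#' @export
midranks <- function(x) {
  if (length(x) == 0L) stop("cannot rank an empty vector")
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("'x' must be finite numeric")
  rank(x, ties.method = "average")
}

## Spearman rho as Pearson correlation of midranks.
spearmanRho <- function(x, y) {
  rx <- midranks(x); ry <- midranks(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("undefined correlation: zero variance")
  cor(rx, ry)
}

## Exact two-sided permutation p for untied data: the permutation
## distribution of rho over all n! pairings of the ranks.
spearmanExactP <- function(rho, n) {
  perms <- allPermutations(n)
  a <- seq_len(n)
  denom <- n * (n^2 - 1)
  d2 <- rowSums((perms - matrix(a, nrow(perms), n, byrow = TRUE))^2)
  rhoPerm <- 1 - 6 * d2 / denom
  mean(abs(rhoPerm) >= abs(rho) - 1e-12)
}

#' Spearman rank correlation test
#'
#' Computes Spearman's rho as the Pearson correlation of midranks. The
#' two-sided p-value is exact (full enumeration of the n! rank pairings)
#' when `n <= 9` and neither vector has ties; otherwise it uses the
#' t-approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2`
#' degrees of freedom. A perfect correlation under the t-approximation
#' reports the smallest representable positive p rather than an exact zero.
#'
#' @param x,y numeric vectors of equal length `n >= 4`, finite.
#' @return list with `rho`, `pTwoSided`, `n` and `method`
#'   (`"exact"` or `"t_approx"`).
#' @examples
#' spearmanTest(1:5, c(1, 3, 2, 5, 4))$rho  # 0.8
#' @export
spearmanTest <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  n <- length(x)
  if (n < 4L) stop("need at least 4 paired observations")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("inputs must be finite")
  rho <- spearmanRho(x, y)
  noTies <- !anyDuplicated(x) && !anyDuplicated(y)
  if (n <= 9L && noTies) {
    p <- spearmanExactP(rho, n)
    method <- "exact"
  } else {
    if (abs(rho) >= 1 - 1e-15) {
      p <- .Machine$double.xmin
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * pt(-abs(tstat), df = n - 2)
      if (p == 0) p <- .Machine$double.xmin
    }
    method <- "t_approx"
  }
  list(rho = rho, pTwoSided = min(p, 1), n = n, method = method)
}

#' Mann-Whitney U test
#'
#' `U = #\{(i, j): x_i > y_j\} + 0.5 * #\{ties\}`. The two-sided p-value is
#' exact — enumeration of all `choose(n1 + n2, n1)` group assignments,
#' rejecting when `|U - n1 n2 / 2|` is at least as large as observed — when
#' `n1 + n2 <= 12` and the pooled data carry no ties; otherwise a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param x,y numeric vectors, each non-empty.
#' @return a [TestResult-class] with the U statistic
#'   (method `"exact"` or `"normal_approx"`).
#' @examples
#' mannWhitneyU(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mannWhitneyU <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be non-empty")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("inputs must be finite")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  pooled <- c(x, y)
  r <- rank(pooled, ties.method = "average")
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  hasTies <- anyDuplicated(pooled) > 0L
  if (n <= 12L && !hasTies) {
    combs <- utils::combn(n, n1)
    Uall <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(Uall - mu) >= abs(U - mu) - 1e-9)
    method <- "exact"
  } else {
    tieTab <- table(pooled)
    tieCorr <- sum(tieTab^3 - tieTab) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tieCorr)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal_approx"
  }
  new("TestResult", statistic = U, pTwoSided = p,
      n1 = n1, n2 = n2, method = method)
}

## Normalize survival input: data.frame with time_days, event, (group).
.checkSurvival <- function(records) {
  if (!is.data.frame(records)) stop("survival records must be a data.frame")
  need <- c("time_days", "event")
  if (!all(need %in% names(records)))
    stop("survival records need columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(records$time_days)) || any(records$time_days <= 0))
    stop("survival times must be positive and finite")
  ev <- records$event
  if (is.numeric(ev) && all(ev %in% c(0, 1))) ev <- ev == 1
  if (!is.logical(ev) || anyNA(ev))
    stop("event indicator must be logical or 0/1")
  records$event <- ev
  records
}

#' Kaplan-Meier product-limit estimate
#'
#' Estimates the survival function of a single group. Subjects censored at
#' an event time remain in the risk set at that time (events precede
#' censorings within a tied time). The median is the first event time at
#' which survival reaches 0.5 or below, `NA` if survival never does.
#'
#' @param records data.frame with columns `time_days` and `event`
#'   (logical or 0/1).
#' @return a [KMCurve-class].
#' @examples
#' km <- kmEstimate(data.frame(time_days = c(5, 10, 15), event = TRUE))
#' medianSurvival(km)  # 10
#' @export
kmEstimate <- function(records) {
  records <- .checkSurvival(records)
  if (nrow(records) == 0L) stop("need at least one record")
  t <- records$time_days; ev <- records$event
  eventTimes <- sort(unique(t[ev]))
  if (length(eventTimes) == 0L) {
    return(new("KMCurve", times = numeric(0), survival = numeric(0),
               atRisk = integer(0), nEvents = integer(0),
               median = NA_real_, n = nrow(records)))
  }
  atRisk <- vapply(eventTimes, function(ti) sum(t >= ti), 0L)
  d <- vapply(eventTimes, function(ti) sum(t == ti & ev), 0L)
  surv <- cumprod(1 - d / atRisk)
  medIdx <- which(surv <= 0.5 + 1e-12)
  med <- if (length(medIdx)) eventTimes[medIdx[1L]] else NA_real_
  new("KMCurve", times = eventTimes, survival = surv,
      atRisk = as.integer(atRisk), nEvents = as.integer(d),
      median = med, n = nrow(records))
}

#' Log-rank (Mantel-Cox) test
#'
#' Compares the survival of exactly two groups. At each distinct event time
#' the observed events in group 1 are compared with their hypergeometric
#' expectation given the pooled risk set; the statistic is
#' `(sum(O - E))^2 / sum(V)` on one degree of freedom.
#'
#' @param records data.frame with columns `time_days`, `event` and `group`
#'   (exactly two levels); at least one event overall.
#' @return a [TestResult-class] with the chi-square statistic
#'   (method `"chi_square"`).
#' @export
logrankTest <- function(records) {
  records <- .checkSurvival(records)
  if (!"group" %in% names(records)) stop("records need a 'group' column")
  grp <- as.character(records$group)
  lev <- sort(unique(grp))
  if (length(lev) != 2L) stop("exactly two groups are required")
  if (!any(records$event)) stop("at least one event is required")
  t <- records$time_days; ev <- records$event; g1 <- grp == lev[1L]
  eventTimes <- sort(unique(t[ev]))
  OmE <- 0; V <- 0; O1 <- 0
  for (ti in eventTimes) {
    atRisk <- t >= ti
    N <- sum(atRisk); N1 <- sum(atRisk & g1)
    d <- sum(t == ti & ev); d1 <- sum(t == ti & ev & g1)
    O1 <- O1 + d1
    OmE <- OmE + d1 - d * N1 / N
    if (N > 1L)
      V <- V + d * (N1 / N) * ((N - N1) / N) * (N - d) / (N - 1)
  }
  chisq <- if (V > 0) OmE^2 / V else 0
  p <- if (V > 0) pchisq(chisq, df = 1, lower.tail = FALSE) else 1
  new("TestResult", statistic = chisq, pTwoSided = p,
      n1 = sum(g1), n2 = sum(!g1), method = "chi_square")
}
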