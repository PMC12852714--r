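# Independent brute-force oracles. These deliberately share no code with
# the package: permutations are generated lexicographically, correlations
# go through stats::cor, U through direct pair counting, and the
# enrichment running sum is evaluated at every list position.

# All permutations of 1:n in lexicographic order (iterative successor).
lexPermutations <- function(n) {
  p <- seq_len(n)
  out <- matrix(NA_integer_, factorial(n), n)
  row <- 1L
  repeat {
    out[row, ] <- p
    i <- n - 1L
    while (i >= 1L && p[i] >= p[i + 1L]) i <- i - 1L
    if (i < 1L) break
    j <- n
    while (p[j] <= p[i]) j <- j - 1L
    tmp <- p[i]; p[i] <- p[j]; p[j] <- tmp
    p[(i + 1L):n] <- rev(p[(i + 1L):n])
    row <- row + 1L
  }
  out
}

# Exact two-sided Spearman permutation p by full enumeration, rho via
# stats::cor on ranks.
oracleSpearmanExactP <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  obs <- stats::cor(rx, ry)
  perms <- lexPermutations(n)
  rhos <- apply(perms, 1L, function(p) stats::cor(rx, ry[p]))
  mean(abs(rhos) >= abs(obs) - 1e-12)
}

# Exact two-sided Mann-Whitney p by enumerating group assignments; U by
# direct pair counting.
oracleMwuExactP <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  uOf <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  mu <- n1 * n2 / 2
  obs <- uOf(x, y)
  combs <- utils::combn(n1 + n2, n1)
  us <- apply(combs, 2L, function(idx) uOf(pooled[idx], pooled[-idx]))
  mean(abs(us - mu) >= abs(obs - mu) - 1e-9)
}

# Brute-force weighted KS enrichment score: evaluate the running sum at
# every position of the ranked list and take the signed maximal deviation.
oracleES <- function(geneIds, metric, setGenes, weightP = 1) {
  hit <- geneIds %in% setGenes
  N <- length(geneIds)
  w <- abs(metric)^weightP
  W <- sum(w[hit])
  inc <- ifelse(hit, if (W > 0) w / W else 1 / sum(hit), -1 / (N - sum(hit)))
  run <- cumsum(inc)
  run[which.max(abs(run))]
}

# Quick labelled expression matrix from a list of gene -> values.
makeExpr <- function(geneValues, groups = NULL) {
  m <- do.call(rbind, geneValues)
  rownames(m) <- names(geneValues)
  colnames(m) <- paste0("s", seq_len(ncol(m)))
  ExprMatrix(m, sampleGroups = groups)
}

# Hand-written decision table derived solely from the printed tier rules:
# strong |r| >= 0.50 & p < 0.05; moderate |r| >= 0.30 & p < 0.05;
# weak |r| >= 0.26 & p < 0.001; otherwise none; sign of r picks the branch.
handTier <- function(rho, p) {
  a <- abs(rho)
  strength <- if (a >= 0.50 && p < 0.05) "strong"
  else if (a >= 0.30 && p < 0.05) "moderate"
  else if (a >= 0.26 && p < 0.001) "weak"
  else "none"
  if (strength == "none") "none"
  else paste0(strength, if (rho >= 0) "_pos" else "_neg")
}
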