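# Independent oracles used across tests. These deliberately reimplement the
# checked quantities with naive loops / enumeration, not via the package.

# brute-force intersection threshold: iterate every candidate and apply the
# tie-break rules (min |sens-spec|, then max sens+spec, then smallest t)
oracleIntersection <- function(score, interacting) {
  u <- sort(unique(score))
  grid <- sort(unique(c(u, (u[-1] + u[-length(u)]) / 2)))
  nPos <- sum(interacting)
  nNeg <- sum(!interacting)
  best <- NULL
  for (t in grid) {
    tp <- sum(score > t & interacting)
    tn <- sum(score <= t & !interacting)
    # compare sens-spec gaps and totals by exact cross-multiplication:
    # sens - spec = (tp*nNeg - tn*nPos) / (nPos*nNeg)
    cand <- c(abs(tp * nNeg - tn * nPos), -(tp * nNeg + tn * nPos), t)
    if (is.null(best)) {
      best <- cand
    } else {
      for (j in 1:3) {
        if (cand[j] < best[j]) { best <- cand; break }
        if (cand[j] > best[j]) break
      }
    }
  }
  best[3]
}

# two-sided Fisher p for a 2x2 table by hypergeometric enumeration
oracleFisherP <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0L, k - n); hi <- min(k, m)
  ks <- lo:hi
  probs <- dhyper(ks, m, n, k)
  pObs <- dhyper(a, m, n, k)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# exact one-sided (greater) rank-sum p by enumerating all label assignments
oracleWilcoxGreater <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  obs <- sum(r[seq_along(x)])
  combos <- combn(length(pooled), length(x))
  stat <- apply(combos, 2L, function(idx) sum(r[idx]))
  mean(stat >= obs - 1e-9)
}

# Gaussian KDE mode by direct evaluation on a dense grid
oracleKdeMode <- function(x, nGrid = 512L) {
  bw <- stats::bw.nrd0(x)
  grid <- seq(min(x), max(x), length.out = nGrid)
  dens <- vapply(grid, function(g) mean(dnorm((g - x) / bw)) / bw,
    numeric(1L))
  grid[which.max(dens)]
}

# tiny well-formed fixtures
makeMfiFixture <- function() {
  data.frame(
    sample_id = c("s1", "s1", "s2"),
    capture_antibody_id = c("capA", "capB", "capA"),
    detection_antibody_id = "det1",
    mfi = c(100, 200, 300),
    stringsAsFactors = FALSE)
}

makeExpressionFixture <- function(genes, contexts, values) {
  grid <- expand.grid(context_id = contexts, gene_id = genes,
    stringsAsFactors = FALSE)[, c("gene_id", "context_id")]
  grid$ntpm <- values
  grid
}
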