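# Independent oracles used to cross-check the implementation. Each is a
# direct transcription of the defining formula or a brute-force enumeration,
# deliberately sharing no code path with the package.

# Hypergeometric upper tail as the exact sum over the support, with plain
# binomial coefficients (the draw enumeration grouped by overlap count).
oracleHypergeomSum <- function(M, x, n, y) {
  ks <- y:min(n, x)
  sum(choose(x, ks) * choose(M - x, n - ks)) / choose(M, n)
}

# Literal enumeration of all C(M, n) draws (tiny M only).
oracleHypergeomEnum <- function(M, x, n, y) {
  if (n == 0) return(as.numeric(y == 0))
  draws <- utils::combn(M, n)
  mean(apply(draws, 2L, function(d) sum(d <= x) >= y))
}

# Average (fractional) ranks by counting, then the Pearson formula.
oracleSpearman <- function(x, y) {
  avgRank <- function(v) vapply(v, function(vi)
    sum(v < vi) + (sum(v == vi) + 1) / 2, 0)
  a <- avgRank(x)
  b <- avgRank(y)
  da <- a - mean(a)
  db <- b - mean(b)
  sum(da * db) / sqrt(sum(da^2) * sum(db^2))
}

# Benjamini-Hochberg step-up from the definition: sort ascending,
# q_(i) = min_{j >= i} p_(j) * m / j capped at 1, map back.
oracleBH <- function(p, m = length(p)) {
  o <- order(p)
  ps <- p[o]
  k <- length(p)
  q <- numeric(k)
  for (i in seq_len(k))
    q[i] <- min(1, min(ps[i:k] * m / (i:k)))
  out <- numeric(k)
  out[o] <- q
  out
}

# Tie-corrected Mann-Whitney AUC: fraction of (positive, negative) pairs
# with the positive ranked strictly better (smaller), ties counting 1/2.
oracleMannWhitneyAuc <- function(posRanks, negRanks) {
  tot <- 0
  for (p in posRanks)
    tot <- tot + sum(p < negRanks) + 0.5 * sum(p == negRanks)
  tot / (length(posRanks) * length(negRanks))
}

# Tiny well-formed expression TSV on disk; returns the path.
writeExprFixture <- function(values, path = tempfile(fileext = ".tsv"),
                             idCol = "entity_id") {
  df <- data.frame(id = rownames(values), values, check.names = FALSE)
  colnames(df)[1L] <- idCol
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Small deterministic expression matrix for network tests.
randomExprMatrix <- function(nEntities, conds, prefix = "e") {
  m <- matrix(round(runif(nEntities * length(conds), 0, 1000)),
              nEntities, length(conds),
              dimnames = list(sprintf("%s%02d", prefix, seq_len(nEntities)),
                              conds))
  ExpressionMatrix(m)
}
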