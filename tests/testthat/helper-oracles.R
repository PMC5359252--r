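# Independent oracles: exhaustive searches and closed-form formulas that the
# package's algorithms are checked against. Deliberately brute-force and
# free of any package internals.

# Centered-sum score of a node subset (clique scoring: all within pairs).
oracleCliqueScore <- function(W, s, lambda) {
  m <- length(s)
  sum(W[s, s][upper.tri(matrix(0, m, m))]) - lambda * m * (m - 1) / 2
}

# Exhaustive best subset of size >= minSize (returns score 0 / NULL nodes
# when nothing positive exists).
oracleBestSubset <- function(W, lambda, minSize = 3L) {
  n <- nrow(W)
  best <- list(score = 0, nodes = NULL)
  for (sz in minSize:n) {
    for (s in combn(n, sz, simplify = FALSE)) {
      sc <- oracleCliqueScore(W, s, lambda)
      if (sc > best$score + 1e-12) best <- list(score = sc, nodes = s)
    }
  }
  best
}

# All partitions of n items into exactly k nonempty sets, as label vectors
# (restricted growth strings).
oraclePartitions <- function(n, k) {
  out <- list()
  rec <- function(lab, maxUsed) {
    i <- length(lab) + 1L
    if (i > n) {
      if (maxUsed == k) out[[length(out) + 1L]] <<- lab
      return(invisible())
    }
    for (c in seq_len(min(maxUsed + 1L, k))) rec(c(lab, c), max(maxUsed, c))
  }
  rec(integer(0), 0L)
  out
}

# Between-set centered score of a labeling.
oraclePartitionScore <- function(W, lab, lambda) {
  n <- length(lab)
  s <- 0
  for (j in 2:n) for (i in 1:(j - 1))
    if (lab[i] != lab[j]) s <- s + W[i, j] - lambda
  s
}

# Exhaustive best partition over k = 2..kMax.
oracleBestPartition <- function(W, lambda, kMax = 3L) {
  n <- nrow(W)
  best <- list(score = -Inf, lab = NULL, k = NA_integer_)
  for (k in 2:min(kMax, n - 1L)) {
    for (lab in oraclePartitions(n, k)) {
      sc <- oraclePartitionScore(W, lab, lambda)
      if (sc > best$score + 1e-12) best <- list(score = sc, lab = lab, k = k)
    }
  }
  best
}

# Two-pass covariance Pearson correlation (independent of stats::cor).
oraclePearson <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Textbook pooled-variance two-sample t.
oraclePooledT <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * pt(-abs(t), na + nb - 2))
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# Plain Rand index between two labelings of the same items.
randIndex <- function(a, b) {
  n <- length(a)
  agree <- 0L
  for (j in 2:n) for (i in 1:(j - 1))
    agree <- agree + ((a[i] == a[j]) == (b[i] == b[j]))
  agree / (n * (n - 1) / 2)
}
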