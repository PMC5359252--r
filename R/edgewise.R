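# Edgewise two-sample tests and the weighted evidence graph.

# Vectorized two-sample t over the rows of an edges x subjects matrix.
# E2 = E * E is passed in so the permutation loop can reuse it.
# Returns t oriented as mean(A) - mean(B), the two-sided p, and the df.
.edgeStatsCore <- function(E, E2, isA, pooled = TRUE) {
  nA <- sum(isA)
  nB <- length(isA) - nA
  ind <- as.numeric(isA)
  # separate products (not total minus A) so that identical group columns
  # give an exactly zero mean difference
  sA <- E %*% ind
  sB <- E %*% (1 - ind)
  mA <- sA / nA
  mB <- sB / nB
  qA <- E2 %*% ind
  qB <- E2 %*% (1 - ind)
  vA <- (qA - nA * mA^2) / (nA - 1)
  vB <- (qB - nB * mB^2) / (nB - 1)
  vA <- pmax(vA, 0)  # guard against tiny negative round-off
  vB <- pmax(vB, 0)
  if (pooled) {
    sp2 <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
    se <- sqrt(sp2 * (1 / nA + 1 / nB))
    df <- rep(nA + nB - 2, length(se))
  } else {
    u <- vA / nA
    v <- vB / nB
    se <- sqrt(u + v)
    df <- (u + v)^2 / (u^2 / (nA - 1) + v^2 / (nB - 1))
  }
  d <- mA - mB
  t <- ifelse(se == 0 & d == 0, 0, d / se)
  p <- 2 * pt(-abs(t), df)
  p[t == 0] <- 1
  list(t = as.numeric(t), p = as.numeric(p), se = as.numeric(se),
       diff = as.numeric(d), df = df)
}

#' Per-edge two-sample tests between groups
#'
#' Performs a two-sample t test on every unordered node pair, comparing the
#' subjects' Fisher-Z values between the two groups, and assembles the
#' weighted evidence graph with `W_ij = -log(p_ij)`. The default is the
#' pooled-variance Student t (`varEqual = TRUE`); set `varEqual = FALSE`
#' for the Welch variant. The log base defaults to the natural log; only
#' the relative ordering of weights matters downstream and the permutation
#' test is invariant to any strictly monotone transform of W.
#'
#' p-values are clipped below at the smallest positive representable double
#' before the log so that W is always finite.
#'
#' @param sample a [ConnectomeSample-class] with >= 2 subjects per group
#' @param varEqual pooled-variance Student t (TRUE, default) or Welch
#' @param logBase base of the logarithm in W (default `exp(1)`; use 10 for
#'   log10 weights)
#' @return an [EdgeEvidence-class]
#' @examples
#' out <- simulateConnectomes(generatorConfig(
#'   nNodes = 10, nSubjectsA = 6, nSubjectsB = 6, seed = 1))
#' ev <- edgewiseTests(out$sample)
#' head(edgeStats(ev))
#' @export
edgewiseTests <- function(sample, varEqual = TRUE, logBase = exp(1)) {
  g <- subjectGroups(sample)
  sizes <- table(g)
  if (any(sizes < 2L))
    stop("both groups need at least 2 subjects")
  E <- SummarizedExperiment::assay(sample, "z")
  isA <- g == levels(g)[1L]
  st <- .edgeStatsCore(E, E * E, isA, pooled = varEqual)
  n <- nNodes(sample)
  ep <- .edgePairs(n)
  # se == 0 can only happen when the within-group variance vanishes in both
  # groups, which the test's preconditions exclude
  degenerate <- which(st$se == 0)
  if (length(degenerate)) {
    e <- ep[degenerate[1L], ]
    stop(sprintf("zero within-group variance in both groups at edge (%d, %d)",
                 e[1L], e[2L]))
  }
  p <- pmax(st$p, .Machine$double.xmin)
  nClipped <- sum(st$p < .Machine$double.xmin)
  if (nClipped > 0)
    message(sprintf("%d p-value(s) clipped at %.3g before taking the log",
                    nClipped, .Machine$double.xmin))
  stats <- data.frame(
    i = ep[, "i"], j = ep[, "j"],
    t = st$t, p = p,
    sign = sign(st$t),
    W = -log(p) / log(logBase)
  )
  new("EdgeEvidence",
    stats = stats,
    nNodes = as.integer(n),
    nodeTable = nodeTable(sample),
    groupLevels = levels(g),
    groupSizes = as.integer(sizes[levels(g)]),
    logBase = logBase,
    pooled = varEqual
  )
}

#' @describeIn edgeStats per-edge statistics of an evidence object
#' @export
setMethod("edgeStats", "EdgeEvidence", function(x) x@stats)

#' @describeIn nodeTable node table of an evidence object
#' @export
setMethod("nodeTable", "EdgeEvidence", function(x) x@nodeTable)

#' @describeIn nNodes number of nodes of an evidence object
#' @export
setMethod("nNodes", "EdgeEvidence", function(x) x@nNodes)

#' @describeIn weightMatrix dense symmetric weight matrix of the evidence
#'   graph
#' @export
setMethod("weightMatrix", "EdgeEvidence", function(x)
  .vecToSym(x@stats$W, x@nNodes))

setMethod("show", "EdgeEvidence", function(object) {
  cat(sprintf(
    "EdgeEvidence: %d edges over %d nodes (%s vs %s, n = %d + %d, %s t)\n",
    nrow(object@stats), object@nNodes,
    object@groupLevels[1L], object@groupLevels[2L],
    object@groupSizes[1L], object@groupSizes[2L],
    if (object@pooled) "pooled" else "Welch"))
  cat(sprintf("  W = -log(p), base %s; max W = %.3g\n",
              format(object@logBase, digits = 4), max(object@stats$W)))
})

#' Write edge evidence to disk
#'
#' Serializes the evidence as an edge-list CSV (`i, j, index_i, index_j, t,
#' p, sign, W`) and as a dense matrix file of W for heatmaps.
#'
#' @param evidence an [EdgeEvidence-class]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
writeEdgeEvidence <- function(evidence, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  st <- edgeStats(evidence)
  nt <- nodeTable(evidence)
  out <- data.frame(i = st$i, j = st$j,
                    index_i = nt$index[st$i], index_j = nt$index[st$j],
                    t = st$t, p = st$p, sign = st$sign, W = st$W)
  write.csv(out, file.path(dir, "edge_evidence.csv"),
            row.names = FALSE, quote = FALSE)
  W <- weightMatrix(evidence)
  write.table(format(W, digits = 17, scientific = TRUE, trim = TRUE),
              file.path(dir, "weight_matrix.txt"),
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(dir)
}
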