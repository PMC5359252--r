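# Network-level significance by max-statistic permutation of subject group
# labels. Re-running the FULL detection pipeline inside every permutation is
# what controls selection bias: each observed network's score is compared
# against the distribution of the best score the same search finds on
# label-permuted data, which bounds the family-wise error over the
# combinatorially many candidate subgraphs.

#' Max-statistic permutation test for detected networks
#'
#' For each of B permutations, subject group labels are permuted (group
#' sizes preserved), the edgewise tests and the full detection pipeline are
#' recomputed with identical configuration, and the maximum detected
#' network score is recorded (0 when nothing is detected). Each observed
#' network then receives the add-one estimator
#' `p = (1 + #\{b : max_b >= score\}) / (B + 1)`,
#' which is a valid (never zero) permutation p-value. Observed networks are
#' compared against the permutation maxima regardless of their own rank.
#' Deterministic given (sample, networks, config, B, seed).
#'
#' @param sample the [ConnectomeSample-class] the networks were detected
#'   from
#' @param networks list of [DetectedNetwork-class] from [detectAll()] on
#'   the unpermuted sample (may be empty; the null distribution is still
#'   computed)
#' @param config the [DetectionConfig-class] used for detection
#' @param B number of permutations (>= 19; 999 is a sensible default for
#'   real analyses, 99 for quick calibration runs)
#' @param seed RNG seed
#' @param alpha significance level (default 0.05)
#' @param varEqual,logBase passed through to the edgewise tests; must match
#'   the evidence the observed networks came from
#' @return an [InferenceResult-class]
#' @examples
#' out <- simulateConnectomes(generatorConfig(
#'   nNodes = 20, nSubjectsA = 12, nSubjectsB = 12,
#'   planted = list(plantedClique(1:5, 1)), seed = 3))
#' W <- weightMatrix(edgewiseTests(out$sample))
#' nets <- detectAll(W)
#' res <- permutationTest(out$sample, nets, B = 49, seed = 3)
#' summarizeInference(res)
#' @export
permutationTest <- function(sample, networks, config = detectionConfig(),
                            B = 999L, seed = 1L, alpha = 0.05,
                            varEqual = TRUE, logBase = exp(1)) {
  B <- as.integer(B)
  if (B < 19L)
    stop("B must be >= 19 to resolve alpha = 0.05")
  g <- subjectGroups(sample)
  E <- SummarizedExperiment::assay(sample, "z")
  E2 <- E * E
  n <- nNodes(sample)
  ut <- upper.tri(matrix(0, n, n))
  refLevel <- levels(g)[1L]
  logDen <- log(logBase)
  maxs <- numeric(B)
  .withSeed(seed, {
    permSeeds <- sample.int(2147483646L, B)
    for (b in seq_len(B)) {
      set.seed(permSeeds[b])
      isA <- (g[sample.int(length(g))] == refLevel)
      st <- .edgeStatsCore(E, E2, isA, pooled = varEqual)
      Wv <- -log(pmax(st$p, .Machine$double.xmin)) / logDen
      Wm <- matrix(0, n, n)
      Wm[ut] <- Wv
      Wm <- Wm + t(Wm)
      nets <- .detectAllCore(Wm, config)
      maxs[b] <- if (length(nets))
        max(0, vapply(nets, `[[`, numeric(1L), "score")) else 0
    }
  })
  nullDist <- new("NullDistribution", maxScores = maxs, B = B,
                  seed = as.integer(seed))
  networks <- lapply(networks, function(net) {
    net@pValue <- (1 + sum(maxs >= networkScore(net))) / (B + 1)
    net
  })
  new("InferenceResult", networks = networks, alpha = alpha,
      nullDist = nullDist)
}

#' Summarize an inference result
#'
#' One row per network: rank, size, topology, score, permutation p-value
#' and the significance flag at the result's alpha.
#'
#' @param result an [InferenceResult-class]
#' @return data.frame (zero rows when no networks were detected)
#' @export
summarizeInference <- function(result) {
  nets <- result@networks
  data.frame(
    rank = seq_along(nets),
    size = vapply(nets, function(x) length(networkNodes(x)), integer(1L)),
    topology = vapply(nets, networkTopology, character(1L)),
    score = vapply(nets, networkScore, numeric(1L)),
    p_value = vapply(nets, networkPValue, numeric(1L)),
    significant = vapply(nets, function(x)
      networkPValue(x) < result@alpha, logical(1L))
  )
}

#' Write the permutation null distribution for audit
#'
#' One max score per line, plain text.
#'
#' @param nullDist a [NullDistribution-class] or [InferenceResult-class]
#' @param path output path
#' @export
writeNullDistribution <- function(nullDist, path) {
  if (is(nullDist, "InferenceResult")) nullDist <- nullDist@nullDist
  writeLines(format(nullDist@maxScores, digits = 17, trim = TRUE), path)
  invisible(path)
}

#' @describeIn maxScores permutation maxima of a null distribution
#' @export
setMethod("maxScores", "NullDistribution", function(x) x@maxScores)

#' @describeIn maxScores permutation maxima underlying an inference result
#' @export
setMethod("maxScores", "InferenceResult", function(x) x@nullDist@maxScores)

#' @describeIn resultNetworks networks with p-values filled
#' @export
setMethod("resultNetworks", "InferenceResult", function(x) x@networks)

setMethod("show", "NullDistribution", function(object) {
  cat(sprintf(
    "NullDistribution: B = %d permutation maxima (median %.3g, max %.3g)\n",
    object@B, stats::median(object@maxScores), max(object@maxScores)))
})

setMethod("show", "InferenceResult", function(object) {
  cat(sprintf("InferenceResult: %d network(s), alpha = %g, B = %d\n",
              length(object@networks), object@alpha, object@nullDist@B))
  if (length(object@networks)) print(summarizeInference(object))
})
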