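# S4 class definitions. Validity functions enforce the structural invariants
# the downstream statistics rely on (symmetry, disjointness, two groups).

#' PlantedNetwork: a differential subnetwork to embed in synthetic data
#'
#' Describes one ground-truth abnormal network for the synthetic generator:
#' a node set with either clique topology (every within-set edge is shifted
#' between groups) or k-partite topology (only between-set edges are
#' shifted). The shift `delta` is on the Fisher-Z scale and applies to the
#' second (case-like) group; `delta < 0` therefore means hypoconnectivity in
#' the case group relative to the reference group.
#'
#' @slot nodes integer vector of node ids (1-based positions in the node
#'   table).
#' @slot topology `"clique"` or `"k_partite"`.
#' @slot partition for k-partite topology, a list of disjoint integer
#'   vectors covering `nodes`; empty list for cliques.
#' @slot delta signed Fisher-Z group mean shift applied to affected edges.
#' @slot signPattern `"uniform_hyper"`, `"uniform_hypo"` or `"mixed"`.
#' @slot signs for `"mixed"`, a numeric vector of +1/-1 named by edge key
#'   `"i-j"` (i < j) giving the per-edge sign of the shift; empty otherwise.
#'
#' @seealso [plantedClique()], [plantedPartite()]
#' @exportClass PlantedNetwork
setClass("PlantedNetwork",
  representation(
    nodes = "integer",
    topology = "character",
    partition = "list",
    delta = "numeric",
    signPattern = "character",
    signs = "numeric"
  )
)

setValidity("PlantedNetwork", function(object) {
  msg <- character()
  if (!object@topology %in% c("clique", "k_partite"))
    msg <- c(msg, "topology must be 'clique' or 'k_partite'")
  if (anyDuplicated(object@nodes))
    msg <- c(msg, "nodes must be distinct")
  if (length(object@delta) != 1L || !is.finite(object@delta) ||
      object@delta == 0)
    msg <- c(msg, "delta must be a single nonzero finite number")
  if (object@topology == "clique") {
    if (length(object@nodes) < 2L)
      msg <- c(msg, "a planted clique needs at least 2 nodes")
  } else {
    p <- object@partition
    if (length(p) < 2L)
      msg <- c(msg, "a k-partite network needs at least 2 sets")
    if (any(lengths(p) == 0L))
      msg <- c(msg, "k-partite sets must be nonempty")
    u <- unlist(p)
    if (anyDuplicated(u) || !setequal(u, object@nodes))
      msg <- c(msg, "partition sets must be disjoint and cover nodes")
  }
  if (!object@signPattern %in% c("uniform_hyper", "uniform_hypo", "mixed"))
    msg <- c(msg, "invalid signPattern")
  if (object@signPattern == "mixed" && length(object@signs) == 0L)
    msg <- c(msg, "mixed sign pattern requires an explicit per-edge sign map")
  if (length(msg)) msg else TRUE
})

#' GeneratorConfig: study conditions for the synthetic connectome generator
#'
#' Holds the group structure, Fisher-Z noise model and planted differential
#' networks that [simulateConnectomes()] and [simulateTimeSeries()] emulate.
#' Defaults mirror a two-site clinical comparison: 90 atlas nodes, 48 + 65
#' subjects, baseline edge mean 0.3 and subject-level edge noise 0.3 on the
#' Fisher-Z scale.
#'
#' @slot nNodes number of nodes (>= 3).
#' @slot nSubjectsA,nSubjectsB group sizes (>= 2). Group A is the reference
#'   (control-like) group; planted deltas shift group B.
#' @slot baselineMean common edge mean mu0 (Fisher-Z units).
#' @slot subjectSD per-edge subject-level noise sigma (> 0, Fisher-Z units).
#' @slot planted list of [PlantedNetwork-class] objects with pairwise
#'   disjoint node sets.
#' @slot groupLabels length-2 character: labels of groups A and B.
#' @slot seed integer RNG seed.
#' @seealso [generatorConfig()]
#' @exportClass GeneratorConfig
setClass("GeneratorConfig",
  representation(
    nNodes = "integer",
    nSubjectsA = "integer",
    nSubjectsB = "integer",
    baselineMean = "numeric",
    subjectSD = "numeric",
    planted = "list",
    groupLabels = "character",
    seed = "integer"
  )
)

setValidity("GeneratorConfig", function(object) {
  msg <- character()
  if (object@nNodes < 3L) msg <- c(msg, "nNodes must be >= 3")
  if (object@nSubjectsA < 2L || object@nSubjectsB < 2L)
    msg <- c(msg, "both group sizes must be >= 2")
  if (!is.finite(object@subjectSD) || object@subjectSD <= 0)
    msg <- c(msg, "subjectSD must be > 0")
  if (length(object@groupLabels) != 2L ||
      anyDuplicated(object@groupLabels))
    msg <- c(msg, "groupLabels must be two distinct labels")
  for (pn in object@planted) {
    if (!is(pn, "PlantedNetwork"))
      msg <- c(msg, "planted must contain PlantedNetwork objects")
    else if (any(pn@nodes < 1L | pn@nodes > object@nNodes))
      msg <- c(msg, "planted nodes out of range 1..nNodes")
  }
  allNodes <- unlist(lapply(object@planted, function(p) p@nodes))
  if (anyDuplicated(allNodes))
    msg <- c(msg, "planted node sets must be pairwise disjoint")
  if (length(msg)) msg else TRUE
})

#' GroundTruth: planted structure emitted alongside a synthetic sample
#'
#' @slot planted the list of [PlantedNetwork-class] objects actually planted.
#' @slot deltaMatrix n x n matrix of true per-edge group mean differences
#'   (group B minus group A) on the Fisher-Z scale.
#' @slot nNodes number of nodes.
#' @seealso [affectedEdges()], [trueDeltaMatrix()]
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(
    planted = "list",
    deltaMatrix = "matrix",
    nNodes = "integer"
  )
)

#' ConnectomeSample: two labeled groups of Fisher-Z connectivity matrices
#'
#' Extends [SummarizedExperiment::SummarizedExperiment]. The `"z"` assay
#' stores each subject's upper-triangle Fisher-Z values as one column
#' (n(n-1)/2 edges x subjects); `rowData` carries the node pair (i, j) of
#' each edge and `colData` the subject id and group label. The node table
#' (region name, abbreviation, atlas index, MNI coordinates) lives in
#' `metadata(x)$nodeTable` and its row order defines matrix row/column
#' order.
#'
#' @seealso [ConnectomeSample()] constructor, [subjectMatrix()],
#'   [nodeTable()], [subjectGroups()]
#' @exportClass ConnectomeSample
setClass("ConnectomeSample", contains = "SummarizedExperiment")

setValidity("ConnectomeSample", function(object) {
  msg <- character()
  if (!"z" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'z' missing")
  nt <- S4Vectors::metadata(object)$nodeTable
  if (is.null(nt)) {
    msg <- c(msg, "metadata nodeTable missing")
  } else {
    n <- nrow(nt)
    if (!all(c("name", "abbrev", "index", "x", "y", "z") %in% names(nt)))
      msg <- c(msg, "nodeTable must have columns name, abbrev, index, x, y, z")
    else if (anyDuplicated(nt$index))
      msg <- c(msg, "nodeTable atlas indices must be unique")
    if (nrow(object) != n * (n - 1L) / 2L)
      msg <- c(msg, "edge count does not match node table")
  }
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("subject_id", "group") %in% names(cd))) {
    msg <- c(msg, "colData must have subject_id and group")
  } else {
    g <- cd$group
    if (!is.factor(g) || nlevels(g) != 2L || !all(levels(g) %in% g))
      msg <- c(msg, "exactly two group labels must be present")
    if (anyDuplicated(cd$subject_id))
      msg <- c(msg, "subject ids must be unique")
  }
  a <- SummarizedExperiment::assay(object, "z")
  if (!all(is.finite(a)))
    msg <- c(msg, "non-finite Fisher-Z values present")
  if (length(msg)) msg else TRUE
})

#' EdgeEvidence: per-edge group-difference statistics and weights
#'
#' For each unordered node pair (i, j), i < j: the two-sample t statistic,
#' its two-sided p-value, the sign of mean(group A) - mean(group B), and the
#' nonnegative weight W = -log(p) that forms the weighted evidence graph for
#' network detection.
#'
#' @slot stats data.frame with columns `i`, `j`, `t`, `p`, `sign`, `W`.
#' @slot nNodes number of nodes n (edges = n(n-1)/2).
#' @slot nodeTable the node table of the originating sample.
#' @slot groupLevels length-2 character, reference group first.
#' @slot groupSizes integer counts per group, same order.
#' @slot logBase base of the logarithm in W (natural log by default).
#' @slot pooled TRUE for pooled-variance Student t, FALSE for Welch.
#' @seealso [edgewiseTests()], [weightMatrix()]
#' @exportClass EdgeEvidence
setClass("EdgeEvidence",
  representation(
    stats = "data.frame",
    nNodes = "integer",
    nodeTable = "data.frame",
    groupLevels = "character",
    groupSizes = "integer",
    logBase = "numeric",
    pooled = "logical"
  )
)

setValidity("EdgeEvidence", function(object) {
  msg <- character()
  n <- object@nNodes
  if (nrow(object@stats) != n * (n - 1L) / 2L)
    msg <- c(msg, "stats must have one row per unordered node pair")
  if (any(object@stats$W < 0)) msg <- c(msg, "weights must be nonnegative")
  if (any(object@stats$p <= 0 | object@stats$p > 1))
    msg <- c(msg, "p-values must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' DetectedNetwork: a candidate differential subnetwork
#'
#' @slot nodes integer node ids (sorted).
#' @slot topology `"clique"` or `"k_partite"`.
#' @slot partition for k-partite networks, the list of disjoint node sets;
#'   empty for cliques.
#' @slot score network test statistic: the sum of centered weights
#'   `W_e - lambda` over the scoring edges.
#' @slot scoringEdges 2-column integer matrix of the edges entering the
#'   score: all within-node pairs for a clique, all between-set pairs for a
#'   k-partite network.
#' @slot pValue network-level permutation p-value (NA until filled by
#'   [permutationTest()]).
#' @seealso [detectAll()], [scoreSubgraph()]
#' @exportClass DetectedNetwork
setClass("DetectedNetwork",
  representation(
    nodes = "integer",
    topology = "character",
    partition = "list",
    score = "numeric",
    scoringEdges = "matrix",
    pValue = "numeric"
  )
)

setValidity("DetectedNetwork", function(object) {
  msg <- character()
  if (!object@topology %in% c("clique", "k_partite"))
    msg <- c(msg, "topology must be 'clique' or 'k_partite'")
  if (object@topology == "k_partite") {
    u <- unlist(object@partition)
    if (length(object@partition) < 2L || anyDuplicated(u) ||
        !setequal(u, object@nodes))
      msg <- c(msg, "partition must be >= 2 disjoint sets covering nodes")
  }
  if (nrow(object@scoringEdges) == 0L)
    msg <- c(msg, "scoring edge set must be nonempty")
  if (length(msg)) msg else TRUE
})

#' DetectionConfig: tuning parameters for network detection
#'
#' @slot minSize smallest reportable network (default 3, the smallest
#'   nontrivial clique).
#' @slot maxNetworks maximum number of node-disjoint networks to extract.
#' @slot lambdaMode `"global_mean"` (lambda = mean(W) + lambdaGamma * sd(W)
#'   over all edges) or `"fixed"` (use `lambdaValue`).
#' @slot lambdaValue the fixed lambda when `lambdaMode = "fixed"`.
#' @slot lambdaGamma dispersion margin multiplier in `"global_mean"` mode;
#'   0 recovers the plain global mean.
#' @slot kMax largest number of parts tried by k-partite detection.
#' @slot nRestarts number of restarts (seed edges for clique growth, random
#'   initial labelings for k-partite relabeling).
#' @slot seed RNG seed used by the exported detection entry points.
#' @seealso [detectionConfig()]
#' @exportClass DetectionConfig
setClass("DetectionConfig",
  representation(
    minSize = "integer",
    maxNetworks = "integer",
    lambdaMode = "character",
    lambdaValue = "numeric",
    lambdaGamma = "numeric",
    kMax = "integer",
    nRestarts = "integer",
    seed = "integer"
  )
)

setValidity("DetectionConfig", function(object) {
  msg <- character()
  if (object@minSize < 3L) msg <- c(msg, "minSize must be >= 3")
  if (object@kMax < 2L) msg <- c(msg, "kMax must be >= 2")
  if (object@nRestarts < 1L) msg <- c(msg, "nRestarts must be >= 1")
  if (!object@lambdaMode %in% c("global_mean", "fixed"))
    msg <- c(msg, "lambdaMode must be 'global_mean' or 'fixed'")
  if (object@lambdaMode == "fixed" && !is.finite(object@lambdaValue))
    msg <- c(msg, "fixed lambdaMode requires a finite lambdaValue")
  if (length(msg)) msg else TRUE
})

#' NullDistribution: per-permutation maxima of the network score
#'
#' @slot maxScores numeric vector of length B: the best detected network's
#'   score in each permutation (0 when nothing was detected).
#' @slot B number of permutations.
#' @slot seed RNG seed used.
#' @exportClass NullDistribution
setClass("NullDistribution",
  representation(maxScores = "numeric", B = "integer", seed = "integer")
)

setValidity("NullDistribution", function(object) {
  msg <- character()
  if (length(object@maxScores) != object@B)
    msg <- c(msg, "maxScores must have length B")
  if (any(object@maxScores < 0))
    msg <- c(msg, "max scores must be >= 0 (0-if-none convention)")
  if (length(msg)) msg else TRUE
})

#' InferenceResult: networks with permutation p-values
#'
#' @slot networks list of [DetectedNetwork-class] with `pValue` filled.
#' @slot alpha significance level (default 0.05).
#' @slot nullDist the [NullDistribution-class] used.
#' @seealso [permutationTest()], [summarizeInference()]
#' @exportClass InferenceResult
setClass("InferenceResult",
  representation(
    networks = "list",
    alpha = "numeric",
    nullDist = "NullDistribution"
  )
)

#' ClassificationReport: LOOCV validation of detected-network features
#'
#' @slot featureEdges 2-column integer matrix of edges used as features.
#' @slot kernel `"radial"` or `"linear"`.
#' @slot nCorrect correctly classified subjects.
#' @slot nTotal total subjects (accuracy = nCorrect / nTotal).
#' @slot accuracy pooled leave-one-out accuracy.
#' @slot details list with per-subject predictions and classifier settings.
#' @seealso [classifyLOOCV()]
#' @exportClass ClassificationReport
setClass("ClassificationReport",
  representation(
    featureEdges = "matrix",
    kernel = "character",
    nCorrect = "integer",
    nTotal = "integer",
    accuracy = "numeric",
    details = "list"
  )
)
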