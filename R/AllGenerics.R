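# Generics for accessor functions (slot access is internal only).

#' Node table of an object
#' @param x a [ConnectomeSample-class] or [EdgeEvidence-class]
#' @return data.frame with columns `name`, `abbrev`, `index`, `x`, `y`, `z`
#' @export
setGeneric("nodeTable", function(x) standardGeneric("nodeTable"))

#' Subject group labels
#' @param x a [ConnectomeSample-class]
#' @return factor with two levels; the first level is the reference group
#' @export
setGeneric("subjectGroups", function(x) standardGeneric("subjectGroups"))

#' Subject identifiers
#' @param x a [ConnectomeSample-class]
#' @return character vector of subject ids
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' Number of nodes
#' @param x an object with a node dimension
#' @return integer
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' Reconstruct one subject's symmetric Fisher-Z matrix
#' @param x a [ConnectomeSample-class]
#' @param subject subject id (character) or column position (integer)
#' @return symmetric n x n matrix with zero diagonal
#' @export
setGeneric("subjectMatrix", function(x, subject)
  standardGeneric("subjectMatrix"))

#' Per-edge statistics table
#' @param x an [EdgeEvidence-class]
#' @return data.frame with columns `i`, `j`, `t`, `p`, `sign`, `W`
#' @export
setGeneric("edgeStats", function(x) standardGeneric("edgeStats"))

#' Symmetric weighted adjacency matrix of edge evidence
#'
#' Entry (i, j) is `W_ij = -log(p_ij)`; the diagonal is 0. This matrix is
#' the input to network detection.
#' @param x an [EdgeEvidence-class]
#' @return symmetric n x n numeric matrix
#' @export
setGeneric("weightMatrix", function(x) standardGeneric("weightMatrix"))

#' Edges affected by a planted network
#'
#' For clique topology, all node pairs within the planted set; for k-partite
#' topology, exactly the between-set pairs (within-set pairs carry no group
#' shift).
#' @param x a [PlantedNetwork-class] or [GroundTruth-class]
#' @return 2-column integer matrix (i < j), one row per affected edge
#' @export
setGeneric("affectedEdges", function(x) standardGeneric("affectedEdges"))

#' True per-edge group mean difference of a synthetic sample
#' @param x a [GroundTruth-class]
#' @return n x n matrix of group B minus group A Fisher-Z means
#' @export
setGeneric("trueDeltaMatrix", function(x) standardGeneric("trueDeltaMatrix"))

#' Nodes of a detected network
#' @param x a [DetectedNetwork-class]
#' @return sorted integer vector of node ids
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' Topology of a detected network
#' @param x a [DetectedNetwork-class]
#' @return `"clique"` or `"k_partite"`
#' @export
setGeneric("networkTopology", function(x) standardGeneric("networkTopology"))

#' Partition of a k-partite detected network
#' @param x a [DetectedNetwork-class]
#' @return list of disjoint integer node sets (empty for cliques)
#' @export
setGeneric("networkPartition", function(x) standardGeneric("networkPartition"))

#' Score of a detected network
#' @param x a [DetectedNetwork-class]
#' @return numeric network test statistic
#' @export
setGeneric("networkScore", function(x) standardGeneric("networkScore"))

#' Permutation p-value of a detected network
#' @param x a [DetectedNetwork-class]
#' @return numeric p-value (NA before [permutationTest()])
#' @export
setGeneric("networkPValue", function(x) standardGeneric("networkPValue"))

#' Scoring edges of a detected network
#' @param x a [DetectedNetwork-class]
#' @return 2-column integer matrix of the edges entering the score
#' @export
setGeneric("scoringEdges", function(x) standardGeneric("scoringEdges"))

#' Per-permutation maximum network scores
#' @param x a [NullDistribution-class] or [InferenceResult-class]
#' @return numeric vector of length B
#' @export
setGeneric("maxScores", function(x) standardGeneric("maxScores"))

#' Networks held by an inference result
#' @param x an [InferenceResult-class]
#' @return list of [DetectedNetwork-class] with p-values filled
#' @export
setGeneric("resultNetworks", function(x) standardGeneric("resultNetworks"))
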