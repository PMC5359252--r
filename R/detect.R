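# Latent network detection on the weighted evidence graph.
#
# The network test statistic is the centered-sum score
#   score(S) = sum_{e in scoring edges} (W_e - lambda),
# so a subgraph of average edges scores about 0 and enrichment scores > 0.
# Scoring edges are all within-set pairs for clique topology and all
# between-set pairs for k-partite topology.

#' Detection configuration
#'
#' @param minSize smallest reportable network size (default 3, the smallest
#'   nontrivial clique)
#' @param maxNetworks maximum number of node-disjoint networks to extract
#' @param lambdaMode `"global_mean"` (default) or `"fixed"`
#' @param lambdaValue lambda for `"fixed"` mode
#' @param lambdaGamma in `"global_mean"` mode, lambda = mean(W) +
#'   lambdaGamma * sd(W) over all edges. The default margin (1) keeps the
#'   optimizer parsimonious: with a plain mean the extremes of the null
#'   weight distribution make weak background nodes look like improvements
#'   and candidate networks absorb them. Set `lambdaGamma = 0` for the
#'   plain global-mean centering.
#' @param kMax largest k tried by k-partite detection (default 3)
#' @param nRestarts restarts for both local searches (default 20)
#' @param seed RNG seed used by exported detection entry points
#' @return a [DetectionConfig-class]
#' @export
detectionConfig <- function(minSize = 3L, maxNetworks = 10L,
                            lambdaMode = c("global_mean", "fixed"),
                            lambdaValue = NA_real_, lambdaGamma = 1,
                            kMax = 3L, nRestarts = 20L, seed = 1L) {
  new("DetectionConfig",
    minSize = as.integer(minSize),
    maxNetworks = as.integer(maxNetworks),
    lambdaMode = match.arg(lambdaMode),
    lambdaValue = as.numeric(lambdaValue),
    lambdaGamma = as.numeric(lambdaGamma),
    kMax = as.integer(kMax),
    nRestarts = as.integer(nRestarts),
    seed = as.integer(seed)
  )
}

#' Effective edge-weight threshold lambda
#'
#' In `"global_mean"` mode, `mean(W) + lambdaGamma * sd(W)` over all
#' n(n-1)/2 edge weights; in `"fixed"` mode, `lambdaValue`.
#'
#' @param W symmetric weight matrix
#' @param config a [DetectionConfig-class]
#' @return numeric lambda
#' @export
effectiveLambda <- function(W, config) {
  if (config@lambdaMode == "fixed") return(config@lambdaValue)
  off <- W[upper.tri(W)]
  mean(off) + config@lambdaGamma * sd(off)
}

# Scoring edges implied by nodes + topology.
.scoringEdges <- function(nodes, topology, partition) {
  if (topology == "clique") {
    e <- t(combn(sort(nodes), 2L))
  } else {
    pairs <- combn(length(partition), 2L)
    e <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(c) {
      as.matrix(expand.grid(partition[[pairs[1L, c]]],
                            partition[[pairs[2L, c]]]))
    }))
    e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
    e <- e[order(e[, 2L], e[, 1L]), , drop = FALSE]
  }
  matrix(as.integer(e), ncol = 2L, dimnames = list(NULL, c("i", "j")))
}

#' Construct a DetectedNetwork by hand
#'
#' Mostly useful for testing and for rescoring externally defined node
#' sets; detection normally builds these objects itself.
#'
#' @param nodes integer node ids
#' @param topology `"clique"` or `"k_partite"`
#' @param partition list of disjoint node sets (k-partite only)
#' @param score network score (optional; computed when `W` and `lambda`
#'   are given)
#' @param W optional weight matrix used to fill the score
#' @param lambda optional lambda used to fill the score
#' @return a [DetectedNetwork-class]
#' @export
detectedNetwork <- function(nodes, topology = c("clique", "k_partite"),
                            partition = list(), score = NA_real_,
                            W = NULL, lambda = NULL) {
  topology <- match.arg(topology)
  nodes <- as.integer(sort(nodes))
  se <- .scoringEdges(nodes, topology, partition)
  net <- new("DetectedNetwork",
    nodes = nodes, topology = topology,
    partition = lapply(partition, function(s) as.integer(sort(s))),
    score = as.numeric(score), scoringEdges = se, pValue = NA_real_)
  if (!is.null(W) && !is.null(lambda))
    net@score <- scoreSubgraph(W, net, lambda)
  net
}

#' Score a subgraph on the evidence graph
#'
#' `score = sum over scoring edges of (W_e - lambda)`. With lambda at the
#' global mean of W, a subgraph of average edges scores about 0 and
#' enrichment in differentially expressed edges scores > 0; the null
#' expectation of the score is 0 when differential edges are randomly
#' scattered, which makes the permutation max statistic comparable across
#' subgraph sizes.
#'
#' @param W symmetric weight matrix
#' @param network a [DetectedNetwork-class]
#' @param lambda centering threshold (see [effectiveLambda()])
#' @return numeric score
#' @examples
#' W <- matrix(1, 4, 4); diag(W) <- 0
#' W[1, 2] <- W[2, 1] <- W[1, 3] <- W[3, 1] <- W[2, 3] <- W[3, 2] <- 5
#' net <- detectedNetwork(1:3, "clique")
#' scoreSubgraph(W, net, lambda = mean(W[upper.tri(W)]))
#' @export
scoreSubgraph <- function(W, network, lambda) {
  se <- scoringEdges(network)
  if (nrow(se) == 0L) stop("scoring edge set is empty")
  sum(W[se] - lambda)
}

# ---- cores (plain lists; no RNG management, no S4) -------------------------

.detectCliquesCore <- function(W, lambda, config) {
  res <- cpp_detect_cliques(W, lambda, config@minSize,
                            config@maxNetworks, config@nRestarts)
  lapply(seq_along(res$scores), function(k)
    list(nodes = sort(res$nodes[[k]]), topology = "clique",
         partition = list(), score = res$scores[k]))
}

# Balanced random initial labelings guaranteeing every label is present.
# One runif + one order call builds all restarts (hot path inside the
# permutation loop).
.kpInits <- function(m, k, nRestarts) {
  u <- runif(m * nRestarts)
  ord <- order(rep(seq_len(nRestarts), each = m), u)
  ord <- ord - rep((seq_len(nRestarts) - 1L) * m, each = m)
  base <- rep_len(seq_len(k), m)
  matrix(base[ord], m, nRestarts)
}

.kpartiteCore <- function(W, nodes, lambda, config) {
  m <- length(nodes)
  Wsub <- W[nodes, nodes, drop = FALSE]
  best <- NULL
  for (k in 2L:min(config@kMax, m - 1L)) {
    inits <- .kpInits(m, k, config@nRestarts)
    res <- cpp_kl_partition(Wsub, lambda, inits)
    if (is.null(best) || res$score > best$score + 1e-9)
      best <- list(k = k, labels = res$labels, score = res$score)
  }
  if (is.null(best) || best$score <= 1e-9) return(NULL)
  sets <- split(nodes, best$labels)
  sets <- lapply(unname(sets), function(s) as.integer(sort(s)))
  sets <- sets[order(vapply(sets, min, integer(1L)))]
  list(nodes = sort(nodes), topology = "k_partite", partition = sets,
       score = best$score)
}

.detectAllCore <- function(W, config, lambda = NULL) {
  if (is.null(lambda)) lambda <- effectiveLambda(W, config)
  nets <- .detectCliquesCore(W, lambda, config)
  # a k-partite reading of each detected node set replaces the clique
  # reading when it strictly beats the clique score
  nets <- lapply(nets, function(net) {
    if (length(net$nodes) >= 4L) {
      kp <- .kpartiteCore(W, net$nodes, lambda, config)
      if (!is.null(kp) && kp$score > net$score + 1e-9) return(kp)
    }
    net
  })
  # the residual graph (nodes in no detected network) may itself hold a
  # k-partite structure too diffuse for the clique stage
  assigned <- unlist(lapply(nets, `[[`, "nodes"))
  resid <- setdiff(seq_len(nrow(W)), assigned)
  if (length(resid) >= max(4L, config@minSize)) {
    kp <- .kpartiteCore(W, resid, lambda, config)
    if (!is.null(kp)) nets <- c(nets, list(kp))
  }
  if (length(nets) > 1L)
    nets <- nets[order(-vapply(nets, `[[`, numeric(1L), "score"))]
  nets
}

.coreToS4 <- function(net) {
  detectedNetwork(net$nodes, net$topology, net$partition, score = net$score)
}

# ---- exported entry points -------------------------------------------------

#' Detect clique-topology differential networks
#'
#' Greedy seed-and-grow with multiple restarts: seeds at each of the top
#' `nRestarts` heaviest edges, then alternately adds the node with the
#' largest score gain and removes the node whose removal gains most until
#' no single move improves the score (ties broken toward the smaller node
#' index). The best positive-scoring result of size >= `minSize` is
#' extracted, its nodes removed from the graph, and extraction repeats
#' until nothing positive remains or `maxNetworks` is reached. Every
#' extraction strictly decreases the residual positive score, so the loop
#' terminates. Deterministic given (W, config).
#'
#' @param W symmetric nonnegative weight matrix with zero diagonal
#' @param config a [DetectionConfig-class]
#' @return list of [DetectedNetwork-class], node-disjoint, in decreasing
#'   score order (possibly empty)
#' @examples
#' W <- matrix(0.5, 10, 10); diag(W) <- 0
#' W[1:4, 1:4] <- 8; diag(W) <- 0
#' detectCliqueNetworks(W, detectionConfig(lambdaGamma = 0))
#' @export
detectCliqueNetworks <- function(W, config = detectionConfig()) {
  .checkWeightMatrix(W)
  lambda <- effectiveLambda(W, config)
  lapply(.detectCliquesCore(W, lambda, config), .coreToS4)
}

#' Detect the best k-partite reading of a node set
#'
#' For each k in `2..kMax`, searches partitions of `nodes` into k nonempty
#' sets maximizing the between-set score via Kernighan-Lin style
#' single-node relabeling from `nRestarts` random balanced initializations.
#' The k with the largest score wins; ties go to the smallest k
#' (parsimony). Returns `NULL` (the degenerate no-network result) when no
#' partition scores above 0.
#'
#' @param W symmetric weight matrix
#' @param nodes integer node ids (>= 4)
#' @param config a [DetectionConfig-class]; `config@seed` fixes the random
#'   initializations
#' @return a [DetectedNetwork-class] with `topology = "k_partite"`, or
#'   `NULL`
#' @export
detectKPartiteNetwork <- function(W, nodes, config = detectionConfig()) {
  .checkWeightMatrix(W)
  if (length(nodes) < 4L)
    stop("k-partite detection needs at least 4 nodes")
  lambda <- effectiveLambda(W, config)
  kp <- .withSeed(config@seed, .kpartiteCore(W, nodes, lambda, config))
  if (is.null(kp)) return(NULL)
  .coreToS4(kp)
}

#' Detect all latent differential networks
#'
#' Runs [detectCliqueNetworks()], then attempts a k-partite reading of
#' each detected node set (kept when it strictly beats the clique score on
#' the same nodes) and of the residual graph. Networks are returned sorted
#' by score, descending. Deterministic given (W, config).
#'
#' @inheritParams detectCliqueNetworks
#' @return list of [DetectedNetwork-class] (possibly empty)
#' @examples
#' out <- simulateConnectomes(generatorConfig(
#'   nNodes = 30, nSubjectsA = 20, nSubjectsB = 20,
#'   planted = list(plantedClique(1:6, 0.8)), seed = 2))
#' W <- weightMatrix(edgewiseTests(out$sample))
#' detectAll(W)
#' @export
detectAll <- function(W, config = detectionConfig()) {
  .checkWeightMatrix(W)
  nets <- .withSeed(config@seed, .detectAllCore(W, config))
  lapply(nets, .coreToS4)
}

# ---- DetectedNetwork accessors --------------------------------------------

#' @describeIn networkNodes nodes of a detected network
#' @export
setMethod("networkNodes", "DetectedNetwork", function(x) x@nodes)

#' @describeIn networkTopology topology of a detected network
#' @export
setMethod("networkTopology", "DetectedNetwork", function(x) x@topology)

#' @describeIn networkPartition partition of a k-partite network
#' @export
setMethod("networkPartition", "DetectedNetwork", function(x) x@partition)

#' @describeIn networkScore score of a detected network
#' @export
setMethod("networkScore", "DetectedNetwork", function(x) x@score)

#' @describeIn networkPValue permutation p-value of a detected network
#' @export
setMethod("networkPValue", "DetectedNetwork", function(x) x@pValue)

#' @describeIn scoringEdges scoring edges of a detected network
#' @export
setMethod("scoringEdges", "DetectedNetwork", function(x) x@scoringEdges)

setMethod("show", "DetectedNetwork", function(object) {
  cat(sprintf("DetectedNetwork (%s): %d nodes, score %.4g%s\n",
              object@topology, length(object@nodes), object@score,
              if (is.na(object@pValue)) ""
              else sprintf(", p = %.4g", object@pValue)))
  if (object@topology == "k_partite")
    for (s in seq_along(object@partition))
      cat(sprintf("  set %d: %s\n", s,
                  paste(object@partition[[s]], collapse = " ")))
  else
    cat("  nodes:", paste(object@nodes, collapse = " "), "\n")
})
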