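# Synthetic connectome generator: two-group samples with planted clique and
# k-partite differential networks, plus a correlated time-series mode that
# exercises the correlation front-end.

#' Describe a planted clique network
#'
#' Every node pair within `nodes` carries a group mean shift of `delta`
#' (Fisher-Z units) in the case-like group B. `delta < 0` plants
#' hypoconnectivity in group B (the "controls > cases" direction).
#'
#' @param nodes integer node ids
#' @param delta signed Fisher-Z shift on affected edges
#' @param signs optional named numeric vector (+1/-1, names `"i-j"` with
#'   i < j) giving a mixed per-edge sign pattern; the magnitude of `delta`
#'   is then applied with these signs
#' @return a [PlantedNetwork-class]
#' @examples
#' plantedClique(1:5, delta = -0.4)
#' @export
plantedClique <- function(nodes, delta, signs = NULL) {
  new("PlantedNetwork",
    nodes = as.integer(nodes),
    topology = "clique",
    partition = list(),
    delta = as.numeric(delta),
    signPattern = if (!is.null(signs)) "mixed"
                  else if (delta > 0) "uniform_hyper" else "uniform_hypo",
    signs = if (is.null(signs)) numeric() else signs
  )
}

#' Describe a planted k-partite network
#'
#' Exactly the between-set node pairs carry a group mean shift of `delta`;
#' within-set pairs are left at the baseline mean.
#'
#' @param partition list of >= 2 disjoint integer node sets
#' @inheritParams plantedClique
#' @return a [PlantedNetwork-class]
#' @examples
#' plantedPartite(list(1:2, 3:4), delta = -0.5)
#' @export
plantedPartite <- function(partition, delta, signs = NULL) {
  partition <- lapply(partition, as.integer)
  new("PlantedNetwork",
    nodes = as.integer(sort(unlist(partition))),
    topology = "k_partite",
    partition = partition,
    delta = as.numeric(delta),
    signPattern = if (!is.null(signs)) "mixed"
                  else if (delta > 0) "uniform_hyper" else "uniform_hypo",
    signs = if (is.null(signs)) numeric() else signs
  )
}

#' Study conditions for the synthetic generator
#'
#' @param nNodes number of nodes (default 90, a standard whole-brain
#'   parcellation size)
#' @param nSubjectsA,nSubjectsB group sizes (defaults 48 and 65, a typical
#'   single-site case/control split); group A is the reference group
#' @param baselineMean common edge mean mu0 in Fisher-Z units (default 0.3)
#' @param subjectSD per-edge subject-level noise sigma in Fisher-Z units
#'   (default 0.3)
#' @param planted list of [PlantedNetwork-class] objects (pairwise disjoint
#'   node sets); empty for a pure-null sample
#' @param groupLabels labels for groups A and B
#' @param seed RNG seed
#' @return a [GeneratorConfig-class]
#' @examples
#' generatorConfig(nNodes = 20, nSubjectsA = 10, nSubjectsB = 10,
#'                 planted = list(plantedClique(1:5, 0.6)))
#' @export
generatorConfig <- function(nNodes = 90L, nSubjectsA = 48L, nSubjectsB = 65L,
                            baselineMean = 0.3, subjectSD = 0.3,
                            planted = list(),
                            groupLabels = c("groupA", "groupB"),
                            seed = 1L) {
  new("GeneratorConfig",
    nNodes = as.integer(nNodes),
    nSubjectsA = as.integer(nSubjectsA),
    nSubjectsB = as.integer(nSubjectsB),
    baselineMean = as.numeric(baselineMean),
    subjectSD = as.numeric(subjectSD),
    planted = planted,
    groupLabels = as.character(groupLabels),
    seed = as.integer(seed)
  )
}

#' @describeIn affectedEdges affected edges of one planted network
#' @export
setMethod("affectedEdges", "PlantedNetwork", function(x) {
  if (x@topology == "clique") {
    e <- t(combn(sort(x@nodes), 2L))
  } else {
    sets <- x@partition
    pairs <- combn(length(sets), 2L)
    e <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(c) {
      as.matrix(expand.grid(sets[[pairs[1L, c]]], sets[[pairs[2L, c]]]))
    }))
    e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
    e <- e[order(e[, 2L], e[, 1L]), , drop = FALSE]
  }
  matrix(as.integer(e), ncol = 2L, dimnames = list(NULL, c("i", "j")))
})

#' @describeIn affectedEdges union of affected edges over all planted
#'   networks
#' @export
setMethod("affectedEdges", "GroundTruth", function(x) {
  if (length(x@planted) == 0L)
    return(matrix(integer(), ncol = 2L, dimnames = list(NULL, c("i", "j"))))
  do.call(rbind, lapply(x@planted, affectedEdges))
})

#' @describeIn trueDeltaMatrix true difference matrix of a synthetic sample
#' @export
setMethod("trueDeltaMatrix", "GroundTruth", function(x) x@deltaMatrix)

#' @describeIn nNodes number of nodes of a ground truth object
#' @export
setMethod("nNodes", "GroundTruth", function(x) x@nNodes)

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d planted network(s) over %d nodes\n",
              length(object@planted), object@nNodes))
  for (pn in object@planted)
    cat(sprintf("  %s on %d nodes, delta = %g (%s)\n",
                pn@topology, length(pn@nodes), pn@delta, pn@signPattern))
})

# Per-edge signed shift of one planted network (group B minus group A).
.plantedShift <- function(pn) {
  e <- affectedEdges(pn)
  d <- rep(pn@delta, nrow(e))
  if (pn@signPattern == "mixed") {
    key <- sprintf("%d-%d", e[, 1L], e[, 2L])
    s <- pn@signs[key]
    if (anyNA(s))
      stop("mixed sign map must cover every affected edge (missing: ",
           paste(key[is.na(s)], collapse = ", "), ")")
    d <- abs(pn@delta) * as.numeric(s)
  }
  list(edges = e, delta = d)
}

# n x n matrix of true group B - group A edge mean differences.
.deltaMatrix <- function(config) {
  n <- config@nNodes
  D <- matrix(0, n, n)
  for (pn in config@planted) {
    sh <- .plantedShift(pn)
    D[sh$edges] <- sh$delta
  }
  D + t(D)
}

#' Generate a two-group synthetic connectome sample
#'
#' Draws each subject's edge values independently as
#' `Normal(mu0 + Delta_g, sigma^2)` on the Fisher-Z scale, where `Delta_g`
#' is the planted shift on affected edges for group B (group A is the
#' reference) and 0 otherwise. Edges are independent given the group means;
#' this matches the exchangeability assumed by the permutation test and
#' keeps analytic oracles tractable. Correlated edges are available through
#' [simulateTimeSeries()].
#'
#' @param config a [GeneratorConfig-class]
#' @return list with elements `sample` (a [ConnectomeSample-class]) and
#'   `truth` (a [GroundTruth-class])
#' @examples
#' out <- simulateConnectomes(generatorConfig(
#'   nNodes = 20, nSubjectsA = 10, nSubjectsB = 10,
#'   planted = list(plantedClique(1:5, 0.6)), seed = 7))
#' out$sample
#' @export
simulateConnectomes <- function(config) {
  validObject(config)
  n <- config@nNodes
  nE <- n * (n - 1L) / 2L
  D <- .deltaMatrix(config)
  dvec <- D[upper.tri(D)]
  nA <- config@nSubjectsA
  nB <- config@nSubjectsB
  E <- .withSeed(config@seed, {
    cbind(
      matrix(rnorm(nE * nA, mean = config@baselineMean,
                   sd = config@subjectSD), nE, nA),
      matrix(rnorm(nE * nB, mean = rep(config@baselineMean + dvec, nB),
                   sd = config@subjectSD), nE, nB)
    )
  })
  ids <- c(sprintf("%s_%03d", config@groupLabels[1L], seq_len(nA)),
           sprintf("%s_%03d", config@groupLabels[2L], seq_len(nB)))
  groups <- factor(rep(config@groupLabels, c(nA, nB)),
                   levels = config@groupLabels)
  truth <- new("GroundTruth", planted = config@planted,
               deltaMatrix = D, nNodes = n)
  list(sample = .newConnectomeSample(E, groups, ids, syntheticNodeTable(n)),
       truth = truth)
}

# Group correlation matrix implied by the config on the Fisher-Z scale.
.impliedCorrelation <- function(config, group) {
  n <- config@nNodes
  Z <- matrix(config@baselineMean, n, n)
  if (group == "B") Z <- Z + .deltaMatrix(config)
  R <- tanh(Z)
  diag(R) <- 1
  bad <- abs(R) >= 1 - 1e-12 & row(R) != col(R)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    culprit <- vapply(config@planted, function(pn)
      idx[1L] %in% pn@nodes && idx[2L] %in% pn@nodes, logical(1L))
    stop(sprintf(
      "implied correlation at edge (%d, %d) reaches |r| >= 1%s",
      idx[1L], idx[2L],
      if (any(culprit))
        sprintf(" (planted delta %g too large for baseline %g)",
                config@planted[[which(culprit)[1L]]]@delta,
                config@baselineMean)
      else ""))
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10) {
    deltas <- vapply(config@planted, function(pn) pn@delta, numeric(1L))
    stop(sprintf(
      paste0("implied correlation matrix for group %s is not positive ",
             "definite (min eigenvalue %.3g); planted delta(s) %s are too ",
             "large for baseline %g"),
      group, min(ev), paste(deltas, collapse = ", "), config@baselineMean))
  }
  R
}

#' Generate per-subject ROI time series with planted correlation structure
#'
#' Samples each subject as `nTimepoints` independent draws from a
#' multivariate normal whose population correlation matrix is
#' `tanh(Z-mean)` of the group's Fisher-Z means, so the population Pearson
#' correlation, after Fisher-Z, has exactly the group means implied by
#' `config`. The implied correlation matrix is verified positive definite
#' before sampling.
#'
#' @param config a [GeneratorConfig-class]
#' @param nTimepoints number of time points per subject (>= 10)
#' @return list with `series` (named list of ROI x time matrices), `groups`
#'   (factor), `nodeTable` and `truth` (a [GroundTruth-class])
#' @seealso [timeSeriesToSample()] to push the series through the
#'   correlation front-end
#' @examples
#' ts <- simulateTimeSeries(generatorConfig(
#'   nNodes = 10, nSubjectsA = 3, nSubjectsB = 3), nTimepoints = 50)
#' dim(ts$series[[1]])
#' @export
simulateTimeSeries <- function(config, nTimepoints) {
  validObject(config)
  if (nTimepoints < 10L) stop("nTimepoints must be >= 10")
  n <- config@nNodes
  RA <- .impliedCorrelation(config, "A")
  RB <- .impliedCorrelation(config, "B")
  LA <- chol(RA)
  LB <- chol(RB)
  nA <- config@nSubjectsA
  nB <- config@nSubjectsB
  series <- .withSeed(config@seed, {
    lapply(seq_len(nA + nB), function(s) {
      L <- if (s <= nA) LA else LB
      # ROI x time: rows are regions
      t(matrix(rnorm(nTimepoints * n), nTimepoints, n) %*% L)
    })
  })
  ids <- c(sprintf("%s_%03d", config@groupLabels[1L], seq_len(nA)),
           sprintf("%s_%03d", config@groupLabels[2L], seq_len(nB)))
  names(series) <- ids
  truth <- new("GroundTruth", planted = config@planted,
               deltaMatrix = .deltaMatrix(config), nNodes = n)
  list(series = series,
       groups = factor(rep(config@groupLabels, c(nA, nB)),
                       levels = config@groupLabels),
       nodeTable = syntheticNodeTable(n),
       truth = truth)
}

#' Convert ROI time series to a ConnectomeSample
#'
#' Applies [correlationToZ()] to each subject's ROI x time matrix.
#'
#' @param series named list of ROI x time matrices
#' @param groups group labels, one per subject
#' @param nodeTable optional node table
#' @return a [ConnectomeSample-class]
#' @export
timeSeriesToSample <- function(series, groups, nodeTable = NULL) {
  ConnectomeSample(lapply(series, correlationToZ), groups,
                   nodeTable = nodeTable, subjectIds = names(series))
}
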