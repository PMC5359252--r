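# Presentation artifacts: heatmap reordering and directional edge tables.

#' Node ordering that lists detected networks first
#'
#' Concatenates each network's nodes (networks by descending score; within
#' a k-partite network set 1 then set 2 and so on, each by atlas index;
#' within a clique, atlas index order), followed by all remaining nodes by
#' atlas index. Reordering a weight-matrix heatmap this way places each
#' detected network in a leading diagonal block.
#'
#' @param networks list of node-disjoint [DetectedNetwork-class]
#' @param nodeTable node table
#' @return integer permutation of 1..n (node row positions)
#' @examples
#' heatmapOrder(list(), syntheticNodeTable(5))
#' @export
heatmapOrder <- function(networks, nodeTable) {
  n <- nrow(nodeTable)
  allNodes <- unlist(lapply(networks, networkNodes))
  if (anyDuplicated(allNodes))
    stop("networks must be node-disjoint")
  if (length(networks) > 1L) {
    networks <- networks[order(-vapply(networks, networkScore, numeric(1L)))]
  }
  idx <- nodeTable$index
  lead <- unlist(lapply(networks, function(net) {
    if (networkTopology(net) == "k_partite")
      unlist(lapply(networkPartition(net), function(s) s[order(idx[s])]))
    else {
      s <- networkNodes(net)
      s[order(idx[s])]
    }
  }))
  rest <- setdiff(seq_len(n), lead)
  out <- c(lead, rest[order(idx[rest])])
  as.integer(out)
}

#' Directional edge table of a detected network
#'
#' One row per scoring edge with node abbreviations, the t statistic,
#' p-value, weight W, and a direction label derived from the sign of
#' mean(group A) - mean(group B) using the actual group names (e.g.
#' `"TC>ASD"`); rows are sorted by W descending (ties by node pair). W
#' doubles as an edge-width encoding of statistical significance in
#' downstream plots.
#'
#' @param network a [DetectedNetwork-class]
#' @param evidence the [EdgeEvidence-class] it was detected from
#' @param nodeTable node table
#' @return data.frame with columns `node_i`, `node_j`, `abbrev_i`,
#'   `abbrev_j`, `t`, `p`, `W`, `direction`
#' @export
directionalEdgeTable <- function(network, evidence, nodeTable) {
  se <- scoringEdges(network)
  st <- edgeStats(evidence)
  pos <- .edgePos(se[, 1L], se[, 2L], nNodes(evidence))
  lev <- evidence@groupLevels
  dirLabel <- ifelse(st$sign[pos] > 0,
                     paste0(lev[1L], ">", lev[2L]),
                     ifelse(st$sign[pos] < 0,
                            paste0(lev[2L], ">", lev[1L]), NA_character_))
  out <- data.frame(
    node_i = nodeTable$index[se[, 1L]],
    node_j = nodeTable$index[se[, 2L]],
    abbrev_i = nodeTable$abbrev[se[, 1L]],
    abbrev_j = nodeTable$abbrev[se[, 2L]],
    t = st$t[pos],
    p = st$p[pos],
    W = st$W[pos],
    direction = dirLabel
  )
  out[order(-out$W, out$node_i, out$node_j), , drop = FALSE]
}
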