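# On-disk formats. All files are plain delimited text so that fixtures stay
# diffable: matrices are dense whitespace-delimited with no header (node
# order defined solely by the node table), node tables and manifests are
# CSV, ground truth and network summaries are JSON. Atlas indices are
# 1-based in every user-facing file.

#' Read a node table
#'
#' @param path CSV file with header `name,abbrev,index,x,y,z`
#' @return validated data.frame; row order defines matrix row/column order
#' @export
readNodeTable <- function(path) {
  nt <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "abbrev", "index", "x", "y", "z")
  if (!all(need %in% names(nt)))
    stop("node table must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(nt$index))
    stop("node table atlas indices must be unique")
  nt[need]
}

#' Write a node table
#' @param nodeTable data.frame as returned by [readNodeTable()]
#' @param path output CSV path
#' @export
writeNodeTable <- function(nodeTable, path) {
  write.csv(nodeTable, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

# Read one dense whitespace/comma-delimited matrix file.
.readMatrixFile <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  as.matrix(read.table(path, header = FALSE, sep = sep))
}

#' Read a connectome sample from disk
#'
#' Expects one matrix file per subject named `<subject_id>.txt` under
#' `matrixDir`, a two-column manifest CSV (`subject_id,group`) and a node
#' table CSV. Each matrix must match the node table dimension, contain only
#' finite values, have a zero diagonal, and be symmetric within 1e-6 (it is
#' then symmetrized as (M + t(M))/2).
#'
#' @param matrixDir directory of per-subject matrix files
#' @param manifest path to the subject manifest CSV
#' @param nodeTable path to the node table CSV
#' @return a validated [ConnectomeSample-class]
#' @export
readConnectomeSample <- function(matrixDir, manifest, nodeTable) {
  nt <- readNodeTable(nodeTable)
  mf <- read.csv(manifest, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "group") %in% names(mf)))
    stop("manifest must have columns subject_id and group")
  ng <- length(unique(mf$group))
  if (ng != 2L)
    stop(sprintf("manifest must contain exactly 2 group labels, found %d", ng))
  paths <- file.path(matrixDir, paste0(mf$subject_id, ".txt"))
  missing <- !file.exists(paths)
  if (any(missing))
    stop("matrix file missing for subject(s): ",
         paste(mf$subject_id[missing], collapse = ", "))
  mats <- lapply(paths, .readMatrixFile)
  names(mats) <- mf$subject_id
  ConnectomeSample(mats, groups = mf$group, nodeTable = nt,
                   subjectIds = mf$subject_id)
}

#' Write a connectome sample to disk
#'
#' Emits one matrix file per subject (`<subject_id>.txt`, dense
#' whitespace-delimited, 17 significant digits so a read/write round trip
#' is the identity to well below 1e-12), `manifest.csv` and
#' `node_table.csv`.
#'
#' @param sample a [ConnectomeSample-class]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
writeConnectomeSample <- function(sample, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- subjectIds(sample)
  for (s in seq_along(ids)) {
    M <- subjectMatrix(sample, s)
    write.table(format(M, digits = 17, scientific = TRUE, trim = TRUE),
                file.path(dir, paste0(ids[s], ".txt")),
                row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  write.csv(
    data.frame(subject_id = ids,
               group = as.character(subjectGroups(sample))),
    file.path(dir, "manifest.csv"), row.names = FALSE, quote = TRUE)
  writeNodeTable(nodeTable(sample), file.path(dir, "node_table.csv"))
  invisible(dir)
}

#' Write the planted ground truth of a synthetic sample as JSON
#'
#' @param truth a [GroundTruth-class]
#' @param path output JSON path
#' @export
writeGroundTruth <- function(truth, path) {
  nets <- lapply(truth@planted, function(pn) {
    out <- list(nodes = pn@nodes, topology = pn@topology,
                delta = pn@delta, sign_pattern = pn@signPattern)
    if (pn@topology == "k_partite") out$partition <- pn@partition
    if (length(pn@signs))
      out$signs <- as.list(pn@signs)
    out
  })
  jsonlite::write_json(list(n_nodes = truth@nNodes, networks = nets),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Fisher-Z connectivity from ROI time series
#'
#' Computes Pearson correlations between all ROI pairs and applies the
#' Fisher-Z (atanh) transform. The diagonal is set to 0.
#'
#' @param roiTimeseries ROI x time numeric matrix (>= 3 time points)
#' @return symmetric n x n Fisher-Z matrix with zero diagonal
#' @examples
#' ts <- matrix(rnorm(40), 4, 10)
#' correlationToZ(ts)
#' @export
correlationToZ <- function(roiTimeseries) {
  if (!is.matrix(roiTimeseries) || ncol(roiTimeseries) < 3L)
    stop("roiTimeseries must be an ROI x time matrix with >= 3 time points")
  sds <- apply(roiTimeseries, 1L, sd)
  if (any(sds == 0))
    stop(sprintf("constant signal in ROI %d", which(sds == 0)[1L]))
  r <- cor(t(roiTimeseries))
  off <- abs(r) >= 1 - 1e-12 & row(r) != col(r)
  if (any(off)) {
    idx <- which(off, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "|r| = 1 between ROIs %d and %d: Fisher-Z is infinite",
      idx[1L], idx[2L]))
  }
  z <- atanh(r)
  diag(z) <- 0
  z
}

#' Write network detection reports
#'
#' Emits the presentation artifacts for a set of detected networks:
#' \itemize{
#'   \item `node_order.csv` -- the heatmap ordering placing detected
#'     networks first (see [heatmapOrder()]);
#'   \item `network<k>_edges.csv` -- per-network directional edge lists
#'     (node pair, abbreviations, t, p, W, direction label);
#'   \item `networks.json` -- per-network summary (nodes by atlas index,
#'     topology, partition, score, p-value).
#' }
#'
#' @param networks list of [DetectedNetwork-class] (may be empty)
#' @param evidence the [EdgeEvidence-class] the networks were detected from
#' @param nodeTable node table
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
writeNetworkReport <- function(networks, evidence, nodeTable, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- nrow(nodeTable)
  for (net in networks)
    if (any(networkNodes(net) < 1L | networkNodes(net) > n))
      stop("network references unknown node id")
  ord <- heatmapOrder(networks, nodeTable)
  write.csv(
    data.frame(position = seq_len(n),
               node = ord,
               index = nodeTable$index[ord],
               abbrev = nodeTable$abbrev[ord]),
    file.path(dir, "node_order.csv"), row.names = FALSE, quote = TRUE)
  summaries <- list()
  for (k in seq_along(networks)) {
    net <- networks[[k]]
    tab <- directionalEdgeTable(net, evidence, nodeTable)
    write.csv(tab, file.path(dir, sprintf("network%d_edges.csv", k)),
              row.names = FALSE, quote = TRUE)
    summaries[[k]] <- list(
      rank = k,
      nodes = nodeTable$index[networkNodes(net)],
      topology = networkTopology(net),
      partition = lapply(networkPartition(net),
                         function(s) nodeTable$index[s]),
      score = networkScore(net),
      p_value = networkPValue(net)
    )
  }
  jsonlite::write_json(summaries, file.path(dir, "networks.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(dir)
}
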