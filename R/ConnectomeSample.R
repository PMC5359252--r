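# ConnectomeSample construction and accessors.

# Internal fast path: build from an edges x subjects matrix already in the
# canonical upper-triangle order.
.newConnectomeSample <- function(E, groups, ids, nodeTable) {
  n <- nrow(nodeTable)
  if (!is.factor(groups))
    groups <- factor(groups, levels = unique(as.character(groups)))
  ep <- .edgePairs(n)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = S4Vectors::SimpleList(z = E),
    rowData = S4Vectors::DataFrame(i = ep[, "i"], j = ep[, "j"]),
    colData = S4Vectors::DataFrame(
      subject_id = as.character(ids),
      group = groups,
      row.names = as.character(ids)
    ),
    metadata = list(nodeTable = nodeTable)
  )
  new("ConnectomeSample", se)
}

#' Construct a ConnectomeSample from per-subject matrices
#'
#' Validates each subject's matrix (finite entries, symmetry within 1e-6 --
#' then symmetrized as (M + t(M))/2 -- and zero diagonal within 1e-6) and
#' packs the upper triangles into an edges x subjects assay.
#'
#' @param matrices named list of n x n Fisher-Z matrices, one per subject
#' @param groups character or factor of group labels (exactly two distinct
#'   labels must be present); the first label encountered is the reference
#'   group
#' @param nodeTable data.frame with columns `name`, `abbrev`, `index`, `x`,
#'   `y`, `z`; defaults to [syntheticNodeTable()] of matching size
#' @param subjectIds character vector of subject ids; defaults to
#'   `names(matrices)`
#' @return a [ConnectomeSample-class]
#' @examples
#' m <- lapply(1:4, function(i) {
#'   z <- matrix(rnorm(25, 0.3, 0.1), 5, 5)
#'   z <- (z + t(z)) / 2; diag(z) <- 0; z
#' })
#' names(m) <- paste0("s", 1:4)
#' cs <- ConnectomeSample(m, groups = c("A", "A", "B", "B"))
#' subjectGroups(cs)
#' @export
ConnectomeSample <- function(matrices, groups, nodeTable = NULL,
                             subjectIds = names(matrices)) {
  if (length(matrices) == 0L) stop("no subject matrices supplied")
  n <- if (is.null(nodeTable)) nrow(matrices[[1L]]) else nrow(nodeTable)
  if (is.null(nodeTable)) nodeTable <- syntheticNodeTable(n)
  if (is.null(subjectIds))
    subjectIds <- sprintf("subject%03d", seq_along(matrices))
  if (length(groups) != length(matrices))
    stop("groups must have one label per subject")
  nE <- n * (n - 1L) / 2L
  E <- matrix(NA_real_, nE, length(matrices))
  for (s in seq_along(matrices)) {
    M <- matrices[[s]]
    id <- subjectIds[s]
    if (!is.matrix(M) || nrow(M) != n || ncol(M) != n)
      stop(sprintf("subject '%s': matrix dimension does not match node table",
                   id))
    if (!all(is.finite(M))) {
      bad <- which(!is.finite(M), arr.ind = TRUE)[1L, ]
      stop(sprintf("subject '%s': non-finite value at (%d, %d)",
                   id, bad[1L], bad[2L]))
    }
    asym <- max(abs(M - t(M)))
    if (asym >= 1e-6)
      stop(sprintf("subject '%s': matrix asymmetry %.3g exceeds tolerance 1e-6",
                   id, asym))
    if (max(abs(diag(M))) > 1e-6)
      stop(sprintf("subject '%s': diagonal must be zero", id))
    M <- (M + t(M)) / 2
    E[, s] <- M[upper.tri(M)]
  }
  .newConnectomeSample(E, groups, subjectIds, nodeTable)
}

#' @describeIn nodeTable node table of a sample
#' @export
setMethod("nodeTable", "ConnectomeSample", function(x)
  S4Vectors::metadata(x)$nodeTable)

#' @describeIn subjectGroups group factor of a sample
#' @export
setMethod("subjectGroups", "ConnectomeSample", function(x)
  SummarizedExperiment::colData(x)$group)

#' @describeIn subjectIds subject ids of a sample
#' @export
setMethod("subjectIds", "ConnectomeSample", function(x)
  SummarizedExperiment::colData(x)$subject_id)

#' @describeIn nNodes number of nodes of a sample
#' @export
setMethod("nNodes", "ConnectomeSample", function(x)
  nrow(nodeTable(x)))

#' @describeIn subjectMatrix reconstruct a subject's symmetric matrix
#' @export
setMethod("subjectMatrix", "ConnectomeSample", function(x, subject) {
  if (is.character(subject)) {
    subject <- match(subject, subjectIds(x))
    if (is.na(subject)) stop("unknown subject id")
  }
  .vecToSym(SummarizedExperiment::assay(x, "z")[, subject], nNodes(x))
})

setMethod("show", "ConnectomeSample", function(object) {
  g <- subjectGroups(object)
  tab <- table(g)
  cat(sprintf(
    "ConnectomeSample: %d nodes, %d edges, %d subjects (%s)\n",
    nNodes(object), nrow(object), ncol(object),
    paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")
  ))
})
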