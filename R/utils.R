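# Internal helpers shared across modules.

# Edge enumeration convention: unordered pairs (i, j), i < j, in the
# column-major order of upper.tri(), i.e. (1,2), (1,3), (2,3), (1,4), ...
# All edge x subject matrices and EdgeEvidence rows follow this order.
.edgePairs <- function(n) {
  j <- rep(seq_len(n), times = seq_len(n) - 1L)
  i <- sequence(seq_len(n) - 1L)
  cbind(i = i, j = j)
}

# Position of edge (i, j), i < j, in the upper-triangle ordering.
.edgePos <- function(i, j, n) {
  stopifnot(all(i < j))
  (j - 1L) * (j - 2L) / 2L + i
}

# Evaluate expr with a fixed seed without disturbing the caller's RNG stream.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Symmetric matrix from an upper-triangle vector (zero diagonal).
.vecToSym <- function(v, n) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- v
  m + t(m)
}

.checkWeightMatrix <- function(W) {
  if (!is.matrix(W) || nrow(W) != ncol(W))
    stop("W must be a square matrix")
  if (!all(is.finite(W)))
    stop("W must be finite")
  if (max(abs(W - t(W))) > 1e-8)
    stop("W must be symmetric")
  if (any(diag(W) != 0))
    stop("W must have a zero diagonal")
  if (any(W < 0))
    stop("W must be nonnegative")
  invisible(TRUE)
}

# A minimal synthetic node table for generated data: atlas index equals the
# node position, coordinates are placeholders.
#' Synthetic node table
#'
#' Builds a placeholder node table (region name, abbreviation, atlas index,
#' MNI coordinates) for synthetic connectomes. Atlas indices are 1..n and
#' coordinates are zero; real analyses should supply their parcellation's
#' table via [readNodeTable()].
#'
#' @param n number of nodes
#' @return data.frame with columns `name`, `abbrev`, `index`, `x`, `y`, `z`
#' @examples
#' head(syntheticNodeTable(90))
#' @export
syntheticNodeTable <- function(n) {
  data.frame(
    name = sprintf("Synthetic region %d", seq_len(n)),
    abbrev = sprintf("SR%03d", seq_len(n)),
    index = seq_len(n),
    x = 0, y = 0, z = 0,
    stringsAsFactors = FALSE
  )
}
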