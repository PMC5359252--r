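# Classification-based validation of detected networks: leave-one-out
# cross-validation of an SVM on subject-level edge features.

#' Leave-one-out SVM classification on edge features
#'
#' For each subject in turn, trains a support vector machine (radial-basis
#' or linear kernel, `e1071` defaults: cost 1, gamma 1/n_features,
#' per-feature standardization estimated on the training fold) on all other
#' subjects' Fisher-Z values over `featureEdges`, predicts the held-out
#' subject, and reports the pooled accuracy.
#'
#' By default the feature edges are taken as given -- typically the scoring
#' edges of networks detected on the full sample, which mirrors the common
#' practice of validating full-sample-detected features but leaks the
#' selection step into the folds. `nested = TRUE` instead re-runs edgewise
#' testing and detection inside every training fold and uses the union of
#' the fold's detected scoring edges (falling back to all edges when a fold
#' detects nothing), giving an honest, selection-free accuracy estimate.
#'
#' @param sample a [ConnectomeSample-class] with >= 2 subjects per group
#' @param featureEdges 2-column integer matrix of node pairs (i < j), e.g.
#'   `scoringEdges(network)` or the union over networks; ignored when
#'   `nested = TRUE`
#' @param kernel `"radial"` (RBF) or `"linear"`
#' @param nested re-detect features within each training fold
#' @param config [DetectionConfig-class] for nested detection
#' @param cost SVM regularization constant (default 1)
#' @param varEqual,logBase edgewise-test settings for nested detection
#' @return a [ClassificationReport-class]
#' @examples
#' out <- simulateConnectomes(generatorConfig(
#'   nNodes = 10, nSubjectsA = 8, nSubjectsB = 8,
#'   planted = list(plantedClique(1:4, 2)), subjectSD = 0.1, seed = 4))
#' rep <- classifyLOOCV(out$sample, affectedEdges(out$truth))
#' rep@accuracy
#' @export
classifyLOOCV <- function(sample, featureEdges = NULL,
                          kernel = c("radial", "linear"), nested = FALSE,
                          config = detectionConfig(), cost = 1,
                          varEqual = TRUE, logBase = exp(1)) {
  kernel <- match.arg(kernel)
  g <- subjectGroups(sample)
  if (any(table(g) < 2L))
    stop("both groups need at least 2 subjects")
  E <- SummarizedExperiment::assay(sample, "z")
  n <- nNodes(sample)
  nSub <- ncol(E)
  if (!nested) {
    if (is.null(featureEdges) || nrow(featureEdges) == 0L)
      stop("featureEdges must be a nonempty 2-column matrix")
    rows <- .edgePos(featureEdges[, 1L], featureEdges[, 2L], n)
  }
  pred <- character(nSub)
  for (s in seq_len(nSub)) {
    trainG <- g[-s]
    if (length(unique(trainG)) < 2L)
      stop("training fold contains a single class")
    if (nested) {
      st <- .edgeStatsCore(E[, -s, drop = FALSE],
                           E[, -s, drop = FALSE]^2,
                           trainG == levels(g)[1L], pooled = varEqual)
      Wv <- -log(pmax(st$p, .Machine$double.xmin)) / log(logBase)
      Wm <- .vecToSym(Wv, n)
      nets <- .withSeed(config@seed, .detectAllCore(Wm, config))
      foldRows <- if (length(nets)) {
        unique(unlist(lapply(nets, function(net) {
          se <- .scoringEdges(net$nodes, net$topology, net$partition)
          .edgePos(se[, 1L], se[, 2L], n)
        })))
      } else seq_len(nrow(E))
    } else {
      foldRows <- rows
    }
    Xtr <- t(E[foldRows, -s, drop = FALSE])
    Xte <- t(E[foldRows, s, drop = FALSE])
    fit <- e1071::svm(Xtr, factor(trainG), kernel = kernel, cost = cost,
                      scale = rep(TRUE, ncol(Xtr)))
    pred[s] <- as.character(predict(fit, Xte))
  }
  nCorrect <- sum(pred == as.character(g))
  new("ClassificationReport",
    featureEdges = if (nested)
      matrix(integer(), ncol = 2L) else
      matrix(as.integer(featureEdges), ncol = 2L,
             dimnames = list(NULL, c("i", "j"))),
    kernel = kernel,
    nCorrect = as.integer(nCorrect),
    nTotal = as.integer(nSub),
    accuracy = nCorrect / nSub,
    details = list(predicted = pred, observed = as.character(g),
                   cost = cost, nested = nested)
  )
}

setMethod("show", "ClassificationReport", function(object) {
  cat(sprintf(
    "ClassificationReport: %s kernel, LOOCV accuracy %.1f%% (%d/%d)%s\n",
    object@kernel, 100 * object@accuracy, object@nCorrect, object@nTotal,
    if (isTRUE(object@details$nested)) " [nested feature selection]" else ""))
})
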