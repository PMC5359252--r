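# Fixtures built in code: small weight matrices and samples.

# Symmetric weight matrix with given background and a heavy block.
blockWeightMatrix <- function(n, background, blocks = list()) {
  W <- matrix(background, n, n)
  for (b in blocks) W[b$nodes, b$nodes] <- b$w
  W[lower.tri(W)] <- t(W)[lower.tri(W)]
  diag(W) <- 0
  W
}

# Random Exp(1)-weighted graph (the null distribution of -log p weights).
randomWeightMatrix <- function(n) {
  W <- matrix(0, n, n)
  W[upper.tri(W)] <- rexp(n * (n - 1) / 2)
  W + t(W)
}

# Small two-group sample built directly from matrices.
smallSample <- function(n = 6, nA = 4, nB = 4, mu = 0.3, sd = 0.2,
                        seed = 42, labels = c("ctl", "cas")) {
  out <- simulateConnectomes(generatorConfig(
    nNodes = n, nSubjectsA = nA, nSubjectsB = nB, baselineMean = mu,
    subjectSD = sd, groupLabels = labels, seed = seed))
  out$sample
}
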