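# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: transition probabilities come from
# Matrix::expm, likelihoods from brute-force enumeration or closed forms.

# Mk likelihood by exhaustive enumeration over internal-node states
mkLoglikEnum <- function(tree, states, Q, prior = rep(1 / nrow(Q), nrow(Q))) {
  k <- nrow(Q)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  E <- tree$edge
  len <- tree$edge.length
  P <- lapply(seq_len(nrow(E)), function(e) as.matrix(Matrix::expm(Q * len[e])))
  root <- ntip + 1
  st <- states[tree$tip.label]
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), nnode)))
  tot <- 0
  for (g in seq_len(nrow(grid))) {
    asg <- c(st, grid[g, ])
    p <- prior[asg[root]]
    for (e in seq_len(nrow(E)))
      p <- p * P[[e]][asg[E[e, 1]], asg[E[e, 2]]]
    tot <- tot + p
  }
  log(tot)
}

# marginal node probabilities from the same enumeration
mkMarginalEnum <- function(tree, states, Q,
                           prior = rep(1 / nrow(Q), nrow(Q))) {
  k <- nrow(Q)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  E <- tree$edge
  len <- tree$edge.length
  P <- lapply(seq_len(nrow(E)), function(e) as.matrix(Matrix::expm(Q * len[e])))
  root <- ntip + 1
  st <- states[tree$tip.label]
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), nnode)))
  out <- matrix(0, nnode, k)
  for (g in seq_len(nrow(grid))) {
    asg <- c(st, grid[g, ])
    p <- prior[asg[root]]
    for (e in seq_len(nrow(E)))
      p <- p * P[[e]][asg[E[e, 1]], asg[E[e, 2]]]
    for (nd in seq_len(nnode)) out[nd, grid[g, nd]] <- out[nd, grid[g, nd]] + p
  }
  sweep(out, 1, rowSums(out), "/")
}

# constant-rate birth-death log-likelihood of an ultrametric tree, Nee-style
# closed form with the same conventions as the MuSSE path defaults
# (lambda factor at every internal node, FitzJohn weighting collapsing to
# D_root for a single observed state, no survival conditioning)
bdLoglikClosed <- function(tree, lambda, mu) {
  ntip <- length(tree$tip.label)
  dep <- ape::node.depth.edgelength(tree)
  H <- max(dep[seq_len(ntip)])
  tt <- H - dep
  r <- lambda - mu
  lnPhi <- if (abs(r) < 1e-12) {
    function(t) -2 * log1p(lambda * t)
  } else {
    function(t) r * t + 2 * (log(r) - log(lambda * exp(r * t) - mu))
  }
  E <- tree$edge
  ln <- 0
  for (e in seq_len(nrow(E)))
    ln <- ln + lnPhi(tt[E[e, 1]]) - lnPhi(tt[E[e, 2]])
  ln + tree$Nnode * log(lambda)
}

# analytic extinction probability of a constant-rate birth-death lineage
bdExtinctionProb <- function(t, lambda, mu) {
  if (mu == 0) return(rep(0, length(t)))
  r <- lambda - mu
  if (abs(r) < 1e-12) return(lambda * t / (1 + lambda * t))
  mu * (exp(r * t) - 1) / (lambda * exp(r * t) - mu)
}

# random ultrametric tree for likelihood cross-checks
randomUltraTree <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ape::rcoal(n)
}

# random Mk generator with off-diagonal rates in (0, max_rate)
randomQ <- function(k = 3, max_rate = 1.5) {
  Q <- matrix(runif(k * k, 0.05, max_rate), k, k)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

obsFrom <- function(x, var = 0, n = 1) {
  traitObservation(names(x), x, var, n)
}
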