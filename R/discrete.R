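#' Build a constrained Mk generator matrix
#'
#' @param rates Vector of non-negative rates: length 1 for `"ER"`,
#'   `k(k-1)/2` for `"SYM"` (upper-triangle order, by row), `k(k-1)` for
#'   `"ARD"` (row-major over off-diagonal entries).
#' @param constraint One of `"ER"`, `"SYM"`, `"ARD"`.
#' @param k Number of states (default 3).
#' @return A `k x k` generator matrix with rows summing to zero.
#' @export
mkQ <- function(rates, constraint = c("ER", "SYM", "ARD"), k = 3) {
  constraint <- match.arg(constraint)
  if (any(rates < 0)) stop("rates must be non-negative")
  np <- mkParamCount(constraint, k)
  if (length(rates) != np)
    stop(sprintf("constraint %s with k = %d needs %d rate(s), got %d",
                 constraint, k, np, length(rates)))
  Q <- matrix(0, k, k)
  if (constraint == "ER") {
    Q[] <- rates[1]
  } else if (constraint == "SYM") {
    idx <- 1L
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      Q[i, j] <- Q[j, i] <- rates[idx]
      idx <- idx + 1L
    }
  } else {
    idx <- 1L
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (i == j) next
      Q[i, j] <- rates[idx]
      idx <- idx + 1L
    }
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

#' Number of free rates under an Mk constraint
#' @inheritParams mkQ
#' @return Integer parameter count.
#' @export
mkParamCount <- function(constraint = c("ER", "SYM", "ARD"), k = 3) {
  constraint <- match.arg(constraint)
  switch(constraint, ER = 1L, SYM = as.integer(k * (k - 1) / 2),
         ARD = as.integer(k * (k - 1)))
}

# matrix exponential by scaling-and-squaring (truncated series); fallback
# for generators whose eigendecomposition is ill-conditioned
.expmSS <- function(A) {
  nrm <- max(abs(A))
  d <- nrow(A)
  if (nrm == 0) return(diag(d))
  s <- max(0L, ceiling(log2(nrm)) + 1L)
  As <- A / 2^s
  E <- diag(d)
  term <- diag(d)
  for (i in 1:16) {
    term <- term %*% As / i
    E <- E + term
  }
  for (i in seq_len(s)) E <- E %*% E
  E
}

# factory returning t -> exp(Qt); eigendecomposition computed once,
# scaling-and-squaring used when the eigenvector basis is near-defective
.qExpFactory <- function(Q) {
  dec <- tryCatch({
    e <- eigen(Q)
    Vi <- solve(e$vectors)
    list(values = e$values, V = e$vectors, Vi = Vi)
  }, error = function(e) NULL)
  ok <- !is.null(dec) &&
    all(is.finite(Mod(dec$Vi))) &&
    max(Mod(dec$Vi)) < 1e12
  if (ok) {
    function(t) {
      M <- Re(dec$V %*% (exp(dec$values * t) * dec$Vi))
      M[M < 0] <- 0
      M
    }
  } else {
    function(t) {
      M <- .expmSS(Q * t)
      M[M < 0] <- 0
      M
    }
  }
}

# normalize tip-state input into an integer vector 1..k named by species;
# NA (or "?") means unknown -> uniform partial likelihood
.checkStates <- function(states, tree, k) {
  if (is.null(names(states))) stop("tip states must be named by species")
  if (is.character(states)) states[states == "?"] <- NA
  st <- suppressWarnings(as.integer(states))
  names(st) <- names(states)
  missing <- setdiff(tree$tip.label, names(st))
  if (length(missing) > 0)
    stop("no state for tip(s): ", paste(missing, collapse = ", "))
  st <- st[tree$tip.label]
  bad <- !is.na(st) & (st < 1 | st > k)
  if (any(bad))
    stop("state outside 1..", k, " for: ",
         paste(names(st)[bad], collapse = ", "))
  st
}

.rootPrior <- function(Q, root_prior) {
  k <- nrow(Q)
  if (root_prior == "uniform") return(rep(1 / k, k))
  # stationary distribution: left null vector of Q
  e <- eigen(t(Q))
  i <- which.min(abs(e$values))
  p <- abs(Re(e$vectors[, i]))
  p / sum(p)
}

# shared pruning engine; returns partials, per-edge P matrices and scalers
.mkPrune <- function(tree, states, Q, root_prior) {
  k <- nrow(Q)
  st <- .checkStates(states, tree, k)
  if (any(tree$edge.length < 0)) stop("negative branch length")
  po <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  E <- po$edge
  len <- po$edge.length
  Pfun <- .qExpFactory(Q)
  L <- matrix(1, ntip + nnode, k)
  for (i in seq_len(ntip))
    L[i, ] <- if (is.na(st[i])) rep(1, k) else as.numeric(seq_len(k) == st[i])
  Pmats <- vector("list", nrow(E))
  Smats <- matrix(NA_real_, nrow(E), k)   # per-edge S = P %*% (scaled child)
  logcomp <- 0
  scaled <- L
  for (e in seq_len(nrow(E))) {
    p <- E[e, 1]; ch <- E[e, 2]
    v <- scaled[ch, ]
    s <- sum(v)
    if (!is.finite(s) || s <= 0) return(NULL)
    logcomp <- logcomp + log(s)
    P <- Pfun(len[e])
    Pmats[[e]] <- P
    Sv <- as.vector(P %*% (v / s))
    Smats[e, ] <- Sv
    scaled[p, ] <- scaled[p, ] * Sv
  }
  root <- E[nrow(E), 1]
  prior <- .rootPrior(Q, root_prior)
  list(edge = E, len = len, P = Pmats, S = Smats, partials = scaled,
       logcomp = logcomp, root = root, prior = prior, ntip = ntip,
       nnode = nnode, k = k)
}

#' Mk-model log-likelihood by Felsenstein pruning
#'
#' Computes the log-likelihood of observed tip states under a continuous-time
#' Markov model with generator `Q`, using per-edge transition matrices
#' `exp(Qt)`, per-node rescaling for underflow protection, and a root prior.
#' Polytomies are handled natively by the product over all children.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param states Named vector of tip states in `1..k`; `NA` (or `"?"`) marks
#'   an unknown state (uniform partial likelihood).
#' @param Q Generator matrix (e.g. from [mkQ()]).
#' @param root_prior `"uniform"` (default, 1/k per state) or `"stationary"`.
#' @return Log-likelihood (scalar).
#' @export
mkLoglik <- function(tree, states, Q, root_prior = c("uniform", "stationary")) {
  root_prior <- match.arg(root_prior)
  pr <- .mkPrune(tree, states, Q, root_prior)
  if (is.null(pr)) return(-Inf)
  lik <- sum(pr$prior * pr$partials[pr$root, ])
  if (!is.finite(lik) || lik <= 0) return(-Inf)
  pr$logcomp + log(lik)
}

#' Fit a constrained Mk model by maximum likelihood
#'
#' Multi-start bounded optimization of the constrained rates in log space.
#' AICc uses `n = ` number of tips (the sample unit for a single character).
#'
#' @inheritParams mkLoglik
#' @param constraint `"ER"`, `"SYM"` or `"ARD"`.
#' @param nstart Number of jittered optimizer restarts.
#' @param seed Optional seed for the restarts.
#' @param lower,upper Rate bounds.
#' @return An [evoFit()] with the fitted rates and the fitted `Q` in
#'   `$details$Q`.
#' @export
fitMkModel <- function(tree, states, constraint = c("ER", "SYM", "ARD"),
                       root_prior = c("uniform", "stationary"), nstart = 3,
                       seed = NULL, lower = 1e-8, upper = 1e3) {
  constraint <- match.arg(constraint)
  root_prior <- match.arg(root_prior)
  if (!is.null(seed)) set.seed(seed)
  k <- 3L
  st <- .checkStates(states, tree, k)
  np <- mkParamCount(constraint, k)
  ntip <- length(tree$tip.label)
  obs <- unique(st[!is.na(st)])
  boundary <- length(obs) < 2
  if (boundary)
    warning("fewer than 2 observed states: likelihood is flat, ",
            "returning boundary (near-zero) rates")
  negll <- function(logr) {
    Q <- mkQ(exp(logr), constraint, k)
    ll <- mkLoglik(tree, st, Q, root_prior)
    if (!is.finite(ll)) 1e10 else -ll
  }
  # coarse profile over a common rate magnitude picks the starting scale
  # (guards the box-constrained optimizer against its first step shooting
  # to a boundary of the flat high-rate plateau)
  grid <- exp(seq(log(lower * 10), log(upper / 10), length.out = 12))
  gv <- vapply(grid, function(r) negll(rep(log(r), np)), numeric(1))
  r0 <- grid[which.min(gv)]
  best <- NULL
  conv <- FALSE
  if (boundary) {
    par <- rep(log(lower), np)
    best <- list(par = par, value = negll(par))
    conv <- TRUE
  } else {
    for (i in seq_len(nstart)) {
      start <- log(r0) + if (i == 1) rep(0, np) else rnorm(np, 0, 1)
      start <- pmin(pmax(start, log(lower)), log(upper))
      fit <- tryCatch(
        optim(start, negll, method = "L-BFGS-B", lower = log(lower),
              upper = log(upper), control = list(maxit = 500)),
        error = function(e) NULL)
      if (is.null(fit)) next
      if (is.null(best) || fit$value < best$value) {
        best <- fit
        conv <- fit$convergence == 0
      }
    }
    if (is.null(best)) stop("Mk optimization failed for all starts")
  }
  rates <- exp(best$par)
  names(rates) <- .mkRateNames(constraint, k)
  Q <- mkQ(rates, constraint, k)
  evoFit(model = constraint, estimates = rates, lnL = -best$value, k = np,
         n = ntip, convergence = conv,
         details = list(Q = Q, root_prior = root_prior,
                        boundary = boundary))
}

.mkRateNames <- function(constraint, k) {
  if (constraint == "ER") return("rate")
  nm <- character(0)
  if (constraint == "SYM") {
    for (i in seq_len(k - 1)) for (j in (i + 1):k)
      nm <- c(nm, sprintf("q%d%d", i, j))
  } else {
    for (i in seq_len(k)) for (j in seq_len(k))
      if (i != j) nm <- c(nm, sprintf("q%d%d", i, j))
  }
  nm
}

#' Marginal ancestral character estimation
#'
#' Node-by-node marginal state probabilities under a fitted Mk model,
#' combining the downward (pruning) pass with an upward pass — equivalent to
#' rerooting at every node. Each row sums to one.
#'
#' @inheritParams mkLoglik
#' @return Matrix of state probabilities, one row per internal node; row
#'   names are ape node ids (`ntip + 1 ... ntip + nnode`, root first).
#' @export
marginalAce <- function(tree, states, Q,
                        root_prior = c("uniform", "stationary")) {
  root_prior <- match.arg(root_prior)
  pr <- .mkPrune(tree, states, Q, root_prior)
  if (is.null(pr)) stop("likelihood underflowed to zero")
  k <- pr$k
  nn <- pr$ntip + pr$nnode
  G <- matrix(NA_real_, nn, k)
  G[pr$root, ] <- pr$prior
  E <- pr$edge
  # children-of lookup (edge indices by parent)
  kids <- split(seq_len(nrow(E)), E[, 1])
  for (e in rev(seq_len(nrow(E)))) {   # preorder: parents before children
    p <- E[e, 1]; ch <- E[e, 2]
    sib <- setdiff(kids[[as.character(p)]], e)
    H <- G[p, ]
    for (s in sib) H <- H * pr$S[s, ]
    g <- as.vector(crossprod(pr$P[[e]], H))
    sg <- sum(g)
    G[ch, ] <- if (sg > 0) g / sg else rep(1 / k, k)
  }
  nodes <- (pr$ntip + 1):nn
  out <- matrix(NA_real_, length(nodes), k,
                dimnames = list(nodes, paste0("P", seq_len(k))))
  for (i in seq_along(nodes)) {
    v <- G[nodes[i], ] * pr$partials[nodes[i], ]
    out[i, ] <- v / sum(v)
  }
  out
}
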