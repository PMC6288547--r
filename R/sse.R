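#' Multi-state speciation-extinction model
#'
#' Rates for a k-state MuSSE model: per-state speciation (`lambda`,
#' events/Myr), per-state extinction (`mu`), and a transition matrix `q`
#' whose off-diagonal entries are the state-change rates.
#'
#' @param lambda Speciation rates (length k).
#' @param mu Extinction rates (length k).
#' @param q k-by-k matrix of transition rates (diagonal ignored).
#' @return An object of class `musseModel`.
#' @export
musseModel <- function(lambda, mu, q) {
  k <- length(lambda)
  stopifnot(length(mu) == k, is.matrix(q), all(dim(q) == k))
  if (any(lambda < 0) || any(mu < 0)) stop("rates must be >= 0")
  qq <- q; diag(qq) <- 0
  if (any(qq < 0)) stop("transition rates must be >= 0")
  structure(list(lambda = lambda, mu = mu, q = qq, k = k),
            class = "musseModel")
}

#' SSE derivatives (pure R reference)
#'
#' The coupled D/E system of the state-dependent birth-death process, with
#' time running from the tips (t = 0) toward the root:
#' `dE_i/dt = mu_i - (lam_i + mu_i + sum_j q_ij) E_i + lam_i E_i^2 + sum_j q_ij E_j`
#' and
#' `dD_i/dt = -(lam_i + mu_i + sum_j q_ij) D_i + 2 lam_i E_i D_i + sum_j q_ij D_j`.
#'
#' @param t Time (unused; the system is autonomous).
#' @param y State vector `c(E_1..E_k, D_1..D_k)`.
#' @param model A [musseModel()].
#' @return Derivative vector of length 2k.
#' @export
sseDerivatives <- function(t, y, model) {
  k <- model$k
  E <- y[seq_len(k)]
  D <- y[k + seq_len(k)]
  qs <- rowSums(model$q)
  s <- model$lambda + model$mu + qs
  dE <- model$mu - s * E + model$lambda * E^2 + as.vector(model$q %*% E)
  dD <- -s * D + 2 * model$lambda * E * D + as.vector(model$q %*% D)
  c(dE, dD)
}

#' Integrate the SSE system along a branch
#'
#' Adaptive Dormand-Prince 5(4) integration (compiled), falling back to
#' `deSolve::lsoda` if step-size control fails.
#'
#' @param model A [musseModel()].
#' @param y0 Initial state `c(E, D)` at `t0`.
#' @param t0,t1 Integration limits, time measured from the tips.
#' @param rtol,atol Relative and absolute tolerances.
#' @return State vector at `t1`.
#' @export
sseIntegrate <- function(model, y0, t0, t1, rtol = 1e-8, atol = 1e-10) {
  if (t1 <= t0) return(y0)
  out <- .sse_branch_cpp(y0, t0, t1, model$lambda, model$mu, model$q,
                         rtol, atol)
  if (!is.null(out)) return(as.numeric(out))
  res <- deSolve::lsoda(y = y0, times = c(t0, t1),
                        func = function(t, y, p) list(sseDerivatives(t, y, p)),
                        parms = model, rtol = rtol, atol = atol)
  as.numeric(res[2, -1])
}

#' MuSSE log-likelihood
#'
#' Joint likelihood of tree shape and tip states under a multi-state
#' speciation-extinction model, by per-branch ODE integration of the D/E
#' system, node products `D_i <- lambda_i * D_i(left) * D_i(right)` with
#' per-node renormalization, and a choice of root treatment: `"obs"`
#' weights states by the data-driven (D-squared-normalized) weights,
#' `"flat"` averages over states. Survival conditioning divides by the
#' standard `lambda (1 - E_root)^2` term under the same weights. Complete
#' sampling is assumed; polytomies are rejected.
#'
#' @param tree Strictly bifurcating rooted `phylo` (ultrametric expected;
#'   deviations beyond tolerance draw a warning).
#' @param states Named tip states in `1..k` (`NA` = unknown).
#' @param model A [musseModel()].
#' @param root Root treatment, `"obs"` (default) or `"flat"`.
#' @param condition_surv Condition the likelihood on clade survival
#'   (off by default).
#' @param renormalize Rescale D at every node (on by default; switchable
#'   only to audit the bookkeeping on small trees).
#' @param rtol,atol Per-branch integration tolerances.
#' @return Log-likelihood (scalar).
#' @export
musseLoglik <- function(tree, states, model, root = c("obs", "flat"),
                        condition_surv = FALSE, renormalize = TRUE,
                        rtol = 1e-8, atol = 1e-10) {
  root <- match.arg(root)
  stopifnot(inherits(model, "musseModel"))
  dat <- .musseData(tree, states, model$k)
  if (renormalize) {
    out <- .musse_lnl_cpp(dat$edge, dat$t_node, dat$tipD, model$lambda,
                          model$mu, model$q,
                          if (root == "obs") 0L else 1L,
                          condition_surv, rtol, atol)
    if (!is.null(out)) return(as.numeric(out))
  }
  .musseLoglikR(dat, model, root, condition_surv, renormalize, rtol, atol)
}

# preprocess tree + states once (shared by the likelihood paths and the
# optimizer, which evaluates the likelihood thousands of times)
.musseData <- function(tree, states, k) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.binary(tree))
    stop("MuSSE requires a strictly bifurcating tree (polytomy found)")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  st <- .checkStates(states, tree, k)
  ntip <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  H <- max(depth[seq_len(ntip)])
  tfromtip <- H - depth
  if (H > 0 && max(tfromtip[seq_len(ntip)]) > 1e-6 * H)
    warning("tree is not ultrametric within tolerance; ",
            "tip times are treated as the present")
  po <- ape::reorder.phylo(tree, "postorder")
  tipD <- matrix(1, ntip, k)
  for (i in seq_len(ntip))
    if (!is.na(st[i])) tipD[i, ] <- as.numeric(seq_len(k) == st[i])
  list(edge = po$edge, t_node = tfromtip, tipD = tipD, ntip = ntip,
       nnode = tree$Nnode)
}

# pure-R traversal (stiff-capable through deSolve; also used to audit the
# renormalization bookkeeping)
.musseLoglikR <- function(dat, model, root, condition_surv, renormalize,
                          rtol, atol) {
  k <- model$k
  ntip <- dat$ntip
  E <- dat$edge
  tfromtip <- dat$t_node
  nn <- ntip + dat$nnode
  Emat <- matrix(NA_real_, nn, k)
  Dmat <- matrix(NA_real_, nn, k)
  Emat[seq_len(ntip), ] <- 0
  Dmat[seq_len(ntip), ] <- dat$tipD
  seen <- rep(FALSE, nn)
  logcomp <- 0
  for (e in seq_len(nrow(E))) {
    p <- E[e, 1]; ch <- E[e, 2]
    y0 <- c(Emat[ch, ], Dmat[ch, ])
    y1 <- sseIntegrate(model, y0, tfromtip[ch], tfromtip[p], rtol, atol)
    Ei <- y1[seq_len(k)]; Di <- y1[k + seq_len(k)]
    if (any(!is.finite(Di))) return(-Inf)
    if (!seen[p]) {
      Emat[p, ] <- Ei
      Dmat[p, ] <- Di
      seen[p] <- TRUE
    } else {
      Dmat[p, ] <- model$lambda * Dmat[p, ] * Di
      if (renormalize) {
        s <- sum(Dmat[p, ])
        if (!is.finite(s) || s <= 0) return(-Inf)
        Dmat[p, ] <- Dmat[p, ] / s
        logcomp <- logcomp + log(s)
      }
    }
  }
  rootnode <- E[nrow(E), 1]
  Dr <- Dmat[rootnode, ]
  Er <- Emat[rootnode, ]
  w <- if (root == "obs") {
    sD <- sum(Dr)
    if (sD <= 0) return(-Inf)
    Dr / sD
  } else rep(1 / k, k)
  L <- sum(w * Dr)
  if (condition_surv) {
    denom <- sum(w * model$lambda * (1 - Er)^2)
    if (denom <= 0) return(-Inf)
    L <- L / denom
  }
  if (!is.finite(L) || L <= 0) return(-Inf)
  log(L) + logcomp
}

# ---- the 15-model constraint family -----------------------------------

.mussePattern <- function(id, lam, mu, q, lam_label, mu_label, q_label) {
  npar <- length(unique(lam)) +
    (if (is.null(mu)) 0L else length(unique(mu))) +
    (if (q == "free") 6L else 1L)
  list(id = id, lam = lam, mu = mu, q = q, npar = npar,
       labels = c(speciation = lam_label, extinction = mu_label,
                  transition = q_label))
}

#' The 15-model MuSSE constraint family
#'
#' Constraint patterns over the three architectural states
#' (1 = Monocaulous, 2 = Intermediate, 3 = Branched): every combination of
#' equal/distinct speciation rates (including the three two-class
#' speciation groupings), equal/distinct/zero extinction rates, and
#' equal/distinct transition rates used in the diversification analysis.
#'
#' @return Named list of 15 constraint patterns; each has `id`, speciation
#'   equality classes `lam`, extinction classes `mu` (`NULL` = fixed at 0),
#'   transition pattern `q` (`"equal"`/`"free"`) and the free-parameter
#'   count `npar`.
#' @export
musseModelFamily <- function() {
  P <- .mussePattern
  fam <- list(
    P("1",  c(1, 2, 3), c(1, 2, 3), "free",  "distinct", "distinct", "distinct"),
    P("2",  c(1, 1, 1), c(1, 1, 1), "equal", "equal", "equal", "equal"),
    P("3",  c(1, 2, 3), c(1, 1, 1), "equal", "distinct", "equal", "equal"),
    P("4",  c(1, 2, 3), c(1, 2, 3), "equal", "distinct", "distinct", "equal"),
    P("5",  c(1, 2, 3), c(1, 1, 1), "free",  "distinct", "equal", "distinct"),
    P("6",  c(1, 1, 1), c(1, 1, 1), "free",  "equal", "equal", "distinct"),
    P("7",  c(1, 1, 1), c(1, 2, 3), "free",  "equal", "distinct", "distinct"),
    P("8a", c(1, 1, 2), c(1, 1, 1), "equal", "M = I; B", "equal", "equal"),
    P("8b", c(1, 2, 2), c(1, 1, 1), "equal", "I = B; M", "equal", "equal"),
    P("8c", c(1, 2, 1), c(1, 1, 1), "equal", "M = B; I", "equal", "equal"),
    P("9a", c(1, 1, 2), NULL,       "equal", "M = I; B", "0", "equal"),
    P("9b", c(1, 2, 2), NULL,       "equal", "I = B; M", "0", "equal"),
    P("9c", c(1, 2, 1), NULL,       "equal", "M = B; I", "0", "equal"),
    P("10", c(1, 1, 1), NULL,       "equal", "equal", "0", "equal"),
    P("11", c(1, 2, 3), NULL,       "equal", "distinct", "0", "equal")
  )
  names(fam) <- vapply(fam, function(p) p$id, character(1))
  fam
}

# project a fitted full-rate model onto a pattern's free parameters
# (class means), giving a warm start whose likelihood is close to the
# source fit whenever the pattern can express it
.musseProject <- function(pattern, model) {
  lam <- vapply(seq_len(max(pattern$lam)), function(cl)
    mean(model$lambda[pattern$lam == cl]), numeric(1))
  mu <- if (is.null(pattern$mu)) numeric(0)
  else vapply(seq_len(max(pattern$mu)), function(cl)
    mean(model$mu[pattern$mu == cl]), numeric(1))
  off <- model$q[row(model$q) != col(model$q)]
  q <- if (pattern$q == "equal") mean(off)
  else as.vector(t(model$q))[as.vector(t(row(model$q) != col(model$q)))]
  pmax(c(lam, mu, q), 1e-8)
}

# expand a free-parameter vector into a musseModel under a pattern
.musseBuild <- function(pattern, par) {
  nl <- length(unique(pattern$lam))
  lam <- par[pattern$lam]
  used <- nl
  if (is.null(pattern$mu)) {
    mu <- rep(0, 3)
  } else {
    nm <- length(unique(pattern$mu))
    mu <- par[used + pattern$mu]
    used <- used + nm
  }
  qpar <- par[(used + 1):length(par)]
  q <- matrix(0, 3, 3)
  if (pattern$q == "equal") {
    q[] <- qpar[1]
  } else {
    idx <- 1L
    for (i in 1:3) for (j in 1:3) {
      if (i == j) next
      q[i, j] <- qpar[idx]; idx <- idx + 1L
    }
  }
  diag(q) <- 0
  musseModel(lam, mu, q)
}

#' Fit one constrained MuSSE model
#'
#' Multi-start maximum likelihood in log-rate space with box constraints,
#' starting from birth-death moment estimates.
#'
#' @inheritParams musseLoglik
#' @param pattern One element of [musseModelFamily()] (or its id).
#' @param nstart Number of optimizer restarts.
#' @param seed Optional seed for the restarts.
#' @param lower,upper Rate bounds.
#' @param extra_starts Optional list of additional rate-space start vectors
#'   (used by [fitMusseFamily()] to warm-start richer models from the fits
#'   of models nested within them).
#' @return An [evoFit()]; full expanded rates in `$details$model`.
#' @export
fitMusseModel <- function(tree, states, pattern, root = c("obs", "flat"),
                          condition_surv = FALSE, nstart = 3, seed = NULL,
                          lower = 1e-8, upper = 1e3, rtol = 1e-8,
                          atol = 1e-10, extra_starts = list()) {
  root <- match.arg(root)
  if (is.character(pattern)) pattern <- musseModelFamily()[[pattern]]
  if (is.null(pattern)) stop("unknown model pattern")
  if (!is.null(seed)) set.seed(seed)
  ntip <- length(tree$tip.label)
  if (ntip < 10)
    warning("fewer than 10 tips: state-dependent rates are weakly identified")
  H <- max(ape::node.depth.edgelength(tree))
  r0 <- max(log(max(ntip, 3) / 2) / H, 0.05)
  nl <- length(unique(pattern$lam))
  nm <- if (is.null(pattern$mu)) 0L else length(unique(pattern$mu))
  nq <- if (pattern$q == "free") 6L else 1L
  st0 <- c(rep(1.2 * r0, nl), rep(0.2 * r0, nm), rep(0.5 / H, nq))
  dat <- .musseData(tree, states, 3L)
  rmode <- if (root == "obs") 0L else 1L
  negll <- function(logpar) {
    m <- .musseBuild(pattern, exp(logpar))
    ll <- .musse_lnl_cpp(dat$edge, dat$t_node, dat$tipD, m$lambda, m$mu,
                         m$q, rmode, condition_surv, rtol, atol)
    if (is.null(ll))
      ll <- .musseLoglikR(dat, m, root, condition_surv, TRUE, rtol, atol)
    ll <- as.numeric(ll)
    if (!is.finite(ll)) 1e10 else -ll
  }
  starts <- list(log(st0))
  for (i in seq_len(max(0, nstart - 1)))
    starts[[length(starts) + 1]] <- log(st0) + rnorm(length(st0), 0, 0.8)
  for (es in extra_starts)
    if (length(es) == length(st0)) starts[[length(starts) + 1]] <- log(es)
  best <- NULL; conv <- FALSE
  for (start in starts) {
    start <- pmin(pmax(start, log(lower)), log(upper))
    fit <- tryCatch(
      optim(start, negll, method = "L-BFGS-B", lower = log(lower),
            upper = log(upper), control = list(maxit = 300, factr = 1e7)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) {
      best <- fit; conv <- fit$convergence == 0
    }
  }
  if (is.null(best)) stop("MuSSE optimization failed for all starts")
  par <- exp(best$par)
  nmv <- c(paste0("lambda", seq_len(nl)),
           if (nm > 0) paste0("mu", seq_len(nm)),
           if (nq == 1) "q" else .mkRateNames("ARD", 3))
  names(par) <- nmv
  m <- .musseBuild(pattern, par)
  evoFit(model = pattern$id, estimates = par, lnL = -best$value,
         k = pattern$npar, n = ntip, convergence = conv,
         details = list(model = m, pattern = pattern, root = root,
                        condition_surv = condition_surv))
}

#' Fit the whole MuSSE model family
#'
#' Fits every constraint pattern, recording per-model failures without
#' aborting the family, and assembles the ranking table in the layout of
#' the diversification analysis (model, rate patterns, k, lnL, AICc,
#' delta-AICc).
#'
#' @inheritParams fitMusseModel
#' @param family List of patterns (default [musseModelFamily()]).
#' @return List with `fits` (named list of [evoFit()]), `table`
#'   (ranking data.frame), `best` (selected fit) and `failed` (character).
#' @export
fitMusseFamily <- function(tree, states, family = musseModelFamily(),
                           root = c("obs", "flat"), condition_surv = FALSE,
                           nstart = 2, seed = NULL, rtol = 1e-8,
                           atol = 1e-10) {
  root <- match.arg(root)
  if (!is.null(seed)) set.seed(seed)
  fits <- list(); failed <- character(0)
  # fit simple models first and warm-start richer ones from the fitted
  # rates of models nested within them (also stabilizes the likelihood
  # monotonicity across the constraint hierarchy)
  ord <- order(vapply(family, function(p) p$npar, numeric(1)))
  for (p in family[ord]) {
    extras <- list()
    if (length(fits) > 0) {
      lnls <- vapply(fits, function(f) f$lnL, numeric(1))
      for (src in unique(c(which.max(lnls), length(lnls))))
        extras[[length(extras) + 1]] <-
          .musseProject(p, fits[[src]]$details$model)
    }
    f <- tryCatch(
      fitMusseModel(tree, states, p, root = root,
                    condition_surv = condition_surv, nstart = nstart,
                    rtol = rtol, atol = atol, extra_starts = extras),
      error = function(e) {
        warning("model ", p$id, " failed: ", conditionMessage(e))
        NULL
      })
    if (is.null(f)) failed <- c(failed, p$id) else fits[[p$id]] <- f
  }
  fits <- fits[intersect(names(family), names(fits))]
  if (length(fits) == 0) stop("every model in the family failed")
  tab <- aicTable(fits)
  lab <- t(vapply(family[tab$model], function(p) p$labels, character(3)))
  tab <- cbind(tab[, "model", drop = FALSE], as.data.frame(lab),
               tab[, c("k", "lnL", "AICc", "dAICc")])
  rownames(tab) <- NULL
  list(fits = fits, table = tab, best = selectModel(fits), failed = failed)
}
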