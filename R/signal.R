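#' Species-level trait observations with intraspecific variation
#'
#' @param species Character vector of species names (must match tree tips).
#' @param mean Species trait means.
#' @param var Within-species variances (0 = no measurement error).
#' @param n Number of individuals per species.
#' @return `data.frame` with columns species, mean, var, n.
#' @export
traitObservation <- function(species, mean, var = 0, n = 1) {
  d <- data.frame(species = as.character(species), mean = mean,
                  var = var, n = n, stringsAsFactors = FALSE)
  if (anyDuplicated(d$species)) stop("duplicate species")
  if (any(d$var < 0)) stop("within-species variance must be >= 0")
  if (any(d$n < 1)) stop("n must be >= 1")
  d
}

# covariance of the species in `obs`, rows/cols in obs order
.obsCov <- function(tree, obs) {
  C <- phyloVcv(tree)
  missing <- setdiff(obs$species, rownames(C))
  if (length(missing) > 0)
    stop("species not on tree: ", paste(missing, collapse = ", "))
  C[obs$species, obs$species, drop = FALSE]
}

# Gaussian GLS machinery: -2*lnL pieces for x ~ N(a*1, V)
.glsLoglik <- function(x, V) {
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  n <- length(x)
  ones <- rep(1, n)
  z1 <- backsolve(R, ones, transpose = TRUE)
  zx <- backsolve(R, x, transpose = TRUE)
  a <- sum(z1 * zx) / sum(z1 * z1)
  r <- zx - a * z1
  list(lnL = -0.5 * (sum(r^2) + 2 * sum(log(diag(R))) + n * log(2 * pi)),
       mean = a, R = R)
}

#' Brownian-motion log-likelihood with measurement error
#'
#' Multivariate-normal log-likelihood of species means under Brownian motion
#' on the lambda-transformed tree, with mean equal to the phylogenetic (GLS)
#' mean and covariance `sigma2 * C_lambda + diag(var / n)`.
#'
#' @param tree Rooted `phylo`.
#' @param obs A [traitObservation()] table.
#' @param sigma2 Brownian rate (> 0).
#' @param lambda Pagel's lambda in \[0, 1\].
#' @return Log-likelihood (scalar); `-Inf` for a singular covariance.
#' @export
bmLoglik <- function(tree, obs, sigma2, lambda = 1) {
  stopifnot(sigma2 > 0)
  C <- .obsCov(tree, obs)
  V <- sigma2 * lambdaTransform(C, lambda) + diag(obs$var / obs$n,
                                                  nrow = nrow(obs))
  g <- .glsLoglik(obs$mean, V)
  if (is.null(g)) return(-Inf)
  g$lnL
}

# profile sigma2 by 1-D optimization at fixed lambda; returns lnL and sigma2
.bmProfile <- function(x, C, se2, lambda) {
  Cl <- lambdaTransform(C, lambda)
  D <- diag(se2, nrow = length(x))
  if (all(se2 == 0)) {
    # closed form: sigma2_hat = r' Cl^-1 r / n
    g0 <- .glsLoglik(x, Cl)
    if (is.null(g0)) return(NULL)
    R <- g0$R
    ones <- rep(1, length(x))
    z1 <- backsolve(R, ones, transpose = TRUE)
    zx <- backsolve(R, x, transpose = TRUE)
    a <- sum(z1 * zx) / sum(z1 * z1)
    q <- sum((zx - a * z1)^2)
    n <- length(x)
    s2 <- q / n
    if (s2 <= 0) {
      # degenerate (constant) data: pin the rate at a floor
      s2 <- 1e-12
      g <- .glsLoglik(x, s2 * Cl)
      return(list(lnL = g$lnL, sigma2 = s2))
    }
    lnL <- -0.5 * (n + n * log(2 * pi) + n * log(s2) + 2 * sum(log(diag(R))))
    return(list(lnL = lnL, sigma2 = s2))
  }
  f <- function(ls) {
    g <- .glsLoglik(x, exp(ls) * Cl + D)
    if (is.null(g)) 1e10 else -g$lnL
  }
  s0 <- var(x) / max(mean(diag(C)), .Machine$double.eps)
  s0 <- max(s0, 1e-10)
  op <- optimize(f, interval = log(s0) + c(-12, 12))
  list(lnL = -op$objective, sigma2 = exp(op$minimum))
}

#' Pagel's lambda with intraspecific variation
#'
#' Maximum-likelihood estimate of lambda (and the Brownian rate) for species
#' means with known within-species sampling variances. The p-value is a
#' likelihood-ratio test against `lambda = 0` referred to a 50:50 mixture of
#' chi-squared with 0 and 1 df (the boundary-corrected reference).
#'
#' @inheritParams bmLoglik
#' @param unbounded Allow lambda above 1 up to the matrix-feasible maximum.
#' @return A `signalResult` list: statistic, estimate, lnL, p_value,
#'   n_species, settings, convergence.
#' @export
pagelLambda <- function(tree, obs, unbounded = FALSE) {
  if (nrow(obs) < 4) stop("need at least 4 species")
  C <- .obsCov(tree, obs)
  x <- obs$mean
  se2 <- obs$var / obs$n
  if (sd(x) == 0) {
    warning("constant trait: lambda is undefined")
    return(structure(list(statistic = "lambda", estimate = NA_real_,
                          lnL = NA_real_, p_value = NA_real_,
                          n_species = nrow(obs), convergence = FALSE,
                          settings = list(unbounded = unbounded)),
                     class = "signalResult"))
  }
  lam_max <- 1
  if (unbounded) {
    off <- C; diag(off) <- NA
    dd <- sqrt(outer(diag(C), diag(C)))
    ratio <- dd / abs(off)
    lam_max <- max(1, min(ratio, na.rm = TRUE) * 0.999)
  }
  prof <- function(lam) {
    p <- .bmProfile(x, C, se2, lam)
    if (is.null(p)) -1e10 else p$lnL
  }
  op <- optimize(function(l) -prof(l), interval = c(0, lam_max), tol = 1e-8)
  # guard against local optima at the edges of the interval
  cand <- c(op$minimum, 0, lam_max)
  lls <- vapply(cand, prof, numeric(1))
  lam_hat <- cand[which.max(lls)]
  lnL1 <- max(lls)
  lnL0 <- prof(0)
  stat <- max(0, 2 * (lnL1 - lnL0))
  p <- if (stat == 0) 1 else 0.5 * pchisq(stat, df = 1, lower.tail = FALSE)
  fit <- .bmProfile(x, C, se2, lam_hat)
  structure(list(statistic = "lambda", estimate = lam_hat, lnL = lnL1,
                 lnL0 = lnL0, sigma2 = fit$sigma2, p_value = p,
                 n_species = nrow(obs), convergence = is.finite(lnL1),
                 settings = list(unbounded = unbounded, lam_max = lam_max)),
            class = "signalResult")
}

#' Blomberg's K with intraspecific variation
#'
#' `K = (MSE0/MSE)_observed / (MSE0/MSE)_expected`, where `MSE0` uses
#' deviations from the phylogenetic mean, `MSE` the covariance-whitened
#' deviations, and the expectation is `(tr(V) - n / (1' V^-1 1)) / (n - 1)`.
#' When within-species variances are supplied, the working covariance is the
#' error-adjusted `C + D / sigma2_hat` with `sigma2_hat` the ML Brownian
#' rate. Significance is a tip-label permutation test: the p-value is the
#' inclusive proportion of permutations whose whitened MSE is at most the
#' observed one.
#'
#' @inheritParams bmLoglik
#' @param nperm Number of permutations (at least 99).
#' @param seed Optional seed for the permutations.
#' @return A `signalResult` list.
#' @export
blombergK <- function(tree, obs, nperm = 999, seed = NULL) {
  if (nrow(obs) < 4) stop("need at least 4 species")
  if (nperm < 99) stop("nperm must be at least 99")
  if (!is.null(seed)) set.seed(seed)
  C <- .obsCov(tree, obs)
  x <- obs$mean
  se2 <- obs$var / obs$n
  n <- length(x)
  has_se <- any(se2 > 0)
  if (has_se) {
    fit <- .bmProfile(x, C, se2, 1)
    if (is.null(fit)) stop("singular covariance")
    s2 <- fit$sigma2
  } else s2 <- NA_real_
  kstat <- function(xv, sev) {
    V <- if (has_se) C + diag(sev / s2, nrow = n) else C
    g <- .glsLoglik(xv, V)
    if (is.null(g)) return(NULL)
    r <- xv - g$mean
    mse0 <- sum(r^2) / (n - 1)
    w <- backsolve(g$R, r, transpose = TRUE)
    mse <- sum(w^2) / (n - 1)
    ones <- rep(1, n)
    z1 <- backsolve(g$R, ones, transpose = TRUE)
    expected <- (sum(diag(V)) - n / sum(z1^2)) / (n - 1)
    list(K = (mse0 / mse) / expected, mse = mse)
  }
  ob <- kstat(x, se2)
  if (is.null(ob)) stop("singular covariance")
  hits <- 0L
  for (b in seq_len(nperm)) {
    idx <- sample.int(n)
    pb <- kstat(x[idx], se2[idx])
    if (!is.null(pb) && pb$mse <= ob$mse) hits <- hits + 1L
  }
  p <- (1 + hits) / (1 + nperm)
  structure(list(statistic = "K", estimate = ob$K, p_value = p,
                 n_species = n, sigma2 = s2, convergence = TRUE,
                 settings = list(nperm = nperm, seed = seed)),
            class = "signalResult")
}

#' @export
print.signalResult <- function(x, ...) {
  cat(sprintf("Phylogenetic signal (%s): estimate = %.4f, p = %.4g, n = %d\n",
              x$statistic, x$estimate, x$p_value, x$n_species))
  invisible(x)
}
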