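#' Bivariate phylogenetic regression with intraspecific variation
#'
#' Maximum-likelihood fit of the bivariate Brownian model: the stacked
#' observations (x, y) are multivariate normal with block covariance
#' `[[sx2*C + Dx, r*sx*sy*C], [r*sx*sy*C, sy2*C + Dy]]`, where `Dx`, `Dy`
#' are diagonal within-species sampling variances and `C` the
#' phylogenetic covariance. The evolutionary regression slope is
#' `beta = r * sy / sx`. Species means are profiled out by GLS at every
#' parameter value; the free parameters are the two Brownian rates and the
#' evolutionary correlation `r` (fixed at 0 when constrained).
#'
#' @param tree Rooted `phylo`.
#' @param x_obs,y_obs [traitObservation()] tables for predictor and response.
#' @param constrain_slope_zero Fit the nested model with the evolutionary
#'   correlation fixed at zero.
#' @param nstart Number of optimizer restarts for the full model.
#' @param seed Optional seed for the restarts.
#' @return A `pglsFit` list: beta, intercept, r, sigma2_x, sigma2_y, means,
#'   lnL, n_species, species, convergence.
#' @export
fitPglsIves <- function(tree, x_obs, y_obs, constrain_slope_zero = FALSE,
                        nstart = 5, seed = NULL) {
  common <- intersect(x_obs$species, y_obs$species)
  common <- intersect(common, tree$tip.label)
  if (length(common) < 5) stop("need at least 5 species in common")
  common <- sort(common)
  xo <- x_obs[match(common, x_obs$species), ]
  yo <- y_obs[match(common, y_obs$species), ]
  C <- phyloVcv(tree)[common, common, drop = FALSE]
  n <- length(common)
  x <- xo$mean; y <- yo$mean
  dx <- xo$var / xo$n; dy <- yo$var / yo$n
  if (!is.null(seed)) set.seed(seed)

  mscale <- max(mean(diag(C)), .Machine$double.eps)
  s2x0 <- max(var(x) / mscale, 1e-10)
  s2y0 <- max(var(y) / mscale, 1e-10)

  if (constrain_slope_zero || sd(y) == 0 || sd(x) == 0) {
    if (sd(y) == 0 && !constrain_slope_zero)
      warning("constant response: slope is 0 by construction")
    px <- .bmProfile(x, C, dx, 1)
    py <- .bmProfile(y, C, dy, 1)
    if (is.null(px) || is.null(py)) stop("singular covariance")
    gx <- .glsLoglik(x, px$sigma2 * C + diag(dx, nrow = n))
    gy <- .glsLoglik(y, py$sigma2 * C + diag(dy, nrow = n))
    out <- list(beta = 0, intercept = gy$mean, r = 0,
                sigma2_x = px$sigma2, sigma2_y = py$sigma2,
                mu_x = gx$mean, mu_y = gy$mean,
                lnL = px$lnL + py$lnL, n_species = n, species = common,
                constrained = TRUE, convergence = TRUE)
    class(out) <- "pglsFit"
    return(out)
  }

  ones <- rep(1, n); zero <- rep(0, n)
  X <- cbind(c(ones, zero), c(zero, ones))
  obs2 <- c(x, y)
  negll <- function(par) {
    sx2 <- exp(par[1]); sy2 <- exp(par[2]); r <- tanh(par[3])
    cxy <- r * sqrt(sx2 * sy2)
    V <- rbind(cbind(sx2 * C + diag(dx, nrow = n), cxy * C),
               cbind(cxy * C, sy2 * C + diag(dy, nrow = n)))
    R <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(R)) return(1e10)
    Zx <- backsolve(R, X, transpose = TRUE)
    zo <- backsolve(R, obs2, transpose = TRUE)
    b <- tryCatch(solve(crossprod(Zx), crossprod(Zx, zo)),
                  error = function(e) NULL)
    if (is.null(b)) return(1e10)
    res <- zo - Zx %*% b
    0.5 * (sum(res^2) + 2 * sum(log(diag(R))) + 2 * n * log(2 * pi))
  }

  r0 <- suppressWarnings(cor(x, y))
  if (!is.finite(r0)) r0 <- 0
  r0 <- min(max(r0, -0.95), 0.95)
  # seed one start at the constrained (r = 0) solution so the full fit can
  # never fall below the nested model
  px0 <- .bmProfile(x, C, dx, 1)
  py0 <- .bmProfile(y, C, dy, 1)
  starts <- list(c(log(s2x0), log(s2y0), atanh(r0)),
                 c(log(px0$sigma2), log(py0$sigma2), 0))
  while (length(starts) < nstart)
    starts[[length(starts) + 1]] <-
      c(log(s2x0) + rnorm(1, 0, 0.7), log(s2y0) + rnorm(1, 0, 0.7),
        atanh(min(max(r0 + rnorm(1, 0, 0.3), -0.97), 0.97)))
  best <- NULL; conv <- FALSE
  for (s in starts[seq_len(nstart)]) {
    fit <- tryCatch(
      optim(s, negll, method = "L-BFGS-B",
            lower = c(-30, -30, -8), upper = c(30, 30, 8),
            control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) {
      best <- fit; conv <- fit$convergence == 0
    }
  }
  if (is.null(best)) stop("PGLS optimization failed for all starts")
  sx2 <- exp(best$par[1]); sy2 <- exp(best$par[2]); r <- tanh(best$par[3])
  # recover the profiled means at the optimum
  cxy <- r * sqrt(sx2 * sy2)
  V <- rbind(cbind(sx2 * C + diag(dx, nrow = n), cxy * C),
             cbind(cxy * C, sy2 * C + diag(dy, nrow = n)))
  R <- chol(V)
  Zx <- backsolve(R, X, transpose = TRUE)
  zo <- backsolve(R, obs2, transpose = TRUE)
  b <- solve(crossprod(Zx), crossprod(Zx, zo))
  beta <- r * sqrt(sy2 / sx2)
  out <- list(beta = beta, intercept = b[2] - beta * b[1], r = r,
              sigma2_x = sx2, sigma2_y = sy2, mu_x = b[1], mu_y = b[2],
              lnL = -best$value, n_species = n, species = common,
              constrained = FALSE, convergence = conv)
  class(out) <- "pglsFit"
  out
}

#' @export
print.pglsFit <- function(x, ...) {
  cat(sprintf(
    "Bivariate phylogenetic regression (%s): beta = %.4f, r = %.3f, lnL = %.3f, n = %d\n",
    if (x$constrained) "slope constrained to 0" else "full",
    x$beta, x$r, x$lnL, x$n_species))
  invisible(x)
}

#' Likelihood-ratio test of a zero evolutionary slope
#'
#' @param full Unconstrained [fitPglsIves()] fit.
#' @param constrained The matching fit with `constrain_slope_zero = TRUE`.
#' @return p-value from `P(chisq_1 >= 2 * (lnL_full - lnL_constrained))`;
#'   negative statistics are clipped to 0 with a warning.
#' @export
lrtSlopeZero <- function(full, constrained) {
  stopifnot(inherits(full, "pglsFit"), inherits(constrained, "pglsFit"))
  if (full$n_species != constrained$n_species ||
      !identical(full$species, constrained$species))
    stop("fits are not on the same data")
  if (!constrained$constrained)
    stop("'constrained' must be a slope-zero fit")
  stat <- 2 * (full$lnL - constrained$lnL)
  if (stat < 0) {
    warning("negative LRT statistic clipped to 0 (optimizer noise)")
    stat <- 0
  }
  if (stat == 0) return(1)
  pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Trait-by-trait phylogenetic regression table
#'
#' Fits one bivariate phylogenetic regression (trait on branching index) per
#' trait, with a slope-zero likelihood-ratio test, and assembles the results
#' in one table (log-likelihood, slope, p-value, species used). Species
#' missing for a trait are dropped for that trait only, and recorded.
#'
#' @param tree Rooted `phylo`.
#' @param index_obs [traitObservation()] for the integrative branching index.
#' @param traits Named list of [traitObservation()] tables, one per trait.
#' @param holm Add Holm-adjusted p-values (off by default; raw p-values are
#'   the primary output).
#' @param nstart Optimizer restarts passed to [fitPglsIves()].
#' @return `data.frame` with columns trait, n, logL, beta, p_value
#'   (and p_holm if requested).
#' @export
correlationTable <- function(tree, index_obs, traits, holm = FALSE,
                             nstart = 5) {
  if (length(traits) == 0)
    return(data.frame(trait = character(0), n = integer(0),
                      logL = numeric(0), beta = numeric(0),
                      p_value = numeric(0)))
  if (is.null(names(traits))) stop("'traits' must be a named list")
  rows <- lapply(names(traits), function(tr) {
    to <- traits[[tr]]
    common <- Reduce(intersect, list(to$species, index_obs$species,
                                     tree$tip.label))
    if (length(common) < 5) {
      message("trait '", tr, "': fewer than 5 species in common, skipped")
      return(data.frame(trait = tr, n = length(common), logL = NA_real_,
                        beta = NA_real_, p_value = NA_real_))
    }
    dropped <- setdiff(union(to$species, index_obs$species), common)
    if (length(dropped) > 0)
      message("trait '", tr, "': dropped ", length(dropped),
              " species without complete data (",
              paste(sort(dropped), collapse = ", "), ")")
    full <- fitPglsIves(tree, index_obs, to, nstart = nstart)
    con <- fitPglsIves(tree, index_obs, to, constrain_slope_zero = TRUE)
    p <- lrtSlopeZero(full, con)
    data.frame(trait = tr, n = full$n_species, logL = full$lnL,
               beta = full$beta, p_value = p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (holm) out$p_holm <- stats::p.adjust(out$p_value, method = "holm")
  out
}
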