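#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 lnL + 2k + 2k(k + 1)/(n - k - 1)`; returns `Inf` when the
#' correction term is undefined (`n <= k + 1`).
#'
#' @param lnL Maximized log-likelihood.
#' @param k Number of free parameters.
#' @param n Sample size (here, number of tips).
#' @return Numeric AICc.
#' @export
aicc <- function(lnL, k, n) {
  if (n - k - 1 <= 0) return(Inf)
  -2 * lnL + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Construct a model-fit record
#'
#' The unit of every model comparison in the package: parameter estimates,
#' log-likelihood, parameter count and AICc.
#'
#' @param model Model identifier (e.g. `"ER"`, `"2"`, `"8a"`).
#' @param estimates Named numeric vector of parameter estimates.
#' @param lnL Maximized log-likelihood.
#' @param k Number of free parameters.
#' @param n Sample size used for AICc.
#' @param convergence Logical optimizer-convergence flag.
#' @param details Free-form list (settings, seeds, labels).
#' @return An object of class `evoFit`.
#' @export
evoFit <- function(model, estimates, lnL, k, n, convergence = TRUE,
                   details = list()) {
  structure(list(model = model, estimates = estimates, lnL = lnL, k = k,
                 n = n, AICc = aicc(lnL, k, n), convergence = convergence,
                 details = details),
            class = "evoFit")
}

#' @export
print.evoFit <- function(x, ...) {
  cat(sprintf("Model fit '%s': lnL = %.4f, k = %d, n = %d, AICc = %.4f%s\n",
              x$model, x$lnL, x$k, x$n, x$AICc,
              if (x$convergence) "" else " (optimizer did not converge)"))
  if (length(x$estimates) > 0) {
    cat("Estimates:\n")
    print(round(x$estimates, 6))
  }
  invisible(x)
}

#' Model-comparison table
#'
#' @param fits List of [evoFit()] objects on identical data.
#' @return `data.frame` with model, k, lnL, AICc and delta-AICc, sorted by
#'   AICc (ties broken toward fewer parameters).
#' @export
aicTable <- function(fits) {
  if (length(fits) == 0) stop("empty fit list")
  tab <- data.frame(
    model = vapply(fits, function(f) as.character(f$model), character(1)),
    k = vapply(fits, function(f) f$k, numeric(1)),
    lnL = vapply(fits, function(f) f$lnL, numeric(1)),
    AICc = vapply(fits, function(f) f$AICc, numeric(1)),
    stringsAsFactors = FALSE
  )
  tab <- tab[order(tab$AICc, tab$k), , drop = FALSE]
  tab$dAICc <- tab$AICc - tab$AICc[1]
  rownames(tab) <- NULL
  tab
}

#' Select the best model by AICc
#'
#' Minimum AICc wins; exact ties are broken toward fewer parameters. The
#' comparison table is attached as attribute `"aic_table"`.
#'
#' @param fits List of [evoFit()] objects on identical data.
#' @return The selected `evoFit`.
#' @export
selectModel <- function(fits) {
  if (length(fits) == 0) stop("empty fit list")
  ns <- vapply(fits, function(f) f$n, numeric(1))
  if (length(unique(ns)) > 1)
    stop("fits were not computed on identical data (n differs)")
  aiccs <- vapply(fits, function(f) f$AICc, numeric(1))
  ks <- vapply(fits, function(f) f$k, numeric(1))
  best <- order(aiccs, ks)[1]
  out <- fits[[best]]
  attr(out, "aic_table") <- aicTable(fits)
  out
}
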