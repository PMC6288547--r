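#' PCA of the species-by-trait matrix
#'
#' Correlation-matrix PCA (z-scored columns) with a deterministic sign
#' convention: per component, the largest-magnitude loading is positive.
#' Constant trait columns are dropped with a message; rows with missing
#' values are dropped listwise with a message.
#'
#' @param table Numeric matrix or data.frame, species in rows (rownames),
#'   traits in columns.
#' @return An `ordinationResult` list: scores, loadings, var_explained,
#'   dropped_traits, dropped_species.
#' @export
pcaTraits <- function(table) {
  m <- as.matrix(table)
  if (is.null(rownames(m))) stop("species rownames are required")
  cc <- stats::complete.cases(m)
  dropped_sp <- rownames(m)[!cc]
  if (length(dropped_sp) > 0)
    message("dropping species with missing traits: ",
            paste(dropped_sp, collapse = ", "))
  m <- m[cc, , drop = FALSE]
  sds <- apply(m, 2, sd)
  dropped_tr <- colnames(m)[sds == 0]
  if (length(dropped_tr) > 0)
    message("dropping constant trait(s): ",
            paste(dropped_tr, collapse = ", "))
  m <- m[, sds > 0, drop = FALSE]
  if (nrow(m) < 3 || ncol(m) < 2)
    stop("need at least 3 complete species and 2 non-constant traits")
  p <- prcomp(m, center = TRUE, scale. = TRUE)
  for (j in seq_len(ncol(p$rotation))) {
    i <- which.max(abs(p$rotation[, j]))
    if (p$rotation[i, j] < 0) {
      p$rotation[, j] <- -p$rotation[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  structure(list(scores = p$x, loadings = p$rotation,
                 var_explained = p$sdev^2 / sum(p$sdev^2),
                 dropped_traits = dropped_tr, dropped_species = dropped_sp),
            class = "ordinationResult")
}

#' PERMANOVA of architectural classes in trait space
#'
#' Permutational multivariate analysis of variance on Euclidean distances
#' of z-scored traits: the pseudo-F comes from the among/within
#' sum-of-squares partition of the squared-distance matrix, and the p-value
#' is the inclusive proportion of free group-label permutations with
#' F at least as large as observed.
#'
#' @param table Species-by-trait matrix (rownames = species).
#' @param groups Class membership: factor or character named by species (or
#'   in row order).
#' @param nperm Number of permutations.
#' @param seed Optional seed for the permutations.
#' @return A `permanovaResult` list: F, R2, p_value, n, n_groups, nperm,
#'   seed.
#' @export
permanovaTraits <- function(table, groups, nperm = 999, seed = NULL) {
  m <- as.matrix(table)
  if (is.null(rownames(m))) stop("species rownames are required")
  if (!is.null(names(groups))) groups <- groups[rownames(m)]
  if (length(groups) != nrow(m)) stop("groups must match the table rows")
  cc <- stats::complete.cases(m) & !is.na(groups)
  if (any(!cc))
    message("dropping incomplete species: ",
            paste(rownames(m)[!cc], collapse = ", "))
  m <- m[cc, , drop = FALSE]
  g <- factor(as.character(groups[cc]))
  sizes <- vapply(levels(g), function(l) sum(g == l), numeric(1))
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(sizes < 2))
    stop("group(s) with fewer than 2 members: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  sds <- apply(m, 2, sd)
  m <- m[, sds > 0, drop = FALSE]
  z <- scale(m)
  D2 <- as.matrix(dist(z))^2
  n <- nrow(D2)
  a <- nlevels(g)
  fstat <- function(gv) {
    sst <- sum(D2) / (2 * n)
    ssw <- 0
    for (lev in levels(gv)) {
      idx <- which(gv == lev)
      ssw <- ssw + sum(D2[idx, idx]) / (2 * length(idx))
    }
    ssa <- sst - ssw
    c(F = (ssa / (a - 1)) / (ssw / (n - a)), R2 = ssa / sst)
  }
  ob <- fstat(g)
  if (!is.null(seed)) set.seed(seed)
  hits <- 0L
  for (b in seq_len(nperm)) {
    if (fstat(g[sample.int(n)])["F"] >= ob["F"]) hits <- hits + 1L
  }
  structure(list(F = unname(ob["F"]), R2 = unname(ob["R2"]),
                 p_value = (1 + hits) / (1 + nperm), n = n, n_groups = a,
                 nperm = nperm, seed = seed),
            class = "permanovaResult")
}

#' @export
print.permanovaResult <- function(x, ...) {
  cat(sprintf("PERMANOVA: F = %.4f, R2 = %.4f, p = %.4g (%d permutations, n = %d)\n",
              x$F, x$R2, x$p_value, x$nperm, x$n))
  invisible(x)
}
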