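#' One plant's trunk and branch measurements
#'
#' Container for the measurements the branching indexes need: trunk length,
#' the trunk's leaf areas, per-branch cumulated length and leaf areas for
#' the measured (representative) branches, and the branch census
#' `n_branches`. When only representative branches were measured,
#' per-branch means are extrapolated to the census total.
#'
#' @param species Species id.
#' @param trunk_length Trunk length (cm).
#' @param trunk_leaf_areas Numeric vector of trunk leaf areas (cm2); the
#'   full trunk complement (may be a single total).
#' @param branches List of branches, each a list with `cumulated_length`
#'   (cm) and `leaf_areas` (cm2 vector).
#' @param n_branches Branch census; must be 0 exactly when `branches` is
#'   empty, and at least the number measured otherwise.
#' @return An object of class `individualArchitecture`.
#' @export
individualArchitecture <- function(species, trunk_length, trunk_leaf_areas,
                                   branches = list(), n_branches = length(branches)) {
  if (trunk_length < 0) stop("trunk_length must be >= 0")
  if (any(trunk_leaf_areas < 0)) stop("leaf areas must be >= 0")
  for (b in branches) {
    if (is.null(b$cumulated_length) || b$cumulated_length < 0)
      stop("each branch needs cumulated_length >= 0")
    if (is.null(b$leaf_areas) || any(b$leaf_areas < 0))
      stop("each branch needs leaf_areas >= 0")
  }
  if ((n_branches == 0) != (length(branches) == 0))
    stop("n_branches must be 0 exactly when no branches are measured")
  if (length(branches) > 0 && n_branches < length(branches))
    stop("n_branches cannot be below the number of measured branches")
  structure(list(species = as.character(species),
                 trunk_length = trunk_length,
                 trunk_leaf_areas = trunk_leaf_areas,
                 branches = branches, n_branches = n_branches),
            class = "individualArchitecture")
}

.branchLeafArea <- function(ind) {
  if (ind$n_branches == 0) return(0)
  mean(vapply(ind$branches, function(b) sum(b$leaf_areas), numeric(1))) *
    ind$n_branches
}

.branchLength <- function(ind) {
  if (ind$n_branches == 0) return(0)
  mean(vapply(ind$branches, function(b) b$cumulated_length, numeric(1))) *
    ind$n_branches
}

#' Photosynthetic branching index
#'
#' Leaf area supported by branches divided by total leaf area
#' (branches + trunk). Zero for an unbranched (monocaulous) individual, one
#' when all leaves sit on branches.
#'
#' @param ind An [individualArchitecture()].
#' @return Value in \[0, 1\].
#' @export
photosyntheticIndex <- function(ind) {
  stopifnot(inherits(ind, "individualArchitecture"))
  bla <- .branchLeafArea(ind)
  total <- bla + sum(ind$trunk_leaf_areas)
  if (total <= 0) stop("total leaf area is zero: index undefined")
  bla / total
}

#' Exploration branching index
#'
#' Branch cumulated length divided by total stem length
#' (branches + trunk).
#'
#' @inheritParams photosyntheticIndex
#' @return Value in \[0, 1\].
#' @export
explorationIndex <- function(ind) {
  stopifnot(inherits(ind, "individualArchitecture"))
  bl <- .branchLength(ind)
  total <- bl + ind$trunk_length
  if (total <= 0) stop("total stem length is zero: index undefined")
  if (ind$trunk_length == 0)
    warning("zero trunk length with branches present: index degenerates to 1")
  bl / total
}

#' Per-individual branching indexes
#'
#' @param individuals List of [individualArchitecture()] objects.
#' @return `data.frame` with species, individual, photo, explo.
#' @export
branchingIndexTable <- function(individuals) {
  data.frame(
    species = vapply(individuals, function(i) i$species, character(1)),
    individual = seq_along(individuals),
    photo = vapply(individuals, photosyntheticIndex, numeric(1)),
    explo = vapply(individuals, explorationIndex, numeric(1)),
    stringsAsFactors = FALSE
  )
}

#' Integrative branching index (PC1 of the two raw indexes)
#'
#' Combines species means of the photosynthetic and exploration indexes by
#' correlation-scaled PCA. The PC1 sign is fixed so both loadings are
#' positive (higher score = more branched); when the two loadings cannot
#' share a sign the tie is broken by a positive photosynthetic loading. The
#' Spearman correlation of the two raw indexes is reported alongside.
#'
#' @param table `data.frame` with columns species, photo, explo (species
#'   means).
#' @return An `integrativeIndex` list: scores (named), loadings,
#'   var_explained, rho, and the centring/scaling used (for projecting
#'   individual-level values via [scoreIndividuals()]).
#' @export
integrativeIndex <- function(table) {
  stopifnot(all(c("species", "photo", "explo") %in% names(table)))
  if (nrow(table) < 3) stop("need at least 3 species")
  z <- cbind(table$photo, table$explo)
  cen <- colMeans(z)
  scl <- apply(z, 2, sd)
  if (any(scl == 0)) stop("constant index column: PCA is degenerate")
  zs <- sweep(sweep(z, 2, cen), 2, scl, "/")
  R <- cor(zs)
  e <- eigen(R, symmetric = TRUE)
  v <- e$vectors[, 1]
  if (all(v <= 0)) v <- -v
  if (v[1] < 0) v <- -v   # tie rule: photosynthetic loading positive
  scores <- as.vector(zs %*% v)
  names(scores) <- table$species
  structure(list(scores = scores,
                 loadings = setNames(v, c("photo", "explo")),
                 var_explained = e$values[1] / sum(e$values),
                 rho = cor(table$photo, table$explo, method = "spearman"),
                 center = setNames(cen, c("photo", "explo")),
                 scale = setNames(scl, c("photo", "explo"))),
            class = "integrativeIndex")
}

#' Project raw indexes onto the integrative axis
#'
#' Applies the species-level centring, scaling and PC1 loadings of an
#' [integrativeIndex()] to (typically individual-level) raw index values.
#'
#' @param index An [integrativeIndex()].
#' @param photo,explo Raw index values.
#' @return Numeric scores.
#' @export
scoreIndividuals <- function(index, photo, explo) {
  stopifnot(inherits(index, "integrativeIndex"))
  (photo - index$center["photo"]) / index$scale["photo"] * index$loadings["photo"] +
    (explo - index$center["explo"]) / index$scale["explo"] * index$loadings["explo"]
}

# compact letter display by insert-and-absorb over significant pairs;
# species indexed 1..n in rank order, sig is a logical matrix
.cld <- function(sig) {
  n <- nrow(sig)
  lets <- list(seq_len(n))
  pairs <- which(sig & upper.tri(sig), arr.ind = TRUE)
  if (nrow(pairs) > 0) {
    ord <- order(pairs[, 1], pairs[, 2])
    pairs <- pairs[ord, , drop = FALSE]
  }
  for (pi in seq_len(nrow(pairs))) {
    i <- pairs[pi, 1]; j <- pairs[pi, 2]
    hit <- which(vapply(lets, function(L) i %in% L && j %in% L, logical(1)))
    if (length(hit) == 0) next
    for (h in hit) {
      L <- lets[[h]]
      lets[[h]] <- setdiff(L, i)
      lets[[length(lets) + 1]] <- setdiff(L, j)
    }
    # absorb letters that are subsets of another
    keep <- rep(TRUE, length(lets))
    for (a in seq_along(lets)) for (b in seq_along(lets)) {
      if (a != b && keep[a] && keep[b] &&
          all(lets[[a]] %in% lets[[b]]) &&
          !(all(lets[[b]] %in% lets[[a]]) && a < b))
        keep[a] <- FALSE
    }
    lets <- lets[keep]
  }
  lets <- lets[order(vapply(lets, min, numeric(1)))]
  labels <- vapply(seq_len(n), function(s) {
    paste(letters[which(vapply(lets, function(L) s %in% L, logical(1)))],
          collapse = "")
  }, character(1))
  list(letters = labels, groups = lets)
}

#' Segregate species into architectural classes
#'
#' Species are ranked by mean integrative score; all species pairs are
#' compared by two-sample Wilcoxon rank-sum tests (exact null distribution
#' for small samples without ties, normal approximation with tie correction
#' otherwise) and summarized as a compact letter display at level `alpha`.
#' Classes are the `k` contiguous runs delimited by the `k - 1` strongest
#' significant breaks, a break being an adjacent ranked pair sharing no
#' letter; break strength is the pair's p-value, ties broken by the larger
#' score gap.
#'
#' @param scores Named list: species -> numeric vector of individual
#'   integrative scores (at least 2 per species).
#' @param alpha Significance level for the letter display (default 0.1).
#' @param k Number of classes to delimit (default 3).
#' @return List with `classes` (named factor, ordered low to high;
#'   levels Monocaulous/Intermediate/Branched when three classes are
#'   recovered with `k = 3`), `letters` (named), `breaks` (data.frame) and
#'   `means`.
#' @export
segregateClasses <- function(scores, alpha = 0.1, k = 3) {
  if (k < 2) stop("k must be at least 2")
  if (is.null(names(scores))) stop("'scores' must be named by species")
  nper <- vapply(scores, length, integer(1))
  if (any(nper < 2))
    stop("need at least 2 individuals per species: ",
         paste(names(scores)[nper < 2], collapse = ", "))
  means <- vapply(scores, mean, numeric(1))
  ord <- order(means)
  sp <- names(scores)[ord]
  n <- length(sp)
  pmat <- matrix(1, n, n, dimnames = list(sp, sp))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    p <- suppressWarnings(
      wilcox.test(scores[[sp[i]]], scores[[sp[j]]], exact = NULL,
                  correct = TRUE)$p.value)
    pmat[i, j] <- pmat[j, i] <- p
  }
  cld <- .cld(pmat < alpha)
  shares <- function(i, j) {
    any(vapply(cld$groups, function(L) i %in% L && j %in% L, logical(1)))
  }
  adj <- seq_len(n - 1)
  is_break <- !vapply(adj, function(i) shares(i, i + 1), logical(1))
  bdf <- data.frame(
    left = sp[adj], right = sp[adj + 1],
    p = pmat[cbind(adj, adj + 1)],
    gap = means[ord][adj + 1] - means[ord][adj],
    is_break = is_break
  )
  cand <- which(is_break)
  if (length(cand) < k - 1)
    warning(sprintf(
      "only %d significant break(s) detected (%d needed for k = %d classes)",
      length(cand), k - 1, k))
  picked <- cand[order(bdf$p[cand], -bdf$gap[cand])][seq_len(min(k - 1, length(cand)))]
  picked <- sort(picked)
  grp <- cumsum(seq_len(n) %in% (picked + 1)) + 1
  ngrp <- max(grp)
  levs <- if (ngrp == 3 && k == 3)
    c("Monocaulous", "Intermediate", "Branched")
  else paste0("class", seq_len(ngrp))
  classes <- factor(levs[grp], levels = levs, ordered = TRUE)
  names(classes) <- sp
  letters_out <- setNames(cld$letters, sp)
  list(classes = classes[names(scores)], letters = letters_out[names(scores)],
       breaks = bdf, means = means)
}

#' Derive the functional trait set from raw measurements
#'
#' Computes the 14 functional traits from one individual's (or one species'
#' averaged) raw primitives: slenderness ratio, specific wood and stem
#' densities, internode diameter (geometric mean of the min and max
#' measures, read as a diameter-unit summary of the tabulated min x max
#' product), internode length, tissue proportions, Huber value, mean and
#' specific leaf area, total leaf area, leaf number and fruit volume.
#' A zero denominator yields `NA` for that trait only, with a message.
#'
#' @param raw Named list or one-row data.frame with fields: height,
#'   basal_diameter, wood_dry_mass, wood_fresh_volume, stem_dry_mass,
#'   stem_fresh_volume, internode_d_min, internode_d_max, internode_l,
#'   area_pith, area_wood, area_cortex, area_section, wood_area_pom,
#'   leaf_area_above_pom, leaf_fresh_area, leaf_dry_mass, mean_la,
#'   n_trunk_leaves, trunk_mean_leaf_area, n_branches,
#'   branch_mean_leaf_number, branch_mean_leaf_area, fruit_length,
#'   fruit_width. Lengths cm, areas cm2, masses g, volumes cm3.
#' @return Named numeric vector of the 14 traits.
#' @export
deriveTraits <- function(raw) {
  raw <- as.list(raw)
  need <- c("area_pith", "area_wood", "area_cortex", "area_section")
  if (all(need %in% names(raw)) && !anyNA(raw[need])) {
    parts <- raw$area_pith + raw$area_wood + raw$area_cortex
    if (parts > raw$area_section * 1.01)
      stop("pith + wood + cortex area exceeds the whole section area ",
           "beyond 1% tolerance")
  }
  ratio <- function(num, den, trait) {
    if (is.null(num) || is.null(den) || is.na(num) || is.na(den)) return(NA_real_)
    if (den == 0) {
      message("trait '", trait, "': zero denominator, recorded as NA")
      return(NA_real_)
    }
    num / den
  }
  g <- function(f) if (is.null(raw[[f]])) NA_real_ else raw[[f]]
  c(
    sr = ratio(g("height"), g("basal_diameter"), "sr"),
    swd = ratio(g("wood_dry_mass"), g("wood_fresh_volume"), "swd"),
    ssd = ratio(g("stem_dry_mass"), g("stem_fresh_volume"), "ssd"),
    internode_d = sqrt(g("internode_d_min") * g("internode_d_max")),
    internode_l = g("internode_l"),
    p_pith = ratio(g("area_pith"), g("area_section"), "p_pith"),
    p_wood = ratio(g("area_wood"), g("area_section"), "p_wood"),
    p_cortex = ratio(g("area_cortex"), g("area_section"), "p_cortex"),
    hv = ratio(g("wood_area_pom"), g("leaf_area_above_pom"), "hv"),
    mean_la = g("mean_la"),
    sla = ratio(g("leaf_fresh_area"), g("leaf_dry_mass"), "sla"),
    total_la = g("branch_mean_leaf_area") * g("n_branches") +
      g("trunk_mean_leaf_area") * g("n_trunk_leaves"),
    nb_leaf = g("n_trunk_leaves") +
      g("branch_mean_leaf_number") * g("n_branches"),
    fruit_vol = g("fruit_length") * g("fruit_width")^2
  )
}

#' Read individuals from a long-format CSV
#'
#' One row per axis: columns `species`, `individual`, `axis_type`
#' (`"trunk"`/`"branch"`), `length_cm`, `total_leaf_area_cm2`, and on trunk
#' rows `n_branches_census`. Leaf areas are stored as per-axis totals.
#'
#' @param file CSV path.
#' @return List of [individualArchitecture()] objects.
#' @export
readIndividuals <- function(file) {
  d <- read.csv(file, stringsAsFactors = FALSE)
  need <- c("species", "individual", "axis_type", "length_cm",
            "total_leaf_area_cm2", "n_branches_census")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0)
    stop("individuals file misses column(s): ", paste(miss, collapse = ", "))
  key <- paste(d$species, d$individual)
  lapply(unique(key), function(kk) {
    di <- d[key == kk, , drop = FALSE]
    tr <- di[di$axis_type == "trunk", , drop = FALSE]
    if (nrow(tr) != 1)
      stop("individual '", kk, "' must have exactly one trunk row")
    br <- di[di$axis_type == "branch", , drop = FALSE]
    branches <- lapply(seq_len(nrow(br)), function(i)
      list(cumulated_length = br$length_cm[i],
           leaf_areas = br$total_leaf_area_cm2[i]))
    individualArchitecture(
      species = tr$species, trunk_length = tr$length_cm,
      trunk_leaf_areas = tr$total_leaf_area_cm2, branches = branches,
      n_branches = if (nrow(br) == 0) 0 else tr$n_branches_census)
  })
}

#' Write individuals to the long-format CSV
#'
#' @param individuals List of [individualArchitecture()] objects.
#' @param file Destination CSV path.
#' @return The path, invisibly.
#' @export
writeIndividuals <- function(individuals, file) {
  rows <- list()
  for (i in seq_along(individuals)) {
    ind <- individuals[[i]]
    rows[[length(rows) + 1]] <- data.frame(
      species = ind$species, individual = i, axis_type = "trunk",
      length_cm = ind$trunk_length,
      total_leaf_area_cm2 = sum(ind$trunk_leaf_areas),
      n_branches_census = ind$n_branches)
    for (b in ind$branches)
      rows[[length(rows) + 1]] <- data.frame(
        species = ind$species, individual = i, axis_type = "branch",
        length_cm = b$cumulated_length,
        total_leaf_area_cm2 = sum(b$leaf_areas),
        n_branches_census = NA_integer_)
  }
  write.csv(do.call(rbind, rows), file, row.names = FALSE)
  invisible(file)
}
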