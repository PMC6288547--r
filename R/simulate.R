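#' Default simulation settings for the synthetic study
#'
#' The defaults emulate the study conditions every stage assumes: a 27-tip
#' ultrametric crown clade of age 2.4 Myr (birth rate chosen so the
#' expected richness at that age is about 27), three architectural classes
#' of sizes 7 Monocaulous / 6 Intermediate / 14 Branched, class-level
#' branching-index targets (photosynthetic/exploration) of 0.82/0.76 for
#' Branched, 0.36/0.45 for Intermediate and 0.03/0.16 for Monocaulous,
#' beta-distributed species and individual values around those targets,
#' five individuals per species, and Brownian traits with replicate noise.
#'
#' @param n_species Number of extant species.
#' @param crown_age Crown age (Myr).
#' @param birth,death Birth-death rates (per Myr) of the tree simulator.
#' @param class_sizes Named sizes of the Monocaulous / Intermediate /
#'   Branched classes (must sum to `n_species`).
#' @param class_targets 3x2 matrix of class-level photo/explo means.
#' @param concentration_species Beta concentration of species-level index
#'   targets around their class mean.
#' @param concentration_individual Beta concentration of individual values
#'   around their species target.
#' @param cross_correlation Gaussian-copula correlation between a species'
#'   photosynthetic and exploration deviations (calibrated so the Spearman
#'   correlation of the two indexes across species is about 0.86).
#' @param n_individuals Individuals per species.
#' @param n_measures Measures (leaves, internodes) per individual.
#' @param trait_sigma2,trait_lambda,trait_within_sd Brownian rate, signal
#'   and replicate noise of the simulated functional traits.
#' @return A list of settings (class `simulationConfig`).
#' @export
simulationConfig <- function(n_species = 27, crown_age = 2.4, birth = 1.1,
                             death = 0,
                             class_sizes = c(Monocaulous = 7,
                                             Intermediate = 6,
                                             Branched = 14),
                             class_targets = rbind(
                               Monocaulous = c(photo = 0.03, explo = 0.16),
                               Intermediate = c(photo = 0.36, explo = 0.45),
                               Branched = c(photo = 0.82, explo = 0.76)),
                             concentration_species = 80,
                             concentration_individual = 120,
                             cross_correlation = 0.4,
                             n_individuals = 5, n_measures = 5,
                             trait_sigma2 = 0.5, trait_lambda = 1,
                             trait_within_sd = 0.4) {
  if (any(class_targets < 0) || any(class_targets > 1))
    stop("class means must lie in [0, 1]")
  if (birth < 0 || death < 0) stop("rates must be >= 0")
  structure(as.list(environment()), class = "simulationConfig")
}

#' Simulate a birth-death tree
#'
#' Either conditioned on the number of extant species (`n`; exact
#' conditioned sampling) or run forward to a fixed `time` (Gillespie
#' simulation; may lose the whole clade, in which case `NULL` is
#' returned). Extinct lineages are pruned; the tree can be rescaled to a
#' stated crown age.
#'
#' @param n Number of surviving species to condition on.
#' @param birth,death Speciation and extinction rates (per Myr).
#' @param time Fixed simulation time (used when `n` is `NULL`).
#' @param crown_age Optional crown age to rescale to.
#' @param seed Optional seed.
#' @return A `phylo` (ultrametric), or `NULL` when a fixed-time simulation
#'   loses the clade.
#' @export
simulateBdTree <- function(n = NULL, birth = 1, death = 0, time = NULL,
                           crown_age = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (birth <= 0) stop("birth rate must be positive")
  if (is.null(n) == is.null(time))
    stop("supply exactly one of 'n' or 'time'")
  if (!is.null(n)) {
    tr <- ape::rphylo(n, birth, death, fossils = FALSE)
  } else {
    lin <- .bdForward(birth, death, time,
                      rates = function(s) c(birth, death),
                      root_states = c(1L, 1L))
    tr <- .lineagesToTree(lin, time)
    if (is.null(tr)) return(NULL)
  }
  if (!is.null(crown_age)) {
    d <- max(tipDepths(tr))
    tr$edge.length <- tr$edge.length * crown_age / d
  }
  tr
}

# forward Gillespie birth-death(-mumble) simulation with per-lineage
# states; returns the lineage table (parent, state at end, birth/death
# times, children)
.bdForward <- function(birth, death, time, rates, root_states,
                       q = NULL, max_n = 100000) {
  parent <- integer(0); tbirth <- numeric(0); tend <- numeric(0)
  state <- integer(0); alive <- logical(0); extinct <- logical(0)
  for (s in root_states) {
    parent <- c(parent, 0L); tbirth <- c(tbirth, 0); tend <- c(tend, NA)
    state <- c(state, s); alive <- c(alive, TRUE); extinct <- c(extinct, FALSE)
  }
  t <- 0
  repeat {
    idx <- which(alive)
    if (length(idx) == 0) break
    if (length(idx) > max_n) break
    per <- vapply(idx, function(i) {
      r <- rates(state[i])
      qr <- if (is.null(q)) 0 else sum(q[state[i], -state[i]])
      r[1] + r[2] + qr
    }, numeric(1))
    tot <- sum(per)
    if (tot <= 0) break
    t <- t + rexp(1, tot)
    if (t >= time) break
    li <- idx[sample.int(length(idx), 1, prob = per)]
    s <- state[li]
    r <- rates(s)
    qrow <- if (is.null(q)) rep(0, 0) else q[s, ]
    qr <- if (is.null(q)) 0 else sum(qrow[-s])
    u <- runif(1) * (r[1] + r[2] + qr)
    if (u < r[1]) {
      # speciation: lineage ends, two daughters begin
      alive[li] <- FALSE; tend[li] <- t
      for (d in 1:2) {
        parent <- c(parent, li); tbirth <- c(tbirth, t); tend <- c(tend, NA)
        state <- c(state, s); alive <- c(alive, TRUE)
        extinct <- c(extinct, FALSE)
      }
    } else if (u < r[1] + r[2]) {
      alive[li] <- FALSE; extinct[li] <- TRUE; tend[li] <- t
    } else {
      others <- setdiff(seq_along(qrow), s)
      state[li] <- others[sample.int(length(others), 1,
                                     prob = qrow[others])]
    }
  }
  tend[alive] <- time
  data.frame(parent = parent, tbirth = tbirth, tend = tend, state = state,
             alive = alive, extinct = extinct)
}

# build a phylo from the forward-simulation lineage table, pruning extinct
# lineages; returns NULL when fewer than 2 lineages survive
.lineagesToTree <- function(lin, time) {
  surv <- which(lin$alive)
  if (length(surv) < 2) return(NULL)
  kids <- split(seq_len(nrow(lin)), lin$parent)
  tip_counter <- 0L
  nwk <- function(i) {
    ch <- kids[[as.character(i)]]
    len <- lin$tend[i] - lin$tbirth[i]
    if (is.null(ch)) {
      tip_counter <<- tip_counter + 1L
      sprintf("L%d:%.12g", i, len)
    } else {
      sprintf("(%s,%s):%.12g", nwk(ch[1]), nwk(ch[2]), len)
    }
  }
  roots <- which(lin$parent == 0L)
  txt <- sprintf("(%s,%s);", nwk(roots[1]), nwk(roots[2]))
  tr <- ape::read.tree(text = txt)
  dead <- tr$tip.label[!(as.integer(sub("^L", "", tr$tip.label)) %in% surv)]
  if (length(tr$tip.label) - length(dead) < 2) return(NULL)
  if (length(dead) > 0) tr <- ape::drop.tip(tr, dead)
  tr
}

#' Simulate a discrete character on a tree
#'
#' Exponential-waiting-time simulation of a continuous-time Markov chain
#' along every branch; the true internal-node states are returned for
#' scoring ancestral-state estimates.
#'
#' @param tree Rooted `phylo`.
#' @param Q Generator matrix.
#' @param root_state Root state (default: drawn uniformly).
#' @param seed Optional seed.
#' @return List with `tip_states` (named) and `node_states`.
#' @export
simulateMkStates <- function(tree, Q, root_state = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- nrow(Q)
  ntip <- length(tree$tip.label)
  if (is.null(root_state)) root_state <- sample.int(k, 1)
  po <- ape::reorder.phylo(tree, "postorder")
  E <- po$edge; len <- po$edge.length
  nn <- ntip + tree$Nnode
  states <- rep(NA_integer_, nn)
  states[E[nrow(E), 1]] <- as.integer(root_state)
  for (e in rev(seq_len(nrow(E)))) {    # preorder
    s <- states[E[e, 1]]
    t <- 0
    repeat {
      rate <- -Q[s, s]
      if (rate <= 0) break
      w <- rexp(1, rate)
      if (t + w > len[e]) break
      t <- t + w
      others <- setdiff(seq_len(k), s)
      s <- others[sample.int(k - 1, 1, prob = Q[s, others])]
    }
    states[E[e, 2]] <- s
  }
  list(tip_states = setNames(states[seq_len(ntip)], tree$tip.label),
       node_states = states[(ntip + 1):nn])
}

#' Joint forward simulation of state-dependent diversification
#'
#' Gillespie simulation of cladogenesis, extinction and state change under
#' a [musseModel()], conditioned on the number of surviving species by
#' rejection; extinct lineages are pruned.
#'
#' @param model A [musseModel()].
#' @param n Number of surviving species to condition on.
#' @param root_state Root state (default: drawn uniformly).
#' @param time Simulation horizon; defaults to the time at which the
#'   expected richness under the model's average net diversification
#'   equals `n`.
#' @param seed Optional seed.
#' @param max_tries Rejection limit.
#' @return List with `tree` (ultrametric `phylo`), `tip_states` (named)
#'   and the generating `model`.
#' @export
simulateMusseTree <- function(model, n, root_state = NULL, time = NULL,
                              seed = NULL, max_tries = 1000) {
  stopifnot(inherits(model, "musseModel"))
  if (!is.null(seed)) set.seed(seed)
  k <- model$k
  if (is.null(time)) {
    r <- mean(model$lambda) - mean(model$mu)
    if (r <= 0) stop("non-positive mean net diversification: supply 'time'")
    time <- log(n / 2) / r
  }
  pure_birth <- all(model$mu == 0)
  for (try in seq_len(max_tries)) {
    rs <- if (is.null(root_state)) sample.int(k, 1) else root_state
    lin <- .bdForward(birth = NA, death = NA, time = time,
                      rates = function(s) c(model$lambda[s], model$mu[s]),
                      root_states = c(rs, rs), q = model$q,
                      max_n = if (pure_birth) n + 1 else 50 * n)
    if (sum(lin$alive) != n) next
    tr <- .lineagesToTree(lin, time)
    if (is.null(tr) || length(tr$tip.label) != n) next
    ids <- as.integer(sub("^L", "", tr$tip.label))
    st <- setNames(lin$state[ids], tr$tip.label)
    tr$tip.label <- sprintf("t%d", seq_along(tr$tip.label))
    names(st) <- tr$tip.label
    return(list(tree = tr, tip_states = st, model = model,
                root_state = rs))
  }
  stop("failed to obtain ", n, " survivors in ", max_tries, " tries")
}

#' Simulate Brownian traits with replicate noise
#'
#' Species values evolve by Brownian motion on the lambda-transformed
#' covariance; individual replicates add iid normal noise. Both the
#' species-level summary and the raw replicates are returned.
#'
#' @param tree Rooted `phylo`.
#' @param sigma2 Brownian rate (> 0).
#' @param lambda Phylogenetic signal of the generating process.
#' @param within_sd Within-species replicate standard deviation.
#' @param n_per_species Replicates per species.
#' @param mean Root (ancestral) trait value.
#' @param seed Optional seed.
#' @return List with `obs` (a [traitObservation()]), `replicates` (matrix)
#'   and `species_values` (the true species means).
#' @export
simulateBmTraits <- function(tree, sigma2 = 1, lambda = 1, within_sd = 0,
                             n_per_species = 5, mean = 0, seed = NULL) {
  stopifnot(sigma2 > 0)
  if (!is.null(seed)) set.seed(seed)
  C <- phyloVcv(tree)
  Cl <- lambdaTransform(C, lambda)
  n <- nrow(Cl)
  R <- chol(sigma2 * Cl + diag(1e-12, n))
  z <- mean + as.vector(t(R) %*% rnorm(n))
  names(z) <- rownames(Cl)
  reps <- matrix(rnorm(n * n_per_species, mean = rep(z, n_per_species),
                       sd = within_sd),
                 nrow = n, ncol = n_per_species)
  rownames(reps) <- names(z)
  obs <- traitObservation(
    species = names(z),
    mean = if (within_sd > 0) rowMeans(reps) else z,
    var = if (within_sd > 0) apply(reps, 1, var) else 0,
    n = n_per_species)
  list(obs = obs, replicates = reps, species_values = z)
}

#' Generate per-individual architectural measurements
#'
#' Draws species-level photosynthetic and exploration index targets from
#' beta distributions around the class means (a Gaussian copula correlates
#' the two within a species), then individual-level indexes around the
#' species target, and finally constructs trunk/branch measurements whose
#' computed indexes reproduce those values: trunk length and leaf set, a
#' branch census, and two representative measured branches.
#'
#' @param classes Named factor/character: species -> architectural class
#'   (levels Monocaulous / Intermediate / Branched).
#' @param config A [simulationConfig()].
#' @param seed Optional seed.
#' @return List of [individualArchitecture()] objects
#'   (`length(classes) * n_individuals`).
#' @export
generateArchitectureIndividuals <- function(classes,
                                            config = simulationConfig(),
                                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(names(classes))) stop("'classes' must be named by species")
  cls <- as.character(classes)
  if (!all(cls %in% rownames(config$class_targets)))
    stop("unknown class label(s)")
  kappa_s <- config$concentration_species
  kappa_i <- config$concentration_individual
  rho <- config$cross_correlation
  # class-dependent scale parameters for the constructed measurements
  leaf_area_mean <- c(Monocaulous = 90, Intermediate = 40, Branched = 15)
  census_mean <- c(Monocaulous = 4, Intermediate = 12, Branched = 30)
  out <- list()
  for (s in seq_along(classes)) {
    tg <- config$class_targets[cls[s], ]
    zc <- rnorm(1)
    zp <- rho * zc + sqrt(1 - rho^2) * rnorm(1)
    ze <- rho * zc + sqrt(1 - rho^2) * rnorm(1)
    photo_s <- qbeta(pnorm(zp), tg["photo"] * kappa_s,
                     (1 - tg["photo"]) * kappa_s)
    explo_s <- qbeta(pnorm(ze), tg["explo"] * kappa_s,
                     (1 - tg["explo"]) * kappa_s)
    for (i in seq_len(config$n_individuals)) {
      p <- rbeta(1, photo_s * kappa_i, (1 - photo_s) * kappa_i)
      e <- rbeta(1, explo_s * kappa_i, (1 - explo_s) * kappa_i)
      p <- min(max(p, 1e-4), 0.999)
      e <- min(max(e, 1e-4), 0.999)
      trunk_len <- rlnorm(1, log(150), 0.2)
      n_br <- max(2L, as.integer(round(rlnorm(1, log(census_mean[cls[s]]),
                                              0.25))))
      branch_total_len <- e / (1 - e) * trunk_len
      la <- leaf_area_mean[cls[s]]
      trunk_leaves <- rlnorm(config$n_measures, log(la), 0.25)
      n_trunk_leaves <- 10
      trunk_area_total <- mean(trunk_leaves) * n_trunk_leaves
      branch_area_total <- p / (1 - p) * trunk_area_total
      per_branch_len <- branch_total_len / n_br
      per_branch_area <- branch_area_total / n_br
      branches <- lapply(1:2, function(b)
        list(cumulated_length = per_branch_len,
             leaf_areas = rep(per_branch_area / config$n_measures,
                              config$n_measures)))
      out[[length(out) + 1]] <- individualArchitecture(
        species = names(classes)[s],
        trunk_length = trunk_len,
        trunk_leaf_areas = rep(trunk_area_total / n_trunk_leaves,
                               n_trunk_leaves),
        branches = branches, n_branches = n_br)
    }
  }
  out
}
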