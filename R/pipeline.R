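#' Simulate a complete synthetic study
#'
#' Builds every input the full analysis consumes: an ultrametric tree,
#' architectural classes placed on it with phylogenetic clustering (a
#' Brownian liability ranks species; the lowest ranks become Monocaulous,
#' then Intermediate, then Branched, with the configured class sizes),
#' per-individual architectural measurements, species-level discrete
#' states, and a 14-trait table in which several traits covary with the
#' branching liability while the rest are pure Brownian noise.
#'
#' @param config A [simulationConfig()].
#' @param seed Master seed; every component is re-seeded from it.
#' @return List: tree, classes (named factor), individuals, traits (named
#'   list of [traitObservation()]), states (named integer,
#'   1 = Monocaulous .. 3 = Branched), liability, trait_spec.
#' @export
simulateStudy <- function(config = simulationConfig(), seed = 1) {
  tree <- simulateBdTree(n = config$n_species, birth = config$birth,
                         death = config$death,
                         crown_age = config$crown_age, seed = seed)
  lia <- simulateBmTraits(tree, sigma2 = 1, lambda = 1, within_sd = 0,
                          seed = seed + 1)$species_values
  sizes <- config$class_sizes
  if (sum(sizes) != config$n_species)
    stop("class sizes must sum to n_species")
  ord <- names(sort(lia))
  cls <- factor(rep(names(sizes), times = sizes),
                levels = c("Monocaulous", "Intermediate", "Branched"),
                ordered = TRUE)
  names(cls) <- ord
  cls <- cls[tree$tip.label]
  individuals <- generateArchitectureIndividuals(cls, config,
                                                 seed = seed + 2)
  # 14 functional traits: slopes against the (scaled) branching liability,
  # signs following the field expectation (branched species: smaller
  # leaves and fruit, thinner internodes, higher SLA and Huber value)
  trait_spec <- data.frame(
    trait = c("sr", "swd", "ssd", "internode_d", "internode_l", "p_pith",
              "p_wood", "p_cortex", "hv", "mean_la", "sla", "total_la",
              "nb_leaf", "fruit_vol"),
    slope = c(-1.5, 0, 0, -0.8, 0, 0, -0.6, 0, 1.2, -1.0, 0.8, 0, 1.0,
              -0.8),
    stringsAsFactors = FALSE)
  zl <- as.vector(scale(lia[tree$tip.label]))
  traits <- list()
  for (i in seq_len(nrow(trait_spec))) {
    sim <- simulateBmTraits(tree, sigma2 = config$trait_sigma2,
                            lambda = config$trait_lambda,
                            within_sd = config$trait_within_sd,
                            n_per_species = config$n_individuals,
                            seed = seed + 10 + i)
    obs <- sim$obs
    shift <- trait_spec$slope[i] * zl[match(obs$species, tree$tip.label)]
    obs$mean <- obs$mean + shift
    traits[[trait_spec$trait[i]]] <- obs
  }
  states <- setNames(as.integer(cls), names(cls))
  list(tree = tree, classes = cls, individuals = individuals,
       traits = traits, states = states, liability = lia,
       trait_spec = trait_spec, config = config, seed = seed)
}

#' Write a synthetic study bundle to disk
#'
#' Dumps the bundle in the same formats the analysis consumes: Newick tree,
#' long-format individuals CSV, long-format trait CSV
#' (species, trait, mean, var, n) and a species/state CSV.
#'
#' @param study Output of [simulateStudy()].
#' @param dir Destination directory (created if needed).
#' @return Named paths, invisibly.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(tree = file.path(dir, "tree.nwk"),
             individuals = file.path(dir, "individuals.csv"),
             traits = file.path(dir, "traits.csv"),
             states = file.path(dir, "states.csv"))
  writeNewick(study$tree, paths["tree"])
  writeIndividuals(study$individuals, paths["individuals"])
  tl <- do.call(rbind, lapply(names(study$traits), function(tr) {
    o <- study$traits[[tr]]
    data.frame(species = o$species, trait = tr, mean = o$mean,
               var = o$var, n = o$n)
  }))
  write.csv(tl, paths["traits"], row.names = FALSE)
  write.csv(data.frame(species = names(study$states),
                       state = study$states),
            paths["states"], row.names = FALSE)
  invisible(paths)
}

#' Analysis configuration
#'
#' One declarative object holding the input paths and every analytical
#' choice the analysis leaves open, each with its documented default.
#'
#' @param tree,individuals,traits,states Input file paths (Newick,
#'   long-format individuals CSV, long-format trait CSV, species/state
#'   CSV; `states` may be `NULL` to use the classes recovered from the
#'   indexes).
#' @param out_dir Output directory.
#' @param alpha Significance level for class segregation.
#' @param nperm Permutations for Blomberg's K and PERMANOVA.
#' @param seed Master seed; each stochastic stage is re-seeded from it.
#' @param k_classes Number of architectural classes.
#' @param fit_musse Fit the MuSSE family (the slowest stage).
#' @param sse_root,sse_condition Root treatment and survival conditioning
#'   for the MuSSE stage.
#' @param root_prior Root prior for the Mk stage.
#' @param nstart Optimizer restarts for the fitting stages.
#' @return A list of class `analysisConfig`.
#' @export
analysisConfig <- function(tree, individuals, traits, states = NULL,
                           out_dir, alpha = 0.1, nperm = 999, seed = 1,
                           k_classes = 3, fit_musse = TRUE,
                           sse_root = "obs", sse_condition = FALSE,
                           root_prior = "uniform", nstart = 3) {
  structure(list(tree = tree, individuals = individuals, traits = traits,
                 states = states, out_dir = out_dir, alpha = alpha,
                 nperm = nperm, seed = seed, k_classes = k_classes,
                 fit_musse = fit_musse, sse_root = sse_root,
                 sse_condition = sse_condition, root_prior = root_prior,
                 nstart = nstart),
            class = "analysisConfig")
}

.readTraitsLong <- function(file) {
  d <- read.csv(file, stringsAsFactors = FALSE)
  need <- c("species", "trait", "mean", "var", "n")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0)
    stop("trait file misses column(s): ", paste(miss, collapse = ", "))
  out <- lapply(split(d, d$trait), function(di)
    traitObservation(di$species, di$mean, di$var, di$n))
  out[unique(d$trait)]
}

#' Validate analysis inputs (report-only)
#'
#' Checks file existence, formats, species-name concordance across inputs
#' and tree ultrametricity, without mutating anything. Name mismatches are
#' reported exhaustively, not first-failure.
#'
#' @param config An [analysisConfig()].
#' @return `data.frame` with columns severity (`"error"`/`"warning"`) and
#'   message; zero rows when everything checks out.
#' @export
validateInputs <- function(config) {
  issues <- data.frame(severity = character(0), message = character(0))
  add <- function(sev, msg)
    issues <<- rbind(issues, data.frame(severity = sev, message = msg))
  paths <- c(tree = config$tree, individuals = config$individuals,
             traits = config$traits)
  if (!is.null(config$states)) paths <- c(paths, states = config$states)
  for (nm in names(paths))
    if (!file.exists(paths[nm]))
      add("error", sprintf("%s file not found: %s", nm, paths[nm]))
  if (nrow(issues) > 0) return(issues)
  tree <- tryCatch(readNewick(file = config$tree), error = function(e) {
    add("error", paste("tree:", conditionMessage(e))); NULL
  })
  inds <- tryCatch(readIndividuals(config$individuals), error = function(e) {
    add("error", paste("individuals:", conditionMessage(e))); NULL
  })
  traits <- tryCatch(.readTraitsLong(config$traits), error = function(e) {
    add("error", paste("traits:", conditionMessage(e))); NULL
  })
  if (is.null(tree) || is.null(inds) || is.null(traits)) return(issues)
  if (!isUltrametric(tree))
    add("warning", "tree is not ultrametric within tolerance (advisory)")
  tiplab <- tree$tip.label
  indsp <- unique(vapply(inds, function(i) i$species, character(1)))
  for (bad in setdiff(indsp, tiplab))
    add("error", sprintf("species in individuals but not on tree: %s", bad))
  for (tr in names(traits))
    for (bad in setdiff(traits[[tr]]$species, tiplab))
      add("error",
          sprintf("species in trait '%s' but not on tree: %s", tr, bad))
  if (!is.null(config$states)) {
    std <- read.csv(config$states, stringsAsFactors = FALSE)
    if (!all(c("species", "state") %in% names(std))) {
      add("error", "states file needs columns species,state")
    } else {
      for (bad in setdiff(std$species, tiplab))
        add("error", sprintf("species in states but not on tree: %s", bad))
    }
  }
  issues
}

# tiny stable config hash (FNV-1a over the serialized settings)
.configHash <- function(config) {
  s <- jsonlite::toJSON(config[sort(names(config))], auto_unbox = TRUE,
                        digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 2166136261
  for (b in bytes) h <- (bitwXor(h, b) * 16777619) %% 2^32
  sprintf("%08x", h)
}

#' Run the full analysis
#'
#' Orchestrates every stage behind one configuration: per-individual
#' branching indexes and class segregation, phylogenetic signal table,
#' phylogenetic-regression table, Mk ancestral-state estimation with AICc
#' model choice, the MuSSE model family, and trait-space ordination with
#' PERMANOVA. Every output is written under `out_dir` together with a run
#' manifest (seeds, settings, config hash); any stage failure halts with
#' the stage name while earlier outputs are preserved.
#'
#' @param config An [analysisConfig()].
#' @return Invisibly, a list with every stage result and the manifest.
#' @export
runFullAnalysis <- function(config) {
  issues <- validateInputs(config)
  errs <- issues$message[issues$severity == "error"]
  if (length(errs) > 0)
    stop("input validation failed:\n  ", paste(errs, collapse = "\n  "))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outp <- function(f) file.path(config$out_dir, f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  res <- list()
  tree <- readNewick(file = config$tree)
  inds <- readIndividuals(config$individuals)
  traits <- .readTraitsLong(config$traits)

  # 1. indexes and classes
  res$indexes <- stage("indexes", {
    bt <- branchingIndexTable(inds)
    spmean <- aggregate(cbind(photo, explo) ~ species, bt, mean)
    iix <- integrativeIndex(spmean)
    bt$score <- scoreIndividuals(iix, bt$photo, bt$explo)
    seg <- segregateClasses(split(bt$score, bt$species),
                            alpha = config$alpha, k = config$k_classes)
    tab <- data.frame(
      species = spmean$species, photo = spmean$photo,
      explo = spmean$explo,
      score = iix$scores[spmean$species],
      letters = seg$letters[spmean$species],
      class = as.character(seg$classes[spmean$species]))
    tab <- tab[order(tab$score), ]
    write.csv(tab, outp("indexes_classes.csv"), row.names = FALSE)
    list(table = tab, index = iix, segregation = seg,
         scores = split(bt$score, bt$species))
  })
  idx_obs <- stage("indexes", {
    sc <- res$indexes$scores
    traitObservation(names(sc), vapply(sc, mean, numeric(1)),
                     vapply(sc, var, numeric(1)),
                     vapply(sc, length, numeric(1)))
  })

  # 2. phylogenetic signal (branching index + every trait)
  res$signal <- stage("signal", {
    set.seed(config$seed + 2)
    all_obs <- c(list(branching_index = idx_obs), traits)
    rows <- lapply(names(all_obs), function(nm) {
      o <- all_obs[[nm]]
      la <- pagelLambda(tree, o)
      kk <- blombergK(tree, o, nperm = config$nperm)
      data.frame(trait = nm, lambda = la$estimate,
                 p_lambda = la$p_value, K = kk$estimate,
                 p_K = kk$p_value)
    })
    tab <- do.call(rbind, rows)
    write.csv(tab, outp("signal_table.csv"), row.names = FALSE)
    tab
  })

  # 3. phylogenetic regressions against the index
  res$pgls <- stage("pgls", {
    set.seed(config$seed + 3)
    tab <- correlationTable(tree, idx_obs, traits, nstart = config$nstart)
    write.csv(tab, outp("pgls_table.csv"), row.names = FALSE)
    tab
  })

  # 4. ancestral character estimation
  res$ace <- stage("ace", {
    set.seed(config$seed + 4)
    states <- if (is.null(config$states)) {
      cl <- res$indexes$segregation$classes
      setNames(as.integer(cl), names(cl))
    } else {
      std <- read.csv(config$states, stringsAsFactors = FALSE)
      setNames(as.integer(std$state), std$species)
    }
    fits <- lapply(c("ER", "SYM", "ARD"), function(con)
      fitMkModel(tree, states, con, root_prior = config$root_prior,
                 nstart = config$nstart))
    best <- selectModel(fits)
    anc <- marginalAce(tree, states, best$details$Q,
                       root_prior = config$root_prior)
    write.csv(data.frame(node = rownames(anc), anc),
              outp("ace_states.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(best_model = best$model, lnL = best$lnL, AICc = best$AICc,
           estimates = as.list(best$estimates),
           aic_table = attr(best, "aic_table")),
      outp("ace_model.json"), auto_unbox = TRUE, digits = NA)
    list(fits = fits, best = best, ancestral = anc, states = states)
  })

  # 5. state-dependent diversification
  if (config$fit_musse) {
    res$musse <- stage("musse", {
      set.seed(config$seed + 5)
      fam <- fitMusseFamily(tree, res$ace$states,
                            root = config$sse_root,
                            condition_surv = config$sse_condition,
                            nstart = max(1, config$nstart - 1))
      write.csv(fam$table, outp("musse_table.csv"), row.names = FALSE)
      jsonlite::write_json(
        list(best_model = fam$best$model, lnL = fam$best$lnL,
             AICc = fam$best$AICc,
             estimates = as.list(fam$best$estimates)),
        outp("musse_best.json"), auto_unbox = TRUE, digits = NA)
      fam
    })
  }

  # 6. ordination + PERMANOVA
  res$ordination <- stage("ordination", {
    set.seed(config$seed + 6)
    sp <- traits[[1]]$species
    mat <- vapply(traits, function(o) o$mean[match(sp, o$species)],
                  numeric(length(sp)))
    rownames(mat) <- sp
    pca <- pcaTraits(mat)
    grp <- setNames(res$indexes$table$class, res$indexes$table$species)
    pmv <- permanovaTraits(mat, grp, nperm = config$nperm)
    write.csv(data.frame(species = rownames(pca$scores), pca$scores),
              outp("ordination_scores.csv"), row.names = FALSE)
    write.csv(data.frame(trait = rownames(pca$loadings), pca$loadings),
              outp("ordination_loadings.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(F = pmv$F, R2 = pmv$R2, p_value = pmv$p_value,
           nperm = pmv$nperm,
           var_explained = pca$var_explained[1:2]),
      outp("permanova.json"), auto_unbox = TRUE, digits = NA)
    list(pca = pca, permanova = pmv)
  })

  manifest <- list(
    package = "archevol",
    version = as.character(utils::packageVersion("archevol")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    stage_seeds = config$seed + 2:6,
    settings = config[c("alpha", "nperm", "k_classes", "fit_musse",
                        "sse_root", "sse_condition", "root_prior",
                        "nstart")],
    config_hash = .configHash(config))
  jsonlite::write_json(manifest, outp("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  res$manifest <- manifest
  invisible(res)
}
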