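test_that("birth-death tree simulation honours its contracts", {
  tr <- simulateBdTree(n = 27, birth = 1.1, seed = 201)
  expect_equal(length(tr$tip.label), 27)
  expect_true(isUltrametric(tr))

  tr24 <- simulateBdTree(n = 27, birth = 1.1, crown_age = 2.4, seed = 201)
  expect_equal(max(tipDepths(tr24)), 2.4, tolerance = 1e-12)

  # pure functions of the seed
  expect_equal(writeNewick(simulateBdTree(n = 12, birth = 1, seed = 7)),
               writeNewick(simulateBdTree(n = 12, birth = 1, seed = 7)))

  expect_error(simulateBdTree(n = 5, birth = 0), "positive")
  expect_error(simulateBdTree(n = 5, time = 3), "exactly one")
})

test_that("fixed-time simulation matches the birth-death expectation", {
  set.seed(202)
  b <- 1; d <- 0.3; t <- 1.2
  counts <- replicate(1000, {
    tr <- simulateBdTree(time = t, birth = b, death = d)
    if (is.null(tr)) 0 else length(tr$tip.label)
  })
  # E[N(t)] = 2 exp((b - d) t); single survivors are uncounted, so allow a
  # small downward bias on top of the Monte Carlo band
  expected <- 2 * exp((b - d) * t)
  expect_lt(abs(mean(counts) - expected) / expected, 0.10)
})

test_that("Mk simulation reproduces the transition kernel", {
  tr <- readNewick("((A:1,B:1):1,C:2);")
  Q0 <- mkQ(0.5, "ER")

  # zero rates: everything inherits the root state
  sim0 <- simulateMkStates(tr, mkQ(0, "ER"), root_state = 2, seed = 203)
  expect_true(all(sim0$tip_states == 2))
  expect_true(all(sim0$node_states == 2))

  # empirical transition frequencies over one long branch match exp(Qt)
  long <- readNewick("(A:2,B:0.001);")
  Q <- mkQ(c(.3, .15, .4), "SYM")
  set.seed(204)
  ends <- replicate(1000,
    simulateMkStates(long, Q, root_state = 1)$tip_states[["A"]])
  P <- as.matrix(Matrix::expm(Q * 2))
  chi <- suppressWarnings(
    chisq.test(tabulate(ends, 3), p = P[1, ]))
  expect_gt(chi$p.value, 0.001)

  # consistent relabeling of the generator relabels the outputs
  perm <- c(3L, 1L, 2L)
  Qp <- Q; Qp[perm, perm] <- Q
  s1 <- simulateMkStates(tr, Q, root_state = 1, seed = 205)
  s2 <- simulateMkStates(tr, Qp, root_state = perm[1], seed = 205)
  expect_equal(unname(perm[s1$tip_states]), unname(s2$tip_states))
})

test_that("joint state-dependent simulation has the right limits", {
  # mu = 0, q = 0: monomorphic clades in the root state
  m0 <- musseModel(c(1, 1, 1), rep(0, 3), matrix(0, 3, 3))
  sim <- simulateMusseTree(m0, n = 10, root_state = 3, seed = 211)
  expect_true(all(sim$tip_states == 3))
  expect_equal(length(sim$tree$tip.label), 10)
  expect_true(isUltrametric(sim$tree))

  # strong speciation advantage of state 3: its tips over-represented
  madv <- musseModel(c(0.4, 0.4, 1.8), rep(0, 3), matrix(0.05, 3, 3))
  set.seed(212)
  frac3 <- mean(replicate(15, {
    s <- simulateMusseTree(madv, n = 25, root_state = 2)
    mean(s$tip_states == 3)
  }))
  expect_gt(frac3, 0.5)

  # with equal rates the tip-count process reduces to plain birth-death
  set.seed(213)
  meq <- musseModel(rep(1, 3), rep(0.2, 3), matrix(0.3, 3, 3))
  n_sse <- replicate(400, {
    lin <- archevol:::.bdForward(NA, NA, time = 1.5,
      rates = function(s) c(1, 0.2), root_states = c(1L, 1L),
      q = meq$q)
    sum(lin$alive)
  })
  n_bd <- replicate(400, {
    lin <- archevol:::.bdForward(1, 0.2, time = 1.5,
      rates = function(s) c(1, 0.2), root_states = c(1L, 1L))
    sum(lin$alive)
  })
  expect_lt(abs(mean(n_sse) - mean(n_bd)) / mean(n_bd), 0.12)
})

test_that("Brownian trait simulation matches its covariance contract", {
  tr <- readNewick("((A:1,B:1):1,(C:1.5,D:1.5):0.5);")

  # zero replicate noise: replicates equal the species value
  s0 <- simulateBmTraits(tr, sigma2 = 1, within_sd = 0, seed = 221)
  expect_true(all(s0$replicates == s0$species_values[rownames(s0$replicates)]))
  expect_equal(s0$obs$var, rep(0, 4))

  # cross-species covariance approximates sigma2 * C_lambda
  set.seed(222)
  sims <- replicate(2000,
    simulateBmTraits(tr, sigma2 = 1, lambda = 0.6)$species_values)
  emp <- cov(t(sims))
  theo <- lambdaTransform(phyloVcv(tr), 0.6)[rownames(emp), colnames(emp)]
  expect_lt(max(abs(emp - theo)), 0.2)   # +- 10% of the unit diagonal

  # lambda = 0: off-diagonal covariance vanishes
  set.seed(223)
  sims0 <- replicate(2000, simulateBmTraits(tr, lambda = 0)$species_values)
  emp0 <- cov(t(sims0))
  expect_lt(max(abs(emp0[row(emp0) != col(emp0)])), 0.12)
})

test_that("architecture generation hits the class means and invariants", {
  cfg_tight <- simulationConfig(concentration_species = 5e4,
                                concentration_individual = 5e4)
  mono <- setNames(rep("Monocaulous", 3), paste0("m", 1:3))
  inds <- generateArchitectureIndividuals(mono, cfg_tight, seed = 231)
  bt <- branchingIndexTable(inds)
  expect_lt(abs(mean(bt$photo) - 0.03), 0.005)
  expect_lt(abs(mean(bt$explo) - 0.16), 0.005)
  expect_lt(sd(bt$photo), 0.01)

  # defaults: the two indexes correlate like the study reports
  cls <- setNames(rep(c("Monocaulous", "Intermediate", "Branched"),
                      c(7, 6, 14)), sprintf("sp%02d", 1:27))
  set.seed(232)
  rhos <- replicate(10, {
    ii <- generateArchitectureIndividuals(cls)
    b <- branchingIndexTable(ii)
    sp <- aggregate(cbind(photo, explo) ~ species, b, mean)
    cor(sp$photo, sp$explo, method = "spearman")
  })
  expect_true(all(rhos >= 0.6 & rhos <= 0.99))
  expect_gte(mean(rhos >= 0.75 & rhos <= 0.95), 0.7)

  # generated individuals always satisfy the type invariants
  ind1 <- inds[[1]]
  expect_s3_class(ind1, "individualArchitecture")
  expect_gte(ind1$n_branches, length(ind1$branches))
  expect_true(all(vapply(inds, function(i) i$trunk_length, numeric(1)) > 0))

  expect_error(generateArchitectureIndividuals(
    setNames("Shrub", "x")), "unknown class")
})
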