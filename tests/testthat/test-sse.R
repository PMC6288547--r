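test_that("SSE derivatives and branch integration match analytic limits", {
  null_model <- musseModel(rep(0, 3), rep(0, 3), matrix(0, 3, 3))
  expect_equal(sseDerivatives(0, c(.2, .3, .4, 1, 2, 3), null_model),
               rep(0, 6))

  # single effective state, q = 0, mu = 0: pure-birth decay of D, E = 0
  yule <- musseModel(c(0.8, 0, 0), rep(0, 3), matrix(0, 3, 3))
  y <- sseIntegrate(yule, c(0, 0, 0, 1, 1, 1), 0, 1.7)
  expect_equal(y[1], 0)
  expect_equal(y[4], exp(-0.8 * 1.7), tolerance = 1e-7)

  # with extinction: E(t) matches the birth-death closed form
  bd <- musseModel(rep(1, 3), rep(0.4, 3), matrix(0, 3, 3))
  for (t in c(0.5, 1, 2)) {
    y <- sseIntegrate(bd, c(0, 0, 0, 1, 1, 1), 0, t)
    expect_equal(y[1], bdExtinctionProb(t, 1, 0.4), tolerance = 1e-8)
  }

  # E is monotone non-decreasing and stays inside [0, 1]
  ts <- seq(0, 3, by = 0.1)
  Es <- numeric(length(ts)); Es[1] <- 0
  y <- c(0, 0, 0, 1, 1, 1)
  for (i in 2:length(ts)) {
    y <- sseIntegrate(bd, y, ts[i - 1], ts[i])
    Es[i] <- y[1]
  }
  expect_true(all(diff(Es) >= -1e-12))
  expect_true(all(Es >= 0 & Es <= 1))
})

test_that("the tree likelihood matches hand and closed-form oracles", {
  # two-tip Yule tree by hand: D_root = lambda * exp(-2 lambda t)
  two <- readNewick("(A:1.3,B:1.3);")
  lam <- 0.9
  m <- musseModel(rep(lam, 3), rep(0, 3), matrix(0, 3, 3))
  expect_equal(musseLoglik(two, c(A = 1, B = 1), m),
               log(lam) - 2 * lam * 1.3, tolerance = 1e-8)

  # constant-rate birth-death closed form on simulated trees
  for (i in 1:5) {
    tr <- simulateBdTree(n = 10, birth = 1, death = 0.3, seed = 120 + i)
    st <- setNames(rep(2L, 10), tr$tip.label)
    mbd <- musseModel(rep(1.1, 3), rep(0.35, 3), matrix(0, 3, 3))
    expect_equal(musseLoglik(tr, st, mbd),
                 bdLoglikClosed(tr, 1.1, 0.35), tolerance = 1e-5)
  }

  poly <- readNewick("((A:1,B:1,C:1):1,D:2);")
  expect_error(musseLoglik(poly, c(A = 1, B = 1, C = 1, D = 1), m),
               "polytomy")
})

test_that("likelihood bookkeeping is invariant to renormalization and labels", {
  set.seed(131)
  tr <- simulateBdTree(n = 12, birth = 1, seed = 132)
  st <- simulateMkStates(tr, mkQ(0.4, "ER"), seed = 133)$tip_states
  m <- musseModel(c(1.2, 0.9, 1.5), c(0.1, 0.2, 0.05),
                  mkQ(c(.2, .1, .3, .15, .25, .05), "ARD"))
  a <- musseLoglik(tr, st, m, renormalize = TRUE)
  b <- musseLoglik(tr, st, m, renormalize = FALSE)
  expect_equal(a, b, tolerance = 1e-8)

  # q-symmetry: a consistent relabeling of states leaves the likelihood
  # unchanged
  perm <- c(2L, 3L, 1L)   # state s -> perm[s]
  st_perm <- setNames(perm[st], names(st))
  qperm <- m$q
  qperm[perm, perm] <- m$q
  m_perm <- musseModel(m$lambda[order(perm)], m$mu[order(perm)], qperm)
  expect_equal(musseLoglik(tr, st_perm, m_perm), a, tolerance = 1e-9)

  # rescaling rates by c and branch lengths by 1/c shifts the likelihood
  # by the speciation-density Jacobian, (ntip - 1) * log(c)
  cc <- 2.5
  tr2 <- tr; tr2$edge.length <- tr$edge.length / cc
  m2 <- musseModel(m$lambda * cc, m$mu * cc, m$q * cc)
  expect_equal(musseLoglik(tr2, st, m2),
               a + (length(tr$tip.label) - 1) * log(cc), tolerance = 1e-7)
})

test_that("the model family reproduces the published constraint patterns", {
  fam <- musseModelFamily()
  expect_length(fam, 15)
  expect_equal(names(fam), c("1", "2", "3", "4", "5", "6", "7",
                             "8a", "8b", "8c", "9a", "9b", "9c",
                             "10", "11"))
  counts <- vapply(fam, function(p) p$npar, numeric(1))
  expect_equal(unname(counts),
               c(12, 3, 5, 7, 10, 8, 10, 4, 4, 4, 3, 3, 3, 2, 4))
  # every model nests in the full model: no pattern frees more than it
  expect_true(all(counts <= fam[["1"]]$npar))
  # zero-extinction rows really pin extinction at zero
  m10 <- archevol:::.musseBuild(fam[["10"]], c(1.2, 0.1))
  expect_equal(m10$mu, rep(0, 3))
  expect_equal(m10$lambda, rep(1.2, 3))
  expect_true(all(m10$q[row(m10$q) != col(m10$q)] == 0.1))
  # two-class speciation groupings
  m8b <- archevol:::.musseBuild(fam[["8b"]], c(.5, .9, .1, .2))
  expect_equal(m8b$lambda, c(.5, .9, .9))
})

test_that("family fitting keeps the likelihood monotone under nesting", {
  m2 <- musseModel(rep(1.2, 3), rep(0, 3), matrix(0.15, 3, 3))
  sim <- simulateMusseTree(m2, n = 16, seed = 141)
  fam <- fitMusseFamily(sim$tree, sim$tip_states, nstart = 1, seed = 142)
  lnls <- vapply(fam$fits, function(f) f$lnL, numeric(1))
  expect_gte(fam$fits[["1"]]$lnL + 1e-6, max(lnls))
  expect_equal(fam$table$dAICc[1], 0)
  expect_s3_class(fam$best, "evoFit")
})
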