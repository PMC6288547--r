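test_that("the BM likelihood matches closed forms and scale identities", {
  # star tree + zero within-species variance: iid normal with the sample
  # mean (the GLS mean collapses to it)
  star <- readNewick("(A:2,B:2,C:2,D:2,E:2);")
  x <- c(A = 0.3, B = -0.5, C = 1.1, D = 0.2, E = -0.8)
  obs <- obsFrom(x)
  s2 <- 0.7
  expect_equal(bmLoglik(star, obs, s2),
               sum(dnorm(x, mean(x), sqrt(s2 * 2), log = TRUE)),
               tolerance = 1e-10)

  # lambda = 1, no error: agreement with an independent dense
  # solve/determinant implementation
  tr <- randomUltraTree(12, seed = 41)
  set.seed(42)
  y <- simulateBmTraits(tr, sigma2 = 1.3)$species_values
  obs2 <- obsFrom(y)
  V <- 1.3 * phyloVcv(tr)[obs2$species, obs2$species]
  Vi <- solve(V)
  a <- sum(Vi %*% y) / sum(Vi)
  r <- y - a
  ref <- -0.5 * (t(r) %*% Vi %*% r + determinant(V)$modulus +
                   length(y) * log(2 * pi))
  expect_equal(bmLoglik(tr, obs2, 1.3), as.numeric(ref), tolerance = 1e-8)

  # doubling branch lengths and halving sigma2 leaves the likelihood
  # unchanged when there is no sampling error
  tr2 <- tr; tr2$edge.length <- tr$edge.length * 2
  expect_equal(bmLoglik(tr, obs2, 1.3), bmLoglik(tr2, obs2, 0.65),
               tolerance = 1e-10)
})

test_that("Pagel's lambda separates phylogenetic and white-noise signal", {
  set.seed(51)
  lam_bm <- lam_wn <- numeric(15)
  for (i in seq_len(15)) {
    tr <- simulateBdTree(n = 60, birth = 1, seed = 500 + i)
    sim <- simulateBmTraits(tr, sigma2 = 1, lambda = 1, within_sd = 0.2,
                            n_per_species = 4, seed = 600 + i)
    lam_bm[i] <- pagelLambda(tr, sim$obs)$estimate
    wn <- sim$obs
    wn$mean <- sample(wn$mean)   # destroy the phylogenetic structure
    lam_wn[i] <- pagelLambda(tr, wn)$estimate
  }
  expect_gte(median(lam_bm), 0.85)
  expect_lte(median(lam_wn), 0.15)

  # ML optimality: the profile likelihood at the estimate dominates the
  # boundaries
  tr <- simulateBdTree(n = 40, birth = 1, seed = 77)
  sim <- simulateBmTraits(tr, lambda = 0.6, within_sd = 0.3,
                          n_per_species = 5, seed = 78)
  fit <- pagelLambda(tr, sim$obs)
  C <- phyloVcv(tr)[sim$obs$species, sim$obs$species]
  se2 <- sim$obs$var / sim$obs$n
  for (lam in c(0, 1))
    expect_gte(fit$lnL + 1e-6,
               archevol:::.bmProfile(sim$obs$mean, C, se2, lam)$lnL)

  # invariance to adding a constant
  shifted <- sim$obs; shifted$mean <- shifted$mean + 100
  fit2 <- pagelLambda(tr, shifted)
  expect_equal(fit2$estimate, fit$estimate, tolerance = 1e-5)

  const <- sim$obs; const$mean <- rep(1, nrow(const))
  expect_warning(fc <- pagelLambda(tr, const), "constant")
  expect_true(is.na(fc$estimate))
})

test_that("lambda agrees with an established implementation without error", {
  skip_if_not_installed("phytools")
  tr <- randomUltraTree(40, seed = 91)
  set.seed(92)
  x <- simulateBmTraits(tr, sigma2 = 1, lambda = 0.7)$species_values
  ours <- pagelLambda(tr, obsFrom(x))
  ref <- phytools::phylosig(tr, x, method = "lambda")
  expect_equal(ours$estimate, ref$lambda, tolerance = 0.02)
  expect_equal(ours$lnL, ref$logL, tolerance = 0.01)
})

test_that("Blomberg's K is centred at one under BM and small for noise", {
  # star tree with unit depth: the expected ratio term is exactly one and
  # K reduces to the observed MSE ratio
  star <- readNewick("(A:1,B:1,C:1,D:1,E:1,F:1);")
  x <- c(A = .1, B = -.2, C = .4, D = .9, E = -.6, F = .3)
  kk <- blombergK(star, obsFrom(x), nperm = 99, seed = 1)
  expect_equal(kk$estimate, 1, tolerance = 1e-8)

  set.seed(61)
  k_bm <- k_wn <- numeric(25)
  for (i in seq_len(25)) {
    tr <- simulateBdTree(n = 60, birth = 1, seed = 700 + i)
    x <- simulateBmTraits(tr, sigma2 = 1, seed = 800 + i)$species_values
    k_bm[i] <- blombergK(tr, obsFrom(x), nperm = 99, seed = i)$estimate
    k_wn[i] <- blombergK(tr, obsFrom(setNames(rnorm(60), names(x))),
                         nperm = 99, seed = i)$estimate
  }
  expect_lt(abs(mean(k_bm) - 1), 0.3)
  expect_lt(mean(k_wn), 0.5)

  # add-a-constant invariance and the permutation-count guard
  tr <- randomUltraTree(20, seed = 63)
  x <- simulateBmTraits(tr, seed = 64)$species_values
  k1 <- blombergK(tr, obsFrom(x), nperm = 199, seed = 5)
  k2 <- blombergK(tr, obsFrom(x + 50), nperm = 199, seed = 5)
  expect_equal(k1$estimate, k2$estimate, tolerance = 1e-10)
  expect_equal(k1$p_value, k2$p_value)
  expect_error(blombergK(tr, obsFrom(x), nperm = 50), "at least 99")
})
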