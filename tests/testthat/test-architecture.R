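mkInd <- function(trunk_len = 100, trunk_areas = 100, branches = list(),
                  n_branches = length(branches), species = "sp") {
  individualArchitecture(species, trunk_len, trunk_areas, branches,
                         n_branches)
}

branch <- function(len, areas) list(cumulated_length = len, leaf_areas = areas)

test_that("raw branching indexes are the branch shares of area and length", {
  mono <- mkInd(100, 100)
  expect_equal(photosyntheticIndex(mono), 0)
  expect_equal(explorationIndex(mono), 0)

  ind <- mkInd(100, 100, list(branch(150, 200), branch(150, 200)))
  expect_equal(photosyntheticIndex(ind), 0.8)   # 400 / 500
  expect_equal(explorationIndex(ind), 0.75)     # 300 / 400

  allbr <- mkInd(100, 0, list(branch(10, 50)))
  expect_equal(photosyntheticIndex(allbr), 1)

  expect_error(photosyntheticIndex(mkInd(100, 0)), "total leaf area")
  expect_error(explorationIndex(mkInd(0, 100)), "total stem length")
  expect_warning(p <- explorationIndex(mkInd(0, 100, list(branch(50, 10)))),
                 "degenerates")
  expect_equal(p, 1)

  # representative-branch extrapolation: means times the census
  rep2 <- mkInd(100, 100, list(branch(10, 20), branch(30, 40)),
                n_branches = 10)
  expect_equal(photosyntheticIndex(rep2), 300 / 400)  # mean 30 * 10
  expect_equal(explorationIndex(rep2), 200 / 300)     # mean 20 * 10
})

test_that("indexes are invariant under a common rescaling of measurements", {
  ind <- mkInd(80, c(30, 40), list(branch(120, c(50, 60)), branch(90, 70)))
  scaled <- mkInd(80 * 3, c(30, 40) * 7,
                  list(branch(120 * 3, c(50, 60) * 7), branch(90 * 3, 70 * 7)))
  expect_equal(photosyntheticIndex(scaled), photosyntheticIndex(ind))
  expect_equal(explorationIndex(scaled), explorationIndex(ind))
})

test_that("individualArchitecture enforces its invariants", {
  expect_error(mkInd(-1, 10), ">= 0")
  expect_error(mkInd(10, 10, list(branch(-5, 10))), ">= 0")
  expect_error(individualArchitecture("s", 10, 10, list(), n_branches = 3),
               "n_branches")
  expect_error(mkInd(10, 10, list(branch(1, 1)), n_branches = 0),
               "n_branches")
})

test_that("the integrative index is PC1 with positive loadings", {
  # perfectly correlated columns: PC1 explains everything and scores are
  # proportional to either column's z-scores
  tb <- data.frame(species = letters[1:4], photo = c(.1, .2, .3, .4),
                   explo = c(.2, .4, .6, .8))
  ii <- integrativeIndex(tb)
  expect_equal(ii$var_explained, 1)
  zs <- scale(tb$photo)[, 1]
  expect_equal(cor(ii$scores, zs), 1, tolerance = 1e-12)
  expect_true(all(ii$loadings > 0))

  # independent eigen oracle on a 4-species table
  tb2 <- data.frame(species = letters[1:4], photo = c(.05, .3, .5, .9),
                    explo = c(.2, .25, .6, .7))
  ii2 <- integrativeIndex(tb2)
  z <- scale(cbind(tb2$photo, tb2$explo))
  eo <- eigen(stats::cor(z))
  v <- eo$vectors[, 1]; if (v[1] < 0) v <- -v
  expect_equal(unname(ii2$scores), as.vector(z %*% v), tolerance = 1e-10)
  expect_equal(ii2$var_explained, eo$values[1] / 2, tolerance = 1e-12)

  expect_error(integrativeIndex(
    data.frame(species = letters[1:3], photo = c(.2, .2, .2),
               explo = c(.1, .2, .3))), "constant")

  # strictly increasing in each raw index holding the other fixed
  base <- scoreIndividuals(ii2, 0.4, 0.4)
  expect_gt(scoreIndividuals(ii2, 0.5, 0.4), base)
  expect_gt(scoreIndividuals(ii2, 0.4, 0.5), base)
})

test_that("class segregation finds the breaks a known structure implies", {
  set.seed(31)
  centers <- rep(c(0.05, 0.45, 0.85), each = 4)
  scores <- lapply(seq_along(centers), function(i)
    rnorm(5, centers[i], 0.03))
  names(scores) <- sprintf("sp%02d", seq_along(centers))
  seg <- segregateClasses(scores, alpha = 0.1, k = 3)
  truth <- rep(c("Monocaulous", "Intermediate", "Branched"), each = 4)
  expect_equal(as.character(seg$classes), truth)

  # all species from one distribution: single letter, warning
  set.seed(32)
  null_scores <- lapply(1:6, function(i) rnorm(5, 0.5, 0.05))
  names(null_scores) <- letters[1:6]
  expect_warning(seg0 <- segregateClasses(null_scores), "break")
  expect_true(all(seg0$letters == seg0$letters[1]))
  expect_equal(length(unique(seg0$classes)), 1L)

  # identical score vectors: same letter, same class
  twin <- c(null_scores, list(g = null_scores$a))
  suppressWarnings(segt <- segregateClasses(twin))
  expect_equal(segt$letters[["g"]], segt$letters[["a"]])
  expect_equal(segt$classes[["g"]], segt$classes[["a"]])

  # rank-based: invariant under order-preserving transforms
  seg_exp <- segregateClasses(lapply(scores, function(x) exp(3 * x)))
  expect_equal(seg_exp$classes, seg$classes)

  expect_error(segregateClasses(scores, k = 1), "at least 2")
  expect_error(segregateClasses(list(a = 1, b = c(1, 2))), "2 individuals")
})

test_that("trait derivation follows the published formulas", {
  raw <- list(height = 300, basal_diameter = 2, wood_dry_mass = 5,
              wood_fresh_volume = 8, stem_dry_mass = 6,
              stem_fresh_volume = 10, internode_d_min = 0.4,
              internode_d_max = 0.9, internode_l = 2.5, area_pith = 2,
              area_wood = 5, area_cortex = 3, area_section = 10,
              wood_area_pom = 0.5, leaf_area_above_pom = 400,
              leaf_fresh_area = 50, leaf_dry_mass = 0.5, mean_la = 45,
              n_trunk_leaves = 12, trunk_mean_leaf_area = 45,
              n_branches = 10, branch_mean_leaf_number = 4,
              branch_mean_leaf_area = 30, fruit_length = 3,
              fruit_width = 2)
  tr <- deriveTraits(raw)
  expect_equal(tr[["internode_d"]], 0.6)          # sqrt(0.36)
  expect_equal(tr[["fruit_vol"]], 12)             # 3 * 2^2
  expect_equal(unname(tr[c("p_pith", "p_wood", "p_cortex")]),
               c(0.2, 0.5, 0.3))
  expect_equal(sum(tr[c("p_pith", "p_wood", "p_cortex")]), 1)
  expect_equal(tr[["sr"]], 150)
  expect_equal(tr[["swd"]], 5 / 8)
  expect_equal(tr[["hv"]], 0.5 / 400)
  expect_equal(tr[["sla"]], 100)
  expect_equal(tr[["total_la"]], 30 * 10 + 45 * 12)
  expect_equal(tr[["nb_leaf"]], 12 + 4 * 10)

  # zero denominator: per-trait NA, not a global failure
  raw2 <- raw; raw2$leaf_dry_mass <- 0
  expect_message(tr2 <- deriveTraits(raw2), "sla")
  expect_true(is.na(tr2[["sla"]]))
  expect_equal(tr2[["sr"]], 150)

  raw3 <- raw; raw3$area_pith <- 4
  expect_error(deriveTraits(raw3), "exceeds")
})

test_that("individuals survive a CSV round trip", {
  cls <- setNames(rep(c("Monocaulous", "Branched"), c(2, 2)),
                  paste0("s", 1:4))
  inds <- generateArchitectureIndividuals(cls, simulationConfig(),
                                          seed = 99)
  f <- tempfile(fileext = ".csv")
  writeIndividuals(inds, f)
  back <- readIndividuals(f)
  expect_equal(length(back), length(inds))
  expect_equal(branchingIndexTable(back)[, c("photo", "explo")],
               branchingIndexTable(inds)[, c("photo", "explo")],
               tolerance = 1e-10)
  unlink(f)
})
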