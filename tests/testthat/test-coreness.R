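test_that("proportional thresholding keeps the m strongest edges", {
  set.seed(9)
  w <- randomSymMatrix(4)
  expect_equal(thresholdLayer(w, 1), w)
  t3 <- thresholdLayer(w, 0.5)           # 6 edges -> 3 retained
  kept <- t3[upper.tri(t3)]
  expect_equal(sum(kept > 0), 3)
  expect_setequal(kept[kept > 0],
                  sort(w[upper.tri(w)], decreasing = TRUE)[1:3])
  expect_error(thresholdLayer(w, 0), "density")
  expect_error(thresholdLayer(w, 1.2), "density")
})

test_that("thresholding ties are broken by (i, j) lexicographic order", {
  w <- matrix(1, 4, 4); diag(w) <- 0
  dimnames(w) <- list(paste0("n", 1:4), paste0("n", 1:4))
  t3 <- thresholdLayer(w, 0.5)
  # retained: (1,2), (1,3), (1,4) - the lexicographically first half
  expect_equal(t3["n1", c("n2", "n3", "n4")], c(n2 = 1, n3 = 1, n4 = 1))
  expect_equal(t3["n2", "n3"], 0)
  expect_equal(t3["n2", "n4"], 0)
  expect_equal(t3["n3", "n4"], 0)
})

test_that("multiplex richness combines layer strengths linearly", {
  mk <- function(w12) {
    m <- matrix(0, 3, 3); m[1, 2] <- m[2, 1] <- w12; m
  }
  mats <- list(mk(2), mk(4), mk(6))
  r <- multiplexRichness(mats, coefficients = c(0.5, 0.5, 0.5))
  expect_equal(unname(r$mu[1]), 6)           # 0.5 * (2 + 4 + 6)
  expect_equal(unname(r$mu[3]), 0)           # isolated node
  expect_equal(unname(r$muPlus[3]), 0)
  expect_true(all(r$muPlus <= r$mu + 1e-12))
  r2 <- multiplexRichness(mats, coefficients = c(1, 1, 1))
  expect_equal(r2$mu, 2 * r$mu)
  expect_equal(r2$muPlus, 2 * r$muPlus)
  expect_error(multiplexRichness(mats, coefficients = c(1, 1)),
               "coefficient count")
})

test_that("rich-core hand traces: star, empty graph, two nodes", {
  expect_equal(richCore(list(starLayerMatrix()), 1), c("A", "B"))
  z <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  expect_length(richCore(list(z), 1), 0)
  w2 <- matrix(c(0, 0.7, 0.7, 0), 2, dimnames = list(c("n1", "n2"),
                                                     c("n1", "n2")))
  expect_equal(richCore(list(w2), 1), c("n1", "n2"))
})

test_that("rich-core boundary maximizes mu-plus on random small multiplexes", {
  # exhaustive check against the loop-based oracle on <= 6-node instances
  for (seed in 1:100) {
    set.seed(seed)
    n <- sample(3:6, 1)
    mats <- replicate(3, randomSymMatrix(n), simplify = FALSE)
    coeffs <- c(0.5, 0.5, 0.5)
    core <- richCore(mats, coeffs)
    oracle <- oracleRichCore(mats, coeffs)
    expect_equal(core, rownames(mats[[1]])[oracle$core])
    if (length(oracle$core)) {
      boundaryVal <- oracle$muPlusByRank[length(oracle$core)]
      expect_true(all(boundaryVal >= oracle$muPlusByRank))
    }
  }
})

test_that("coreness over a hand-traceable sweep", {
  w <- matrix(0, 3, 3, dimnames = list(paste0("n", 1:3), paste0("n", 1:3)))
  w[1, 2] <- w[2, 1] <- 3
  w[1, 3] <- w[3, 1] <- 2
  w[2, 3] <- w[3, 2] <- 1.9
  grid <- c(0.3, 0.7, 0.9, 1.0)  # retains 1, 2, 3, 3 of the 3 edges
  cp <- coreness(ConnectivityLayer("SC", w), grid)
  # n1, n2 in the core at every density; n3 only at the two full densities
  expect_equal(corenessValues(cp),
               c(n1 = 1, n2 = 1, n3 = 0.5))
  expect_s4_class(cp, "CorenessProfile")
  expect_identical(cp@domain, "SC")
})

test_that("sweep agrees with per-density threshold + rich-core composition", {
  pm <- plantedCoreMultiplex(15, 1:4, noise = 0.2, seed = 31)
  mats <- lapply(multiplexLayers(pm$multiplex), layerWeights)
  grid <- densityGrid(0.1, 1, 0.1)
  cp <- coreness(pm$multiplex, grid)
  counts <- setNames(numeric(15), rownames(mats[[1]]))
  for (d in grid) {
    filt <- lapply(mats, thresholdLayer, density = d)
    core <- richCore(filt, c(0.5, 0.5, 0.5))
    counts[core] <- counts[core] + 1
  }
  expect_equal(corenessValues(cp), counts / length(grid))
})

test_that("coreness is permutation-equivariant and grid-quantized", {
  pm <- plantedCoreMultiplex(12, 1:3, noise = 0.15, seed = 17)
  grid <- densityGrid(0.05, 1, 0.05)
  cp <- corenessValues(coreness(pm$multiplex, grid))
  set.seed(1)
  perm <- sample(12)
  mats <- lapply(multiplexLayers(pm$multiplex), function(l) {
    w <- layerWeights(l)
    w[perm, perm]
  })
  mx2 <- new("MultiplexNetwork",
             layers = mapply(function(w, k) ConnectivityLayer(k, w),
                             mats, c("MC", "SC", "FC"), SIMPLIFY = FALSE))
  cp2 <- corenessValues(coreness(mx2, grid))
  expect_equal(cp2, cp[perm])
  expect_true(all(abs(cp * length(grid) - round(cp * length(grid))) < 1e-9))
})

test_that("disruption index matches closed-form least squares", {
  r <- c(0.8, 0.5, 0.2)
  k <- disruptionIndex(c(0.4, 0.35, 0.2), r)
  expect_equal(kappaValue(k), -2 / 3, tolerance = 1e-12)
  expect_equal(kappaValue(disruptionIndex(r, r)), 0)
  expect_equal(disruptionIndex(r, r)@intercept, 0)
  k0 <- disruptionIndex(rep(0, 3), r)
  expect_equal(kappaValue(k0), -1)
  expect_equal(k0@intercept, 0)
  # slope is recomputable from the stored vectors
  expect_equal(kappaValue(k),
               unname(coef(lm(k@delta ~ k@reference))[2]),
               tolerance = 1e-12)
  expect_error(disruptionIndex(r, rep(0.4, 3)), "constant")
})

test_that("group disruption index averages coreness before the fit", {
  r <- c(0.9, 0.6, 0.3, 0.1)
  subj <- rbind(c(0.5, 0.4, 0.3, 0.1), c(0.3, 0.4, 0.1, 0.1))
  g <- groupDisruptionIndex(subj, r)
  expect_equal(kappaValue(g), kappaValue(disruptionIndex(colMeans(subj), r)))
  # identical subjects equal the individual kappa
  same <- rbind(subj[1, ], subj[1, ])
  expect_equal(kappaValue(groupDisruptionIndex(same, r)),
               kappaValue(disruptionIndex(subj[1, ], r)))
  # the reference sample itself has kappa 0 exactly
  hcSample <- rbind(r + c(0.1, -0.1, 0, 0), r - c(0.1, -0.1, 0, 0))
  expect_equal(kappaValue(groupDisruptionIndex(hcSample, r)), 0)
})
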