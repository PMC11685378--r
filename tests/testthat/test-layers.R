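test_that("volume z-scoring against the HC norm matches hand computation", {
  # three HC with identical covariate structure: intercept-only norm
  v <- matrix(c(10, 12, 14), ncol = 1, dimnames = list(NULL, "n1"))
  vz <- zscoreVolumes(v, covariates = NULL, hcMask = rep(TRUE, 3))
  expect_equal(unname(vz$z[, 1]), c(-1, 0, 1))
  # z has mean 0 / SD 1 over the fitting sample
  expect_equal(mean(vz$z[, 1]), 0)
  expect_equal(sd(vz$z[, 1]), 1)
})

test_that("a subject at the HC-model prediction gets z = 0", {
  set.seed(1)
  n <- 30
  age <- runif(n, 20, 60)
  sexn <- rbinom(n, 1, 0.5)
  tiv <- rnorm(n, 1450, 100)
  vol <- 5 + 0.1 * age + 0.5 * sexn + 0.002 * tiv + rnorm(n, 0, 0.3)
  hc <- rep(TRUE, n)
  vz <- zscoreVolumes(cbind(r1 = vol), data.frame(age, sex = sexn, tiv), hc)
  # append a subject exactly on the fitted plane
  beta <- vz$coefficients[, 1]
  newCov <- c(1, 45, 1, 1500)
  volAll <- rbind(cbind(r1 = vol), r1 = sum(beta * newCov))
  vz2 <- zscoreVolumes(volAll,
                       data.frame(age = c(age, 45), sex = c(sexn, 1),
                                  tiv = c(tiv, 1500)),
                       c(hc, FALSE))
  expect_equal(unname(vz2$z[n + 1, 1]), 0, tolerance = 1e-10)
})

test_that("covariate adjustment removes a planted age slope", {
  set.seed(7)
  n <- 200
  age <- runif(n, 20, 70)
  vol <- 8 + 0.5 * age + rnorm(n, 0, 1)
  vz <- zscoreVolumes(cbind(r1 = vol),
                      data.frame(age, sex = rbinom(n, 1, 0.5),
                                 tiv = rnorm(n, 1450, 100)),
                      rep(TRUE, n))
  expect_lt(abs(cor(vz$z[, 1], age)), 0.05)
})

test_that("z-scoring rejects degenerate designs", {
  v <- matrix(rnorm(20), ncol = 1)
  expect_error(
    zscoreVolumes(v, data.frame(age = rnorm(20), sex = 0, tiv = 1500),
                  rep(TRUE, 20)),
    "singular")
  expect_error(zscoreVolumes(v, data.frame(age = rnorm(20)),
                             rep(c(TRUE, FALSE), c(5, 15))),
               "at least 10 HC")
})

test_that("morphological covariance weights follow exp(-(zi - zj)^2)", {
  l <- buildMCLayer(c(a = 0, b = 1, c = 2))
  w <- layerWeights(l)
  expect_equal(w["a", "b"], exp(-1), tolerance = 1e-8)
  expect_equal(w["a", "b"], 0.36787944, tolerance = 1e-7)
  expect_equal(w["a", "c"], exp(-4), tolerance = 1e-8)
  expect_equal(w["a", "c"], 0.01831564, tolerance = 1e-7)
  # weight 1 exactly iff the z difference is 0
  l2 <- buildMCLayer(c(0.5, 0.5, 1.2))
  expect_equal(layerWeights(l2)[1, 2], 1)
  expect_true(all(layerWeights(l2)[1, 3] < 1))
  expect_error(buildMCLayer(c(0, NA, 1)), "non-finite")
})

test_that("MC weights depend only on z differences (shift invariance)", {
  set.seed(3)
  z <- rnorm(10)
  expect_equal(layerWeights(buildMCLayer(z)),
               layerWeights(buildMCLayer(z + 2.7)), tolerance = 1e-12)
  w <- layerWeights(buildMCLayer(z))
  expect_equal(w, t(w))
})

test_that("SC transform is log10(1 + w), zero-preserving and monotone", {
  raw <- matrix(c(0, 9, 99, 9, 0, 0, 99, 0, 0), 3)
  w <- layerWeights(transformSC(raw))
  expect_equal(w[1, 2], 1)
  expect_equal(w[1, 3], 2)
  expect_equal(w[2, 3], 0)
  expect_error(transformSC(matrix(c(0, -1, -1, 0), 2)), "nonnegative")
  x <- sort(runif(20, 0, 100))
  expect_true(all(diff(log10(1 + x)) > 0))
})

test_that("FC transform is |atanh(r)| with hard bounds", {
  r <- matrix(c(1, -0.5, 0.76159416, -0.5, 1, 0, 0.76159416, 0, 1), 3)
  w <- layerWeights(transformFC(r))
  expect_equal(w[1, 2], 0.54930614, tolerance = 1e-7)
  expect_equal(w[1, 3], 1, tolerance = 1e-7)
  expect_equal(w[2, 3], 0)
  bad <- r; bad[1, 2] <- bad[2, 1] <- 1
  expect_error(transformFC(bad), "strictly inside")
})

test_that("spectral-norm normalization has singular value 1 and is idempotent", {
  m <- matrix(c(0, 2, 2, 0), 2)
  expect_equal(svdNormalize(m), matrix(c(0, 1, 1, 0), 2))
  set.seed(5)
  for (i in 1:5) {
    w <- randomSymMatrix(12)
    nw <- svdNormalize(w)
    expect_equal(max(svd(nw)$d), 1, tolerance = 1e-9)
    # idempotence and rank-order preservation
    expect_equal(svdNormalize(nw), nw, tolerance = 1e-12)
    expect_equal(order(w[upper.tri(w)]), order(nw[upper.tri(nw)]))
  }
  expect_error(svdNormalize(matrix(0, 3, 3)), "all-zero")
})

test_that("multiplex assembly enforces label alignment and normalization", {
  pm <- plantedCoreMultiplex(6, 1:2, noise = 0.05, seed = 2)
  expect_true(validObject(pm$multiplex))
  ls <- multiplexLayers(pm$multiplex)
  expect_identical(names(ls), c("MC", "SC", "FC"))
  # permuted labels in one layer is a hard error
  scW <- layerWeights(ls$SC)
  perm <- rev(rownames(scW))
  scBad <- ConnectivityLayer("SC", scW[perm, perm])
  expect_error(assembleMultiplex(ls$MC, scBad, ls$FC), "mismatch")
  # unnormalized layer rejected when checked
  scBig <- ConnectivityLayer("SC", layerWeights(ls$SC) * 3)
  expect_error(assembleMultiplex(ls$MC, scBig, ls$FC), "not normalized")
})
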