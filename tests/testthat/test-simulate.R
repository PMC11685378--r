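test_that("noise-free planted multiplex recovers its core exactly", {
  pm <- plantedCoreMultiplex(6, 1:3, weightMeans = c(cc = 1, cp = 0.5,
                                                     pp = 0.1), noise = 0)
  expect_equal(richCore(pm$multiplex), pm$coreNodes)
  # a 2-node instance: the planted core node is never outranked
  pm2 <- plantedCoreMultiplex(2, 1, noise = 0)
  cp <- corenessValues(coreness(pm2$multiplex, densityGrid(0.25, 1, 0.25)))
  expect_gte(cp["node001"], cp["node002"])
})

test_that("planted multiplex generation is permutation-equivariant", {
  pm <- plantedCoreMultiplex(10, 1:3, noise = 0)
  grid <- densityGrid(0.1, 1, 0.1)
  base <- corenessValues(coreness(pm$multiplex, grid))
  perm <- c(4:10, 1:3)   # cores moved to the end
  pmP <- plantedCoreMultiplex(10, which(perm %in% 1:3), noise = 0)
  permuted <- corenessValues(coreness(pmP$multiplex, grid))
  expect_equal(unname(sort(permuted, decreasing = TRUE)),
               unname(sort(base, decreasing = TRUE)))
  expect_setequal(names(sort(permuted, decreasing = TRUE))[1:3],
                  pmP$coreNodes)
})

test_that("targeted attack scales edges by endpoint affinity", {
  pm <- plantedCoreMultiplex(5, 1:2, noise = 0.05, seed = 4)
  mx <- pm$multiplex
  # identity at delta 0
  a0 <- applyTargetedAttack(mx, rep(1, 5), 0)
  expect_equal(layerWeights(a0, "SC"), layerWeights(mx, "SC"))
  # annihilation at delta 1 with affinity 1 everywhere
  a1 <- applyTargetedAttack(mx, rep(1, 5), 1)
  expect_true(all(layerWeights(a1, "MC") == 0))
  expect_true(all(layerWeights(a1, "FC") == 0))
  # affinity concentrated at node 1, delta 0.5: its edges halve
  aff <- c(1, 0, 0, 0, 0)
  ah <- applyTargetedAttack(mx, aff, 0.5)
  w0 <- layerWeights(mx, "SC"); wh <- layerWeights(ah, "SC")
  expect_equal(wh[1, -1], w0[1, -1] / 2)
  expect_equal(wh[-1, -1], w0[-1, -1])
  expect_error(applyTargetedAttack(mx, rep(1, 5), 1.5), "delta")
  expect_error(applyTargetedAttack(mx, rep(2, 5), 0.5), "affinity")
})

test_that("the cohort generator is deterministic under a fixed seed", {
  s1 <- simulateCohort(5, 8, nNodes = 20, nCore = 5, seed = 99)
  s2 <- simulateCohort(5, 8, nNodes = 20, nCore = 5, seed = 99)
  expect_identical(subjectRecords(s1$cohort), subjectRecords(s2$cohort))
  expect_identical(s1$cohort@volumes, s2$cohort@volumes)
  expect_identical(s1$cohort@sc, s2$cohort@sc)
  expect_identical(s1$cohort@fc, s2$cohort@fc)
  expect_identical(s1$truth@attackStrength, s2$truth@attackStrength)
})

test_that("generated matrices satisfy their range contracts", {
  sim <- simulateCohort(4, 6, nNodes = 30, nCore = 6, seed = 12)
  for (id in subjectRecords(sim$cohort)$subject_id) {
    fc <- sim$cohort@fc[[id]]
    off <- fc[row(fc) != col(fc)]
    expect_true(all(off > -1 & off < 1))
    expect_true(all(sim$cohort@sc[[id]] >= 0))
  }
  expect_true(validObject(sim$cohort))
  rec <- subjectRecords(sim$cohort)
  hc <- rec$group == "HC"
  expect_true(all(is.na(rec$edss[hc])))
  expect_true(all(sim$truth@attackStrength[rec$subject_id[hc]] == 0))
})

test_that("strong signal puts heavier weight inside the planted core", {
  sim <- simulateCohort(3, 5, nNodes = 114, nCore = 20, seed = 5,
                        params = list(weightMeans = c(cc = 1, cp = 0.35,
                                                      pp = 0.08)))
  core <- sim$truth@coreNodes
  for (id in subjectRecords(sim$cohort)$subject_id) {
    sc <- sim$cohort@sc[[id]]
    inCore <- sc[core, core]
    periph <- sc[setdiff(rownames(sc), core), setdiff(rownames(sc), core)]
    expect_gt(mean(inCore[upper.tri(inCore)]),
              mean(periph[upper.tri(periph)]))
  }
})

test_that("with no attack and no site effects the groups are exchangeable", {
  pass <- 0L
  nRuns <- 50L
  noEffect <- list(deltaByPhenotype = c(CIS = 0, RRMS = 0, SPMS = 0,
                                        PPMS = 0),
                   deltaSD = 0, siteVolLocSD = 0, siteVolScaleSD = 0,
                   siteScScaleSD = 0, siteFcScaleSD = 0)
  for (r in seq_len(nRuns)) {
    sim <- simulateCohort(3, 3, nNodes = 25, nCore = 5, siteCount = 2,
                          params = noEffect, seed = 500 + r)
    rec <- subjectRecords(sim$cohort)
    hcIds <- rec$subject_id[rec$group == "HC"]
    msIds <- rec$subject_id[rec$group == "MS"]
    pool <- function(ids) {
      unlist(lapply(ids, function(id) {
        m <- sim$cohort@sc[[id]]
        m[upper.tri(m)][1:100]
      }))
    }
    p <- permutationTtest(pool(msIds), pool(hcIds), nPerm = 1000,
                          seed = r)$p
    if (p > 0.05) pass <- pass + 1L
  }
  expect_gte(pass / nRuns, 0.9)
})

test_that("generator rejects invalid phenotype mixes and core sizes", {
  expect_error(simulateCohort(3, 3, nNodes = 10, nCore = 10, seed = 1),
               "nCore")
  expect_error(simulateCohort(3, 3, nNodes = 10, nCore = 2,
                              phenotypeMix = c(CIS = 0.9, RRMS = 0.9,
                                               SPMS = 0, PPMS = 0),
                              seed = 1),
               "phenotypeMix")
  expect_error(plantedCoreMultiplex(5, integer(0)), "nonempty")
  expect_error(simulateCohort(3, 3, nNodes = 10, nCore = 2,
                              params = list(bogus = 1), seed = 1),
               "unknown simulation parameter")
})
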