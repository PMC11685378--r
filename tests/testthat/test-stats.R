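test_that("HC-anchored adjustment standardizes the fitting sample exactly", {
  set.seed(20)
  n <- 80
  hc <- rep(c(TRUE, FALSE), each = n / 2)
  age <- rnorm(n, 45, 10)
  sexn <- rbinom(n, 1, 0.5)
  v <- -0.1 + 0.01 * age + 0.2 * sexn + rnorm(n, 0, 0.5)
  adj <- adjustConfounders(v, data.frame(age = age, sex = sexn), hc)
  expect_equal(mean(adj$z[hc]), 0, tolerance = 1e-8)
  expect_equal(sd(adj$z[hc]), 1, tolerance = 1e-8)
  # an HC subject sitting at the HC mean of corrected values scores 0
  iMid <- which(hc)[which.min(abs(adj$corrected[hc] - adj$hcMean))]
  expect_equal(adj$z[iMid],
               (adj$corrected[iMid] - adj$hcMean) / adj$hcSD)
  expect_error(adjustConfounders(rep(1, n), data.frame(age = age), hc),
               "zero variance")
})

test_that("adjustment removes a planted age effect on kappa", {
  set.seed(21)
  n <- 200
  age <- runif(n, 20, 70)
  kappa <- -0.01 * age + rnorm(n, 0, 0.05)
  adj <- adjustConfounders(kappa, data.frame(age = age,
                                             sex = rbinom(n, 1, 0.5)),
                           rep(TRUE, n))
  expect_lt(abs(cor(adj$z, age)), 0.05)
})

test_that("permutation t test: exhaustive enumeration hand cases", {
  # identical groups: every relabeling ties or exceeds, p = 1
  r <- permutationTtest(c(1, 2), c(1, 2))
  expect_true(r$exhaustive)
  expect_equal(r$p, 1)
  # extreme separation: 2 of the 6 arrangements reach |t_obs|
  r2 <- permutationTtest(c(1, 2), c(10, 11))
  expect_true(r2$exhaustive)
  expect_equal(r2$p, 1 / 3)
  expect_error(permutationTtest(1, c(1, 2)), "at least 2")
})

test_that("Monte Carlo permutation p-values are never zero", {
  set.seed(22)
  x <- rnorm(30) + 10   # enormous effect
  y <- rnorm(30)
  r <- permutationTtest(x, y, nPerm = 1000, seed = 1,
                        exhaustiveIfSmall = FALSE)
  expect_gte(r$p, 1 / 1001)
  expect_false(r$exhaustive)
  expect_error(permutationTtest(x, y, nPerm = 100,
                                exhaustiveIfSmall = FALSE),
               "at least 1000")
  # the pooled-t statistic agrees with the textbook computation
  expect_equal(r$statistic, unname(t.test(x, y, var.equal = TRUE)$statistic))
})

test_that("nodal comparison flags planted effects and controls nulls", {
  set.seed(23)
  n <- 60
  grp <- factor(rep(c("MS", "HC"), each = n / 2), levels = c("MS", "HC"))
  Z <- matrix(rnorm(n * 20), n)
  colnames(Z) <- sprintf("node%03d", 1:20)
  Z[grp == "MS", 1:3] <- Z[grp == "MS", 1:3] - 1.5
  res <- nodalComparison(Z, grp, nPerm = 2000, q = 0.05, seed = 3)
  expect_equal(nrow(res), 20)
  expect_true(all(res$significant[1:3]))
  expect_lt(sum(res$significant[4:20]), 3)
  expect_true(all(res$p > 0))
  expect_true(all(res$pBH >= res$p - 1e-12))
  expect_lt(res$statistic[1], 0)
  expect_lt(res$g[1], 0)
})

test_that("Hedges' g matches the J-corrected closed form", {
  set.seed(24)
  y <- as.numeric(scale(rnorm(20)))   # mean 0, sample SD 1
  x <- y + 1                          # mean diff 1, pooled SD 1
  g <- hedgesG(x, y, nBoot = 200, seed = 1)
  expect_equal(g$g, 1 - 3 / 151, tolerance = 1e-10)
  expect_equal(round(g$g, 5), 0.98013)
  expect_true(g$ciLow <= g$g && g$g <= g$ciHigh)
  # equal samples give g = 0
  expect_equal(hedgesG(y, y, nBoot = 100, seed = 1)$g, 0)
  expect_error(hedgesG(rep(1, 5), rep(1, 5), nBoot = 10), "pooled")
})

test_that("one-way ANOVA and Tukey HSD hand cases", {
  v <- c(1, 2, 3, 2, 3, 4, 3, 4, 5)
  g <- rep(c("a", "b", "c"), each = 3)
  res <- anovaTukey(v, g)
  expect_equal(res$F, 3)                       # SSB 6 / SSW 6, df 2 and 6
  expect_equal(res$p, pf(3, 2, 6, lower.tail = FALSE))
  expect_equal(unname(res$df), c(2, 6))
  # identical groups: F = 0, all pairwise Tukey p = 1
  res0 <- anovaTukey(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(res0$F, 0)
  expect_true(all(res0$tukey$pAdj == 1))
  expect_error(anovaTukey(c(1, 2, 3), c("a", "a", "b")), "fewer than 2")
})

test_that("clinical dichotomies use the printed cutoffs", {
  rec <- data.frame(edss = c(4.0, 3.5, NA, 6.5),
                    sdmt_z = c(-1.5, -1.51, 0.2, NA))
  d <- suppressMessages(dichotomizeClinical(rec, "disability"))
  expect_equal(as.character(d), c("EDSS>=4", "EDSS<4", NA, "EDSS>=4"))
  expect_equal(attr(d, "nExcluded"), 1L)
  i <- suppressMessages(dichotomizeClinical(rec, "ips"))
  # z exactly -1.5 is preserved (strict <), just below is impaired
  expect_equal(as.character(i), c("IPS-P", "IPS-I", "IPS-P", NA))
  expect_message(dichotomizeClinical(rec, "ips"), "excluded")
})
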