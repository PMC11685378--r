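test_that("bagged trees learn a separable feature and stay at chance otherwise", {
  set.seed(30)
  n <- 200
  y <- factor(rep(c("a", "b"), each = n / 2))
  sep <- ifelse(y == "a", 0, 4) + rnorm(n, 0, 0.3)
  fitSep <- fitBaggedTrees(cbind(sep = sep, noise = rnorm(n)), y,
                           searchBudget = 4, seed = 1)
  expect_gte(fitSep$report$oobAccuracy, 0.95)
  # a single constant feature cannot beat the majority class
  yU <- factor(rep(c("a", "b"), c(120, 80)))
  fitC <- fitBaggedTrees(cbind(flat = rep(1, n)), yU,
                         searchBudget = 2, seed = 1)
  expect_lt(abs(fitC$report$oobAccuracy - 0.6), 0.05)
  expect_error(fitBaggedTrees(cbind(x = rnorm(30)),
                              factor(rep("a", 30))), "2 classes")
})

test_that("model fitting and importance are reproducible under a seed", {
  set.seed(31)
  n <- 60
  X <- cbind(a = rnorm(n), b = rnorm(n))
  y <- factor(ifelse(X[, "a"] + rnorm(n, 0, 0.5) > 0, "p", "q"))
  f1 <- fitBaggedTrees(X, y, searchBudget = 4, seed = 7)
  f2 <- fitBaggedTrees(X, y, searchBudget = 4, seed = 7)
  expect_identical(f1$report, f2$report)
  i1 <- oobPermutationImportance(f1, nRepeats = 3, seed = 5)
  i2 <- oobPermutationImportance(f2, nRepeats = 3, seed = 5)
  expect_identical(i1, i2)
})

test_that("pure-noise features have near-zero OOB permutation importance", {
  set.seed(32)
  n <- 500
  y <- factor(rep(c("a", "b"), each = n / 2))
  strong <- ifelse(y == "a", 0, 2) + rnorm(n, 0, 0.5)
  X <- cbind(strong = strong, noise1 = rnorm(n), noise2 = rnorm(n))
  fit <- fitBaggedTrees(X, y, searchBudget = 4, seed = 2)
  imp <- oobPermutationImportance(fit, nRepeats = 10, seed = 2)
  expect_lt(abs(imp$importance[imp$feature == "noise1"]), 0.02)
  expect_lt(abs(imp$importance[imp$feature == "noise2"]), 0.02)
  expect_gt(imp$importance[imp$feature == "strong"],
            max(imp$importance[imp$feature != "strong"]))
  expect_equal(nrow(imp), ncol(X))
})

test_that("duplicated informative features share importance nonnegatively", {
  set.seed(33)
  n <- 200
  y <- factor(rep(c("a", "b"), each = n / 2))
  strong <- ifelse(y == "a", 0, 2) + rnorm(n, 0, 0.5)
  X <- cbind(s1 = strong, s2 = strong, noise = rnorm(n))
  fit <- fitBaggedTrees(X, y, searchBudget = 4, seed = 3)
  imp <- oobPermutationImportance(fit, nRepeats = 10, seed = 3)
  expect_gte(imp$importance[imp$feature == "s1"], 0)
  expect_gte(imp$importance[imp$feature == "s2"], 0)
})

test_that("feature tables follow the task schemas", {
  fx <- disruptedCohortKappa()
  tabS <- suppressMessages(buildFeatureTables(fx$kappaTable, fx$records,
                                              "status"))
  expect_equal(ncol(tabS$features), 6)
  expect_setequal(colnames(tabS$features),
                  c("kappa_multiplex", "kappa_mc", "kappa_sc", "kappa_fc",
                    "bpf_z", "log_tlv"))
  expect_setequal(levels(tabS$labels), c("HC", "MS"))
  expect_equal(nrow(tabS$features), nrow(fx$records))
  tabD <- suppressMessages(buildFeatureTables(fx$kappaTable, fx$records,
                                              "disability"))
  hcIds <- fx$records$subject_id[fx$records$group == "HC"]
  expect_false(any(rownames(tabD$features) %in% hcIds))
  expect_error(buildFeatureTables(fx$kappaTable[, 1:3], fx$records,
                                  "status"),
               "lacks columns")
})

test_that("kappa in the disrupted cohort separates patients from controls", {
  fx <- disruptedCohortKappa()
  ms <- fx$records$group == "MS"
  expect_lt(mean(fx$kappaTable$multiplex[ms]),
            mean(fx$kappaTable$multiplex[!ms]))
  rep <- suppressMessages(runPredictionTask(fx$kappaTable, fx$records,
                                            "status", searchBudget = 4,
                                            nRepeats = 3, seed = 9))
  expect_gte(rep$oobAccuracy, 0.65)
  expect_equal(nrow(rep$importance), 6)
})
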