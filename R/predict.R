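#' @importFrom randomForest randomForest
NULL

# majority vote over each sample's out-of-bag trees; samples that are
# in-bag for every tree get NA and are excluded from accuracy
.oobVotes <- function(rf, X) {
  ind <- stats::predict(rf, X, predict.all = TRUE)$individual
  oob <- rf$inbag == 0
  lev <- levels(rf$y)
  votes <- matrix(0L, nrow(X), length(lev))
  for (k in seq_along(lev))
    votes[, k] <- rowSums((ind == lev[k]) & oob)
  pred <- lev[max.col(votes, ties.method = "first")]
  pred[rowSums(oob) == 0] <- NA
  factor(pred, levels = lev)
}

.oobAccuracy <- function(rf, X, y) {
  pred <- .oobVotes(rf, X)
  ok <- !is.na(pred)
  mean(pred[ok] == y[ok])
}

#' Fit a bagged decision-tree classifier with tuned hyperparameters
#'
#' Combines decision-tree learners with bootstrap aggregation
#' (a random-forest ensemble) and tunes the hyperparameters that matter -
#' features tried per split (`mtry`) and minimum node size - by a seeded
#' search minimizing the 10-fold cross-validated classification error
#' (1 - accuracy). Model performance is expressed as out-of-bag (OOB)
#' accuracy: each sample is predicted by majority vote of the trees whose
#' bootstrap resample excluded it.
#'
#' @param features numeric matrix or data.frame of predictors (finite).
#' @param labels two-or-more-level factor of class labels.
#' @param searchBudget maximum number of hyperparameter combinations
#'   evaluated by the cross-validated search.
#' @param seed RNG seed controlling the search, folds and final fit.
#' @param ntree trees in the final ensemble.
#' @param cvFolds folds of the tuning cross-validation.
#' @return list of class `bagged_trees` with `rf` (the fitted ensemble,
#'   with in-bag records kept), `X`, `y`, and `report`: feature names,
#'   `oobAccuracy`, tuned hyperparameters, CV error of the selected
#'   configuration and the seed.
#' @export
fitBaggedTrees <- function(features, labels, searchBudget = 12L,
                           seed = NULL, ntree = 500L, cvFolds = 10L) {
  X <- as.matrix(features)
  if (any(!is.finite(X))) stop("features must be finite")
  y <- factor(labels)
  y <- droplevels(y)
  if (nlevels(y) < 2L) stop("labels must contain at least 2 classes")
  if (nrow(X) < 20L) stop("need at least 20 samples")
  if (nrow(X) != length(y)) stop("features and labels disagree in length")
  if (!is.null(seed)) set.seed(seed)
  if (all(apply(X, 2, function(v) length(unique(v))) == 1L)) {
    # no feature can split a tree: the ensemble degenerates to the
    # majority-class predictor, whose out-of-bag accuracy is the majority
    # class proportion
    maj <- names(which.max(table(y)))
    report <- list(features = colnames(X),
                   oobAccuracy = mean(y == maj),
                   tuned = list(mtry = NA_integer_, nodesize = NA_integer_,
                                ntree = 0L),
                   cvError = 1 - mean(y == maj), seed = seed)
    return(structure(list(rf = NULL, majority = maj, X = X, y = y,
                          report = report), class = "bagged_trees"))
  }
  p <- ncol(X)
  grid <- expand.grid(mtry = seq_len(p), nodesize = c(1L, 5L, 10L))
  if (nrow(grid) > searchBudget)
    grid <- grid[sample.int(nrow(grid), searchBudget), , drop = FALSE]
  folds <- sample(rep_len(seq_len(cvFolds), nrow(X)))
  cvErr <- vapply(seq_len(nrow(grid)), function(g) {
    errs <- vapply(seq_len(cvFolds), function(f) {
      tr <- folds != f
      if (nlevels(droplevels(y[tr])) < 2L) return(NA_real_)
      fit <- randomForest(X[tr, , drop = FALSE], y[tr], ntree = 200L,
                          mtry = grid$mtry[g], nodesize = grid$nodesize[g])
      mean(stats::predict(fit, X[!tr, , drop = FALSE]) != y[!tr])
    }, numeric(1))
    mean(errs, na.rm = TRUE)
  }, numeric(1))
  best <- which.min(cvErr)
  rf <- randomForest(X, y, ntree = ntree, mtry = grid$mtry[best],
                     nodesize = grid$nodesize[best], keep.inbag = TRUE,
                     keep.forest = TRUE)
  oobAcc <- .oobAccuracy(rf, X, y)
  report <- list(
    features = colnames(X), oobAccuracy = oobAcc,
    tuned = list(mtry = grid$mtry[best], nodesize = grid$nodesize[best],
                 ntree = as.integer(ntree)),
    cvError = cvErr[best], seed = seed)
  structure(list(rf = rf, X = X, y = y, report = report),
            class = "bagged_trees")
}

#' Out-of-bag permutation feature importance
#'
#' For each feature, its values are permuted and the model's out-of-bag
#' accuracy recomputed; importance is the mean accuracy drop over
#' `nRepeats` permutations (with its SD). Every sample is scored only by
#' the trees that did not see it during training, so the drop measures
#' genuine predictive contribution rather than training fit.
#'
#' @param fit a `bagged_trees` object from [fitBaggedTrees()].
#' @param nRepeats permutations per feature.
#' @param seed optional RNG seed.
#' @return data.frame with `feature`, `importance` (mean OOB accuracy
#'   drop) and `sd`.
#' @export
oobPermutationImportance <- function(fit, nRepeats = 10L, seed = NULL) {
  if (!inherits(fit, "bagged_trees") || is.null(fit$rf$inbag))
    stop("fit must be a bagged_trees model with stored in-bag records")
  if (!is.null(seed)) set.seed(seed)
  X <- fit$X
  y <- fit$y
  base <- .oobAccuracy(fit$rf, X, y)
  p <- ncol(X)
  imp <- sdv <- numeric(p)
  for (j in seq_len(p)) {
    drops <- vapply(seq_len(nRepeats), function(r) {
      Xp <- X
      Xp[, j] <- X[sample.int(nrow(X)), j]
      base - .oobAccuracy(fit$rf, Xp, y)
    }, numeric(1))
    imp[j] <- mean(drops)
    sdv[j] <- stats::sd(drops)
  }
  nm <- colnames(X)
  if (is.null(nm)) nm <- paste0("feature", seq_len(p))
  data.frame(feature = nm, importance = imp, sd = sdv,
             stringsAsFactors = FALSE)
}

#' Assemble prediction features and labels for a clinical task
#'
#' Combines the per-subject coreness disruption indices in the four
#' domains (multiplex, MC, SC, FC) with conventional MRI measures:
#' age/sex-adjusted brain parenchymal fraction z-scores (HC-anchored, via
#' [adjustConfounders()]) and log-transformed total lesion volume
#' (`log(1 + TLV)`; controls, who have no MS lesions, enter the status
#' task with TLV 0). The `status` task uses all subjects with HC/MS
#' labels; `disability` and `ips` use patients only, labeled by
#' [dichotomizeClinical()]. Rows with missing inputs are dropped and
#' counted.
#'
#' @param kappaTable data.frame with columns `subject_id`, `multiplex`,
#'   `MC`, `SC`, `FC` (per-subject kappa in each domain).
#' @param records cohort record data.frame.
#' @param task `"status"`, `"disability"` or `"ips"`.
#' @return list with `features` (numeric matrix, 6 columns), `labels`
#'   (factor) and `dropped` (row count removed for missing data).
#' @export
buildFeatureTables <- function(kappaTable,
                               records,
                               task = c("status", "disability", "ips")) {
  task <- match.arg(task)
  need <- c("subject_id", "multiplex", "MC", "SC", "FC")
  miss <- setdiff(need, names(kappaTable))
  if (length(miss))
    stop(sprintf("kappaTable lacks columns: %s", paste(miss, collapse = ", ")))
  m <- merge(records, kappaTable, by = "subject_id", sort = FALSE)
  hc <- m$group == "HC"
  bpfZ <- adjustConfounders(m$bpf,
                            data.frame(age = m$age,
                                       sex = as.numeric(m$sex == "M")),
                            hcMask = hc)$z
  tlv <- m$tlv
  if (task == "status") tlv[hc & is.na(tlv)] <- 0
  feat <- cbind(kappa_multiplex = m$multiplex, kappa_mc = m$MC,
                kappa_sc = m$SC, kappa_fc = m$FC,
                bpf_z = bpfZ, log_tlv = log1p(tlv))
  rownames(feat) <- m$subject_id
  if (task == "status") {
    labels <- factor(m$group, levels = GROUP_LEVELS)
    keep <- rep(TRUE, nrow(m))
  } else {
    labels <- dichotomizeClinical(m, task)
    keep <- m$group == "MS" & !is.na(labels)
  }
  ok <- keep & stats::complete.cases(feat)
  dropped <- sum(keep) - sum(ok)
  if (dropped > 0)
    message(sprintf("%d row(s) dropped for missing inputs in the %s task",
                    dropped, task))
  if (!any(ok)) stop(sprintf("no usable rows for the %s task", task))
  list(features = feat[ok, , drop = FALSE],
       labels = droplevels(labels[ok]), dropped = dropped)
}

#' Run one clinical prediction task end to end
#'
#' Builds the feature table for the task, fits the tuned bagged-tree
#' ensemble and computes OOB permutation feature importance.
#'
#' @inheritParams buildFeatureTables
#' @param searchBudget hyperparameter combinations tried.
#' @param nRepeats importance permutations per feature.
#' @param seed RNG seed (controls tuning, fit and importance).
#' @return prediction report: list with `task`, `features`,
#'   `oobAccuracy`, `importance` (data.frame), `tuned`, `n`, `seed`.
#' @export
runPredictionTask <- function(kappaTable, records,
                              task = c("status", "disability", "ips"),
                              searchBudget = 12L, nRepeats = 10L,
                              seed = NULL) {
  task <- match.arg(task)
  tab <- buildFeatureTables(kappaTable, records, task)
  fit <- fitBaggedTrees(tab$features, tab$labels,
                        searchBudget = searchBudget, seed = seed)
  imp <- oobPermutationImportance(fit, nRepeats = nRepeats, seed = seed)
  list(task = task, features = fit$report$features,
       oobAccuracy = fit$report$oobAccuracy, importance = imp,
       tuned = fit$report$tuned, n = length(tab$labels),
       dropped = tab$dropped, seed = seed)
}
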