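#' Write a square connectivity matrix as TSV
#'
#' Tab-delimited square table with a node-label header row and a leading
#' node-label column; chosen for diff-ability and language neutrality.
#'
#' @param m square numeric matrix with node labels as dimnames.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeMatrixTSV <- function(m, path) {
  df <- data.frame(node = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = NA),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a square connectivity matrix from TSV
#'
#' @param path TSV file written in the layout of [writeMatrixTSV()].
#' @param expectedNodes optional node count to enforce.
#' @return numeric matrix with node labels as dimnames (not yet
#'   symmetrized).
#' @export
readMatrixTSV <- function(path, expectedNodes = NULL) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  labs <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- labs
  if (nrow(m) != ncol(m))
    stop(sprintf("matrix in '%s' is not square (%d x %d)", path,
                 nrow(m), ncol(m)))
  if (!is.null(expectedNodes) && nrow(m) != expectedNodes)
    stop(sprintf("matrix in '%s' has %d nodes, expected %d", path,
                 nrow(m), expectedNodes))
  m
}

.symmetrizeLoaded <- function(m, what) {
  asym <- max(abs(m - t(m)))
  if (asym > 1e-6)
    message(sprintf("%s: max asymmetry %.3g, symmetrized as (M + t(M))/2",
                    what, asym))
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}

#' Read a cohort from disk
#'
#' Reads the subject table, regional volumes, parcellation and the
#' per-subject raw SC/FC matrices (files named `<subject_id>_sc.tsv` and
#' `<subject_id>_fc.tsv` under `matrixDir`). Matrices are symmetrized as
#' `(M + t(M))/2` with the diagonal zeroed; an asymmetry above 1e-6 is
#' reported. Missing matrices, non-square matrices and unknown enum values
#' are hard errors.
#'
#' @param cohortPath TSV with the subject records.
#' @param volumesPath TSV with `subject_id` plus one column per node (ml).
#' @param matrixDir directory of per-subject matrix TSVs.
#' @param parcellationPath TSV with columns `label` and `system`.
#' @return a [CohortData-class].
#' @export
readCohort <- function(cohortPath, volumesPath, matrixDir,
                       parcellationPath) {
  for (f in c(cohortPath, volumesPath, parcellationPath))
    if (!file.exists(f)) stop(sprintf("file not found: %s", f))
  parc <- utils::read.delim(parcellationPath, stringsAsFactors = FALSE)
  rec <- utils::read.delim(cohortPath, stringsAsFactors = FALSE,
                           na.strings = "NA")
  rec$subject_id <- as.character(rec$subject_id)
  if (!is.null(rec$phenotype)) rec$phenotype <- as.character(rec$phenotype)
  vol <- utils::read.delim(volumesPath, check.names = FALSE,
                           stringsAsFactors = FALSE)
  volumes <- as.matrix(vol[, -1, drop = FALSE])
  storage.mode(volumes) <- "double"
  rownames(volumes) <- vol[[1]]
  volumes <- volumes[rec$subject_id, , drop = FALSE]
  n <- nrow(parc)
  scList <- fcList <- stats::setNames(vector("list", nrow(rec)),
                                      rec$subject_id)
  for (id in rec$subject_id) {
    for (layer in c("sc", "fc")) {
      path <- file.path(matrixDir, sprintf("%s_%s.tsv", id, layer))
      if (!file.exists(path))
        stop(sprintf("missing %s matrix for subject %s (expected %s)",
                     toupper(layer), id, path))
      m <- readMatrixTSV(path, expectedNodes = n)
      m <- .symmetrizeLoaded(m, sprintf("%s %s", id, toupper(layer)))
      if (layer == "sc") scList[[id]] <- m else fcList[[id]] <- m
    }
  }
  new("CohortData", records = rec, volumes = volumes, sc = scList,
      fc = fcList, parcellation = parc)
}

#' Write a cohort to disk
#'
#' Inverse of [readCohort()]: writes `cohort.tsv`, `volumes.tsv`,
#' `parcellation.tsv` and per-subject matrices under `matrices/`.
#'
#' @param cohort a [CohortData-class].
#' @param dir output directory (created if needed).
#' @return named list of written paths, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(file.path(dir, "matrices"), recursive = TRUE,
             showWarnings = FALSE)
  paths <- list(cohort = file.path(dir, "cohort.tsv"),
                volumes = file.path(dir, "volumes.tsv"),
                parcellation = file.path(dir, "parcellation.tsv"),
                matrixDir = file.path(dir, "matrices"))
  utils::write.table(cohort@records, paths$cohort, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  vol <- data.frame(subject_id = rownames(cohort@volumes), cohort@volumes,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(format(vol, digits = 17, trim = TRUE, scientific = NA),
                     paths$volumes, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort@parcellation, paths$parcellation, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (id in cohort@records$subject_id) {
    writeMatrixTSV(cohort@sc[[id]],
                   file.path(paths$matrixDir, sprintf("%s_sc.tsv", id)))
    writeMatrixTSV(cohort@fc[[id]],
                   file.path(paths$matrixDir, sprintf("%s_fc.tsv", id)))
  }
  invisible(paths)
}

#' Write pipeline results
#'
#' Writes the subjects x nodes coreness table and the subjects x domains
#' kappa table as TSV (deterministic column order: subject id first, then
#' nodes in parcellation order / domains multiplex, MC, SC, FC) and the
#' statistics and prediction reports as one JSON document.
#'
#' @param outDir output directory (must be writable; created if needed).
#' @param corenessTable subjects x nodes matrix (multiplex coreness).
#' @param kappaTable data.frame with `subject_id`, `multiplex`, `MC`,
#'   `SC`, `FC`.
#' @param statsReport list of statistics results (may be empty).
#' @param predictionReport list of prediction reports (may be empty).
#' @return named list of written paths, invisibly.
#' @export
writeResults <- function(outDir, corenessTable, kappaTable,
                         statsReport = list(), predictionReport = list()) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outDir) || file.access(outDir, 2) != 0)
    stop(sprintf("output directory '%s' is not writable", outDir))
  paths <- list(coreness = file.path(outDir, "coreness.tsv"),
                kappa = file.path(outDir, "kappa.tsv"),
                report = file.path(outDir, "report.json"))
  ct <- data.frame(subject_id = rownames(corenessTable), corenessTable,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(format(ct, digits = 17, trim = TRUE, scientific = NA),
                     paths$coreness, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  kt <- kappaTable[, c("subject_id", "multiplex", "MC", "SC", "FC")]
  utils::write.table(format(kt, digits = 17, trim = TRUE, scientific = NA),
                     paths$kappa, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(statistics = statsReport,
                            prediction = predictionReport),
                       paths$report, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE,
                       force = TRUE)
  invisible(paths)
}
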