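# File-format surface: PyClone-style bulk count TSV, genotype-matrix TSV,
# YAML run configuration, and the output files (calls, PSM, traces,
# manifest). TSV dialect: tab-separated, mandatory header, UTF-8, no
# quoting. Locus ids are "chrom:pos" strings with 1-based positions.

bulkRequiredCols <- c("mutation_id", "ref_counts", "var_counts",
                      "normal_cn", "minor_cn", "major_cn")

#' Validate a bulk count table
#'
#' Checks the PyClone-style schema (columns \code{mutation_id, ref_counts,
#' var_counts, normal_cn, minor_cn, major_cn}), non-negative counts and
#' unique locus ids, reporting offending line numbers.
#'
#' @param bulk data.frame to validate.
#' @return The validated data.frame (count columns coerced to integer).
#' @export
validateBulkTable <- function(bulk) {
  missing <- setdiff(bulkRequiredCols, names(bulk))
  if (length(missing) > 0L) {
    stop("bulk table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("ref_counts", "var_counts", "normal_cn", "minor_cn", "major_cn")) {
    v <- suppressWarnings(as.integer(bulk[[col]]))
    bad <- which(is.na(v) | v < 0)
    if (length(bad) > 0L) {
      stop(sprintf("bulk table column '%s': malformed value at row %d",
                   col, bad[1L]), call. = FALSE)
    }
    bulk[[col]] <- v
  }
  if (anyDuplicated(bulk$mutation_id)) {
    stop("duplicated mutation_id in bulk table", call. = FALSE)
  }
  bulk
}

#' Read a bulk count TSV
#'
#' @param path Path to a tab-separated file with the PyClone-style columns
#'   of \code{\link{validateBulkTable}}.
#' @return Validated data.frame.
#' @export
readBulkTable <- function(path) {
  validateBulkTable(utils::read.delim(path, stringsAsFactors = FALSE,
                                      check.names = FALSE))
}

#' Read a genotype matrix TSV
#'
#' First column: genotype/cell id; remaining columns: locus ids
#' ("chrom:pos"); entries 0/1.
#'
#' @param path Path to the TSV.
#' @return A \linkS4class{ScGenotypes}.
#' @export
readGenotypeMatrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- as.character(df[[1L]])
  ScGenotypes(mat)
}

#' Write a genotype matrix TSV
#'
#' @param delta \linkS4class{ScGenotypes}.
#' @param path Output path.
#' @export
writeGenotypeMatrix <- function(delta, path) {
  df <- data.frame(id = rownames(delta), delta@.Data, check.names = FALSE)
  writeTsv(df, path)
}

writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a YAML run configuration
#'
#' Maps the YAML keys (iterations, burnin_fraction, grid_size, alpha, a, s,
#' epsilon, tumour_content, state_prior_strategy, seed,
#' resample_hyperparams, decay, fn_weight, fp_weight) onto
#' \code{\link{ddcloneParams}}; unknown keys are fatal.
#'
#' @param path Path to the YAML file.
#' @return A \code{ddcloneParams} list.
#' @export
readConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  keyMap <- c(iterations = "iterations", burnin_fraction = "burninFraction",
              grid_size = "gridSize", alpha = "alpha", a = "a", s = "s",
              epsilon = "epsilon", tumour_content = "tumourContent",
              state_prior_strategy = "statePriorStrategy", seed = "seed",
              resample_hyperparams = "resampleHyperparams", decay = "decay",
              scan_order = "scanOrder", fn_weight = "fnWeight",
              fp_weight = "fpWeight")
  unknown <- setdiff(names(cfg), names(keyMap))
  if (length(unknown) > 0L) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  args <- stats::setNames(cfg, keyMap[names(cfg)])
  do.call(ddcloneParams, args)
}

writeManifest <- function(path, command, params, inputs = character()) {
  hashes <- vapply(inputs, function(f) {
    as.character(tools::md5sum(f))
  }, character(1))
  manifest <- list(command = command,
                   version = as.character(utils::packageVersion("ddclone")),
                   seed = params$seed,
                   params = unclass(params),
                   input_md5 = as.list(hashes),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

# Write via a temporary file in the same directory, then rename: readers
# never observe a half-written output.
atomically <- function(path, writer) {
  tmp <- paste0(path, ".tmp")
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Run the full pipeline on input files
#'
#' File-level wrapper around \code{\link{runDdclone}} +
#' \code{\link{summarizeClones}}: reads the bulk TSV, genotype TSV and
#' optional YAML config, runs inference and writes \code{calls.tsv},
#' \code{psm.tsv}, the MEM/POM reports, gzipped per-iteration cluster and
#' prevalence traces, and \code{manifest.json} into \code{outDir}. All
#' outputs are written atomically.
#'
#' @param bulkFile,genotypeFile Input TSV paths.
#' @param configFile Optional YAML config path.
#' @param outDir Output directory (created if needed).
#' @param seed Optional seed overriding the config.
#' @return Invisibly, the calls data.frame.
#' @export
ddcloneRunFiles <- function(bulkFile, genotypeFile, configFile = NULL,
                            outDir = ".", seed = NULL) {
  params <- if (is.null(configFile)) ddcloneParams() else readConfig(configFile)
  if (!is.null(seed)) params$seed <- as.integer(seed)
  bulk <- readBulkTable(bulkFile)
  delta <- readGenotypeMatrix(genotypeFile)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  fit <- runDdclone(bulk, delta, params = params)
  calls <- summarizeClones(fit)
  psm <- posteriorSimilarity(fit)
  shared <- lociIds(fit)
  deltaShared <- ScGenotypes(delta@.Data[, shared, drop = FALSE])
  mems <- findMems(deltaShared)
  poms <- findPoms(deltaShared, calls$cluster, bulk)
  atomically(file.path(outDir, "calls.tsv"), function(p) writeTsv(calls, p))
  atomically(file.path(outDir, "psm.tsv"), function(p) {
    writeTsv(data.frame(mutation_id = rownames(psm), psm,
                        check.names = FALSE), p)
  })
  atomically(file.path(outDir, "mems.tsv"), function(p) writeTsv(mems, p))
  atomically(file.path(outDir, "poms.tsv"), function(p) writeTsv(poms, p))
  atomically(file.path(outDir, "cluster_trace.tsv.gz"), function(p) {
    con <- gzfile(p, "w")
    utils::write.table(clusterTrace(fit), con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = shared)
    close(con)
  })
  atomically(file.path(outDir, "phi_trace.tsv.gz"), function(p) {
    con <- gzfile(p, "w")
    utils::write.table(phiTrace(fit), con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = shared)
    close(con)
  })
  writeManifest(file.path(outDir, "manifest.json"), "run", params,
                c(bulkFile, genotypeFile))
  invisible(calls)
}

#' Simulate a dataset to files
#'
#' Emits bulk TSV, clone genotype TSV, (possibly corrupted) cell matrix
#' TSV, ground-truth TSV and a JSON manifest of all parameters.
#'
#' @param outDir Output directory.
#' @param nGenotypes,nLoci,nCells Simulation dimensions.
#' @param concentration,rDoublet,rAdo Noise settings (see the simulator
#'   functions).
#' @param meanDepth,tumourContent,s,epsilon Bulk read-count settings.
#' @param seed RNG seed.
#' @return Invisibly, the output directory.
#' @export
ddcloneSimulateFiles <- function(outDir, nGenotypes = 10, nLoci = 48,
                                 nCells = 50, concentration = Inf,
                                 rDoublet = 0, rAdo = 0, meanDepth = 1000,
                                 tumourContent = 1, s = 100, epsilon = 0.001,
                                 seed = 1) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  sim <- simulateClones(nGenotypes, nLoci)
  bk <- simulateBulk(sim, meanDepth = meanDepth,
                     tumourContent = tumourContent, s = s, epsilon = epsilon)
  cs <- sampleCells(sim, nCells, concentration = concentration)
  cells <- applyDoublets(cs$cells, rDoublet, sim,
                         phiObserved = cs$phiObserved)$cells
  cells <- applyAdo(cells, rAdo)
  atomically(file.path(outDir, "bulk.tsv"),
             function(p) writeTsv(bk$bulk, p))
  atomically(file.path(outDir, "genotypes.tsv"),
             function(p) writeGenotypeMatrix(cloneGenotypes(sim), p))
  atomically(file.path(outDir, "cells.tsv"),
             function(p) writeGenotypeMatrix(ScGenotypes(cells), p))
  atomically(file.path(outDir, "truth.tsv"),
             function(p) writeTsv(bk$truth, p))
  params <- list(nGenotypes = nGenotypes, nLoci = nLoci, nCells = nCells,
                 concentration = concentration, rDoublet = rDoublet,
                 rAdo = rAdo, meanDepth = meanDepth,
                 tumourContent = tumourContent, s = s, epsilon = epsilon,
                 seed = seed)
  writeManifest(file.path(outDir, "manifest.json"), "simulate", params)
  invisible(outDir)
}

#' Score calls against ground truth, to files
#'
#' @param truthFile TSV with \code{mutation_id}, \code{true_phi},
#'   \code{true_cluster}.
#' @param callsFile TSV with \code{mutation_id}, \code{cluster},
#'   \code{phi_hat} (as written by \code{\link{ddcloneRunFiles}}).
#' @param outFile Optional JSON output path.
#' @return List with \code{v_measure} and \code{mean_phi_error}.
#' @export
ddcloneEvaluateFiles <- function(truthFile, callsFile, outFile = NULL) {
  truth <- utils::read.delim(truthFile, stringsAsFactors = FALSE)
  calls <- utils::read.delim(callsFile, stringsAsFactors = FALSE)
  m <- match(calls$mutation_id, truth$mutation_id)
  if (anyNA(m)) stop("calls contain loci absent from the truth table", call. = FALSE)
  truth <- truth[m, ]
  metrics <- list(v_measure = vMeasure(truth$true_cluster, calls$cluster),
                  mean_phi_error = meanPhiError(truth$true_phi,
                                                pmin(1, pmax(0, calls$phi_hat))),
                  n_loci = nrow(calls))
  if (!is.null(outFile)) {
    jsonlite::write_json(metrics, outFile, auto_unbox = TRUE, digits = NA)
  }
  metrics
}
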