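# Benchmark metrics (V-measure, mean prevalence error), the concentration
# calibration against bulk/single-cell concordance, and the grid harness
# that drives simulate -> infer -> summarize -> score sweeps.

entropyFromCounts <- function(n) {
  p <- n[n > 0] / sum(n)
  -sum(p * log(p))
}

#' V-measure clustering agreement
#'
#' Harmonic mean of homogeneity (each predicted cluster contains members of
#' a single true class) and completeness (each true class is assigned to a
#' single predicted cluster), computed from the label contingency table
#' with natural-log entropies (beta = 1). Invariant to permutations of
#' either labelling.
#'
#' @param trueLabels,predLabels Equal-length categorical label vectors.
#' @return Score in [0, 1]; 1 iff the partitions are identical.
#' @examples
#' vMeasure(c(1, 1, 2, 2), c(2, 2, 1, 1))  # 1: same partition
#' vMeasure(c(1, 1, 2, 2), c(1, 1, 1, 1))  # 0: single predicted cluster
#' @export
vMeasure <- function(trueLabels, predLabels) {
  if (length(trueLabels) != length(predLabels)) {
    stop("label vectors must have equal length", call. = FALSE)
  }
  tab <- table(trueLabels, predLabels)
  n <- sum(tab)
  hC <- entropyFromCounts(rowSums(tab))
  hK <- entropyFromCounts(colSums(tab))
  # conditional entropies from the joint table
  hCgivenK <- -sum(vapply(seq_len(ncol(tab)), function(k) {
    nk <- tab[, k]
    pos <- nk > 0
    sum(nk[pos] / n * log(nk[pos] / sum(nk)))
  }, numeric(1)))
  hKgivenC <- -sum(vapply(seq_len(nrow(tab)), function(c) {
    nc <- tab[c, ]
    pos <- nc > 0
    sum(nc[pos] / n * log(nc[pos] / sum(nc)))
  }, numeric(1)))
  h <- if (hC == 0) 1 else 1 - hCgivenK / hC
  cpl <- if (hK == 0) 1 else 1 - hKgivenC / hK
  if (h + cpl == 0) 0 else 2 * h * cpl / (h + cpl)
}

#' Mean absolute cellular prevalence error
#'
#' Average over loci of \code{|phi_hat - phi_true|}, the prevalence accuracy
#' metric used throughout the benchmarks.
#'
#' @param phiTrue,phiHat Equal-length vectors of prevalences in [0, 1].
#' @return Mean absolute error.
#' @export
meanPhiError <- function(phiTrue, phiHat) {
  if (length(phiTrue) != length(phiHat)) {
    stop("prevalence vectors must have equal length", call. = FALSE)
  }
  assertProb(phiTrue, "phiTrue"); assertProb(phiHat, "phiHat")
  mean(abs(phiHat - phiTrue))
}

#' Per-locus prevalence estimators for bulk/single-cell concordance
#'
#' The single-cell-side estimate of a locus's cellular prevalence is the
#' fraction of cells mutated there; the bulk-side estimate is the
#' copy-number- and cellularity-corrected VAF,
#' \code{min(1, vaf * total_cn / t)}. These feed the concordance (R^2)
#' matching of \code{\link{estimateConcentration}}.
#'
#' @param cells Binary cells x loci matrix.
#' @return Numeric vector of per-locus prevalence estimates.
#' @export
scPhiEstimate <- function(cells) colMeans(cells)

#' @rdname scPhiEstimate
#' @param bulk Bulk count table.
#' @param tumourContent Cellularity t.
#' @export
bulkPhiEstimate <- function(bulk, tumourContent = 1) {
  vaf <- bulk$var_counts / pmax(bulk$var_counts + bulk$ref_counts, 1L)
  pmin(1, vaf * (bulk$major_cn + bulk$minor_cn) / tumourContent)
}

#' Calibrate the assortment-bias concentration from concordance
#'
#' Estimates the Dirichlet-multinomial concentration of a real dataset by
#' matching its observed bulk/single-cell prevalence concordance (squared
#' Pearson correlation, R^2) against a simulated calibration curve: for
#' each grid concentration, paired datasets are simulated, their R^2
#' averaged and the curve monotone-smoothed (isotonic regression); the
#' returned concentration is the log-scale linear interpolation at the
#' observed R^2. Observed values outside the simulated range return the
#' boundary concentration with a warning.
#'
#' @param bulkPhi,scPhi Paired per-locus prevalence estimates from the bulk
#'   and single-cell sides of the dataset.
#' @param lambdaGrid Concentrations at which to simulate the curve.
#' @param nReps Simulated replicates per grid value.
#' @param nGenotypes,nLoci,nCells Simulation dimensions.
#' @param seed RNG seed for the calibration simulations.
#' @return The matched concentration (a single number) with attribute
#'   \code{"curve"} (data.frame of concentration and mean R^2).
#' @export
estimateConcentration <- function(bulkPhi, scPhi,
                                  lambdaGrid = c(0.01, 0.1, 1, 10, 100, 1000),
                                  nReps = 10, nGenotypes = 10, nLoci = 48,
                                  nCells = 50, seed = 1) {
  if (length(bulkPhi) != length(scPhi)) {
    stop("paired prevalence estimates must have equal length", call. = FALSE)
  }
  r2 <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
    stats::cor(x, y)^2
  }
  # calibration simulations are seeded locally; the caller's RNG stream is
  # restored on exit
  oldSeed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv()))
  set.seed(seed)
  curve <- vapply(lambdaGrid, function(lam) {
    mean(vapply(seq_len(nReps), function(r) {
      sim <- simulateClones(nGenotypes, nLoci)
      cs <- sampleCells(sim, nCells, concentration = lam)
      bk <- simulateBulk(sim)
      shared <- match(bk$bulk$mutation_id, lociIds(sim))
      r2(bulkPhiEstimate(bk$bulk), scPhiEstimate(cs$cells)[shared])
    }, numeric(1)))
  }, numeric(1))
  smooth <- stats::isoreg(log(lambdaGrid), curve)$yf
  obs <- r2(bulkPhi, scPhi)
  out <- if (obs <= min(smooth)) {
    warning("observed R^2 below simulated curve; returning smallest concentration")
    lambdaGrid[1L]
  } else if (obs >= max(smooth)) {
    warning("observed R^2 above simulated curve; returning largest concentration")
    lambdaGrid[length(lambdaGrid)]
  } else {
    exp(stats::approx(smooth, log(lambdaGrid), xout = obs, ties = "ordered")$y)
  }
  attr(out, "curve") <- data.frame(concentration = lambdaGrid, r2 = smooth)
  out
}

#' Simulate-infer-score benchmark grid
#'
#' For every combination of the supplied noise settings: simulate a clone
#' set and bulk counts, sample (and corrupt) single cells, run the full
#' inference, summarize, and score clustering (V-measure) and prevalence
#' accuracy (mean absolute error) against the ground truth. Failures in a
#' grid cell are logged and reported as NA rows, not fatal.
#'
#' @param nDatasets Replicate clone sets per grid cell.
#' @param concentration,nCells,rDoublet,rAdo,nHidden Noise grids (vectors;
#'   the full factorial design is run). \code{concentration = Inf} samples
#'   cells without assortment bias.
#' @param nGenotypes,nLoci Simulation dimensions.
#' @param params \code{\link{ddcloneParams}} used for every inference run.
#' @param useCellMatrix Feed the sampled (possibly corrupted) cell matrix
#'   to the prior (TRUE, as in the noise benchmarks); FALSE uses the true
#'   clone genotype matrix, optionally after hiding genotypes.
#' @param seed Base seed; dataset d uses \code{seed + d}.
#' @return data.frame with one row per grid cell x dataset: the settings,
#'   \code{v_measure}, \code{mean_phi_error} and \code{n_loci} scored.
#' @export
runBenchmark <- function(nDatasets = 10, concentration = Inf, nCells = 50,
                         rDoublet = 0, rAdo = 0, nHidden = 0,
                         nGenotypes = 10, nLoci = 48,
                         params = ddcloneParams(), useCellMatrix = TRUE,
                         seed = 1) {
  grid <- expand.grid(dataset = seq_len(nDatasets),
                      concentration = concentration, nCells = nCells,
                      rDoublet = rDoublet, rAdo = rAdo, nHidden = nHidden,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(r) {
    g <- grid[r, ]
    out <- try({
      set.seed(seed + g$dataset)
      sim <- simulateClones(nGenotypes, nLoci)
      bk <- simulateBulk(sim)
      prior <- if (useCellMatrix) {
        cs <- sampleCells(sim, g$nCells, concentration = g$concentration)
        cells <- applyDoublets(cs$cells, g$rDoublet, sim,
                               phiObserved = cs$phiObserved)$cells
        ScGenotypes(applyAdo(cells, g$rAdo))
      } else {
        hideGenotypes(sim, g$nHidden)
      }
      p <- params
      p$seed <- seed + g$dataset
      fit <- suppressMessages(suppressWarnings(runDdclone(bk$bulk, prior,
                                                          params = p)))
      calls <- summarizeClones(fit)
      truth <- bk$truth[match(calls$mutation_id, bk$truth$mutation_id), ]
      data.frame(v_measure = vMeasure(truth$true_cluster, calls$cluster),
                 mean_phi_error = meanPhiError(truth$true_phi, calls$phi_hat),
                 n_loci = nrow(calls))
    }, silent = TRUE)
    if (inherits(out, "try-error")) {
      message(sprintf("benchmark cell %d failed: %s", r, attr(out, "condition")$message))
      out <- data.frame(v_measure = NA_real_, mean_phi_error = NA_real_,
                        n_loci = NA_integer_)
    }
    cbind(g, out)
  })
  do.call(rbind, res)
}
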