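# Synthetic ground truth: clone genotypes from a Dollo gain/loss process on
# a random phylogeny, single-cell sampling with Dirichlet-multinomial
# assortment bias, doublet and allelic-dropout corruption, and
# beta-binomial bulk read counts under the three-subpopulation model.

# Exact Dirichlet draw that is stable for arbitrarily small concentrations:
# Gamma(a) == Gamma(a + 1) * U^{1/a} lets us work in log space, so tiny
# shapes (near-one-hot draws) never underflow to an all-zero vector.
rdirichletLog <- function(shape) {
  stopifnot(all(shape > 0))
  logx <- log(stats::rgamma(length(shape), shape + 1, 1)) +
    log(stats::runif(length(shape))) / shape
  w <- exp(logx - max(logx))
  w / sum(w)
}

#' Simulate clone genotypes on a random phylogeny
#'
#' Grows a random binary tree with \code{nGenotypes} leaves by sequential
#' random edge attachment, then evolves each locus under a Dollo process:
#' the mutation is gained on one uniformly chosen edge (and inherited by all
#' descendants) and lost independently on each strict-descendant edge with
#' probability \code{pLoss} (single gain, multiple losses). Mutated
#' genotypes carry 1 or 2 variant copies; per-locus total copy number is 2,
#' 3 or 4 with probabilities \code{totalCnProbs}. The genotype matrix is the
#' binarized (variant copies > 0) carrier matrix. Clonal prevalences are a
#' symmetric Dirichlet(1) draw over genotypes.
#'
#' @param nGenotypes Number of clone genotypes (tree leaves), >= 2.
#' @param nLoci Number of genomic loci.
#' @param pLoss Per-edge loss probability of the Dollo process.
#' @param totalCnProbs Named probabilities of per-locus total copy number.
#' @param seed Optional RNG seed.
#' @return A \linkS4class{CloneSim}.
#' @examples
#' sim <- simulateClones(10, 48, seed = 1)
#' @export
simulateClones <- function(nGenotypes, nLoci, pLoss = 0.1,
                           totalCnProbs = c("2" = 0.7, "3" = 0.2, "4" = 0.1),
                           seed = NULL) {
  stopifnot(nGenotypes >= 2, nLoci >= 1, pLoss >= 0, pLoss <= 1)
  if (!is.null(seed)) set.seed(seed)
  M <- as.integer(nGenotypes)
  nLoci <- as.integer(nLoci)
  # Nodes: leaves 1..M, internal M+1..2M-1; parent[v] = 0 marks the root.
  nNodes <- 2L * M - 1L
  parent <- integer(nNodes)
  root <- M + 1L
  parent[1L] <- root; parent[2L] <- root
  nextInternal <- root
  for (leaf in seq_len(M)[-(1:2)]) {
    attachable <- which(parent != 0L)         # nodes below an existing edge
    e <- if (length(attachable) == 1L) attachable else sample(attachable, 1L)
    nextInternal <- nextInternal + 1L
    parent[nextInternal] <- parent[e]
    parent[e] <- nextInternal
    parent[leaf] <- nextInternal
  }
  children <- lapply(seq_len(nNodes), function(v) which(parent == v))
  leavesUnder <- function(v) {
    if (v <= M) return(v)
    unlist(lapply(children[[v]], leavesUnder))
  }
  edgeNodes <- which(parent != 0L)            # nodes with an incoming edge
  geno <- matrix(0L, M, nLoci)
  for (j in seq_len(nLoci)) {
    gain <- if (length(edgeNodes) == 1L) edgeNodes else sample(edgeNodes, 1L)
    present <- logical(nNodes)
    present[gain] <- TRUE
    stack <- gain
    while (length(stack) > 0L) {              # propagate with per-edge loss
      v <- stack[1L]; stack <- stack[-1L]
      for (w in children[[v]]) {
        present[w] <- present[v] && (stats::runif(1) > pLoss)
        stack <- c(stack, w)
      }
    }
    geno[, j] <- as.integer(present[seq_len(M)])
  }
  chrom <- (seq_len(nLoci) - 1L) %% 22L + 1L
  pos <- 10000L + 137L * seq_len(nLoci)
  colnames(geno) <- sprintf("%d:%d", chrom, pos)
  rownames(geno) <- paste0("clone", seq_len(M))
  totalCn <- as.integer(sample(names(totalCnProbs), nLoci, replace = TRUE,
                               prob = totalCnProbs))
  varCopies <- sample(1:2, nLoci, replace = TRUE)
  cn <- data.frame(locus_id = colnames(geno),
                   total_cn = totalCn,
                   major_cn = pmax(varCopies, totalCn - varCopies),
                   minor_cn = pmin(varCopies, totalCn - varCopies),
                   var_copies = varCopies,
                   stringsAsFactors = FALSE)
  new("CloneSim", genotypes = ScGenotypes(geno),
      prevalences = rdirichletLog(rep(1, M)),
      tree = parent, cnStates = cn)
}

#' Sample single cells with assortment bias
#'
#' Observed genotype prevalences are drawn from
#' \code{Dirichlet(concentration * Phi)} around the true clonal prevalences
#' \code{Phi} (\code{concentration = Inf} uses \code{Phi} exactly), then
#' \code{nCells} cells are drawn multinomially — together a
#' Dirichlet-multinomial cell assortment. Small concentrations give
#' near-one-hot observed prevalences, i.e. heavily biased cell sampling.
#'
#' @param clones A \linkS4class{CloneSim}.
#' @param nCells Number of cells to sample.
#' @param concentration Dirichlet concentration coefficient (> 0, or
#'   \code{Inf} for unbiased multinomial sampling).
#' @param seed Optional RNG seed.
#' @return List with \code{cells} (cells x loci binary matrix),
#'   \code{phiObserved} (the Dirichlet draw), \code{genotypeOfCell}
#'   (integer genotype index per cell) and \code{counts} (cells per
#'   genotype).
#' @export
sampleCells <- function(clones, nCells, concentration = Inf, seed = NULL) {
  stopifnot(nCells >= 1, concentration > 0)
  if (!is.null(seed)) set.seed(seed)
  phi <- clonePrevalences(clones)
  phiObs <- if (is.infinite(concentration)) phi else {
    rdirichletLog(concentration * pmax(phi, .Machine$double.xmin))
  }
  counts <- as.vector(stats::rmultinom(1L, nCells, phiObs))
  assign <- rep.int(seq_along(counts), counts)
  cells <- cloneGenotypes(clones)@.Data[assign, , drop = FALSE]
  rownames(cells) <- paste0("cell", seq_len(nCells))
  list(cells = cells, phiObserved = phiObs, genotypeOfCell = assign,
       counts = counts)
}

#' Corrupt sampled cells with doublets
#'
#' Replaces \code{floor(rate * m)} randomly chosen rows by the element-wise
#' OR of the original row and a freshly sampled co-trapped cell (drawn by
#' the same cell-sampling law, i.e. multinomially from
#' \code{phiObserved}), emulating two cells captured in one well.
#'
#' @param cells Binary cells x loci matrix.
#' @param rate Doublet rate in [0, 1].
#' @param clones The \linkS4class{CloneSim} the cells came from.
#' @param phiObserved Observed prevalences used to draw co-trapped cells
#'   (defaults to the true prevalences).
#' @param seed Optional RNG seed.
#' @return List with \code{cells} (same dimensions, corrupted),
#'   \code{doubletRows} (indices of replaced rows) and \code{partner}
#'   (genotype index of each co-trapped cell).
#' @export
applyDoublets <- function(cells, rate, clones, phiObserved = NULL,
                          seed = NULL) {
  assertProb(rate, "rate")
  if (!is.null(seed)) set.seed(seed)
  m <- nrow(cells)
  nd <- floor(rate * m)
  if (nd == 0L) {
    return(list(cells = cells, doubletRows = integer(0), partner = integer(0)))
  }
  if (is.null(phiObserved)) phiObserved <- clonePrevalences(clones)
  rows <- sample.int(m, nd)
  partner <- sample.int(length(phiObserved), nd, replace = TRUE,
                        prob = phiObserved)
  geno <- cloneGenotypes(clones)@.Data
  cells[rows, ] <- 1L * ((cells[rows, , drop = FALSE] +
                            geno[partner, , drop = FALSE]) > 0L)
  list(cells = cells, doubletRows = rows, partner = partner)
}

#' Corrupt sampled cells with allelic dropout
#'
#' Flips exactly \code{round(rate * #ones)} mutated entries to zero, chosen
#' uniformly without replacement across the whole matrix; unmutated entries
#' are never altered (dropout of a reference allele leaves the binary
#' genotype unchanged).
#'
#' @param cells Binary cells x loci matrix.
#' @param rate ADO rate in [0, 1].
#' @param seed Optional RNG seed.
#' @return Corrupted matrix of identical dimensions.
#' @export
applyAdo <- function(cells, rate, seed = NULL) {
  assertProb(rate, "rate")
  if (!is.null(seed)) set.seed(seed)
  ones <- which(cells == 1L)
  k <- round(rate * length(ones))
  if (k > 0L) {
    cells[if (length(ones) == 1L) ones else sample(ones, k)] <- 0L
  }
  cells
}

#' Hide low-prevalence genotypes from the prior
#'
#' Removes the \code{k} lowest-prevalence genotype rows (ties broken by row
#' index), emulating clonal genotype loss through under-sampling.
#'
#' @param clones A \linkS4class{CloneSim}.
#' @param k Number of genotypes to hide, \code{0 <= k < M}.
#' @return \linkS4class{ScGenotypes} with the remaining rows.
#' @export
hideGenotypes <- function(clones, k) {
  phi <- clonePrevalences(clones)
  if (k < 0 || k >= length(phi)) stop("need 0 <= k < number of genotypes", call. = FALSE)
  keep <- sort(order(phi, seq_along(phi))[seq_len(length(phi) - k) + k])
  ScGenotypes(cloneGenotypes(clones)@.Data[keep, , drop = FALSE])
}

#' Simulate bulk read counts from a clone set
#'
#' For every locus carried by at least one genotype: the true cellular
#' prevalence is the summed prevalence of its carrier genotypes, the locus
#' genotype state is assembled from the simulated copy-number state, depth
#' is Poisson and the variant count beta-binomial with mean
#' \code{xi(psi, phi, t)} and precision \code{s} (\code{s = Inf} draws
#' exact binomial counts). Loci carried by no genotype (lost everywhere)
#' produce no variant and are excluded.
#'
#' @param clones A \linkS4class{CloneSim}.
#' @param meanDepth Mean sequencing depth (Poisson).
#' @param tumourContent Cellularity t of the simulated sample.
#' @param s Beta-binomial precision (Inf = binomial).
#' @param epsilon Sequencing error probability.
#' @param seed Optional RNG seed.
#' @return List with \code{bulk} (PyClone-style count table) and
#'   \code{truth} (per-locus \code{true_phi} and \code{true_cluster}; loci
#'   with identical carrier sets share a cluster).
#' @export
simulateBulk <- function(clones, meanDepth = 1000, tumourContent = 1,
                         s = 100, epsilon = 0.001, seed = NULL) {
  stopifnot(meanDepth > 0, s > 0)
  assertProb(tumourContent, "tumourContent")
  if (!is.null(seed)) set.seed(seed)
  geno <- cloneGenotypes(clones)@.Data
  phiTrue <- as.vector(clonePrevalences(clones) %*% geno)
  carried <- which(phiTrue > 0)
  cn <- clones@cnStates
  t <- tumourContent
  rows <- lapply(carried, function(j) {
    psi <- list(c(2L, 0L),
                c(cn$total_cn[j], 0L),
                c(cn$total_cn[j] - cn$var_copies[j], cn$var_copies[j]))
    d <- stats::rpois(1L, meanDepth)
    m <- xiExpectedVaf(psi, phiTrue[j], t, epsilon)
    b <- if (d == 0L) 0L else if (is.infinite(s)) {
      stats::rbinom(1L, d, m)
    } else {
      stats::rbinom(1L, d, stats::rbeta(1L, s * m, s * (1 - m)))
    }
    data.frame(mutation_id = cn$locus_id[j], ref_counts = d - b,
               var_counts = b, normal_cn = 2L, minor_cn = cn$minor_cn[j],
               major_cn = cn$major_cn[j], stringsAsFactors = FALSE)
  })
  bulk <- do.call(rbind, rows)
  carrierKey <- apply(geno[, carried, drop = FALSE], 2L, paste, collapse = "")
  truth <- data.frame(mutation_id = cn$locus_id[carried],
                      true_phi = phiTrue[carried],
                      true_cluster = match(carrierKey, unique(carrierKey)),
                      stringsAsFactors = FALSE)
  list(bulk = bulk, truth = truth)
}

#' Average absolute prevalence error
#'
#' \code{e_Phi = (1/M) sum_i |Phi_i - Phi_i^observed|}: the mean absolute
#' difference between true and observed genotype prevalences, the
#' assortment-bias summary of a cell sample.
#'
#' @param phi,phiObserved Simplex vectors of equal length.
#' @return A single non-negative number.
#' @export
ePhi <- function(phi, phiObserved) {
  if (length(phi) != length(phiObserved)) {
    stop("prevalence vectors must have equal length", call. = FALSE)
  }
  mean(abs(phi - phiObserved))
}
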