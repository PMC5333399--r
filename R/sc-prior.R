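# Between-locus distances from single-cell genotype co-occurrence, and the
# distance-dependent CRP link prior built on them.

asBinaryMatrix <- function(delta) {
  if (is(delta, "ScGenotypes")) delta <- delta@.Data
  delta <- as.matrix(delta)
  if (!all(delta %in% c(0, 1))) stop("genotype matrix must be binary", call. = FALSE)
  storage.mode(delta) <- "double"
  delta
}

#' Jaccard distance between genomic loci
#'
#' Treats each column of the genotype matrix as the set of genotypes carrying
#' that mutation and returns the pairwise Jaccard distance
#' \code{1 - |A intersect B| / |A union B|}. Loci that never co-occur in any
#' genotype (empty intersection, non-empty union) are at distance exactly 1;
#' these are the mutually exclusive mutation (MEM) pairs.
#'
#' A pair of all-zero columns has an empty union; its distance is defined as
#' 1 (no co-occurrence evidence, so the bulk likelihood should dominate) and
#' a warning is emitted.
#'
#' @param delta \linkS4class{ScGenotypes} or binary genotypes-by-loci matrix.
#' @return Symmetric N x N matrix in [0, 1] with zero diagonal, locus ids as
#'   dimnames.
#' @examples
#' d <- ScGenotypes(matrix(c(1, 1, 0, 1, 0, 1), nrow = 3,
#'                  dimnames = list(NULL, c("1:1", "1:2"))))
#' jaccardDistanceMatrix(d)  # 2/3 off-diagonal
#' @seealso \code{\link{modifiedJaccardDistanceMatrix}} for the noise-weighted
#'   variant, \code{\link{findMems}}.
#' @export
jaccardDistanceMatrix <- function(delta) {
  modifiedJaccardDistanceMatrix(delta, fnWeight = 1, fpWeight = 1)
}

#' Noise-weighted (modified) Jaccard distance between loci
#'
#' Generalizes \code{\link{jaccardDistanceMatrix}} to account for the
#' asymmetric error rates of single-cell genotyping:
#' \deqn{d(A,B) = 1 - w_{fp} n_{11} / (w_{fp} n_{11} + w_{fn}(n_{10}+n_{01}))}
#' where \code{n11} counts genotypes carrying both mutations and
#' \code{n10 + n01} counts disagreements. \code{fnWeight < 1} down-weights
#' disagreements (candidate false negatives from allelic dropout);
#' \code{fpWeight < 1} down-weights co-occurrences (candidate doublet-driven
#' false positives). With both weights 1 this is the plain Jaccard distance.
#'
#' @param delta \linkS4class{ScGenotypes} or binary genotypes-by-loci matrix.
#' @param fnWeight,fpWeight Weights in [0, 1].
#' @return Symmetric N x N distance matrix in [0, 1], zero diagonal.
#' @export
modifiedJaccardDistanceMatrix <- function(delta, fnWeight = 1, fpWeight = 1) {
  X <- asBinaryMatrix(delta)
  if (fnWeight < 0 || fnWeight > 1 || fpWeight < 0 || fpWeight > 1) {
    stop("fnWeight and fpWeight must lie in [0, 1]", call. = FALSE)
  }
  n11 <- crossprod(X)                       # co-occurrence counts
  cs <- colSums(X)
  mism <- outer(cs, cs, "+") - 2 * n11      # n10 + n01
  denom <- fpWeight * n11 + fnWeight * mism
  D <- 1 - (fpWeight * n11) / denom
  if (any(cs == 0) && ncol(X) > 1L) {
    warning(sprintf("%d all-zero genotype column(s): no co-occurrence evidence, distance 1 to every other locus",
                    sum(cs == 0)))
  }
  D[denom == 0] <- 1                        # includes empty unions
  D[mism == 0 & n11 > 0] <- 0               # identical non-empty columns
  diag(D) <- 0
  dimnames(D) <- list(colnames(X), colnames(X))
  D
}

#' Distance decay functions for the ddCRP prior
#'
#' The link probability of two loci is proportional to a non-increasing decay
#' of their distance. The default is the exponential decay
#' \code{f(d) = exp(-d / a)}; a hard window \code{f(d) = 1(d < a)} (with a
#' small floor so link probabilities stay positive) and a logistic decay
#' \code{f(d) = 1 / (1 + exp((d - 1/2) / a))} are available behind the
#' \code{kind} switch. Large \code{a} flattens all three towards a constant,
#' recovering the traditional CRP.
#'
#' @param d Numeric distances in [0, 1].
#' @param a Decay scale, > 0.
#' @param kind One of "exponential", "window", "logistic", "constant".
#'   "constant" ignores distances entirely, reducing the ddCRP to the
#'   traditional CRP (useful as a distance-blind ablation).
#' @return Decay values in (0, 1].
#' @examples
#' decayFunction(1, a = 1)  # exp(-1)
#' @export
decayFunction <- function(d, a, kind = c("exponential", "window", "logistic", "constant")) {
  kind <- match.arg(kind)
  if (!is.numeric(a) || length(a) != 1L || is.na(a) || a <= 0) {
    stop("decay scale 'a' must be a single positive number", call. = FALSE)
  }
  assertProb(d, "d")
  switch(kind,
    exponential = exp(-d / a),
    window      = ifelse(d < a, 1, 1e-10),
    logistic    = 1 / (1 + exp((d - 0.5) / a)),
    constant    = rep(1, length(d)) * d^0
  )
}

#' ddCRP customer link prior
#'
#' Row-stochastic matrix of prior link probabilities: customer (locus) i
#' links to customer j with probability proportional to \code{f(D[i, j])}
#' for \code{j != i} and to the self-link mass \code{alpha} for
#' \code{j == i}. Connected components of the sampled link graph form the
#' mutation clusters. With a constant decay this reduces exactly to the
#' customer-joining representation of the traditional CRP.
#'
#' @param D Symmetric distance matrix in [0, 1] (zero diagonal).
#' @param alpha Self-link mass, > 0.
#' @param a Decay scale passed to \code{\link{decayFunction}}.
#' @param decay Decay kind, see \code{\link{decayFunction}}.
#' @return N x N matrix with strictly positive rows summing to 1.
#' @export
linkPriorMatrix <- function(D, alpha = 1, a = 0.1, decay = "exponential") {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D)) stop("D must be square", call. = FALSE)
  if (alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  W <- decayFunction(D, a = a, kind = decay)
  diag(W) <- alpha
  W / rowSums(W)
}

# Unnormalized log link-prior weights, used inside the sampler where the
# normalizing constant cancels.
linkPriorLogWeights <- function(D, alpha, a, decay = "exponential") {
  W <- decayFunction(as.matrix(D), a = a, kind = decay)
  diag(W) <- alpha
  log(W)
}

#' Intersect bulk loci with single-cell genotype loci
#'
#' Restricts a bulk count table and a genotype matrix to their shared locus
#' ids (mirroring the practice of keeping only loci present in both assays),
#' reporting how many loci were dropped from each side.
#'
#' @param bulk Bulk count data.frame with a \code{mutation_id} column.
#' @param delta \linkS4class{ScGenotypes}.
#' @return List with elements \code{bulk} and \code{delta}, row/column
#'   subsets in a common locus order.
#' @export
matchLoci <- function(bulk, delta) {
  shared <- intersect(bulk$mutation_id, lociIds(delta))
  if (length(shared) < 2L) {
    stop(sprintf(
      "only %d locus shared between bulk (%d loci) and genotype (%d loci) inputs",
      length(shared), nrow(bulk), ncol(delta)), call. = FALSE)
  }
  droppedBulk <- sum(!bulk$mutation_id %in% shared)
  droppedSc <- sum(!lociIds(delta) %in% shared)
  if (droppedBulk + droppedSc > 0) {
    message(sprintf("dropping %d bulk-only and %d single-cell-only loci; %d shared",
                    droppedBulk, droppedSc, length(shared)))
  }
  list(bulk = bulk[match(shared, bulk$mutation_id), , drop = FALSE],
       delta = ScGenotypes(delta@.Data[, shared, drop = FALSE]))
}
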