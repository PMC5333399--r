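# Gibbs sampler over ddCRP customer links with cached Griddy Gibbs
# resampling of per-cluster cellular prevalences.
#
# The per-locus likelihood over a fixed prevalence grid is computed once per
# hyperparameter state (the "cache", an N x G matrix of log-likelihoods);
# every cluster marginal is then a log-sum-exp over grid columns of summed
# cache rows, so one link update costs O(K * G).

#' Sampler configuration with package defaults
#'
#' Assembles the full configuration of \code{\link{runDdclone}}. All values
#' are echoed into the returned trace for reproducibility.
#'
#' @param iterations Number of Gibbs sweeps (one sweep reassigns every
#'   customer link, then redraws per-cluster prevalences).
#' @param burninFraction Fraction of initial sweeps discarded by the
#'   summarization functions.
#' @param gridSize Number of prevalence grid points; grid g uses midpoints
#'   \code{(1:g - 0.5) / g} so prevalence is resolved to \code{1/g}.
#' @param alpha ddCRP self-link mass.
#' @param a Decay scale of the distance decay function.
#' @param s Beta-binomial precision shared by all loci.
#' @param epsilon Sequencing error probability.
#' @param tumourContent Tumour cellularity t of the bulk sample.
#' @param statePriorStrategy Locus genotype state prior construction, see
#'   \code{\link{statePrior}}.
#' @param seed Integer RNG seed; all randomness flows from it.
#' @param resampleHyperparams Enable Metropolis-Hastings updates of
#'   (s, a, alpha)? Off by default.
#' @param hyperProposalScale Log-normal random-walk scale for the MH updates.
#' @param decay Decay kind, see \code{\link{decayFunction}}; "constant"
#'   gives the distance-blind traditional CRP.
#' @param scanOrder "fixed" (index order within a sweep, reproducible
#'   default) or "random" (fresh permutation each sweep).
#' @param fnWeight,fpWeight Modified-Jaccard weights used when the distance
#'   matrix is built from genotypes.
#' @return Named list of class \code{ddcloneParams}.
#' @export
ddcloneParams <- function(iterations = 10000L, burninFraction = 0.5,
                          gridSize = 100L, alpha = 1, a = 0.1, s = 100,
                          epsilon = 0.001, tumourContent = 1,
                          statePriorStrategy = "parental_cn", seed = 1L,
                          resampleHyperparams = FALSE,
                          hyperProposalScale = 0.1,
                          decay = "exponential", scanOrder = "fixed",
                          fnWeight = 1, fpWeight = 1) {
  stopifnot(iterations >= 1, gridSize >= 2, burninFraction >= 0,
            burninFraction < 1, alpha > 0, a > 0, s > 0)
  assertProb(tumourContent, "tumourContent")
  p <- as.list(environment())
  class(p) <- "ddcloneParams"
  p
}

phiGrid <- function(gridSize) (seq_len(gridSize) - 0.5) / gridSize

#' Partition induced by a customer link configuration
#'
#' Connected components of the undirected graph with an edge \code{{i,
#' c_i}} for every customer; each component is one mutation cluster (a table
#' in the restaurant metaphor).
#'
#' @param links Integer vector of customer links, \code{links[i]} in
#'   \code{1..N}; self-loops allowed.
#' @return Integer vector of cluster labels, canonicalized to
#'   first-appearance order.
#' @examples
#' inducedPartition(c(2, 3, 3))     # one cluster
#' inducedPartition(c(2, 1, 4, 3))  # {1,2} {3,4}
#' @export
inducedPartition <- function(links) {
  n <- length(links)
  if (any(links < 1L | links > n)) stop("invalid link index", call. = FALSE)
  p <- seq_len(n)
  for (i in seq_len(n)) {
    a <- i
    while (p[a] != a) { p[a] <- p[p[a]]; a <- p[a] }
    b <- links[i]
    while (p[b] != b) { p[b] <- p[p[b]]; b <- p[b] }
    if (a != b) p[a] <- b
  }
  for (i in seq_len(n)) {
    a <- i
    while (p[a] != a) a <- p[a]
    p[i] <- a
  }
  canonicalLabels(p)
}

#' Marginal log-likelihood of one cluster over the prevalence grid
#'
#' Integrates the shared cluster prevalence against its uniform grid prior:
#' \code{log( (1/G) sum_g exp( sum_{i in cluster} cache[i, g] ) )}, computed
#' by log-sum-exp.
#'
#' @param cluster Integer indices of the cluster members.
#' @param cache N x G matrix of per-locus grid log-likelihoods.
#' @return Log marginal likelihood of the cluster's counts.
#' @export
clusterMarginalLogLik <- function(cluster, cache) {
  if (length(cluster) == 0L) stop("empty cluster", call. = FALSE)
  logSumExp(colSums(cache[cluster, , drop = FALSE])) - log(ncol(cache))
}

# One Gibbs update of customer i's link. Candidate weights: the ddCRP link
# prior everywhere, times the marginal-likelihood ratio
# merged / (separate product) for targets whose component differs from i's
# once i's own outgoing link is removed.
linkUpdate <- function(i, links, cache, logPriorW) {
  G <- ncol(cache)
  links[i] <- i                               # sever i's outgoing link
  labels <- inducedPartition(links)
  compLL <- rowsum(cache, labels)             # K x G summed log-lik rows
  marg <- rowLogSumExp(compLL) - log(G)
  li <- labels[i]
  K <- nrow(compLL)
  merged <- rowLogSumExp(compLL + rep(compLL[li, ], each = K)) - log(G)
  deltaK <- merged - marg - marg[li]
  deltaK[li] <- 0                             # same-component targets: prior only
  logw <- logPriorW[i, ] + deltaK[labels]
  links[i] <- gumbelMaxDraw(logw)
  links
}

#' Gibbs update of a single customer link
#'
#' Exposed for diagnostics and exact-posterior comparisons; the full sampler
#' in \code{\link{ddcrpGibbs}} applies this to every customer each sweep.
#'
#' @param i Customer (locus) index to update.
#' @param links Current integer link vector.
#' @param cache N x G per-locus grid log-likelihood matrix.
#' @param logPriorW N x N unnormalized log link-prior weights (log decay
#'   off-diagonal, log alpha on the diagonal).
#' @return Updated link vector.
#' @export
resampleLink <- function(i, links, cache, logPriorW) {
  linkUpdate(i, links, cache, logPriorW)
}

#' Griddy Gibbs draw of a cluster's cellular prevalence
#'
#' Samples a grid point with probability proportional to
#' \code{exp(sum_{i in cluster} cache[i, g])} (uniform grid prior).
#'
#' @param cluster Integer indices of the cluster members.
#' @param cache N x G per-locus grid log-likelihood matrix.
#' @param grid Prevalence grid values.
#' @return A single grid value.
#' @export
resamplePhi <- function(cluster, cache, grid) {
  w <- colSums(cache[cluster, , drop = FALSE])
  if (all(!is.finite(w))) stop("degenerate data: all-zero posterior mass", call. = FALSE)
  grid[gumbelMaxDraw(w)]
}

# Joint log target used by the hyperparameter MH step: link prior
# (normalized) + cluster marginals + log-normal hyperpriors.
hyperLogTarget <- function(links, cache, logPriorW, hp, hpPrior) {
  labels <- inducedPartition(links)
  compLL <- rowsum(cache, labels)
  lik <- sum(rowLogSumExp(compLL) - log(ncol(cache)))
  norm <- rowLogSumExp(logPriorW)
  prior <- sum(logPriorW[cbind(seq_along(links), links)] - norm)
  hyp <- sum(stats::dlnorm(c(hp$s, hp$a, hp$alpha),
                           meanlog = hpPrior$meanlog, sdlog = hpPrior$sdlog,
                           log = TRUE))
  lik + prior + hyp
}

# Metropolis-Hastings update of (s, a, alpha) with log-normal random-walk
# proposals under log-normal priors centred at the initial values. The
# scheme is a documented stand-in and is disabled by default.
resampleHyperparamsStep <- function(links, hp, hpPrior, scale, D, decay,
                                    bulk, priors, grid, tumourContent, epsilon,
                                    cache, logPriorW) {
  cur <- hyperLogTarget(links, cache, logPriorW, hp, hpPrior)
  accepted <- logical(3)
  for (which in c("s", "a", "alpha")) {
    prop <- hp
    prop[[which]] <- hp[[which]] * exp(scale * stats::rnorm(1))
    propCache <- if (which == "s") {
      gridLogLikCache(bulk, priors, grid, tumourContent, prop$s, epsilon)
    } else cache
    propPriorW <- if (which %in% c("a", "alpha")) {
      linkPriorLogWeights(D, prop$alpha, prop$a, decay)
    } else logPriorW
    new <- hyperLogTarget(links, propCache, propPriorW, prop, hpPrior)
    # log-normal RW proposal: Hastings ratio contributes log(prop/cur)
    if (log(stats::runif(1)) < new - cur + log(prop[[which]] / hp[[which]])) {
      hp <- prop; cache <- propCache; logPriorW <- propPriorW; cur <- new
      accepted[match(which, c("s", "a", "alpha"))] <- TRUE
    }
  }
  list(hp = hp, cache = cache, logPriorW = logPriorW, accepted = accepted)
}

#' Low-level ddCRP Gibbs sampler over a precomputed likelihood cache
#'
#' Runs the customer-link Gibbs sweep with Griddy Gibbs prevalence draws on
#' an arbitrary N x G grid log-likelihood matrix. \code{\link{runDdclone}}
#' is the user-facing wrapper that builds the cache from bulk counts; this
#' entry point is useful for simulation studies and exact-posterior checks
#' (e.g. a flat cache of zeros targets the link prior exactly).
#'
#' The sampler starts from all-singleton clusters (every customer
#' self-linked). Each sweep reassigns every customer link (fixed index order
#' by default), then draws one prevalence per cluster which is recorded for
#' each member locus.
#'
#' @param cache N x G matrix of per-locus grid log-likelihoods.
#' @param D N x N distance matrix.
#' @param params \code{\link{ddcloneParams}} configuration. \code{gridSize}
#'   is taken from \code{ncol(cache)}.
#' @param bulk,priors Only required when \code{resampleHyperparams} is on,
#'   to rebuild the cache at proposed precisions.
#' @return A \linkS4class{CloneMCMC} trace.
#' @export
ddcrpGibbs <- function(cache, D, params = ddcloneParams(), bulk = NULL,
                       priors = NULL) {
  N <- nrow(cache)
  G <- ncol(cache)
  grid <- phiGrid(G)
  if (nrow(D) != N) stop("cache and distance matrix disagree on loci", call. = FALSE)
  set.seed(params$seed)
  hp <- list(s = params$s, a = params$a, alpha = params$alpha)
  hpPrior <- list(meanlog = log(c(hp$s, hp$a, hp$alpha)), sdlog = rep(1, 3))
  logPriorW <- linkPriorLogWeights(D, hp$alpha, hp$a, params$decay)
  links <- seq_len(N)                        # all customers self-linked
  iters <- params$iterations
  linkTrace <- matrix(NA_integer_, iters, N)
  clusterTrace <- matrix(NA_integer_, iters, N)
  phiTrace <- matrix(NA_real_, iters, N)
  hyperTrace <- matrix(NA_real_, iters, 3,
                       dimnames = list(NULL, c("s", "a", "alpha")))
  for (it in seq_len(iters)) {
    order <- if (params$scanOrder == "random") sample.int(N) else seq_len(N)
    for (i in order) {
      links <- linkUpdate(i, links, cache, logPriorW)
    }
    labels <- inducedPartition(links)
    compLL <- rowsum(cache, labels)
    phiK <- vapply(seq_len(nrow(compLL)), function(k) {
      grid[gumbelMaxDraw(compLL[k, ])]
    }, numeric(1))
    if (isTRUE(params$resampleHyperparams)) {
      upd <- resampleHyperparamsStep(links, hp, hpPrior,
                                     params$hyperProposalScale, D,
                                     params$decay, bulk, priors, grid,
                                     params$tumourContent, params$epsilon,
                                     cache, logPriorW)
      hp <- upd$hp; cache <- upd$cache; logPriorW <- upd$logPriorW
    }
    linkTrace[it, ] <- links
    clusterTrace[it, ] <- labels
    phiTrace[it, ] <- phiK[labels]
    hyperTrace[it, ] <- c(hp$s, hp$a, hp$alpha)
  }
  loci <- rownames(cache)
  if (is.null(loci)) loci <- as.character(seq_len(N))
  new("CloneMCMC", linkTrace = linkTrace, clusterTrace = clusterTrace,
      phiTrace = phiTrace, hyperTrace = hyperTrace, loci = loci,
      params = unclass(params))
}

#' Cluster mutations and infer cellular prevalences
#'
#' Main entry point: joint inference of mutation clusters and cellular
#' prevalences from bulk allele counts with a single-cell genotype prior.
#' Wires the distance matrix (modified Jaccard on the genotype columns, with
#' the configured decay), the copy-number-aware beta-binomial grid
#' likelihood, and the ddCRP Gibbs sampler.
#'
#' @param bulk data.frame with columns \code{mutation_id}, \code{ref_counts},
#'   \code{var_counts}, \code{normal_cn}, \code{minor_cn}, \code{major_cn}.
#' @param genotypes \linkS4class{ScGenotypes}; loci are matched to
#'   \code{bulk$mutation_id} by id and non-shared loci dropped.
#' @param distance Optional precomputed distance matrix (overrides
#'   \code{genotypes}-derived distances; must match the bulk loci order).
#' @param params \code{\link{ddcloneParams}} configuration.
#' @return A \linkS4class{CloneMCMC} trace; summarize it with
#'   \code{\link{summarizeClones}}.
#' @examples
#' sim <- simulateClones(4, 12, seed = 7)
#' bulk <- simulateBulk(sim, seed = 7)
#' fit <- runDdclone(bulk$bulk, cloneGenotypes(sim),
#'                   params = ddcloneParams(iterations = 50, seed = 7))
#' summarizeClones(fit)
#' @export
runDdclone <- function(bulk, genotypes = NULL, distance = NULL,
                       params = ddcloneParams()) {
  bulk <- validateBulkTable(bulk)
  if (is.null(distance)) {
    if (is.null(genotypes)) stop("provide either genotypes or a distance matrix", call. = FALSE)
    matched <- matchLoci(bulk, genotypes)
    bulk <- matched$bulk
    distance <- modifiedJaccardDistanceMatrix(matched$delta,
                                              fnWeight = params$fnWeight,
                                              fpWeight = params$fpWeight)
  } else {
    distance <- as.matrix(distance)
    if (nrow(distance) != nrow(bulk)) {
      stop("distance matrix does not match bulk loci", call. = FALSE)
    }
  }
  priors <- statePriorsForBulk(bulk, params$statePriorStrategy)
  usable <- !vapply(priors, is.null, logical(1))
  if (!all(usable)) {
    bulk <- bulk[usable, , drop = FALSE]
    priors <- priors[usable]
    distance <- distance[usable, usable, drop = FALSE]
  }
  grid <- phiGrid(params$gridSize)
  cache <- gridLogLikCache(bulk, priors, grid, params$tumourContent,
                           params$s, params$epsilon)
  ddcrpGibbs(cache, distance, params, bulk = bulk, priors = priors)
}
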