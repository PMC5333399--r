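# Point-estimate clustering and prevalence summaries from an MCMC trace,
# plus the MEM / POM diagnostic reports.

retainedRows <- function(trace, burnin) {
  iters <- nrow(clusterTrace(trace))
  first <- floor(burnin * iters) + 1L
  if (first > iters) stop("no samples retained after burn-in", call. = FALSE)
  seq.int(first, iters)
}

#' Posterior similarity matrix
#'
#' Fraction of retained (post burn-in) MCMC samples in which each pair of
#' loci is assigned to the same cluster.
#'
#' @param trace A \linkS4class{CloneMCMC}.
#' @param burnin Fraction of initial samples to discard; defaults to the
#'   value the trace was configured with.
#' @return Symmetric N x N matrix in [0, 1] with unit diagonal.
#' @export
posteriorSimilarity <- function(trace, burnin = NULL) {
  if (is.null(burnin)) burnin <- trace@params$burninFraction
  ct <- clusterTrace(trace)[retainedRows(trace, burnin), , drop = FALSE]
  N <- ncol(ct)
  psm <- matrix(0, N, N)
  for (r in seq_len(nrow(ct))) {
    lab <- ct[r, ]
    psm <- psm + outer(lab, lab, "==")
  }
  psm <- psm / nrow(ct)
  dimnames(psm) <- list(lociIds(trace), lociIds(trace))
  psm
}

# Fritsch-Ickstadt posterior expected adjusted Rand of a candidate
# partition against a PSM. Degenerate zero denominators (candidate and PSM
# both trivially concordant or discordant) score 1 when the numerator also
# vanishes, so identical degenerate partitions are preferred.
pearScore <- function(labels, psm) {
  N <- length(labels)
  up <- upper.tri(psm)
  I <- outer(labels, labels, "==")[up]
  p <- psm[up]
  B <- N * (N - 1) / 2
  expIp <- sum(I) * sum(p) / B
  num <- sum(I * p) - expIp
  den <- (sum(I) + sum(p)) / 2 - expIp
  if (abs(den) < 1e-12) return(as.numeric(abs(num) < 1e-12))
  num / den
}

#' Point-estimate clustering maximizing the posterior expected adjusted Rand
#'
#' Builds an average-linkage dendrogram on \code{1 - PSM}, scores every cut
#' (k = 1..N clusters) by the posterior expected adjusted Rand index (PEAR,
#' Fritsch-Ickstadt estimator computed from the PSM) and returns the best
#' cut. Ties are broken towards fewer clusters; labels are canonicalized to
#' first-appearance order.
#'
#' @param psm Posterior similarity matrix.
#' @return Integer vector of cluster labels.
#' @export
maxpearPartition <- function(psm) {
  psm <- as.matrix(psm)
  N <- nrow(psm)
  if (N == 1L) return(1L)
  hc <- stats::hclust(stats::as.dist(1 - psm), method = "average")
  best <- NULL
  bestScore <- -Inf
  for (k in seq_len(N)) {
    labels <- stats::cutree(hc, k = k)
    sc <- pearScore(labels, psm)
    if (sc > bestScore + 1e-12) {           # strict: ties keep fewer clusters
      bestScore <- sc
      best <- labels
    }
  }
  canonicalLabels(unname(best))
}

#' Per-locus cellular prevalence point estimates
#'
#' Arithmetic mean of the retained post burn-in prevalence draws, per locus.
#'
#' @inheritParams posteriorSimilarity
#' @return Named numeric vector of prevalence estimates in [0, 1].
#' @export
phiPointEstimates <- function(trace, burnin = NULL) {
  if (is.null(burnin)) burnin <- trace@params$burninFraction
  pt <- phiTrace(trace)[retainedRows(trace, burnin), , drop = FALSE]
  stats::setNames(colMeans(pt), lociIds(trace))
}

#' Summarize a trace into clonal calls
#'
#' @inheritParams posteriorSimilarity
#' @return data.frame with one row per locus: \code{mutation_id},
#'   \code{cluster} (maxPEAR label), \code{phi_hat} (posterior mean
#'   prevalence) and \code{n_cluster_members}.
#' @export
summarizeClones <- function(trace, burnin = NULL) {
  psm <- posteriorSimilarity(trace, burnin)
  cl <- maxpearPartition(psm)
  phi <- phiPointEstimates(trace, burnin)
  data.frame(mutation_id = lociIds(trace),
             cluster = cl,
             phi_hat = unname(phi),
             n_cluster_members = as.integer(table(cl)[as.character(cl)]),
             row.names = NULL)
}

#' Mutually exclusive mutation (MEM) pairs
#'
#' Locus pairs whose mutations never co-occur in any genotype: Jaccard
#' distance exactly 1 with a non-empty union. Clustering methods driven by
#' prevalence alone are prone to merging MEMs from distinct clones that
#' happen to share a prevalence; the co-occurrence prior separates them.
#'
#' @param delta \linkS4class{ScGenotypes} or binary matrix.
#' @return data.frame with columns \code{locus_a}, \code{locus_b}.
#' @export
findMems <- function(delta) {
  X <- asBinaryMatrix(delta)
  n11 <- crossprod(X)
  cs <- colSums(X)
  union <- outer(cs, cs, "+") - n11
  mem <- n11 == 0 & union > 0
  idx <- which(mem & upper.tri(mem), arr.ind = TRUE)
  data.frame(locus_a = colnames(X)[idx[, 1L]],
             locus_b = colnames(X)[idx[, 2L]],
             stringsAsFactors = FALSE)
}

#' Prior overriding mutation (POM) pairs
#'
#' Locus pairs with bitwise-identical genotype columns (hence identical
#' prior and zero distance) that the model nonetheless assigned to different
#' clusters, i.e. places where bulk evidence overrode the single-cell
#' prior. When a bulk table is supplied the report includes each pair's
#' bulk VAF ratio (larger VAF over smaller).
#'
#' @param delta \linkS4class{ScGenotypes} or binary matrix.
#' @param clusters Integer cluster labels covering \code{delta}'s loci, in
#'   column order.
#' @param bulk Optional bulk table (for VAF diagnostics).
#' @return data.frame with columns \code{locus_a}, \code{locus_b} and, when
#'   bulk counts are available, \code{vaf_ratio}.
#' @export
findPoms <- function(delta, clusters, bulk = NULL) {
  X <- asBinaryMatrix(delta)
  if (length(clusters) != ncol(X)) {
    stop("clusters must cover every locus of delta", call. = FALSE)
  }
  key <- apply(X, 2L, paste, collapse = "")
  idx <- which(outer(key, key, "==") & outer(clusters, clusters, "!=") &
                 upper.tri(diag(ncol(X))), arr.ind = TRUE)
  out <- data.frame(locus_a = colnames(X)[idx[, 1L]],
                    locus_b = colnames(X)[idx[, 2L]],
                    stringsAsFactors = FALSE)
  if (!is.null(bulk) && nrow(out) > 0L) {
    vaf <- bulk$var_counts / pmax(bulk$var_counts + bulk$ref_counts, 1L)
    names(vaf) <- bulk$mutation_id
    va <- vaf[out$locus_a]
    vb <- vaf[out$locus_b]
    out$vaf_ratio <- pmax(va, vb) / pmax(pmin(va, vb), .Machine$double.eps)
  }
  out
}
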