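# Independent oracles and small fixture builders. Every oracle here avoids
# the code path it checks: entropies from the mutual-information identity,
# beta-binomial mass by numeric integration, posteriors by exhaustive
# enumeration.

# V-measure via I(C;K): homogeneity = I/H(C), completeness = I/H(K), so the
# harmonic mean is 2I / (H(C) + H(K)).
vMeasureOracle <- function(trueLabels, predLabels) {
  tab <- table(trueLabels, predLabels)
  n <- sum(tab)
  pj <- rowSums(tab) / n
  pk <- colSums(tab) / n
  hC <- -sum(pj[pj > 0] * log(pj[pj > 0]))
  hK <- -sum(pk[pk > 0] * log(pk[pk > 0]))
  pjk <- tab / n
  info <- 0
  for (j in seq_len(nrow(tab))) {
    for (k in seq_len(ncol(tab))) {
      if (pjk[j, k] > 0) {
        info <- info + pjk[j, k] * log(pjk[j, k] / (pj[j] * pk[k]))
      }
    }
  }
  if (hC + hK == 0) return(1)
  as.numeric(2 * info / (hC + hK))
}

# Beta-binomial mass by adaptive quadrature over the mixing probability.
betaBinomOracle <- function(b, d, m, s) {
  stats::integrate(function(p) {
    stats::dbinom(b, d, p) * stats::dbeta(p, s * m, s * (1 - m))
  }, 0, 1, rel.tol = 1e-10)$value
}

partitionKey <- function(labels) paste(match(labels, unique(labels)), collapse = "-")

# Exact ddCRP posterior over partitions by enumerating all N^N link
# configurations: p(C) prop to prod_i prior(c_i) * prod_k marginal(T_k).
exactPartitionPosterior <- function(cache, logPriorW) {
  N <- nrow(cache)
  normPrior <- logPriorW - ddclone:::rowLogSumExp(logPriorW)
  configs <- as.matrix(expand.grid(rep(list(seq_len(N)), N)))
  logp <- apply(configs, 1L, function(links) {
    labels <- inducedPartition(links)
    lik <- sum(vapply(unique(labels), function(k) {
      clusterMarginalLogLik(which(labels == k), cache)
    }, numeric(1)))
    sum(normPrior[cbind(seq_len(N), links)]) + lik
  })
  keys <- apply(configs, 1L, function(links) partitionKey(inducedPartition(links)))
  p <- exp(logp - max(logp))
  tapply(p, keys, sum) / sum(p)
}

# All set partitions of n items as label vectors (restricted growth strings).
allPartitions <- function(n) {
  out <- list()
  grow <- function(labels) {
    if (length(labels) == n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    for (k in seq_len(max(labels) + 1L)) grow(c(labels, k))
  }
  grow(1L)
  out
}

# Fritsch-Ickstadt PEAR of a candidate labelling against a PSM, written
# independently of the package internals.
pearOracle <- function(labels, psm) {
  N <- length(labels)
  num <- den <- sI <- sP <- 0
  for (i in seq_len(N - 1)) {
    for (j in (i + 1):N) {
      I <- as.numeric(labels[i] == labels[j])
      sI <- sI + I; sP <- sP + psm[i, j]
      num <- num + I * psm[i, j]
    }
  }
  B <- N * (N - 1) / 2
  e <- sI * sP / B
  if (abs((sI + sP) / 2 - e) < 1e-12) return(as.numeric(abs(num - e) < 1e-12))
  (num - e) / ((sI + sP) / 2 - e)
}

# Toy bulk table: diploid heterozygous loci with given variant counts.
makeToyBulk <- function(b, d = rep(100L, length(b)), ids = NULL) {
  if (is.null(ids)) ids <- sprintf("1:%d", seq_along(b) * 100L)
  data.frame(mutation_id = ids, ref_counts = as.integer(d - b),
             var_counts = as.integer(b), normal_cn = 2L, minor_cn = 1L,
             major_cn = 1L, stringsAsFactors = FALSE)
}

# Hand-built CloneSim: genotype matrix, prevalences, diploid heterozygous
# copy-number states and a star-ish tree (sufficient for bulk simulation).
makeCloneSim <- function(geno, prev, totalCn = 2L, varCopies = 1L) {
  M <- nrow(geno)
  N <- ncol(geno)
  if (is.null(colnames(geno))) {
    colnames(geno) <- sprintf("1:%d", seq_len(N) * 100L)
  }
  tree <- c(rep.int(M + 1L, M), 0L)
  cn <- data.frame(locus_id = colnames(geno),
                   total_cn = rep.int(as.integer(totalCn), N),
                   major_cn = pmax(varCopies, totalCn - varCopies),
                   minor_cn = pmin(varCopies, totalCn - varCopies),
                   var_copies = rep.int(as.integer(varCopies), N),
                   stringsAsFactors = FALSE)
  new("CloneSim", genotypes = ScGenotypes(geno), prevalences = prev,
      tree = tree, cnStates = cn)
}

# Minimal CloneMCMC wrapper around hand-set traces.
makeTrace <- function(clusterMat, phiMat = NULL, burnin = 0) {
  if (is.null(phiMat)) phiMat <- matrix(0.5, nrow(clusterMat), ncol(clusterMat))
  new("CloneMCMC",
      linkTrace = clusterMat,
      clusterTrace = clusterMat,
      phiTrace = phiMat,
      hyperTrace = matrix(1, nrow(clusterMat), 3),
      loci = as.character(seq_len(ncol(clusterMat))),
      params = list(burninFraction = burnin))
}
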