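#' @import methods
NULL

#' Binary genotype-by-locus matrix from single-cell sequencing
#'
#' Wraps a binary matrix with rows corresponding to cell genotypes (or
#' individual cells) and columns to genomic loci. Entry \code{[m, n]} is 1 if
#' genotype \code{m} carries a somatic mutation at locus \code{n}. Column
#' names are locus identifiers in \code{"chrom:pos"} form (1-based positions)
#' and must be unique; they key the match against the bulk count table.
#'
#' @slot .Data Binary integer matrix.
#' @export
setClass("ScGenotypes", contains = "matrix", validity = function(object) {
  v <- object@.Data
  if (length(v) == 0L) return("genotype matrix must be non-empty")
  if (!all(v %in% c(0, 1))) return("all entries must be 0 or 1")
  if (is.null(colnames(v))) return("locus ids (column names) are required")
  if (anyDuplicated(colnames(v))) return("locus ids must be unique")
  TRUE
})

#' Construct a ScGenotypes object
#'
#' @param mat Matrix (or coercible) of 0/1 entries, genotypes x loci, with
#'   locus ids as column names.
#' @return A \linkS4class{ScGenotypes} object.
#' @examples
#' delta <- ScGenotypes(matrix(c(1, 0, 1, 1, 0, 1), nrow = 2,
#'                      dimnames = list(NULL, c("1:100", "1:200", "2:300"))))
#' @export
ScGenotypes <- function(mat) {
  mat <- as.matrix(mat)
  storage.mode(mat) <- "integer"
  if (is.null(rownames(mat))) {
    rownames(mat) <- paste0("g", seq_len(nrow(mat)))
  }
  new("ScGenotypes", mat)
}

#' Simulated clone set with ground truth
#'
#' Output of \code{\link{simulateClones}}: binarized clone genotypes, their
#' clonal prevalences, the generating phylogeny and the per-locus copy-number
#' state used for the bulk read-count model.
#'
#' @slot genotypes \linkS4class{ScGenotypes} clone-by-locus matrix.
#' @slot prevalences Numeric simplex vector of clonal prevalences (one per
#'   genotype).
#' @slot tree Integer parent vector over the internal tree nodes (0 = root);
#'   leaves 1..M are the genotypes.
#' @slot cnStates data.frame with one row per locus: \code{locus_id},
#'   \code{total_cn}, \code{major_cn}, \code{minor_cn}, \code{var_copies}.
#' @export
setClass("CloneSim", representation(
  genotypes   = "ScGenotypes",
  prevalences = "numeric",
  tree        = "integer",
  cnStates    = "data.frame"
), validity = function(object) {
  M <- nrow(object@genotypes)
  if (length(object@prevalences) != M) return("one prevalence per genotype required")
  if (any(object@prevalences < 0) || abs(sum(object@prevalences) - 1) > 1e-8) {
    return("prevalences must form a probability simplex")
  }
  if (nrow(object@cnStates) != ncol(object@genotypes)) {
    return("one copy-number state row per locus required")
  }
  TRUE
})

#' MCMC trace of the ddCRP sampler
#'
#' Per-iteration customer-link configurations, their induced partitions and
#' per-locus cellular prevalence draws, together with the configuration that
#' produced them.
#'
#' @slot linkTrace Integer iterations x loci matrix of customer links c_i.
#' @slot clusterTrace Integer iterations x loci matrix of canonical cluster
#'   labels (connected components of the link graph).
#' @slot phiTrace Numeric iterations x loci matrix of cellular prevalence
#'   draws (grid values).
#' @slot hyperTrace Numeric iterations x 3 matrix of (s, a, alpha) values.
#' @slot loci Character vector of locus ids, column order of the traces.
#' @slot params List echoing the full sampler configuration (incl. seed).
#' @export
setClass("CloneMCMC", representation(
  linkTrace    = "matrix",
  clusterTrace = "matrix",
  phiTrace     = "matrix",
  hyperTrace   = "matrix",
  loci         = "character",
  params       = "list"
), validity = function(object) {
  if (ncol(object@clusterTrace) != length(object@loci)) {
    return("trace columns must match loci")
  }
  if (!identical(dim(object@clusterTrace), dim(object@phiTrace))) {
    return("cluster and phi traces must have identical dimensions")
  }
  TRUE
})

setMethod("show", "ScGenotypes", function(object) {
  cat(sprintf("ScGenotypes: %d genotypes x %d loci (%.1f%% mutated)\n",
              nrow(object), ncol(object), 100 * mean(object@.Data)))
})

setMethod("show", "CloneSim", function(object) {
  cat(sprintf("CloneSim: %d clone genotypes over %d loci\n",
              nrow(object@genotypes), ncol(object@genotypes)))
  cat("  prevalences:", paste(sprintf("%.3f", object@prevalences), collapse = " "), "\n")
})

setMethod("show", "CloneMCMC", function(object) {
  cat(sprintf("CloneMCMC: %d iterations over %d loci\n",
              nrow(object@clusterTrace), length(object@loci)))
  k <- apply(object@clusterTrace, 1L, function(z) length(unique(z)))
  cat(sprintf("  clusters per iteration: median %d (range %d-%d)\n",
              as.integer(stats::median(k)), min(k), max(k)))
})
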