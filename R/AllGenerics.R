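#' Locus identifiers of an object
#'
#' @param x An object carrying per-locus data.
#' @return Character vector of locus ids.
#' @export
setGeneric("lociIds", function(x) standardGeneric("lociIds"))

#' @rdname lociIds
#' @export
setMethod("lociIds", "ScGenotypes", function(x) colnames(x))

#' @rdname lociIds
#' @export
setMethod("lociIds", "CloneMCMC", function(x) x@loci)

#' @rdname lociIds
#' @export
setMethod("lociIds", "CloneSim", function(x) colnames(x@genotypes))

#' Clone genotype matrix of a simulation
#'
#' @param x A \linkS4class{CloneSim}.
#' @return The \linkS4class{ScGenotypes} clone-by-locus matrix.
#' @export
setGeneric("cloneGenotypes", function(x) standardGeneric("cloneGenotypes"))

#' @rdname cloneGenotypes
#' @export
setMethod("cloneGenotypes", "CloneSim", function(x) x@genotypes)

#' Clonal prevalences of a simulation
#'
#' @param x A \linkS4class{CloneSim}.
#' @return Numeric simplex vector, one prevalence per clone genotype.
#' @export
setGeneric("clonePrevalences", function(x) standardGeneric("clonePrevalences"))

#' @rdname clonePrevalences
#' @export
setMethod("clonePrevalences", "CloneSim", function(x) x@prevalences)

#' Per-iteration cluster labels of an MCMC trace
#'
#' @param x A \linkS4class{CloneMCMC}.
#' @return Integer iterations x loci matrix of canonical cluster labels.
#' @export
setGeneric("clusterTrace", function(x) standardGeneric("clusterTrace"))

#' @rdname clusterTrace
#' @export
setMethod("clusterTrace", "CloneMCMC", function(x) x@clusterTrace)

#' Per-iteration cellular prevalence draws of an MCMC trace
#'
#' @param x A \linkS4class{CloneMCMC}.
#' @return Numeric iterations x loci matrix of phi draws.
#' @export
setGeneric("phiTrace", function(x) standardGeneric("phiTrace"))

#' @rdname phiTrace
#' @export
setMethod("phiTrace", "CloneMCMC", function(x) x@phiTrace)
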