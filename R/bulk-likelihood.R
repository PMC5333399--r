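# Beta-binomial emission model for bulk variant read counts under the
# three-subpopulation (normal / reference / variant) assumption, marginalized
# over copy-number-aware locus genotype states.
#
# A locus genotype g is a pair (ref_copies, var_copies); zeta(g) is its total
# copy number and a locus genotype state psi = (g_N, g_R, g_V) gives the
# genotypes of the three subpopulations at one locus.

zetaCn <- function(g) g[1L] + g[2L]

#' Probability of sampling a variant allele from one subpopulation
#'
#' For a subpopulation with locus genotype \code{g = (ref_copies,
#' var_copies)}: returns the sequencing error rate \code{epsilon} when no
#' variant copies are present, \code{1 - epsilon} when all copies are
#' variant, and the variant copy fraction \code{var_copies / total_cn}
#' otherwise.
#'
#' @param g Integer pair \code{c(ref_copies, var_copies)}.
#' @param epsilon Sequencing error probability in [0, 0.5); 0 is permitted
#'   for worked examples.
#' @return Probability in [0, 1].
#' @examples
#' muVariant(c(2, 0), 0.001)  # 0.001
#' muVariant(c(1, 2), 0)      # 2/3
#' @export
muVariant <- function(g, epsilon = 0.001) {
  if (epsilon < 0 || epsilon >= 0.5) stop("epsilon must lie in [0, 0.5)", call. = FALSE)
  b <- g[2L]
  z <- zetaCn(g)
  if (b == 0) {
    if (z == 0) message("homozygous-deletion genotype (0,0) fed to muVariant")
    epsilon
  } else if (b == z) {
    1 - epsilon
  } else {
    b / z
  }
}

#' Expected variant-read fraction of a mixed bulk sample
#'
#' Copy-number-weighted mixture of per-subpopulation variant-allele sampling
#' probabilities. With tumour cellularity \code{t} and cellular prevalence
#' \code{phi} (the fraction of cancer cells carrying the mutation), the
#' normal, reference and variant subpopulations contribute cell fractions
#' \code{1 - t}, \code{t (1 - phi)} and \code{t phi}; each is additionally
#' weighted by its total copy number since cells with more DNA at the locus
#' contribute more reads:
#' \deqn{\xi = [ (1-t)\zeta_N \mu_N + t(1-\phi)\zeta_R \mu_R +
#'              t\phi \zeta_V \mu_V ] / Z}
#' with \code{Z} the same sum without the \code{mu} factors.
#'
#' @param psi List of three genotype pairs \code{list(gN, gR, gV)}, each
#'   \code{c(ref_copies, var_copies)}.
#' @param phi Cellular prevalence in [0, 1] (may be a vector).
#' @param t Tumour cellularity in [0, 1].
#' @param epsilon Sequencing error probability.
#' @return Expected variant read fraction(s), same length as \code{phi}.
#' @examples
#' # 9-cell toy: 1 normal (2,0), 3 reference (3,0), 5 variant (1,2) cells
#' xiExpectedVaf(list(c(2, 0), c(3, 0), c(1, 2)), phi = 5 / 8, t = 8 / 9,
#'               epsilon = 0)  # 5/13
#' @export
xiExpectedVaf <- function(psi, phi, t, epsilon = 0.001) {
  assertProb(phi, "phi"); assertProb(t, "t")
  zN <- zetaCn(psi[[1L]]); zR <- zetaCn(psi[[2L]]); zV <- zetaCn(psi[[3L]])
  muN <- muVariant(psi[[1L]], epsilon)
  muR <- muVariant(psi[[2L]], epsilon)
  muV <- muVariant(psi[[3L]], epsilon)
  Z <- (1 - t) * zN + t * (1 - phi) * zR + t * phi * zV
  if (any(Z <= 0)) stop("degenerate locus genotype state: zero total copy mass", call. = FALSE)
  ((1 - t) * zN * muN + t * (1 - phi) * zR * muR + t * phi * zV * muV) / Z
}

#' Beta-binomial probability mass function
#'
#' Parameterized by mean \code{m} and precision \code{s}:
#' \code{p(b | d, m, s) = choose(d, b) B(b + sm, d - b + s(1-m)) / B(sm,
#' s(1-m))}. As \code{s} grows the distribution converges to
#' \code{Binomial(d, m)}; \code{s = Inf} is accepted as an exact binomial
#' sentinel. Computed in log space.
#'
#' @param b Variant read count(s), 0 <= b <= d.
#' @param d Total read depth(s).
#' @param m Mean in (0, 1); values of exactly 0 or 1 are clamped to machine
#'   epsilon with a warning.
#' @param s Precision, > 0, or \code{Inf} for the binomial limit.
#' @param log Return log-probabilities?
#' @return Probability (or log-probability) of each count.
#' @examples
#' dbetabinom(1, 2, m = 0.5, s = 2)  # 1/3
#' @export
dbetabinom <- function(b, d, m, s, log = FALSE) {
  if (any(b < 0) || any(b > d)) stop("need 0 <= b <= d", call. = FALSE)
  if (any(s <= 0)) stop("precision s must be > 0", call. = FALSE)
  if (any(m <= 0) || any(m >= 1)) {
    if (any(m < 0) || any(m > 1)) stop("mean m must lie in [0, 1]", call. = FALSE)
    warning("beta-binomial mean clamped away from {0, 1}")
    m <- pmin(pmax(m, .Machine$double.eps), 1 - .Machine$double.eps)
  }
  if (all(is.infinite(s))) {
    ll <- stats::dbinom(b, d, m, log = TRUE)
  } else {
    ll <- lchoose(d, b) + lbeta(b + s * m, d - b + s * (1 - m)) -
      lbeta(s * m, s * (1 - m))
  }
  if (log) ll else exp(ll)
}

#' Enumerate locus genotype states and their prior weights
#'
#' Builds the informative prior over locus genotype states
#' \code{psi = (g_N, g_R, g_V)} at one locus from its copy-number call.
#' Three strategies are provided, each assigning equal weight to the
#' enumerated states; the normal genotype is always diploid reference
#' \code{(2, 0)}:
#' \describe{
#'   \item{diploid}{single state with \code{g_R = (2, 0)}, \code{g_V = (1, 1)}
#'     (heterozygous SNV, copy number ignored).}
#'   \item{total_cn}{\code{g_R = (total_cn, 0)}; one state per variant copy
#'     count \code{v} in \code{1..total_cn} with \code{g_V = (total_cn - v,
#'     v)}.}
#'   \item{parental_cn}{\code{g_R = (total_cn, 0)}; variant copy candidates
#'     are 1 (late event after the CN change), \code{minor_cn} and
#'     \code{major_cn} (mutation preceding the CN change on either parental
#'     allele), deduplicated and zero dropped.}
#' }
#'
#' @param majorCn,minorCn Major/minor parental copy numbers of the locus.
#' @param strategy Prior construction strategy (default \code{parental_cn}).
#' @param normalCn Copy number of the normal subpopulation (diploid default).
#' @return List with \code{states} (list of \code{list(gN, gR, gV)} triples)
#'   and \code{weights} (equal, summing to 1), or \code{NULL} when
#'   \code{total_cn = 0} (locus unusable, reported via a message).
#' @export
statePrior <- function(majorCn, minorCn,
                       strategy = c("parental_cn", "total_cn", "diploid"),
                       normalCn = 2L) {
  strategy <- match.arg(strategy)
  majorCn <- as.integer(majorCn)
  minorCn <- as.integer(minorCn)
  totalCn <- majorCn + minorCn
  gN <- c(as.integer(normalCn), 0L)
  if (strategy == "diploid") {
    states <- list(list(gN = gN, gR = c(2L, 0L), gV = c(1L, 1L)))
  } else {
    if (totalCn == 0) {
      message("locus with total_cn = 0 excluded from state priors")
      return(NULL)
    }
    gR <- c(totalCn, 0L)
    varCandidates <- if (strategy == "total_cn") {
      seq_len(totalCn)
    } else {
      setdiff(unique(c(1L, minorCn, majorCn)), 0L)
    }
    states <- lapply(varCandidates, function(v) {
      list(gN = gN, gR = gR, gV = c(totalCn - v, v))
    })
  }
  list(states = states, weights = rep(1 / length(states), length(states)))
}

#' Log-likelihood of one locus's variant count at given prevalence
#'
#' Mixture over the locus genotype state prior of beta-binomial likelihoods
#' whose mean is the expected variant read fraction
#' \code{xi(psi, phi, t)}; combined by log-sum-exp.
#'
#' @param b,d Variant count and depth at the locus.
#' @param phi Cellular prevalence value(s) at which to evaluate.
#' @param prior State prior from \code{\link{statePrior}}.
#' @param t Tumour cellularity.
#' @param s Beta-binomial precision.
#' @param epsilon Sequencing error probability.
#' @return Log-likelihood, same length as \code{phi}.
#' @export
locusLogLikelihood <- function(b, d, phi, prior, t, s, epsilon = 0.001) {
  if (is.null(prior) || length(prior$states) == 0L) {
    stop("empty locus genotype state prior", call. = FALSE)
  }
  perState <- vapply(seq_along(prior$states), function(k) {
    st <- prior$states[[k]]
    m <- xiExpectedVaf(list(st$gN, st$gR, st$gV), phi, t, epsilon)
    dbetabinom(b, d, m, s, log = TRUE) + log(prior$weights[k])
  }, numeric(length(phi)))
  perState <- matrix(perState, nrow = length(phi))
  rowLogSumExp(perState)
}

# N x G cache of locus log-likelihoods over the prevalence grid; the core
# quantity reused by the Griddy Gibbs sampler. priors is a list of state
# priors, one per bulk row.
gridLogLikCache <- function(bulk, priors, grid, t, s, epsilon = 0.001) {
  N <- nrow(bulk)
  cache <- matrix(NA_real_, N, length(grid))
  for (i in seq_len(N)) {
    cache[i, ] <- locusLogLikelihood(bulk$var_counts[i],
                                     bulk$var_counts[i] + bulk$ref_counts[i],
                                     grid, priors[[i]], t, s, epsilon)
  }
  rownames(cache) <- bulk$mutation_id
  cache
}

# State priors for every row of a bulk table.
statePriorsForBulk <- function(bulk, strategy = "parental_cn") {
  lapply(seq_len(nrow(bulk)), function(i) {
    statePrior(bulk$major_cn[i], bulk$minor_cn[i], strategy = strategy,
               normalCn = if ("normal_cn" %in% names(bulk)) bulk$normal_cn[i] else 2L)
  })
}
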