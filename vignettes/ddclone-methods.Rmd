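---
title: "Methods: joint clonal inference from bulk and single-cell data"
author: "ddclone package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint clonal inference from bulk and single-cell data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`ddclone` clusters somatic point mutations and estimates their cellular
prevalences by combining two data sources with complementary strengths.
Single-cell genotyping observes which mutations co-occur in the same cells
but estimates prevalences poorly (few cells, biased sampling); bulk deep
sequencing estimates per-mutation allele fractions precisely but carries no
co-occurrence information. The package encodes the former as a clustering
prior and the latter as a likelihood.

## Prior: distance-dependent CRP over mutations

Every genomic locus is a customer in a distance-dependent Chinese
restaurant process. Customer $i$ draws a link $c_i$ to some customer $j$
with probability proportional to $f(d_{ij})$ for $j \neq i$ and to the
self-link mass $\alpha$ for $j = i$; the clusters are the connected
components of the undirected link graph. Distances come from the binary
genotype-by-locus matrix $\Delta$: $d_{ij}$ is the Jaccard distance between
columns $i$ and $j$, i.e. one minus the fraction of genotypes carrying both
mutations among genotypes carrying either. Loci that always co-occur are at
distance 0; loci that never co-occur (mutually exclusive mutations, MEMs)
are at distance exactly 1. With a constant decay $f \equiv 1$ the link
conditional reduces to the customer-joining form of the traditional CRP —
the package exposes this as the `constant` decay, which doubles as a
distance-blind ablation. We assert (and test) this identity at the level of
the per-customer link conditional, which is what the two processes share;
we make no claim about the marginal partition laws.

A noise-weighted variant of the distance is available:
$d = 1 - w_{fp} n_{11} / (w_{fp} n_{11} + w_{fn}(n_{10} + n_{01}))$,
where $n_{11}$ counts co-occurrences and $n_{10}+n_{01}$ disagreements.
`fnWeight` down-weights disagreements (plausible allelic-dropout false
negatives), `fpWeight` down-weights co-occurrences (plausible
doublet-driven false positives); both default to 1, recovering the plain
Jaccard distance. This weighting is this package's own construction for an
asymmetric-noise-aware distance, kept deliberately simple and
configuration-exposed.

## Likelihood: copy-number-aware beta-binomial

At each locus the sample is assumed to consist of three subpopulations:
normal cells (fraction $1-t$, diploid reference genotype), mutation-free
cancer cells (fraction $t(1-\phi)$), and variant cells (fraction $t\phi$),
where $t$ is the externally supplied tumour cellularity and $\phi$ the
cellular prevalence — **defined here as the fraction of cancer cells
carrying the mutation**, so the three weights partition the sample. (An
alternative convention counts $\phi$ over all cells; the two are related by
the factor $t$ and the package consistently uses the cancer-cell
convention, matching the subpopulation weights above.)

Each subpopulation has a locus genotype $g$ = (reference copies, variant
copies); the probability of sampling a variant allele from it is
$\mu(g) = \epsilon$ if it has no variant copies, $1-\epsilon$ if all copies
are variant, and the variant copy fraction otherwise, with $\epsilon$ the
sequencing error rate (default 0.001). The expected variant read fraction
$\xi(\psi, \phi, t)$ weights the three $\mu$ values by cell fraction times
total copy number (cells with more DNA at the locus contribute more
reads). Variant counts are beta-binomial with mean $\xi$ and a single
shared precision $s$, which absorbs overdispersion relative to the
binomial; $s = \infty$ is accepted as an exact-binomial sentinel.

Since the true locus genotype state is unobserved, the likelihood
marginalizes over an enumerated state prior with equal weights. Three
strategies are provided: `diploid` (single heterozygous state), `total_cn`
(every variant copy count up to the total), and the default `parental_cn`
(variant copies 1, minor, or major — the mutation arriving after, or
before, the copy-number event on either parental allele — deduplicated).
The equal-weight enumeration is this package's design choice; it mirrors
the state-prior style of prevalence-clustering models in this family.
Loci with total copy number 0 are excluded with a message.

## Inference

A Gibbs sampler starts from all-singleton clusters. One sweep resamples
every customer link in fixed index order (a random-scan option exists
behind `scanOrder`), then draws one prevalence per cluster. Removing
$c_i$ may split a component; candidate links that would join two components
are weighted by the link prior times the ratio of the merged cluster's
marginal likelihood to the product of the separate marginals, all other
candidates by the prior alone.

Cluster marginals integrate $\phi$ against a uniform prior by **cached
Griddy Gibbs**: the per-locus log-likelihood is evaluated once per
hyperparameter state on a fixed grid (`gridSize` = 100 midpoints
$(g-\tfrac12)/G$, resolving prevalence to 0.01), and every cluster marginal
is a log-sum-exp of summed cache rows, so a link update costs
$O(K \cdot G)$. The uniform quadrature constant $1/G$ cancels in ratios but
is kept so marginals remain interpretable. Per-cluster $\phi$ draws sample
grid points with mass proportional to the exponentiated cache column sums.

Numerical choices: all weight arithmetic stays in log space; categorical
draws use Gumbel-max, which is immune to underflow when every candidate
weight is tiny; components are recomputed by union-find on the 48-locus
scale this package targets (profiling showed no need for incremental
updates). Degenerate inputs are handled explicitly: an all-zero genotype
column (a locus never observed mutated) is placed at distance 1 from every
other locus with a warning, so the bulk likelihood alone decides its
cluster; beta-binomial means of exactly 0 or 1 are clamped to machine
epsilon with a warning.

## Hyperparameters

| parameter | meaning | default |
|---|---|---|
| `alpha` | self-link (new-cluster) mass | 1 |
| `a` | decay scale of $f(d)=e^{-d/a}$ | 0.1 |
| `s` | beta-binomial precision | 100 |
| `epsilon` | sequencing error rate | 0.001 |
| `gridSize` | prevalence grid points | 100 |
| `iterations` / `burninFraction` | sweeps / discarded fraction | 10000 / 0.5 |

The decay scale deserves comment. Merging two clusters whose prevalence
posteriors overlap buys a marginal-likelihood (Occam) factor of roughly
$G \times \int p_A p_B \approx 1/(2\sqrt{\pi}\,\sigma_\phi)$ — about 5–20
under deep (1000x) coverage with $s = 100$. For the co-occurrence prior to
be able to keep maximally distant loci (MEM pairs, $d = 1$) apart when
their prevalences coincide, the prior penalty $e^{-1/a}$ must dominate that
factor. $a = 1$ gives $e^{-1} \approx 0.37$ and can never do so; the
default $a = 0.1$ gives $e^{-10} \approx 4.5\times10^{-5}$, which does, while
leaving within-cluster links ($d \approx 0$) unpenalized. This is a design
decision of the package, made from the analysis above rather than from any
benchmark outcome.

An optional Metropolis–Hastings update of $(s, a, \alpha)$ — log-normal
random-walk proposals under log-normal priors centred at the initial
values — is provided behind `resampleHyperparams` and is **off by
default**; it is a simple stand-in scheme, and changing $s$ forces a cache
rebuild, making it expensive.

## Summarization

Retained (post burn-in) partitions are condensed into the posterior
similarity matrix (PSM): the fraction of samples co-clustering each locus
pair. The point-estimate clustering maximizes the posterior expected
adjusted Rand (PEAR, Fritsch–Ickstadt estimator computed from the PSM) over
all cuts of an average-linkage dendrogram built on $1-$PSM — the candidate
set used by the standard `maxpear` implementation. Ties break towards fewer
clusters, then labels are canonicalized, making the output deterministic.
When a candidate's expected and observed co-clustering both degenerate to
zero variance (identity or all-ones PSMs), the score is defined as 1 when
they agree exactly and 0 otherwise, so degenerate PSMs resolve to the
obvious partitions. Per-locus prevalence estimates are means of retained
draws (per-locus, since the evaluation metrics are per-locus; cluster means
are derivable).

Two diagnostic reports accompany the calls: MEM pairs (Jaccard distance
exactly 1 — pairs the prior should keep apart) and POM pairs
("prior-overriding mutations": bitwise-identical genotype columns assigned
to different clusters, with their bulk VAF ratio — places where bulk
evidence overrode the prior).

# The synthetic-data generator

The simulator provides ground-truth datasets with all four noise processes
studied in the benchmarks.

**Clone genotypes** evolve on a random binary tree grown by sequential
random edge attachment, under a Dollo process: each locus gains its
mutation on one uniformly chosen edge and loses it independently on each
strict-descendant edge with probability `pLoss` (single gain, multiple
losses). The main-text description of the original benchmark does not fix
the tree law, loss rate or copy-number event rates, so this package chooses
once: `pLoss` = 0.1, variant copies uniform on {1, 2}, total copy number
{2, 3, 4} with probabilities (0.7, 0.2, 0.1) — all configuration-exposed.
Clonal prevalences are symmetric Dirichlet(1). Binarization sets any
genotype with non-zero variant copies to 1.

**Cell sampling** draws observed prevalences from
$\mathrm{Dir}(\lambda \Phi)$ and then cells multinomially — together a
Dirichlet-multinomial with concentration $\lambda$ controlling assortment
bias ($\lambda = \infty$ means unbiased multinomial sampling). The
Dirichlet draw uses the log-space identity
$\Gamma(a) \stackrel{d}{=} \Gamma(a+1)\,U^{1/a}$ so that near-one-hot draws
at tiny $\lambda$ never underflow. **Doublets** replace
$\lfloor r \cdot m \rfloor$ rows by the OR of the row and a freshly drawn
co-trapped cell (the floor is this package's rounding choice). **Allelic
dropout** flips exactly `round(r x #ones)` mutated entries to zero,
uniformly across the matrix (round-half-even); zeros never change.
**Genotype hiding** removes the $k$ lowest-prevalence rows (ties by index),
emulating clonal genotype loss.

**Bulk counts** per carried locus: $\phi$ is the summed prevalence of
carrier genotypes, depth is Poisson(`meanDepth` = 1000, the deep targeted
sequencing setting), and the variant count is beta-binomial with the same
$s$ as the inference default — a deliberately well-specified regime
(binomial available via $s=\infty$). Default cellularity in simulations is
$t = 1$ (pure-tumour benchmark setting).

What the generator does **not** emulate: read-level artefacts (mapping,
strand, sequencing cycles), errors in copy-number calls or cellularity,
site-specific error rates, and genotype-inference noise beyond
doublets/ADO. Passing tests therefore demonstrate correctness of the
method under its own modelling assumptions plus the four injected noise
processes — not robustness to everything real amplicon data can do.

# Evaluation and calibration

Clustering accuracy is the V-measure (harmonic mean of entropy-based
homogeneity and completeness, $\beta = 1$); prevalence accuracy is the mean
absolute per-locus error. The assortment concentration of a real dataset is
approximated by matching its observed bulk/single-cell concordance —
defined here as the squared Pearson correlation ($R^2$) of paired per-locus
prevalence estimates, with the single-cell side estimated by cell counting
and the bulk side by copy-number/cellularity-corrected VAF — against a
simulated, isotonic-smoothed $\lambda \mapsto E[R^2]$ curve, interpolating
on $\log\lambda$; out-of-range concordances return the boundary
concentration with a warning. The regression framing behind the original
$R^2$ matching is unspecified, so squared correlation is this package's
documented choice, and the testable contract is round-trip
self-consistency (median recovered concentration within a factor of 3).

# Problem sizes used by the test suite

The exactness checks run on enumerable sizes (4 loci, 20 grid points,
all 256 link configurations). Recovery and benchmark checks use the
10-genotype / 48-locus / depth-1000 setting with 2000 sweeps and 2–3
replicate datasets per condition, and the noise-direction checks use
10 replicates at 24 loci with 500 sweeps — sizes chosen so the whole suite
exercises every claim at meaningful scale while remaining a routine
desk-side run. The acceptance script's statistics use 200 replicates, the
scale at which the published means are quoted.

# Known limitations

- Single-sample only; longitudinal/multi-sample sharing is out of scope.
- No split-merge moves: mixing relies on single-link updates, which is
  adequate at the tens-of-loci scale but would slow on hundreds of loci.
- The state-prior enumeration and the noise-weighted distance are
  documented stand-ins for constructions whose original details are not
  public; both are behind configuration switches.
- Copy-number calls and cellularity are trusted inputs; errors in them
  propagate directly into $\xi$.
- With very low depth or tiny $s$, prevalence posteriors flatten and the
  prior dominates; with a flat prior (constant decay) the model degrades to
  a prevalence-only clustering.
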