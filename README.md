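# ddclone

Joint inference of tumour clonal structure from bulk and single-cell
sequencing.

## The problem

Bulk deep sequencing of a tumour measures, for every somatic point mutation
*i*, a variant read count *b_i* out of depth *d_i*. Clustering mutations by
their cellular prevalence φ_i — the fraction of cancer cells carrying the
mutation — is the standard route to the tumour's clonal composition, but
prevalence alone cannot separate distinct clones that happen to sit at
similar prevalences. Single-cell genotyping measures the complementary
signal, mutation *co-occurrence*, but its prevalence estimates are distorted
by assortment bias, doublets and allelic dropout.

`ddclone` combines both: single-cell genotypes enter as a Bayesian
non-parametric prior over mutation clusterings, bulk counts enter through a
copy-number-aware likelihood, and inference produces both a clustering of
loci and per-locus cellular prevalence estimates. The package is aimed at
cancer genomics analysts with matched bulk + single-cell data, and ships
simulators and metrics so the whole method can be exercised and benchmarked
without any external dataset.

## The model

Mutations are customers in a **distance-dependent Chinese restaurant process
(ddCRP)**: customer *i* links to customer *j* with probability

    p(c_i = j) ∝ f(d_ij)   for j ≠ i,      p(c_i = i) ∝ α,

where `d_ij` is the Jaccard distance between loci *i* and *j* across the
binary genotype-by-locus matrix Δ from single-cell sequencing, and
`f(d) = exp(−d/a)` is an exponential decay. Connected components of the
link graph are the mutation clusters; loci that co-occur in genotypes are
encouraged to co-cluster.

Each cluster shares a cellular prevalence φ with a uniform prior. A locus's
variant count is beta-binomial,

    b_i | d_i ~ BetaBinomial(d_i, m = ξ(ψ_i, φ_i, t), s),

where ξ is the expected variant read fraction of a three-subpopulation
mixture (normal / mutation-free cancer / variant cells weighted (1−t),
t(1−φ), tφ and by their total copy numbers), t is the tumour cellularity and
ψ_i the locus genotype state, marginalized over an enumerated copy-number
prior. Inference is Gibbs sampling over customer links with cached Griddy
Gibbs draws of φ on a 100-point grid; the trace is summarized by the
posterior similarity matrix, a maxPEAR point-estimate clustering and
posterior-mean prevalences.

## Worked example

Simulate a 5-clone tumour over 16 loci, sample 50 single cells with
moderate assortment bias, and run the full pipeline:

```r
library(ddclone)
sim   <- simulateClones(nGenotypes = 5, nLoci = 16, seed = 7)
bulk  <- simulateBulk(sim, meanDepth = 1000, seed = 7)
cells <- sampleCells(sim, nCells = 50, concentration = 10, seed = 7)
fit   <- runDdclone(bulk$bulk, ScGenotypes(cells$cells),
                    params = ddcloneParams(iterations = 1000, seed = 7))
calls <- summarizeClones(fit)
head(calls, 8)
```

```
  mutation_id cluster phi_hat n_cluster_members
1     1:10137       1 0.44092                 6
2     2:10274       2 0.14038                 5
3     3:10411       2 0.14182                 5
4     4:10548       1 0.42862                 6
5     5:10685       3 0.65048                 1
6     6:10822       4 0.01398                 1
7     7:10959       1 0.43058                 6
8     8:11096       5 0.02930                 1
```

Each row is one locus: its maxPEAR cluster label, posterior-mean cellular
prevalence and the cluster size. Loci 1, 4 and 7 are called one clone at
prevalence ≈ 0.43; loci 2 and 3 a second clone at ≈ 0.14. Scoring against
the simulation's ground truth:

```r
truth <- bulk$truth[match(calls$mutation_id, bulk$truth$mutation_id), ]
vMeasure(truth$true_cluster, calls$cluster)        # 0.81
meanPhiError(truth$true_phi, calls$phi_hat)        # 0.072
```

i.e. clustering agreement (V-measure, 1 = perfect) of 0.81 and a mean
absolute prevalence error of 0.072 under deliberately biased single-cell
sampling. (A warning notes loci never observed mutated in the 50 cells;
they carry no co-occurrence evidence and are driven by the bulk likelihood
alone.)

A command-line surface is available at `exec/ddclone`
(`ddclone run|simulate|evaluate|benchmark`); flags mirror the YAML config
keys and every command writes a JSON manifest with its seed and input
hashes.

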