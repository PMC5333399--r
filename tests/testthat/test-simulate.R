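test_that("simulated clone sets satisfy the Dollo-process contracts", {
  sim <- simulateClones(6, 30, seed = 11)
  geno <- cloneGenotypes(sim)@.Data
  expect_true(all(geno %in% c(0L, 1L)))
  expect_equal(sum(clonePrevalences(sim)), 1, tolerance = 1e-12)
  expect_true(all(clonePrevalences(sim) >= 0))
  expect_equal(dim(geno), c(6L, 30L))
  # parent vector is a tree: one root, every other node reaches it
  tree <- sim@tree
  expect_equal(sum(tree == 0L), 1L)
  root <- which(tree == 0L)
  for (v in seq_along(tree)[-root]) {
    steps <- 0L
    while (v != root && steps < length(tree)) { v <- tree[v]; steps <- steps + 1L }
    expect_equal(v, root)
  }
  # no losses: every locus has at least one carrier (single guaranteed gain)
  sim0 <- simulateClones(6, 40, pLoss = 0, seed = 3)
  expect_true(all(colSums(cloneGenotypes(sim0)@.Data) >= 1))
  # copy-number states are consistent
  cn <- sim@cnStates
  expect_true(all(cn$total_cn == cn$major_cn + cn$minor_cn))
  expect_true(all(cn$var_copies >= 1 & cn$var_copies <= cn$total_cn))
})

test_that("certain losses leave at most the gain-edge clade founder", {
  sim <- simulateClones(5, 40, pLoss = 1, seed = 9)
  # with p_loss = 1 the mutation never survives past its gain edge, so each
  # locus has at most one carrier (exactly one when gained on a leaf edge)
  expect_true(all(colSums(cloneGenotypes(sim)@.Data) <= 1))
})

test_that("cell sampling follows the Dirichlet-multinomial assortment law", {
  geno <- matrix(c(1, 0, 0, 1, 1, 1), nrow = 2,
                 dimnames = list(NULL, c("1:1", "1:2", "1:3")))
  onehot <- makeCloneSim(geno, prev = c(1, 0))
  cs <- sampleCells(onehot, 20, concentration = Inf, seed = 1)
  expect_true(all(cs$genotypeOfCell == 1L))
  expect_equal(unname(cs$cells), geno[rep(1, 20), ], ignore_attr = TRUE)

  sim <- simulateClones(10, 4, seed = 21)
  # lambda = Inf: observed prevalences are exactly the truth
  expect_equal(sampleCells(sim, 10, Inf)$phiObserved, clonePrevalences(sim))
  # deduplicated clean cells are a subset of the true genotype rows
  cs2 <- sampleCells(sim, 50, Inf, seed = 2)
  gkeys <- apply(cloneGenotypes(sim)@.Data, 1, paste, collapse = "")
  ckeys <- unique(apply(cs2$cells, 1, paste, collapse = ""))
  expect_true(all(ckeys %in% gkeys))
  # observed prevalences are a simplex for any concentration
  for (lam in c(0.01, 1, 1000)) {
    po <- sampleCells(sim, 5, lam)$phiObserved
    expect_equal(sum(po), 1, tolerance = 1e-12)
    expect_true(all(po >= 0))
  }
})

test_that("mean assortment error shrinks monotonically with concentration", {
  set.seed(17)
  sim <- simulateClones(10, 2)
  means <- vapply(c(0.01, 1, 10, 1000), function(lam) {
    mean(replicate(150, ePhi(clonePrevalences(sim),
                             sampleCells(sim, 50, lam)$phiObserved)))
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("doublet corruption ORs the recorded constituents and nothing else", {
  sim <- simulateClones(5, 20, seed = 6)
  cs <- sampleCells(sim, 40, Inf, seed = 7)
  out <- applyDoublets(cs$cells, 0.25, sim, phiObserved = cs$phiObserved,
                       seed = 8)
  expect_equal(nrow(out$cells), 40L)
  expect_length(out$doubletRows, floor(0.25 * 40))
  geno <- cloneGenotypes(sim)@.Data
  for (k in seq_along(out$doubletRows)) {
    r <- out$doubletRows[k]
    expect_equal(out$cells[r, ],
                 pmax(cs$cells[r, ], geno[out$partner[k], ]))
  }
  untouched <- setdiff(seq_len(40), out$doubletRows)
  expect_equal(out$cells[untouched, ], cs$cells[untouched, ])
  # zero rate: identity
  expect_equal(applyDoublets(cs$cells, 0, sim)$cells, cs$cells)
  # OR with itself changes nothing: force partner = own genotype
  own <- makeCloneSim(matrix(c(1, 0, 1), 1, dimnames = list(NULL, c("1:1", "1:2", "1:3"))),
                      prev = 1)
  cso <- sampleCells(own, 8, Inf)
  expect_equal(applyDoublets(cso$cells, 0.5, own)$cells, cso$cells)
})

test_that("allelic dropout flips exactly the prescribed number of mutated entries", {
  set.seed(10)
  cells <- matrix(0L, 10, 10)
  cells[sample(100, 40)] <- 1L
  out <- applyAdo(cells, 0.3)
  flipped <- which(cells == 1L & out == 0L)
  expect_length(flipped, 12L)              # round(0.3 * 40)
  expect_true(all(out[cells == 0L] == 0L)) # zeros never change
  expect_true(all(out <= cells))           # only 1 -> 0
  expect_equal(applyAdo(cells, 0), cells)
  expect_equal(sum(applyAdo(cells, 1)), 0L)
  # round-half-even bookkeeping on an odd count
  cells2 <- matrix(c(1L, 1L, 1L, 0L), 2)
  expect_equal(sum(cells2) - sum(applyAdo(cells2, 0.5)), round(0.5 * 3))
})

test_that("hiding genotypes removes the lowest-prevalence rows first", {
  geno <- matrix(c(1, 0, 0, 0, 1, 0, 0, 0, 1), 3,
                 dimnames = list(NULL, c("1:1", "1:2", "1:3")))
  sim <- makeCloneSim(geno, prev = c(0.5, 0.3, 0.2))
  expect_equal(nrow(hideGenotypes(sim, 0)), 3L)
  expect_equal(unname(hideGenotypes(sim, 1)@.Data), unname(geno[1:2, ]))
  expect_equal(unname(hideGenotypes(sim, 2)@.Data), unname(geno[1, , drop = FALSE]))
  expect_error(hideGenotypes(sim, 3), "0 <= k")
  # prevalence ties broken by row index
  simTie <- makeCloneSim(geno, prev = c(0.4, 0.3, 0.3))
  expect_equal(unname(hideGenotypes(simTie, 1)@.Data), unname(geno[c(1, 3), ]))
})

test_that("bulk simulation reproduces the expected variant read fractions", {
  # single carrier clone at prevalence 0.4, diploid het, t = 1, eps = 0:
  # xi = 0.4 * 0.5 = 0.2
  N <- 400
  geno <- rbind(rep(1L, N), rep(0L, N))
  colnames(geno) <- sprintf("1:%d", seq_len(N))
  sim <- makeCloneSim(geno, prev = c(0.4, 0.6))
  bk <- simulateBulk(sim, meanDepth = 500, tumourContent = 1, s = 100,
                     epsilon = 0, seed = 13)
  expect_equal(nrow(bk$bulk), N)           # all loci carried by clone 1
  vaf <- bk$bulk$var_counts / (bk$bulk$var_counts + bk$bulk$ref_counts)
  expect_equal(mean(vaf), 0.2, tolerance = 0.03)
  expect_equal(bk$truth$true_phi, rep(0.4, N))
  expect_equal(bk$truth$true_cluster, rep(1L, N))
  # locus carried by every genotype: xi = 0.5
  simAll <- makeCloneSim(matrix(1L, 2, 50,
                                dimnames = list(NULL, sprintf("1:%d", 1:50))),
                         prev = c(0.3, 0.7))
  bkAll <- simulateBulk(simAll, meanDepth = 800, s = Inf, epsilon = 0,
                        seed = 14)
  vafAll <- bkAll$bulk$var_counts / (bkAll$bulk$var_counts + bkAll$bulk$ref_counts)
  expect_equal(mean(vafAll), 0.5, tolerance = 0.02)
  # loci carried by nobody are excluded
  genoNone <- rbind(c(1L, 0L), c(1L, 0L))
  colnames(genoNone) <- c("1:1", "1:2")
  bkNone <- simulateBulk(makeCloneSim(genoNone, prev = c(0.5, 0.5)), seed = 2)
  expect_equal(bkNone$bulk$mutation_id, "1:1")
})

test_that("average prevalence error is plain arithmetic with strict length checks", {
  expect_equal(ePhi(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(ePhi(c(1, 0), c(0, 1)), 1)
  expect_equal(ePhi(c(0.5, 0.3, 0.2), c(0.4, 0.4, 0.2)), 0.2 / 3,
               tolerance = 1e-12)
  expect_error(ePhi(c(0.5, 0.5), c(1)), "length")
})
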