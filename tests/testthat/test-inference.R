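test_that("induced partitions are the connected components of the link graph", {
  expect_equal(inducedPartition(c(1, 2, 3)), c(1, 2, 3))      # self-loops
  expect_equal(inducedPartition(c(2, 3, 3)), c(1, 1, 1))      # chain
  expect_equal(inducedPartition(c(2, 1, 4, 3)), c(1, 1, 2, 2))
  expect_equal(inducedPartition(c(5, 1, 3, 3, 2)), c(1, 1, 2, 2, 1))
  expect_error(inducedPartition(c(2, 9)), "invalid")
})

test_that("cluster marginal log-likelihood is an explicit grid quadrature", {
  # 2-locus cluster on a 3-point grid, hand-set values
  cache <- rbind(log(c(0.2, 0.5, 0.1)), log(c(0.3, 0.4, 0.6)))
  hand <- log((0.2 * 0.3 + 0.5 * 0.4 + 0.1 * 0.6) / 3)
  expect_equal(clusterMarginalLogLik(1:2, cache), hand)
  # singleton: log-mean of the row
  expect_equal(clusterMarginalLogLik(1L, cache), log(mean(c(0.2, 0.5, 0.1))))
  # flat rows: constants factor out (per-locus constant c, any grid)
  flat <- matrix(log(0.25), 2, 5)
  expect_equal(clusterMarginalLogLik(1:2, flat), 2 * log(0.25))
  expect_error(clusterMarginalLogLik(integer(0), cache), "empty")
})

test_that("single-link conditionals match the exhaustive enumeration oracle", {
  set.seed(31)
  bulk <- makeToyBulk(c(20, 26, 60))
  priors <- ddclone:::statePriorsForBulk(bulk, "diploid")
  grid <- ddclone:::phiGrid(10)
  cache <- ddclone:::gridLogLikCache(bulk, priors, grid, t = 1, s = 50)
  D <- matrix(c(0, 0.2, 0.9, 0.2, 0, 0.7, 0.9, 0.7, 0), 3, 3)
  logPriorW <- ddclone:::linkPriorLogWeights(D, alpha = 1, a = 0.5)
  links <- c(1L, 2L, 3L)
  # exact conditional for c_1 given c_2=2, c_3=3
  logw <- vapply(1:3, function(j) {
    l <- links; l[1] <- j
    labels <- inducedPartition(l)
    lik <- sum(vapply(unique(labels), function(k) {
      clusterMarginalLogLik(which(labels == k), cache)
    }, numeric(1)))
    logPriorW[1, j] + lik
  }, numeric(1))
  exact <- exp(logw - max(logw)); exact <- exact / sum(exact)
  nDraw <- 20000
  draws <- replicate(nDraw, resampleLink(1L, links, cache, logPriorW)[1])
  freq <- tabulate(draws, 3) / nDraw
  se <- sqrt(exact * (1 - exact) / nDraw)
  expect_true(all(abs(freq - exact) <= 3 * se + 1e-3))
})

test_that("with alpha huge both of two customers self-loop almost surely", {
  cache <- matrix(0, 2, 5)  # flat likelihood
  logPriorW <- ddclone:::linkPriorLogWeights(matrix(0.5, 2, 2) - diag(0.5, 2),
                                             alpha = 1e8, a = 1)
  set.seed(4)
  draws <- replicate(500, resampleLink(1L, c(1L, 2L), cache, logPriorW)[1])
  expect_true(mean(draws == 1L) > 0.99)
})

test_that("griddy phi draws follow the cached posterior masses", {
  grid <- ddclone:::phiGrid(10)
  set.seed(8)
  # mass concentrated on one grid point
  cache <- matrix(-Inf, 1, 10); cache[1, 4] <- 0
  expect_equal(resamplePhi(1L, cache, grid), grid[4])
  # hand-normalized two-point mass 2:1
  cache2 <- matrix(-Inf, 1, 10); cache2[1, 3] <- log(2); cache2[1, 7] <- log(1)
  draws <- replicate(6000, resamplePhi(1L, cache2, grid))
  expect_equal(mean(draws == grid[3]), 2 / 3, tolerance = 0.03)
  # flat likelihood: uniform over the grid
  flat <- matrix(0, 2, 10)
  draws <- replicate(8000, resamplePhi(1:2, flat, grid))
  expect_gt(chisq.test(table(factor(draws, levels = grid)))$p.value, 1e-4)
  expect_error(resamplePhi(1L, matrix(-Inf, 1, 10), grid), "degenerate")
})

test_that("flat-likelihood link updates are iid draws from the ddCRP prior", {
  N <- 4
  set.seed(12)
  D <- matrix(runif(N * N, 0, 1), N, N); D <- (D + t(D)) / 2; diag(D) <- 0
  prior <- linkPriorMatrix(D, alpha = 1.3, a = 0.6)
  cache <- matrix(0, N, 8)
  fit <- ddcrpGibbs(cache, D, ddcloneParams(iterations = 4000, alpha = 1.3,
                                            a = 0.6, seed = 99))
  lt <- fit@linkTrace
  for (i in seq_len(N)) {
    freq <- tabulate(lt[, i], N) / nrow(lt)
    se <- sqrt(prior[i, ] * (1 - prior[i, ]) / nrow(lt))
    expect_true(all(abs(freq - prior[i, ]) <= 4 * se + 2e-3))
  }
})

test_that("the sampler is bitwise reproducible and handles one locus", {
  bulk <- makeToyBulk(c(30, 35, 70, 72))
  delta <- ScGenotypes(matrix(c(1, 0, 1, 0, 0, 1, 0, 1), nrow = 2,
                              dimnames = list(NULL, bulk$mutation_id)))
  p <- ddcloneParams(iterations = 40, seed = 123)
  f1 <- runDdclone(bulk, delta, params = p)
  f2 <- runDdclone(bulk, delta, params = p)
  expect_identical(clusterTrace(f1), clusterTrace(f2))
  expect_identical(phiTrace(f1), phiTrace(f2))
  # single locus: always its own singleton cluster
  cache1 <- ddclone:::gridLogLikCache(makeToyBulk(50),
                                      ddclone:::statePriorsForBulk(makeToyBulk(50)),
                                      ddclone:::phiGrid(20), 1, 100)
  fit1 <- ddcrpGibbs(cache1, matrix(0, 1, 1),
                     ddcloneParams(iterations = 30, seed = 5))
  expect_true(all(clusterTrace(fit1) == 1L))
  expect_true(all(phiTrace(fit1) %in% ddclone:::phiGrid(20)))
})

test_that("random-scan sweeps keep the trace valid", {
  bulk <- makeToyBulk(c(30, 40, 60))
  cache <- ddclone:::gridLogLikCache(bulk,
                                     ddclone:::statePriorsForBulk(bulk),
                                     ddclone:::phiGrid(20), 1, 100)
  D <- matrix(0.5, 3, 3) - diag(0.5, 3)
  fit <- ddcrpGibbs(cache, D, ddcloneParams(iterations = 50, seed = 2,
                                            scanOrder = "random"))
  expect_equal(dim(clusterTrace(fit)), c(50L, 3L))
  expect_false(anyNA(phiTrace(fit)))
})

test_that("hyperparameters stay fixed when resampling is disabled or frozen", {
  bulk <- makeToyBulk(c(20, 60))
  priors <- ddclone:::statePriorsForBulk(bulk)
  cache <- ddclone:::gridLogLikCache(bulk, priors, ddclone:::phiGrid(15), 1, 100)
  D <- matrix(0.4, 2, 2) - diag(0.4, 2)
  fit <- ddcrpGibbs(cache, D, ddcloneParams(iterations = 25, seed = 6))
  expect_true(all(fit@hyperTrace[, "s"] == 100))
  expect_true(all(fit@hyperTrace[, "alpha"] == 1))
  # zero proposal scale: MH chain cannot move
  fit0 <- ddcrpGibbs(cache, D,
                     ddcloneParams(iterations = 25, seed = 6,
                                   resampleHyperparams = TRUE,
                                   hyperProposalScale = 0),
                     bulk = bulk, priors = priors)
  expect_true(all(fit0@hyperTrace[, "s"] == 100))
  # with a real scale the chain moves but stays positive
  fit1 <- ddcrpGibbs(cache, D,
                     ddcloneParams(iterations = 40, seed = 6,
                                   resampleHyperparams = TRUE,
                                   hyperProposalScale = 0.2),
                     bulk = bulk, priors = priors)
  expect_true(all(fit1@hyperTrace > 0))
  expect_gt(stats::sd(fit1@hyperTrace[, "s"]), 0)
})
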