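test_that("stationary draws and limit cases match closed forms", {
  jc <- substModel("JC")
  expect_equal(pruningLoglik(oneTipGenealogy(), c(s1 = "ACGT"), jc),
               4 * log(0.25), tolerance = 1e-10)
  # two identical tips at (numerically) zero divergence
  g <- threeTipGenealogy()
  g@time <- g@time * 1e-12
  aln <- c(t1 = "ACGTAC", t2 = "ACGTAC", t3 = "ACGTAC")
  expect_equal(pruningLoglik(g, aln, jc), 6 * log(0.25), tolerance = 1e-6)
})

test_that("pruning equals brute-force state enumeration on a 3-tip tree", {
  g <- threeTipGenealogy()
  aln <- c(t1 = "ACGTA", t2 = "ACTTA", t3 = "GCGTC")
  models <- list(
    substModel("JC"),
    substModel("HKY", kappa = 4, freqs = c(0.3, 0.2, 0.2, 0.3)),
    substModel("GTR", rates = c(1, 3, 0.5, 1, 4, 1),
               freqs = c(0.35, 0.15, 0.15, 0.35), gammaShape = 0.6,
               pInv = 0.2))
  for (m in models) {
    expect_equal(pruningLoglik(g, aln, m), bruteForceLoglik(g, aln, m),
                 tolerance = 1e-8)
  }
})

test_that("compiled and reference pruning kernels agree on random trees", {
  set.seed(42)
  cfg <- simulationConfig(c(F = 6L, S = 6L, A = 6L), seed = 2)
  sim <- demeflow:::simulateDataset(cfg)
  cp <- demeflow:::compressAlignment(demeflow:::asAlignmentMatrix(sim$alignment))
  models <- list(substModel("JC"),
                 substModel("GTR", rates = c(1, 2, 1, 1, 3, 1),
                            freqs = c(0.3, 0.2, 0.2, 0.3),
                            gammaShape = 0.4, pInv = 0.3))
  for (s in 1:3) for (m in models) {
    g <- simulateGenealogy(cfg, seed = s)
    a <- demeflow:::prunedLoglik(g@parent, g@time, cp$patterns, cp$weights, m)
    b <- demeflow:::prunedLoglikR(g@parent, g@time, cp$patterns, cp$weights, m)
    expect_equal(a, b, tolerance = 1e-8)
  }
})

test_that("zero branch lengths give identical sequences", {
  g <- threeTipGenealogy()
  g@time[] <- 0
  seqs <- mutateOnGenealogy(g, substModel("JC"), length = 50, seed = 1)
  expect_length(unique(seqs), 1L)
})

test_that("simulated divergence matches the Jukes-Cantor closed form", {
  # two tips separated by 2t: P(diff) = 3/4 (1 - exp(-8t/3))
  t <- 0.15
  emptyPath <- matrix(numeric(0), 0, 2)
  g <- new("Genealogy", tipLabels = c("x", "y"), demeLabels = "F",
           parent = c(3L, 3L, 0L), time = c(0, 0, t),
           nodeDeme = rep(1L, 3), paths = rep(list(emptyPath), 3))
  L <- 10000L
  seqs <- mutateOnGenealogy(g, substModel("JC"), length = L, seed = 9)
  p <- mean(strsplit(seqs[1], "")[[1]] != strsplit(seqs[2], "")[[1]])
  expected <- 3 / 4 * (1 - exp(-8 * t / 3))
  se <- sqrt(expected * (1 - expected) / L)
  expect_lt(abs(p - expected), 3 * se)
})

test_that("long-branch tip composition approaches the stationary frequencies", {
  freqs <- c(0.25, 0.25, 0.25, 0.25)
  emptyPath <- matrix(numeric(0), 0, 2)
  g <- new("Genealogy", tipLabels = c("x", "y"), demeLabels = "F",
           parent = c(3L, 3L, 0L), time = c(0, 0, 5),
           nodeDeme = rep(1L, 3), paths = rep(list(emptyPath), 3))
  L <- 100000L
  m <- substModel("GTR", rates = c(1, 2, 1, 1, 2, 1), freqs = freqs)
  seqs <- mutateOnGenealogy(g, m, length = L, seed = 4)
  comp <- table(factor(strsplit(seqs[1], "")[[1]], c("A", "C", "G", "T"))) / L
  se <- sqrt(freqs * (1 - freqs) / L)
  expect_true(all(abs(as.numeric(comp) - freqs) < 3.5 * se))
})

test_that("invalid model parameters are rejected", {
  expect_error(substModel("GTR", rates = c(-1, 1, 1, 1, 1, 1)),
               "positive")
  expect_error(new("SubstModel", name = "GTR", rates = rep(1, 6),
                   freqs = c(0.5, 0.5, 0.1, 0.1), gammaShape = Inf,
                   nGammaCat = 4L, pInv = 0), "summing to 1")
})
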