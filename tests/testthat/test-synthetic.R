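test_that("degenerate sample sizes are handled", {
  cfg <- simulationConfig(c(F = 1L, S = 0L, A = 0L), seed = 1)
  g <- simulateGenealogy(cfg)
  expect_length(g@parent, 1L)
  expect_identical(g@parent, 0L)
  expect_error(simulationConfig(c(F = 0L, S = 0L, A = 0L), seed = 1),
               "at least one sample")
})

test_that("simulated genealogies satisfy the structural invariants", {
  cfgs <- list(
    simulationConfig(c(F = 5L, S = 5L, A = 5L), seed = 1),
    simulationConfig(c(F = 8L, S = 2L, A = 4L), seed = 2,
                     growth = list(onset = 3e-4, ratio = 0.1)),
    simulationConfig(c(F = 4L, S = 4L, A = 4L),
                     scenario = enumerateScenarios()[["full model"]],
                     migrationRate = 20, seed = 3))
  for (cfg in cfgs) for (s in 1:8) {
    g <- simulateGenealogy(cfg, seed = s)
    expect_true(isTRUE(validObject(g, test = TRUE)))
  }
})

test_that("pairwise coalescence time matches the closed-form expectation", {
  theta <- 0.01
  reps <- 2500
  set.seed(5)
  ts <- replicate(reps, {
    g <- demeflow:::simCoalescent(c("a", "b"), c(1L, 1L), "F", theta,
                                  matrix(0, 1, 1))
    max(g@time)
  })
  # E[T2] = theta/2, sd(T2) = theta/2
  se <- (theta / 2) / sqrt(reps)
  expect_lt(abs(mean(ts) - theta / 2), 3 * se)
})

test_that("masked routes carry exactly zero migration events", {
  cfg <- simulationConfig(c(F = 4L, S = 4L, A = 4L), seed = 1)
  forbidden <- !(cfg@scenario@mask | diag(3) > 0)
  for (s in 1:100) {
    g <- simulateGenealogy(cfg, seed = s)
    expect_identical(sum(genealogyStats(g)$migrations[forbidden]), 0L)
  }
})

test_that("the final coalescence happens in the origin deme", {
  # scenario S>A>F: S lineages never leave S, so with samples in both A and
  # S the root coalescence must be in S (A lineages migrate A->S to meet them)
  cfg <- simulationConfig(c(F = 0L, S = 4L, A = 4L), seed = 2)
  for (s in 1:10) {
    g <- simulateGenealogy(cfg, seed = s)
    root <- which(g@parent == 0L)
    expect_identical(g@demeLabels[g@nodeDeme[root]], "S")
  }
})

test_that("a disconnected scenario with multi-deme samples is refused", {
  sc <- migrationScenario(c("F", "S", "A"), edges = rbind(c("S", "A")),
                          origin = "S")
  expect_error(
    simulateGenealogy(simulationConfig(c(F = 2L, S = 2L, A = 2L),
                                       scenario = sc, seed = 1)),
    "non-coalescible")
})

test_that("Watterson-type diversity is recovered across replicates", {
  theta <- 0.01
  n <- 20L
  L <- 600L
  an <- sum(1 / seq_len(n - 1))
  est <- numeric(50)
  for (r in 1:50) {
    d <- simulateExpansionDataset(n = n, locusLength = L, theta = theta,
                                  onset = Inf, ratio = 1,
                                  mutModel = substModel("JC"), seed = r)
    S <- sum(classifySegregatingSites(d$alignment))
    est[r] <- S / (an * L)
  }
  expect_lt(abs(mean(est) - theta) / theta, 0.15)
})

test_that("dataset generation is byte-identical under a fixed seed", {
  cfg <- simulationConfig(c(F = 3L, S = 3L, A = 3L), locusLength = 120L,
                          seed = 7)
  d1 <- file.path(tempdir(), "gen1")
  d2 <- file.path(tempdir(), "gen2")
  generateDataset(cfg, d1)
  generateDataset(cfg, d2)
  for (f in c("synthetic.fasta", "synthetic.demes.tsv", "synthetic.truth.json"))
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
})

test_that("preset configurations emulate the empirical data shapes", {
  mito <- presetConfig("mito", seed = 1)
  sim <- demeflow:::simulateDataset(mito)
  expect_length(sim$alignment, 138L)
  expect_true(all(nchar(sim$alignment) == 604L))
  expect_identical(nrow(sim$demeMap), 138L)

  nuc <- presetConfig("nuclear", seed = 1)
  sim2 <- demeflow:::simulateDataset(nuc)
  expect_length(sim2$alignment, 76L) # 38 diploid individuals, phased
  expect_true(all(grepl("\\|a[12]$", names(sim2$alignment))))
  expect_true(all(nchar(sim2$alignment) == 219L))
})

test_that("site and diversity summaries agree with an independent coalescent simulator", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  theta <- 0.01; n <- 15L; L <- 400L; reps <- 25L
  mine <- matrix(NA_real_, reps, 2)
  for (r in seq_len(reps)) {
    d <- simulateExpansionDataset(n = n, locusLength = L, theta = theta,
                                  onset = Inf, ratio = 1,
                                  mutModel = substModel("JC"), seed = 100 + r)
    tab <- collapseHaplotypes(d$alignment,
                              data.frame(sample_id = names(d$alignment),
                                         deme = "P"))
    mine[r, ] <- c(sum(classifySegregatingSites(d$alignment)),
                   nucleotideDiversity(tab))
  }
  py <- sprintf(
    "import msprime, numpy\nS=[];P=[]\nfor r in range(%d):\n    ts=msprime.sim_ancestry(samples=%d, ploidy=1, population_size=1.0, sequence_length=%d, random_seed=r+1)\n    mts=msprime.sim_mutations(ts, rate=%.8g, random_seed=r+101, model='jc69')\n    S.append(mts.segregating_sites(span_normalise=False))\n    P.append(mts.diversity(span_normalise=True))\nprint(numpy.mean(S), numpy.std(S)/numpy.sqrt(len(S)), numpy.mean(P), numpy.std(P)/numpy.sqrt(len(P)))",
    reps, n, L, theta / 2)
  out <- system2("python", "-", input = py, stdout = TRUE, stderr = FALSE)
  vals <- as.numeric(strsplit(tail(out, 1), "\\s+")[[1]])
  seS <- sqrt(vals[2]^2 + stats::var(mine[, 1]) / reps)
  seP <- sqrt(vals[4]^2 + stats::var(mine[, 2]) / reps)
  expect_lt(abs(mean(mine[, 1]) - vals[1]), 3 * seS)
  expect_lt(abs(mean(mine[, 2]) - vals[3]), 3 * seP)
})
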