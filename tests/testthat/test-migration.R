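# Quadrature oracle for two identical sequences in one deme under JC:
# L(theta) = int (2/theta) exp(-2t/theta) [(1/4)(1/4 + 3/4 e^{-8t/3})]^L dt
quadratureTwoSeqLoglik <- function(theta, L) {
  # substituted u = 2t/theta so the integrand is well-scaled for all theta
  g <- function(u)
    exp(-u + L * log(0.25 * (0.25 + 0.75 * exp(-4 * theta * u / 3))))
  log(stats::integrate(g, 0, Inf, rel.tol = 1e-12)$value)
}

twoSeqData <- function(L = 60) {
  s <- paste(rep(c("A", "C", "G", "T"), length.out = L), collapse = "")
  list(alignment = stats::setNames(c(s, s), c("x", "y")),
       demeMap = data.frame(sample_id = c("x", "y"), deme = "F"))
}

test_that("the Monte-Carlo likelihood matches numeric quadrature", {
  d <- twoSeqData(60)
  theta <- 0.01
  est <- estimateLoglik(d$alignment, d$demeMap, theta, matrix(0, 1, 1),
                        demeLabels = "F", model = substModel("JC"),
                        nsim = 3000, seed = 8)
  expect_lt(abs(est$logLik - quadratureTwoSeqLoglik(theta, 60)), 3 * est$se)
})

test_that("vectorised and event-level genealogy densities agree", {
  cfg <- simulationConfig(c(F = 5L, S = 5L, A = 5L), seed = 3)
  set.seed(3)
  for (s in 1:5) {
    g <- simulateGenealogy(cfg, seed = s)
    st <- genealogyStats(g)
    Smat <- matrix(c(st$coal, st$pairTime, st$lineageTime,
                     as.vector(t(st$migrations))), 1)
    theta <- runif(3, 0.003, 0.03)
    M <- matrix(runif(9, 1, 50), 3, 3); diag(M) <- 0
    expect_equal(demeflow:::statsLogDens(Smat, theta, M)[1],
                 demeflow:::logGenealogyDensity(st, theta, M),
                 tolerance = 1e-10)
    # masked-rate impossibility
    M0 <- M; M0[st$migrations > 0] <- 0
    if (any(st$migrations > 0))
      expect_identical(demeflow:::statsLogDens(Smat, theta, M0)[1], -Inf)
  }
})

test_that("the compiled chain run at power zero samples the prior", {
  cfg <- simulationConfig(c(F = 3L, S = 3L, A = 3L), migrationRate = 30,
                          seed = 4)
  sim <- demeflow:::simulateDataset(cfg)
  td <- demeflow:::tipDemesFor(sim$alignment, sim$demeMap, c("F", "S", "A"))
  mod <- substModel("JC")
  cp <- demeflow:::compressAlignment(td$aln)
  ctx <- demeflow:::likContext(cp$patterns, cp$weights, mod)
  theta <- rep(0.01, 3)
  M <- cfg@migrationRates
  set.seed(5)
  run <- demeflow:::runChain(td$tipDeme, c("F", "S", "A"), ctx, theta, M,
                             nIter = 6000, burnin = 1000, thin = 10,
                             power = 0)
  set.seed(6)
  direct <- replicate(600, {
    g <- demeflow:::simCoalescent(rownames(td$aln), td$tipDeme,
                                  c("F", "S", "A"), theta, M)
    s <- genealogyStats(g)
    c(s$pairTime, as.vector(t(s$migrations)))
  })
  chain <- cbind(run$stats[, 4:6], run$stats[, 10:18])
  dm <- rowMeans(direct)
  dse <- apply(direct, 1, sd) / sqrt(ncol(direct))
  cm <- colMeans(chain)
  # allow for chain autocorrelation: compare at 5 combined direct-SEs
  keep <- dse > 0
  expect_true(all(abs(cm[keep] - dm[keep]) < 5 * dse[keep] + 0.02 * abs(dm[keep])))
})

test_that("chain states stay valid and consistent with their traces", {
  cfg <- simulationConfig(c(F = 5L, S = 5L, A = 5L), seed = 6)
  sim <- demeflow:::simulateDataset(cfg)
  td <- demeflow:::tipDemesFor(sim$alignment, sim$demeMap, c("F", "S", "A"))
  mod <- demeflow:::empiricalModel(td$aln)
  cp <- demeflow:::compressAlignment(td$aln)
  ctx <- demeflow:::likContext(cp$patterns, cp$weights, mod)
  mom <- momentEstimates(sim$alignment, sim$demeMap, c("F", "S", "A"))
  set.seed(7)
  run <- demeflow:::runChain(td$tipDeme, c("F", "S", "A"), ctx, mom$theta,
                             mom$M, nIter = 800, burnin = 200, thin = 10)
  st <- run$state
  g <- demeflow:::genealogyFromState(st, rownames(td$aln), c("F", "S", "A"))
  expect_true(isTRUE(validObject(g, test = TRUE)))
  ll <- demeflow:::prunedLoglik(st$parent, st$time, cp$patterns, cp$weights,
                                mod)
  expect_equal(ll, tail(run$loglik, 1), tolerance = 1e-6)
  s <- genealogyStats(g)
  expect_equal(as.numeric(tail(run$stats, 1)),
               c(s$coal, s$pairTime, s$lineageTime, as.vector(t(s$migrations))),
               tolerance = 1e-8)
})

test_that("the likelihood is symmetric under deme relabeling", {
  cfg <- simulationConfig(c(F = 2L, S = 2L, A = 2L), migrationRate = 20,
                          locusLength = 200L, seed = 9)
  sim <- demeflow:::simulateDataset(cfg)
  theta <- rep(0.01, 3)
  M <- matrix(15, 3, 3); diag(M) <- 0 # fully symmetric parameters
  dm2 <- sim$demeMap
  dm2$deme <- c(F = "S", S = "A", A = "F")[dm2$deme]
  e1 <- replicate(3, simplify = FALSE, estimateLoglik(
    sim$alignment, sim$demeMap, theta, M, demeLabels = c("F", "S", "A"),
    model = substModel("JC"), nsim = 800,
    seed = sample.int(1e6, 1)))
  e2 <- replicate(3, simplify = FALSE, estimateLoglik(
    sim$alignment, dm2, theta, M, demeLabels = c("F", "S", "A"),
    model = substModel("JC"), nsim = 800,
    seed = sample.int(1e6, 1)))
  m1 <- vapply(e1, function(x) x$logLik, 1)
  m2 <- vapply(e2, function(x) x$logLik, 1)
  spread <- sd(c(m1 - mean(m1), m2 - mean(m2)))
  expect_lt(abs(mean(m1) - mean(m2)), 4 * spread / sqrt(3) + 1)
})

test_that("the true parameters dominate a ten-fold theta perturbation", {
  wins <- 0L
  for (r in 1:10) {
    cfg <- simulationConfig(c(F = 10L, S = 10L, A = 10L), theta = 0.01,
                            migrationRate = 100, seed = 40 + r)
    sim <- demeflow:::simulateDataset(cfg)
    mod <- substModel("HKY", kappa = 4, freqs = c(0.25, 0.15, 0.2, 0.4))
    eTrue <- estimateLoglik(sim$alignment, sim$demeMap, cfg@theta,
                            cfg@migrationRates, demeLabels = c("F", "S", "A"),
                            model = mod, nsim = 150, seed = 100 + r)
    ePert <- estimateLoglik(sim$alignment, sim$demeMap, cfg@theta * 10,
                            cfg@migrationRates, demeLabels = c("F", "S", "A"),
                            model = mod, nsim = 150, seed = 200 + r)
    if (eTrue$logLik > ePert$logLik) wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})

test_that("fits respect the scenario constraints and the AIC identity", {
  cfg <- simulationConfig(c(F = 8L, S = 8L, A = 8L), locusLength = 300L,
                          seed = 12)
  sim <- demeflow:::simulateDataset(cfg)
  sc <- enumerateScenarios()[["S>A>F"]]
  st <- fitSettings(nIter = 600, burnin = 200, drivingIters = 1,
                    ssRungs = 6, ssIters = 150, ssBurnin = 50, seed = 3)
  fit <- fitScenario(sim$alignment, sim$demeMap, sc, settings = st)
  expect_identical(fit@migrationRates[!sc@mask], rep(0, 7))
  expect_true(all(fit@migrationRates[sc@mask] > 0))
  expect_true(all(fit@theta > 0))
  expect_lt(abs(fit@aic - (2 * fit@k - 2 * fit@logLik)), 1e-9)
  # seeded determinism
  fit2 <- fitScenario(sim$alignment, sim$demeMap, sc, settings = st)
  expect_identical(fit@logLik, fit2@logLik)
  expect_identical(fit@theta, fit2@theta)
})

test_that("the full model is not beaten by a nested scenario", {
  cfg <- simulationConfig(c(F = 6L, S = 6L, A = 6L), locusLength = 300L,
                          seed = 21)
  sim <- demeflow:::simulateDataset(cfg)
  sc <- enumerateScenarios()
  st <- fitSettings(nIter = 1000, burnin = 300, drivingIters = 1,
                    ssRungs = 8, ssIters = 250, ssBurnin = 80,
                    bridgeRungs = 6, bridgeIters = 300, seed = 5)
  res <- fitAllScenarios(sim$alignment, sim$demeMap,
                         scenarios = sc[c("S>A>F", "full model")],
                         settings = st)
  full <- res$fits[["full model"]]
  con <- res$fits[["S>A>F"]]
  ## 2 reported MC errors plus an allowance for the (unreported) annealing
  ## error of the bridge estimate
  tol <- 2 * sqrt(full@logLikSE^2 + con@logLikSE^2) + 4
  expect_gte(full@logLik, con@logLik - tol)
})

test_that("theta is recovered within a factor of two at the median", {
  est <- numeric(6)
  for (r in 1:6) {
    cfg <- simulationConfig(c(F = 10L, S = 10L, A = 10L), theta = 0.01,
                            migrationRate = 100, locusLength = 400L,
                            seed = 60 + r)
    sim <- demeflow:::simulateDataset(cfg)
    st <- fitSettings(nIter = 800, burnin = 250, drivingIters = 1,
                      anchor = "none", seed = 70 + r)
    fc <- demeflow:::fitContext(sim$alignment, sim$demeMap, c("F", "S", "A"),
                                st)
    set.seed(st$seed)
    pars <- demeflow:::fitScenarioParams(fc, cfg@scenario, st)
    est[r] <- mean(pars$theta)
  }
  expect_lt(abs(log(median(est) / 0.01)), log(2))
})
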