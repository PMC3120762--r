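#' Scenario-recovery experiment
#'
#' Generates replicate datasets under the sequential-colonization scenario
#' with origin in the middle deme (forward S>A then A>F on the default
#' labels), fits all nine constrained colonization hypotheses on each, and
#' reports how often the generating scenario attains the minimum AIC, as
#' well as the replicate-summed AIC per scenario. Log-likelihoods are
#' computed relative to the full model on each dataset (the absolute anchor
#' is a shared constant that cannot change the ranking), so AIC values are
#' comparable within but not across replicates.
#'
#' @param nrep number of replicate datasets.
#' @param seed root seed; replicate r uses seed + r for its dataset and fits.
#' @param sampleSizes,theta,migrationRate,locusLength,growth generating
#'   conditions (defaults: 20 sequences per deme, theta 0.01 per site,
#'   backward rate 300 on each colonization route, 600 bp, and a recent
#'   ten-fold expansion -- strong directional colonization, the regime in
#'   which the colonization order is identifiable; see the methods
#'   vignette).
#' @param settings sampler settings; the default is a reduced budget sized
#'   for a 9 x nrep fit campaign.
#' @param verbose print one line per replicate.
#' @return list: \code{winners} (character per replicate), \code{recovery}
#'   (fraction of replicates won by the true scenario), \code{summedAIC}
#'   (named vector), \code{trueScenario}, \code{tables} (per-replicate
#'   ranked tables).
#' @export
modelRecoveryExperiment <- function(nrep = 20L, seed = 1L,
                                    sampleSizes = c(F = 20L, S = 20L, A = 20L),
                                    theta = 0.01, migrationRate = 300,
                                    locusLength = 600L,
                                    growth = list(onset = 3.424e-4,
                                                  ratio = 0.1),
                                    settings = fitSettings(
                                      nIter = 1500L, burnin = 400L,
                                      drivingIters = 1L, bridgeRungs = 6L,
                                      bridgeIters = 350L, anchor = "none"),
                                    verbose = FALSE) {
  scenarios <- enumerateScenarios(names(sampleSizes))
  constrained <- scenarios[vapply(scenarios, function(s) s@name, "") != "full model"]
  trueName <- scenarios[[which(vapply(scenarios, function(s)
    identical(s@origin, names(sampleSizes)[2]) && nrow(s@edges) == 2 &&
      s@edges[1, 2] == s@edges[2, 1], TRUE))[1]]]@name
  winners <- character(nrep)
  tables <- vector("list", nrep)
  summed <- NULL
  for (r in seq_len(nrep)) {
    cfg <- simulationConfig(sampleSizes = sampleSizes, theta = theta,
                            migrationRate = migrationRate,
                            locusLength = locusLength, growth = growth,
                            seed = seed + r)
    sim <- simulateDataset(cfg)
    st <- settings
    st$seed <- seed + 1000L * r
    res <- fitAllScenarios(sim$alignment, sim$demeMap,
                           scenarios = constrained, settings = st)
    tab <- res$table
    tables[[r]] <- tab
    winners[r] <- tab$scenario[tab$rank == 1][1]
    a <- stats::setNames(tab$aic, tab$scenario)[names(constrained)]
    summed <- if (is.null(summed)) a else summed + a
    if (verbose)
      message(sprintf("replicate %d: best = %s", r, winners[r]))
  }
  list(winners = winners, recovery = mean(winners == trueName),
       summedAIC = summed, trueScenario = trueName, tables = tables)
}

#' Expansion-onset coverage experiment
#'
#' Simulates replicate single-population datasets that underwent a ten-fold
#' expansion at a known onset time, runs the coalescent skyline analysis on
#' each at a reduced chain length, and checks how often the 95% credible
#' interval of the expansion onset covers the true time.
#'
#' @param nrep number of replicates.
#' @param seed root seed.
#' @param n,locusLength,theta,onset,ratio generating conditions (defaults:
#'   60 sequences, 604 bp, present-day theta 0.01 per site, onset 3.424e-4
#'   substitutions per site -- 8000 years at the default clock -- and
#'   ancestral/present ratio 0.1).
#' @param clock a \linkS4class{ClockModel}.
#' @param settings skyline MCMC settings (reduced default).
#' @param gtrFit logical; when FALSE (default) the replicates use the
#'   simulation substitution model directly instead of re-estimating
#'   nuisance parameters, saving time.
#' @return list: \code{covered} (logical per replicate), \code{coverage},
#'   \code{onsets} (3 x nrep summary matrix), \code{trueOnsetYears}.
#' @export
expansionCoverageExperiment <- function(nrep = 20L, seed = 1L, n = 60L,
                                        locusLength = 604L, theta = 0.01,
                                        onset = 3.424e-4, ratio = 0.1,
                                        clock = clockModel(),
                                        settings = skylineSettings(
                                          nIter = 4500L, burnin = 1200L,
                                          thin = 4L),
                                        gtrFit = FALSE) {
  trueYears <- timeToYears(onset, clock)
  covered <- logical(nrep)
  onsets <- matrix(NA_real_, 3, nrep,
                   dimnames = list(c("median", "lower", "upper"), NULL))
  simModel <- substModel("HKY", kappa = 4, freqs = c(0.25, 0.15, 0.2, 0.4))
  for (r in seq_len(nrep)) {
    d <- simulateExpansionDataset(n = n, locusLength = locusLength,
                                  theta = theta, onset = onset,
                                  ratio = ratio, mutModel = simModel,
                                  seed = seed + r)
    model <- if (gtrFit) NULL else simModel
    post <- skylineMcmc(d$alignment, clock = clock, settings = settings,
                        model = model, seed = seed + 5000L + r)
    onsets[, r] <- post@onsetSummary
    covered[r] <- !anyNA(post@onsetSummary) &&
      post@onsetSummary["lower"] <= trueYears &&
      post@onsetSummary["upper"] >= trueYears
  }
  list(covered = covered, coverage = mean(covered), onsets = onsets,
       trueOnsetYears = trueYears)
}
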