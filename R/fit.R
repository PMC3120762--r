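logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## Map a deme-map data.frame + alignment to integer tip demes ordered like
## the alignment.
tipDemesFor <- function(alignment, demeMap, demeLabels = NULL) {
  aln <- asAlignmentMatrix(alignment)
  missing <- setdiff(rownames(aln), demeMap$sample_id)
  if (length(missing))
    stop("sequence id(s) missing from deme map: ",
         paste(missing, collapse = ", "))
  dm <- stats::setNames(demeMap$deme, demeMap$sample_id)[rownames(aln)]
  if (is.null(demeLabels)) demeLabels <- unique(demeMap$deme)
  idx <- match(dm, demeLabels)
  if (anyNA(idx)) stop("deme(s) not in demeLabels: ",
                       paste(unique(dm[is.na(idx)]), collapse = ", "))
  list(aln = aln, tipDeme = idx, demeLabels = demeLabels)
}

#' Default sampler settings for migration-rate inference
#'
#' Run budgets of the genealogy sampler and likelihood estimator. Defaults
#' are sized for datasets of a few dozen sequences; raise the budgets for
#' final analyses.
#'
#' @param nIter MH iterations per driving round.
#' @param burnin discarded initial iterations.
#' @param thin retain every \code{thin}-th state.
#' @param drivingIters rounds of (sample at driving values, re-optimize,
#'   recentre) before the final likelihood evaluation.
#' @param ssRungs,ssIters,ssBurnin stepping-stone ladder size and per-rung
#'   chain budget of the absolute log-likelihood anchor.
#' @param bridgeRungs,bridgeIters ladder size and per-rung budget of the
#'   scenario-to-full-model bridge used by \code{\link{fitAllScenarios}}.
#' @param kappa HKY transition/transversion ratio of the inference model.
#' @param seed integer seed.
#' @param essFloor minimum importance effective sample size before a fit is
#'   flagged non-converged.
#' @return list of settings.
#' @export
fitSettings <- function(nIter = 2000L, burnin = 500L, thin = 5L,
                        drivingIters = 2L,
                        ssRungs = 12L, ssIters = 400L, ssBurnin = 100L,
                        bridgeRungs = 6L, bridgeIters = 400L,
                        anchor = c("steppingstone", "none"),
                        kappa = 4, seed = 1L, essFloor = 10) {
  list(nIter = as.integer(nIter), burnin = as.integer(burnin),
       thin = as.integer(thin), drivingIters = as.integer(drivingIters),
       ssRungs = as.integer(ssRungs), ssIters = as.integer(ssIters),
       ssBurnin = as.integer(ssBurnin),
       bridgeRungs = as.integer(bridgeRungs),
       bridgeIters = as.integer(bridgeIters),
       anchor = match.arg(anchor),
       kappa = kappa, seed = as.integer(seed), essFloor = essFloor)
}

## HKY model with empirical base composition of the data.
empiricalModel <- function(aln, kappa = 4) {
  tab <- table(factor(as.vector(aln), levels = BASES))
  f <- as.numeric(tab) + 1
  substModel("HKY", kappa = kappa, freqs = f / sum(f))
}

#' Moment (F_ST-style) starting values for theta and migration rates
#'
#' Per-deme theta from within-deme nucleotide diversity; pairwise backward
#' migration rates from Hudson-style F_ST = 1 - Hw/Hb via the island-model
#' relation Nm = (1/F_ST - 1)/2, divided by the mean theta of the pair.
#' Degenerate cases (monomorphic demes, F_ST <= 0) fall back to documented
#' defaults (theta 0.005, M 20); rates are clamped to [1, 5000].
#'
#' @param alignment named character vector or matrix.
#' @param demeMap deme map data.frame.
#' @param demeLabels ordered deme labels.
#' @return list with \code{theta} (per deme) and \code{M} (matrix).
#' @export
momentEstimates <- function(alignment, demeMap, demeLabels) {
  td <- tipDemesFor(alignment, demeMap, demeLabels)
  idx <- matrix(match(toupper(td$aln), BASES, nomatch = 0L), nrow(td$aln))
  L <- ncol(idx)
  nd <- length(demeLabels)
  pdist <- function(rows) { # mean pairwise difference per site
    if (length(rows) < 2) return(NA_real_)
    tot <- 0; np <- 0
    for (i in seq_along(rows)[-length(rows)])
      for (j in (i + 1):length(rows)) {
        ok <- idx[rows[i], ] > 0 & idx[rows[j], ] > 0
        tot <- tot + sum(idx[rows[i], ok] != idx[rows[j], ok])
        np <- np + 1
      }
    tot / np / L
  }
  xdist <- function(r1, r2) {
    tot <- 0
    for (i in r1) for (j in r2) {
      ok <- idx[i, ] > 0 & idx[j, ] > 0
      tot <- tot + sum(idx[i, ok] != idx[j, ok])
    }
    tot / (length(r1) * length(r2)) / L
  }
  rows <- split(seq_len(nrow(idx)), td$tipDeme)
  piW <- vapply(as.character(seq_len(nd)), function(d)
    if (!is.null(rows[[d]])) pdist(rows[[d]]) else NA_real_, 0)
  theta <- ifelse(is.na(piW) | piW <= 0, 0.005, piW)
  M <- matrix(0, nd, nd, dimnames = list(demeLabels, demeLabels))
  for (i in seq_len(nd - 1)) for (j in (i + 1):nd) {
    ri <- rows[[as.character(i)]]; rj <- rows[[as.character(j)]]
    m <- 20
    if (!is.null(ri) && !is.null(rj)) {
      hb <- xdist(ri, rj)
      hw <- mean(c(piW[i], piW[j]), na.rm = TRUE)
      if (is.finite(hb) && hb > 0 && is.finite(hw)) {
        fst <- max(1 - hw / hb, 0.01)
        m <- (1 / fst - 1) / 2 / mean(theta[c(i, j)])
      }
    }
    M[i, j] <- M[j, i] <- min(max(m, 1), 5000)
  }
  list(theta = theta, M = M)
}

#' Monte-Carlo structured-coalescent log-likelihood
#'
#' Unbiased importance-sampling estimate of the probability of the alignment
#' integrated over genealogies and migration histories: genealogies are
#' drawn from the structured coalescent at the given parameters and the
#' Felsenstein likelihood of the data is averaged over the draws. Returns
#' the log estimate with its delta-method Monte-Carlo standard error and the
#' importance effective sample size.
#'
#' @param alignment named character vector or matrix.
#' @param demeMap deme map data.frame.
#' @param theta per-deme scaled population sizes.
#' @param M backward migration-rate matrix (masked entries 0).
#' @param demeLabels ordered deme labels (default from the map).
#' @param model substitution model; default HKY with empirical base
#'   composition.
#' @param nsim number of genealogy draws.
#' @param seed integer seed.
#' @return list: \code{logLik}, \code{se}, \code{ess}, \code{nsim}.
#' @export
estimateLoglik <- function(alignment, demeMap, theta, M, demeLabels = NULL,
                           model = NULL, nsim = 500L, seed = 1L) {
  td <- tipDemesFor(alignment, demeMap, demeLabels)
  if (is.null(model)) model <- empiricalModel(td$aln)
  cp <- compressAlignment(td$aln)
  ctx <- likContext(cp$patterns, cp$weights, model)
  set.seed(as.integer(seed))
  ll <- numeric(nsim)
  for (i in seq_len(nsim)) {
    g <- simCoalescent(rownames(td$aln), td$tipDeme, td$demeLabels, theta, M)
    ll[i] <- if (length(g@parent) == 1L)
      pruningLoglik(g, td$aln, model)
    else prunedLoglik(g@parent, g@time, cp$patterns, cp$weights, model,
                      ctx = ctx)
  }
  m <- max(ll)
  w <- exp(ll - m)
  est <- m + log(mean(w))
  se <- stats::sd(w) / sqrt(nsim) / mean(w)
  list(logLik = est, se = se, ess = sum(w)^2 / sum(w^2), nsim = nsim)
}

## Optimize the importance-ratio likelihood surface over the free
## parameters of a scenario given a matrix of retained sufficient
## statistics sampled at driving values. Works on log-parameters with a
## +/- log(50) trust region around the driving values.
optimizeRatio <- function(stats, scenario, theta0, M0) {
  free <- which(t(scenario@mask)) # row-major free rate positions
  nd <- length(theta0)
  pack <- function(theta, M) c(log(theta), log(t(M))[free])
  unpack <- function(phi) {
    theta <- exp(phi[seq_len(nd)])
    tM <- t(matrix(0, nd, nd))
    tM[free] <- exp(phi[-seq_len(nd)])
    list(theta = theta, M = t(tM))
  }
  phi0 <- pack(theta0, M0)
  base <- statsLogDens(stats, theta0, M0)
  obj <- function(phi) {
    if (any(abs(phi - phi0) > log(50))) return(1e10)
    pp <- unpack(phi)
    d <- statsLogDens(stats, pp$theta, pp$M)
    -(logSumExp(d - base) - log(length(d)))
  }
  fit <- stats::optim(phi0, obj, method = "Nelder-Mead",
                      control = list(maxit = 600, reltol = 1e-7))
  pp <- unpack(fit$par)
  d <- statsLogDens(stats, pp$theta, pp$M) - base
  w <- exp(d - max(d))
  list(theta = pp$theta, M = pp$M, logRatio = -fit$value,
       ess = sum(w)^2 / sum(w^2), converged = fit$convergence == 0L)
}

## Shared per-dataset fitting context.
fitContext <- function(alignment, demeMap, demeLabels, settings) {
  td <- tipDemesFor(alignment, demeMap, demeLabels)
  if (nrow(td$aln) < 2) stop("at least 2 sequences are required")
  model <- empiricalModel(td$aln, settings$kappa)
  cp <- compressAlignment(td$aln)
  ctx <- likContext(cp$patterns, cp$weights, model)
  mom <- momentEstimates(alignment, demeMap, demeLabels)
  list(td = td, model = model, ctx = ctx, mom = mom)
}

## Maximum-likelihood parameters of one scenario: MH sampling at driving
## values, importance-ratio maximization over the free parameters,
## re-centred over drivingIters rounds.
fitScenarioParams <- function(fc, scenario, settings) {
  sampled <- tabulate(fc$td$tipDeme, length(fc$td$demeLabels)) > 0
  if (!scenarioConnected(scenario@mask, sampled))
    stop("non-coalescible configuration: scenario '", scenario@name,
         "' cannot bring the sampled demes together")
  theta <- fc$mom$theta
  M <- fc$mom$M * scenario@mask
  accs <- numeric(0); ess <- NA_real_; conv <- TRUE
  init <- NULL
  for (round in seq_len(settings$drivingIters)) {
    run <- runChain(fc$td$tipDeme, fc$td$demeLabels, fc$ctx, theta, M,
                    settings$nIter, settings$burnin, settings$thin,
                    init = init)
    init <- run$state
    accs <- c(accs, run$acceptance)
    opt <- optimizeRatio(run$stats, scenario, theta, M)
    theta <- opt$theta
    M <- opt$M
    ess <- opt$ess
    conv <- conv && opt$converged
  }
  list(theta = theta, M = M, acceptance = accs, ess = ess,
       converged = conv, state = init)
}

makeFitResult <- function(scenario, pars, logLik, se, settings) {
  flagged <- !pars$converged || is.na(pars$ess) ||
    pars$ess < settings$essFloor
  new("FitResult", scenario = scenario@name, theta = pars$theta,
      migrationRates = pars$M, logLik = logLik, logLikSE = se,
      k = scenario@k, aic = aic(logLik, scenario@k),
      diagnostics = list(acceptance = pars$acceptance,
                         importanceESS = pars$ess, converged = !flagged))
}

#' Fit one colonization scenario by maximum likelihood
#'
#' Estimates the per-deme theta and the scenario's free backward migration
#' rates by the migrate-style two-stage scheme: genealogies with migration
#' histories are sampled by Metropolis-Hastings at driving values (initial
#' values from \code{\link{momentEstimates}}, masked to the scenario), the
#' likelihood ratio to the driving values is maximized over the free
#' parameters via importance weighting, and the procedure is re-centred for
#' \code{drivingIters} rounds. The reported log-likelihood at the optimum is
#' then computed by stepping-stone sampling from the structured-coalescent
#' prior (see \code{\link{fitSettings}}).
#'
#' Log-likelihoods are comparable between scenarios only when estimated
#' with the same budget and seed on the same data;
#' \code{\link{fitAllScenarios}} arranges this and additionally uses
#' common-path bridge estimates between each scenario and the full model,
#' which removes most of the shared Monte-Carlo error from the AIC ranking.
#'
#' @param alignment named character vector or matrix.
#' @param demeMap deme map data.frame.
#' @param scenario a \linkS4class{MigrationScenario}.
#' @param settings see \code{\link{fitSettings}}.
#' @param anchorSeed seed of the final likelihood evaluation; share it
#'   across scenarios fitted on the same data.
#' @return a \linkS4class{FitResult}.
#' @export
fitScenario <- function(alignment, demeMap, scenario,
                        settings = fitSettings(),
                        anchorSeed = settings$seed + 777L) {
  fc <- fitContext(alignment, demeMap, scenario@demeLabels, settings)
  set.seed(settings$seed)
  pars <- fitScenarioParams(fc, scenario, settings)
  set.seed(anchorSeed)
  anchor <- ssLogLik(fc$td$tipDeme, fc$td$demeLabels, fc$ctx, pars$theta,
                     pars$M, rungs = settings$ssRungs,
                     itersPerRung = settings$ssIters,
                     burninPerRung = settings$ssBurnin)
  makeFitResult(scenario, pars, anchor$logLik, anchor$se, settings)
}

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult '%s': LnL = %.2f (MC se %.2f), k = %d, AIC = %.2f%s\n",
              object@scenario, object@logLik, object@logLikSE, object@k,
              object@aic,
              if (isTRUE(object@diagnostics$converged)) "" else "  [flagged]"))
  cat("  theta:", sprintf("%.4g", object@theta), "\n")
})

#' Fit all scenarios on one dataset and rank them by AIC
#'
#' Fits the unconstrained full model first and anchors its log-likelihood by
#' stepping-stone sampling from the structured-coalescent prior; every
#' constrained scenario is then fitted by the same driving scheme and its
#' log-likelihood difference to the full model is estimated along a short
#' geometric bridge between the two fitted priors (mirroring the practice of
#' obtaining comparable likelihoods from a final unconstrained run). This
#' keeps the scenario ranking free of most of the annealing error of the
#' absolute anchor, which is common to all scenarios.
#'
#' @inheritParams fitScenario
#' @param scenarios list of scenarios; default
#'   \code{enumerateScenarios()} on the demes of the map (9 constrained +
#'   full model).
#' @return list with \code{fits} (list of \linkS4class{FitResult}) and
#'   \code{table} (ranked data.frame from \code{\link{rankModels}}).
#' @export
fitAllScenarios <- function(alignment, demeMap, scenarios = NULL,
                            settings = fitSettings()) {
  if (is.null(scenarios)) {
    labs <- unique(demeMap$deme)
    scenarios <- enumerateScenarios(labs)
  }
  labs <- scenarios[[1]]@demeLabels
  fc <- fitContext(alignment, demeMap, labs, settings)
  full <- migrationScenario(labs, edges = NULL)
  set.seed(settings$seed)
  parsFull <- fitScenarioParams(fc, full, settings)
  if (settings$anchor == "steppingstone") {
    set.seed(settings$seed + 777L)
    anchor <- ssLogLik(fc$td$tipDeme, fc$td$demeLabels, fc$ctx,
                       parsFull$theta, parsFull$M, rungs = settings$ssRungs,
                       itersPerRung = settings$ssIters,
                       burninPerRung = settings$ssBurnin)
  } else {
    ## log-likelihoods reported relative to the full model (ranking and
    ## AIC differences are unaffected; the absolute level is not estimated)
    anchor <- list(logLik = 0, se = 0)
  }
  fits <- list()
  for (s in scenarios) {
    if (s@name == full@name) {
      fits[[s@name]] <- makeFitResult(s, parsFull, anchor$logLik, anchor$se,
                                      settings)
      next
    }
    set.seed(settings$seed + utf8Seed(s@name))
    pars <- fitScenarioParams(fc, s, settings)
    br <- bridgeDeltaLogLik(fc$td$tipDeme, fc$td$demeLabels, fc$ctx,
                            parsFull$theta, parsFull$M, pars$theta, pars$M,
                            rungs = settings$bridgeRungs,
                            itersPerRung = settings$bridgeIters,
                            init = parsFull$state)
    fits[[s@name]] <- makeFitResult(s, pars, anchor$logLik + br$delta,
                                    sqrt(anchor$se^2 + br$se^2), settings)
  }
  tab <- data.frame(
    scenario = vapply(fits, function(f) f@scenario, ""),
    k = vapply(fits, function(f) f@k, 1L),
    logLik = vapply(fits, function(f) f@logLik, 1),
    stringsAsFactors = FALSE)
  list(fits = fits, table = rankModels(tab))
}

utf8Seed <- function(x) sum(utf8ToInt(x) * seq_len(nchar(x))) %% 10000L
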