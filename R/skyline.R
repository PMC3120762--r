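#' Strict molecular clock constructor
#'
#' @param rate substitution rate in changes per site per year (default
#'   4.28e-8, a rate estimated for an intraspecific land-snail COI lineage).
#' @return a \linkS4class{ClockModel}.
#' @export
clockModel <- function(rate = 4.28e-8) new("ClockModel", rate = rate)

setMethod("show", "ClockModel", function(object)
  cat(sprintf("ClockModel: %.3g substitutions/site/year\n", object@rate)))

#' Convert a tree height to years via the strict clock
#'
#' @param height height in expected substitutions per site.
#' @param clock a \linkS4class{ClockModel} (or a bare rate).
#' @return height / rate, in years.
#' @examples
#' timeToYears(3.424e-4, clockModel(4.28e-8)) # 8000 years
#' @export
timeToYears <- function(height, clock = clockModel()) {
  rate <- if (is(clock, "ClockModel")) clock@rate else as.numeric(clock)
  if (!is.finite(rate) || rate <= 0) stop("clock rate must be positive")
  stopifnot(all(height >= 0))
  height / rate
}

#' Skyline prior constructor
#'
#' Priors of the piecewise-linear coalescent skyline: a truncated Poisson
#' prior on the number of population-size change points (mean 2 by default,
#' reflecting an expectation of two expansion events) and a bounded prior on
#' effective population sizes between 1e4 and 1e12 individuals. The default
#' size prior is log-uniform on those bounds, which makes posterior time
#' summaries rescale exactly when the clock rate changes;
#' \code{sizePrior = "uniform"} matches a flat prior on the natural scale
#' instead.
#'
#' @param changePointPriorMean Poisson mean of the change-point count.
#' @param maxChangePoints truncation of the change-point count.
#' @param sizeBounds lower/upper population-size bounds (individuals).
#' @param sizePrior \code{"loguniform"} or \code{"uniform"}.
#' @return a \linkS4class{SkylinePriors}.
#' @export
skylinePriors <- function(changePointPriorMean = 2, maxChangePoints = 4L,
                          sizeBounds = c(1e4, 1e12),
                          sizePrior = "loguniform") {
  new("SkylinePriors", changePointPriorMean = changePointPriorMean,
      maxChangePoints = as.integer(maxChangePoints),
      sizeBounds = sizeBounds, sizePrior = sizePrior)
}

#' MCMC settings for the skyline sampler
#'
#' @param nIter total iterations.
#' @param burnin discarded iterations.
#' @param thin retain every \code{thin}-th iteration.
#' @param essFloor minimum effective sample size of the log-likelihood and
#'   root-height traces before the run is flagged non-converged.
#' @param maxTrajectories cap on stored trajectory samples.
#' @return list of settings.
#' @export
skylineSettings <- function(nIter = 6000L, burnin = 1500L, thin = 5L,
                            essFloor = 50, maxTrajectories = 200L) {
  list(nIter = as.integer(nIter), burnin = as.integer(burnin),
       thin = as.integer(thin), essFloor = essFloor,
       maxTrajectories = as.integer(maxTrajectories))
}

## ---- internal machinery ---------------------------------------------------

## UPGMA starting tree (parent/time in substitutions per site) from
## JC-corrected distances.
upgmaStartTree <- function(aln) {
  n <- nrow(aln)
  idx <- matrix(match(toupper(aln), BASES, nomatch = 0L), n)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- idx[i, ] > 0 & idx[j, ] > 0
    p <- sum(idx[i, ok] != idx[j, ok]) / sum(ok)
    p <- min(p, 0.70)
    d[i, j] <- d[j, i] <- -3 / 4 * log(1 - 4 * p / 3)
  }
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  nnode <- 2L * n - 1L
  parent <- integer(nnode)
  time <- numeric(nnode)
  rootH <- max(hc$height / 2, 1e-6)
  ## spread zero-height merges (identical haplotypes) over the recent half
  ## of the tree: a start state with all-instant coalescences sits in a
  ## degenerate small-size mode the sampler escapes only slowly
  floorH <- 0.5 * rootH * seq_len(n - 1L) / (n - 1L)
  for (m in seq_len(n - 1L)) {
    v <- n + m
    time[v] <- max(hc$height[m] / 2, floorH[m], max(time) * 1.0001)
    for (side in 1:2) {
      ch <- hc$merge[m, side]
      ch <- if (ch < 0) -ch else n + ch
      parent[ch] <- v
    }
  }
  list(parent = parent, time = time)
}

## Ne(t) of a piecewise-linear trajectory: points (0, N[1]), (s[k], N[k+1]),
## constant beyond the last change point.
trajectoryAt <- function(t, s, N) {
  ts <- c(0, s)
  i <- findInterval(t, ts)
  out <- numeric(length(t))
  K <- length(s)
  last <- i > K
  out[last] <- N[K + 1]
  m <- !last
  if (any(m)) {
    a <- ts[i[m]]; b <- ts[i[m] + 1]
    out[m] <- N[i[m]] + (N[i[m] + 1] - N[i[m]]) * (t[m] - a) / (b - a)
  }
  out
}

## integral of 1/Ne over [a, b] for one linear segment from (ta, Na) to
## (tb, Nb) with [a, b] inside [ta, tb].
segIntegral <- function(a, b, ta, tb, Na, Nb) {
  if (b <= a) return(0)
  if (Na == Nb || tb == ta) return((b - a) / Na)
  slope <- (Nb - Na) / (tb - ta)
  (log(Na + slope * (b - ta)) - log(Na + slope * (a - ta))) / slope
}

## Coalescent log density of an ultrametric tree (times in years) under the
## piecewise-linear trajectory; pairwise rate 1/Ne(t) per year.
logCoalDensity <- function(parent, time, s, N, ntip) {
  coalT <- sort(time[time > 0])
  H <- max(coalT)
  grid <- sort(unique(c(0, coalT, s[s < H], H)))
  k <- ntip
  lp <- 0
  ts <- c(0, s, Inf)
  Ns <- c(N, N[length(N)])
  for (i in seq_len(length(grid) - 1)) {
    a <- grid[i]; b <- grid[i + 1]
    seg <- findInterval(a, ts)
    I <- segIntegral(a, b, ts[seg], min(ts[seg + 1], 1e300),
                     Ns[seg], Ns[seg + 1])
    lp <- lp - k * (k - 1) / 2 * I
    if (b %in% coalT) {
      lp <- lp - log(trajectoryAt(b, s, N))
      k <- k - sum(coalT == b)
    }
  }
  lp
}

## Size prior on the rate-scaled sizes nu = N * clockRate; bounds are the
## Ne bounds times the clock rate. Density ratios are scale-free for the
## default log-uniform prior, which is what makes posterior time summaries
## rescale exactly under a clock-rate change.
logSizePrior <- function(nu, priors, rate) {
  lo <- priors@sizeBounds[1] * rate; hi <- priors@sizeBounds[2] * rate
  if (any(nu < lo | nu > hi)) return(-Inf)
  if (priors@sizePrior == "loguniform")
    sum(-log(nu) - log(log(priors@sizeBounds[2] / priors@sizeBounds[1])))
  else sum(-log(hi - lo))
}

logKPrior <- function(K, priors) {
  lam <- priors@changePointPriorMean
  ks <- 0:priors@maxChangePoints
  stats::dpois(K, lam, log = TRUE) - log(sum(stats::dpois(ks, lam)))
}

## Full log posterior (likelihood handled separately for power tempering).
## All state components live in substitution units: node times and change
## times in substitutions per site, sizes as nu = Ne * clockRate.
skylineLogPrior <- function(state, priors, ntip, rate) {
  H <- max(state$time)
  K <- length(state$s)
  if (K && (any(state$s <= 0) || any(state$s >= H) ||
            is.unsorted(state$s, strictly = TRUE))) return(-Inf)
  sp <- logSizePrior(state$N, priors, rate)
  if (!is.finite(sp)) return(-Inf)
  lt <- if (K) lgamma(K + 1) - K * log(H) else 0
  logCoalDensity(state$parent, state$time, state$s, state$N, ntip) +
    sp + lt + logKPrior(K, priors)
}

skylineLoglik <- function(state, ctx, rate) {
  prunedLoglik(state$parent, state$time, ctx$patterns, ctx$weights,
               ctx$model, rateScale = 1, ctx = ctx)
}

## One MCMC sweep. Returns the updated (state, ll, lp). `power` tempers the
## data likelihood (stepping-stone); w is the log-window of size proposals.
skylineMove <- function(state, ll, lp, ctx, rate, priors, ntip, power = 1,
                        w = log(50), fixedK = FALSE) {
  ## state in substitution units; `rate` enters only the size-prior bounds
  nnode <- length(state$parent)
  root <- which(state$parent == 0L)
  K <- length(state$s)
  maxK <- priors@maxChangePoints
  move <- sample.int(8L, 1L, prob = c(0.22, 0.08, 0.15, 0.20, 0.08,
                                      0.06, 0.06, 0.15))
  if (fixedK && move %in% c(6L, 7L))
    return(list(state = state, ll = ll, lp = lp))
  prop <- state
  logq <- 0
  if (move == 1L) { # slide one internal node height
    ints <- setdiff((ntip + 1L):nnode, root)
    if (length(ints)) {
      v <- if (length(ints) == 1L) ints else sample(ints, 1L)
      lo <- max(state$time[state$parent == v])
      hi <- state$time[state$parent[v]]
      prop$time[v] <- lo + runif(1) * (hi - lo)
    }
  } else if (move == 2L) { # scale all internal heights
    f <- exp(runif(1, -0.3, 0.3))
    prop$time[(ntip + 1L):nnode] <- state$time[(ntip + 1L):nnode] * f
    logq <- (nnode - ntip) * log(f)
  } else if (move == 3L) { # narrow exchange
    cand <- setdiff((ntip + 1L):nnode, root)
    if (length(cand)) {
      v <- if (length(cand) == 1L) cand else sample(cand, 1L)
      p <- state$parent[v]
      sib <- setdiff(which(state$parent == p), v)
      kids <- which(state$parent == v)
      c1 <- kids[sample.int(2L, 1L)]
      if (state$time[sib] < state$time[v]) {
        prop$parent[c1] <- p
        prop$parent[sib] <- v
      }
    }
  } else if (move == 4L) { # resize one trajectory point
    j <- sample.int(K + 1L, 1L)
    prop$N[j] <- state$N[j] * exp(runif(1, -1, 1))
  } else if (move == 5L) { # slide one change time
    if (K) {
      k <- sample.int(K, 1L)
      lo <- if (k == 1L) 0 else state$s[k - 1L]
      hi <- if (k == K) max(state$time) else state$s[k + 1L]
      prop$s[k] <- lo + runif(1) * (hi - lo)
    }
  } else if (move == 6L) { # birth of a change point
    if (K < maxK) {
      H <- max(state$time)
      snew <- runif(1) * H
      Nbase <- trajectoryAt(snew, state$s, state$N)
      Nnew <- Nbase * exp(runif(1, -w, w))
      pos <- findInterval(snew, state$s)
      prop$s <- append(state$s, snew, after = pos)
      prop$N <- append(state$N, Nnew, after = pos + 1L)
      ## q(birth) = 1/H * 1/(2 w Nnew); q(death) = 1/(K+1)
      logq <- log(H) + log(2 * w * Nnew) - log(K + 1)
    }
  } else if (move == 8L) { # joint scale of heights, sizes and change times
    f <- exp(runif(1, -0.25, 0.25))
    prop$time[(ntip + 1L):nnode] <- state$time[(ntip + 1L):nnode] * f
    prop$N <- state$N * f
    prop$s <- state$s * f
    logq <- (nnode - ntip + 2 * K + 1) * log(f)
  } else { # death of a change point
    if (K > 0L) {
      H <- max(state$time)
      k <- sample.int(K, 1L)
      Nold <- state$N[k + 1L]
      sold <- state$s[k]
      prop$s <- state$s[-k]
      prop$N <- state$N[-(k + 1L)]
      Nbase <- trajectoryAt(sold, prop$s, prop$N)
      if (abs(log(Nold / Nbase)) > w) return(list(state = state, ll = ll, lp = lp))
      logq <- log(K) - log(H) - log(2 * w * Nold)
    }
  }
  ## reject structurally invalid trees (child above parent)
  nr <- which(prop$parent > 0L)
  if (any(prop$time[prop$parent[nr]] < prop$time[nr]))
    return(list(state = state, ll = ll, lp = lp))
  lp2 <- skylineLogPrior(prop, priors, ntip, rate)
  if (!is.finite(lp2)) return(list(state = state, ll = ll, lp = lp))
  ll2 <- if (move %in% c(1L, 2L, 3L, 8L)) skylineLoglik(prop, ctx, rate)
         else ll
  if (!is.finite(ll2)) return(list(state = state, ll = ll, lp = lp))
  if (log(runif(1)) < power * (ll2 - ll) + lp2 - lp + logq)
    list(state = prop, ll = ll2, lp = lp2)
  else list(state = state, ll = ll, lp = lp)
}

## Expansion onset of one sample: the most recent change time among
## trajectories whose modern size exceeds the ancestral size >= 2-fold.
onsetOf <- function(state) {
  K <- length(state$s)
  if (K == 0L) return(NA_real_)
  if (state$N[1] / state$N[K + 1L] < 2) return(NA_real_)
  state$s[1]
}

## Initial-positive-sequence effective sample size.
essOf <- function(x) {
  n <- length(x)
  if (n < 10 || stats::sd(x) == 0) return(n)
  r <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  neg <- which(r < 0)
  if (length(neg)) r <- r[seq_len(neg[1] - 1)]
  max(1, n / (1 + 2 * sum(r)))
}

skylineInit <- function(aln, ctx, clockRate, priors) {
  tr <- upgmaStartTree(aln)
  n <- nrow(aln)
  idx <- matrix(match(toupper(aln), BASES, nomatch = 0L), n)
  pd <- 0; np <- 0
  for (i in seq_len(min(n - 1, 20))) {
    ok <- idx[i, ] > 0 & idx[i + 1, ] > 0
    pd <- pd + sum(idx[i, ok] != idx[i + 1, ok]) / max(sum(ok), 1)
    np <- np + 1
  }
  theta <- max(pd / np, 1 / ncol(aln))
  nu0 <- min(max(theta, priors@sizeBounds[1] * clockRate * 1.01),
             priors@sizeBounds[2] * clockRate * 0.99)
  H <- max(tr$time)
  list(parent = tr$parent, time = tr$time, s = H / 2, N = c(nu0, nu0))
}

## Init with exactly K change points (used by the fixed-K ladders).
skylineInitK <- function(aln, ctx, clockRate, priors, K) {
  st <- skylineInit(aln, ctx, clockRate, priors)
  H <- max(st$time)
  if (K == 0L) { st$s <- numeric(0); st$N <- st$N[1] }
  else { st$s <- H * seq_len(K) / (K + 1); st$N <- rep(st$N[1], K + 1) }
  st
}

## ---- user-facing operations ----------------------------------------------

#' Bayesian coalescent skyline analysis under a strict clock
#'
#' Samples the posterior of the genealogy and a piecewise-linear effective
#' population size trajectory with a Poisson-weighted number of change
#' points (reversible-jump birth/death moves over 0..maxChangePoints), under
#' a strict molecular clock. The substitution model defaults to GTR with
#' empirical base frequencies, four discrete gamma categories and invariant
#' sites; its nuisance parameters are plugged in by a quick ML fit
#' (empirical Bayes) when \pkg{phangorn} is available, else fixed defaults
#' are used. The MCMC starts from a UPGMA tree.
#'
#' Expansion onset is summarised as the most recent change-point time among
#' posterior trajectories whose modern size exceeds the ancestral size at
#' least two-fold, converted to years before present via the clock.
#'
#' @param alignment named character vector (or matrix) of aligned sequences.
#' @param clock a \linkS4class{ClockModel}.
#' @param priors a \linkS4class{SkylinePriors}.
#' @param settings see \code{\link{skylineSettings}}.
#' @param model optional \linkS4class{SubstModel} overriding the default.
#' @param seed integer seed.
#' @return a \linkS4class{SkylinePosterior}.
#' @export
skylineMcmc <- function(alignment, clock = clockModel(),
                        priors = skylinePriors(),
                        settings = skylineSettings(), model = NULL,
                        seed = 1L) {
  aln <- asAlignmentMatrix(alignment)
  if (nrow(aln) < 3) stop("at least 3 sequences are required")
  if (is.null(model)) model <- empiricalGtrModel(aln)
  cp <- compressAlignment(aln)
  ctx <- likContext(cp$patterns, cp$weights, model)
  rate <- clock@rate
  set.seed(as.integer(seed))
  state <- skylineInit(aln, ctx, rate, priors)
  if (priors@maxChangePoints == 0L) {
    state$s <- numeric(0); state$N <- state$N[1]
  }
  ntip <- nrow(aln)
  ll <- skylineLoglik(state, ctx, rate)
  lp <- skylineLogPrior(state, priors, ntip, rate)
  keep <- list()
  rows <- list()
  for (it in seq_len(settings$nIter)) {
    upd <- skylineMove(state, ll, lp, ctx, rate, priors, ntip)
    state <- upd$state; ll <- upd$ll; lp <- upd$lp
    if (it > settings$burnin && (it - settings$burnin) %% settings$thin == 0L) {
      K <- length(state$s)
      rows[[length(rows) + 1L]] <- c(
        rootHeight = max(state$time) / rate, K = K,
        onset = onsetOf(state) / rate,
        modernN = state$N[1] / rate, ancestralN = state$N[K + 1L] / rate,
        logLik = ll, logPrior = lp)
      keep[[length(keep) + 1L]] <- list(s = state$s / rate,
                                        N = state$N / rate,
                                        H = max(state$time) / rate)
    }
  }
  samples <- as.data.frame(do.call(rbind, rows))
  onset <- samples$onset[!is.na(samples$onset)]
  onsetSummary <- if (length(onset) >= 3)
    stats::quantile(onset, c(0.5, 0.025, 0.975), names = FALSE)
  else rep(NA_real_, 3)
  names(onsetSummary) <- c("median", "lower", "upper")
  nt <- min(length(keep), settings$maxTrajectories)
  sel <- unique(round(seq(1, length(keep), length.out = nt)))
  traj <- lapply(keep[sel], function(x) {
    tt <- sort(unique(c(0, x$s, seq(0, x$H, length.out = 25))))
    cbind(time = tt, size = trajectoryAt(tt, x$s, x$N))
  })
  ess <- c(logLik = essOf(samples$logLik),
           rootHeight = essOf(samples$rootHeight))
  new("SkylinePosterior", samples = samples, trajectories = traj,
      onsetSummary = onsetSummary, clockRate = rate, ess = ess,
      converged = all(ess >= settings$essFloor))
}

setMethod("show", "SkylinePosterior", function(object) {
  cat(sprintf("SkylinePosterior: %d samples, onset median %.0f years BP (95%% CI %.0f-%.0f)%s\n",
              nrow(object@samples), object@onsetSummary[1],
              object@onsetSummary[3], object@onsetSummary[2],
              if (object@converged) "" else "  [non-converged]"))
  cat(sprintf("  P(K >= 1) = %.2f, ESS(logLik) = %.0f\n",
              mean(object@samples$K >= 1), object@ess["logLik"]))
})

#' Expansion-onset summary in years before present
#' @param posterior a \linkS4class{SkylinePosterior}.
#' @return named numeric (median, lower, upper).
#' @export
onsetSummary <- function(posterior) posterior@onsetSummary

## GTR+G4+I with empirical frequencies; shape/pInv (and exchangeabilities)
## plugged in by a quick ML fit when phangorn is available.
empiricalGtrModel <- function(aln) {
  tab <- table(factor(as.vector(toupper(aln)), levels = BASES))
  f <- (as.numeric(tab) + 1) / (sum(tab) + 4)
  shape <- 0.5; pinv <- 0.2; rates <- rep(1, 6)
  if (requireNamespace("phangorn", quietly = TRUE)) {
    fitted <- tryCatch({
      pd <- phangorn::phyDat(aln, type = "DNA")
      tree <- ape::nj(ape::dist.dna(ape::as.DNAbin(aln), model = "JC69",
                                    pairwise.deletion = TRUE))
      tree$edge.length[tree$edge.length < 0] <- 1e-9
      fit <- phangorn::pml(tree, pd, k = 4, inv = 0.2, model = "GTR",
                           bf = f)
      fit <- phangorn::optim.pml(fit, optEdge = TRUE, optGamma = TRUE,
                                 optInv = TRUE, optQ = TRUE,
                                 control = phangorn::pml.control(trace = 0))
      list(shape = fit$shape, pinv = fit$inv, rates = fit$Q)
    }, error = function(e) NULL)
    if (!is.null(fitted)) {
      shape <- min(max(fitted$shape, 0.05), 50)
      pinv <- min(max(fitted$pinv, 0), 0.95)
      rates <- pmin(pmax(fitted$rates, 1e-4), 1e4)
    }
  }
  substModel("GTR", rates = rates, freqs = f, gammaShape = shape,
             nGammaCat = 4L, pInv = pinv)
}

#' Log marginal likelihood by stepping-stone sampling
#'
#' Estimates the log marginal likelihood of the skyline model or the
#' constant-size model by stepping-stone sampling along power-posterior
#' ladders with Beta(0.3, 1)-spaced exponents, warm-starting each rung from
#' the last. The skyline marginal likelihood is obtained by marginalizing
#' the change-point count over 0..maxChangePoints with its truncated
#' Poisson prior weights, one fixed-dimension ladder per count (the
#' reversible-jump moves are used only for posterior sampling, where
#' trans-dimensional mixing matters less than marginal-likelihood
#' accuracy). A thermodynamic-integration (trapezoidal) estimate over the
#' same rungs is returned as a cross-check.
#'
#' @inheritParams skylineMcmc
#' @param demographicModel \code{"skyline"} or \code{"constant"}.
#' @param rungs number of ladder steps.
#' @param itersPerRung,burninPerRung per-rung chain budget.
#' @return list: \code{logML}, \code{se}, \code{logML_ti} (cross-check),
#'   \code{perK} (per-count components for the skyline model).
#' @export
logMarginalLikelihood <- function(alignment, demographicModel = c("skyline", "constant"),
                                  clock = clockModel(),
                                  priors = skylinePriors(),
                                  rungs = 16L, itersPerRung = 400L,
                                  burninPerRung = 120L, model = NULL,
                                  seed = 1L) {
  demographicModel <- match.arg(demographicModel)
  aln <- asAlignmentMatrix(alignment)
  if (is.null(model)) model <- empiricalGtrModel(aln)
  cp <- compressAlignment(aln)
  ctx <- likContext(cp$patterns, cp$weights, model)
  rate <- clock@rate
  ntip <- nrow(aln)
  Ks <- if (demographicModel == "constant") 0L
        else 0:priors@maxChangePoints
  perK <- data.frame(K = Ks, logML = NA_real_, se = NA_real_,
                     logML_ti = NA_real_)
  set.seed(as.integer(seed))
  for (ki in seq_along(Ks)) {
    K <- Ks[ki]
    fixPriors <- skylinePriors(priors@changePointPriorMean, K,
                               priors@sizeBounds, priors@sizePrior)
    state <- skylineInitK(aln, ctx, rate, fixPriors, K)
    ll <- skylineLoglik(state, ctx, rate)
    lp <- skylineLogPrior(state, fixPriors, ntip, rate)
    beta <- (seq(0, rungs) / rungs)^(1 / 0.3)
    logml <- 0; varsum <- 0
    meanLL <- numeric(rungs + 1)
    for (k in seq_len(rungs)) {
      lls <- numeric(0)
      for (it in seq_len(itersPerRung)) {
        upd <- skylineMove(state, ll, lp, ctx, rate, fixPriors, ntip,
                           power = beta[k], fixedK = TRUE)
        state <- upd$state; ll <- upd$ll; lp <- upd$lp
        if (it > burninPerRung) lls <- c(lls, ll)
      }
      d <- (beta[k + 1] - beta[k]) * lls
      m <- max(d)
      w <- exp(d - m)
      logml <- logml + m + log(mean(w))
      varsum <- varsum + stats::var(w) / length(w) / mean(w)^2
      meanLL[k] <- mean(lls)
    }
    lls <- numeric(0) # final rung at beta = 1 for the TI cross-check
    for (it in seq_len(itersPerRung)) {
      upd <- skylineMove(state, ll, lp, ctx, rate, fixPriors, ntip,
                         power = 1, fixedK = TRUE)
      state <- upd$state; ll <- upd$ll; lp <- upd$lp
      if (it > burninPerRung) lls <- c(lls, ll)
    }
    meanLL[rungs + 1] <- mean(lls)
    perK$logML[ki] <- logml
    perK$se[ki] <- sqrt(varsum)
    perK$logML_ti[ki] <- sum(diff(beta) *
                             (meanLL[-1] + meanLL[-length(meanLL)]) / 2)
  }
  wK <- stats::dpois(Ks, priors@changePointPriorMean)
  if (demographicModel == "skyline")
    wK <- stats::dpois(Ks, priors@changePointPriorMean) /
      sum(stats::dpois(0:priors@maxChangePoints, priors@changePointPriorMean))
  else wK <- 1
  comb <- log(wK) + perK$logML
  m <- max(comb)
  logML <- m + log(sum(exp(comb - m)))
  post <- exp(comb - m) / sum(exp(comb - m))
  combTi <- log(wK) + perK$logML_ti
  mt <- max(combTi)
  list(logML = logML, se = sqrt(sum(post^2 * perK$se^2)),
       logML_ti = mt + log(sum(exp(combTi - mt))), perK = perK)
}

#' Bayes factor of expansion versus constant population size
#'
#' Log Bayes factor of the skyline model against the constant-size model,
#' estimated by stepping-stone sampling on identical data, clock and
#' substitution model.
#'
#' @inheritParams logMarginalLikelihood
#' @return a \linkS4class{BayesFactorResult}.
#' @export
bayesFactor <- function(alignment, clock = clockModel(),
                        priors = skylinePriors(), rungs = 16L,
                        itersPerRung = 400L, burninPerRung = 120L,
                        model = NULL, seed = 1L) {
  aln <- asAlignmentMatrix(alignment)
  if (is.null(model)) model <- empiricalGtrModel(aln)
  sky <- logMarginalLikelihood(aln, "skyline", clock, priors, rungs,
                               itersPerRung, burninPerRung, model, seed)
  cst <- logMarginalLikelihood(aln, "constant", clock, priors, rungs,
                               itersPerRung, burninPerRung, model, seed + 1L)
  new("BayesFactorResult",
      logML = c(skyline = sky$logML, constant = cst$logML),
      logBF = sky$logML - cst$logML,
      se = sqrt(sky$se^2 + cst$se^2))
}

setMethod("show", "BayesFactorResult", function(object) {
  cat(sprintf("BayesFactorResult: log BF (skyline - constant) = %.2f (se %.2f)\n",
              object@logBF, object@se))
})
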