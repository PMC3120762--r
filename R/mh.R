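## Metropolis-Hastings sampling of genealogies-with-migration-histories.
##
## The sampler targets P(D | G)^power p(G | psi0) for driving parameters
## psi0 = (theta0, M0) using the classic single-lineage re-simulation
## proposal: a random lineage is detached and re-grown backward in time from
## the conditional structured coalescent given the remaining tree, so the
## Hastings ratio reduces to the data-likelihood ratio. Retained states are
## summarised by their structured-coalescent sufficient statistics (per-deme
## coalescence counts, pair-time and lineage-time integrals, migration-event
## counts), from which the genealogy density can be evaluated for any
## parameter values. The chain itself runs in compiled code
## (src/mhchain.cpp); an R reference implementation of the same kernel is
## kept below for cross-validation.

## Raw mutable state mirrors the Genealogy slots.
stateFromGenealogy <- function(gen) {
  list(n = length(gen@tipLabels), nd = length(gen@demeLabels),
       parent = gen@parent, time = gen@time, nodeDeme = gen@nodeDeme,
       paths = gen@paths)
}

genealogyFromState <- function(st, tipLabels, demeLabels) {
  new("Genealogy", tipLabels = tipLabels, demeLabels = demeLabels,
      parent = as.integer(st$parent), time = st$time,
      nodeDeme = as.integer(st$nodeDeme), paths = st$paths)
}

## Vectorised structured-coalescent log density for a matrix of sufficient
## statistics (rows = samples, columns = coal[nd], pairTime[nd],
## lineageTime[nd], migrations[nd x nd] row-major).
statsLogDens <- function(S, theta, M) {
  nd <- length(theta)
  ll <- as.vector(S[, seq_len(nd), drop = FALSE] %*% log(2 / theta) -
                  S[, nd + seq_len(nd), drop = FALSE] %*% (2 / theta))
  for (i in seq_len(nd)) for (j in seq_len(nd)) {
    if (i == j) next
    m <- S[, 3 * nd + (i - 1) * nd + j]
    if (M[i, j] <= 0) {
      ll[m > 0] <- -Inf
    } else {
      ll <- ll + m * log(M[i, j]) - M[i, j] * S[, 2 * nd + i]
    }
  }
  ll
}

## Run the compiled chain. Returns stats matrix, loglik trace, acceptance
## (of the tree moves) and the final raw state. `power` tempers the data
## likelihood. Each iteration is one single-lineage re-simulation attempt
## plus `nRefresh` cheap migration-history refreshes (deme-path redraws and
## node-deme flips) that leave the tree and likelihood unchanged.
runChain <- function(tipDeme, demeLabels, ctx, theta, M, nIter, burnin, thin,
                     power = 1, init = NULL, nRefresh = 10L, cap = 1e3) {
  if (is.null(init)) {
    labs <- paste0("t", seq_along(tipDeme))
    g <- simCoalescent(labs, tipDeme, demeLabels, theta, M)
    init <- stateFromGenealogy(g)
  }
  .mhChainCpp(init, theta, M, ctx$patterns, as.numeric(ctx$weights),
              ctx$eg$right, ctx$eg$vals, ctx$eg$left, ctx$model@freqs,
              ctx$rc$rate, ctx$rc$prob, as.integer(nIter),
              as.integer(burnin), as.integer(thin), power, cap,
              as.integer(nRefresh))
}

## Stepping-stone estimate of log L(theta, M) = log E_prior[ P(D|G) ] along
## a power-posterior path beta_k = (k/K)^(1/0.3), warm-started from exact
## prior sampling at beta = 0. Returns the log-likelihood with a per-rung
## delta-method standard error. This is the absolute anchor; its (shared)
## annealing bias cancels in comparisons that use the same budget.
ssLogLik <- function(tipDeme, demeLabels, ctx, theta, M,
                     rungs = 12L, itersPerRung = 400L, burninPerRung = 100L,
                     thin = 2L, init = NULL) {
  beta <- (seq(0, rungs) / rungs)^(1 / 0.3)
  st <- init
  logml <- 0
  varsum <- 0
  accs <- numeric(0)
  for (k in seq_len(rungs)) {
    run <- runChain(tipDeme, demeLabels, ctx, theta, M,
                    nIter = itersPerRung, burnin = burninPerRung,
                    thin = thin, power = beta[k], init = st)
    st <- run$state
    accs <- c(accs, run$acceptance)
    d <- (beta[k + 1] - beta[k]) * run$loglik
    m <- max(d)
    w <- exp(d - m)
    logml <- logml + m + log(mean(w))
    varsum <- varsum + stats::var(w) / length(w) / mean(w)^2
  }
  list(logLik = logml, se = sqrt(varsum), acceptance = accs, state = st)
}

## Bridge estimate of log L(theta1, M1) - log L(theta0, M0) on the same
## data, along a ladder of intermediate parameter values: free parameters
## are interpolated log-linearly and rates that vanish in the target decay
## as exp(-s) before dropping to exactly zero at the last step. Each rung
## samples the ordinary posterior at its own parameters (so the
## re-simulation kernel applies unchanged) and contributes the telescoping
## ratio E_k[ p(G | psi_{k+1}) / p(G | psi_k) ] = L_{k+1}/L_k. The
## annealing distance between two fitted models is far shorter than from
## the prior, so the shared absolute-anchor bias cancels in comparisons.
bridgeDeltaLogLik <- function(tipDeme, demeLabels, ctx, theta0, M0,
                              theta1, M1, rungs = 6L, itersPerRung = 300L,
                              burninPerRung = 80L, thin = 2L, init = NULL) {
  decay <- c(seq(0, 6, length.out = rungs), Inf)
  frac <- seq(0, 1, length.out = rungs + 1)
  ladder <- lapply(seq_len(rungs + 1), function(k) {
    th <- exp((1 - frac[k]) * log(theta0) + frac[k] * log(theta1))
    M <- M0
    pos <- M1 > 0 & M0 > 0
    M[pos] <- exp((1 - frac[k]) * log(M0[pos]) + frac[k] * log(M1[pos]))
    M[M1 > 0 & M0 <= 0] <- M1[M1 > 0 & M0 <= 0] * frac[k] # rare: new route
    dead <- M1 <= 0 & M0 > 0
    M[dead] <- M0[dead] * exp(-decay[k])
    list(theta = th, M = M)
  })
  st <- init
  delta <- 0
  varsum <- 0
  accs <- numeric(0)
  for (k in seq_len(rungs)) {
    tries <- if (k == rungs) 3L else 1L
    iters <- itersPerRung
    repeat {
      run <- runChain(tipDeme, demeLabels, ctx, ladder[[k]]$theta,
                      ladder[[k]]$M, nIter = iters,
                      burnin = burninPerRung, thin = thin, init = st)
      st <- run$state
      accs <- c(accs, run$acceptance)
      d <- statsLogDens(run$stats, ladder[[k + 1]]$theta, ladder[[k + 1]]$M) -
           statsLogDens(run$stats, ladder[[k]]$theta, ladder[[k]]$M)
      m <- max(d)
      tries <- tries - 1L
      ## at the final rung the target drops the dying routes to exactly
      ## zero; if every retained genealogy still carries an event there the
      ## chain has not flushed them yet -- continue it rather than give up
      if (is.finite(m) || tries <= 0L) break
      iters <- 2L * iters
    }
    if (!is.finite(m)) return(list(delta = -Inf, se = Inf, acceptance = accs))
    w <- exp(d - m)
    delta <- delta + m + log(mean(w))
    varsum <- varsum + stats::var(w) / length(w) / mean(w)^2
  }
  list(delta = delta, se = sqrt(varsum), acceptance = accs, state = st)
}

## ---- R reference implementation of the kernel (used by tests) ------------

## Deme of lineage v at time t (t within its lifetime).
stateDemeAt <- function(st, v, t) {
  pth <- st$paths[[v]]
  d <- st$nodeDeme[v]
  if (nrow(pth)) {
    k <- sum(pth[, 1] <= t)
    if (k > 0) d <- as.integer(pth[k, 2])
  }
  d
}

## Lineage segments (node, t0, t1, deme) of all lineages except `excl`,
## with the root lineage extended to t1 = Inf.
stateSegments <- function(st, excl) {
  nn <- length(st$parent)
  nmig <- vapply(st$paths, nrow, 1L)
  tot <- nn - length(excl) + sum(nmig[-excl])
  out <- matrix(0, tot, 4)
  r <- 0L
  for (v in seq_len(nn)) {
    if (v == excl[1] || v == excl[2]) next
    p <- st$parent[v]
    top <- if (p == 0L) Inf else st$time[p]
    k <- nmig[v]
    if (k == 0L) {
      r <- r + 1L
      out[r, ] <- c(v, st$time[v], top, st$nodeDeme[v])
    } else {
      pth <- st$paths[[v]]
      t0 <- c(st$time[v], pth[, 1])
      rows <- r + seq_len(k + 1L)
      out[rows, 1] <- v
      out[rows, 2] <- t0
      out[rows, 3] <- c(t0[-1], top)
      out[rows, 4] <- c(st$nodeDeme[v], pth[, 2])
      r <- r + k + 1L
    }
  }
  out
}

## One re-simulation proposal at driving rates (R reference). Returns the
## proposed state or NULL when the re-growth deadlocks or overruns the cap.
proposeResim <- function(st, theta, M, cap = 1e3) {
  n <- st$n
  nnode <- length(st$parent)
  root <- which(st$parent == 0L)
  c0 <- sample(setdiff(seq_len(nnode), root), 1L)
  p <- st$parent[c0]
  kids <- which(st$parent == p)
  sib <- kids[kids != c0]
  g <- st$parent[p]
  parent <- st$parent; time <- st$time; nodeDeme <- st$nodeDeme
  paths <- st$paths
  parent[sib] <- g
  paths[[sib]] <- rbind(paths[[sib]], paths[[p]])
  paths[[p]] <- matrix(numeric(0), 0, 2)
  parent[p] <- -1L
  st2 <- list(n = n, nd = st$nd, parent = parent, time = time,
              nodeDeme = nodeDeme, paths = paths)
  segs <- stateSegments(st2, excl = c(c0, p))
  outRate <- rowSums(M)
  bps <- sort(unique(segs[is.finite(segs[, 3]), 3]))
  t <- st$time[c0]
  a <- st$nodeDeme[c0]
  newPath <- NULL
  rootNode <- if (g == 0L) sib else root
  rootExtra <- NULL
  maxT <- max(st$time) + cap * max(theta)
  repeat {
    alive <- segs[segs[, 2] <= t & segs[, 3] > t, , drop = FALSE]
    joint <- nrow(alive) == 1L && !is.finite(alive[1, 3])
    if (joint) {
      rdeme <- alive[1, 4]
      rateMigA <- outRate[a]
      rateMigR <- outRate[rdeme]
      rateCoal <- if (a == rdeme) 2 / theta[a] else 0
      tot <- rateMigA + rateMigR + rateCoal
      if (tot <= 0) return(NULL)
      t <- t + rexp(1, tot)
      if (t > maxT) return(NULL)
      u <- runif(1) * tot
      if (u < rateCoal) { target <- alive[1, 1]; break }
      if (u < rateCoal + rateMigA) {
        a <- sample.int(st$nd, 1L, prob = M[a, ])
        newPath <- rbind(newPath, c(t, a))
      } else {
        rdeme <- sample.int(st$nd, 1L, prob = M[rdeme, ])
        rootExtra <- rbind(rootExtra, c(t, rdeme))
        segs[!is.finite(segs[, 3]), 4] <- rdeme
      }
      next
    }
    partners <- alive[alive[, 4] == a, , drop = FALSE]
    rate <- outRate[a] + 2 / theta[a] * nrow(partners)
    nxt <- bps[bps > t]
    nxt <- if (length(nxt)) nxt[1] else Inf
    if (rate <= 0) {
      if (!is.finite(nxt)) return(NULL)
      t <- nxt
      next
    }
    dt <- rexp(1, rate)
    if (t + dt > nxt) { t <- nxt; next }
    t <- t + dt
    if (t > maxT) return(NULL)
    if (runif(1) * rate < outRate[a]) {
      a <- sample.int(st$nd, 1L, prob = M[a, ])
      newPath <- rbind(newPath, c(t, a))
    } else {
      target <- partners[sample.int(nrow(partners), 1L), 1]
      break
    }
  }
  x <- as.integer(target)
  time[p] <- t
  nodeDeme[p] <- a
  if (!is.null(rootExtra)) {
    paths[[rootNode]] <- rbind(paths[[rootNode]],
                               rootExtra[rootExtra[, 1] <= t, , drop = FALSE])
  }
  if (x == rootNode && st2$parent[x] == 0L) {
    parent[p] <- 0L
    paths[[p]] <- matrix(numeric(0), 0, 2)
    if (nrow(paths[[x]])) # lineage above the new root no longer exists
      paths[[x]] <- paths[[x]][paths[[x]][, 1] <= t, , drop = FALSE]
  } else {
    xp <- st2$parent[x]
    parent[p] <- xp
    keep <- paths[[x]][, 1] <= t
    paths[[p]] <- paths[[x]][!keep, , drop = FALSE]
    paths[[x]] <- paths[[x]][keep, , drop = FALSE]
  }
  parent[x] <- p
  parent[c0] <- p
  paths[[c0]] <- if (is.null(newPath)) matrix(numeric(0), 0, 2) else newPath
  colnames(paths[[c0]]) <- c("time", "deme")
  list(n = n, nd = st$nd, parent = parent, time = time,
       nodeDeme = nodeDeme, paths = paths)
}

## Sufficient statistics from a raw state (same contract as genealogyStats).
stateStats <- function(st) {
  g <- genealogyFromState(st, paste0("t", seq_len(st$n)),
                          paste0("d", seq_len(st$nd)))
  genealogyStats(g)
}

## R reference chain (same kernel as the compiled one; slow, for tests).
mhGenealogiesR <- function(tipDeme, demeLabels, patterns, weights, model,
                           theta, M, nIter, burnin, thin, init = NULL,
                           power = 1) {
  st <- if (is.null(init)) {
    g <- simCoalescent(paste0("t", seq_along(tipDeme)), tipDeme, demeLabels,
                       theta, M)
    stateFromGenealogy(g)
  } else init
  ctx <- likContext(patterns, weights, model)
  ll <- prunedLoglik(st$parent, st$time, patterns, weights, model, ctx = ctx)
  keepStats <- list()
  keepLL <- numeric(0)
  acc <- 0L
  for (it in seq_len(nIter)) {
    st2 <- proposeResim(st, theta, M)
    if (!is.null(st2)) {
      ll2 <- prunedLoglik(st2$parent, st2$time, patterns, weights, model,
                          ctx = ctx)
      if (is.finite(ll2) && log(runif(1)) < power * (ll2 - ll)) {
        st <- st2; ll <- ll2; acc <- acc + 1L
      }
    }
    if (it > burnin && (it - burnin) %% thin == 0L) {
      keepStats[[length(keepStats) + 1L]] <- stateStats(st)
      keepLL <- c(keepLL, ll)
    }
  }
  list(stats = keepStats, loglik = keepLL, acceptance = acc / nIter,
       state = st)
}
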