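BASES <- c("A", "C", "G", "T")

#' Construct a substitution model
#'
#' Builds a \linkS4class{SubstModel}. \code{"JC"} fixes equal rates and
#' frequencies; \code{"HKY"} takes a transition/transversion ratio
#' \code{kappa}; \code{"GTR"} takes six exchangeabilities. Rate heterogeneity
#' is discrete-gamma with \code{nGammaCat} categories plus an invariant-site
#' class of weight \code{pInv}; category rates are normalised so the mean
#' rate over all classes is one.
#'
#' @param name one of \code{"JC"}, \code{"HKY"}, \code{"GTR"}.
#' @param freqs stationary base frequencies (A, C, G, T); ignored for JC.
#' @param kappa transition/transversion rate ratio (HKY).
#' @param rates six exchangeabilities AC, AG, AT, CG, CT, GT (GTR).
#' @param gammaShape gamma shape; \code{Inf} for rate homogeneity.
#' @param nGammaCat number of discrete gamma categories.
#' @param pInv proportion of invariant sites.
#' @return a \linkS4class{SubstModel}.
#' @examples
#' substModel("HKY", kappa = 4, freqs = c(0.3, 0.2, 0.2, 0.3))
#' @export
substModel <- function(name = c("JC", "HKY", "GTR"), freqs = rep(0.25, 4),
                       kappa = 2, rates = rep(1, 6), gammaShape = Inf,
                       nGammaCat = 4L, pInv = 0) {
  name <- match.arg(name)
  freqs <- freqs / sum(freqs)
  r <- switch(name,
    JC  = { freqs <- rep(0.25, 4); rep(1, 6) },
    HKY = c(1, kappa, 1, 1, kappa, 1),
    GTR = rates)
  new("SubstModel", name = name, rates = as.numeric(r),
      freqs = as.numeric(freqs), gammaShape = as.numeric(gammaShape),
      nGammaCat = as.integer(nGammaCat), pInv = as.numeric(pInv))
}

setMethod("show", "SubstModel", function(object) {
  het <- if (is.finite(object@gammaShape))
    sprintf("+G%d(%.3g)", object@nGammaCat, object@gammaShape) else ""
  inv <- if (object@pInv > 0) sprintf("+I(%.3g)", object@pInv) else ""
  cat(sprintf("SubstModel %s%s%s  freqs = %s\n", object@name, het, inv,
              paste(sprintf("%.3f", object@freqs), collapse = " ")))
})

## Normalised GTR rate matrix: Q[i,j] = s_ij * pi_j, mean rate 1 at
## stationarity over the variable-site classes.
rateMatrix <- function(model) {
  s <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  s[lower.tri(s)] <- model@rates[c(1, 2, 3, 4, 5, 6)]
  ## order AC,AG,AT,CG,CT,GT fills (C,A),(G,A),(T,A),(G,C),(T,C),(T,G)
  s <- s + t(s)
  Q <- s * rep(model@freqs, each = 4)
  diag(Q) <- -rowSums(Q)
  Q / sum(model@freqs * -diag(Q))
}

## Mean rates of the discrete-gamma categories (equal-probability bins).
discreteGammaRates <- function(shape, ncat) {
  if (!is.finite(shape)) return(rep(1, ncat))
  b <- qgamma(seq(0, 1, length.out = ncat + 1), shape, shape)
  ## mean of a gamma(shape, shape) within each quantile bin
  up <- pgamma(b * shape / shape, shape + 1, shape)
  m <- ncat * diff(up)
  m / mean(m)
}

## Site-rate classes: rate and probability per class, overall mean 1.
rateClasses <- function(model) {
  g <- discreteGammaRates(model@gammaShape, model@nGammaCat)
  if (model@pInv > 0) {
    list(rate = c(0, g / (1 - model@pInv)),
         prob = c(model@pInv, rep((1 - model@pInv) / length(g), length(g))))
  } else {
    list(rate = g, prob = rep(1 / length(g), length(g)))
  }
}

## Eigen machinery for fast P(t); reversible Q symmetrised by sqrt(pi).
modelEigen <- function(model) {
  Q <- rateMatrix(model)
  d <- sqrt(model@freqs)
  B <- Q * (d / rep(d, each = 4)) # wrong orientation fixed below
  B <- diag(d) %*% Q %*% diag(1 / d)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  list(vals = e$values,
       right = diag(1 / d) %*% e$vectors,
       left = t(e$vectors) %*% diag(d))
}

## Transition matrix P(t) from a modelEigen() decomposition.
transitionMatrix <- function(eg, t) {
  P <- eg$right %*% (exp(eg$vals * t) * eg$left)
  P[P < 0] <- 0
  P / rowSums(P)
}

## Compress an alignment (character matrix, rows = sequences) into site
## patterns. Non-ACGT symbols become 0 (fully ambiguous) for likelihoods.
compressAlignment <- function(aln) {
  stopifnot(is.matrix(aln))
  idx <- matrix(match(toupper(aln), BASES, nomatch = 0L), nrow(aln),
                dimnames = list(rownames(aln), NULL))
  key <- apply(idx, 2, paste, collapse = ",")
  u <- !duplicated(key)
  list(patterns = idx[, u, drop = FALSE],
       weights = as.vector(table(key)[key[u]]),
       n = nrow(aln), L = ncol(aln))
}

## Precomputed likelihood context for repeated pruning over the same
## alignment and model (the hot path of the MCMC samplers).
likContext <- function(patterns, weights, model) {
  list(patterns = patterns, weights = weights, model = model,
       eg = modelEigen(model), rc = rateClasses(model),
       ntip = nrow(patterns), npat = ncol(patterns))
}

## Felsenstein pruning over a clock tree given as parent/time vectors.
## patterns: ntip x npat base-index matrix (0 = ambiguous); weights per
## pattern. Returns the total log-likelihood (compiled kernel).
prunedLoglik <- function(parent, time, patterns, weights, model,
                         rateScale = 1, ctx = NULL) {
  if (is.null(ctx)) ctx <- likContext(patterns, weights, model)
  .prunedLoglikCpp(as.integer(parent), as.numeric(time), ctx$patterns,
                   as.numeric(ctx$weights), ctx$eg$right, ctx$eg$vals,
                   ctx$eg$left, ctx$model@freqs, ctx$rc$rate, ctx$rc$prob,
                   rateScale)
}

## Reference R implementation of the pruning kernel (kept for
## cross-validation of the compiled version).
prunedLoglikR <- function(parent, time, patterns, weights, model,
                          rateScale = 1, ctx = NULL) {
  if (is.null(ctx)) ctx <- likContext(patterns, weights, model)
  ntip <- ctx$ntip
  npat <- ctx$npat
  nnode <- length(parent)
  ord <- order(time) # tips first (time 0), then internal nodes upward: a
  ## valid postorder for ultrametric trees
  ord <- ord[ord > ntip]
  kidOf <- vector("list", nnode)
  for (v in seq_len(nnode)) {
    p <- parent[v]
    if (p > 0L) kidOf[[p]] <- c(kidOf[[p]], v)
  }
  root <- which(parent == 0L)
  freqs <- ctx$model@freqs
  ncat <- length(ctx$rc$rate)
  catLL <- matrix(-Inf, ncat, npat)
  for (k in seq_len(ncat)) {
    rk <- ctx$rc$rate[k] * rateScale
    part <- vector("list", nnode)
    scal <- numeric(npat)
    for (v in ord) {
      pv <- NULL
      for (c in kidOf[[v]]) {
        len <- (time[v] - time[c]) * rk
        P <- transitionMatrix(ctx$eg, len)
        contrib <- if (c <= ntip) {
          idx <- ctx$patterns[c, ]
          m <- matrix(1, 4, npat)
          known <- idx > 0L
          m[, known] <- P[, idx[known]]
          m
        } else P %*% part[[c]]
        pv <- if (is.null(pv)) contrib else pv * contrib
      }
      mx <- pmax(pv[1, ], pv[2, ], pv[3, ], pv[4, ])
      mx[mx == 0] <- 1
      part[[v]] <- pv / rep(mx, each = 4)
      scal <- scal + log(mx)
    }
    rootlik <- (freqs %*% part[[root]])[1, ]
    catLL[k, ] <- log(ctx$rc$prob[k]) + log(rootlik) + scal
  }
  top <- apply(catLL, 2, max)
  siteLL <- top + log(colSums(exp(catLL - rep(top, each = ncat))))
  if (!all(is.finite(siteLL))) return(-Inf)
  sum(ctx$weights * siteLL)
}

#' Exact alignment log-likelihood on a genealogy
#'
#' Felsenstein pruning of the alignment over the timed genealogy under a
#' substitution model, summed over sites. Branch lengths are node-time
#' differences in expected substitutions per site.
#'
#' @param gen a \linkS4class{Genealogy}.
#' @param alignment named character vector of equal-length sequences, or a
#'   character matrix with one row per sequence; names must match the
#'   genealogy tip labels.
#' @param model a \linkS4class{SubstModel}.
#' @return the log-likelihood (a single number).
#' @examples
#' g <- new("Genealogy", tipLabels = "s1", demeLabels = "F",
#'          parent = 0L, time = 0, nodeDeme = 1L,
#'          paths = list(matrix(numeric(0), 0, 2)))
#' pruningLoglik(g, c(s1 = "ACGT"), substModel("JC")) # 4 * log(1/4)
#' @export
pruningLoglik <- function(gen, alignment, model) {
  aln <- asAlignmentMatrix(alignment)
  if (!setequal(rownames(aln), gen@tipLabels))
    stop("alignment ids do not match genealogy tips")
  aln <- aln[gen@tipLabels, , drop = FALSE]
  cp <- compressAlignment(aln)
  if (length(gen@parent) == 1L) { # single lineage: stationary draw
    known <- cp$patterns[1, ] > 0
    return(sum(cp$weights[known] * log(model@freqs[cp$patterns[1, known]])))
  }
  prunedLoglik(gen@parent, gen@time, cp$patterns, cp$weights, model)
}

## Accept either a named character vector of sequences or a character matrix.
asAlignmentMatrix <- function(alignment) {
  if (is.matrix(alignment)) {
    if (is.null(rownames(alignment))) stop("alignment matrix must have rownames")
    return(alignment)
  }
  if (is.null(names(alignment))) stop("sequences must be named")
  L <- unique(nchar(alignment))
  if (length(L) != 1L) stop("sequences must be aligned (equal length)")
  m <- matrix(unlist(strsplit(toupper(alignment), "")), byrow = TRUE,
              nrow = length(alignment), dimnames = list(names(alignment), NULL))
  m
}

#' Evolve sequences along a genealogy
#'
#' Places substitutions by a continuous-time Markov process along every
#' branch of the genealogy and returns one aligned sequence per tip. Site
#' rate classes (gamma / invariant) are drawn independently per site.
#'
#' @param gen a \linkS4class{Genealogy}.
#' @param model a \linkS4class{SubstModel}.
#' @param length number of sites.
#' @param seed integer seed.
#' @return named character vector of tip sequences.
#' @examples
#' cfg <- simulationConfig(sampleSizes = c(F = 4, S = 0, A = 0), seed = 1)
#' g <- simulateGenealogy(cfg)
#' mutateOnGenealogy(g, substModel("JC"), length = 60, seed = 2)
#' @export
mutateOnGenealogy <- function(gen, model, length, seed) {
  stopifnot(length >= 1)
  set.seed(as.integer(seed))
  eg <- modelEigen(model)
  rc <- rateClasses(model)
  L <- as.integer(length)
  cls <- sample.int(length(rc$rate), L, replace = TRUE, prob = rc$prob)
  nnode <- length(gen@parent)
  root <- which(gen@parent == 0L)
  states <- matrix(NA_integer_, nnode, L)
  states[root, ] <- sample.int(4, L, replace = TRUE, prob = model@freqs)
  ord <- integer(0) # root-to-tips traversal (robust to tied node times)
  pending <- root
  while (length(pending)) {
    v <- pending[1]
    pending <- c(pending[-1], which(gen@parent == v))
    ord <- c(ord, v)
  }
  for (v in ord) {
    if (v == root) next
    len <- gen@time[gen@parent[v]] - gen@time[v]
    ps <- states[gen@parent[v], ]
    out <- integer(L)
    for (k in unique(cls)) {
      s <- which(cls == k)
      if (rc$rate[k] == 0 || len == 0) { out[s] <- ps[s]; next }
      P <- transitionMatrix(eg, len * rc$rate[k])
      cp <- t(apply(P, 1, cumsum))
      u <- runif(length(s))
      out[s] <- 1L + rowSums(u > cp[ps[s], 1:3, drop = FALSE])
    }
    states[v, ] <- out
  }
  seqs <- apply(states[seq_along(gen@tipLabels), , drop = FALSE], 1,
                function(x) paste(BASES[x], collapse = ""))
  names(seqs) <- gen@tipLabels
  seqs
}
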