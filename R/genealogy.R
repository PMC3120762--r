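## Validity of a Genealogy: binary, ultrametric from the tips, deme paths
## partition every lineage's lifetime, coalescences join lineages that are in
## the same deme.
.validGenealogy <- function(object) {
  msg <- character()
  n <- length(object@tipLabels)
  nnode <- length(object@parent)
  if (nnode != max(1L, 2L * n - 1L))
    return("a binary genealogy of n tips has 2n-1 nodes")
  if (length(object@time) != nnode || length(object@nodeDeme) != nnode ||
      length(object@paths) != nnode)
    return("parent, time, nodeDeme and paths must have one entry per node")
  root <- which(object@parent == 0L)
  if (length(root) != 1L) return("exactly one root required")
  if (any(object@time[seq_len(n)] != 0)) msg <- c(msg, "tips must be at time 0")
  if (n > 1L) {
    tab <- tabulate(object@parent, nnode)
    if (any(tab[(n + 1):nnode] != 2L))
      msg <- c(msg, "every internal node must have exactly 2 children")
    for (v in seq_len(nnode)) {
      p <- object@parent[v]
      if (p == 0L) next
      if (object@time[p] < object@time[v])
        msg <- c(msg, "node times must not decrease towards the root")
      pth <- object@paths[[v]]
      if (nrow(pth)) {
        if (is.unsorted(pth[, 1]) || any(pth[, 1] <= object@time[v]) ||
            any(pth[, 1] >= object@time[p]))
          msg <- c(msg, "migration times must lie strictly within the lineage's lifetime, ordered")
      }
      if (lineageEndDeme(object, v) != object@nodeDeme[p])
        msg <- c(msg, "coalescing lineages must be in the deme of their parent node")
    }
  }
  if (length(msg)) unique(msg) else TRUE
}

## Deme of lineage v just below its parent (after all its migration events).
lineageEndDeme <- function(gen, v) {
  pth <- gen@paths[[v]]
  if (nrow(pth)) as.integer(pth[nrow(pth), 2]) else gen@nodeDeme[v]
}

setMethod("show", "Genealogy", function(object) {
  n <- length(object@tipLabels)
  nm <- sum(vapply(object@paths, nrow, 1L))
  cat(sprintf("Genealogy: %d tips in %d demes (%s), root height %.4g, %d migration events\n",
              n, length(object@demeLabels),
              paste(object@demeLabels, collapse = "/"),
              max(object@time), nm))
})

#' Number of tips of a genealogy
#' @param gen a \linkS4class{Genealogy}.
#' @return integer tip count.
#' @export
nTips <- function(gen) length(gen@tipLabels)

#' Convert a genealogy to an ape \code{phylo} tree
#'
#' Drops the migration history and returns the timed topology with branch
#' lengths in scaled units (expected substitutions per site).
#'
#' @param gen a \linkS4class{Genealogy}.
#' @return an object of class \code{phylo}.
#' @export
asPhylo <- function(gen) {
  n <- length(gen@tipLabels)
  if (n < 2) stop("a phylo tree needs at least 2 tips")
  nnode <- length(gen@parent)
  root <- which(gen@parent == 0L)
  map <- integer(nnode)
  map[seq_len(n)] <- seq_len(n)
  ints <- setdiff((n + 1L):nnode, root)
  map[root] <- n + 1L
  map[ints] <- n + 1L + seq_along(ints)
  child <- which(gen@parent != 0L)
  edge <- cbind(map[gen@parent[child]], map[child])
  len <- gen@time[gen@parent[child]] - gen@time[child]
  structure(list(edge = edge, edge.length = len, Nnode = n - 1L,
                 tip.label = gen@tipLabels),
            class = "phylo", order = "cladewise")
}

#' Sufficient statistics of a genealogy under the structured coalescent
#'
#' Sweeps the event timeline of a genealogy and returns, per deme, the number
#' of coalescences, the integrated pair-time \eqn{\sum C(k_i,2)\,dt}, the
#' integrated lineage-time, and the count matrix of backward migration
#' events. These four statistics determine the structured-coalescent density
#' of the genealogy for any (theta, M).
#'
#' @param gen a \linkS4class{Genealogy}.
#' @return list with elements \code{coal}, \code{pairTime}, \code{lineageTime}
#'   (per deme) and \code{migrations} (deme x deme counts).
#' @export
genealogyStats <- function(gen) {
  nd <- length(gen@demeLabels)
  n <- length(gen@tipLabels)
  ev <- data.frame(t = numeric(0), type = integer(0), i = integer(0), j = integer(0))
  nnode <- length(gen@parent)
  if (n > 1) {
    coalNodes <- (n + 1L):nnode
    ev <- rbind(ev, data.frame(t = gen@time[coalNodes], type = 1L,
                               i = gen@nodeDeme[coalNodes], j = 0L))
  }
  for (v in seq_len(nnode)) {
    pth <- gen@paths[[v]]
    if (!nrow(pth)) next
    from <- c(gen@nodeDeme[v], pth[-nrow(pth), 2])
    ev <- rbind(ev, data.frame(t = pth[, 1], type = 2L,
                               i = as.integer(from), j = as.integer(pth[, 2])))
  }
  ev <- ev[order(ev$t), , drop = FALSE]
  k <- tabulate(gen@nodeDeme[seq_len(n)], nd)
  coal <- pairT <- linT <- numeric(nd)
  mig <- matrix(0L, nd, nd, dimnames = list(gen@demeLabels, gen@demeLabels))
  t0 <- 0
  for (r in seq_len(nrow(ev))) {
    dt <- ev$t[r] - t0
    pairT <- pairT + k * (k - 1) / 2 * dt
    linT <- linT + k * dt
    t0 <- ev$t[r]
    if (ev$type[r] == 1L) {
      coal[ev$i[r]] <- coal[ev$i[r]] + 1
      k[ev$i[r]] <- k[ev$i[r]] - 1L
    } else {
      mig[ev$i[r], ev$j[r]] <- mig[ev$i[r], ev$j[r]] + 1L
      k[ev$i[r]] <- k[ev$i[r]] - 1L
      k[ev$j[r]] <- k[ev$j[r]] + 1L
    }
  }
  list(coal = coal, pairTime = pairT, lineageTime = linT, migrations = mig)
}

## log density of a genealogy-with-migration-history under the constant-size
## structured coalescent at (theta, M), from its sufficient statistics.
## Coalescence rate per pair in deme i is 2/theta_i; a lineage in deme i
## migrates to j at rate M[i, j].
logGenealogyDensity <- function(stats, theta, M) {
  nd <- length(theta)
  ll <- sum(stats$coal * log(2 / theta)) - sum(2 / theta * stats$pairTime)
  off <- row(M) != col(M)
  m <- stats$migrations
  for (i in seq_len(nd)) for (j in seq_len(nd)) {
    if (i == j) next
    if (m[i, j] > 0) {
      if (M[i, j] <= 0) return(-Inf)
      ll <- ll + m[i, j] * log(M[i, j])
    }
    ll <- ll - M[i, j] * stats$lineageTime[i]
  }
  ll
}
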