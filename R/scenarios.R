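#' Build a migration scenario from forward-time colonization edges
#'
#' Encodes a colonization hypothesis over three demes as a constraint mask on
#' the backward migration-rate matrix. Each forward-time edge X>Y frees the
#' backward lineage-migration rate Y->X (a lineage sampled in the colonised
#' deme traces back to its source); all other off-diagonal rates are fixed to
#' zero. The full (unconstrained) model is obtained with \code{edges = NULL}.
#'
#' @param demeLabels character(3) deme labels.
#' @param edges two-column character matrix of forward colonization edges
#'   (from, to), or \code{NULL} for the full model.
#' @param origin origin deme label (\code{NA} for the full model).
#' @param name scenario name; derived from the edges when missing.
#' @return a \linkS4class{MigrationScenario}.
#' @examples
#' migrationScenario(c("F", "S", "A"),
#'                   edges = rbind(c("S", "A"), c("A", "F")), origin = "S")
#' @export
migrationScenario <- function(demeLabels, edges = NULL, origin = NA_character_,
                              name = NULL) {
  if (length(demeLabels) != 3L)
    stop("only 3-deme scenarios are supported")
  mask <- matrix(FALSE, 3, 3, dimnames = list(demeLabels, demeLabels))
  if (is.null(edges)) {
    mask[row(mask) != col(mask)] <- TRUE
    edges <- matrix(character(0), 0, 2)
    if (is.null(name)) name <- "full model"
  } else {
    edges <- matrix(as.character(edges), ncol = 2)
    for (r in seq_len(nrow(edges))) {
      x <- edges[r, 1]; y <- edges[r, 2]
      if (!all(c(x, y) %in% demeLabels)) stop("edge labels must be deme labels")
      mask[y, x] <- TRUE # backward rate colonised -> source is free
    }
    if (is.null(name)) name <- scenarioName(edges)
  }
  colnames(edges) <- c("from", "to")
  new("MigrationScenario", name = name, demeLabels = demeLabels,
      origin = origin, edges = edges, mask = mask,
      k = 3L + sum(mask))
}

scenarioName <- function(edges) {
  if (nrow(edges) == 2 && edges[1, 2] == edges[2, 1])
    paste(edges[1, 1], edges[1, 2], edges[2, 2], sep = ">")
  else
    paste(apply(edges, 1, paste, collapse = ">"), collapse = ", ")
}

setMethod("show", "MigrationScenario", function(object) {
  free <- which(object@mask, arr.ind = TRUE)
  cat(sprintf("MigrationScenario '%s' (k = %d): free backward rates %s\n",
              object@name, object@k,
              if (nrow(free)) paste(sprintf("%s->%s",
                object@demeLabels[free[, 1]], object@demeLabels[free[, 2]]),
                collapse = ", ") else "none"))
})

#' Enumerate the nine colonization hypotheses plus the full model
#'
#' Taking each deme in turn as the potential origin, builds (i) the
#' independent model in which the other two demes are colonised separately
#' from the origin and (ii) the two sequential models in which one deme is
#' colonised first and the remaining deme from there. With three demes this
#' yields nine constrained hypotheses (k = 5 each: three thetas plus two free
#' migration rates), to which the unconstrained full model (k = 9) is added.
#'
#' @param demeLabels character(3) deme labels (default F, S, A).
#' @return named list of 10 \linkS4class{MigrationScenario} objects.
#' @examples
#' names(enumerateScenarios())
#' @export
enumerateScenarios <- function(demeLabels = c("F", "S", "A")) {
  if (length(demeLabels) != 3L)
    stop("only the documented 3-deme scope is supported")
  out <- list()
  for (x in demeLabels) {
    others <- sort(setdiff(demeLabels, x))
    out <- c(out, list(migrationScenario(demeLabels,
      edges = rbind(c(x, others[1]), c(x, others[2])), origin = x)))
    for (y in others) {
      z <- setdiff(others, y)
      out <- c(out, list(migrationScenario(demeLabels,
        edges = rbind(c(x, y), c(y, z)), origin = x)))
    }
  }
  out <- c(out, list(migrationScenario(demeLabels, edges = NULL)))
  names(out) <- vapply(out, function(s) s@name, "")
  out
}

#' Constraint mask of a scenario
#'
#' @param scenario a \linkS4class{MigrationScenario}.
#' @return 3x3 logical matrix; \code{TRUE} entries are free backward rates.
#' @export
scenarioMask <- function(scenario) scenario@mask

#' Fill a rate matrix according to a scenario mask
#'
#' @param scenario a \linkS4class{MigrationScenario}.
#' @param rates values for the free entries, in row-major mask order; a
#'   single value is recycled.
#' @return 3x3 numeric backward migration-rate matrix with masked entries 0.
#' @export
scenarioRates <- function(scenario, rates) {
  M <- matrix(0, 3, 3, dimnames = dimnames(scenario@mask))
  idx <- which(t(scenario@mask), arr.ind = FALSE) # row-major order
  tM <- t(M)
  tM[idx] <- rates
  t(tM)
}

## Can every sampled deme reach a common deme through allowed backward moves?
scenarioConnected <- function(mask, sampled) {
  nd <- nrow(mask)
  reach <- function(i) {
    r <- logical(nd); r[i] <- TRUE
    repeat {
      r2 <- r
      for (a in which(r)) r2 <- r2 | mask[a, ]
      if (identical(r2, r)) break
      r <- r2
    }
    r
  }
  common <- rep(TRUE, nd)
  for (i in which(sampled)) common <- common & reach(i)
  any(common)
}
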