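#' Akaike Information Criterion
#'
#' @param logLik maximized log-likelihood.
#' @param k number of free parameters.
#' @return \code{2 * k - 2 * logLik}.
#' @examples
#' aic(21.6, 5) # -33.2
#' @export
aic <- function(logLik, k) {
  stopifnot(k >= 0, k == round(k))
  2 * k - 2 * logLik
}

#' Rank colonization scenarios by AIC
#'
#' Builds the model-selection table: AIC per scenario (computed from
#' \code{logLik} and \code{k} unless an \code{aic} column is supplied),
#' ranks, and the AIC difference of every model to the best *constrained*
#' scenario. The unconstrained full model takes part in the ranking but is
#' excluded from the best-vs-rest comparison among the colonization
#' hypotheses, so \code{deltaAIC} is relative to the best constrained model
#' and the reported decisiveness is the gap between the best and runner-up
#' constrained models.
#'
#' @param models data.frame with columns \code{scenario}, \code{k} and
#'   either \code{logLik} or \code{aic} (or both; \code{aic} wins).
#' @param fullModelName name identifying the unconstrained model.
#' @return data.frame sorted by AIC ascending with columns \code{scenario},
#'   \code{k}, \code{logLik}, \code{aic}, \code{deltaAIC}, \code{rank},
#'   \code{best}; attribute \code{deltaBestVsRunnerUp} holds the decisive
#'   gap among constrained models.
#' @examples
#' m <- data.frame(scenario = c("S>A>F", "S>A, S>F", "full model"),
#'                 k = c(5, 5, 9), logLik = c(21.6, -6.0, 21.6))
#' rankModels(m)
#' @export
rankModels <- function(models, fullModelName = "full model") {
  stopifnot(is.data.frame(models), nrow(models) >= 1,
            all(c("scenario", "k") %in% names(models)))
  if (anyDuplicated(models$scenario))
    stop("duplicate scenario names: ",
         paste(unique(models$scenario[duplicated(models$scenario)]),
               collapse = ", "))
  out <- models
  if (!"aic" %in% names(out)) {
    if (!"logLik" %in% names(out)) stop("need a logLik or aic column")
    out$aic <- aic(out$logLik, out$k)
  }
  if (!"logLik" %in% names(out)) out$logLik <- (2 * out$k - out$aic) / 2
  out <- out[order(out$aic, out$scenario), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  constrained <- out$scenario != fullModelName
  bestC <- if (any(constrained)) min(out$aic[constrained]) else min(out$aic)
  out$deltaAIC <- out$aic - bestC
  out$best <- constrained & out$aic == bestC
  gap <- if (sum(constrained) >= 2) {
    a <- sort(out$aic[constrained])
    a[2] - a[1]
  } else 0
  attr(out, "deltaBestVsRunnerUp") <- gap
  rownames(out) <- NULL
  out
}

#' Load the bundled reference model-selection table
#'
#' Returns the transcription of a published 3-deme model-selection table
#' (scenario, parameter count, log-likelihood and printed AIC for a
#' mitochondrial and a nuclear locus) that ships with the package as
#' \code{inst/extdata/table1.tsv}. Used by the unit tests and the worked
#' examples of the AIC arithmetic.
#'
#' @param locus optional \code{"COI"} or \code{"hsp70"} to filter.
#' @return data.frame with columns \code{locus}, \code{scenario}, \code{k},
#'   \code{logLik}, \code{aic_printed}.
#' @export
referenceModelTable <- function(locus = NULL) {
  path <- system.file("extdata", "table1.tsv", package = "demeflow",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!is.null(locus)) tab <- tab[tab$locus == locus, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
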