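#' @import methods
NULL

#' Nucleotide substitution model
#'
#' Time-reversible substitution model (JC, HKY or GTR) with optional
#' discrete-gamma rate heterogeneity and a proportion of invariant sites.
#' Branch lengths are always interpreted as expected substitutions per site,
#' i.e. the rate matrix is normalised so that the mean substitution rate at
#' stationarity (including invariant sites) equals one.
#'
#' @slot name model family, one of \code{"JC"}, \code{"HKY"}, \code{"GTR"}.
#' @slot rates numeric(6), exchangeabilities in the order AC, AG, AT, CG, CT, GT.
#' @slot freqs numeric(4), stationary base frequencies in the order A, C, G, T.
#' @slot gammaShape numeric(1), shape of the discrete-gamma rate distribution;
#'   \code{Inf} disables rate heterogeneity.
#' @slot nGammaCat integer(1), number of discrete gamma categories.
#' @slot pInv numeric(1), proportion of invariant sites.
#' @exportClass SubstModel
setClass("SubstModel",
  representation(name = "character", rates = "numeric", freqs = "numeric",
                 gammaShape = "numeric", nGammaCat = "integer", pInv = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@rates) != 6L || any(object@rates <= 0))
      msg <- c(msg, "rates must be 6 positive exchangeabilities")
    if (length(object@freqs) != 4L || any(object@freqs <= 0) ||
        abs(sum(object@freqs) - 1) > 1e-9)
      msg <- c(msg, "freqs must be 4 positive values summing to 1 (within 1e-9)")
    if (length(object@gammaShape) != 1L || object@gammaShape <= 0)
      msg <- c(msg, "gammaShape must be a single positive value (Inf = no heterogeneity)")
    if (object@pInv < 0 || object@pInv >= 1)
      msg <- c(msg, "pInv must lie in [0, 1)")
    if (length(msg)) msg else TRUE
  })

#' Colonization scenario as a constrained migration model
#'
#' One colonization hypothesis over three demes, encoded as a constraint
#' mask over the 6 off-diagonal entries of the 3x3 backward migration-rate
#' matrix. A forward-time colonization edge X>Y frees the backward (coalescent)
#' lineage-migration rate Y->X; every other off-diagonal rate is pinned to
#' zero. The free parameter count is k = 3 (one theta per deme) + number of
#' free rates.
#'
#' @slot name scenario name, e.g. \code{"S>A>F"} or \code{"full model"}.
#' @slot demeLabels character(3), the deme labels.
#' @slot origin origin deme label (\code{NA} for the full model).
#' @slot edges character matrix with columns \code{from}, \code{to}: the
#'   forward-time colonization edges (0 rows for the full model).
#' @slot mask 3x3 logical matrix; \code{mask[i, j]} is \code{TRUE} when the
#'   backward migration rate from deme i to deme j is a free parameter.
#' @slot k integer(1), number of free parameters.
#' @exportClass MigrationScenario
setClass("MigrationScenario",
  representation(name = "character", demeLabels = "character",
                 origin = "character", edges = "matrix",
                 mask = "matrix", k = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@demeLabels) != 3L)
      msg <- c(msg, "exactly 3 deme labels are supported")
    if (!is.logical(object@mask) || !all(dim(object@mask) == c(3L, 3L)))
      msg <- c(msg, "mask must be a 3x3 logical matrix")
    else {
      if (any(diag(object@mask)))
        msg <- c(msg, "diagonal mask entries must be FALSE")
      if (object@k != 3L + sum(object@mask[row(object@mask) != col(object@mask)]))
        msg <- c(msg, "k must equal 3 + number of free off-diagonal rates")
    }
    if (length(msg)) msg else TRUE
  })

#' Structured-coalescent genealogy with migration history
#'
#' A timed binary coalescent tree for n sampled sequences, together with the
#' full deme path of every lineage. Node times are in scaled units (expected
#' substitutions per site), tips at time 0. Nodes are numbered 1..n for tips
#' and n+1..2n-1 for internal nodes; each node identifies the lineage running
#' from the node towards its parent.
#'
#' @slot tipLabels character(n), sample ids.
#' @slot demeLabels character, ordered deme labels.
#' @slot parent integer(2n-1), parent node of each lineage (0 for the root).
#' @slot time numeric(2n-1), node times (coalescence times for internal nodes).
#' @slot nodeDeme integer(2n-1), deme index at the node's own time (sampling
#'   deme for tips, deme of coalescence for internal nodes).
#' @slot paths list(2n-1) of numeric matrices with columns \code{time},
#'   \code{deme}: the backward migration events along each lineage, ordered by
#'   increasing time; a 0-row matrix means the lineage never migrates.
#' @exportClass Genealogy
setClass("Genealogy",
  representation(tipLabels = "character", demeLabels = "character",
                 parent = "integer", time = "numeric",
                 nodeDeme = "integer", paths = "list"),
  validity = function(object) .validGenealogy(object))

#' Simulation configuration for a synthetic multi-deme dataset
#'
#' Full specification of one synthetic locus: deme structure, colonization
#' scenario, scaled population sizes, backward migration rates, optional
#' recent expansion, mutation model and seed. Theta is the migrate-style
#' scaled population size theta_i = x * N_i * mu per site, where x is the
#' inheritance scalar (1 for a haploid maternally inherited locus, 4 for a
#' nuclear autosomal one); all times are scaled in expected substitutions per
#' site.
#'
#' @slot demeLabels character, ordered deme labels (default F, S, A).
#' @slot sampleSizes integer, sequences per deme (individuals per deme in
#'   diploid mode, which emits two phased allele copies each).
#' @slot scenario a \linkS4class{MigrationScenario}.
#' @slot theta numeric, per-deme scaled population size (per site).
#' @slot migrationRates 3x3 numeric matrix of backward lineage migration
#'   rates (per lineage per scaled time unit); entries masked by the scenario
#'   are zero.
#' @slot growth list; empty for constant size, else fields \code{onset}
#'   (scaled time of expansion onset) and \code{ratio} (ancestral/present
#'   size, < 1 for an expansion); sizes ramp linearly from the ancestral
#'   value at \code{onset} to the present value at time 0 in every deme.
#' @slot locusLength integer(1), number of sites.
#' @slot mutModel a \linkS4class{SubstModel}.
#' @slot ploidy \code{"haploid"} (maternal) or \code{"diploid"} (phased).
#' @slot seed integer(1), root seed; all stages derive their streams from it.
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(demeLabels = "character", sampleSizes = "integer",
                 scenario = "MigrationScenario", theta = "numeric",
                 migrationRates = "matrix", growth = "list",
                 locusLength = "integer", mutModel = "SubstModel",
                 ploidy = "character", seed = "integer"),
  validity = function(object) {
    msg <- character()
    nd <- length(object@demeLabels)
    if (length(object@sampleSizes) != nd || any(object@sampleSizes < 0))
      msg <- c(msg, "sampleSizes must be one non-negative count per deme")
    if (sum(object@sampleSizes) < 1)
      msg <- c(msg, "at least one sample is required")
    if (length(object@theta) != nd || any(object@theta <= 0))
      msg <- c(msg, "theta must be positive for every deme")
    if (!all(dim(object@migrationRates) == c(nd, nd)) ||
        any(object@migrationRates[row(object@migrationRates) != col(object@migrationRates)] < 0))
      msg <- c(msg, "migrationRates must be a square matrix with non-negative off-diagonals")
    if (any(object@migrationRates[!object@scenario@mask & row(object@migrationRates) != col(object@migrationRates)] != 0))
      msg <- c(msg, "rates masked by the scenario must be exactly 0")
    if (length(object@growth) && (!all(c("onset", "ratio") %in% names(object@growth)) ||
        object@growth$onset <= 0 || object@growth$ratio <= 0))
      msg <- c(msg, "growth must have positive onset and ratio")
    if (object@locusLength < 1L)
      msg <- c(msg, "locusLength must be >= 1")
    if (!object@ploidy %in% c("haploid", "diploid"))
      msg <- c(msg, "ploidy must be 'haploid' or 'diploid'")
    if (length(msg)) msg else TRUE
  })

#' Haplotype table
#'
#' Distinct sequences observed in an alignment with their per-deme counts;
#' the unit of network construction and diversity statistics.
#'
#' @slot sequences named character vector, haplotype id -> sequence.
#' @slot counts integer matrix, haplotype x deme.
#' @slot locusLength integer(1), alignment length.
#' @slot excludedColumns integer, 1-based alignment columns that contained
#'   non-ACGT symbols and were excluded from distances and site statistics.
#' @exportClass HaplotypeTable
setClass("HaplotypeTable",
  representation(sequences = "character", counts = "matrix",
                 locusLength = "integer", excludedColumns = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@sequences) != nrow(object@counts))
      msg <- c(msg, "one count row per haplotype required")
    if (any(object@counts < 0))
      msg <- c(msg, "counts must be non-negative")
    if (anyDuplicated(object@sequences))
      msg <- c(msg, "haplotypes must be distinct sequences")
    if (length(msg)) msg else TRUE
  })

#' Statistical-parsimony haplotype network
#'
#' Haplotype graph in which every edge is a single mutational step; pairs of
#' sampled haplotypes further apart than the connection limit remain in
#' separate components. Multi-step connections are routed through inferred
#' intermediate haplotypes of frequency 0.
#'
#' @slot graph an \code{igraph} object; vertex attributes \code{name},
#'   \code{frequency}, \code{inferred} and one \code{n_<deme>} count per deme.
#' @slot limit integer(1), connection limit in mutational steps.
#' @slot demeLabels character, deme labels.
#' @exportClass HaplotypeNetwork
setClass("HaplotypeNetwork",
  representation(graph = "ANY", limit = "integer", demeLabels = "character"))

#' Per-scenario maximum-likelihood fit
#'
#' Maximum-likelihood estimates of the scaled population sizes and free
#' migration rates of one colonization scenario, with the log-likelihood,
#' AIC and Monte-Carlo diagnostics of the estimator.
#'
#' @slot scenario scenario name.
#' @slot theta numeric, estimated per-deme theta.
#' @slot migrationRates 3x3 numeric, estimated backward rates (masked = 0).
#' @slot logLik numeric(1), estimated maximized log-likelihood.
#' @slot logLikSE numeric(1), Monte-Carlo standard error of \code{logLik}.
#' @slot k integer(1), free parameter count.
#' @slot aic numeric(1), 2k - 2 logLik.
#' @slot diagnostics list: sampler acceptance rate, importance-weight
#'   effective sample sizes, convergence flag.
#' @exportClass FitResult
setClass("FitResult",
  representation(scenario = "character", theta = "numeric",
                 migrationRates = "matrix", logLik = "numeric",
                 logLikSE = "numeric", k = "integer", aic = "numeric",
                 diagnostics = "list"),
  validity = function(object) {
    if (is.finite(object@logLik) &&
        abs(object@aic - (2 * object@k - 2 * object@logLik)) > 1e-9)
      "aic must equal 2k - 2 logLik" else TRUE
  })

#' Strict molecular clock
#'
#' @slot rate numeric(1), substitution rate in changes per site per year.
#' @exportClass ClockModel
setClass("ClockModel", representation(rate = "numeric"),
  validity = function(object) {
    if (length(object@rate) != 1L || !is.finite(object@rate) || object@rate <= 0)
      "clock rate must be a single positive number" else TRUE
  })

#' Priors of the coalescent skyline model
#'
#' @slot changePointPriorMean numeric(1), mean of the (truncated) Poisson
#'   prior on the number of population-size change points.
#' @slot maxChangePoints integer(1), truncation of the change-point count.
#' @slot sizeBounds numeric(2), bounds of the population-size prior
#'   (effective individuals).
#' @slot sizePrior \code{"loguniform"} (default) or \code{"uniform"} on
#'   \code{sizeBounds}.
#' @exportClass SkylinePriors
setClass("SkylinePriors",
  representation(changePointPriorMean = "numeric", maxChangePoints = "integer",
                 sizeBounds = "numeric", sizePrior = "character"),
  validity = function(object) {
    msg <- character()
    if (object@changePointPriorMean <= 0)
      msg <- c(msg, "change-point prior mean must be positive")
    if (length(object@sizeBounds) != 2L || any(object@sizeBounds <= 0) ||
        diff(object@sizeBounds) <= 0)
      msg <- c(msg, "sizeBounds must be positive and increasing")
    if (!object@sizePrior %in% c("loguniform", "uniform"))
      msg <- c(msg, "sizePrior must be 'loguniform' or 'uniform'")
    if (length(msg)) msg else TRUE
  })

#' Posterior of the coalescent skyline analysis
#'
#' Retained MCMC samples of the genealogy summaries and population-size
#' trajectory, with expansion-onset summaries in years before present.
#'
#' @slot samples data.frame, one retained iteration per row: root height
#'   (years), number of change points, onset (years, NA when the sample shows
#'   no >= 2-fold expansion), modern and ancestral size, log-likelihood and
#'   log-prior.
#' @slot trajectories list of per-sample trajectory matrices (time in years,
#'   size in individuals).
#' @slot onsetSummary numeric(3): median and 95% credible bounds of the
#'   expansion onset in years before present.
#' @slot clockRate numeric(1), substitutions per site per year.
#' @slot ess named numeric, effective sample sizes of key traces.
#' @slot converged logical(1).
#' @exportClass SkylinePosterior
setClass("SkylinePosterior",
  representation(samples = "data.frame", trajectories = "list",
                 onsetSummary = "numeric", clockRate = "numeric",
                 ess = "numeric", converged = "logical"))

#' Bayes-factor comparison of demographic models
#'
#' @slot logML named numeric, log marginal likelihood per model.
#' @slot logBF numeric(1), log Bayes factor (first model minus second).
#' @slot se numeric(1), combined Monte-Carlo standard error.
#' @exportClass BayesFactorResult
setClass("BayesFactorResult",
  representation(logML = "numeric", logBF = "numeric", se = "numeric"))
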