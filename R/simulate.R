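#' Create a simulation configuration
#'
#' Assembles a \linkS4class{SimulationConfig} with study-shaped defaults:
#' three demes F/S/A, a sequential colonization scenario with origin S
#' (forward S>A then A>F), theta = 0.01 per deme per site, strong
#' directional backward migration (rate 300 on each colonization route),
#' and no growth.
#'
#' @param sampleSizes named integer vector, sequences per deme (individuals
#'   per deme in diploid mode); names are the deme labels.
#' @param scenario a \linkS4class{MigrationScenario}; default the sequential
#'   S>A>F analogue on the given labels.
#' @param theta per-deme scaled population size (recycled).
#' @param migrationRate value(s) for the free backward rates (recycled), or a
#'   full 3x3 matrix via \code{migrationRates}.
#' @param migrationRates optional explicit 3x3 backward rate matrix.
#' @param growth empty list for constant size, or
#'   \code{list(onset =, ratio =)}: sizes ramp linearly from
#'   \code{ratio * theta} at scaled time \code{onset} to \code{theta} at the
#'   present (ratio < 1 is an expansion).
#' @param locusLength number of sites.
#' @param mutModel a \linkS4class{SubstModel}.
#' @param ploidy \code{"haploid"} or \code{"diploid"} (phased, two allele
#'   copies emitted per individual).
#' @param seed integer root seed.
#' @return a \linkS4class{SimulationConfig}.
#' @examples
#' simulationConfig(sampleSizes = c(F = 5, S = 5, A = 5), seed = 1)
#' @export
simulationConfig <- function(sampleSizes = c(F = 20L, S = 20L, A = 20L),
                             scenario = NULL, theta = 0.01,
                             migrationRate = 300, migrationRates = NULL,
                             growth = list(), locusLength = 600L,
                             mutModel = substModel("HKY", kappa = 4,
                               freqs = c(0.25, 0.15, 0.2, 0.4)),
                             ploidy = "haploid", seed = 1L) {
  labs <- names(sampleSizes)
  if (is.null(labs)) stop("sampleSizes must be named by deme")
  if (is.null(scenario)) {
    if (length(labs) != 3L) stop("a scenario must be given for non-3-deme runs")
    scenario <- migrationScenario(labs,
      edges = rbind(c(labs[2], labs[3]), c(labs[3], labs[1])),
      origin = labs[2])
  }
  if (!identical(scenario@demeLabels, labs))
    stop("scenario deme labels must match names(sampleSizes)")
  if (is.null(migrationRates))
    migrationRates <- scenarioRates(scenario, migrationRate)
  new("SimulationConfig", demeLabels = labs,
      sampleSizes = as.integer(sampleSizes), scenario = scenario,
      theta = rep_len(as.numeric(theta), length(labs)),
      migrationRates = migrationRates, growth = growth,
      locusLength = as.integer(locusLength), mutModel = mutModel,
      ploidy = ploidy, seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf("SimulationConfig: %s sequences in demes %s, scenario '%s', L = %d, %s, seed %d\n",
              paste(object@sampleSizes, collapse = "/"),
              paste(object@demeLabels, collapse = "/"),
              object@scenario@name, object@locusLength, object@ploidy,
              object@seed))
  if (length(object@growth))
    cat(sprintf("  growth: linear ramp, onset %.4g, ancestral/present ratio %.3g\n",
                object@growth$onset, object@growth$ratio))
})

## theta multiplier at scaled time t under the two-epoch linear-ramp growth.
growthFactor <- function(growth, t) {
  if (!length(growth)) return(1)
  r <- growth$ratio
  ifelse(t >= growth$onset, r, 1 + (r - 1) * t / growth$onset)
}

## Core structured-coalescent simulation. tipDeme: integer deme index per
## sample; theta/M per deme; growth as in SimulationConfig. Caller controls
## the RNG state. Time-varying coalescence rates are handled by thinning.
simCoalescent <- function(tipLabels, tipDeme, demeLabels, theta, M,
                          growth = list()) {
  n <- length(tipDeme)
  nd <- length(demeLabels)
  nnode <- max(1L, 2L * n - 1L)
  parent <- integer(nnode)
  time <- numeric(nnode)
  nodeDeme <- integer(nnode)
  nodeDeme[seq_len(n)] <- tipDeme
  paths <- rep(list(matrix(numeric(0), 0, 2,
                           dimnames = list(NULL, c("time", "deme")))), nnode)
  if (n == 1L)
    return(new("Genealogy", tipLabels = tipLabels, demeLabels = demeLabels,
               parent = parent, time = time, nodeDeme = nodeDeme,
               paths = paths))
  sampled <- tabulate(tipDeme, nd) > 0
  if (!scenarioConnected(M > 0, sampled))
    stop("non-coalescible configuration: sampled demes cannot reach a common deme")
  thetaFloor <- theta * min(1, growthFactor(growth, Inf))
  outRate <- rowSums(M)
  active <- seq_len(n)          # node ids of live lineages
  deme <- tipDeme               # their current demes
  pathAcc <- vector("list", nnode)
  t <- 0
  nxt <- n + 1L
  while (length(active) > 1L) {
    k <- tabulate(deme, nd)
    coalMax <- k * (k - 1) / thetaFloor
    migTot <- k * outRate
    lamMax <- sum(coalMax) + sum(migTot)
    if (lamMax <= 0)
      stop("non-coalescible configuration: lineages are stranded in disconnected demes")
    t <- t + rexp(1, lamMax)
    coalNow <- k * (k - 1) / (theta * growthFactor(growth, t))
    lam <- sum(coalNow) + sum(migTot)
    if (runif(1) > lam / lamMax) next
    rates <- c(coalNow, migTot)
    ev <- sample.int(2L * nd, 1L, prob = rates)
    if (ev <= nd) { # coalescence in deme ev
      pair <- sample(which(deme == ev), 2L)
      a <- active[pair[1]]; b <- active[pair[2]]
      parent[a] <- parent[b] <- nxt
      time[nxt] <- t
      nodeDeme[nxt] <- ev
      active <- c(active[-pair], nxt)
      deme <- c(deme[-pair], ev)
      nxt <- nxt + 1L
    } else {        # migration out of deme ev - nd
      i <- ev - nd
      cand <- which(deme == i)
      w <- if (length(cand) == 1L) cand else sample(cand, 1L)
      j <- sample.int(nd, 1L, prob = M[i, ])
      pathAcc[[active[w]]] <- c(pathAcc[[active[w]]], t, j)
      deme[w] <- j
    }
  }
  for (v in seq_len(nnode)) {
    if (!is.null(pathAcc[[v]])) {
      m <- matrix(pathAcc[[v]], ncol = 2, byrow = TRUE,
                  dimnames = list(NULL, c("time", "deme")))
      ## events recorded while the lineage was live, i.e. within its lifetime
      paths[[v]] <- m
    }
  }
  new("Genealogy", tipLabels = tipLabels, demeLabels = demeLabels,
      parent = parent, time = time, nodeDeme = nodeDeme, paths = paths)
}

#' Simulate a structured-coalescent genealogy
#'
#' Runs the backward-in-time structured coalescent for the samples of a
#' configuration: within deme i, any pair of lineages coalesces at rate
#' 2/theta_i (so j lineages coalesce at rate j(j-1)/theta_i); a lineage in
#' deme i relocates to deme j at the backward rate M[i, j]. Under a growth
#' specification the coalescence rates are time-varying (simulated exactly by
#' thinning). All times are in expected substitutions per site.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param seed optional integer seed overriding \code{config@seed}.
#' @return a \linkS4class{Genealogy}.
#' @examples
#' g <- simulateGenealogy(simulationConfig(c(F = 3, S = 3, A = 3), seed = 7))
#' genealogyStats(g)$migrations
#' @export
simulateGenealogy <- function(config, seed = config@seed) {
  validObject(config)
  set.seed(as.integer(seed))
  td <- rep(seq_along(config@demeLabels), config@sampleSizes)
  if (config@ploidy == "diploid") td <- rep(td, each = 2L)
  labs <- makeTipLabels(config)
  simCoalescent(labs, td, config@demeLabels, config@theta,
                config@migrationRates, config@growth)
}

makeTipLabels <- function(config) {
  per <- config@sampleSizes
  ids <- unlist(lapply(seq_along(per), function(i)
    if (per[i] > 0) sprintf("%s%03d|%s", config@demeLabels[i],
                            seq_len(per[i]), config@demeLabels[i])
    else character(0)))
  if (config@ploidy == "diploid")
    ids <- as.vector(t(outer(ids, c("a1", "a2"), paste, sep = "|")))
  ids
}

#' Generate a complete synthetic dataset
#'
#' Simulates a genealogy and sequences under a configuration and writes a
#' FASTA alignment, a tab-separated sample-to-deme map and a JSON truth
#' record (generating scenario, theta, rates, growth, seeds) for
#' parameter-recovery tests. Byte-identical under identical configuration
#' and seed.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param dir output directory (created if needed).
#' @param basename stem for the three output files.
#' @return invisibly, a list with the alignment (named character vector), the
#'   deme map (data.frame), the truth record and the file paths.
#' @export
generateDataset <- function(config, dir = ".", basename = "synthetic") {
  validObject(config)
  sim <- simulateDataset(config)
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", dir)
  paths <- file.path(dir, paste0(basename, c(".fasta", ".demes.tsv", ".truth.json")))
  writeFastaAlignment(sim$alignment, paths[1])
  utils::write.table(sim$demeMap, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(sim$truth, paths[3], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(sim, list(files = paths)))
}

## In-memory dataset generation shared by generateDataset() and the
## experiment drivers. Derives independent sub-streams for the genealogy and
## the mutations from the root seed.
simulateDataset <- function(config) {
  seedG <- (config@seed * 2654435761) %% 2147483587 + 1
  seedM <- (config@seed * 97561 + 13) %% 2147483587 + 1
  gen <- simulateGenealogy(config, seed = seedG)
  aln <- mutateOnGenealogy(gen, config@mutModel, config@locusLength,
                           seed = seedM)
  demeMap <- data.frame(
    sample_id = gen@tipLabels,
    deme = config@demeLabels[tipDemeIndex(gen)],
    stringsAsFactors = FALSE)
  truth <- list(
    scenario = config@scenario@name,
    demes = config@demeLabels,
    sample_sizes = as.integer(config@sampleSizes),
    theta = config@theta,
    migration_rates = config@migrationRates,
    growth = if (length(config@growth)) config@growth else NULL,
    locus_length = config@locusLength,
    mutation_model = config@mutModel@name,
    ploidy = config@ploidy,
    seed = config@seed,
    derived_seeds = c(genealogy = seedG, mutation = seedM))
  list(alignment = aln, demeMap = demeMap, genealogy = gen, truth = truth)
}

tipDemeIndex <- function(gen) gen@nodeDeme[seq_along(gen@tipLabels)]

#' Simulate a single-population expansion dataset
#'
#' Coalescent simulation of one panmictic population that expanded
#' \code{1/ratio}-fold, with the expansion onset given in scaled time
#' (substitutions per site); used to exercise the skyline machinery.
#'
#' @param n number of sequences.
#' @param locusLength sites.
#' @param theta present-day scaled population size per site; the default
#'   0.01 with a ten-fold expansion gives shallow intraspecific diversity
#'   (about 10-15 segregating sites at n = 60, L = 604, with the expansion
#'   onset roughly a third of the tree depth, as in shallow range-expansion
#'   data).
#' @param onset expansion onset in substitutions per site.
#' @param ratio ancestral/present size ratio (< 1 for expansion).
#' @param mutModel a \linkS4class{SubstModel}.
#' @param seed integer seed.
#' @return list with \code{alignment}, \code{genealogy} and \code{truth}.
#' @examples
#' d <- simulateExpansionDataset(n = 10, seed = 1)
#' range(nchar(d$alignment))
#' @export
simulateExpansionDataset <- function(n, locusLength = 600L, theta = 0.01,
                                     onset = 3.424e-4, ratio = 0.1,
                                     mutModel = substModel("HKY", kappa = 4,
                                       freqs = c(0.25, 0.15, 0.2, 0.4)),
                                     seed = 1L) {
  growth <- if (is.finite(onset) && ratio != 1)
    list(onset = onset, ratio = ratio) else list()
  seedG <- (as.integer(seed) * 2654435761) %% 2147483587 + 1
  seedM <- (as.integer(seed) * 97561 + 13) %% 2147483587 + 1
  set.seed(seedG)
  gen <- simCoalescent(sprintf("P%03d", seq_len(n)), rep(1L, n), "P",
                       theta, matrix(0, 1, 1), growth)
  aln <- mutateOnGenealogy(gen, mutModel, locusLength, seed = seedM)
  list(alignment = aln, genealogy = gen,
       truth = list(n = n, locus_length = locusLength, theta = theta,
                    onset = onset, ratio = ratio, seed = seed))
}

#' Study-shaped preset configurations
#'
#' Ready-made configurations emulating the two empirical data shapes the
#' package is designed around: a ~600 bp haploid maternally inherited locus
#' typed for 138 individuals across demes F/S/A (34/52/52), and a ~220 bp
#' diploid nuclear locus typed for 38 individuals (10/14/14), both generated
#' under sequential colonization S>A>F with a recent ten-fold expansion.
#'
#' @param locus \code{"mito"} or \code{"nuclear"}.
#' @param seed integer root seed.
#' @return a \linkS4class{SimulationConfig}.
#' @examples
#' presetConfig("mito", seed = 1)
#' @export
presetConfig <- function(locus = c("mito", "nuclear"), seed = 1L) {
  locus <- match.arg(locus)
  growth <- list(onset = 3.424e-4, ratio = 0.1)
  ## theta and route rates are calibrated to the stated data shape: about
  ## 13-18 haplotypes and 15-30 segregating sites among 138 mitochondrial
  ## sequences, with haplotype sharing between demes
  if (locus == "mito")
    simulationConfig(sampleSizes = c(F = 34L, S = 52L, A = 52L),
                     theta = 0.005, migrationRate = 150, growth = growth,
                     locusLength = 604L, ploidy = "haploid", seed = seed)
  else
    simulationConfig(sampleSizes = c(F = 10L, S = 14L, A = 14L),
                     theta = 0.008, migrationRate = 150, growth = growth,
                     locusLength = 219L, ploidy = "diploid", seed = seed)
}
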