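#' Run the full phylogeographic analysis pipeline
#'
#' Drives the analysis stages over one dataset: (optional) simulation,
#' haplotype statistics, statistical-parsimony network, migration-model
#' fitting over all colonization scenarios, AIC model selection, and
#' (optional) coalescent skyline dating. Writes all results beneath
#' \code{outDir} with a provenance block (package version, seed) in the
#' JSON outputs. Every output is regenerable from the inputs and the seed
#' alone.
#'
#' @param fasta path to an aligned FASTA file (ignored when \code{config}
#'   is given).
#' @param demeMap path to the tab-separated sample-to-deme map.
#' @param config optional \linkS4class{SimulationConfig}; when supplied the
#'   dataset is simulated first and written next to the results.
#' @param outDir output directory.
#' @param stages character subset of \code{c("stats", "network", "fit",
#'   "skyline")}.
#' @param fitSettings see \code{\link{fitSettings}}.
#' @param clock a \linkS4class{ClockModel} for the skyline stage.
#' @param skylineSettings see \code{\link{skylineSettings}}.
#' @param seed root seed.
#' @param verbose emit stage-tagged progress lines to standard error.
#' @return invisibly, a list with the per-stage results.
#' @export
runPipeline <- function(fasta = NULL, demeMap = NULL, config = NULL,
                        outDir = "demeflow-results",
                        stages = c("stats", "network", "fit"),
                        fitSettings = demeflow::fitSettings(),
                        clock = clockModel(),
                        skylineSettings = demeflow::skylineSettings(),
                        seed = 1L, verbose = TRUE) {
  say <- function(stage, ...) if (verbose)
    message(format(Sys.time(), "%H:%M:%S "), "[", stage, "] ", ...)
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outDir)
  prov <- provenance(seed)
  results <- list()
  if (!is.null(config)) {
    say("simulate", "generating synthetic dataset (seed ", config@seed, ")")
    gd <- generateDataset(config, dir = outDir, basename = "dataset")
    aln <- gd$alignment
    dm <- gd$demeMap
    results$simulate <- gd
  } else {
    if (is.null(fasta) || is.null(demeMap))
      stop("either a configuration or fasta + demeMap paths are required")
    aln <- readFastaAlignment(fasta)
    dm <- readDemeMap(demeMap, alignment = aln)
  }
  if ("stats" %in% stages) {
    say("stats", "haplotype collapse and diversity statistics")
    tab <- collapseHaplotypes(aln, dm)
    demes <- colnames(tab@counts)
    stats <- data.frame(
      deme = c(demes, "pooled"),
      n = c(colSums(tab@counts), sum(tab@counts)),
      haplotypes = c(vapply(demes, function(d) sum(tab@counts[, d] > 0), 1L),
                     nrow(tab@counts)),
      haplotype_diversity = c(vapply(demes, function(d)
        haplotypeDiversity(tab@counts[, d]), 1),
        haplotypeDiversity(rowSums(tab@counts))),
      nucleotide_diversity = c(vapply(demes, function(d)
        nucleotideDiversity(tab, d), 1), nucleotideDiversity(tab)))
    seg <- classifySegregatingSites(aln)
    utils::write.table(stats, file.path(outDir, "statistics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(provenance = prov,
                              segregating_sites = as.list(seg)),
                         file.path(outDir, "sites.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    results$stats <- list(table = tab, statistics = stats,
                          segregating = seg)
  }
  if ("network" %in% stages) {
    say("network", "statistical-parsimony network")
    tab <- results$stats$table
    if (is.null(tab)) tab <- collapseHaplotypes(aln, dm)
    net <- buildNetwork(tab)
    writeNetworkGraphML(net, file.path(outDir, "network.graphml"))
    results$network <- net
  }
  if ("fit" %in% stages) {
    say("fit", "fitting all colonization scenarios (this is the slow stage)")
    fitSettings$seed <- as.integer(seed)
    fit <- fitAllScenarios(aln, dm, settings = fitSettings)
    utils::write.table(
      fit$table[, c("scenario", "k", "logLik", "aic", "deltaAIC", "rank")],
      file.path(outDir, "model_selection.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(provenance = prov,
           best = fit$table$scenario[fit$table$best][1],
           deltaAIC_best_vs_runnerup = attr(fit$table, "deltaBestVsRunnerUp"),
           table = fit$table),
      file.path(outDir, "model_selection.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    results$fit <- fit
  }
  if ("skyline" %in% stages) {
    say("skyline", "coalescent skyline dating")
    post <- skylineMcmc(aln, clock = clock, settings = skylineSettings,
                        seed = seed)
    jsonlite::write_json(
      list(provenance = prov, clock_rate = clock@rate,
           onset_years = as.list(post@onsetSummary),
           ess = as.list(post@ess), converged = post@converged),
      file.path(outDir, "skyline.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    tr <- do.call(rbind, lapply(seq_along(post@trajectories), function(i)
      cbind(sample = i, post@trajectories[[i]])))
    utils::write.table(tr, file.path(outDir, "skyline_trajectories.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    results$skyline <- post
  }
  say("done", "outputs in ", outDir)
  invisible(results)
}
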