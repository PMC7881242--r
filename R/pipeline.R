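# End-to-end orchestration driven by a single configuration list (plain R
# list or YAML file). All randomness flows from one root seed through named
# substreams; every writer records the seed and a config hash in a JSON
# manifest, so identical configurations reproduce outputs byte for byte.

#' Read a run configuration from YAML
#'
#' The configuration mirrors [defaultRunConfig()]: either synthetic
#' generator settings or input CSV paths, plus discretization / filter /
#' search / bootstrap parameters, periods, seeds and an output directory.
#'
#' @param path YAML file path.
#' @return A config list with defaults filled in.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  utils::modifyList(defaultRunConfig(), cfg)
}

#' Default run configuration
#'
#' @return Named list of pipeline settings: `seed` (root seed), `alpha`
#'   (contingency filter), `ess`, `maxParents`, `restarts`, `nBoot`,
#'   `bootFrac`, `threshold` (`"valley"` or numeric), `periods`
#'   (see [decadePeriods()]), `outDir` (`NA` = no files written), and the
#'   synthetic-generation block `synthetic`.
#' @export
defaultRunConfig <- function() {
  list(seed = 1L, alpha = 0.25, ess = 1, maxParents = 3, restarts = 10,
       nBoot = 100, bootFrac = 0.9, threshold = "valley",
       periods = decadePeriods(), outDir = NA_character_,
       synthetic = list(nYears = 30, startYear = 1971,
                        regimeShiftYear = 1985))
}

.substreamSeed <- function(root, k) (as.integer(root) * 101L + k) %% 2147483647L

.cfgScoreConfig <- function(cfg) {
  scoreConfig(ess = cfg$ess, maxParents = cfg$maxParents,
              restarts = cfg$restarts)
}

.writeManifest <- function(cfg, outDir, files, stage) {
  if (is.na(outDir)) return(invisible(NULL))
  tmp <- tempfile()
  saveRDS(rapply(cfg, as.character, how = "replace"), tmp)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  jsonlite::write_json(list(stage = stage, seed = cfg$seed,
                            configHash = hash, files = files),
                       file.path(outDir, paste0(stage, ".manifest.json")),
                       auto_unbox = TRUE)
  invisible(NULL)
}

# Shared learning chain: discretize -> filter -> bootstrap -> consensus.
.learnConsensus <- function(st, cfg, seed, variables = NULL) {
  d <- discretizeThreeBins(st)
  vars <- if (is.null(variables))
    setdiff(variableNames(st), degenerateVariables(d)) else variables
  bl <- contingencyFilter(d, alpha = cfg$alpha, variables = vars)
  nets <- bootstrapNetworks(d, bl, .cfgScoreConfig(cfg),
                            nBoot = cfg$nBoot, frac = cfg$bootFrac,
                            seed = seed)
  summ <- summarizeEdges(nets)
  cons <- suppressWarnings(
    consensusNetwork(summ, threshold = cfg$threshold, nBoot = cfg$nBoot))
  list(discrete = d, blacklist = bl, networks = nets, consensus = cons)
}

#' Spatial (cruise snapshot) network analysis
#'
#' Grouping (if taxa are present), discretization, contingency filtering,
#' bootstrap structure learning and consensus extraction on a spatial
#' station table.
#'
#' @param cfg config list (see [defaultRunConfig()]).
#' @param table optional [SampleTable-class]; by default a synthetic
#'   snapshot from [spatialSpec()] under the config seed.
#' @return List with `table`, `discrete`, `blacklist`, `consensus`
#'   ([ConsensusNetwork-class]) and `network` (consensus reduced to a
#'   fitted [BayesNet-class]).
#' @export
runSpatial <- function(cfg = defaultRunConfig(), table = NULL) {
  if (is.null(table)) {
    sp <- spatialSpec(seed = .substreamSeed(cfg$seed, 1L))
    table <- sampleSpatial(sp)
  }
  if (!nrow(table)) stop("empty input table")
  if (any(variableTypes(table) == "taxon"))
    table <- applyGrouping(table)
  res <- .learnConsensus(table, cfg, .substreamSeed(cfg$seed, 2L))
  net <- consensusToNetwork(res$consensus,
                            nodes = setdiff(variableNames(table),
                                            degenerateVariables(res$discrete)),
                            maxParents = cfg$maxParents)
  net <- fitCPTs(net, res$discrete, .cfgScoreConfig(cfg))
  out <- list(table = table, discrete = res$discrete,
              blacklist = res$blacklist, consensus = res$consensus,
              network = net)
  if (!is.na(cfg$outDir)) {
    dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
    files <- c(writeEdgeList(res$consensus,
                             file.path(cfg$outDir, "spatial_edges.csv")),
               writeGraphML(res$consensus,
                            file.path(cfg$outDir, "spatial.graphml")))
    .writeManifest(cfg, cfg$outDir, files, "spatial")
  }
  out
}

#' Decadal (weekly time-series) network analysis
#'
#' Grouping, weekly averaging, temporal split, then the learning chain per
#' period, plus pairwise chi-squared comparisons of edge occurrence.
#'
#' @param cfg config list.
#' @param table optional sample-level dated [SampleTable-class]; by default
#'   a synthetic series from [syntheticSpec()] under the config seed.
#' @return List with `weekly` (the averaged table), per-period `results`
#'   (each as in [runSpatial()] plus a fitted `network`), and `comparisons`
#'   (data.frame of pairwise p-values).
#' @export
runDecades <- function(cfg = defaultRunConfig(), table = NULL) {
  if (is.null(table)) {
    spArgs <- cfg$synthetic
    spArgs$seed <- .substreamSeed(cfg$seed, 3L)
    table <- sampleTimeseries(do.call(syntheticSpec, spArgs))
  }
  if (any(variableTypes(table) == "taxon"))
    table <- applyGrouping(table)
  weekly <- weeklyAverage(table)
  splits <- temporalSplit(weekly, cfg$periods)
  results <- lapply(seq_along(splits), function(i) {
    res <- .learnConsensus(splits[[i]], cfg,
                           .substreamSeed(cfg$seed, 10L + i))
    net <- consensusToNetwork(
      res$consensus,
      nodes = setdiff(variableNames(weekly),
                      degenerateVariables(res$discrete)),
      maxParents = cfg$maxParents)
    res$network <- fitCPTs(net, res$discrete, .cfgScoreConfig(cfg))
    res
  })
  names(results) <- names(splits)
  labs <- names(splits)
  comparisons <- NULL
  if (length(labs) > 1L) {
    prs <- utils::combn(labs, 2)
    comparisons <- data.frame(
      a = prs[1, ], b = prs[2, ],
      p = apply(prs, 2, function(pr)
        comparePeriods(edgeSummaries(results[[pr[1]]]$consensus),
                       edgeSummaries(results[[pr[2]]]$consensus),
                       nBoot = cfg$nBoot)))
  }
  if (!is.na(cfg$outDir)) {
    dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
    files <- unlist(lapply(labs, function(lbl) c(
      writeEdgeList(results[[lbl]]$consensus,
                    file.path(cfg$outDir, sprintf("decade_%s_edges.csv", lbl))),
      writeGraphML(results[[lbl]]$consensus,
                   file.path(cfg$outDir, sprintf("decade_%s.graphml", lbl))))))
    .writeManifest(cfg, cfg$outDir, files, "decades")
  }
  list(weekly = weekly, results = results, comparisons = comparisons)
}

#' Historic jellyfish abundance inference
#'
#' Composes [runSpatial()] and [runDecades()] (or accepts their results),
#' transposes the jellyfish dependencies onto each decadal network and
#' queries the target posterior under LOW and HIGH evidence states.
#'
#' @param cfg config list.
#' @param spatial,decades optional precomputed results of [runSpatial()] /
#'   [runDecades()].
#' @param target queried node (default `"Aurelia aurita"`).
#' @param evidenceNode evidence variable (default `"SST"`).
#' @return The posterior table from [historicAbundance()].
#' @export
runHistoricInference <- function(cfg = defaultRunConfig(), spatial = NULL,
                                 decades = NULL, target = "Aurelia aurita",
                                 evidenceNode = "SST") {
  if (is.null(spatial)) spatial <- runSpatial(cfg)
  if (is.null(decades)) decades <- runDecades(cfg)
  nets <- lapply(decades$results, `[[`, "network")
  # Imported nodes = spatial variables the decadal networks lack (the
  # jellyfish); re-orient their consensus edges toward them before fitting,
  # so their spatial dependencies transpose as parent edges.
  imported <- setdiff(variableNames(spatial$table),
                      c(netNodes(nets[[1]]),
                        degenerateVariables(spatial$discrete)))
  spatialNet <- consensusToNetwork(
    spatial$consensus,
    nodes = setdiff(variableNames(spatial$table),
                    degenerateVariables(spatial$discrete)),
    maxParents = cfg$maxParents, sinks = imported)
  spatialNet <- fitCPTs(spatialNet, spatial$discrete, .cfgScoreConfig(cfg))
  tab <- historicAbundance(nets, spatialNet, target, evidenceNode,
                           importedNodes = imported)
  if (!is.na(cfg$outDir)) {
    dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
    f <- file.path(cfg$outDir, "historic_abundance.csv")
    utils::write.csv(tab, f, row.names = FALSE, quote = FALSE)
    .writeManifest(cfg, cfg$outDir, f, "historic")
  }
  tab
}

#' Forced-edge ranking of groups against an annual catch series
#'
#' September-anchored yearly averages are formed per period, the catch is
#' attached (year `t+1` against the Sep `t` to Aug `t+1` window by default,
#' configurable via `lagYears`), the joined table is discretized per
#' period, and each group is ranked by forced-edge score change.
#'
#' @param cfg config list.
#' @param table optional sample-level dated [SampleTable-class] (defaults
#'   to the same synthetic series as [runDecades()]).
#' @param catch data.frame with columns `year`, `catch`; by default a
#'   synthetic series driven by Temperate Oceanic zooplankton.
#' @param lagYears catch year minus zooplankton window start year
#'   (default 1).
#' @return Named list per period of ranking data.frames from
#'   [rankGroups()].
#' @export
runHerringRanking <- function(cfg = defaultRunConfig(), table = NULL,
                              catch = NULL, lagYears = 1L) {
  if (is.null(table)) {
    spArgs <- cfg$synthetic
    spArgs$seed <- .substreamSeed(cfg$seed, 3L)
    table <- sampleTimeseries(do.call(syntheticSpec, spArgs))
  }
  if (any(variableTypes(table) == "taxon"))
    table <- applyGrouping(table)
  if (is.null(catch))
    catch <- syntheticHerring(table, "Temperate Oceanic")
  yearly <- yearlyAverageFromSeptember(table)
  yrs <- as.integer(rownames(sampleValues(yearly)))
  idx <- match(yrs + lagYears, catch$year)
  keep <- !is.na(idx)
  vals <- cbind(sampleValues(yearly)[keep, , drop = FALSE],
                Herring = catch$catch[idx[keep]])
  joined <- SampleTable(vals, date = sampleDates(yearly)[keep],
                        varType = c(variableTypes(yearly),
                                    Herring = "env"))
  splits <- temporalSplit(joined, cfg$periods)
  out <- lapply(splits, function(st) {
    d <- suppressWarnings(discretizeThreeBins(st))
    rankGroups(d, "Herring", config = .cfgScoreConfig(cfg))
  })
  if (!is.na(cfg$outDir)) {
    dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
    files <- vapply(names(out), function(lbl) {
      f <- file.path(cfg$outDir, sprintf("ranking_%s.csv", lbl))
      utils::write.csv(out[[lbl]], f, row.names = FALSE, quote = FALSE)
      f
    }, character(1))
    .writeManifest(cfg, cfg$outDir, files, "ranking")
  }
  out
}
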