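# Synthetic CPR-like weekly series and cruise-like spatial snapshots from a
# known ground-truth network: latent ZERO/LOW/HIGH states are drawn by
# ancestral sampling, group state probabilities are tilted by a seasonal
# cycle, and counts are emitted through a zero-inflated negative binomial.
# Emission defaults are chosen so the weekly-averaged tables carry roughly
# the zero mass typical of grouped CPR data (~39%).

.posCPT <- function() {
  m <- cbind(c(0.70, 0.22, 0.08), c(0.30, 0.45, 0.25), c(0.06, 0.24, 0.70))
  dimnames(m) <- list(stateLevels(), stateLevels())
  m
}
.negCPT <- function() .posCPT()[, 3:1]
# Children of SST: parent occupies LOW/HIGH only; ZERO column is a uniform
# placeholder.
.posCPT2 <- function() {
  m <- cbind(rep(1 / 3, 3), c(0.60, 0.30, 0.10), c(0.10, 0.30, 0.60))
  dimnames(m) <- list(stateLevels(), stateLevels())
  m
}
.negCPT2 <- function() .posCPT2()[, c(1, 3, 2)]
# Sharper conditionals for the cruise-like snapshot: net hauls resolve
# abundance states far better than weekly-averaged silk-transect counts.
.posCPTSharp <- function() {
  m <- cbind(c(0.86, 0.11, 0.03), c(0.15, 0.70, 0.15), c(0.03, 0.11, 0.86))
  dimnames(m) <- list(stateLevels(), stateLevels())
  m
}
.negCPTSharp <- function() .posCPTSharp()[, 3:1]
.rootP <- function() c(ZERO = 0.34, LOW = 0.33, HIGH = 0.33)

# Build a truth BayesNet from node -> list(parents, cpt) definitions.
.truthNet <- function(defs) {
  nodes <- names(defs)
  edges <- do.call(rbind, lapply(nodes, function(v) {
    pa <- defs[[v]]$parents
    if (length(pa)) cbind(pa, rep(v, length(pa))) else NULL
  }))
  if (is.null(edges)) edges <- matrix(character(0), 0, 2)
  net <- BayesNet(nodes, edges)
  net@cpts <- lapply(defs, function(d) {
    probs <- d$cpt
    if (is.null(probs)) return(NULL)   # externally driven node (SST, NAOI)
    attr(probs, "parents") <- d$parents
    q <- if (is.matrix(probs)) ncol(probs) else 1L
    attr(probs, "configWeights") <- rep(1 / q, q)
    probs
  })
  net
}

#' Specification of a synthetic CPR-like weekly time series
#'
#' Defines the ground-truth dependency network over the five biogeographic
#' groups plus chlorophyll index, SST and NAO index, the seasonal cycle,
#' the count-emission model and the mid-series regime shift. The defaults
#' emulate a 30-year Irish Sea series: sinusoidal SST (annual mean 10.5 deg
#' C, amplitude 3.5, late-summer peak), 1-4 samples per week, heavy zero
#' inflation, and a 1985 regime shift that rewires the group dependencies.
#'
#' @param variables which variables to generate; any subset of the five
#'   canonical groups plus `"Chlorophyll"`, `"SST"`, `"NAOI"` that keeps
#'   each retained node's parents (default: all eight).
#' @param nYears length of the series in years (default 30).
#' @param nWeeks optional exact number of weeks (overrides `nYears`).
#' @param startYear first calendar year (default 1971).
#' @param samplesPerWeek integer range of samples drawn per week
#'   (default `1:4`).
#' @param regimeShiftYear calendar year after which the post-shift network
#'   applies, or `NA` for none (default 1985).
#' @param seasonalAmplitude strength of the seasonal tilt on group state
#'   probabilities (log-odds units per state step, default 0.3).
#' @param peakMonths named numeric vector of per-group seasonal peak months.
#' @param emission list with zero-inflation `piLow`, `piHigh`, negative
#'   binomial means `muLow`, `muHigh` and dispersion `size`.
#' @param sst list `mean`, `amplitude`, `peakDay` (day of year), `noiseSD`.
#' @param seed integer seed used by [sampleTimeseries()].
#' @return A `"planknetSyntheticSpec"` list.
#' @export
syntheticSpec <- function(variables = c(canonicalGroups(),
                                        "Chlorophyll", "SST", "NAOI"),
                          nYears = 30, nWeeks = NULL, startYear = 1971,
                          samplesPerWeek = 1:4, regimeShiftYear = 1985,
                          seasonalAmplitude = 0.3,
                          peakMonths = c("Warm Temperate" = 8,
                                         "Warm Temperate Oceanic" = 6,
                                         "Temperate Oceanic" = 4,
                                         "Shelf Sea" = 5,
                                         "Sub Arctic" = 3),
                          emission = list(piLow = 0.25, piHigh = 0.02,
                                          muLow = 5, muHigh = 50, size = 1),
                          sst = list(mean = 10.5, amplitude = 3.5,
                                     peakDay = 227, noiseSD = 0.4),
                          seed = 1L) {
  if (emission$muLow >= emission$muHigh)
    stop("emission means must satisfy muLow < muHigh")
  if (emission$piLow < 0 || emission$piLow >= 1 ||
      emission$piHigh < 0 || emission$piHigh >= 1)
    stop("zero-inflation probabilities must lie in [0, 1)")
  if (any(samplesPerWeek < 1)) stop("samplesPerWeek must be >= 1")
  defsPre <- list(
    "SST" = list(parents = character(0), cpt = NULL),  # driven by sinusoid
    "Warm Temperate" = list(parents = "SST", cpt = .posCPT2()),
    "Temperate Oceanic" = list(parents = "SST", cpt = .negCPT2()),
    "Warm Temperate Oceanic" = list(parents = character(0), cpt = .rootP()),
    "Shelf Sea" = list(parents = "Temperate Oceanic", cpt = .posCPT()),
    "Sub Arctic" = list(parents = "Warm Temperate Oceanic", cpt = .posCPT()),
    "Chlorophyll" = list(parents = "SST", cpt = .posCPT2()),
    "NAOI" = list(parents = character(0), cpt = NULL))  # monthly index
  defsPost <- defsPre
  # Regime shift: Warm Temperate Oceanic becomes dependent on Shelf Sea
  # (the decoupled sub-networks join) and the Warm Temperate / SST
  # dependence flips sign.
  defsPost[["Warm Temperate Oceanic"]] <-
    list(parents = "Shelf Sea", cpt = .posCPT())
  defsPost[["Warm Temperate"]] <- list(parents = "SST", cpt = .negCPT2())
  unknown <- setdiff(variables, names(defsPre))
  if (length(unknown))
    stop("unknown variable(s): ", paste(unknown, collapse = ", "))
  prune <- function(defs) {
    defs <- defs[variables]
    for (v in names(defs)) {
      miss <- setdiff(defs[[v]]$parents, variables)
      if (length(miss))
        stop("variable '", v, "' needs parent(s) ",
             paste(miss, collapse = ", "))
    }
    defs
  }
  structure(list(
    variables = variables,
    truthPre = .truthNet(prune(defsPre)),
    truthPost = .truthNet(prune(defsPost)),
    nYears = nYears, nWeeks = nWeeks, startYear = startYear,
    samplesPerWeek = samplesPerWeek, regimeShiftYear = regimeShiftYear,
    seasonalAmplitude = seasonalAmplitude, peakMonths = peakMonths,
    emission = emission, sst = sst, seed = as.integer(seed)),
    class = "planknetSyntheticSpec")
}

#' Ground-truth edges of a synthetic specification
#'
#' @param spec a spec from [syntheticSpec()] or [spatialSpec()].
#' @param period `"pre"` (default) or `"post"` the regime shift (time-series
#'   specs only).
#' @return Two-column character matrix of generating edges.
#' @export
groundTruthEdges <- function(spec, period = c("pre", "post")) {
  period <- match.arg(period)
  if (inherits(spec, "planknetSpatialSpec")) return(netEdges(spec$truth))
  net <- if (period == "pre") spec$truthPre else spec$truthPost
  netEdges(net)
}

.zinbSample <- function(n, state, em) {
  out <- numeric(n)
  nz <- state >= 2L
  if (any(nz)) {
    pi0 <- ifelse(state[nz] == 2L, em$piLow, em$piHigh)
    mu <- ifelse(state[nz] == 2L, em$muLow, em$muHigh)
    cnt <- stats::rnbinom(sum(nz), size = em$size, mu = mu)
    cnt[stats::runif(sum(nz)) < pi0] <- 0
    out[nz] <- cnt
  }
  out
}

.seasonTilt <- function(p, z, gamma) {
  w <- p * exp(gamma * z * (seq_len(3) - 2))
  w / sum(w)
}

# Ancestral draw of latent states for one week given fixed SST state.
.drawStates <- function(truth, sstState, doy, spec) {
  states <- setNames(integer(length(truth@nodes)), truth@nodes)
  for (v in .topoOrder(truth@nodes, truth@edges)) {
    if (v == "SST") { states[v] <- sstState; next }
    if (v == "NAOI") { states[v] <- 2L; next }   # value attached later
    probs <- truth@cpts[[v]]
    pa <- attr(probs, "parents")
    p <- if (length(pa)) probs[, .configIndex(t(as.matrix(states[pa])), pa)]
         else as.numeric(probs)
    if (v %in% names(spec$peakMonths)) {
      z <- cos(2 * pi * (doy - (spec$peakMonths[[v]] * 30.4 - 15)) / 365.25)
      p <- .seasonTilt(p, z, spec$seasonalAmplitude)
    }
    states[v] <- sample.int(3L, 1L, prob = p)
  }
  states
}

#' Generate a CPR-like weekly sample series
#'
#' Draws latent weekly states from the ground-truth network (pre- or
#' post-shift as the week falls), tilts group state probabilities by each
#' group's seasonal cycle, then emits 1-4 samples per week: zero-inflated
#' negative binomial counts for groups, lognormal values for the
#' chlorophyll index, the SST sinusoid plus noise, and a monthly normal NAO
#' index carried to samples by month. Deterministic given `spec$seed`.
#'
#' @param spec a [syntheticSpec()] specification.
#' @return A dated sample-level [SampleTable-class] (feed to
#'   [weeklyAverage()] and onwards).
#' @export
sampleTimeseries <- function(spec) {
  stopifnot(inherits(spec, "planknetSyntheticSpec"))
  .withSeed(spec$seed, .sampleTimeseriesImpl(spec))
}

.sampleTimeseriesImpl <- function(spec) {
  jan1 <- as.Date(sprintf("%d-01-01", spec$startYear))
  monday1 <- .isoWeekStart(jan1 + 7)
  nWeeks <- if (!is.null(spec$nWeeks)) spec$nWeeks
            else round(spec$nYears * 365.25 / 7)
  weekStart <- monday1 + 7 * (seq_len(nWeeks) - 1)
  doy <- as.integer(format(weekStart + 3, "%j"))
  yr <- as.integer(format(weekStart, "%Y"))
  sstWeek <- spec$sst$mean + spec$sst$amplitude *
    cos(2 * pi * (doy - spec$sst$peakDay) / 365.25) +
    stats::rnorm(nWeeks, sd = spec$sst$noiseSD)
  sstState <- ifelse(sstWeek > spec$sst$mean, 3L, 2L)
  months <- unique(format(weekStart, "%Y-%m"))
  nao <- setNames(stats::rnorm(length(months)), months)
  groups <- intersect(canonicalGroups(), spec$variables)
  hasChl <- "Chlorophyll" %in% spec$variables
  hasSST <- "SST" %in% spec$variables
  hasNAO <- "NAOI" %in% spec$variables
  rows <- vector("list", nWeeks)
  for (w in seq_len(nWeeks)) {
    truth <- if (!is.na(spec$regimeShiftYear) && yr[w] > spec$regimeShiftYear)
      spec$truthPost else spec$truthPre
    st <- .drawStates(truth, sstState[w], doy[w], spec)
    k <- if (length(spec$samplesPerWeek) == 1L) spec$samplesPerWeek
         else sample(spec$samplesPerWeek, 1L)
    vals <- matrix(0, k, length(spec$variables),
                   dimnames = list(NULL, spec$variables))
    for (g in groups)
      vals[, g] <- .zinbSample(k, rep(st[[g]], k), spec$emission)
    if (hasChl)
      vals[, "Chlorophyll"] <- stats::rlnorm(
        k, meanlog = log(c(0.2, 0.5, 1.5))[st[["Chlorophyll"]]], sdlog = 0.25)
    if (hasSST)
      vals[, "SST"] <- sstWeek[w] + stats::rnorm(k, sd = 0.2)
    if (hasNAO)
      vals[, "NAOI"] <- nao[[format(weekStart[w], "%Y-%m")]]
    rows[[w]] <- list(vals = vals,
                      date = weekStart[w] + seq_len(k) - 1)
  }
  vals <- do.call(rbind, lapply(rows, `[[`, "vals"))
  dates <- do.call(c, lapply(rows, `[[`, "date"))
  rownames(vals) <- sprintf("s%05d", seq_len(nrow(vals)))
  vt <- setNames(ifelse(spec$variables %in% groups, "group", "env"),
                 spec$variables)
  SampleTable(vals, date = dates, varType = vt)
}

#' Specification of a cruise-like spatial snapshot
#'
#' A station-indexed snapshot with the five biogeographic groups and two
#' jellyfish variables generated from a known parent structure: by default
#' *Aurelia aurita* depends negatively on Warm Temperate and positively on
#' Temperate Oceanic zooplankton, and the other-jellyfish pool follows
#' *Aurelia*.
#'
#' @param nStations number of stations (default 144).
#' @param aurelia list with `parents` (two group names) and `signs`
#'   (`+1`/`-1` per parent).
#' @param emission as in [syntheticSpec()]; station samples are less
#'   zero-inflated than single CPR trawls (net hauls filter far more
#'   water), so the defaults use lighter zero inflation.
#' @param seed integer seed used by [sampleSpatial()].
#' @return A `"planknetSpatialSpec"` list with the ground-truth network in
#'   `$truth`.
#' @export
spatialSpec <- function(nStations = 144,
                        aurelia = list(parents = c("Warm Temperate",
                                                   "Temperate Oceanic"),
                                       signs = c(-1, 1)),
                        emission = list(piLow = 0.10, piHigh = 0.01,
                                        muLow = 5, muHigh = 50, size = 3),
                        seed = 1L) {
  pa <- sort(aurelia$parents)
  signs <- aurelia$signs[match(pa, aurelia$parents)]
  single <- lapply(signs, function(s)
    if (s > 0) .posCPTSharp() else .negCPTSharp())
  # Two-parent CPT as the normalized product of the single-parent columns;
  # configuration order: first (sorted) parent fastest.
  cptA <- matrix(0, 3, 9)
  for (b in 1:3) for (a in 1:3) {
    col <- single[[1]][, a] * single[[2]][, b]
    cptA[, (b - 1) * 3 + a] <- col / sum(col)
  }
  defs <- c(
    setNames(lapply(canonicalGroups(),
                    function(g) list(parents = character(0), cpt = .rootP())),
             canonicalGroups()),
    list("Aurelia aurita" = list(parents = pa, cpt = cptA),
         "Other jellyfish" = list(parents = "Aurelia aurita",
                                  cpt = .posCPTSharp())))
  structure(list(nStations = nStations, truth = .truthNet(defs),
                 aurelia = list(parents = pa, signs = signs),
                 emission = emission, seed = as.integer(seed)),
            class = "planknetSpatialSpec")
}

#' Generate a cruise-like spatial station snapshot
#'
#' @param spec a [spatialSpec()] specification.
#' @return An undated [SampleTable-class] with `nStations` rows, station
#'   coordinates, the five group columns and two jellyfish columns.
#' @export
sampleSpatial <- function(spec) {
  stopifnot(inherits(spec, "planknetSpatialSpec"))
  .withSeed(spec$seed, {
    truth <- spec$truth
    n <- spec$nStations
    em <- spec$emission
    ord <- .topoOrder(truth@nodes, truth@edges)
    states <- matrix(0L, n, length(truth@nodes),
                     dimnames = list(NULL, truth@nodes))
    for (v in ord) {
      probs <- truth@cpts[[v]]
      pa <- attr(probs, "parents")
      if (!length(pa)) {
        states[, v] <- sample.int(3L, n, replace = TRUE,
                                  prob = as.numeric(probs))
      } else {
        cfg <- .configIndex(states, pa)
        states[, v] <- vapply(cfg, function(cl)
          sample.int(3L, 1L, prob = probs[, cl]), integer(1))
      }
    }
    vals <- matrix(0, n, length(truth@nodes),
                   dimnames = list(sprintf("st%03d", seq_len(n)),
                                   truth@nodes))
    for (v in truth@nodes)
      vals[, v] <- .zinbSample(n, states[, v], em)
    SampleTable(vals,
                lon = stats::runif(n, -6, -3), lat = stats::runif(n, 52, 55),
                varType = setNames(rep("group", length(truth@nodes)),
                                   truth@nodes))
  })
}

#' Synthetic annual catch series driven by one group
#'
#' Builds a response (catch) series as a strictly increasing function of
#' the driver group's September-anchored yearly mean, optionally with
#' lognormal noise; the catch for spawning year `t` is labelled year
#' `t + 1` (spawning-to-capture lag).
#'
#' @param x a dated sample-level or weekly [SampleTable-class].
#' @param driver group column driving the catch.
#' @param noiseSD lognormal noise on the catch (default 0: deterministic
#'   monotone link).
#' @param seed RNG seed when `noiseSD > 0`.
#' @return Data.frame with columns `year`, `catch` (tonnes).
#' @export
syntheticHerring <- function(x, driver, noiseSD = 0, seed = NA_integer_) {
  yearly <- yearlyAverageFromSeptember(x)
  v <- sampleValues(yearly)[, driver]
  catch <- 5000 * (1 + v)^0.8
  if (noiseSD > 0)
    catch <- .withSeed(seed,
                       catch * stats::rlnorm(length(catch), sdlog = noiseSD))
  data.frame(year = as.integer(rownames(sampleValues(yearly))) + 1L,
             catch = unname(catch))
}
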