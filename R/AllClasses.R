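#' @import methods
NULL

#' Ordered abundance states used throughout the package
#'
#' All variables are coded on the common ordinal scale ZERO < LOW < HIGH.
#' Environmental variables without zero values simply never occupy the ZERO
#' state.
#'
#' @return Character vector of the three state labels, in order.
#' @export
#' @examples
#' stateLevels()
stateLevels <- function() c("ZERO", "LOW", "HIGH")

#' SampleTable: abundance and environment observations per sample
#'
#' A samples-by-variables numeric matrix together with optional per-sample
#' dates (weekly/annual series) or positions (spatial station snapshots).
#' Taxon and group variables hold non-negative counts per unit volume;
#' environmental variables (sea surface temperature, NAO index, catch) may
#' take any real value.
#'
#' @slot values numeric matrix, samples in rows (unique rownames = sample
#'   ids), variables in columns.
#' @slot date `Date` vector of length `nrow(values)`, or length 0 for undated
#'   (spatial) tables.
#' @slot lon,lat numeric vectors of station coordinates (degrees), length
#'   `nrow(values)` or 0.
#' @slot varType named character vector over columns, each one of
#'   `"taxon"`, `"group"`, `"env"`.
#' @name SampleTable-class
#' @aliases SampleTable-class
#' @exportClass SampleTable
setClass("SampleTable",
  representation(
    values = "matrix",
    date = "Date",
    lon = "numeric",
    lat = "numeric",
    varType = "character"
  )
)

setValidity("SampleTable", function(object) {
  v <- object@values
  msg <- character()
  if (!is.numeric(v)) msg <- c(msg, "values must be a numeric matrix")
  if (nrow(v) > 0L && (is.null(rownames(v)) || anyDuplicated(rownames(v))))
    msg <- c(msg, "sample ids (rownames) must be present and unique")
  if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
    msg <- c(msg, "variable names (colnames) must be present and unique")
  if (!identical(sort(names(object@varType)), sort(colnames(v))))
    msg <- c(msg, "varType must be named by the variable names")
  if (!all(object@varType %in% c("taxon", "group", "env")))
    msg <- c(msg, "varType entries must be 'taxon', 'group' or 'env'")
  if (length(object@date) != 0L && length(object@date) != nrow(v))
    msg <- c(msg, "date must have one entry per sample (or none)")
  for (co in c("lon", "lat")) {
    n <- length(slot(object, co))
    if (n != 0L && n != nrow(v))
      msg <- c(msg, sprintf("%s must have one entry per sample (or none)", co))
  }
  abund <- colnames(v)[object@varType[colnames(v)] != "env"]
  if (length(abund) && any(v[, abund, drop = FALSE] < 0, na.rm = TRUE)) {
    bad <- which(v[, abund, drop = FALSE] < 0, arr.ind = TRUE)[1, ]
    msg <- c(msg, sprintf("negative abundance for '%s' in sample '%s'",
                          abund[bad[2]], rownames(v)[bad[1]]))
  }
  if (length(msg)) msg else TRUE
})

#' DiscreteMatrix: samples coded into ZERO/LOW/HIGH states
#'
#' @slot states integer matrix (1 = ZERO, 2 = LOW, 3 = HIGH) with the source
#'   table's dimnames.
#' @slot thresholds named numeric: per variable, the median of its non-zero
#'   values that separates LOW from HIGH (`NA` for all-zero variables).
#' @slot degenerate character: variables occupying fewer than two states,
#'   excluded from network learning.
#' @slot provenance character scalar describing the source table.
#' @name DiscreteMatrix-class
#' @exportClass DiscreteMatrix
setClass("DiscreteMatrix",
  representation(
    states = "matrix",
    thresholds = "numeric",
    degenerate = "character",
    provenance = "character"
  )
)

setValidity("DiscreteMatrix", function(object) {
  s <- object@states
  msg <- character()
  if (!is.integer(s)) msg <- c(msg, "states must be an integer matrix")
  if (any(is.na(s)) || (length(s) && (min(s) < 1L || max(s) > 3L)))
    msg <- c(msg, "states must lie in 1:3 with no missing values")
  if (!identical(sort(names(object@thresholds)), sort(colnames(s))))
    msg <- c(msg, "thresholds must be named by the variable names")
  if (!all(object@degenerate %in% colnames(s)))
    msg <- c(msg, "degenerate lists unknown variables")
  if (length(msg)) msg else TRUE
})

#' EdgeBlacklist: variable pairs disallowed as network edges
#'
#' Produced by [contingencyFilter()]: unordered pairs whose joint state
#' distribution shows no evidence of departure from independence
#' (chi-squared p > alpha) are barred from the structure search.
#'
#' @slot pairs character matrix with two columns; each row an unordered pair
#'   stored in sorted order.
#' @slot alpha numeric scalar, the significance cut (default 0.25).
#' @slot tests data.frame of per-pair statistics and p-values.
#' @name EdgeBlacklist-class
#' @exportClass EdgeBlacklist
setClass("EdgeBlacklist",
  representation(pairs = "matrix", alpha = "numeric", tests = "data.frame")
)

setValidity("EdgeBlacklist", function(object) {
  p <- object@pairs
  msg <- character()
  if (ncol(p) != 2L) msg <- c(msg, "pairs must have two columns")
  if (nrow(p) && any(p[, 1] >= p[, 2]))
    msg <- c(msg, "pairs must be stored sorted within row with no self-pairs")
  if (length(object@alpha) != 1L || object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "alpha must be a probability in (0,1)")
  if (length(msg)) msg else TRUE
})

#' ScoreConfig: settings for network scoring and search
#'
#' @slot ess equivalent sample size of the BDeu Dirichlet prior (> 0).
#' @slot maxParents per-node in-degree limit (default 3).
#' @slot budget maximum number of candidate moves scored during a search.
#' @slot restarts number of hill-climbing restarts (first from the empty
#'   graph, later ones from random starting DAGs).
#' @slot seed integer seed, or `NA` to use the current RNG stream.
#' @name ScoreConfig-class
#' @exportClass ScoreConfig
setClass("ScoreConfig",
  representation(ess = "numeric", maxParents = "numeric",
                 budget = "numeric", restarts = "numeric", seed = "numeric")
)

setValidity("ScoreConfig", function(object) {
  msg <- character()
  if (object@ess <= 0) msg <- c(msg, "ess must be > 0")
  if (object@maxParents < 0) msg <- c(msg, "maxParents must be >= 0")
  if (object@budget < 1) msg <- c(msg, "budget must be >= 1")
  if (object@restarts < 1) msg <- c(msg, "restarts must be >= 1")
  if (length(msg)) msg else TRUE
})

#' BayesNet: a directed acyclic network over discrete ordinal variables
#'
#' @slot nodes character vector of variable names.
#' @slot edges character matrix with columns `parent`, `child` (0 rows for
#'   the empty network).
#' @slot cpts named list; for each node a `3 x q` probability matrix whose
#'   columns index parent configurations in mixed-radix order (first parent
#'   fastest), with attributes `parents` (character) and, once fitted from
#'   data, `configWeights` (empirical parent-configuration distribution).
#'   Empty list until [fitCPTs()] is applied.
#' @slot score numeric; total log BDeu network score if known, else `NA`.
#' @slot info list of free-form annotations (search diagnostics etc.).
#' @name BayesNet-class
#' @exportClass BayesNet
setClass("BayesNet",
  representation(nodes = "character", edges = "matrix",
                 cpts = "list", score = "numeric", info = "list")
)

setValidity("BayesNet", function(object) {
  msg <- character()
  if (anyDuplicated(object@nodes)) msg <- c(msg, "duplicate node names")
  e <- object@edges
  if (ncol(e) != 2L) msg <- c(msg, "edges must have two columns (parent, child)")
  else if (nrow(e)) {
    if (!all(e %in% object@nodes)) msg <- c(msg, "edge endpoints must be nodes")
    if (any(e[, 1] == e[, 2])) msg <- c(msg, "self-loops are not allowed")
    if (anyDuplicated(paste(e[, 1], e[, 2], sep = "\r")))
      msg <- c(msg, "duplicate edges")
    if (is.null(.topoOrder(object@nodes, e)))
      msg <- c(msg, "graph must be acyclic")
  }
  if (length(msg)) msg else TRUE
})

#' ConsensusNetwork: bootstrap-averaged network
#'
#' Edges whose bootstrap occurrence frequency passed the bimodality
#' threshold, with mean influence scores and a mutuality flag for pairs that
#' passed in both directions.
#'
#' @slot edges data.frame with columns `parent`, `child`, `frequency`,
#'   `meanIS`, `mutual`.
#' @slot threshold numeric scalar in (0,1), the frequency cut applied.
#' @slot nBoot integer, number of bootstrap replicates summarized.
#' @slot summaries data.frame of all observed edges (pre-threshold).
#' @name ConsensusNetwork-class
#' @exportClass ConsensusNetwork
setClass("ConsensusNetwork",
  representation(edges = "data.frame", threshold = "numeric",
                 nBoot = "numeric", summaries = "data.frame")
)

setValidity("ConsensusNetwork", function(object) {
  msg <- character()
  need <- c("parent", "child", "frequency", "meanIS", "mutual")
  if (!all(need %in% names(object@edges)))
    msg <- c(msg, "edges must have parent/child/frequency/meanIS/mutual")
  if (nrow(object@edges) &&
      (any(object@edges$frequency < 0) || any(object@edges$frequency > 1)))
    msg <- c(msg, "frequencies must lie in [0,1]")
  if (length(object@threshold) != 1L || object@threshold <= 0 ||
      object@threshold >= 1)
    msg <- c(msg, "threshold must lie in (0,1)")
  if (length(msg)) msg else TRUE
})
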