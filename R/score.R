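#' Create a ScoreConfig
#'
#' @param ess equivalent sample size of the BDeu prior (default 1).
#' @param maxParents in-degree limit (default 3).
#' @param budget cap on the number of candidate moves scored in one search
#'   (default 1e7).
#' @param restarts hill-climbing restarts (default 10).
#' @param seed integer seed for tie-breaking and restart randomization;
#'   `NA` (default) draws from the current RNG stream.
#' @return A [ScoreConfig-class].
#' @export
#' @examples
#' scoreConfig(ess = 1, maxParents = 3, seed = 7)
scoreConfig <- function(ess = 1, maxParents = 3, budget = 1e7,
                        restarts = 10, seed = NA_integer_) {
  new("ScoreConfig", ess = as.numeric(ess), maxParents = as.numeric(maxParents),
      budget = as.numeric(budget), restarts = as.numeric(restarts),
      seed = as.numeric(seed))
}

setMethod("show", "ScoreConfig", function(object) {
  cat(sprintf(
    "ScoreConfig: ess = %g, maxParents = %d, budget = %g, restarts = %d\n",
    object@ess, object@maxParents, object@budget, object@restarts))
})

# Log BDeu family score from an r x q count matrix.
# alpha_cell = ess / (q * r), alpha_config = ess / q.
.bdeuFromCounts <- function(counts, ess) {
  q <- ncol(counts)
  r <- nrow(counts)
  aij <- ess / q
  aijk <- ess / (q * r)
  nj <- colSums(counts)
  sum(lgamma(aij) - lgamma(aij + nj)) +
    sum(lgamma(aijk + counts) - lgamma(aijk))
}

# Occupied states (integer subset of 1:3) per variable.
.occupiedLevels <- function(states) {
  lapply(seq_len(ncol(states)),
         function(j) which(tabulate(states[, j], nbins = 3L) > 0L))
}

# Full 3 x 3^k count matrix of child states by parent configuration
# (used for CPT fitting; mixed-radix order, first sorted parent fastest).
.familyCounts <- function(states, child, parents) {
  q <- 3L^length(parents)
  cfg <- .configIndex(states, parents)
  counts <- matrix(0, 3L, q)
  tab <- table(factor(states[, child], levels = 1:3),
               factor(cfg, levels = seq_len(q)))
  counts[] <- tab
  counts
}

# Effective r_eff x q_eff count matrix over *occupied* states only: the
# scoring cardinality of each variable is its number of occupied states, so
# variables without zeros are binary and a constant parent contributes a
# single configuration.
.familyCountsEffective <- function(states, child, parents,
                                   levels = .occupiedLevels(states)) {
  cols <- colnames(states)
  chLev <- levels[[match(child, cols)]]
  paLev <- lapply(parents, function(p) levels[[match(p, cols)]])
  card <- vapply(paLev, length, integer(1))
  q <- prod(card)
  idx <- rep.int(0L, nrow(states))
  mult <- 1L
  for (i in seq_along(parents)) {
    idx <- idx + (match(states[, parents[i]], paLev[[i]]) - 1L) * mult
    mult <- mult * card[i]
  }
  counts <- matrix(0, length(chLev), max(q, 1L))
  tab <- table(factor(states[, child], levels = chLev),
               factor(idx + 1L, levels = seq_len(max(q, 1L))))
  counts[] <- tab
  counts
}

#' Log BDeu score of one node's family
#'
#' The log Dirichlet-multinomial marginal likelihood of the child's states
#' partitioned by parent configuration, under a symmetric BDeu prior with
#' `ess / (q * r)` pseudo-counts per cell. Cardinalities are *effective*:
#' `r` is the child's number of occupied states and `q` the product of the
#' parents' occupied-state counts, so a zero-free environmental variable is
#' binary and a constant parent leaves the score unchanged. The total
#' network score is the sum of family scores over nodes (decomposability).
#'
#' @param child child variable name.
#' @param parents character vector of parent names (possibly empty).
#' @param x a [DiscreteMatrix-class].
#' @param config a [ScoreConfig-class].
#' @return Log score (numeric scalar).
#' @export
familyScore <- function(child, parents, x, config = scoreConfig()) {
  stopifnot(is(x, "DiscreteMatrix"), is(config, "ScoreConfig"))
  if (child %in% parents) stop("child must not be among its parents")
  if (length(parents) > config@maxParents)
    stop("parent set exceeds maxParents")
  vars <- colnames(stateMatrix(x))
  missing <- setdiff(c(child, parents), vars)
  if (length(missing))
    stop("variable(s) not in the discretized matrix: ",
         paste(missing, collapse = ", "))
  .bdeuFromCounts(.familyCountsEffective(stateMatrix(x), child, parents),
                  config@ess)
}

#' Log BDeu score of a whole network
#'
#' @param net a [BayesNet-class] (structure only is sufficient).
#' @param x a [DiscreteMatrix-class].
#' @param config a [ScoreConfig-class].
#' @return Sum of family scores over the network's nodes.
#' @export
networkScore <- function(net, x, config = scoreConfig()) {
  stopifnot(is(net, "BayesNet"))
  sum(vapply(net@nodes, function(v)
    familyScore(v, .netParents(net@edges, v), x, config), numeric(1)))
}

.netParents <- function(edges, node) {
  if (!nrow(edges)) character(0) else edges[edges[, 2] == node, 1]
}
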