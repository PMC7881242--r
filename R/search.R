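# Greedy hill-climbing structure search under the BDeu score.
#
# Moves are single-edge additions, deletions and reversals; at each step the
# move with the greatest score gain is taken (ties broken at random under
# the configured seed), stopping when no move improves the score or the
# candidate budget is exhausted. Restart 1 climbs from the empty graph,
# later restarts from sparse random DAGs; the best-scoring network
# encountered anywhere is returned.

#' Construct a BayesNet
#'
#' @param nodes character vector of node names.
#' @param edges two-column character matrix (parent, child), or a
#'   data.frame/list of such pairs; may be empty.
#' @param cpts optional named list of conditional probability tables (see
#'   [fitCPTs()]).
#' @param score optional log network score.
#' @return A validated [BayesNet-class].
#' @export
#' @examples
#' BayesNet(c("A", "B"), rbind(c("A", "B")))
BayesNet <- function(nodes, edges = NULL, cpts = list(), score = NA_real_) {
  if (is.null(edges) || (is.matrix(edges) && nrow(edges) == 0L))
    edges <- matrix(character(0), 0, 2)
  edges <- as.matrix(edges)
  if (!is.character(edges)) storage.mode(edges) <- "character"
  colnames(edges) <- c("parent", "child")
  new("BayesNet", nodes = nodes, edges = edges, cpts = cpts,
      score = as.numeric(score), info = list())
}

#' @rdname BayesNet-class
#' @exportMethod netNodes
setMethod("netNodes", "BayesNet", function(x) x@nodes)

#' @rdname BayesNet-class
#' @exportMethod netEdges
setMethod("netEdges", "BayesNet", function(x) x@edges)

#' @rdname BayesNet-class
#' @exportMethod netScore
setMethod("netScore", "BayesNet", function(x) x@score)

#' @rdname BayesNet-class
#' @exportMethod cpt
setMethod("cpt", "BayesNet", function(x, node) {
  if (!node %in% names(x@cpts))
    stop("no CPT for node '", node, "' (run fitCPTs first?)")
  x@cpts[[node]]
})

#' @rdname BayesNet-class
#' @exportMethod parentsOf
setMethod("parentsOf", "BayesNet", function(x, node) {
  if (!node %in% x@nodes) stop("unknown node '", node, "'")
  .netParents(x@edges, node)
})

setMethod("show", "BayesNet", function(object) {
  cat(sprintf("BayesNet: %d nodes, %d edges%s%s\n",
              length(object@nodes), nrow(object@edges),
              if (is.na(object@score)) "" else
                sprintf(", log score %.4f", object@score),
              if (length(object@cpts)) ", CPTs fitted" else ""))
  if (nrow(object@edges))
    cat(paste0("  ", object@edges[, 1], " -> ", object@edges[, 2],
               collapse = "\n"), "\n")
})

# Adjacency-matrix helpers used only inside the search.
.adjToEdges <- function(A) {
  idx <- which(A, arr.ind = TRUE)
  e <- cbind(parent = rownames(A)[idx[, 1]], child = colnames(A)[idx[, 2]])
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}

.adjHasPath <- function(A, from, to) {
  # TRUE if `to` is reachable from `from` (indices) in adjacency matrix A.
  seen <- logical(nrow(A))
  frontier <- from
  seen[from] <- TRUE
  while (length(frontier)) {
    nxt <- which(colSums(A[frontier, , drop = FALSE]) > 0 & !seen)
    if (to %in% nxt) return(TRUE)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  seen[to]
}

#' Greedy structure search
#'
#' Hill-climbing over single-edge additions, deletions and reversals from
#' the empty graph (plus random-restart starting points), maximizing the
#' total BDeu score subject to the blacklist and the per-node parent limit.
#' Deterministic given the data, blacklist, configuration and seed.
#'
#' @param x a [DiscreteMatrix-class]; degenerate variables are excluded.
#' @param blacklist an [EdgeBlacklist-class] or `NULL`.
#' @param config a [ScoreConfig-class].
#' @param variables variables to search over (default: all non-degenerate).
#' @return The best [BayesNet-class] encountered, with its log score and
#'   search diagnostics in `@info` (`movesScored`, `restartScores`).
#' @export
greedySearch <- function(x, blacklist = NULL, config = scoreConfig(),
                         variables = NULL) {
  stopifnot(is(x, "DiscreteMatrix"), is(config, "ScoreConfig"))
  if (is.null(variables))
    variables <- setdiff(colnames(stateMatrix(x)), degenerateVariables(x))
  else {
    deg <- intersect(variables, degenerateVariables(x))
    if (length(deg)) {
      message("excluding degenerate variable(s): ", paste(deg, collapse = ", "))
      variables <- setdiff(variables, deg)
    }
  }
  if (length(variables) < 2L)
    stop("need at least two non-degenerate variables")
  .withSeed(config@seed, .greedySearchImpl(x, blacklist, config, variables))
}

.greedySearchImpl <- function(x, blacklist, config, variables) {
  states <- stateMatrix(x)[, variables, drop = FALSE]
  p <- length(variables)
  ess <- config@ess
  maxPar <- config@maxParents

  # Family-score cache keyed by child and sorted parent set.
  cache <- new.env(parent = emptyenv())
  levels <- .occupiedLevels(states)
  famScore <- function(childIdx, parentIdx) {
    key <- paste(childIdx, paste(sort(parentIdx), collapse = ","), sep = "|")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    val <- .bdeuFromCounts(
      .familyCountsEffective(states, variables[childIdx],
                             variables[sort(parentIdx)], levels), ess)
    cache[[key]] <- val
    val
  }

  allowed <- matrix(TRUE, p, p)
  diag(allowed) <- FALSE
  if (!is.null(blacklist) && nrow(blacklistPairs(blacklist))) {
    for (k in seq_len(nrow(blacklistPairs(blacklist)))) {
      a <- match(blacklistPairs(blacklist)[k, 1], variables)
      b <- match(blacklistPairs(blacklist)[k, 2], variables)
      if (!is.na(a) && !is.na(b)) allowed[a, b] <- allowed[b, a] <- FALSE
    }
  }
  if (!any(allowed)) {
    warning("all variable pairs are blacklisted; returning the empty network")
    net <- BayesNet(variables)
    net@score <- sum(vapply(seq_len(p), function(j) famScore(j, integer(0)),
                            numeric(1)))
    return(net)
  }

  movesScored <- 0L
  bestScore <- -Inf
  bestAdj <- NULL
  restartScores <- numeric(0)

  for (rs in seq_len(config@restarts)) {
    A <- matrix(FALSE, p, p, dimnames = list(variables, variables))
    if (rs > 1L) {
      # Sparse random DAG start: random topological order, each allowed
      # forward edge kept with probability 0.15 (parent limit respected).
      ord <- sample.int(p)
      for (jj in 2:p) for (ii in 1:(jj - 1)) {
        a <- ord[ii]; b <- ord[jj]
        if (allowed[a, b] && sum(A[, b]) < maxPar && stats::runif(1) < 0.15)
          A[a, b] <- TRUE
      }
    }
    fam <- vapply(seq_len(p), function(j) famScore(j, which(A[, j])),
                  numeric(1))
    current <- sum(fam)
    if (current > bestScore) { bestScore <- current; bestAdj <- A }

    repeat {
      if (movesScored >= config@budget) break
      bestDelta <- 0
      cand <- list()
      for (i in seq_len(p)) for (j in seq_len(p)) {
        if (i == j) next
        if (A[i, j]) {
          # deletion
          d <- famScore(j, setdiff(which(A[, j]), i)) - fam[j]
          movesScored <- movesScored + 1L
          if (d > bestDelta - 1e-12)
            cand <- c(cand, list(list(type = "del", i = i, j = j, delta = d)))
          if (d > bestDelta) bestDelta <- d
          # reversal: i->j becomes j->i
          if (allowed[j, i] && sum(A[, i]) < maxPar && !A[j, i]) {
            A[i, j] <- FALSE
            ok <- !.adjHasPath(A, i, j)  # j->i must not close a cycle
            A[i, j] <- TRUE
            if (ok) {
              d <- (famScore(j, setdiff(which(A[, j]), i)) - fam[j]) +
                   (famScore(i, c(which(A[, i]), j)) - fam[i])
              movesScored <- movesScored + 1L
              if (d > bestDelta - 1e-12)
                cand <- c(cand, list(list(type = "rev", i = i, j = j,
                                          delta = d)))
              if (d > bestDelta) bestDelta <- d
            }
          }
        } else if (allowed[i, j] && sum(A[, j]) < maxPar &&
                   !.adjHasPath(A, j, i)) {
          # addition
          d <- famScore(j, c(which(A[, j]), i)) - fam[j]
          movesScored <- movesScored + 1L
          if (d > bestDelta - 1e-12)
            cand <- c(cand, list(list(type = "add", i = i, j = j, delta = d)))
          if (d > bestDelta) bestDelta <- d
        }
      }
      if (bestDelta <= 1e-10) break
      cand <- Filter(function(m) m$delta >= bestDelta - 1e-12, cand)
      mv <- cand[[sample.int(length(cand), 1L)]]
      if (mv$type == "add") {
        A[mv$i, mv$j] <- TRUE
        fam[mv$j] <- famScore(mv$j, which(A[, mv$j]))
      } else if (mv$type == "del") {
        A[mv$i, mv$j] <- FALSE
        fam[mv$j] <- famScore(mv$j, which(A[, mv$j]))
      } else {
        A[mv$i, mv$j] <- FALSE
        A[mv$j, mv$i] <- TRUE
        fam[mv$j] <- famScore(mv$j, which(A[, mv$j]))
        fam[mv$i] <- famScore(mv$i, which(A[, mv$i]))
      }
      current <- sum(fam)
      if (current > bestScore) { bestScore <- current; bestAdj <- A }
    }
    restartScores <- c(restartScores, current)
    if (movesScored >= config@budget) break
  }

  net <- BayesNet(variables, .adjToEdges(bestAdj))
  net@score <- bestScore
  net@info <- list(movesScored = movesScored, restartScores = restartScores)
  net
}

#' Exhaustively score all DAGs on a small variable set
#'
#' Enumerates every directed acyclic graph over the given variables (feasible
#' up to ~4 nodes; 3 nodes have 25 DAGs), applies the blacklist and parent
#' limit, and returns the exact score optimum. Used as an independent check
#' of the greedy search.
#'
#' @inheritParams greedySearch
#' @param variables variables to enumerate over (>= 2, <= 5).
#' @return A [BayesNet-class] with the optimal structure and score, and the
#'   number of DAGs scored in `@info$nDags`.
#' @export
exhaustiveSearch <- function(x, blacklist = NULL, config = scoreConfig(),
                             variables = NULL) {
  stopifnot(is(x, "DiscreteMatrix"))
  if (is.null(variables))
    variables <- setdiff(colnames(stateMatrix(x)), degenerateVariables(x))
  p <- length(variables)
  if (p < 2L || p > 5L) stop("exhaustive enumeration supports 2..5 variables")
  slots <- which(upper.tri(matrix(0, p, p)) | lower.tri(matrix(0, p, p)),
                 arr.ind = TRUE)  # all ordered pairs
  nSlot <- nrow(slots)
  best <- -Inf; bestEdges <- NULL; nDags <- 0L
  cache <- new.env(parent = emptyenv())
  fs <- function(j, pa) {
    key <- paste(j, paste(sort(pa), collapse = ","), sep = "|")
    v <- cache[[key]]
    if (is.null(v)) {
      v <- familyScore(variables[j], variables[sort(pa)], x, config)
      cache[[key]] <- v
    }
    v
  }
  for (mask in 0:(2^nSlot - 1)) {
    on <- which(bitwAnd(mask, bitwShiftL(1, seq_len(nSlot) - 1)) != 0)
    E <- slots[on, , drop = FALSE]
    if (nrow(E)) {
      if (max(tabulate(E[, 2], nbins = p)) > config@maxParents) next
      edges <- cbind(variables[E[, 1]], variables[E[, 2]])
      if (is.null(.topoOrder(variables, edges))) next
      if (!is.null(blacklist) &&
          any(mapply(function(a, b) isBlacklisted(blacklist, a, b),
                     edges[, 1], edges[, 2]))) next
    }
    nDags <- nDags + 1L
    sc <- sum(vapply(seq_len(p), function(j) {
      pa <- if (nrow(E)) E[E[, 2] == j, 1] else integer(0)
      fs(j, pa)
    }, numeric(1)))
    if (sc > best) {
      best <- sc
      bestEdges <- if (nrow(E)) cbind(variables[E[, 1]], variables[E[, 2]])
                   else matrix(character(0), 0, 2)
    }
  }
  net <- BayesNet(variables, bestEdges)
  net@score <- best
  net@info <- list(nDags = nDags)
  net
}
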