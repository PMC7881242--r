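#' Fit conditional probability tables by Dirichlet-smoothed counts
#'
#' Each CPT cell is `(count + prior) / (configTotal + r * prior)` with the
#' same BDeu prior partition used for scoring (`prior = ess / (q * r)` per
#' cell). Parent configurations never observed therefore fall back to the
#' uniform distribution. The empirical distribution of parent
#' configurations is stored alongside each CPT (attribute `configWeights`)
#' for use by the influence score.
#'
#' @param net a [BayesNet-class] (structure).
#' @param x a [DiscreteMatrix-class] containing every network node.
#' @param config a [ScoreConfig-class]; `config@ess` sets the smoothing.
#' @return `net` with `@cpts` populated and `@score` refreshed on `x`.
#' @export
fitCPTs <- function(net, x, config = scoreConfig()) {
  stopifnot(is(net, "BayesNet"), is(x, "DiscreteMatrix"))
  states <- stateMatrix(x)
  missing <- setdiff(net@nodes, colnames(states))
  if (length(missing))
    stop("variable(s) missing from the data: ", paste(missing, collapse = ", "))
  ess <- config@ess
  cpts <- lapply(net@nodes, function(v) {
    parents <- sort(.netParents(net@edges, v))
    counts <- .familyCounts(states, v, parents)
    q <- ncol(counts)
    # Prior mass follows the scoring convention: spread over occupied child
    # states and parent configurations composed of occupied states only.
    # Unoccupied child states keep probability 0; impossible parent
    # configurations (never reachable through the parents' own CPTs) are
    # filled uniformly.
    chOcc <- which(tabulate(states[, v], nbins = 3L) > 0L)
    paOcc <- lapply(parents,
                    function(p) which(tabulate(states[, p], nbins = 3L) > 0L))
    cfg <- seq_len(q) - 1L
    valid <- rep(TRUE, q)
    for (i in seq_along(parents))
      valid <- valid & ((cfg %/% 3L^(i - 1L)) %% 3L + 1L) %in% paOcc[[i]]
    qEff <- max(prod(vapply(paOcc, length, integer(1))), 1L)
    prior <- ess / (qEff * length(chOcc))
    sm <- counts
    sm[chOcc, valid] <- sm[chOcc, valid] + prior
    probs <- matrix(1 / 3, 3L, q)
    probs[, valid] <- sweep(sm[, valid, drop = FALSE], 2,
                            colSums(sm)[valid], "/")
    dimnames(probs) <- list(stateLevels(), NULL)
    attr(probs, "parents") <- parents
    cw <- colSums(counts)
    attr(probs, "configWeights") <- if (sum(cw) > 0) cw / sum(cw)
                                    else rep(1 / q, q)
    attr(probs, "counts") <- counts
    probs
  })
  names(cpts) <- net@nodes
  net@cpts <- cpts
  net@score <- networkScore(net, x, config)
  net
}

#' Marginal distributions implied by a fitted network
#'
#' @param net a fitted [BayesNet-class].
#' @return Matrix (3 states x nodes) of exact marginal probabilities.
#' @export
netMarginals <- function(net) {
  stopifnot(is(net, "BayesNet"), length(net@cpts) > 0)
  out <- vapply(net@nodes, function(v) queryPosterior(net, v),
                numeric(3))
  rownames(out) <- stateLevels()
  out
}
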