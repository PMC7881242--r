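#' Signed influence score of an edge
#'
#' Characterizes the ordinal dependence of the child on the parent along an
#' edge of a fitted network. With co-parents marginalized at their empirical
#' configuration weights, the child's conditional cumulative distribution is
#' compared across adjacent occupied parent states (ZERO < LOW < HIGH):
#'
#' * every comparison stochastically increasing -> positive IS (aggregation);
#' * every comparison decreasing -> negative IS (segregation);
#' * mixed directions -> IS = 0 (non-monotonic dependence);
#' * identical conditionals -> IS = 0 (no dependence).
#'
#' The magnitude is the mean absolute difference between the child CDFs at
#' the two extreme occupied parent states, so a deterministic identity CPT
#' scores +1 and a deterministic reversal -1. |IS| <= 1 always, and the
#' score depends only on the CPT (not on sample size).
#'
#' @param net a fitted [BayesNet-class] (see [fitCPTs()]).
#' @param parent,child node names; `parent -> child` must be an edge of
#'   `net`.
#' @return Numeric scalar in `[-1, 1]`.
#' @export
influenceScore <- function(net, parent, child) {
  stopifnot(is(net, "BayesNet"))
  e <- net@edges
  if (!nrow(e) || !any(e[, 1] == parent & e[, 2] == child))
    stop("edge ", parent, " -> ", child, " is not in the network")
  if (!length(net@cpts)) stop("CPTs not fitted; run fitCPTs first")
  tab <- .childGivenParent(net, parent, child)   # 3 child x 3 parent
  occ <- attr(tab, "occupied")
  if (sum(occ) < 2L) return(0)
  states <- which(occ)
  cdf <- apply(tab, 2, cumsum)                   # per parent state
  dir <- integer(0)
  for (k in seq_len(length(states) - 1L)) {
    d <- cdf[1:2, states[k]] - cdf[1:2, states[k + 1L]]
    dir <- c(dir,
             if (all(abs(d) < 1e-12)) 0L
             else if (all(d >= -1e-12)) 1L
             else if (all(d <= 1e-12)) -1L
             else NA_integer_)
  }
  if (anyNA(dir)) return(0)                      # non-monotonic
  sgn <- if (any(dir == 1L) && !any(dir == -1L)) 1
         else if (any(dir == -1L) && !any(dir == 1L)) -1
         else 0
  if (sgn == 0) return(0)
  lo <- states[1L]; hi <- states[length(states)]
  mag <- mean(abs(cdf[1:2, lo] - cdf[1:2, hi]))
  sgn * mag
}

# Child conditional distribution given each parent state, with the other
# parents of `child` marginalized at their empirical joint weights.
# Returns a 3 x 3 matrix (child state x parent state) with attribute
# `occupied`: which parent states carry empirical mass.
#
# When the CPT carries its fitted counts, the empirical (maximum-likelihood)
# conditionals are used: monotonicity voting on the *smoothed* CPT would
# pick up sub-prior-sized artifacts from unequal configuration totals.
.childGivenParent <- function(net, parent, child) {
  probs <- net@cpts[[child]]
  parents <- attr(probs, "parents")
  w <- attr(probs, "configWeights")
  counts <- attr(probs, "counts")
  if (!is.null(counts)) {
    tot <- colSums(counts)
    mle <- sweep(counts, 2, pmax(tot, 1), "/")
    mle[, tot == 0] <- 1 / 3
    attributes(mle) <- attributes(probs)[c("dim", "parents")]
    dimnames(mle) <- dimnames(probs)
    probs <- mle
  }
  k <- length(parents)
  pos <- match(parent, parents)
  if (is.na(pos)) stop(parent, " is not a parent of ", child)
  # Configuration index decomposed into the focal parent's digit and the
  # co-parents' digits.
  cfg <- seq_len(3L^k) - 1L
  focal <- (cfg %/% 3L^(pos - 1L)) %% 3L + 1L
  out <- matrix(0, 3, 3, dimnames = list(stateLevels(), stateLevels()))
  wPar <- numeric(3)
  for (s in 1:3) {
    cols <- which(focal == s)
    ws <- w[cols]
    wPar[s] <- sum(ws)
    if (sum(ws) > 0) {
      out[, s] <- as.numeric(probs[, cols, drop = FALSE] %*% (ws / sum(ws)))
    } else {
      # Parent state never observed: weight co-parent configurations by
      # their marginal distribution instead.
      coId <- cfg - (focal - 1L) * 3L^(pos - 1L)
      coW <- vapply(cols, function(cl) sum(w[coId == coId[cl]]), numeric(1))
      out[, s] <- if (sum(coW) > 0)
        as.numeric(probs[, cols, drop = FALSE] %*% (coW / sum(coW)))
      else rowMeans(probs[, cols, drop = FALSE])
    }
  }
  attr(out, "occupied") <- wPar > 0
  out
}
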