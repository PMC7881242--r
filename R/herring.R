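#' Rank candidate groups by forced-edge score change against a response
#'
#' Naive-Bayes-style screening of an annual response series (herring catch)
#' that is too short to enter the structure search directly: for each
#' candidate group `g` the edge `g -> response` is forced into the network
#' and the change in network score recorded. By score decomposability the
#' change involves only the response node's family,
#' `deltaScore = -(familyScore(response, g) - familyScore(response, NULL))`,
#' reported on the conventional cost scale where *more negative = better
#' fit* (an uninformative forced edge costs prior parameters, so its
#' deltaScore is >= 0). Entries are sorted ascending by `deltaScore` with
#' lexicographic tie-break; the forced edge's influence score is computed
#' from its fitted CPT.
#'
#' @param x a [DiscreteMatrix-class] of September-anchored yearly averages
#'   (response discretized with the rest).
#' @param response the response variable name.
#' @param candidates candidate variables (default: all non-degenerate
#'   variables except the response).
#' @param base optional [BayesNet-class] over the candidate variables; only
#'   used for validation since the ranking is family-local.
#' @param config a [ScoreConfig-class].
#' @return Data.frame with columns `group`, `deltaScore`, `is`, `rank`
#'   (rank 1 = most negative deltaScore).
#' @export
rankGroups <- function(x, response,
                       candidates = NULL, base = NULL,
                       config = scoreConfig()) {
  stopifnot(is(x, "DiscreteMatrix"))
  vars <- colnames(stateMatrix(x))
  if (!response %in% vars) stop("response '", response, "' not in the data")
  if (is.null(candidates))
    candidates <- setdiff(vars, c(response, degenerateVariables(x)))
  if (response %in% candidates)
    stop("response must not be among the candidates")
  if (!is.null(base) && response %in% netNodes(base))
    stop("response must not participate in the base network")
  s0 <- familyScore(response, character(0), x, config)
  rows <- lapply(candidates, function(g) {
    s1 <- familyScore(response, g, x, config)
    forced <- BayesNet(c(g, response), rbind(c(g, response)))
    forced <- fitCPTs(forced, x, config)
    data.frame(group = g,
               deltaScore = -(s1 - s0),
               is = influenceScore(forced, g, response))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$deltaScore, out$group), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
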