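# Bootstrap model averaging: structure learning is repeated on random 90%
# row subsamples (without replacement; rows are the weekly samples), edge
# occurrence frequencies and mean influence scores are tallied, and the
# bimodal frequency distribution is thresholded into a consensus network.

#' Learn networks on repeated row subsamples
#'
#' @param x a [DiscreteMatrix-class].
#' @param blacklist an [EdgeBlacklist-class] or `NULL`.
#' @param config a [ScoreConfig-class] (its `seed` slot is ignored here;
#'   use the `seed` argument).
#' @param nBoot number of replicates (default 100).
#' @param frac fraction of rows drawn without replacement per replicate
#'   (default 0.9).
#' @param seed integer seed making the whole run reproducible; `NA` uses
#'   the current RNG stream.
#' @return List of fitted [BayesNet-class] objects (CPTs fitted on each
#'   subsample, so influence scores can be summarized).
#' @export
bootstrapNetworks <- function(x, blacklist = NULL, config = scoreConfig(),
                              nBoot = 100, frac = 0.9, seed = NA_integer_) {
  stopifnot(is(x, "DiscreteMatrix"))
  if (frac <= 0 || frac > 1) stop("frac must lie in (0, 1]")
  n <- nrow(stateMatrix(x))
  if (n < 10L) stop("need at least 10 samples to subsample")
  m <- floor(frac * n)
  cfg <- config
  base <- if (is.na(seed)) 0 else as.numeric(seed) * 7919
  .withSeed(seed, {
    lapply(seq_len(nBoot), function(b) {
      rows <- if (m == n) seq_len(n) else sort(sample.int(n, m))
      # The search seed is a hash of the drawn rows, so identical
      # subsamples (e.g. frac = 1) always search identically.
      cfg@seed <- (base + sum(rows * (seq_along(rows) %% 97 + 1))) %%
        2147483647
      sub <- new("DiscreteMatrix",
                 states = stateMatrix(x)[rows, , drop = FALSE],
                 thresholds = x@thresholds, degenerate = x@degenerate,
                 provenance = sprintf("%s; bootstrap %d/%d",
                                      x@provenance, b, nBoot))
      net <- greedySearch(sub, blacklist, cfg)
      fitCPTs(net, sub, cfg)
    })
  })
}

#' Summarize edge occurrence over bootstrap networks
#'
#' @param nets non-empty list of fitted [BayesNet-class] objects.
#' @return Data.frame with one row per directed edge observed at least
#'   once: `parent`, `child`, `frequency` (occurrences / length(nets)) and
#'   `meanIS` (mean influence score over the networks containing the edge).
#' @export
summarizeEdges <- function(nets) {
  if (!length(nets)) stop("empty network list")
  recs <- lapply(nets, function(net) {
    e <- netEdges(net)
    if (!nrow(e)) return(NULL)
    data.frame(parent = e[, 1], child = e[, 2],
               is = vapply(seq_len(nrow(e)), function(k)
                 influenceScore(net, e[k, 1], e[k, 2]), numeric(1)))
  })
  recs <- do.call(rbind, recs)
  if (is.null(recs))
    return(data.frame(parent = character(0), child = character(0),
                      frequency = numeric(0), meanIS = numeric(0)))
  key <- .edgeKey(recs$parent, recs$child)
  agg <- lapply(split(recs, key), function(g)
    data.frame(parent = g$parent[1], child = g$child[1],
               frequency = nrow(g) / length(nets), meanIS = mean(g$is)))
  out <- do.call(rbind, agg)
  out <- out[order(-out$frequency, out$parent, out$child), ]
  rownames(out) <- NULL
  out
}

# Otsu-style two-class split of edge frequencies: brute force over cut
# points, maximizing between-class variance. Returns the threshold (midpoint
# between the two classes' nearest members).
.valleyThreshold <- function(freq) {
  u <- sort(unique(freq))
  if (length(u) < 2L) return(NA_real_)
  best <- -Inf; cut <- NA_real_
  for (k in seq_len(length(u) - 1L)) {
    lo <- freq[freq <= u[k]]; hi <- freq[freq > u[k]]
    bc <- length(lo) * length(hi) / length(freq)^2 *
      (mean(hi) - mean(lo))^2
    if (bc > best) { best <- bc; cut <- (u[k] + u[k + 1L]) / 2 }
  }
  cut
}

# Crude bimodality check on the frequency histogram: TRUE when the split
# separates two non-trivial classes with an empty or depressed valley bin.
.looksBimodal <- function(freq, cut) {
  if (is.na(cut)) return(FALSE)
  lo <- freq[freq < cut]; hi <- freq[freq >= cut]
  length(lo) > 0 && length(hi) > 0 &&
    (min(hi) - max(lo)) > stats::sd(freq) / 2
}

#' Threshold edge summaries into a consensus network
#'
#' The occurrence frequency of a *dependence* is the combined frequency of
#' its two directions (a DAG never holds both at once, so the sum is the
#' fraction of bootstraps containing the unordered pair): score-based
#' search identifies the dependence far more reliably than its
#' orientation, and thresholding directions separately would discard a
#' pair that appears in every bootstrap with an unstable arrow. The
#' `"valley"` rule locates the split between the two modes of the
#' (bimodal) pair-frequency distribution by an exhaustive two-class
#' variance split; if the distribution does not look bimodal it falls back
#' to a fixed 0.5 with a warning. All observed directions of a passing
#' pair are kept; a pair whose minority direction carries at least a
#' quarter of its occurrences is flagged `mutual` (rendered as an
#' undirected edge).
#'
#' @param summaries data.frame from [summarizeEdges()].
#' @param threshold `"valley"` (default) or a fixed numeric in \[0, 1),
#'   applied to the pair frequency.
#' @param nBoot number of bootstraps behind the summaries (metadata).
#' @return A [ConsensusNetwork-class]; its `edges` carry both the directed
#'   `frequency` and the unordered `pairFrequency`.
#' @export
consensusNetwork <- function(summaries, threshold = "valley", nBoot = NA) {
  if (!nrow(summaries)) stop("no edge summaries to threshold")
  pairKey <- paste(pmin(summaries$parent, summaries$child),
                   pmax(summaries$parent, summaries$child), sep = " -- ")
  pairFreq <- tapply(summaries$frequency, pairKey, function(f) min(sum(f), 1))
  summaries$pairFrequency <- as.numeric(pairFreq[pairKey])
  if (identical(threshold, "valley")) {
    cut <- .valleyThreshold(as.numeric(pairFreq))
    if (!.looksBimodal(as.numeric(pairFreq), cut)) {
      warning("pair-frequency distribution does not look bimodal; ",
              "falling back to threshold 0.5")
      cut <- 0.5
    }
  } else {
    cut <- as.numeric(threshold)
    if (is.na(cut) || cut < 0 || cut >= 1)
      stop("fixed threshold must lie in [0, 1)")
    if (cut == 0) cut <- .Machine$double.eps  # keep all observed edges
  }
  keep <- summaries[summaries$pairFrequency >= cut, , drop = FALSE]
  keepKey <- paste(pmin(keep$parent, keep$child),
                   pmax(keep$parent, keep$child), sep = " -- ")
  minShare <- vapply(seq_len(nrow(keep)), function(k) {
    f <- keep$frequency[keepKey == keepKey[k]]
    if (length(f) < 2L) 0 else min(f) / sum(f)
  }, numeric(1))
  keep$mutual <- minShare >= 0.25
  rownames(keep) <- NULL
  new("ConsensusNetwork", edges = keep, threshold = cut,
      nBoot = as.numeric(nBoot), summaries = summaries)
}

#' @rdname ConsensusNetwork-class
#' @exportMethod consensusEdges
setMethod("consensusEdges", "ConsensusNetwork", function(x) x@edges)

#' @rdname ConsensusNetwork-class
#' @exportMethod edgeSummaries
setMethod("edgeSummaries", "ConsensusNetwork", function(x) x@summaries)

setMethod("show", "ConsensusNetwork", function(object) {
  cat(sprintf(
    "ConsensusNetwork: %d edge(s) at frequency >= %.3f (of %d observed)\n",
    nrow(object@edges), object@threshold, nrow(object@summaries)))
})

#' Reduce a consensus network to a DAG for inference
#'
#' Edges are replayed in decreasing frequency order (ties: lexicographic);
#' the lower-frequency direction of a mutual pair, any edge that would
#' close a directed cycle, and any edge beyond the parent limit are
#' dropped. Edge direction within a dependent pair is only weakly
#' identified by the search, so nodes whose dependencies are known to point
#' into them (e.g. jellyfish fed by zooplankton groups in the spatial
#' snapshot) can be declared `sinks`: edges incident to a sink are oriented
#' toward it first.
#'
#' @param x a [ConsensusNetwork-class].
#' @param nodes node set of the result (default: all endpoint names).
#' @param maxParents in-degree cap (default 3).
#' @param sinks nodes whose incident edges are re-oriented toward them
#'   (edges between two sinks are left as learned).
#' @return A [BayesNet-class] (structure only; fit CPTs on data next).
#' @export
consensusToNetwork <- function(x, nodes = NULL, maxParents = 3,
                               sinks = character(0)) {
  stopifnot(is(x, "ConsensusNetwork"))
  e <- x@edges
  if (is.null(nodes)) nodes <- sort(unique(c(e$parent, e$child)))
  flip <- e$parent %in% sinks & !(e$child %in% sinks)
  if (any(flip)) {
    tmp <- e$parent[flip]
    e$parent[flip] <- e$child[flip]
    e$child[flip] <- tmp
  }
  e <- e[order(-e$frequency, e$parent, e$child), , drop = FALSE]
  acc <- matrix(character(0), 0, 2)
  for (k in seq_len(nrow(e))) {
    if (any(acc[, 1] == e$parent[k] & acc[, 2] == e$child[k])) next
    if (any(acc[, 1] == e$child[k] & acc[, 2] == e$parent[k])) next
    cand <- rbind(acc, c(e$parent[k], e$child[k]))
    if (sum(cand[, 2] == e$child[k]) > maxParents) next
    if (is.null(.topoOrder(nodes, cand))) next
    acc <- cand
  }
  BayesNet(nodes, acc)
}

#' Chi-squared comparison of edge occurrence between two periods
#'
#' Builds a periods-by-edges contingency table of bootstrap occurrence
#' counts over the union of observed edges and applies Pearson's
#' chi-squared test (no continuity correction). Identical summaries give
#' p = 1.
#'
#' @param a,b edge-summary data.frames from [summarizeEdges()], built with
#'   the same number of bootstraps.
#' @param nBoot that common number of bootstraps (default 100).
#' @return The test p-value.
#' @export
comparePeriods <- function(a, b, nBoot = 100) {
  keys <- union(.edgeKey(a$parent, a$child), .edgeKey(b$parent, b$child))
  if (!length(keys)) stop("no edges to compare")
  ca <- a$frequency[match(keys, .edgeKey(a$parent, a$child))] * nBoot
  cb <- b$frequency[match(keys, .edgeKey(b$parent, b$child))] * nBoot
  ca[is.na(ca)] <- 0; cb[is.na(cb)] <- 0
  tab <- round(rbind(ca, cb))
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (identical(tab[1, ], tab[2, ])) return(1)
  suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
}
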