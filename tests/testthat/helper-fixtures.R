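# Shared fixture builders. Everything is generated in code; no data files.

# SampleTable from a plain matrix with auto sample ids.
makeTable <- function(values, date = NULL, varType = NULL) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("s%03d", seq_len(nrow(values)))
  SampleTable(values, date = date, varType = varType)
}

# DiscreteMatrix straight from an integer state matrix (1/2/3).
makeDiscrete <- function(states, degenerate = character(0)) {
  if (is.null(rownames(states)))
    rownames(states) <- sprintf("s%03d", seq_len(nrow(states)))
  storage.mode(states) <- "integer"
  new("DiscreteMatrix", states = states,
      thresholds = setNames(rep(1, ncol(states)), colnames(states)),
      degenerate = degenerate, provenance = "test fixture")
}

# Hand-built fitted network: nodes/edges plus a named list of CPT matrices
# (3 x 3^k, columns in mixed-radix order over the *sorted* parents).
# Config weights default to uniform.
makeFittedNet <- function(nodes, edges, cpts, weights = NULL) {
  net <- BayesNet(nodes, edges)
  net@cpts <- lapply(nodes, function(v) {
    probs <- cpts[[v]]
    parents <- sort(if (nrow(net@edges)) {
      net@edges[net@edges[, 2] == v, 1]
    } else character(0))
    attr(probs, "parents") <- parents
    q <- if (is.matrix(probs)) ncol(probs) else 1L
    w <- if (!is.null(weights[[v]])) weights[[v]] else rep(1 / q, q)
    attr(probs, "configWeights") <- w
    probs
  })
  names(net@cpts) <- nodes
  net
}

# Deterministic 3x3 CPTs used by the influence-score contracts.
identityCPT <- function() diag(3)
reversalCPT <- function() diag(3)[, 3:1]

# Random fitted network over p nodes with random Dirichlet CPTs; used for
# inference oracle checks.
randomFittedNet <- function(p, seed, edgeProb = 0.35, maxParents = 3) {
  set.seed(seed)
  nodes <- sprintf("V%02d", seq_len(p))
  ord <- sample(nodes)
  edges <- NULL
  for (j in seq_along(ord)) {
    if (j == 1L) next
    pool <- ord[seq_len(j - 1L)]
    pa <- pool[runif(length(pool)) < edgeProb]
    if (length(pa) > maxParents) pa <- sample(pa, maxParents)
    if (length(pa)) edges <- rbind(edges, cbind(pa, ord[j]))
  }
  net <- BayesNet(nodes, if (is.null(edges)) NULL else edges)
  net@cpts <- lapply(nodes, function(v) {
    parents <- sort(if (nrow(net@edges)) {
      net@edges[net@edges[, 2] == v, 1]
    } else character(0))
    q <- 3L^length(parents)
    raw <- matrix(rgamma(3 * q, shape = 1) + 1e-3, 3, q)
    probs <- sweep(raw, 2, colSums(raw), "/")
    dimnames(probs) <- list(stateLevels(), NULL)
    attr(probs, "parents") <- parents
    attr(probs, "configWeights") <- rep(1 / q, q)
    probs
  })
  names(net@cpts) <- nodes
  net
}

# Direction-agnostic edge keys and F1 against a truth edge matrix.
undirectedKeys <- function(parent, child) {
  unique(paste(pmin(parent, child), pmax(parent, child), sep = " -- "))
}

edgeF1 <- function(parent, child, truth) {
  got <- undirectedKeys(parent, child)
  want <- undirectedKeys(truth[, 1], truth[, 2])
  tp <- sum(got %in% want)
  if (!length(got) || !tp) return(0)
  prec <- tp / length(got)
  rec <- tp / length(want)
  2 * prec * rec / (prec + rec)
}

# States sampled through a 3x3 CPT given parent states.
sampleChild <- function(parentStates, cptMat) {
  vapply(parentStates,
         function(s) sample.int(3L, 1L, prob = cptMat[, s]), integer(1))
}
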