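# Internal helpers shared across modules.

# Kahn topological order; NULL if the edge set contains a cycle.
.topoOrder <- function(nodes, edges) {
  if (!nrow(edges)) return(nodes)
  indeg <- setNames(integer(length(nodes)), nodes)
  tab <- table(factor(edges[, 2], levels = nodes))
  indeg[names(tab)] <- as.integer(tab)
  childrenOf <- split(edges[, 2], factor(edges[, 1], levels = nodes))
  order <- character(0)
  ready <- nodes[indeg == 0L]
  while (length(ready)) {
    v <- ready[1L]; ready <- ready[-1L]
    order <- c(order, v)
    for (ch in childrenOf[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) ready <- c(ready, ch)
    }
  }
  if (length(order) == length(nodes)) order else NULL
}

# TRUE if `to` is reachable from `from` along directed edges.
.reachable <- function(from, to, edges) {
  if (from == to) return(TRUE)
  if (!nrow(edges)) return(FALSE)
  seen <- from
  frontier <- from
  while (length(frontier)) {
    nxt <- unique(edges[edges[, 1] %in% frontier, 2])
    nxt <- setdiff(nxt, seen)
    if (to %in% nxt) return(TRUE)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  FALSE
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# stream; seed = NA means "use the current stream".
.withSeed <- function(seed, expr) {
  if (is.na(seed)) return(force(expr))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(seed)
    return(force(expr))
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

.edgeKey <- function(parent, child) paste(parent, child, sep = " -> ")

# Mixed-radix parent-configuration index (first parent fastest), 1-based.
# `states` is an integer matrix of sample states, `parents` a character
# vector of column names; returns a vector of config indices in 1:3^k.
.configIndex <- function(states, parents) {
  if (!length(parents)) return(rep.int(1L, nrow(states)))
  idx <- rep.int(0L, nrow(states))
  mult <- 1L
  for (p in parents) {
    idx <- idx + (states[, p] - 1L) * mult
    mult <- mult * 3L
  }
  idx + 1L
}

.assertScalarString <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(what, " must be a single string", call. = FALSE)
}
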