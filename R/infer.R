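# Exact inference on fitted networks. queryPosterior() runs sum-product
# variable elimination over the CPT factorization; posteriorByEnumeration()
# is a deliberately independent brute-force path over the full joint, used
# to validate the elimination code on small networks.

# A factor is list(vars = character, vals = array with dim rep(3, length(vars))).
.cptFactor <- function(net, node) {
  probs <- net@cpts[[node]]
  parents <- attr(probs, "parents")
  vars <- c(node, parents)
  list(vars = vars, vals = array(as.numeric(probs), dim = rep(3L, length(vars))))
}

.factorReduce <- function(f, var, state) {
  pos <- match(var, f$vars)
  if (is.na(pos)) return(f)
  idx <- rep(list(quote(expr = )), length(f$vars))
  idx[[pos]] <- state
  vals <- do.call(`[`, c(list(f$vals), idx, list(drop = FALSE)))
  keep <- setdiff(seq_along(f$vars), pos)
  if (!length(keep)) return(list(vars = character(0), vals = sum(vals)))
  list(vars = f$vars[keep],
       vals = array(vals, dim = rep(3L, length(keep))))
}

.factorMultiply <- function(f, g) {
  if (!length(f$vars))
    return(list(vars = g$vars, vals = g$vals * as.numeric(f$vals)))
  if (!length(g$vars))
    return(list(vars = f$vars, vals = f$vals * as.numeric(g$vals)))
  vars <- union(f$vars, g$vars)
  n <- length(vars)
  expand <- function(h) {
    pos <- match(h$vars, vars)
    perm <- c(pos, setdiff(seq_len(n), pos))
    out <- array(h$vals, dim = rep(3L, n))   # recycles over trailing dims
    aperm(out, order(perm))
  }
  list(vars = vars, vals = expand(f) * expand(g))
}

.factorMarginalize <- function(f, var) {
  pos <- match(var, f$vars)
  if (is.na(pos)) return(f)
  keep <- setdiff(seq_along(f$vars), pos)
  if (!length(keep))
    return(list(vars = character(0), vals = sum(f$vals)))
  vals <- apply(f$vals, keep, sum)
  list(vars = f$vars[keep], vals = array(vals, dim = rep(3L, length(keep))))
}

.asStateIndex <- function(state) {
  if (is.character(state)) {
    s <- match(toupper(state), stateLevels())
    if (anyNA(s)) stop("unknown state label: ", state)
    s
  } else as.integer(state)
}

#' Exact posterior query by variable elimination
#'
#' Computes `P(target = s | evidence)` exactly by sum-product variable
#' elimination over the network's CPT factorization (all nodes on paths
#' between evidence and target contribute through their factors).
#'
#' @param net a fitted [BayesNet-class].
#' @param target node to query.
#' @param evidence named list/vector of hard evidence, e.g.
#'   `c(SST = "LOW")`; states may be labels or indices 1:3. Empty for a
#'   marginal query.
#' @return Named probability vector over `ZERO`, `LOW`, `HIGH`.
#' @export
#' @examples
#' net <- BayesNet("A")
#' net@cpts <- list(A = structure(matrix(c(.2, .3, .5), 3),
#'   parents = character(0), configWeights = 1))
#' queryPosterior(net, "A")
queryPosterior <- function(net, target, evidence = list()) {
  stopifnot(is(net, "BayesNet"))
  if (!length(net@cpts)) stop("CPTs not fitted; run fitCPTs first")
  if (!target %in% net@nodes) stop("unknown target node '", target, "'")
  ev <- vapply(evidence, .asStateIndex, integer(1))
  if (length(ev)) {
    if (target %in% names(ev)) stop("target must not carry evidence")
    bad <- setdiff(names(ev), net@nodes)
    if (length(bad)) stop("unknown evidence node(s): ",
                          paste(bad, collapse = ", "))
  }
  factors <- lapply(net@nodes, .cptFactor, net = net)
  for (v in names(ev))
    factors <- lapply(factors, .factorReduce, var = v, state = ev[[v]])
  elim <- setdiff(net@nodes, c(target, names(ev)))
  # Greedy min-degree elimination order.
  while (length(elim)) {
    deg <- vapply(elim, function(v) {
      touching <- Filter(function(f) v %in% f$vars, factors)
      length(unique(unlist(lapply(touching, `[[`, "vars")))) - 1L
    }, integer(1))
    v <- elim[which.min(deg)]
    elim <- setdiff(elim, v)
    touching <- vapply(factors, function(f) v %in% f$vars, logical(1))
    if (!any(touching)) next
    prod <- Reduce(.factorMultiply, factors[touching])
    factors <- c(factors[!touching], list(.factorMarginalize(prod, v)))
  }
  res <- Reduce(.factorMultiply, factors)
  # Collapse any residual scalar factors and order by target.
  if (!identical(res$vars, target)) {
    for (v in setdiff(res$vars, target))
      res <- .factorMarginalize(res, v)
  }
  p <- as.numeric(res$vals)
  z <- sum(p)
  if (z <= 0)
    stop("evidence assignment has zero probability: ",
         paste(names(ev), stateLevels()[unlist(ev)], sep = "=",
               collapse = ", "))
  setNames(p / z, stateLevels())
}

#' Brute-force posterior by full-joint enumeration
#'
#' Materializes the full joint over all `3^p` configurations and sums it.
#' Exponential in the node count (intended for networks of up to ~12 nodes);
#' serves as an independent oracle for [queryPosterior()].
#'
#' @inheritParams queryPosterior
#' @return Named probability vector over the three states.
#' @export
posteriorByEnumeration <- function(net, target, evidence = list()) {
  stopifnot(is(net, "BayesNet"), length(net@cpts) > 0)
  p <- length(net@nodes)
  if (p > 14L) stop("enumeration limited to 14 nodes")
  ev <- vapply(evidence, .asStateIndex, integer(1))
  n <- 3L^p
  cols <- lapply(seq_len(p), function(j)
    rep(rep(1:3, each = 3L^(j - 1L)), length.out = n))
  names(cols) <- net@nodes
  joint <- rep(1, n)
  for (v in net@nodes) {
    probs <- net@cpts[[v]]
    parents <- attr(probs, "parents")
    cfg <- rep.int(1L, n)
    mult <- 1L
    for (pa in parents) {
      cfg <- cfg + (cols[[pa]] - 1L) * mult
      mult <- mult * 3L
    }
    joint <- joint * probs[cbind(cols[[v]], cfg)]
  }
  keep <- rep(TRUE, n)
  for (v in names(ev)) keep <- keep & cols[[v]] == ev[[v]]
  num <- vapply(1:3, function(s) sum(joint[keep & cols[[target]] == s]),
                numeric(1))
  if (sum(num) <= 0)
    stop("evidence assignment has zero probability")
  setNames(num / sum(num), stateLevels())
}

#' Graft spatially inferred dependencies onto a temporal network
#'
#' The temporal network is left untouched; each imported node (e.g. a
#' jellyfish variable from the cruise snapshot) is added with its
#' spatial-network parent edges and CPT verbatim, after normalizing parent
#' names through [canonicalGroupName()]. Imported nodes therefore enter as
#' sink nodes and the temporal nodes' marginals are unchanged.
#'
#' @param spatial fitted [BayesNet-class] the nodes are imported from.
#' @param temporal fitted [BayesNet-class] receiving them.
#' @param importedNodes character vector of `spatial` node names.
#' @param aliases optional extra name synonyms.
#' @return A fitted [BayesNet-class] over the union node set.
#' @export
transposeDependencies <- function(spatial, temporal, importedNodes,
                                  aliases = NULL) {
  stopifnot(is(spatial, "BayesNet"), is(temporal, "BayesNet"))
  if (!length(importedNodes)) return(temporal)
  missingNodes <- setdiff(importedNodes, spatial@nodes)
  if (length(missingNodes))
    stop("not in the spatial network: ", paste(missingNodes, collapse = ", "))
  if (!length(spatial@cpts) || !length(temporal@cpts))
    stop("both networks must have fitted CPTs")
  net <- temporal
  for (v in importedNodes) {
    pa <- .netParents(spatial@edges, v)
    paMapped <- canonicalGroupName(pa, aliases)
    paMapped[paMapped %in% importedNodes] <- pa[paMapped %in% importedNodes]
    unmatched <- setdiff(paMapped, c(net@nodes, importedNodes))
    if (length(unmatched))
      stop("parent(s) of '", v, "' missing from the temporal network: ",
           paste(unmatched, collapse = ", "))
    probs <- spatial@cpts[[v]]
    # Re-label the stored parent names to the temporal network's names,
    # keeping the (sorted-parent) configuration order intact.
    ord <- order(attr(probs, "parents"))
    mapSorted <- paMapped[match(sort(pa), pa)]
    if (!identical(mapSorted, sort(mapSorted))) {
      # Renaming may reorder parents; rebuild the CPT column order.
      k <- length(pa)
      perm <- order(mapSorted)
      cfg <- seq_len(3L^k) - 1L
      digits <- sapply(seq_len(k), function(i) (cfg %/% 3L^(i - 1L)) %% 3L)
      digits <- matrix(digits, ncol = k)
      newCfg <- as.integer(digits[, perm, drop = FALSE] %*% 3L^(seq_len(k) - 1L)) + 1L
      reordered <- probs
      reordered[, newCfg] <- probs[, seq_len(3L^k)]
      w <- attr(probs, "configWeights")
      wNew <- w; wNew[newCfg] <- w
      attr(reordered, "configWeights") <- wNew
      probs <- reordered
    }
    attr(probs, "parents") <- sort(mapSorted)
    newEdges <- cbind(parent = mapSorted, child = rep(v, length(mapSorted)))
    net@nodes <- c(net@nodes, v)
    net@edges <- rbind(net@edges, newEdges)
    net@cpts[[v]] <- probs
  }
  validObject(net)
  net@score <- NA_real_
  net
}

#' Historic abundance probabilities across decadal networks
#'
#' For each period, transposes the imported (jellyfish) dependencies onto
#' the period's network and queries the target's posterior under each
#' evidence state of the evidence node (sea surface temperature LOW and
#' HIGH). Emits both the full zero/low/high posterior and the pair
#' renormalized over LOW/HIGH with zeros excluded, as percentages.
#'
#' @param decadeNets named list of fitted [BayesNet-class] objects, one per
#'   period.
#' @param spatial fitted [BayesNet-class] holding the imported nodes.
#' @param target imported node to query (e.g. `"Aurelia aurita"`).
#' @param evidenceNode evidence variable present in every decadal network
#'   (e.g. `"SST"`).
#' @param importedNodes nodes to transpose (default: `target` and every
#'   spatial ancestor of it that is absent from the decadal networks).
#' @param aliases optional name synonyms for parent matching.
#' @return Data.frame ("posterior table"): one row per period and evidence
#'   state with columns `pZero`, `pLow`, `pHigh` (sum to 1) and
#'   `pctLowGivenNonzero`, `pctHighGivenNonzero` (sum to 100).
#' @export
historicAbundance <- function(decadeNets, spatial, target,
                              evidenceNode = "SST", importedNodes = NULL,
                              aliases = NULL) {
  stopifnot(is.list(decadeNets), length(decadeNets) > 0)
  rows <- list()
  for (lbl in names(decadeNets)) {
    tempNet <- decadeNets[[lbl]]
    if (!evidenceNode %in% tempNet@nodes)
      stop("evidence node '", evidenceNode, "' missing from period ", lbl)
    imp <- importedNodes
    if (is.null(imp)) {
      anc <- target
      repeat {
        more <- unique(unlist(lapply(anc, function(v)
          .netParents(spatial@edges, v))))
        more <- setdiff(more,
                        c(anc, canonicalGroupName(tempNet@nodes, aliases)))
        more <- more[!canonicalGroupName(more, aliases) %in% tempNet@nodes]
        if (!length(more)) break
        anc <- c(anc, more)
      }
      imp <- rev(anc)   # parents before children so grafting stays acyclic
    }
    net <- transposeDependencies(spatial, tempNet, imp, aliases)
    for (st in c("LOW", "HIGH")) {
      post <- queryPosterior(net, target,
                             stats::setNames(list(st), evidenceNode))
      nz <- post["LOW"] + post["HIGH"]
      rows[[length(rows) + 1L]] <- data.frame(
        period = lbl, evidence = st,
        pZero = unname(post["ZERO"]), pLow = unname(post["LOW"]),
        pHigh = unname(post["HIGH"]),
        pctLowGivenNonzero = unname(100 * post["LOW"] / nz),
        pctHighGivenNonzero = unname(100 * post["HIGH"] / nz))
    }
  }
  do.call(rbind, rows)
}
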