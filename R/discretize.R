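#' Discretize abundances into ZERO / LOW / HIGH states
#'
#' Exact zeros form their own state (absence is ecologically distinct from
#' low abundance). For each variable the LOW/HIGH break is the median of its
#' *non-zero* values: values at or below the median code LOW, values above
#' it HIGH. Variables occupying fewer than two states (all zero, or constant
#' positive) are flagged degenerate and excluded from network learning.
#'
#' @param x a [SampleTable-class] with no missing values in the columns to
#'   be discretized.
#' @param variables columns to discretize (default: all).
#' @return A [DiscreteMatrix-class].
#' @export
#' @examples
#' m <- matrix(c(0, 0, 1:8), ncol = 1,
#'             dimnames = list(paste0("s", 1:10), "grp"))
#' d <- discretizeThreeBins(SampleTable(m))
#' table(factor(stateMatrix(d), levels = 1:3, labels = stateLevels()))
discretizeThreeBins <- function(x, variables = variableNames(x)) {
  stopifnot(is(x, "SampleTable"))
  v <- sampleValues(x)[, variables, drop = FALSE]
  if (anyNA(v)) {
    bad <- variables[colSums(is.na(v)) > 0]
    stop("missing values in column(s): ", paste(bad, collapse = ", "))
  }
  states <- matrix(1L, nrow(v), ncol(v), dimnames = dimnames(v))
  thresholds <- setNames(rep(NA_real_, ncol(v)), colnames(v))
  degenerate <- character(0)
  for (j in seq_len(ncol(v))) {
    nz <- v[, j] != 0
    if (!any(nz)) {            # all zeros: single-state
      degenerate <- c(degenerate, colnames(v)[j])
      next
    }
    med <- stats::median(v[nz, j])
    thresholds[j] <- med
    states[nz, j] <- ifelse(v[nz, j] <= med, 2L, 3L)
    if (length(unique(states[, j])) < 2L)
      degenerate <- c(degenerate, colnames(v)[j])
  }
  if (length(degenerate))
    warning("single-state variable(s) excluded from learning: ",
            paste(degenerate, collapse = ", "))
  new("DiscreteMatrix", states = states, thresholds = thresholds,
      degenerate = degenerate,
      provenance = sprintf("discretizeThreeBins on %d samples", nrow(v)))
}

#' @rdname DiscreteMatrix-class
#' @exportMethod stateMatrix
setMethod("stateMatrix", "DiscreteMatrix", function(x) x@states)

#' @rdname DiscreteMatrix-class
#' @exportMethod stateThresholds
setMethod("stateThresholds", "DiscreteMatrix", function(x) x@thresholds)

#' @rdname DiscreteMatrix-class
#' @exportMethod degenerateVariables
setMethod("degenerateVariables", "DiscreteMatrix", function(x) x@degenerate)

setMethod("show", "DiscreteMatrix", function(object) {
  s <- object@states
  cat(sprintf("DiscreteMatrix: %d samples x %d variables (ZERO/LOW/HIGH)\n",
              nrow(s), ncol(s)))
  if (length(object@degenerate))
    cat("  degenerate:", paste(object@degenerate, collapse = ", "), "\n")
})

#' Per-variable state tallies
#'
#' @param x a [DiscreteMatrix-class].
#' @return Data.frame with one row per variable: `median`, `nZero`, `nLow`,
#'   `nHigh` (the layout of the published count-summary tables).
#' @export
stateTallies <- function(x) {
  stopifnot(is(x, "DiscreteMatrix"))
  s <- stateMatrix(x)
  cnt <- t(apply(s, 2, function(col) tabulate(col, nbins = 3L)))
  data.frame(variable = colnames(s),
             median = unname(x@thresholds[colnames(s)]),
             nZero = cnt[, 1], nLow = cnt[, 2], nHigh = cnt[, 3],
             row.names = NULL)
}

#' Serialize a DiscreteMatrix
#'
#' Writes the state labels as CSV and the thresholds as a JSON sidecar
#' (`<path>.thresholds.json`).
#'
#' @param x a [DiscreteMatrix-class].
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
writeDiscreteMatrix <- function(x, path) {
  stopifnot(is(x, "DiscreteMatrix"))
  lab <- matrix(stateLevels()[stateMatrix(x)], nrow(stateMatrix(x)),
                dimnames = dimnames(stateMatrix(x)))
  utils::write.csv(as.data.frame(lab), path, row.names = TRUE, quote = FALSE)
  jsonlite::write_json(as.list(x@thresholds),
                       paste0(path, ".thresholds.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Blacklist variable pairs showing no joint-distribution signal
#'
#' For every unordered variable pair, a Pearson chi-squared test (no
#' continuity correction; empty rows/columns dropped before computing the
#' statistic) compares the observed joint state table with the product of
#' its margins. Pairs with p > `alpha` are blacklisted: with heavily
#' zero-inflated data, such pairs would otherwise attract spurious edges
#' driven by mutual zeros.
#'
#' @param x a [DiscreteMatrix-class].
#' @param alpha significance cut; pairs with p > alpha are disallowed
#'   (default 0.25).
#' @param variables variables to consider (default: all non-degenerate).
#' @return An [EdgeBlacklist-class].
#' @export
contingencyFilter <- function(x, alpha = 0.25,
                              variables = setdiff(colnames(stateMatrix(x)),
                                                  degenerateVariables(x))) {
  stopifnot(is(x, "DiscreteMatrix"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)")
  s <- stateMatrix(x)[, variables, drop = FALSE]
  if (!ncol(s)) stop("no variables to test")
  if (ncol(s) < 2L) {
    empty <- matrix(character(0), 0, 2,
                    dimnames = list(NULL, c("var1", "var2")))
    return(new("EdgeBlacklist", pairs = empty, alpha = alpha,
               tests = data.frame(var1 = character(0), var2 = character(0),
                                  statistic = numeric(0), p = numeric(0),
                                  blacklisted = logical(0))))
  }
  pairs <- utils::combn(sort(variables), 2)
  res <- apply(pairs, 2, function(pr) {
    tab <- table(factor(s[, pr[1]], levels = 1:3),
                 factor(s[, pr[2]], levels = 1:3))
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    if (nrow(tab) < 2L || ncol(tab) < 2L) return(c(stat = 0, p = 1))
    ts <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    c(stat = unname(ts$statistic), p = unname(ts$p.value))
  })
  tests <- data.frame(var1 = pairs[1, ], var2 = pairs[2, ],
                      statistic = res["stat", ], p = res["p", ],
                      blacklisted = res["p", ] > alpha, row.names = NULL)
  bl <- as.matrix(tests[tests$blacklisted, c("var1", "var2")])
  colnames(bl) <- c("var1", "var2")
  new("EdgeBlacklist", pairs = matrix(bl, ncol = 2,
                                      dimnames = list(NULL, c("var1", "var2"))),
      alpha = alpha, tests = tests)
}

#' @rdname EdgeBlacklist-class
#' @exportMethod blacklistPairs
setMethod("blacklistPairs", "EdgeBlacklist", function(x) x@pairs)

setMethod("show", "EdgeBlacklist", function(object) {
  cat(sprintf("EdgeBlacklist: %d pair(s) disallowed at alpha = %.2f\n",
              nrow(object@pairs), object@alpha))
})

#' Is an (unordered) pair blacklisted?
#'
#' @param x an [EdgeBlacklist-class] (or `NULL`, meaning nothing is
#'   blacklisted).
#' @param a,b variable names.
#' @return Logical scalar; symmetric in `a`, `b`.
#' @export
isBlacklisted <- function(x, a, b) {
  if (is.null(x)) return(FALSE)
  stopifnot(is(x, "EdgeBlacklist"))
  lo <- pmin(a, b); hi <- pmax(a, b)
  p <- x@pairs
  any(p[, 1] == lo & p[, 2] == hi)
}

#' Write an EdgeBlacklist as two-column CSV
#'
#' @param x an [EdgeBlacklist-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBlacklist <- function(x, path) {
  stopifnot(is(x, "EdgeBlacklist"))
  utils::write.csv(as.data.frame(x@pairs), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
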