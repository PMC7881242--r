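test_that("three-bin coding reproduces the published tally pattern", {
  # ten yearly values, two zeros, non-zero median 0.71 -> 2/4/4
  vals <- c(0, 0, 0.30, 0.50, 0.60, 0.70, 0.72, 0.90, 1.10, 1.30)
  st <- makeTable(matrix(vals, ncol = 1, dimnames = list(NULL, "WT")))
  d <- discretizeThreeBins(st)
  tal <- stateTallies(d)
  expect_equal(tal$median, 0.71)
  expect_equal(c(tal$nZero, tal$nLow, tal$nHigh), c(2L, 4L, 4L))
})

test_that("zeros are their own state and ties at the median code LOW", {
  st <- makeTable(matrix(c(0, 0, 1:8), ncol = 1, dimnames = list(NULL, "A")))
  d <- discretizeThreeBins(st)
  expect_equal(unname(stateThresholds(d)["A"]), 4.5)
  tal <- stateTallies(d)
  expect_equal(c(tal$nZero, tal$nLow, tal$nHigh), c(2L, 4L, 4L))
  # state is ZERO exactly for raw zeros
  expect_equal(unname(which(stateMatrix(d)[, "A"] == 1L)), 1:2)
  # a value equal to the median is LOW
  st2 <- makeTable(matrix(c(1, 2, 2, 5), ncol = 1,
                          dimnames = list(NULL, "A")))
  expect_equal(unname(stateMatrix(discretizeThreeBins(st2))[, "A"]),
               c(2L, 2L, 2L, 3L))
})

test_that("degenerate variables are flagged and excluded", {
  st <- makeTable(cbind(A = c(0, 0, 0), B = c(2, 2, 2), C = c(0, 1, 5)))
  expect_warning(d <- discretizeThreeBins(st), "single-state")
  expect_setequal(degenerateVariables(d), c("A", "B"))
  # all-positive constant vector ties the median everywhere -> all LOW
  expect_true(all(stateMatrix(d)[, "B"] == 2L))
  expect_true(is.na(stateThresholds(d)["A"]))
  expect_error(contingencyFilter(d), NA)  # degenerate columns are skipped
})

test_that("missing values in a discretized column are rejected", {
  st <- makeTable(cbind(A = c(1, NA, 3), SST = c(1, 2, 3)),
                  varType = c(A = "env", SST = "env"))
  expect_error(discretizeThreeBins(st), "A")
})

test_that("tallies conserve the sample count on fuzzed inputs", {
  set.seed(501)
  for (rep in 1:20) {
    n <- sample(10:60, 1)
    m <- cbind(A = rbinom(n, 1, 0.6) * rlnorm(n),
               B = rbinom(n, 1, 0.8) * rpois(n, 4))
    d <- suppressWarnings(discretizeThreeBins(makeTable(m)))
    tal <- stateTallies(d)
    expect_equal(tal$nZero + tal$nLow + tal$nHigh, rep(n, 2L))
  }
})

test_that("discretization is invariant to monotone relabelling above zero", {
  set.seed(502)
  x <- rbinom(40, 1, 0.7) * rlnorm(40, 1)
  d1 <- discretizeThreeBins(makeTable(matrix(x, ncol = 1,
                                             dimnames = list(NULL, "A"))))
  d2 <- discretizeThreeBins(makeTable(matrix(x^2, ncol = 1,
                                             dimnames = list(NULL, "A"))))
  expect_identical(stateMatrix(d1), stateMatrix(d2))
})

test_that("contingency filter keeps dependent pairs and drops independence", {
  # perfect dependence: identical state sequences over 100 samples
  set.seed(503)
  s <- sample(1:3, 100, replace = TRUE)
  d <- makeDiscrete(cbind(A = s, B = s))
  bl <- contingencyFilter(d)
  expect_false(isBlacklisted(bl, "A", "B"))
  expect_lt(bl@tests$p[1], 1e-10)
  # joint exactly proportional to the product of margins: statistic 0, p 1
  a <- rep(1:3, each = 30)
  b <- rep(rep(1:3, times = 3), times = 10)
  d2 <- makeDiscrete(cbind(A = a, B = b))
  bl2 <- contingencyFilter(d2)
  expect_true(isBlacklisted(bl2, "A", "B"))
  expect_equal(bl2@tests$statistic[1], 0)
  expect_equal(bl2@tests$p[1], 1)
})

test_that("chi-squared statistic matches the textbook closed form", {
  # a specified 3x3 joint table, statistic = sum (O-E)^2 / E by hand
  tab <- matrix(c(20, 5, 5,
                  5, 20, 5,
                  5, 5, 20), 3, 3, byrow = TRUE)
  a <- rep(1:3, times = rowSums(tab))
  b <- unlist(lapply(1:3, function(i) rep(1:3, times = tab[i, ])))
  d <- makeDiscrete(cbind(A = a, B = b))
  bl <- contingencyFilter(d)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  oracle <- sum((tab - expected)^2 / expected)
  expect_equal(bl@tests$statistic[1], oracle)
})

test_that("the blacklist is symmetric and honours alpha", {
  set.seed(504)
  s <- sample(1:3, 60, replace = TRUE)
  noise <- sample(1:3, 60, replace = TRUE)
  d <- makeDiscrete(cbind(A = s, B = s, C = noise))
  bl <- contingencyFilter(d, alpha = 0.25)
  for (pr in list(c("A", "B"), c("A", "C"), c("B", "C")))
    expect_identical(isBlacklisted(bl, pr[1], pr[2]),
                     isBlacklisted(bl, pr[2], pr[1]))
  expect_error(contingencyFilter(d, alpha = 1.2), "alpha")
})

test_that("discrete matrices serialize with a threshold sidecar", {
  st <- makeTable(cbind(A = c(0, 1, 2, 5), B = c(1, 2, 3, 4)))
  d <- discretizeThreeBins(st)
  path <- withr::local_tempfile(fileext = ".csv")
  writeDiscreteMatrix(d, path)
  lab <- utils::read.csv(path, row.names = 1)
  expect_equal(lab[1, "A"], "ZERO")
  side <- jsonlite::read_json(paste0(path, ".thresholds.json"))
  expect_equal(side$A, 2)
})
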