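test_that("family score matches the Dirichlet-multinomial closed form", {
  # binary-occupancy variable with counts (3, 1), ess = 1, no parents:
  # log [ B(alpha + counts) / B(alpha) ] with alpha = (1/2, 1/2)
  d <- makeDiscrete(cbind(A = c(2L, 2L, 2L, 3L)))
  counts <- c(3, 1)
  alpha <- c(0.5, 0.5)
  lmbeta <- function(a) sum(lgamma(a)) - lgamma(sum(a))
  oracle <- lmbeta(alpha + counts) - lmbeta(alpha)
  expect_equal(familyScore("A", character(0), d, scoreConfig(ess = 1)),
               oracle, tolerance = 1e-12)
  # three occupied states, counts (2, 3, 5): same closed form at r = 3
  d3 <- makeDiscrete(cbind(A = rep(1:3, times = c(2, 3, 5))))
  alpha3 <- rep(1 / 3, 3)
  expect_equal(familyScore("A", character(0), d3, scoreConfig(ess = 1)),
               lmbeta(alpha3 + c(2, 3, 5)) - lmbeta(alpha3),
               tolerance = 1e-12)
})

test_that("a constant parent leaves the family score unchanged", {
  d <- makeDiscrete(cbind(A = rep(1:3, times = c(3, 4, 3)), K = rep(2L, 10)))
  expect_equal(familyScore("A", "K", d), familyScore("A", character(0), d))
})

test_that("the network score decomposes into family scores", {
  set.seed(601)
  s <- cbind(A = sample(1:3, 80, TRUE), B = sample(1:3, 80, TRUE),
             C = sample(1:3, 80, TRUE))
  d <- makeDiscrete(s)
  net <- BayesNet(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
  expect_equal(networkScore(net, d),
               familyScore("A", character(0), d) +
                 familyScore("B", "A", d) +
                 familyScore("C", "B", d))
})

test_that("family score validates its arguments", {
  d <- makeDiscrete(cbind(A = rep(1:2, 5), B = rep(1:2, each = 5)))
  expect_error(familyScore("A", "A", d), "parents")
  expect_error(familyScore("Z", character(0), d), "Z")
  expect_error(familyScore("A", c("B", "B", "B", "B"), d,
                           scoreConfig(maxParents = 3)), "maxParents")
})

test_that("greedy search attains the exhaustive optimum on three nodes", {
  hits <- 0L
  nSeeds <- 20L
  for (sd in seq_len(nSeeds)) {
    set.seed(sd)
    a <- sample(1:3, 200, TRUE, prob = c(0.3, 0.4, 0.3))
    b <- sampleChild(a, planknet:::.posCPT())
    c_ <- sample(1:3, 200, TRUE)
    d <- makeDiscrete(cbind(A = a, B = b, C = c_))
    cfg <- scoreConfig(seed = sd, restarts = 3)
    g <- greedySearch(d, NULL, cfg)
    e <- exhaustiveSearch(d, NULL, cfg)
    hits <- hits + (abs(netScore(g) - netScore(e)) < 1e-9)
  }
  expect_gte(hits / nSeeds, 0.95)
})

test_that("exhaustive enumeration visits all 25 DAGs on three nodes", {
  d <- makeDiscrete(cbind(A = rep(1:3, 10), B = rep(1:3, each = 10),
                          C = rep(c(1L, 2L, 3L), times = c(10, 10, 10))))
  e <- exhaustiveSearch(d, NULL, scoreConfig())
  expect_equal(e@info$nDags, 25L)
})

test_that("independent data yields the empty network", {
  # note: very large ess makes BDeu *denser*, not sparser; a moderate
  # prior keeps chance dependence below the parameter cost
  for (sd in c(602, 603, 604)) {
    set.seed(sd)
    d <- makeDiscrete(cbind(A = sample(1:3, 120, TRUE),
                            B = sample(1:3, 120, TRUE),
                            C = sample(1:3, 120, TRUE)))
    net <- greedySearch(d, NULL, scoreConfig(ess = 5, seed = 1))
    expect_equal(nrow(netEdges(net)), 0L)
  }
})

test_that("blacklisted pairs never appear even when truly dependent", {
  set.seed(603)
  a <- sample(1:3, 300, TRUE)
  b <- sampleChild(a, planknet:::.posCPT())
  d <- makeDiscrete(cbind(A = a, B = b))
  bl <- new("EdgeBlacklist",
            pairs = matrix(c("A", "B"), 1, 2,
                           dimnames = list(NULL, c("var1", "var2"))),
            alpha = 0.25, tests = data.frame())
  expect_warning(net <- greedySearch(d, bl, scoreConfig(seed = 2)),
                 "blacklisted")
  expect_equal(nrow(netEdges(net)), 0L)
})

test_that("search results are deterministic given the seed and acyclic", {
  set.seed(604)
  a <- sample(1:3, 150, TRUE)
  b <- sampleChild(a, planknet:::.posCPT())
  c_ <- sampleChild(b, planknet:::.negCPT())
  d <- makeDiscrete(cbind(A = a, B = b, C = c_))
  n1 <- greedySearch(d, NULL, scoreConfig(seed = 42))
  n2 <- greedySearch(d, NULL, scoreConfig(seed = 42))
  expect_identical(netEdges(n1), netEdges(n2))
  expect_false(is.null(planknet:::.topoOrder(netNodes(n1), netEdges(n1))))
  # the parent limit binds
  expect_lte(max(table(factor(netEdges(n1)[, 2], levels = netNodes(n1)))), 3)
})

test_that("CPT fitting recovers empirical proportions as ess vanishes", {
  d <- makeDiscrete(cbind(A = rep(1:3, times = c(2, 3, 5))))
  net <- fitCPTs(BayesNet("A"), d, scoreConfig(ess = 1e-9))
  expect_equal(as.numeric(cpt(net, "A")), c(0.2, 0.3, 0.5),
               tolerance = 1e-6)
})

test_that("unobserved parent configurations fall back to the prior", {
  # parent only ever LOW or HIGH; the ZERO column is unreachable
  d <- makeDiscrete(cbind(P = rep(2:3, each = 6),
                          C = c(rep(1:3, 2), rep(3L, 6))))
  net <- fitCPTs(BayesNet(c("P", "C"), rbind(c("P", "C"))), d)
  probs <- cpt(net, "C")
  expect_equal(colSums(probs), rep(1, 3))
  # an occupied config with zero counts spreads uniformly over occupied
  # child states
  d2 <- makeDiscrete(cbind(P = c(rep(2L, 6), rep(3L, 3), 1L),
                           C = c(rep(1:3, 3), 2L)))
  net2 <- fitCPTs(BayesNet(c("P", "C"), rbind(c("P", "C"))), d2,
                  scoreConfig(ess = 1))
  expect_equal(colSums(cpt(net2, "C")), rep(1, 3))
  expect_error(fitCPTs(BayesNet(c("P", "Q"), rbind(c("P", "Q"))), d),
               "Q")
})

test_that("every fitted CPT row is a probability vector", {
  set.seed(605)
  a <- sample(1:3, 100, TRUE)
  b <- sampleChild(a, planknet:::.posCPT())
  d <- makeDiscrete(cbind(A = a, B = b))
  net <- fitCPTs(greedySearch(d, NULL, scoreConfig(seed = 5)), d)
  for (v in netNodes(net))
    expect_equal(colSums(cpt(net, v)), rep(1, ncol(cpt(net, v))),
                 tolerance = 1e-9)
})
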