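# Exact inference, transposition of spatial dependencies and the historic
# abundance table.

test_that("single-edge and disconnected queries reduce to CPT rows", {
  cptC <- planknet:::.posCPT()
  net <- makeFittedNet(c("P", "C", "Z"), rbind(c("P", "C")),
                       list(P = c(0.2, 0.3, 0.5), C = cptC,
                            Z = c(0.1, 0.6, 0.3)))
  # evidence on the only parent returns the CPT column
  post <- queryPosterior(net, "C", c(P = "HIGH"))
  expect_equal(unname(post), unname(cptC[, 3]))
  # a disconnected target returns its marginal
  post2 <- queryPosterior(net, "Z", c(P = "LOW"))
  expect_equal(unname(post2), c(0.1, 0.6, 0.3))
})

test_that("a three-node chain matches the hand-summed propagation", {
  cptY <- planknet:::.posCPT()
  cptZ <- planknet:::.negCPT()
  net <- makeFittedNet(c("X", "Y", "Z"),
                       rbind(c("X", "Y"), c("Y", "Z")),
                       list(X = c(0.3, 0.4, 0.3), Y = cptY, Z = cptZ))
  post <- queryPosterior(net, "Z", c(X = "HIGH"))
  oracle <- as.numeric(cptZ %*% cptY[, 3])  # sum over Y of P(Z|Y) P(Y|X=H)
  expect_equal(unname(post), oracle)
})

test_that("variable elimination equals full-joint enumeration", {
  for (sd in 1:25) {
    p <- 3 + (sd %% 8)
    net <- randomFittedNet(p, seed = 9000 + sd)
    target <- netNodes(net)[1]
    evNode <- netNodes(net)[p]
    for (ev in list(list(), setNames(list("LOW"), evNode))) {
      a <- queryPosterior(net, target, ev)
      b <- posteriorByEnumeration(net, target, ev)
      expect_lt(max(abs(a - b)), 1e-9)
    }
  }
})

test_that("impossible evidence raises an identifying error", {
  cptC <- cbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  net <- makeFittedNet(c("P", "C"), rbind(c("P", "C")),
                       list(P = c(1, 0, 0), C = cptC))
  expect_error(queryPosterior(net, "C", c(P = "HIGH")), "zero probability")
  expect_error(queryPosterior(net, "P", c(P = "LOW")), "target")
  expect_error(queryPosterior(net, "C", c(Q = "LOW")), "Q")
})

test_that("transposition grafts sink nodes without disturbing the host", {
  # temporal network: SST -> WT
  temporal <- makeFittedNet(
    c("SST", "Warm Temperate"), rbind(c("SST", "Warm Temperate")),
    list("SST" = c(0, 0.5, 0.5), "Warm Temperate" = planknet:::.posCPT2()))
  # spatial network: WT -> Aurelia
  spatial <- makeFittedNet(
    c("Warm Temperate", "Aurelia"), rbind(c("Warm Temperate", "Aurelia")),
    list("Warm Temperate" = c(1, 1, 1) / 3, "Aurelia" = planknet:::.negCPT()))
  combined <- transposeDependencies(spatial, temporal, "Aurelia")
  expect_setequal(netNodes(combined), c("SST", "Warm Temperate", "Aurelia"))
  expect_true(any(netEdges(combined)[, 1] == "Warm Temperate" &
                    netEdges(combined)[, 2] == "Aurelia"))
  # marginals of host nodes unchanged by adding a sink
  for (v in c("SST", "Warm Temperate"))
    expect_equal(queryPosterior(combined, v), queryPosterior(temporal, v),
                 tolerance = 1e-12)
  # empty import returns the host unchanged
  expect_identical(transposeDependencies(spatial, temporal, character(0)),
                   temporal)
  # unmatched parent names the missing node
  orphan <- makeFittedNet(
    c("Nonesuch", "Aurelia"), rbind(c("Nonesuch", "Aurelia")),
    list("Nonesuch" = c(1, 1, 1) / 3, "Aurelia" = planknet:::.posCPT()))
  expect_error(transposeDependencies(orphan, temporal, "Aurelia"),
               "Nonesuch")
})

test_that("parent aliases are normalized during transposition", {
  temporal <- makeFittedNet(
    c("SST", "Temperate Oceanic"), rbind(c("SST", "Temperate Oceanic")),
    list("SST" = c(0, 0.5, 0.5),
         "Temperate Oceanic" = planknet:::.posCPT2()))
  # spatial net names the group by its synonym "Cold Temperate"
  spatial <- makeFittedNet(
    c("Cold Temperate", "Aurelia"), rbind(c("Cold Temperate", "Aurelia")),
    list("Cold Temperate" = c(1, 1, 1) / 3,
         "Aurelia" = planknet:::.posCPT()))
  combined <- transposeDependencies(spatial, temporal, "Aurelia")
  expect_true(any(netEdges(combined)[, 1] == "Temperate Oceanic" &
                    netEdges(combined)[, 2] == "Aurelia"))
})

test_that("historic abundance rows renormalize and track the evidence", {
  # decade net where the target's parent tracks SST positively
  temporal <- makeFittedNet(
    c("SST", "Warm Temperate"), rbind(c("SST", "Warm Temperate")),
    list("SST" = c(0, 0.5, 0.5), "Warm Temperate" = planknet:::.posCPT2()))
  spatial <- makeFittedNet(
    c("Warm Temperate", "Aurelia"), rbind(c("Warm Temperate", "Aurelia")),
    list("Warm Temperate" = c(1, 1, 1) / 3,
         "Aurelia" = planknet:::.posCPT()))
  tab <- historicAbundance(list("1970s" = temporal, "1980s" = temporal),
                           spatial, "Aurelia", "SST",
                           importedNodes = "Aurelia")
  expect_equal(nrow(tab), 4L)  # 2 periods x 2 evidence states
  expect_equal(tab$pZero + tab$pLow + tab$pHigh, rep(1, 4))
  expect_equal(tab$pctLowGivenNonzero + tab$pctHighGivenNonzero,
               rep(100, 4))
  # positive chain SST -> WT -> Aurelia: high SST raises P(high Aurelia)
  hi <- tab$pHigh[tab$evidence == "HIGH"][1]
  lo <- tab$pHigh[tab$evidence == "LOW"][1]
  expect_gt(hi, lo)
  # an evidence node with no influence yields identical rows
  flatSpatial <- makeFittedNet(
    c("Warm Temperate", "Aurelia"), NULL,
    list("Warm Temperate" = c(1, 1, 1) / 3,
         "Aurelia" = c(0.2, 0.5, 0.3)))
  tab2 <- historicAbundance(list(d = temporal), flatSpatial, "Aurelia",
                            "SST", importedNodes = "Aurelia")
  expect_equal(tab2$pHigh[1], tab2$pHigh[2])
})
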