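test_that("generation is bit-reproducible from the seed", {
  spec <- plantedSpec(nCommunities = 3, nodesPerCommunity = 5, frames = 50,
                      interContactP = rbind(c(1, 2, 0.3)), seed = 99)
  a <- generateState(spec, "s")
  b <- generateState(spec, "s")
  expect_identical(repCoords(a$ensemble), repCoords(b$ensemble))
  expect_identical(a$ensemble@heavy, b$ensemble@heavy)
  # a different state label gives the same topology, different frames
  c_ <- generateState(spec, "t")
  expect_identical(nodeTable(a$ensemble), nodeTable(c_$ensemble))
  expect_false(identical(repCoords(a$ensemble), repCoords(c_$ensemble)))
})

test_that("full intra occupancy is planted exactly", {
  spec <- plantedSpec(nCommunities = 2, nodesPerCommunity = 6, frames = 40,
                      intraContactP = 1, interContactP = rbind(c(1, 2, 0.5)),
                      seed = 17)
  st <- generateState(spec, "x")
  P <- probMatrix(contactProbability(st$ensemble))
  memb <- st$membership
  n <- length(memb)
  nodes <- nodeTable(st$ensemble)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (memb[i] != memb[j]) next
    if (nodes$chain[i] == nodes$chain[j] &&
        abs(nodes$resno[i] - nodes$resno[j]) <= 1) next
    expect_identical(P[i, j], 1)
  }
})

test_that("planted occupancies are recovered within sampling error", {
  spec <- plantedSpec(nCommunities = 2, nodesPerCommunity = 6, frames = 1000,
                      intraContactP = 0.9,
                      interContactP = rbind(c(1, 2, 0.3)), seed = 23)
  st <- generateState(spec, "x")
  P <- probMatrix(contactProbability(st$ensemble))
  pp <- st$plantedPairs
  expect_equal(nrow(pp), 1L)
  expect_lt(abs(P[pp$bridgeA, pp$bridgeB] - 0.3), 0.05)
  # intra pairs concentrate around 0.9
  memb <- st$membership
  nodes <- nodeTable(st$ensemble)
  vals <- c()
  for (i in 1:11) for (j in (i + 1):12) {
    if (memb[i] != memb[j]) next
    if (abs(nodes$resno[i] - nodes$resno[j]) <= 1 &&
        nodes$chain[i] == nodes$chain[j]) next
    vals <- c(vals, P[i, j])
  }
  expect_lt(max(abs(vals - 0.9)), 0.06)
})

test_that("transition pairs plant signed contact changes with shared bridges", {
  spec <- plantedSpec(nCommunities = 4, nodesPerCommunity = 8, frames = 600,
                      intraContactP = 0.95,
                      interContactP = rbind(c(1, 2, 0.3), c(3, 4, 0.5)),
                      seed = 7)
  tp <- generateTransitionPair(spec, rbind(c(1, 2, 0.4), c(3, 4, -0.4)))
  expect_identical(nodeTable(tp$stateA$ensemble),
                   nodeTable(tp$stateB$ensemble))
  expect_identical(tp$stateA$bridgeNodes, tp$stateB$bridgeNodes)
  expect_equal(tp$signMatrix[1, 2], 1)
  expect_equal(tp$signMatrix[3, 4], -1)
  pa <- probMatrix(contactProbability(tp$stateA$ensemble))
  pb <- probMatrix(contactProbability(tp$stateB$ensemble))
  pp <- tp$stateA$plantedPairs
  r12 <- pp[pp$communityA == 1, ]
  r34 <- pp[pp$communityA == 3, ]
  expect_lt(abs(pb[r12$bridgeA, r12$bridgeB] -
                  pa[r12$bridgeA, r12$bridgeB] - 0.4), 0.08)
  expect_lt(abs(pb[r34$bridgeA, r34$bridgeB] -
                  pa[r34$bridgeA, r34$bridgeB] + 0.4), 0.08)

  expect_error(generateTransitionPair(spec, rbind(c(1, 2, 0.9))),
               "out of range")
})

test_that("infeasible or non-adjacent plantings are rejected", {
  expect_error(plantedSpec(nCommunities = 4, nodesPerCommunity = 5,
                           frames = 20, interContactP = rbind(c(1, 3, 0.5)),
                           seed = 1),
               "ring-adjacent")
  expect_error(plantedSpec(nCommunities = 2, nodesPerCommunity = 5,
                           frames = 20, noiseAmplitude = 2, seed = 1),
               "infeasible")
  expect_error(plantedSpec(nCommunities = 2, nodesPerCommunity = 5,
                           frames = 20, intraContactP = 0.5,
                           interContactP = rbind(c(1, 2, 0.9)), seed = 1),
               "exceed")
  expect_error(generateState(plantedSpec(nCommunities = 2,
                                         nodesPerCommunity = 1,
                                         frames = 20, seed = 1), "x"),
               "nodes per community")
})

test_that("a mobile community dominates B-factors and mode amplitudes", {
  spec <- plantedSpec(nCommunities = 5, nodesPerCommunity = 8, frames = 400,
                      intraContactP = 1, mobileCommunities = 2L,
                      mobilityFactor = 5, seed = 37)
  st <- generateState(spec, "mob")
  sup <- superpose(st$ensemble)
  memb <- st$membership

  b <- bFactorValues(bFactors(sup))
  meanB <- tapply(b, memb, mean)
  expect_equal(unname(which.max(meanB)), 2L)

  pca <- principalModes(sup, nModes = 1)
  amp <- sqrt(rowSums(matrix(pca@modes[, 1], ncol = 3, byrow = TRUE)^2))
  meanAmp <- tapply(amp, memb, mean)
  expect_gte(meanAmp[[2]] / max(meanAmp[-2]), 3)
})

test_that("mutation fixtures reproduce their planted expectations", {
  spec <- plantedSpec(nCommunities = 3, nodesPerCommunity = 8, frames = 300,
                      intraContactP = 0.95,
                      interContactP = rbind(c(1, 2, 0.9), c(2, 3, 0.9)),
                      seed = 11)
  fx <- generateMutationFixture(spec, nInternal = 2, nInterfacial = 2)
  P <- contactProbability(fx$state$ensemble)
  net <- buildNetwork(P)
  part <- girvanNewman(net)
  muts <- loadMutations(fx$path, nodes = nodeTable(fx$state$ensemble))
  asg <- classifyInterfacial(muts, part, net)
  expect_equal(asg$classification, fx$expected$classification)

  # no interfacial requests: no interfacial expectations
  fx0 <- generateMutationFixture(spec, nInternal = 3, nInterfacial = 0)
  expect_false(any(fx0$expected$classification == "interfacial"))

  # regeneration with the same seed gives identical expectations
  fx2 <- generateMutationFixture(spec, nInternal = 2, nInterfacial = 2)
  expect_identical(fx$expected, fx2$expected)

  expect_error(generateMutationFixture(spec, 2, 7), "boundary")
})

test_that("the pipeline recovers the planted partition from contacts", {
  spec <- plantedSpec(
    nCommunities = 4, nodesPerCommunity = 10, frames = 500,
    intraContactP = 0.95,
    interContactP = rbind(c(1, 2, 0.05), c(2, 3, 0.05), c(3, 4, 0.05),
                          c(1, 4, 0.05)),
    seed = 2024)
  st <- generateState(spec, "apo")
  part <- girvanNewman(buildNetwork(contactProbability(st$ensemble)))
  expect_equal(ariIndex(communityMembership(part), st$membership), 1.0)
})
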