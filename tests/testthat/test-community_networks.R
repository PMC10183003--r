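## small probability-matrix builder around mkNodes
mkCPM <- function(P, nodes = NULL, state = "x") {
  n <- nrow(P)
  if (is.null(nodes)) nodes <- mkNodes(n, chain = LETTERS[seq_len(n)],
                                       resno = rep(1, n))
  dimnames(P) <- list(nodeKeys(nodes), nodeKeys(nodes))
  new("ContactProbabilityMatrix", P = P, nodes = nodes, cutoff = 4.5,
      exclusion = 1L, geometry = "representative", state = state,
      frames = 100L)
}

symm <- function(n, entries) {
  P <- matrix(0, n, n)
  for (r in seq_len(nrow(entries))) {
    P[entries[r, 1], entries[r, 2]] <- entries[r, 3]
    P[entries[r, 2], entries[r, 1]] <- entries[r, 3]
  }
  P
}

test_that("dCNA networks carry occupancies; covariance networks -ln|c|", {
  P <- mkCPM(symm(3, rbind(c(1, 2, 0.9), c(2, 3, 0.6))))
  net <- buildNetwork(P, mode = "dcna")
  expect_equal(nrow(edgeTable(net)), 2L)
  expect_equal(edgeTable(net)$weight, c(0.9, 0.6))

  cc <- diag(3)
  cc[1, 2] <- cc[2, 1] <- 1     # perfectly correlated: weight 0
  cc[2, 3] <- cc[3, 2] <- 0.5   # weight ln 2
  cov1 <- buildNetwork(mkCPM(symm(3, rbind(c(1, 2, 0.8), c(2, 3, 0.8)))),
                       correlation = cc, mode = "covariance")
  expect_equal(cov1@edges$weight, c(0, log(2)), tolerance = 1e-12)

  # occupancy below the binary threshold never becomes a covariance edge
  cov2 <- buildNetwork(mkCPM(symm(3, rbind(c(1, 2, 0.6)))),
                       correlation = cc, mode = "covariance")
  expect_equal(nrow(edgeTable(cov2)), 0L)

  ccz <- cc; ccz[1, 2] <- ccz[2, 1] <- 0
  expect_error(buildNetwork(mkCPM(symm(3, rbind(c(1, 2, 0.8)))),
                            correlation = ccz, mode = "covariance"),
               "infinite weight")
  expect_error(buildNetwork(P, mode = "covariance"), "requires")
})

test_that("consensus keeps only contacts stable in every state", {
  mk <- function(p12, p13, state)
    buildNetwork(mkCPM(symm(3, rbind(c(1, 2, p12), c(1, 3, p13))),
                       state = state))
  cons <- consensusNetwork(list(mk(0.9, 0.9, "a"), mk(0.8, 0.2, "b"),
                                mk(0.95, 0.95, "c")), 0.75)
  e <- edgeTable(cons)
  expect_equal(nrow(e), 1L)                   # 1-3 dropped: 0.2 in state b
  expect_equal(e$P.a, 0.9)
  expect_equal(e$P.b, 0.8)
  expect_equal(e$P.c, 0.95)
  expect_error(consensusNetwork(list(mk(1, 1, "a")), 0.75), "two states")
})

test_that("three-state consensus equals the intersection of pairwise consensi", {
  set.seed(41)
  nets <- lapply(c("a", "b", "c"), function(s) {
    P <- matrix(0, 8, 8)
    up <- upper.tri(P)
    P[up] <- sample(c(0, 0.3, 0.8, 0.95), sum(up), replace = TRUE)
    P <- P + t(P)
    buildNetwork(mkCPM(P, nodes = mkNodes(8), state = s))
  })
  full <- edgeTable(consensusNetwork(nets, 0.75))
  pairKey <- function(e) paste(e$i, e$j)
  inter <- Reduce(intersect, list(
    pairKey(edgeTable(consensusNetwork(nets[c(1, 2)], 0.75))),
    pairKey(edgeTable(consensusNetwork(nets[c(2, 3)], 0.75))),
    pairKey(edgeTable(consensusNetwork(nets[c(1, 3)], 0.75)))))
  expect_setequal(pairKey(full), inter)
})

test_that("consensus restricts to the shared node set and reports drops", {
  nA <- buildNetwork(mkCPM(symm(3, rbind(c(1, 2, 0.9))),
                           nodes = mkNodes(3), state = "a"))
  nB <- buildNetwork(mkCPM(symm(4, rbind(c(1, 2, 0.9))),
                           nodes = mkNodes(4), state = "b"))
  cons <- consensusNetwork(list(nA, nB), 0.75)
  expect_equal(nrow(nodeTable(cons)), 3L)
  expect_equal(cons@dropped, "A:4")
  expect_equal(nrow(edgeTable(cons)), 1L)
})

test_that("modularity matches hand-computed values", {
  tri2 <- mkNet(6, rbind(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6),
                         c(5, 6)))
  expect_equal(newmanModularity(tri2, c(1, 1, 1, 2, 2, 2)), 0.5)
  bridge <- mkNet(6, rbind(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6),
                           c(5, 6), c(3, 4)))
  expect_equal(newmanModularity(bridge, c(1, 1, 1, 2, 2, 2)), 5 / 14)
  expect_equal(newmanModularity(bridge, rep(1, 6)), 0)  # single community
  empty <- mkNet(3, matrix(integer(0), ncol = 2))
  expect_error(newmanModularity(empty, c(1, 2, 3)), "no edges")
  expect_error(newmanModularity(bridge, c(1, 1)), "cover")
})

test_that("modularity agrees with igraph on random graphs and partitions", {
  for (seed in 1:6) {
    n <- sample(5:8, 1)
    net <- mkNet(n, randomConnectedGraph(n, seed = 400 + seed))
    g <- igraph::graph_from_data_frame(
      data.frame(from = edgeTable(net)$i, to = edgeTable(net)$j),
      directed = FALSE, vertices = data.frame(name = seq_len(n)))
    for (r in 1:5) {
      memb <- sample(1:3, n, replace = TRUE)
      expect_equal(newmanModularity(net, memb),
                   igraph::modularity(g, memb), tolerance = 1e-12)
    }
  }
})

test_that("Girvan-Newman splits two cliques across their bridge", {
  bridge <- mkNet(6, rbind(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6),
                           c(5, 6), c(3, 4)))
  part <- girvanNewman(bridge)
  m <- communityMembership(part)
  expect_equal(nCommunities(part), 2L)
  expect_equal(unname(m[1:3]), rep(m[[1]], 3))
  expect_equal(unname(m[4:6]), rep(m[[4]], 3))
  expect_equal(part@Q, 5 / 14)
})

test_that("disconnected components are the starting partition", {
  tri2 <- mkNet(6, rbind(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6),
                         c(5, 6)))
  part <- girvanNewman(tri2)
  expect_equal(nCommunities(part), 2L)
  expect_equal(part@Q, 0.5)
})

test_that("a clique is never subdivided", {
  k4 <- mkNet(4, t(combn(4, 2)))
  part <- girvanNewman(k4)
  expect_equal(nCommunities(part), 1L)
  expect_equal(part@Q, 0)
})

test_that("returned Q never exceeds the exhaustive maximum", {
  parts6 <- enumeratePartitions(6)
  for (seed in 1:5) {
    net <- mkNet(6, randomConnectedGraph(6, seed = 600 + seed))
    best <- max(vapply(parts6, function(p) newmanModularity(net, p),
                       numeric(1)))
    got <- girvanNewman(net)
    expect_lte(got@Q, best + 1e-12)
  }
  # planted two-clique graphs: the exhaustive optimum is attained
  bridge <- mkNet(6, rbind(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6),
                           c(5, 6), c(3, 4)))
  best <- max(vapply(parts6, function(p) newmanModularity(bridge, p),
                     numeric(1)))
  expect_equal(girvanNewman(bridge)@Q, best)
})

test_that("the dendrogram trace is retained and deterministic", {
  net <- mkNet(7, randomConnectedGraph(7, seed = 3))
  p1 <- girvanNewman(net)
  p2 <- girvanNewman(net)
  expect_identical(communityMembership(p1), communityMembership(p2))
  expect_identical(p1@trace, p2@trace)
  expect_gte(nrow(p1@trace), 1L)
  expect_equal(p1@trace$Q[p1@selected], p1@Q)
  # without an early stop, the best trace partition is what is returned
  expect_equal(max(p1@trace$Q), p1@Q)
})

test_that("difference networks subtract occupancies with antisymmetry", {
  mk <- function(p12, p13, state)
    buildNetwork(mkCPM(symm(3, rbind(c(1, 2, p12), c(1, 3, p13))),
                       state = state))
  cons <- consensusNetwork(list(mk(0.9, 0.8, "apo"), mk(0.2, 0.8, "NER")),
                           0.1)
  dn <- differenceNetwork(cons, "apo", "NER")
  e <- edgeTable(dn)
  expect_equal(e$deltaP[e$i == 1 & e$j == 2], -0.7)
  rev <- differenceNetwork(cons, "NER", "apo")
  expect_equal(edgeTable(rev)$deltaP, -e$deltaP)
  same <- differenceNetwork(cons, "apo", "apo")
  expect_true(all(edgeTable(same)$deltaP == 0))
  expect_error(differenceNetwork(cons, "apo", "holo"), "unknown state")
})

test_that("community delta aggregates edges by community pair", {
  nodes <- mkNodes(4, chain = LETTERS[1:4], resno = rep(1, 4))
  e <- data.frame(i = c(1L, 2L, 1L), j = c(3L, 4L, 2L),
                  deltaP = c(0.3, -0.1, 0.2), P.a = 0, P.b = 0)
  dn <- new("DifferenceNetwork", nodes = nodes, edges = e,
            stateA = "a", stateB = "b")
  memb <- stats::setNames(c(1L, 1L, 2L, 2L), nodeKeys(nodes))
  part <- new("CommunityPartition", membership = memb, Q = 0.1,
              trace = data.frame(step = 0L, nCommunities = 2L, Q = 0.1),
              traceMembership = list(memb), selected = 1L)
  cdm <- communityDelta(dn, part)
  d <- deltaMatrix(cdm)
  expect_equal(d[1, 2], 0.2)         # +0.3 - 0.1 across communities
  expect_equal(d[1, 1], 0.2)         # intra edge 1-2
  expect_equal(d[2, 1], d[1, 2])
  # conservation: grand total equals total edge deltaP
  expect_equal(sum(d[upper.tri(d)]) + sum(diag(d)), sum(e$deltaP))
  expect_equal(cdm@sizes, c(2L, 2L))
})

test_that("community delta equals brute-force accumulation on random fixtures", {
  set.seed(12)
  nodes <- mkNodes(12)
  pairs <- t(combn(12, 2))
  pick <- pairs[runif(nrow(pairs)) < 0.4, ]
  e <- data.frame(i = pick[, 1], j = pick[, 2],
                  deltaP = round(runif(nrow(pick), -1, 1), 3),
                  P.a = 0, P.b = 0)
  dn <- new("DifferenceNetwork", nodes = nodes, edges = e,
            stateA = "a", stateB = "b")
  memb <- stats::setNames(sample(1:3, 12, replace = TRUE), nodeKeys(nodes))
  memb[1:3] <- 1:3   # ensure all labels occur
  part <- new("CommunityPartition", membership = memb, Q = 0,
              trace = data.frame(step = 0L, nCommunities = 3L, Q = 0),
              traceMembership = list(memb), selected = 1L)
  d <- deltaMatrix(communityDelta(dn, part))
  oracle <- matrix(0, 3, 3)
  for (r in seq_len(nrow(e))) {
    a <- memb[[e$i[r]]]; b <- memb[[e$j[r]]]
    oracle[a, b] <- oracle[a, b] + e$deltaP[r]
    if (a != b) oracle[b, a] <- oracle[b, a] + e$deltaP[r]
  }
  expect_equal(unname(d), oracle)
})

test_that("top changed residues rank by absolute aggregate with sign", {
  nodes <- mkNodes(4)
  e <- data.frame(i = c(1L, 1L, 2L, 3L), j = c(2L, 3L, 3L, 4L),
                  deltaP = c(0.5, 0.4, 0.3, -0.4), P.a = 0, P.b = 0)
  dn <- new("DifferenceNetwork", nodes = nodes, edges = e,
            stateA = "a", stateB = "b")
  top <- topChangedResidues(dn)
  # aggregates: node1 = 0.9, node2 = 0.8, node3 = 0.3, node4 = -0.4
  expect_equal(top$key[1:2], c("A:1", "A:2"))
  expect_equal(top$direction[top$key == "A:4"], "loss")
  expect_equal(topChangedResidues(dn, k = 2)$key, c("A:1", "A:2"))
  expect_equal(nrow(topChangedResidues(dn, minAbsDelta = 0.5)), 2L)

  # a cancelled node ranks last; ties break by (chain, resno)
  dn2 <- new("DifferenceNetwork", nodes = nodes,
             edges = data.frame(i = c(1L, 3L), j = c(2L, 4L),
                                deltaP = c(0, 0.2), P.a = 0, P.b = 0),
             stateA = "a", stateB = "b")
  top2 <- topChangedResidues(dn2)
  expect_equal(top2$key[1:2], c("A:3", "A:4"))   # |0.2| ties: chain/resno order
  expect_true(all(top2$key[3:4] == c("A:1", "A:2")))
})

test_that("graph and partition exports round-trip through files", {
  net <- mkNet(5, rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(1, 5)))
  tsv <- tempfile(fileext = ".tsv")
  writeEdgeList(net, tsv)
  back <- read.delim(tsv)
  expect_equal(nrow(back), 5L)
  expect_true(all(c("nodeA", "nodeB", "weight") %in% names(back)))

  gml <- tempfile(fileext = ".graphml")
  writeGraphML(net, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(g), 5)

  part <- girvanNewman(net)
  ptsv <- tempfile(fileext = ".tsv")
  writePartition(part, ptsv)
  ptab <- read.delim(ptsv)
  expect_equal(nrow(ptab), 5L)
  summ <- jsonlite::read_json(sub("\\.tsv$", ".json", ptsv))
  expect_equal(summ$n_communities, nCommunities(part))
})
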