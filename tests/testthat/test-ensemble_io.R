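test_that("loadTopology builds one node per residue with its representative atom", {
  lines <- c(
    pdbLine(1, "N",  "ALA", "A", 1, 0, 0, 0),
    pdbLine(2, "CA", "ALA", "A", 1, 1, 0, 0),
    pdbLine(3, "CA", "GLY", "A", 2, 2, 0, 0),
    pdbLine(4, "CA", "SER", "A", 3, 3, 0, 0),
    pdbLine(5, "P",  "DA",  "B", 1, 0, 5, 0),
    pdbLine(6, "C1'", "DA", "B", 1, 1, 5, 0),
    pdbLine(7, "P",  "DT",  "B", 2, 2, 5, 0),
    "END")
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  nodes <- loadTopology(f, verbose = FALSE)
  expect_equal(nrow(nodes), 5L)
  expect_equal(nodes$kind, c(rep("protein", 3), rep("nucleic", 2)))
  expect_equal(nodes$repAtom, c("CA", "CA", "CA", "P", "P"))
  expect_equal(nodeKeys(nodes), c("A:1", "A:2", "A:3", "B:1", "B:2"))
})

test_that("residues without a representative atom are skipped with a message", {
  lines <- c(
    pdbLine(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdbLine(2, "N",  "GLY", "A", 2, 1, 0, 0),   # no CA: skipped
    pdbLine(3, "CA", "SER", "A", 3, 2, 0, 0),
    pdbLine(4, "CA", "THR", "A", 4, 3, 0, 0),
    pdbLine(5, "CA", "VAL", "A", 5, 4, 0, 0),
    "END")
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  expect_message(nodes <- loadTopology(f), "skipped")
  expect_equal(nrow(nodes), 4L)
  expect_false(2L %in% nodes$resno)
})

test_that("a 5'-terminal nucleotide lacking P contributes no node", {
  lines <- c(
    pdbLine(1, "C1'", "DA", "C", 1, 0, 0, 0),   # 5' end, no phosphate
    pdbLine(2, "P",   "DT", "C", 2, 1, 0, 0),
    pdbLine(3, "P",   "DG", "C", 3, 2, 0, 0),
    "END")
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  nodes <- suppressMessages(loadTopology(f))
  expect_equal(nrow(nodes), 2L)
  expect_equal(nodes$resno, c(2L, 3L))
})

test_that("topology errors are informative", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(pdbLine(1, "N", "ALA", "A", 1, 0, 0, 0), "END"), f)
  expect_error(suppressMessages(loadTopology(f)), "empty model")
  expect_error(loadTopology(tempfile()), "cannot parse|does not exist|exist")
})

test_that("loadEnsemble concatenates, strides and round-trips coordinates", {
  spec <- plantedSpec(nCommunities = 2, nodesPerCommunity = 4, frames = 20,
                      intraContactP = 1, seed = 21)
  st <- generateState(spec, "rt")
  f1 <- tempfile(fileext = ".pdb"); f2 <- tempfile(fileext = ".pdb")
  writeEnsemblePDB(st$ensemble, f1, frames = 1:12)
  writeEnsemblePDB(st$ensemble, f2, frames = 13:20)

  ens <- loadEnsemble(f1, c(f1, f2), stride = 1, state = "rt")
  expect_equal(nFrames(ens), 20L)
  # coordinates survive the 3-decimal PDB round trip, order preserved
  expect_lt(max(abs(repCoords(ens) - repCoords(st$ensemble))), 6e-4)
  expect_equal(nodeKeys(nodeTable(ens)), nodeKeys(nodeTable(st$ensemble)))

  ens4 <- loadEnsemble(f1, c(f1, f2), stride = 5)
  expect_equal(nFrames(ens4), 4L)
  expect_lt(max(abs(repCoords(ens4)[2, , ] - repCoords(st$ensemble)[6, , ])),
            6e-4)

  expect_error(loadEnsemble(f1, tempfile(fileext = ".xtc")), "XTC")
  expect_error(loadEnsemble(f1, c(f1), stride = 0), "stride")
})

test_that("loadEnsemble rejects an atom-count mismatch", {
  specA <- plantedSpec(nCommunities = 2, nodesPerCommunity = 4, frames = 10,
                       intraContactP = 1, seed = 1)
  specB <- plantedSpec(nCommunities = 2, nodesPerCommunity = 5, frames = 10,
                       intraContactP = 1, seed = 1)
  fa <- tempfile(fileext = ".pdb"); fb <- tempfile(fileext = ".pdb")
  writeEnsemblePDB(generateState(specA, "a")$ensemble, fa)
  writeEnsemblePDB(generateState(specB, "b")$ensemble, fb)
  expect_error(loadEnsemble(fa, fb), "atom-count mismatch")
})

test_that("superpose removes rigid motion exactly and is idempotent", {
  set.seed(9)
  n <- 6; f <- 8
  base <- matrix(runif(n * 3, 0, 5), n, 3)
  rep <- array(0, dim = c(f, n, 3))
  for (fr in seq_len(f)) {
    th <- runif(3, 0, 2 * pi)
    Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
                c(0, sin(th[1]), cos(th[1])))
    Rz <- rbind(c(cos(th[3]), -sin(th[3]), 0),
                c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
    rep[fr, , ] <- base %*% t(Rz %*% Rx) +
      matrix(runif(3, -10, 10), n, 3, byrow = TRUE)
  }
  ens <- Ensemble(mkNodes(n), rep, state = "rigid")
  sup <- superpose(ens, referenceFrame = 1)
  for (fr in seq_len(f))
    expect_lt(max(abs(sup@rep[fr, , ] - sup@rep[1, , ])), 1e-8)

  sup2 <- superpose(superpose(ens))
  expect_lt(max(abs(sup2@rep - superpose(ens)@rep)), 1e-8)
  expect_true(sup@superposed)
})

test_that("superpose preserves intra-frame distances and never increases RMSD", {
  ens <- randomEnsemble(8, 6, seed = 13, jitter = 0.8)
  sup <- superpose(ens)
  for (fr in c(1, 4, 6)) {
    d0 <- dist(ens@rep[fr, , ])
    d1 <- dist(sup@rep[fr, , ])
    expect_lt(max(abs(d0 - d1)), 1e-8)
  }
  ## single-pass fit to frame 1 against the bio3d Kabsch implementation
  sup1 <- superpose(ens, referenceFrame = 1)
  ref <- as.vector(t(ens@rep[1, , ]))
  for (fr in seq_len(nFrames(ens))) {
    mob <- as.vector(t(ens@rep[fr, , ]))
    fitted <- suppressWarnings(bio3d::fit.xyz(ref, mob))
    expect_lt(max(abs(matrix(fitted, ncol = 3, byrow = TRUE) -
                        sup1@rep[fr, , ])), 1e-6)
  }
  expect_error(superpose(ens, fitNodes = 1:2), "underdetermined")
})

test_that("writeAnnotatedPDB stamps per-residue values with clipping", {
  lines <- c(
    pdbLine(1, "N",  "ALA", "A", 1, 0, 0, 0),
    pdbLine(2, "CA", "ALA", "A", 1, 1, 0, 0),
    pdbLine(3, "CA", "GLY", "A", 2, 2, 0, 0),
    "END")
  f <- tempfile(fileext = ".pdb"); out <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  nodes <- loadTopology(f, verbose = FALSE)

  writeAnnotatedPDB(nodes, c(0, 0), f, out)
  res <- readLines(out)
  expect_true(all(substr(res[1:3], 61, 66) == "  0.00"))
  # every other byte of the atom records untouched
  expect_equal(substr(res[1:3], 1, 60), substr(lines[1:3], 1, 60))

  expect_warning(writeAnnotatedPDB(nodes, c(1234.5, 3), f, out), "clipped")
  res <- readLines(out)
  expect_equal(substr(res[1], 61, 66), "999.99")
  expect_equal(substr(res[3], 61, 66), "  3.00")

  # community labels render as whole numbers
  writeAnnotatedPDB(nodes, c(16, 7), f, out)
  expect_equal(substr(readLines(out)[2], 61, 66), " 16.00")

  expect_error(writeAnnotatedPDB(nodes, 1, f, out), "cover")
})

test_that("annotated output round-trips the node set exactly", {
  spec <- plantedSpec(nCommunities = 2, nodesPerCommunity = 5, frames = 10,
                      intraContactP = 1, seed = 4)
  st <- generateState(spec, "s")
  f <- tempfile(fileext = ".pdb"); out <- tempfile(fileext = ".pdb")
  writeEnsemblePDB(st$ensemble, f, frames = 1)
  nodes <- loadTopology(f, verbose = FALSE)
  writeAnnotatedPDB(nodes, seq_len(nrow(nodes)), f, out)
  nodes2 <- loadTopology(out, verbose = FALSE)
  expect_equal(nodeKeys(nodes2), nodeKeys(nodes))
})
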