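## Shared fixture builders and independent oracles.  Oracles are deliberately
## naive (double loops, exhaustive enumeration) and never call the package
## code paths they check.

mkNodes <- function(n, chain = rep("A", n), resno = seq_len(n)) {
  data.frame(node = seq_len(n), chain = chain, resno = resno, insert = "",
             resid = "ALA", kind = "protein", repAtom = "CA",
             stringsAsFactors = FALSE)
}

## unweighted network from an edge matrix (rows of i, j)
mkNet <- function(n, edges, weights = NULL, nodes = NULL, state = "x") {
  if (is.null(nodes)) nodes <- mkNodes(n)
  edges <- matrix(as.integer(edges), ncol = 2)
  w <- if (is.null(weights)) rep(1, nrow(edges)) else weights
  e <- data.frame(i = pmin(edges[, 1], edges[, 2]),
                  j = pmax(edges[, 1], edges[, 2]), weight = w, P = w)
  e <- e[order(e$i, e$j), ]
  new("ContactNetwork", nodes = nodes, edges = e, mode = "dcna",
      state = state)
}

## random ensemble in a box, with a 3-atoms-per-node heavy layer
randomEnsemble <- function(n, f, seed, box = 10, jitter = 1,
                           state = "rand", superposed = FALSE) {
  set.seed(seed)
  base <- matrix(runif(n * 3, 0, box), n, 3)
  rep <- array(0, dim = c(f, n, 3))
  for (fr in seq_len(f))
    rep[fr, , ] <- base + matrix(rnorm(n * 3, sd = jitter), n, 3)
  off <- matrix(rnorm(2 * n * 3), 2 * n, 3)
  off <- 0.5 * off / sqrt(rowSums(off^2))
  heavy <- array(0, dim = c(f, 3 * n, 3))
  idx <- rep(seq_len(n), each = 3)
  sel <- rep(c(FALSE, TRUE, TRUE), n)
  for (fr in seq_len(f)) {
    hv <- rep[fr, idx, , drop = FALSE]
    hv <- matrix(hv, ncol = 3)
    hv[sel, ] <- hv[sel, ] + off
    heavy[fr, , ] <- hv
  }
  Ensemble(mkNodes(n), rep, heavy = heavy, atomNode = idx, state = state,
           superposed = superposed)
}

## frame-by-frame, pair-by-pair contact occupancy oracle
bruteContactProbability <- function(ensemble, cutoff = 4.5, exclusion = 1,
                                    geometry = "heavy") {
  nodes <- nodeTable(ensemble)
  n <- nrow(nodes)
  f <- nFrames(ensemble)
  P <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (nodes$chain[i] == nodes$chain[j] &&
        abs(nodes$resno[i] - nodes$resno[j]) <= exclusion) next
    hits <- 0
    for (fr in seq_len(f)) {
      if (geometry == "heavy") {
        ai <- which(ensemble@atomNode == i)
        aj <- which(ensemble@atomNode == j)
        dmin <- Inf
        for (a in ai) for (b in aj) {
          d <- sqrt(sum((ensemble@heavy[fr, a, ] - ensemble@heavy[fr, b, ])^2))
          dmin <- min(dmin, d)
        }
      } else {
        dmin <- sqrt(sum((ensemble@rep[fr, i, ] - ensemble@rep[fr, j, ])^2))
      }
      if (dmin <= cutoff) hits <- hits + 1
    }
    P[i, j] <- P[j, i] <- hits / f
  }
  P
}

## all set partitions of n elements as canonical label vectors
enumeratePartitions <- function(n) {
  out <- list()
  recurse <- function(labels, nextLab) {
    k <- length(labels)
    if (k == n) {
      out[[length(out) + 1]] <<- labels
      return(invisible())
    }
    for (lab in seq_len(nextLab)) recurse(c(labels, lab),
                                          max(nextLab, lab + 1))
  }
  recurse(integer(0), 1)
  out
}

## random connected graph: random spanning tree + extra edges
randomConnectedGraph <- function(n, seed, pExtra = 0.35) {
  set.seed(seed)
  perm <- sample(n)
  edges <- cbind(perm[-1], perm[sapply(2:n, function(i) sample(i - 1, 1))])
  all <- t(combn(n, 2))
  key <- function(e) paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  extra <- all[!(key(all) %in% key(edges)) & runif(nrow(all)) < pExtra, ,
               drop = FALSE]
  rbind(edges, extra)
}

## adjusted Rand index between two labelings (contingency-table formula)
ariIndex <- function(a, b) {
  tab <- table(a, b)
  sumij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  nn <- choose(sum(tab), 2)
  expected <- ai * bj / nn
  (sumij - expected) / ((ai + bj) / 2 - expected)
}

## hand-built PDB text for topology tests
pdbLine <- function(serial, name, resid, chain, resno, x, y, z,
                    record = "ATOM") {
  sprintf("%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          record, serial, ifelse(nchar(name) < 4, paste0(" ", name), name),
          resid, chain, resno, x, y, z, 1, 0)
}
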