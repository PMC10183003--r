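## Per-state weighted residue networks, the consensus network, Girvan-Newman
## community detection with a modularity stopping rule, difference networks
## and community-aggregated deltaP matrices.

#' @importFrom igraph graph_from_data_frame edge_betweenness components
#'   delete_edges ecount vcount E ends write_graph V
NULL

.edgeFrame <- function(i, j, weight, P) {
  swap <- i > j
  tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
  o <- order(i, j)
  data.frame(i = as.integer(i[o]), j = as.integer(j[o]),
             weight = weight[o], P = P[o])
}

#' Build a per-state residue network
#'
#' In `dcna` mode (the difference-contact analysis) the network carries every
#' residue pair with non-zero contact occupancy, weighted by the occupancy
#' `P_ij` itself. In `covariance` mode (traditional community network
#' analysis) edges are the pairs passing the binary occupancy threshold and
#' carry `w_ij = -ln|c_ij|`, with `c_ij` the dynamic cross-correlation --
#' small weights mean strongly coupled residues.
#'
#' @param P a [ContactProbabilityMatrix-class].
#' @param correlation symmetric correlation matrix (required in covariance
#'   mode; see [crossCorrelation()]).
#' @param mode `"dcna"` (default) or `"covariance"`.
#' @param occupancyThreshold binary-contact threshold used in covariance
#'   mode (default 0.75).
#' @return a [ContactNetwork-class].
#' @export
buildNetwork <- function(P, correlation = NULL,
                         mode = c("dcna", "covariance"),
                         occupancyThreshold = 0.75) {
  stopifnot(is(P, "ContactProbabilityMatrix"))
  mode <- match.arg(mode)
  pm <- P@P
  if (mode == "dcna") {
    idx <- which(upper.tri(pm) & pm > 0, arr.ind = TRUE)
    edges <- .edgeFrame(idx[, 1], idx[, 2], pm[idx], pm[idx])
  } else {
    if (is.null(correlation))
      stop("covariance mode requires a correlation matrix")
    if (!identical(dim(correlation), dim(pm)))
      stop("correlation and contact matrices must share the node set")
    adj <- binaryContacts(P, occupancyThreshold)
    idx <- which(upper.tri(adj) & adj, arr.ind = TRUE)
    cvals <- abs(correlation[idx])
    zero <- cvals == 0
    if (any(zero)) {
      keys <- nodeKeys(P@nodes)
      bad <- idx[which(zero)[1], ]
      stop("infinite weight: |c| = 0 on contact edge ",
           keys[bad[1]], " -- ", keys[bad[2]])
    }
    edges <- .edgeFrame(idx[, 1], idx[, 2], -log(cvals), pm[idx])
  }
  new("ContactNetwork", nodes = P@nodes, edges = edges, mode = mode,
      state = P@state)
}

#' Consensus network of stable contacts across states
#'
#' Keeps an edge only when its contact occupancy reaches
#' `stabilityMinProbability` in every input state; each surviving edge
#' retains one probability per state. Node sets are aligned on
#' `chain:resno[insert]` keys and restricted to nodes present in all states
#' (dropped keys are recorded on the result).
#'
#' @param networks list of `dcna`-mode [ContactNetwork-class] objects (or
#'   [ContactProbabilityMatrix-class] objects), one per state, at least two.
#' @param stabilityMinProbability per-state stability threshold
#'   (default 0.75, the occupancy threshold of the binary contact rule).
#' @return a [ConsensusNetwork-class].
#' @export
consensusNetwork <- function(networks, stabilityMinProbability = 0.75) {
  if (length(networks) < 2L) stop("consensus needs at least two states")
  nets <- lapply(networks, function(x) {
    if (is(x, "ContactProbabilityMatrix")) buildNetwork(x, mode = "dcna")
    else x
  })
  stopifnot(all(vapply(nets, is, logical(1), "ContactNetwork")))
  states <- vapply(nets, stateLabel, character(1))
  if (anyDuplicated(states)) stop("state labels must be unique")

  keysPer <- lapply(nets, function(x) nodeKeys(x@nodes))
  common <- Reduce(intersect, keysPer)
  if (!length(common)) stop("alignment error: no nodes shared by all states")
  dropped <- setdiff(unique(unlist(keysPer)), common)

  ref <- nets[[1]]@nodes
  keep <- match(common, keysPer[[1]])
  nodes <- ref[keep, , drop = FALSE]
  nodes$node <- seq_len(nrow(nodes))
  rownames(nodes) <- NULL

  ## per-state occupancy lookup on the common node set, keyed "i|j"
  pairKey <- function(i, j) paste(pmin(i, j), pmax(i, j), sep = "|")
  lookups <- lapply(nets, function(net) {
    map <- match(nodeKeys(net@nodes), common)   # old index -> consensus index
    e <- net@edges
    ok <- !is.na(map[e$i]) & !is.na(map[e$j])
    stats::setNames(e$P[ok], pairKey(map[e$i[ok]], map[e$j[ok]]))
  })

  cand <- names(lookups[[1]])[lookups[[1]] >= stabilityMinProbability]
  for (s in seq_along(lookups)[-1]) {
    p <- lookups[[s]][cand]
    cand <- cand[!is.na(p) & p >= stabilityMinProbability]
  }
  ij <- do.call(rbind, strsplit(cand, "|", fixed = TRUE))
  edges <- if (length(cand)) {
    data.frame(i = as.integer(ij[, 1]), j = as.integer(ij[, 2]))
  } else data.frame(i = integer(0), j = integer(0))
  for (s in seq_along(states))
    edges[[paste0("P.", states[s])]] <-
      if (length(cand)) unname(lookups[[s]][cand]) else numeric(0)
  o <- order(edges$i, edges$j)
  edges <- edges[o, , drop = FALSE]
  rownames(edges) <- NULL
  new("ConsensusNetwork", nodes = nodes, edges = edges, states = states,
      threshold = stabilityMinProbability, dropped = dropped)
}

.asIgraph <- function(network) {
  nodes <- nodeTable(network)
  e <- edgeTable(network)
  df <- data.frame(from = e$i, to = e$j)
  if ("weight" %in% names(e)) df$weight <- e$weight
  igraph::graph_from_data_frame(df, directed = FALSE,
                                vertices = data.frame(name = seq_len(nrow(nodes))))
}

#' Newman-Girvan modularity of a partition
#'
#' Evaluates `Q = sum_c [ e_c / m - (d_c / 2m)^2 ]` where `m` is the total
#' edge count, `e_c` the number of intra-community edges of community `c`
#' and `d_c` its total degree. Unweighted by default, matching the
#' non-weighted Girvan-Newman usage; with `weighted = TRUE` edge weights
#' replace counts.
#'
#' @param network a [ContactNetwork-class] or [ConsensusNetwork-class].
#' @param membership integer community labels covering all nodes.
#' @param weighted use edge weights instead of counts (default `FALSE`).
#' @return modularity `Q` (unitless, in `[-0.5, 1]`).
#' @export
newmanModularity <- function(network, membership, weighted = FALSE) {
  e <- edgeTable(network)
  n <- nrow(nodeTable(network))
  if (length(membership) != n)
    stop("membership must cover all ", n, " nodes")
  w <- if (weighted && "weight" %in% names(e)) e$weight else rep(1, nrow(e))
  m <- sum(w)
  if (m == 0) stop("undefined modularity: network has no edges")
  ci <- membership[e$i]; cj <- membership[e$j]
  intra <- tapply(w[ci == cj], ci[ci == cj], sum)
  deg <- tapply(c(w, w), c(ci, cj), sum)
  ec <- numeric(length(deg))
  names(ec) <- names(deg)
  ec[names(intra)] <- intra
  sum(ec / m - (deg / (2 * m))^2)
}

#' Girvan-Newman community detection with a modularity stopping rule
#'
#' Iteratively removes the edge of highest betweenness (unweighted
#' betweenness by default; ties broken deterministically in favour of the
#' lexicographically smallest node-index pair). Each time an edge removal
#' splits a connected component, the induced partition is recorded together
#' with its modularity on the original graph. Subdivision stops when a newly
#' recorded partition improves modularity by less than `stopDeltaQ` over the
#' previously recorded one; the best-Q partition recorded up to that point
#' is returned, and the full dendrogram trace is retained on the result.
#'
#' @param network a [ContactNetwork-class] or [ConsensusNetwork-class] with
#'   at least one edge.
#' @param useWeights use edge weights as betweenness distances and weighted
#'   modularity (default `FALSE`, the non-weighted algorithm).
#' @param stopDeltaQ modularity-improvement stopping threshold
#'   (default 0.001).
#' @return a [CommunityPartition-class].
#' @export
girvanNewman <- function(network, useWeights = FALSE, stopDeltaQ = 0.001) {
  e0 <- edgeTable(network)
  if (nrow(e0) == 0L) stop("network has no edges")
  nodes <- nodeTable(network)
  g <- .asIgraph(network)
  keys <- nodeKeys(nodes)

  recordQ <- function(memb) newmanModularity(network, memb,
                                             weighted = useWeights)
  gw <- g
  memb <- igraph::components(gw)$membership
  traceM <- list(as.integer(memb))
  traceQ <- recordQ(as.integer(memb))
  traceK <- length(unique(memb))
  step <- 0L
  stoppedEarly <- FALSE

  while (igraph::ecount(gw) > 0L) {
    wts <- if (useWeights) igraph::E(gw)$weight else NA
    eb <- igraph::edge_betweenness(gw, weights = wts)
    mx <- which(eb >= max(eb) - 1e-12)
    if (length(mx) > 1L) {
      en <- igraph::ends(gw, mx, names = TRUE)
      a <- as.integer(en[, 1]); b <- as.integer(en[, 2])
      lo <- pmin(a, b); hi <- pmax(a, b)
      mx <- mx[order(lo, hi)][1]
    }
    nComp <- igraph::components(gw)$no
    gw <- igraph::delete_edges(gw, mx[1])
    step <- step + 1L
    comp <- igraph::components(gw)
    if (comp$no > nComp) {
      m <- as.integer(comp$membership)
      q <- recordQ(m)
      traceM[[length(traceM) + 1L]] <- m
      traceQ <- c(traceQ, q)
      traceK <- c(traceK, comp$no)
      if (q - traceQ[length(traceQ) - 1L] < stopDeltaQ) {
        stoppedEarly <- TRUE
        break
      }
    }
  }

  best <- which.max(traceQ)
  memb <- traceM[[best]]
  ## relabel communities 1..K in order of first appearance
  memb <- as.integer(factor(memb, levels = unique(memb)))
  names(memb) <- keys
  trace <- data.frame(step = seq_along(traceQ) - 1L,
                      nCommunities = traceK, Q = traceQ)
  new("CommunityPartition", membership = memb, Q = traceQ[best],
      trace = trace, traceMembership = traceM, selected = as.integer(best))
}

#' Difference contact network between two states
#'
#' For every consensus edge, `deltaP = P(stateB) - P(stateA)`; positive
#' values are contacts gained in the A to B transition. Reversing the
#' transition negates every entry.
#'
#' @param consensus a [ConsensusNetwork-class].
#' @param stateA,stateB labels of the transition end states (must be among
#'   the consensus states).
#' @return a [DifferenceNetwork-class].
#' @export
differenceNetwork <- function(consensus, stateA, stateB) {
  stopifnot(is(consensus, "ConsensusNetwork"))
  for (s in c(stateA, stateB))
    if (!s %in% consensus@states)
      stop("unknown state label '", s, "'; consensus holds: ",
           paste(consensus@states, collapse = ", "))
  e <- consensus@edges
  pa <- e[[paste0("P.", stateA)]]
  pb <- e[[paste0("P.", stateB)]]
  edges <- data.frame(i = e$i, j = e$j, deltaP = pb - pa, P.a = pa, P.b = pb)
  new("DifferenceNetwork", nodes = consensus@nodes, edges = edges,
      stateA = stateA, stateB = stateB)
}

#' Community-aggregated contact probability changes
#'
#' Sums the per-edge `deltaP` of a difference network over pairs of
#' communities: entry (A, B) aggregates all consensus edges with one end in
#' A and the other in B; the diagonal holds within-community sums. The grand
#' total over the upper triangle plus diagonal equals the total edge
#' `deltaP` (conservation).
#'
#' @param diff a [DifferenceNetwork-class].
#' @param partition a [CommunityPartition-class] covering the difference
#'   network's nodes.
#' @return a [CommunityDeltaMatrix-class].
#' @export
communityDelta <- function(diff, partition) {
  stopifnot(is(diff, "DifferenceNetwork"), is(partition, "CommunityPartition"))
  nodes <- diff@nodes
  memb <- partition@membership
  idx <- match(nodeKeys(nodes), names(memb))
  if (anyNA(idx))
    stop("coverage error: partition does not label node(s) ",
         paste(nodeKeys(nodes)[is.na(idx)][1:min(3, sum(is.na(idx)))],
               collapse = ", "))
  lab <- memb[idx]
  k <- max(memb)
  delta <- matrix(0, k, k)
  e <- diff@edges
  for (r in seq_len(nrow(e))) {
    a <- lab[e$i[r]]; b <- lab[e$j[r]]
    if (a == b) {
      delta[a, a] <- delta[a, a] + e$deltaP[r]
    } else {
      delta[a, b] <- delta[a, b] + e$deltaP[r]
      delta[b, a] <- delta[b, a] + e$deltaP[r]
    }
  }
  sizes <- as.integer(tabulate(memb, nbins = k))
  dimnames(delta) <- list(seq_len(k), seq_len(k))
  new("CommunityDeltaMatrix", delta = delta, sizes = sizes,
      stateA = diff@stateA, stateB = diff@stateB)
}

#' Residues with the largest net contact change
#'
#' Aggregates each node's incident edge `deltaP` values (signed sum) and
#' ranks nodes by absolute aggregate, reporting the sign so gains and losses
#' remain distinguishable. Ties in absolute aggregate are broken by (chain,
#' residue number) ascending.
#'
#' @param diff a [DifferenceNetwork-class] with at least one edge.
#' @param k return the top `k` nodes (default: all with non-missing rank).
#' @param minAbsDelta alternatively, return nodes with `|aggregate|` at
#'   least this value.
#' @return `data.frame` with node key, chain, resno, aggregate deltaP and
#'   direction (`"gain"`/`"loss"`/`"none"`), ranked.
#' @export
topChangedResidues <- function(diff, k = NULL, minAbsDelta = NULL) {
  stopifnot(is(diff, "DifferenceNetwork"))
  e <- diff@edges
  if (nrow(e) == 0L) stop("difference network has no edges")
  n <- nrow(diff@nodes)
  agg <- numeric(n)
  for (r in seq_len(nrow(e))) {
    agg[e$i[r]] <- agg[e$i[r]] + e$deltaP[r]
    agg[e$j[r]] <- agg[e$j[r]] + e$deltaP[r]
  }
  nodes <- diff@nodes
  out <- data.frame(key = nodeKeys(nodes), chain = nodes$chain,
                    resno = nodes$resno, aggregate = agg,
                    direction = ifelse(agg > 0, "gain",
                                       ifelse(agg < 0, "loss", "none")),
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$aggregate), out$chain, out$resno), , drop = FALSE]
  if (!is.null(minAbsDelta)) out <- out[abs(out$aggregate) >= minAbsDelta, ]
  if (!is.null(k)) out <- utils::head(out, k)
  rownames(out) <- NULL
  out
}

## ---------------------------------------------------------------------------
## Exports
## ---------------------------------------------------------------------------

#' Write a network as a weighted edge-list TSV
#'
#' Columns: the two node keys (`chain:resno`), weight (when present), and
#' any per-state probability columns.
#'
#' @param network a [ContactNetwork-class], [ConsensusNetwork-class] or
#'   [DifferenceNetwork-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeEdgeList <- function(network, path) {
  nodes <- nodeTable(network)
  keys <- nodeKeys(nodes)
  e <- edgeTable(network)
  out <- cbind(data.frame(nodeA = keys[e$i], nodeB = keys[e$j],
                          stringsAsFactors = FALSE),
               e[, setdiff(names(e), c("i", "j")), drop = FALSE])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a network in GraphML format
#'
#' @param network a network-like object accepted by [writeEdgeList()].
#' @param path output `.graphml` path.
#' @return `path`, invisibly.
#' @export
writeGraphML <- function(network, path) {
  g <- .asIgraph(network)
  igraph::V(g)$key <- nodeKeys(nodeTable(network))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write a community partition as TSV plus JSON summary
#'
#' @param partition a [CommunityPartition-class].
#' @param path output TSV path (`node`, `community`); a `.json` sibling with
#'   `{n_communities, Q, sizes}` is written alongside.
#' @return `path`, invisibly.
#' @export
writePartition <- function(partition, path) {
  m <- partition@membership
  utils::write.table(data.frame(node = names(m), community = as.integer(m)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  summ <- list(n_communities = nCommunities(partition), Q = partition@Q,
               sizes = as.integer(table(m)))
  jsonPath <- if (grepl("\\.tsv$", path)) sub("\\.tsv$", ".json", path)
              else paste0(path, ".json")
  jsonlite::write_json(summ, jsonPath, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a community delta matrix as TSV
#'
#' @param cdm a [CommunityDeltaMatrix-class].
#' @param path output TSV path; the first column carries community ids and
#'   sizes.
#' @return `path`, invisibly.
#' @export
writeDeltaMatrix <- function(cdm, path) {
  d <- cdm@delta
  out <- data.frame(community = seq_len(nrow(d)), size = cdm@sizes,
                    as.data.frame(d, check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
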