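## Synthetic multi-state ensembles with planted community structure, planted
## contact-probability changes and planted mobile/rigid modules.  These toy
## ensembles reproduce the statistical structure the network analysis relies
## on -- stable intra-community contacts, state-dependent inter-community
## contact probabilities with known signs, community-coherent motions --
## without any physical force field.

#' Planted-ensemble specification
#'
#' Defines the study conditions for a synthetic multi-state ensemble: `K`
#' communities of equal size laid out as tight clusters on a ring, planted
#' intra- and inter-community contact probabilities, community-coherent
#' motion amplitudes, and a mandatory seed. Inter-community contacts are
#' carried by dedicated bridge nodes (one per community per planted pair)
#' that jump, jointly for the pair and with the planted Bernoulli
#' probability, to a "near" position inside the contact cutoff; intra
#' occupancies below one are planted by per-node "out" excursions with
#' probability `1 - sqrt(intraContactP)`, so that every (non-excluded) intra
#' pair has occupancy `intraContactP` and every planted inter pair has its
#' specified occupancy. Planted inter pairs must connect ring-adjacent
#' communities (a geometric feasibility constraint) and cannot exceed
#' `intraContactP`.
#'
#' @slot nCommunities number of planted communities K (>= 2).
#' @slot nodesPerCommunity residues per community.
#' @slot frames number of frames F (>= 10).
#' @slot cutoff contact cutoff the geometry is built for, Angstrom.
#' @slot intraContactP planted intra-community occupancy, (0, 1].
#' @slot interContactP `K x K` symmetric matrix of planted inter-community
#'   occupancies (0 = no planted contact).
#' @slot correlatedAmplitude per-axis s.d. of the shared per-community
#'   Gaussian translation, Angstrom.
#' @slot noiseAmplitude half-width of the bounded uniform per-node jitter,
#'   Angstrom per coordinate.
#' @slot mobileCommunities community ids whose shared motion is amplified.
#' @slot mobilityFactor amplitude multiplier for mobile communities.
#' @slot seed integer seed; all generation is reproducible from it.
#' @export
setClass("PlantedSpec",
  representation(nCommunities = "integer", nodesPerCommunity = "integer",
                 frames = "integer", cutoff = "numeric",
                 intraContactP = "numeric", interContactP = "matrix",
                 correlatedAmplitude = "numeric", noiseAmplitude = "numeric",
                 mobileCommunities = "integer", mobilityFactor = "numeric",
                 seed = "integer"))

.ringAdjacent <- function(k, l, K) {
  if (K == 2L) return(TRUE)
  d <- abs(k - l)
  d == 1L || d == K - 1L
}

setValidity("PlantedSpec", function(object) {
  K <- object@nCommunities
  if (K < 2L) return("need at least 2 communities")
  if (object@nodesPerCommunity < 2L) return("need >= 2 nodes per community")
  if (object@frames < 10L) return("need F >= 10")
  p <- object@interContactP
  if (!identical(dim(p), c(K, K))) return("interContactP must be K x K")
  if (any(p < 0) || any(p > 1)) return("interContactP entries must be in [0,1]")
  if (!isTRUE(all.equal(p, t(p)))) return("interContactP must be symmetric")
  if (object@intraContactP <= 0 || object@intraContactP > 1)
    return("intraContactP must lie in (0, 1]")
  if (any(p > object@intraContactP + 1e-12))
    return("planted inter occupancies cannot exceed intraContactP")
  for (k in seq_len(K)) for (l in seq_len(K)) {
    if (l > k && p[k, l] > 0 && !.ringAdjacent(k, l, K))
      return("spec error: planted inter contacts only between ring-adjacent communities")
  }
  ## geometric feasibility: cluster diameter + jitter must fit the cutoff,
  ## and the bridge near-position must keep intra contacts
  noise <- 2 * sqrt(3) * object@noiseAmplitude
  if (2 * 1.0 + noise >= object@cutoff)
    return("spec error: infeasible geometry (jitter too large for the cutoff)")
  n <- (object@cutoff + 1.7) / 2
  if (n + 1.0 + noise >= object@cutoff + 0.06)
    return("spec error: infeasible geometry (noise breaks bridge contacts)")
  if (length(object@seed) != 1L || is.na(object@seed))
    return("seed is mandatory")
  TRUE
})

#' Construct a PlantedSpec
#'
#' @param nCommunities,nodesPerCommunity,frames,cutoff see
#'   [PlantedSpec-class].
#' @param intraContactP planted intra-community occupancy (default 0.95).
#' @param interContactP either a `K x K` matrix, or a `data.frame`/matrix of
#'   rows `(k, l, p)` listing planted pairs, or `NULL` for none.
#' @param correlatedAmplitude,noiseAmplitude,mobileCommunities,mobilityFactor,seed
#'   see [PlantedSpec-class].
#' @return a validated [PlantedSpec-class].
#' @export
plantedSpec <- function(nCommunities = 4L, nodesPerCommunity = 10L,
                        frames = 500L, cutoff = 4.5, intraContactP = 0.95,
                        interContactP = NULL, correlatedAmplitude = 0.1,
                        noiseAmplitude = 0.1, mobileCommunities = integer(),
                        mobilityFactor = 5, seed) {
  K <- as.integer(nCommunities)
  if (is.null(interContactP)) {
    interContactP <- matrix(0, K, K)
  } else if (!(is.matrix(interContactP) &&
               identical(dim(interContactP), c(K, K)))) {
    ## rows of (communityA, communityB, p)
    pr <- as.matrix(interContactP)
    m <- matrix(0, K, K)
    for (r in seq_len(nrow(pr))) {
      m[pr[r, 1], pr[r, 2]] <- pr[r, 3]
      m[pr[r, 2], pr[r, 1]] <- pr[r, 3]
    }
    interContactP <- m
  }
  new("PlantedSpec", nCommunities = K,
      nodesPerCommunity = as.integer(nodesPerCommunity),
      frames = as.integer(frames), cutoff = cutoff,
      intraContactP = intraContactP, interContactP = interContactP,
      correlatedAmplitude = correlatedAmplitude,
      noiseAmplitude = noiseAmplitude,
      mobileCommunities = as.integer(mobileCommunities),
      mobilityFactor = mobilityFactor, seed = as.integer(seed))
}

setMethod("show", "PlantedSpec", function(object) {
  cat("PlantedSpec:", object@nCommunities, "communities x",
      object@nodesPerCommunity, "nodes,", object@frames, "frames\n")
  cat("  intraContactP =", object@intraContactP, "| planted inter pairs:",
      sum(object@interContactP[upper.tri(object@interContactP)] > 0),
      "| seed =", object@seed, "\n")
})

## Evaluate expr with a local RNG state, leaving the global state untouched.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.stateSeed <- function(seed, label) {
  off <- if (nzchar(label)) sum(utf8ToInt(label)) * 1009L else 0L
  as.integer((as.numeric(seed) + off) %% 2100000000) + 1L
}

## Deterministic base geometry shared by all states generated from one spec.
.baseGeometry <- function(spec, pairSupport) {
  K <- spec@nCommunities
  m <- spec@nodesPerCommunity
  N <- K * m
  D <- 2 * spec@cutoff + 1           # adjacent centroid spacing
  R <- 1.0                           # community ball radius
  nearD <- (spec@cutoff + 1.7) / 2   # bridge near-position centroid distance

  if (K == 2L) {
    centroids <- rbind(c(-D / 2, 0, 0), c(D / 2, 0, 0))
  } else {
    rc <- D / (2 * sin(pi / K))
    ang <- 2 * pi * (seq_len(K) - 1) / K
    centroids <- cbind(rc * cos(ang), rc * sin(ang), 0)
  }
  outDir <- centroids / sqrt(rowSums(centroids^2))

  ## planted pairs (upper triangle of the support)
  pairs <- which(upper.tri(pairSupport) & pairSupport, arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]

  ## bridge node (within-community position index) per community per pair
  bridgeOf <- matrix(NA_integer_, nrow(pairs), 2)  # node index (global)
  used <- integer(K)
  if (nrow(pairs)) {
    for (r in seq_len(nrow(pairs))) for (s in 1:2) {
      k <- pairs[r, s]
      used[k] <- used[k] + 1L
      if (used[k] > m)
        stop("spec error: community ", k,
             " has more planted pairs than nodes")
      bridgeOf[r, s] <- (k - 1L) * m + used[k]
    }
  }

  base <- .withSeed(spec@seed, {
    ## uniform positions in a ball of radius R around each centroid
    u <- matrix(stats::rnorm(N * 3), N, 3)
    u <- u / sqrt(rowSums(u^2))
    rad <- R * stats::runif(N)^(1 / 3)
    pos <- u * rad + centroids[rep(seq_len(K), each = m), ]
    ## two heavy-atom offsets per node, 0.25 A
    od <- matrix(stats::rnorm(N * 6), 2 * N, 3)
    od <- 0.25 * od / sqrt(rowSums(od^2))
    list(pos = pos, offsets = od)
  })

  community <- rep(seq_len(K), each = m)
  outPos <- centroids[community, ] +
    outDir[community, ] * (2 * spec@cutoff + (rep(seq_len(m), K) - 1) *
                             (spec@cutoff + 2))
  nearPos <- matrix(NA_real_, nrow(pairs) * 2, 3)
  if (nrow(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      k <- pairs[r, 1]; l <- pairs[r, 2]
      ukl <- centroids[l, ] - centroids[k, ]
      ukl <- ukl / sqrt(sum(ukl^2))
      nearPos[2 * r - 1, ] <- centroids[k, ] + nearD * ukl
      nearPos[2 * r, ] <- centroids[l, ] - nearD * ukl
    }
  }

  nodes <- data.frame(node = seq_len(N), chain = LETTERS[community],
                      resno = rep(seq_len(m), K), insert = "",
                      resid = "ALA", kind = "protein", repAtom = "CA",
                      stringsAsFactors = FALSE)
  list(nodes = nodes, community = community, base = base$pos,
       offsets = base$offsets, outPos = outPos, pairs = pairs,
       bridgeOf = bridgeOf, nearPos = nearPos)
}

#' Generate one synthetic state
#'
#' Draws an ensemble for one functional state from a [PlantedSpec-class].
#' The base geometry (node and heavy-atom positions) depends only on the
#' spec's seed, so all states generated from one spec share a topology; the
#' per-frame randomness is seeded from the seed and the state label, so
#' distinct labels give independent but reproducible ensembles.
#'
#' @param spec a [PlantedSpec-class].
#' @param stateLabel label for the generated state.
#' @param interContactP optional `K x K` matrix overriding the spec's planted
#'   inter-community occupancies (used for transition pairs).
#' @param pairSupport optional logical `K x K` matrix fixing which community
#'   pairs carry bridge nodes (so two states of a transition share bridges).
#' @return list with `ensemble` (an [Ensemble-class], heavy-atom layer
#'   populated), `membership` (named ground-truth community vector),
#'   `bridgeNodes` (integer node indices carrying planted inter contacts)
#'   and `plantedPairs` (`data.frame`: community pair, bridge nodes, p).
#' @export
generateState <- function(spec, stateLabel = "A", interContactP = NULL,
                          pairSupport = NULL) {
  stopifnot(is(spec, "PlantedSpec"))
  interP <- if (is.null(interContactP)) spec@interContactP else interContactP
  if (any(interP > spec@intraContactP + 1e-12))
    stop("spec error: inter occupancy exceeds intraContactP")
  if (is.null(pairSupport)) pairSupport <- interP > 0
  geo <- .baseGeometry(spec, pairSupport)
  K <- spec@nCommunities
  m <- spec@nodesPerCommunity
  N <- K * m
  f <- spec@frames
  q <- 1 - sqrt(spec@intraContactP)    # per-node out-excursion probability

  mult <- rep(1, K)
  mult[spec@mobileCommunities] <- spec@mobilityFactor
  nPairs <- nrow(geo$pairs)

  draws <- .withSeed(.stateSeed(spec@seed, stateLabel), {
    out <- matrix(stats::runif(f * N) < q, f, N)
    z <- if (nPairs) {
      pz <- numeric(nPairs)
      for (r in seq_len(nPairs))
        pz[r] <- interP[geo$pairs[r, 1], geo$pairs[r, 2]] / spec@intraContactP
      matrix(stats::runif(f * nPairs) <
               rep(pz, each = f), f, nPairs)
    } else matrix(FALSE, f, 0)
    g <- array(stats::rnorm(f * K * 3), dim = c(f, K, 3)) *
      spec@correlatedAmplitude *
      array(rep(mult, each = f), dim = c(f, K, 3))
    noise <- array(stats::runif(f * N * 3, -spec@noiseAmplitude,
                                spec@noiseAmplitude), dim = c(f, N, 3))
    list(out = out, z = z, g = g, noise = noise)
  })

  rep <- array(0, dim = c(f, N, 3))
  heavy <- array(0, dim = c(f, 3 * N, 3))
  atomNode <- rep(seq_len(N), each = 3)
  offIdx <- rep(seq_len(N), each = 3)  # per heavy atom, owning node
  comm <- geo$community

  for (fr in seq_len(f)) {
    pos <- geo$base
    ## near-position jumps for planted pairs (jointly for both bridges)
    if (nPairs) for (r in seq_len(nPairs)) {
      if (draws$z[fr, r]) {
        a <- geo$bridgeOf[r, 1]; b <- geo$bridgeOf[r, 2]
        pos[a, ] <- geo$nearPos[2 * r - 1, ]
        pos[b, ] <- geo$nearPos[2 * r, ]
      }
    }
    ## out excursions override everything
    o <- which(draws$out[fr, ])
    if (length(o)) pos[o, ] <- geo$outPos[o, , drop = FALSE]
    ## shared community translation + bounded per-node jitter
    pos <- pos + draws$g[fr, comm, ] + draws$noise[fr, , ]
    rep[fr, , ] <- pos
    ## heavy layer: representative atom plus the two offset atoms per node
    hv <- pos[offIdx, , drop = FALSE]
    sel <- rep(c(FALSE, TRUE, TRUE), N)
    hv[sel, ] <- hv[sel, ] + geo$offsets
    heavy[fr, , ] <- hv
  }

  ens <- Ensemble(geo$nodes, rep, heavy = heavy, atomNode = atomNode,
                  state = stateLabel)
  membership <- stats::setNames(comm, nodeKeys(geo$nodes))
  planted <- if (nPairs) data.frame(
    communityA = geo$pairs[, 1], communityB = geo$pairs[, 2],
    bridgeA = geo$bridgeOf[, 1], bridgeB = geo$bridgeOf[, 2],
    p = vapply(seq_len(nPairs), function(r)
      interP[geo$pairs[r, 1], geo$pairs[r, 2]], numeric(1)))
  else data.frame(communityA = integer(0), communityB = integer(0),
                  bridgeA = integer(0), bridgeB = integer(0), p = numeric(0))
  list(ensemble = ens, membership = membership,
       bridgeNodes = unique(as.integer(geo$bridgeOf)),
       plantedPairs = planted)
}

#' Generate a two-state transition pair with planted contact changes
#'
#' State B's planted inter-community occupancies are state A's plus the
#' requested per-pair deltas; both states share topology and bridge-node
#' assignment, so consensus and difference networks are directly comparable.
#' The ground truth records the intended sign of every community-pair
#' contact change.
#'
#' @param spec a [PlantedSpec-class] (its `interContactP` defines state A).
#' @param deltas `K x K` symmetric matrix of planted occupancy changes, or a
#'   rows-of-`(k, l, delta)` table as in [plantedSpec()].
#' @param labels length-2 character vector of state labels.
#' @return list with `stateA`, `stateB` (each as from [generateState()]),
#'   `membership`, and `signMatrix` (`K x K` matrix of intended signs).
#' @export
generateTransitionPair <- function(spec, deltas,
                                   labels = c("stateA", "stateB")) {
  stopifnot(is(spec, "PlantedSpec"))
  K <- spec@nCommunities
  if (!is.matrix(deltas) || !identical(dim(deltas), c(K, K))) {
    pr <- as.matrix(deltas)
    m <- matrix(0, K, K)
    for (r in seq_len(nrow(pr))) {
      m[pr[r, 1], pr[r, 2]] <- pr[r, 3]
      m[pr[r, 2], pr[r, 1]] <- pr[r, 3]
    }
    deltas <- m
  }
  pA <- spec@interContactP
  pB <- pA + deltas
  if (any(pB < -1e-12) || any(pB > spec@intraContactP + 1e-12))
    stop("spec error: state B occupancy out of range after applying deltas")
  support <- (pA > 0) | (pB > 0)
  a <- generateState(spec, labels[1], interContactP = pA,
                     pairSupport = support)
  b <- generateState(spec, labels[2], interContactP = pB,
                     pairSupport = support)
  list(stateA = a, stateB = b, membership = a$membership,
       signMatrix = sign(deltas))
}

#' Generate a mutation-mapping fixture with known expectations
#'
#' Places `nInternal` mutations on nodes with no planted inter-community
#' contacts and `nInterfacial` mutations on bridge nodes, writes them as a
#' standard mutation TSV, and returns the expected internal/interfacial
#' classification for each.
#'
#' @param spec a [PlantedSpec-class] with at least one planted inter pair
#'   when `nInterfacial > 0`.
#' @param nInternal,nInterfacial requested mutation counts.
#' @param path output TSV path (default: a tempfile).
#' @param stateLabel label for the generated state.
#' @return list with `state` (as from [generateState()]), `path` (the TSV),
#'   `mutations` (the written table) and `expected` (`data.frame` with the
#'   planted classification per mutation).
#' @export
generateMutationFixture <- function(spec, nInternal, nInterfacial,
                                    path = tempfile(fileext = ".tsv"),
                                    stateLabel = "mutfix") {
  st <- generateState(spec, stateLabel)
  nodes <- nodeTable(st$ensemble)
  bridges <- st$bridgeNodes
  nonBridges <- setdiff(seq_len(nrow(nodes)), bridges)
  if (nInterfacial > length(bridges))
    stop("spec error: only ", length(bridges),
         " boundary (bridge) nodes available")
  if (nInternal > length(nonBridges))
    stop("spec error: only ", length(nonBridges), " internal nodes available")
  pick <- c(utils::head(nonBridges, nInternal),
            utils::head(bridges, nInterfacial))
  cls <- c(rep("internal", nInternal), rep("interfacial", nInterfacial))

  muts <- data.frame(
    subunit = nodes$chain[pick], chain_id = nodes$chain[pick],
    wild_type = "A", position = nodes$resno[pick], mutant = "V",
    phenotype = rep(PHENOTYPES, length.out = length(pick)),
    note = "synthetic planted mutation", stringsAsFactors = FALSE)
  utils::write.table(muts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expected <- cbind(muts[, c("chain_id", "position")],
                    classification = cls, node = pick,
                    stringsAsFactors = FALSE)
  list(state = st, path = path, mutations = muts, expected = expected)
}
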