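#' @importFrom methods new validObject is slot setClass setValidity setGeneric
#'   setMethod show
NULL

## ---------------------------------------------------------------------------
## Node tables
## ---------------------------------------------------------------------------

NODE_COLUMNS <- c("node", "chain", "resno", "insert", "resid", "kind", "repAtom")

#' Validate a node table
#'
#' A node table is a plain `data.frame` with one row per network node (one
#' residue represented by its CA or P atom) and columns `node` (1-based
#' contiguous index), `chain`, `resno` (author numbering), `insert`
#' (insertion code, `""` when absent), `resid` (3-letter residue name),
#' `kind` (`"protein"` or `"nucleic"`) and `repAtom` (`"CA"` or `"P"`).
#'
#' @param nodes candidate `data.frame`.
#' @return the node table, invisibly, after validation.
#' @export
validateNodeTable <- function(nodes) {
  if (!is.data.frame(nodes))
    stop("node table must be a data.frame")
  missing <- setdiff(NODE_COLUMNS, names(nodes))
  if (length(missing))
    stop("node table lacks columns: ", paste(missing, collapse = ", "))
  n <- nrow(nodes)
  if (n == 0L)
    stop("empty node table")
  if (!identical(as.integer(nodes$node), seq_len(n)))
    stop("node indices must be contiguous 1..N")
  key <- nodeKeys(nodes)
  if (anyDuplicated(key))
    stop("duplicate (chain, resno, insert) keys in node table")
  if (!all(nodes$kind %in% c("protein", "nucleic")))
    stop("node kind must be 'protein' or 'nucleic'")
  invisible(nodes)
}

#' Node keys
#'
#' Stable textual identifiers `chain:resno[insert]` used to align node sets
#' across states and in all file outputs (author numbering preserved).
#'
#' @param nodes a node table.
#' @return character vector of keys, one per node.
#' @export
nodeKeys <- function(nodes) {
  paste0(nodes$chain, ":", nodes$resno,
         ifelse(nodes$insert == "", "", nodes$insert))
}

## ---------------------------------------------------------------------------
## Ensemble
## ---------------------------------------------------------------------------

#' Ensemble of conformations
#'
#' Holds one functional state's conformational ensemble in node-centric form:
#' an `F x N x 3` stack of representative-atom coordinates (CA for protein
#' residues, P for nucleic residues, in Angstrom) plus an optional heavy-atom
#' layer (`F x A x 3` with an atom-to-node map) used for heavy-atom contact
#' geometry.
#'
#' @slot nodes node table (see [validateNodeTable()]).
#' @slot rep numeric array `F x N x 3`, Angstrom.
#' @slot heavy numeric array `F x A x 3` or a zero-length array when absent.
#' @slot atomNode integer vector of length `A` mapping heavy atoms to nodes.
#' @slot state state label, e.g. `"apo"`, `"PIC"`, `"NER"`.
#' @slot superposed logical; `TRUE` once frames share a common reference frame.
#' @export
setClass("Ensemble",
  representation(nodes = "data.frame", rep = "array", heavy = "array",
                 atomNode = "integer", state = "character",
                 superposed = "logical"))

setValidity("Ensemble", function(object) {
  nodes <- object@nodes
  msg <- tryCatch({ validateNodeTable(nodes); NULL },
                  error = function(e) conditionMessage(e))
  if (!is.null(msg)) return(msg)
  d <- dim(object@rep)
  if (length(d) != 3L || d[3] != 3L)
    return("rep coordinates must be an F x N x 3 array")
  if (d[2] != nrow(nodes))
    return("rep coordinate node dimension does not match node table")
  if (d[1] < 1L) return("ensemble holds no frames")
  if (!all(is.finite(object@rep)))
    return("rep coordinates contain non-finite values")
  if (length(object@heavy)) {
    dh <- dim(object@heavy)
    if (length(dh) != 3L || dh[3] != 3L || dh[1] != d[1])
      return("heavy coordinates must be an F x A x 3 array with matching F")
    if (length(object@atomNode) != dh[2])
      return("atomNode must map every heavy atom to a node")
    if (any(object@atomNode < 1L) || any(object@atomNode > nrow(nodes)))
      return("atomNode indices out of range")
  }
  TRUE
})

#' Construct an Ensemble
#'
#' @param nodes node table.
#' @param rep `F x N x 3` representative-atom coordinate array (Angstrom).
#' @param heavy optional `F x A x 3` heavy-atom coordinate array.
#' @param atomNode integer atom-to-node map (required with `heavy`).
#' @param state state label.
#' @param superposed logical, default `FALSE`.
#' @return an [Ensemble-class] object.
#' @export
Ensemble <- function(nodes, rep, heavy = NULL, atomNode = NULL,
                     state = "", superposed = FALSE) {
  if (is.null(heavy)) {
    heavy <- array(numeric(0), dim = c(0, 0, 3))
    atomNode <- integer(0)
  }
  new("Ensemble", nodes = nodes, rep = rep, heavy = heavy,
      atomNode = as.integer(atomNode), state = as.character(state),
      superposed = isTRUE(superposed))
}

#' @describeIn Ensemble number of frames
#' @param x,object an `Ensemble`.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname Ensemble
#' @export
setMethod("nFrames", "Ensemble", function(x) dim(x@rep)[1])

#' Accessors for node tables
#'
#' @param x an object carrying a node table.
#' @return the node `data.frame`.
#' @export
setGeneric("nodeTable", function(x) standardGeneric("nodeTable"))

#' @rdname nodeTable
#' @export
setMethod("nodeTable", "Ensemble", function(x) x@nodes)

#' State label accessor
#' @param x an object carrying a state label.
#' @export
setGeneric("stateLabel", function(x) standardGeneric("stateLabel"))

#' @rdname stateLabel
#' @export
setMethod("stateLabel", "Ensemble", function(x) x@state)

#' Representative coordinates accessor
#' @param x an `Ensemble`.
#' @return numeric `F x N x 3` array.
#' @export
repCoords <- function(x) x@rep

setMethod("show", "Ensemble", function(object) {
  cat("Ensemble of", dim(object@rep)[1], "frames,",
      nrow(object@nodes), "nodes",
      if (nzchar(object@state)) paste0("(state '", object@state, "')") else "",
      "\n")
  cat("  heavy-atom layer:",
      if (length(object@heavy)) paste(dim(object@heavy)[2], "atoms") else "absent",
      "| superposed:", object@superposed, "\n")
})

## ---------------------------------------------------------------------------
## Contact probability matrix
## ---------------------------------------------------------------------------

#' Contact probability matrix
#'
#' Symmetric `N x N` matrix of contact occupancies `P_ij` in `[0,1]`: the
#' fraction of ensemble frames in which two non-adjacent residues are within
#' the contact cutoff. Sequence-adjacent same-chain pairs (separation up to
#' `exclusion`) and the diagonal are fixed at zero.
#'
#' @slot P symmetric numeric matrix with node keys as dimnames.
#' @slot nodes node table.
#' @slot cutoff contact cutoff, Angstrom.
#' @slot exclusion minimum excluded sequence separation (same chain).
#' @slot geometry `"heavy"` or `"representative"`.
#' @slot state state label.
#' @slot frames number of frames the occupancy was measured over.
#' @export
setClass("ContactProbabilityMatrix",
  representation(P = "matrix", nodes = "data.frame", cutoff = "numeric",
                 exclusion = "integer", geometry = "character",
                 state = "character", frames = "integer"))

setValidity("ContactProbabilityMatrix", function(object) {
  P <- object@P
  if (nrow(P) != ncol(P)) return("P must be square")
  if (nrow(P) != nrow(object@nodes)) return("P does not match node table")
  if (any(P < 0) || any(P > 1)) return("P entries must lie in [0,1]")
  if (!isTRUE(all.equal(P, t(P), tolerance = 1e-12))) return("P must be symmetric")
  if (any(diag(P) != 0)) return("diagonal of P must be zero")
  TRUE
})

#' @rdname nodeTable
#' @export
setMethod("nodeTable", "ContactProbabilityMatrix", function(x) x@nodes)

#' @rdname stateLabel
#' @export
setMethod("stateLabel", "ContactProbabilityMatrix", function(x) x@state)

#' Extract the raw occupancy matrix
#' @param x a `ContactProbabilityMatrix`.
#' @return symmetric numeric matrix.
#' @export
probMatrix <- function(x) x@P

setMethod("show", "ContactProbabilityMatrix", function(object) {
  up <- object@P[upper.tri(object@P)]
  cat("ContactProbabilityMatrix:", nrow(object@P), "nodes,",
      sum(up > 0), "pairs with P > 0\n")
  cat(sprintf("  cutoff %.2f A, exclusion %d, geometry '%s', %d frames%s\n",
              object@cutoff, object@exclusion, object@geometry, object@frames,
              if (nzchar(object@state)) paste0(", state '", object@state, "'")
              else ""))
})

## ---------------------------------------------------------------------------
## Networks
## ---------------------------------------------------------------------------

#' Weighted residue contact network for one state
#'
#' In `dcna` mode edges carry the contact probability `P_ij` (every pair with
#' `P_ij > 0`); in `covariance` mode edges are the pairs passing the binary
#' occupancy threshold, weighted `w_ij = -ln|c_ij|` from the dynamic
#' cross-correlation.
#'
#' @slot nodes node table.
#' @slot edges `data.frame` with integer columns `i`, `j` (`i < j`), numeric
#'   `weight`, and `P` (the occupancy backing the edge).
#' @slot mode `"dcna"` or `"covariance"`.
#' @slot state state label.
#' @export
setClass("ContactNetwork",
  representation(nodes = "data.frame", edges = "data.frame",
                 mode = "character", state = "character"))

setValidity("ContactNetwork", function(object) {
  e <- object@edges
  if (!all(c("i", "j", "weight", "P") %in% names(e)))
    return("edges need columns i, j, weight, P")
  if (nrow(e)) {
    if (any(e$i >= e$j)) return("edges must have i < j (no self-edges)")
    if (any(e$i < 1L) || any(e$j > nrow(object@nodes)))
      return("edge endpoints out of node range")
    if (any(!is.finite(e$weight)) || any(e$weight < 0))
      return("edge weights must be finite and non-negative")
  }
  if (!object@mode %in% c("dcna", "covariance"))
    return("mode must be 'dcna' or 'covariance'")
  TRUE
})

#' @rdname nodeTable
#' @export
setMethod("nodeTable", "ContactNetwork", function(x) x@nodes)

#' @rdname stateLabel
#' @export
setMethod("stateLabel", "ContactNetwork", function(x) x@state)

#' Edge table accessor
#' @param x a network-like object.
#' @return `data.frame` of edges.
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname edgeTable
#' @export
setMethod("edgeTable", "ContactNetwork", function(x) x@edges)

setMethod("show", "ContactNetwork", function(object) {
  cat("ContactNetwork (", object@mode, " mode): ", nrow(object@nodes),
      " nodes, ", nrow(object@edges), " edges",
      if (nzchar(object@state)) paste0(", state '", object@state, "'"), "\n",
      sep = "")
})

#' Consensus residue network across functional states
#'
#' Edge set restricted to contacts whose occupancy meets the stability
#' threshold in every input state; each edge retains its per-state
#' probabilities. The node set is the intersection of the per-state node sets
#' (matched on `chain:resno[insert]` keys); nodes absent from any state are
#' recorded in `dropped`.
#'
#' @slot nodes node table (consensus node set, re-indexed).
#' @slot edges `data.frame` with `i`, `j` and one `P.<state>` column per state.
#' @slot states character vector of state labels, in input order.
#' @slot threshold stability threshold applied per state.
#' @slot dropped character vector of node keys excluded from the consensus.
#' @export
setClass("ConsensusNetwork",
  representation(nodes = "data.frame", edges = "data.frame",
                 states = "character", threshold = "numeric",
                 dropped = "character"))

setValidity("ConsensusNetwork", function(object) {
  pc <- paste0("P.", object@states)
  if (!all(c("i", "j", pc) %in% names(object@edges)))
    return("consensus edges need i, j and one P.<state> column per state")
  if (nrow(object@edges)) {
    pm <- as.matrix(object@edges[pc])
    if (any(pm < object@threshold - 1e-12))
      return("a consensus edge falls below the stability threshold in a state")
  }
  TRUE
})

#' @rdname nodeTable
#' @export
setMethod("nodeTable", "ConsensusNetwork", function(x) x@nodes)

#' @rdname edgeTable
#' @export
setMethod("edgeTable", "ConsensusNetwork", function(x) x@edges)

setMethod("show", "ConsensusNetwork", function(object) {
  cat("ConsensusNetwork over states {",
      paste(object@states, collapse = ", "), "}: ",
      nrow(object@nodes), " nodes, ", nrow(object@edges),
      " stable edges (P >= ", object@threshold, " in every state)\n", sep = "")
  if (length(object@dropped))
    cat("  ", length(object@dropped), "nodes dropped (absent from a state)\n")
})

## ---------------------------------------------------------------------------
## Community partition
## ---------------------------------------------------------------------------

#' Community partition of a residue network
#'
#' Result of the Girvan-Newman subdivision: a node-to-community labelling, its
#' Newman-Girvan modularity `Q`, and the dendrogram trace of every partition
#' recorded while removing maximal-betweenness edges.
#'
#' @slot membership integer community ids (1..K), named by node key.
#' @slot Q modularity of the returned partition.
#' @slot trace `data.frame` with columns `step`, `nCommunities`, `Q`, one row
#'   per recorded partition.
#' @slot traceMembership list of membership vectors parallel to `trace`.
#' @slot selected index into the trace of the returned partition.
#' @export
setClass("CommunityPartition",
  representation(membership = "integer", Q = "numeric", trace = "data.frame",
                 traceMembership = "list", selected = "integer"))

setValidity("CommunityPartition", function(object) {
  m <- object@membership
  if (!length(m)) return("empty membership")
  if (any(is.na(m))) return("membership labels must cover all nodes")
  if (object@Q < -0.5 - 1e-9 || object@Q > 1 + 1e-9)
    return("Q out of range [-0.5, 1]")
  TRUE
})

#' Community membership accessor
#' @param x a `CommunityPartition`.
#' @return named integer vector of community ids.
#' @export
communityMembership <- function(x) x@membership

#' Number of communities
#' @param x a `CommunityPartition`.
#' @export
nCommunities <- function(x) length(unique(x@membership))

setMethod("show", "CommunityPartition", function(object) {
  cat("CommunityPartition:", nCommunities(object), "communities over",
      length(object@membership), "nodes, Q =",
      formatC(object@Q, digits = 4, format = "f"), "\n")
  cat("  dendrogram trace:", nrow(object@trace), "recorded partitions\n")
})

## ---------------------------------------------------------------------------
## Difference network and community delta matrix
## ---------------------------------------------------------------------------

#' Difference contact network for one state transition
#'
#' Per consensus edge, the signed change in contact probability
#' `deltaP = P(state B) - P(state A)`; positive values are contacts gained in
#' the A to B transition.
#'
#' @slot nodes consensus node table.
#' @slot edges `data.frame` with `i`, `j`, `deltaP`, `P.a`, `P.b`.
#' @slot stateA,stateB transition end-state labels (A to B).
#' @export
setClass("DifferenceNetwork",
  representation(nodes = "data.frame", edges = "data.frame",
                 stateA = "character", stateB = "character"))

setValidity("DifferenceNetwork", function(object) {
  e <- object@edges
  if (!all(c("i", "j", "deltaP") %in% names(e)))
    return("difference edges need i, j, deltaP")
  if (nrow(e) && (any(e$deltaP < -1 - 1e-12) || any(e$deltaP > 1 + 1e-12)))
    return("deltaP must lie in [-1, 1]")
  TRUE
})

#' @rdname nodeTable
#' @export
setMethod("nodeTable", "DifferenceNetwork", function(x) x@nodes)

#' @rdname edgeTable
#' @export
setMethod("edgeTable", "DifferenceNetwork", function(x) x@edges)

setMethod("show", "DifferenceNetwork", function(object) {
  cat("DifferenceNetwork ", object@stateA, " -> ", object@stateB, ": ",
      nrow(object@edges), " consensus edges, net deltaP = ",
      formatC(sum(object@edges$deltaP), digits = 3, format = "f"),
      "\n", sep = "")
})

#' Community-aggregated contact probability changes
#'
#' `K x K` symmetric matrix whose off-diagonal entry (A, B) is the sum of edge
#' `deltaP` over consensus edges spanning communities A and B, and whose
#' diagonal holds within-community sums.
#'
#' @slot delta `K x K` numeric matrix.
#' @slot sizes integer community sizes (number of residues).
#' @slot stateA,stateB transition labels.
#' @export
setClass("CommunityDeltaMatrix",
  representation(delta = "matrix", sizes = "integer",
                 stateA = "character", stateB = "character"))

setValidity("CommunityDeltaMatrix", function(object) {
  d <- object@delta
  if (nrow(d) != ncol(d)) return("delta must be square")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-9)))
    return("delta must be symmetric")
  if (length(object@sizes) != nrow(d))
    return("sizes must have one entry per community")
  TRUE
})

#' Extract the community delta matrix
#' @param x a `CommunityDeltaMatrix`.
#' @export
deltaMatrix <- function(x) x@delta

setMethod("show", "CommunityDeltaMatrix", function(object) {
  cat("CommunityDeltaMatrix ", object@stateA, " -> ", object@stateB, ": ",
      nrow(object@delta), " communities, grand total deltaP = ",
      formatC(sum(object@delta[upper.tri(object@delta)]) +
              sum(diag(object@delta)), digits = 3, format = "f"),
      "\n", sep = "")
})

## ---------------------------------------------------------------------------
## B-factor profile and PCA result
## ---------------------------------------------------------------------------

#' Per-node B-factor profile
#'
#' Isotropic temperature factors computed from mean-square fluctuations of the
#' representative atoms: `B_i = (8 pi^2 / 3) <dr_i^2>`, both in Angstrom^2.
#'
#' @slot B numeric per-node B-factors, Angstrom^2.
#' @slot msf underlying mean-square fluctuations `<dr_i^2>`, Angstrom^2.
#' @slot nodes node table.
#' @slot state state label.
#' @export
setClass("BFactorProfile",
  representation(B = "numeric", msf = "numeric", nodes = "data.frame",
                 state = "character"))

setValidity("BFactorProfile", function(object) {
  if (length(object@B) != nrow(object@nodes)) return("B does not cover nodes")
  if (any(object@B < 0)) return("B-factors must be non-negative")
  if (!isTRUE(all.equal(object@B, 8 * pi^2 / 3 * object@msf)))
    return("B must equal (8 pi^2/3) msf")
  TRUE
})

#' @rdname nodeTable
#' @export
setMethod("nodeTable", "BFactorProfile", function(x) x@nodes)

#' B-factor accessor
#' @param x a `BFactorProfile`.
#' @export
bFactorValues <- function(x) x@B

setMethod("show", "BFactorProfile", function(object) {
  cat("BFactorProfile:", length(object@B), "nodes, mean B =",
      formatC(mean(object@B), digits = 2, format = "f"), "A^2\n")
})

#' Principal component analysis of representative-atom coordinates
#'
#' Eigen-decomposition of the `3N x 3N` Cartesian coordinate covariance of a
#' superposed ensemble. Modes are orthonormal 3N-vectors sorted by decreasing
#' variance; projections are the per-frame mode coordinates.
#'
#' @slot eigenvalues all `3N` eigenvalues (Angstrom^2, descending).
#' @slot modes `3N x nModes` orthonormal mode matrix (node-major x,y,z order).
#' @slot mean `N x 3` mean structure, Angstrom.
#' @slot projections `F x nModes` mode coordinates, Angstrom.
#' @slot nodes node table.
#' @slot totalVariance trace of the coordinate covariance, Angstrom^2.
#' @export
setClass("PCAResult",
  representation(eigenvalues = "numeric", modes = "matrix", mean = "matrix",
                 projections = "matrix", nodes = "data.frame",
                 totalVariance = "numeric"))

setValidity("PCAResult", function(object) {
  ev <- object@eigenvalues
  if (any(ev < -1e-8)) return("eigenvalues must be non-negative")
  if (is.unsorted(rev(ev), strictly = FALSE)) return("eigenvalues must descend")
  g <- crossprod(object@modes)
  if (max(abs(g - diag(ncol(object@modes)))) > 1e-8)
    return("modes must be pairwise orthonormal")
  if (abs(sum(ev) - object@totalVariance) >
      1e-6 * max(object@totalVariance, 1e-12))
    return("eigenvalue sum must equal covariance trace")
  TRUE
})

#' @rdname nodeTable
#' @export
setMethod("nodeTable", "PCAResult", function(x) x@nodes)

setMethod("show", "PCAResult", function(object) {
  ev <- object@eigenvalues
  frac <- if (sum(ev) > 0) ev[1] / sum(ev) else NA_real_
  cat("PCAResult:", ncol(object@modes), "modes retained of", length(ev), "\n")
  cat("  mode 1 variance fraction:",
      formatC(frac, digits = 3, format = "f"), "\n")
})
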