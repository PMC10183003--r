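## Contact probability maps, binary contact maps, dynamic cross-correlation
## and B-factor profiles from a conformational ensemble.

## Pairs excluded from contacts: same chain, |resno difference| <= exclusion.
.exclusionMask <- function(nodes, exclusion) {
  n <- nrow(nodes)
  sameChain <- outer(nodes$chain, nodes$chain, "==")
  sep <- abs(outer(nodes$resno, nodes$resno, "-"))
  excl <- sameChain & sep <= exclusion
  diag(excl) <- TRUE
  excl
}

#' Contact probability matrix of an ensemble
#'
#' For every non-adjacent residue pair, the fraction of frames in which the
#' minimum inter-residue distance falls within `cutoff`. The distance is
#' measured between heavy atoms by default (a 4.5-Angstrom cutoff is a
#' heavy-atom-scale contact criterion); `geometry = "representative"` uses
#' the CA/P representative atoms instead. Same-chain pairs with sequence
#' separation up to `exclusion` are excluded (set to zero), so trivially
#' bonded neighbours never count as contacts; inter-chain pairs are never
#' excluded.
#'
#' @param ensemble an [Ensemble-class] with at least 2 frames.
#' @param cutoff contact cutoff in Angstrom (default 4.5).
#' @param exclusion minimum excluded sequence separation (default 1:
#'   residues i and i+1 of the same chain are excluded).
#' @param geometry `"heavy"` (default) or `"representative"`.
#' @return a [ContactProbabilityMatrix-class].
#' @export
contactProbability <- function(ensemble, cutoff = 4.5, exclusion = 1L,
                               geometry = c("heavy", "representative")) {
  stopifnot(is(ensemble, "Ensemble"))
  geometry <- match.arg(geometry)
  f <- nFrames(ensemble)
  if (f < 2L) stop("insufficient frames: contact statistics need F >= 2")
  nodes <- ensemble@nodes
  n <- nrow(nodes)

  if (geometry == "heavy") {
    if (!length(ensemble@heavy))
      stop("geometry error: heavy-atom mode requires a heavy-atom layer")
    coords <- ensemble@heavy
    grp <- ensemble@atomNode
  } else {
    coords <- ensemble@rep
    grp <- seq_len(n)
  }
  a <- dim(coords)[2]
  ## atom -> node incidence; node-pair contact = any atom-pair contact
  M <- matrix(0, a, n)
  M[cbind(seq_len(a), grp)] <- 1
  cut2 <- cutoff^2

  counts <- matrix(0, n, n)
  for (fr in seq_len(f)) {
    x <- matrix(coords[fr, , ], ncol = 3)
    sq <- rowSums(x^2)
    d2 <- outer(sq, sq, "+") - 2 * tcrossprod(x)
    ct <- d2 <= cut2
    nodeContact <- crossprod(M, ct %*% M) > 0
    counts <- counts + nodeContact
  }
  P <- counts / f
  P[.exclusionMask(nodes, as.integer(exclusion))] <- 0
  P <- (P + t(P)) / 2  # exact by construction; guards numeric symmetry
  dimnames(P) <- list(nodeKeys(nodes), nodeKeys(nodes))
  new("ContactProbabilityMatrix", P = P, nodes = nodes, cutoff = cutoff,
      exclusion = as.integer(exclusion), geometry = geometry,
      state = ensemble@state, frames = as.integer(f))
}

#' Binary contact map from an occupancy matrix
#'
#' Applies the occupancy rule: residues are in contact when they are within
#' the cutoff for at least `threshold` of the trajectory (inclusive, so an
#' occupancy exactly at the threshold qualifies).
#'
#' @param P a [ContactProbabilityMatrix-class].
#' @param threshold occupancy fraction in (0, 1], default 0.75.
#' @return logical adjacency matrix (node keys as dimnames).
#' @export
binaryContacts <- function(P, threshold = 0.75) {
  stopifnot(is(P, "ContactProbabilityMatrix"))
  if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]")
  P@P >= threshold
}

#' Dynamic cross-correlation matrix
#'
#' Vector dot-product cross-correlation of representative-atom displacements,
#' `c_ij = <dr_i . dr_j> / sqrt(<dr_i^2><dr_j^2>)` with
#' `dr_i = r_i - <r_i>` -- the standard correlation coefficient of residue
#' network analysis (not a per-axis Pearson correlation). Requires a
#' superposed ensemble so that rigid-body motion does not masquerade as
#' correlation.
#'
#' @param ensemble a superposed [Ensemble-class], F >= 2.
#' @return symmetric `N x N` matrix with unit diagonal.
#' @export
crossCorrelation <- function(ensemble) {
  stopifnot(is(ensemble, "Ensemble"))
  if (!ensemble@superposed)
    stop("ensemble must be superposed before computing correlations")
  f <- nFrames(ensemble)
  if (f < 2L) stop("insufficient frames: need F >= 2")
  n <- nrow(ensemble@nodes)

  num <- matrix(0, n, n)
  for (ax in 1:3) {
    dev <- ensemble@rep[, , ax, drop = TRUE]
    if (is.null(dim(dev))) dev <- matrix(dev, nrow = f)
    dev <- sweep(dev, 2, colMeans(dev))
    num <- num + crossprod(dev) / f
  }
  msf <- diag(num)
  zero <- which(msf <= 0)
  if (length(zero))
    stop("undefined correlation: zero-variance node(s) ",
         paste(nodeKeys(ensemble@nodes)[zero], collapse = ", "))
  c_ <- num / sqrt(outer(msf, msf))
  c_ <- (c_ + t(c_)) / 2
  diag(c_) <- 1
  dimnames(c_) <- list(nodeKeys(ensemble@nodes), nodeKeys(ensemble@nodes))
  c_
}

#' Per-node B-factor profile of an ensemble
#'
#' Mean-square fluctuation of each representative atom about its ensemble
#' mean, converted to an isotropic temperature factor with the
#' crystallographic convention `B_i = (8 pi^2 / 3) <dr_i^2>`. Requires a
#' superposed ensemble: the fit removes global rigid-body motion that would
#' otherwise inflate the profile.
#'
#' @param ensemble a superposed [Ensemble-class], F >= 2.
#' @return a [BFactorProfile-class].
#' @export
bFactors <- function(ensemble) {
  stopifnot(is(ensemble, "Ensemble"))
  if (!ensemble@superposed)
    stop("ensemble must be superposed before computing B-factors")
  f <- nFrames(ensemble)
  if (f < 2L) stop("insufficient frames: need F >= 2")
  msf <- numeric(nrow(ensemble@nodes))
  for (ax in 1:3) {
    dev <- ensemble@rep[, , ax, drop = TRUE]
    if (is.null(dim(dev))) dev <- matrix(dev, nrow = f)
    dev <- sweep(dev, 2, colMeans(dev))
    msf <- msf + colMeans(dev^2)
  }
  new("BFactorProfile", B = 8 * pi^2 / 3 * msf, msf = msf,
      nodes = ensemble@nodes, state = ensemble@state)
}
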