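## Principal component analysis of representative-atom coordinates and
## mapping of principal-mode displacements onto dynamic communities.

## Flatten F x N x 3 coordinates to F x 3N, node-major (x1,y1,z1,x2,...).
.flattenCoords <- function(rep) {
  f <- dim(rep)[1]; n <- dim(rep)[2]
  x <- matrix(0, f, 3 * n)
  x[, seq(1, 3 * n, by = 3)] <- rep[, , 1]
  x[, seq(2, 3 * n, by = 3)] <- rep[, , 2]
  x[, seq(3, 3 * n, by = 3)] <- rep[, , 3]
  x
}

#' Cartesian coordinate covariance of an ensemble
#'
#' `3N x 3N` covariance of the flattened representative coordinates about the
#' ensemble mean (population convention, division by F), on the same
#' superposed frames used for the B-factor profile so that rigid-body motion
#' is excluded.
#'
#' @param ensemble a superposed [Ensemble-class], F >= 2.
#' @return symmetric positive-semidefinite `3N x 3N` matrix (Angstrom^2).
#' @export
coordinateCovariance <- function(ensemble) {
  stopifnot(is(ensemble, "Ensemble"))
  if (!ensemble@superposed)
    stop("ensemble must be superposed before computing the covariance")
  f <- nFrames(ensemble)
  if (f < 2L) stop("insufficient frames: need F >= 2")
  x <- .flattenCoords(ensemble@rep)
  x <- sweep(x, 2, colMeans(x))
  crossprod(x) / f
}

#' Principal modes of an ensemble
#'
#' Diagonalizes the Cartesian coordinate covariance and retains the
#' `nModes` dominant (largest-variance) eigenpairs -- the "lowest" principal
#' modes in the essential-dynamics sense. No mass weighting is applied.
#' Mode signs follow a deterministic convention: the largest-magnitude
#' component of each mode is positive. Frame projections onto the retained
#' modes are included; their per-mode variance equals the corresponding
#' eigenvalue.
#'
#' @param ensemble a superposed [Ensemble-class].
#' @param nModes number of modes to retain (default 5, capped at 3N).
#' @return a [PCAResult-class].
#' @export
principalModes <- function(ensemble, nModes = 5L) {
  stopifnot(is(ensemble, "Ensemble"))
  cov <- coordinateCovariance(ensemble)
  if (max(abs(cov - t(cov))) > 1e-8)
    stop("covariance matrix is not symmetric")
  nModes <- min(as.integer(nModes), ncol(cov))
  if (nModes < 1L) stop("nModes must be at least 1")

  eg <- eigen(cov, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  modes <- eg$vectors[, seq_len(nModes), drop = FALSE]
  for (k in seq_len(nModes)) {
    pivot <- which.max(abs(modes[, k]))
    if (modes[pivot, k] < 0) modes[, k] <- -modes[, k]
  }

  x <- .flattenCoords(ensemble@rep)
  mu <- colMeans(x)
  proj <- sweep(x, 2, mu) %*% modes
  meanStructure <- matrix(mu, ncol = 3, byrow = TRUE)
  new("PCAResult", eigenvalues = ev, modes = modes, mean = meanStructure,
      projections = proj, nodes = ensemble@nodes,
      totalVariance = sum(diag(cov)))
}

#' Per-node mode displacement arrows grouped by community
#'
#' Converts one principal mode into per-node 3-vector displacements
#' (porcupine arrows, mode component times `scale`) annotated with community
#' ids, plus a per-community summary: mean displacement direction (unit
#' vector of the mean arrow) and mean amplitude, the quantities used to
#' contrast mobile and locked modules.
#'
#' @param pca a [PCAResult-class].
#' @param modeIndex which retained mode to expand (default 1).
#' @param partition a [CommunityPartition-class] covering the PCA nodes.
#' @param scale multiplier applied to every arrow (default 1).
#' @return list with `arrows` (`data.frame`: key, dx, dy, dz, amplitude,
#'   community) and `summary` (`data.frame`: community, size, meanAmplitude,
#'   mean direction components).
#' @export
modeArrowsByCommunity <- function(pca, modeIndex = 1L, partition, scale = 1) {
  stopifnot(is(pca, "PCAResult"), is(partition, "CommunityPartition"))
  modeIndex <- as.integer(modeIndex)
  if (modeIndex < 1L || modeIndex > ncol(pca@modes))
    stop("modeIndex out of range")
  nodes <- pca@nodes
  keys <- nodeKeys(nodes)
  idx <- match(keys, names(partition@membership))
  if (anyNA(idx)) stop("partition does not cover all PCA nodes")
  lab <- as.integer(partition@membership[idx])

  v <- matrix(pca@modes[, modeIndex], ncol = 3, byrow = TRUE) * scale
  arrows <- data.frame(key = keys, dx = v[, 1], dy = v[, 2], dz = v[, 3],
                       amplitude = sqrt(rowSums(v^2)), community = lab,
                       stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(sort(unique(lab)), function(cc) {
    sel <- lab == cc
    mv <- colMeans(v[sel, , drop = FALSE])
    nrm <- sqrt(sum(mv^2))
    dir <- if (nrm > 0) mv / nrm else c(0, 0, 0)
    data.frame(community = cc, size = sum(sel),
               meanAmplitude = mean(arrows$amplitude[sel]),
               dirX = dir[1], dirY = dir[2], dirZ = dir[3])
  }))
  list(arrows = arrows, summary = summ)
}

#' Write porcupine arrows as a viewer-ready text table
#'
#' @param arrows the `arrows` element of [modeArrowsByCommunity()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeArrows <- function(arrows, path) {
  utils::write.table(arrows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
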