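#' @importFrom bio3d read.pdb read.dcd aa321
#' @importFrom stats sd
NULL

## Residues keep altloc "" or "A" only; representative atom is CA for any
## residue containing one, else P (nucleotides); others are skipped.

.keepAlt <- function(alt) is.na(alt) | alt %in% c("", "A")

#' Load a PDB topology into a node table
#'
#' Builds the node-centric model of a structure: one node per residue that
#' possesses its representative atom (CA for protein residues, P for nucleic
#' residues). Residues lacking the representative atom -- e.g. a 5'-terminal
#' nucleotide without a phosphate -- are skipped with a message. Nodes are
#' ordered by (chain, residue number, insertion code) with author numbering
#' preserved.
#'
#' @param path path to a PDB file.
#' @param verbose emit a message listing skipped residues.
#' @return a node table `data.frame` (see [validateNodeTable()]).
#' @export
loadTopology <- function(path, verbose = TRUE) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e)
                    stop("cannot parse PDB topology '", path, "': ",
                         conditionMessage(e)))
  at <- pdb$atom
  at <- at[.keepAlt(at$alt) & !at$type %in% "TER", , drop = FALSE]
  at$insert[is.na(at$insert)] <- ""
  at$chain[is.na(at$chain)] <- ""
  rkey <- paste(at$chain, at$resno, at$insert, sep = "\r")
  split_idx <- split(seq_len(nrow(at)), factor(rkey, levels = unique(rkey)))

  rows <- lapply(split_idx, function(ix) {
    a <- at[ix, , drop = FALSE]
    if ("CA" %in% a$elety) {
      kind <- "protein"; repAtom <- "CA"
    } else if ("P" %in% a$elety) {
      kind <- "nucleic"; repAtom <- "P"
    } else {
      return(NULL)
    }
    data.frame(chain = a$chain[1], resno = a$resno[1], insert = a$insert[1],
               resid = a$resid[1], kind = kind, repAtom = repAtom,
               stringsAsFactors = FALSE)
  })
  skipped <- sum(vapply(rows, is.null, logical(1)))
  nodes <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(nodes) || nrow(nodes) == 0L)
    stop("empty model: no residue in '", path,
         "' carries a CA or P representative atom")
  o <- order(nodes$chain, nodes$resno, nodes$insert)
  nodes <- nodes[o, , drop = FALSE]
  nodes <- cbind(node = seq_len(nrow(nodes)), nodes)
  rownames(nodes) <- NULL
  if (skipped > 0L && verbose)
    message(skipped, " residue(s) without a representative atom skipped")
  validateNodeTable(nodes)
  nodes
}

## Atom bookkeeping shared by loadEnsemble: for a parsed PDB, the indices of
## representative atoms (one per node, node order) and of heavy atoms with
## their node map.  Hydrogens (element H or name starting H/[0-9]H) excluded.
.atomPlan <- function(pdb, nodes) {
  at <- pdb$atom
  keep <- .keepAlt(at$alt)
  at$insert[is.na(at$insert)] <- ""
  at$chain[is.na(at$chain)] <- ""
  rkey <- paste(at$chain, at$resno, at$insert, sep = "\r")
  nkey <- paste(nodes$chain, nodes$resno, nodes$insert, sep = "\r")
  nodeOf <- match(rkey, nkey)

  repIdx <- integer(nrow(nodes))
  for (k in seq_len(nrow(nodes))) {
    hit <- which(keep & nodeOf == k & at$elety == nodes$repAtom[k])
    if (!length(hit))
      stop("topology/trajectory mismatch: node ", nkey[k],
           " lacks its representative atom")
    repIdx[k] <- hit[1]
  }
  elety <- at$elety
  isH <- grepl("^[0-9]*H", elety)
  heavyIdx <- which(keep & !is.na(nodeOf) & !isH)
  list(repIdx = repIdx, heavyIdx = heavyIdx, heavyNode = nodeOf[heavyIdx])
}

.readTrajectoryXYZ <- function(path, nAtomsExpected) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "xtc")
    stop("XTC trajectories are not supported; supply DCD or multi-model PDB")
  xyz <- if (ext == "dcd") {
    bio3d::read.dcd(path, verbose = FALSE)
  } else {
    p <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    p$xyz
  }
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L * nAtomsExpected)
    stop("atom-count mismatch: trajectory '", path, "' has ",
         ncol(xyz) / 3, " atoms, topology has ", nAtomsExpected)
  xyz
}

#' Load a trajectory ensemble against a topology
#'
#' Reads one or more trajectory files (DCD or multi-model PDB), concatenates
#' the frames in the order given, subsamples by `stride`, and extracts the
#' representative-atom and heavy-atom coordinate layers defined by the
#' topology.
#'
#' @param topology path to the PDB topology defining atoms and residues.
#' @param trajectories character vector of trajectory paths; a zero-length
#'   vector uses the topology's own models (multi-model PDB input).
#' @param stride keep every `stride`-th frame (default 1).
#' @param state state label attached to the ensemble.
#' @param verbose passed to [loadTopology()].
#' @return an [Ensemble-class] with both coordinate layers populated.
#' @export
loadEnsemble <- function(topology, trajectories = character(), stride = 1L,
                         state = "", verbose = TRUE) {
  stride <- as.integer(stride)
  if (is.na(stride) || stride < 1L) stop("stride must be a positive integer")
  nodes <- loadTopology(topology, verbose = verbose)
  pdb <- bio3d::read.pdb(topology, verbose = FALSE)
  plan <- .atomPlan(pdb, nodes)
  nAtoms <- nrow(pdb$atom)

  if (length(trajectories) == 0L) trajectories <- topology
  xyz <- do.call(rbind, lapply(trajectories, .readTrajectoryXYZ, nAtoms))
  xyz <- xyz[seq(1L, nrow(xyz), by = stride), , drop = FALSE]
  if (nrow(xyz) == 0L) stop("empty ensemble: no frames survive the stride")

  f <- nrow(xyz)
  toArray <- function(idx) {
    cols <- rbind(3 * (idx - 1) + 1, 3 * (idx - 1) + 2, 3 * (idx - 1) + 3)
    a <- array(0, dim = c(f, length(idx), 3))
    a[, , 1] <- xyz[, cols[1, ], drop = FALSE]
    a[, , 2] <- xyz[, cols[2, ], drop = FALSE]
    a[, , 3] <- xyz[, cols[3, ], drop = FALSE]
    a
  }
  Ensemble(nodes,
           rep = toArray(plan$repIdx),
           heavy = toArray(plan$heavyIdx),
           atomNode = plan$heavyNode,
           state = state)
}

## Kabsch rigid-body fit: rotation + translation mapping mobile onto target
## (both n x 3, same row order), no scaling.
.kabsch <- function(mobile, target) {
  cm <- colMeans(mobile); ct <- colMeans(target)
  A <- sweep(mobile, 2, cm); B <- sweep(target, 2, ct)
  s <- svd(crossprod(A, B))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = R, center = cm, shift = ct)
}

.applyRigid <- function(coords, fit) {
  sweep(sweep(coords, 2, fit$center) %*% t(fit$R), 2, fit$shift, "+")
}

#' Superpose an ensemble onto a common reference
#'
#' Removes global rigid-body motion by least-squares fitting every frame
#' (rotation + translation, no scaling) over the representative atoms of
#' `fitNodes`. By default a two-pass scheme is used: frames are first fitted
#' to frame 1, then refitted to the resulting ensemble-average structure,
#' which removes global drift that would otherwise inflate B-factors and PCA
#' modes. Supplying `referenceFrame` fits to that frame in a single pass. The
#' heavy-atom layer is transformed by the same rigid motions.
#'
#' @param ensemble an [Ensemble-class].
#' @param referenceFrame optional frame index for a single-pass fit.
#' @param fitNodes node indices used for the fit (default all nodes).
#' @return the superposed [Ensemble-class] (`superposed = TRUE`).
#' @export
superpose <- function(ensemble, referenceFrame = NULL, fitNodes = NULL) {
  stopifnot(is(ensemble, "Ensemble"))
  n <- nrow(ensemble@nodes)
  if (is.null(fitNodes)) fitNodes <- seq_len(n)
  fitNodes <- as.integer(fitNodes)
  if (length(fitNodes) < 3L)
    stop("underdetermined fit: need at least 3 fit nodes")
  if (any(fitNodes < 1L) || any(fitNodes > n)) stop("fitNodes out of range")
  f <- nFrames(ensemble)

  fitAll <- function(rep, heavy, refSel) {
    for (fr in seq_len(f)) {
      fit <- .kabsch(rep[fr, fitNodes, , drop = TRUE], refSel)
      rep[fr, , ] <- .applyRigid(rep[fr, , , drop = TRUE], fit)
      if (length(heavy))
        heavy[fr, , ] <- .applyRigid(
          matrix(heavy[fr, , ], ncol = 3), fit)
    }
    list(rep = rep, heavy = heavy)
  }

  rep <- ensemble@rep; heavy <- ensemble@heavy
  if (!is.null(referenceFrame)) {
    referenceFrame <- as.integer(referenceFrame)
    if (referenceFrame < 1L || referenceFrame > f)
      stop("referenceFrame out of range")
    ref <- rep[referenceFrame, fitNodes, , drop = TRUE]
    out <- fitAll(rep, heavy, ref)
  } else {
    pass1 <- fitAll(rep, heavy, rep[1L, fitNodes, , drop = TRUE])
    meanRef <- apply(pass1$rep[, fitNodes, , drop = FALSE], c(2, 3), mean)
    out <- fitAll(pass1$rep, pass1$heavy, meanRef)
  }
  new("Ensemble", nodes = ensemble@nodes, rep = out$rep, heavy = out$heavy,
      atomNode = ensemble@atomNode, state = ensemble@state, superposed = TRUE)
}

#' Write per-node values into the B-factor column of a PDB template
#'
#' Annotates a structure for molecular-viewer colouring: every atom of a
#' residue receives that residue's value (B-factor profile, community id,
#' etc.), formatted to two decimals and clipped to the PDB column range
#' `[0, 999.99]` (with a warning when clipping occurs). All other bytes of
#' the atom records, and all non-atom records, are left untouched.
#'
#' @param nodes node table matching the template.
#' @param values numeric vector, one value per node.
#' @param template path to the template PDB.
#' @param out output path.
#' @return `out`, invisibly.
#' @export
writeAnnotatedPDB <- function(nodes, values, template, out) {
  validateNodeTable(nodes)
  if (length(values) != nrow(nodes))
    stop("values must cover all ", nrow(nodes), " nodes")
  clipped <- pmin(pmax(values, 0), 999.99)
  if (any(clipped != values))
    warning("values outside [0, 999.99] clipped to the PDB B-factor range")

  lines <- readLines(template)
  isAtom <- grepl("^(ATOM  |HETATM)", lines)
  nkey <- paste(nodes$chain, nodes$resno, nodes$insert, sep = "\r")
  nAnnotated <- 0L
  for (ix in which(isAtom)) {
    ln <- lines[ix]
    chain <- trimws(substr(ln, 22, 22))
    resno <- suppressWarnings(as.integer(trimws(substr(ln, 23, 26))))
    insert <- trimws(substr(ln, 27, 27))
    k <- match(paste(chain, resno, insert, sep = "\r"), nkey)
    if (is.na(k)) next
    if (nchar(ln) < 66) ln <- formatC(ln, width = -66)
    substr(ln, 61, 66) <- formatC(clipped[k], width = 6, digits = 2,
                                  format = "f")
    lines[ix] <- ln
    nAnnotated <- nAnnotated + 1L
  }
  if (nAnnotated == 0L)
    stop("node/template mismatch: no atom record matched a node key")
  writeLines(lines, out)
  invisible(out)
}

#' Write an ensemble as a multi-model PDB
#'
#' Emits the heavy-atom layer (or the representative layer when no heavy
#' atoms are present) as standard `MODEL`/`ENDMDL` blocks, suitable for
#' round-tripping through [loadEnsemble()] and for viewer inspection.
#'
#' @param ensemble an [Ensemble-class].
#' @param path output path.
#' @param frames frame indices to write (default all).
#' @return `path`, invisibly.
#' @export
writeEnsemblePDB <- function(ensemble, path, frames = NULL) {
  stopifnot(is(ensemble, "Ensemble"))
  nodes <- ensemble@nodes
  if (is.null(frames)) frames <- seq_len(nFrames(ensemble))
  useHeavy <- length(ensemble@heavy) > 0L

  if (useHeavy) {
    nodeOf <- ensemble@atomNode
    ## name atoms per node: representative first, then CB, CG, CD, ...
    sidenames <- c("CB", "CG", "CD", "CE", "CZ", "CH")
    elety <- character(length(nodeOf))
    for (k in seq_len(nrow(nodes))) {
      ats <- which(nodeOf == k)
      elety[ats[1]] <- nodes$repAtom[k]
      if (length(ats) > 1L)
        elety[ats[-1]] <- sidenames[seq_len(length(ats) - 1L)]
    }
  } else {
    nodeOf <- seq_len(nrow(nodes))
    elety <- nodes$repAtom
  }

  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    writeLines(sprintf("MODEL     %4d", match(fr, frames)), con)
    xyz <- if (useHeavy) matrix(ensemble@heavy[fr, , ], ncol = 3)
           else matrix(ensemble@rep[fr, , ], ncol = 3)
    recs <- sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
      seq_along(nodeOf),
      ifelse(nchar(elety[seq_along(nodeOf)]) < 4,
             paste0(" ", elety[seq_along(nodeOf)]),
             elety[seq_along(nodeOf)]),
      nodes$resid[nodeOf], nodes$chain[nodeOf], nodes$resno[nodeOf],
      xyz[, 1], xyz[, 2], xyz[, 3], 1, 0)
    writeLines(recs, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
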