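## End-to-end orchestration: configuration, the four-step dCNA workflow
## (per-state contact networks -> consensus -> communities -> difference
## networks), per-state flexibility/PCA profiles, and mutation mapping.

#' Assemble a run configuration
#'
#' Collects every tunable of the workflow with its default. Defaults follow
#' the contact rule and stopping rule of the analysis: 4.5 Angstrom cutoff,
#' 0.75 occupancy threshold, 0.75 consensus stability threshold, 0.001
#' modularity stopping threshold.
#'
#' @param states list of per-state entries, each a list with `label`,
#'   `topology` (PDB path), optional `trajectories` (character vector) and
#'   optional `stride` (default 1).
#' @param transitions list of length-2 character vectors
#'   `c(stateA, stateB)`; defaults to consecutive state pairs.
#' @param cutoff,occupancyThreshold,stabilityMinProbability,stopDeltaQ
#'   numeric workflow parameters (defaults 4.5, 0.75, 0.75, 0.001).
#' @param geometry contact geometry, `"heavy"` or `"representative"`.
#' @param exclusion excluded sequence separation (default 1).
#' @param nModes PCA modes to retain in profiles (default 5).
#' @param mutations optional mutation TSV path.
#' @param outputDir output directory (created when missing).
#' @return a validated configuration list of class `"dcnaRunConfig"`.
#' @export
runConfig <- function(states, transitions = NULL, cutoff = 4.5,
                      occupancyThreshold = 0.75,
                      stabilityMinProbability = 0.75, stopDeltaQ = 0.001,
                      geometry = c("heavy", "representative"),
                      exclusion = 1L, nModes = 5L, mutations = NULL,
                      outputDir = "dcna-output") {
  geometry <- match.arg(geometry)
  if (!length(states)) stop("config error: at least one state is required")
  labels <- vapply(states, function(s) as.character(s$label), character(1))
  if (anyDuplicated(labels)) stop("config error: duplicate state labels")
  states <- lapply(states, function(s) {
    if (is.null(s$topology)) stop("config error: state lacks a topology")
    s$trajectories <- as.character(s$trajectories %||% character())
    s$stride <- as.integer(s$stride %||% 1L)
    s
  })
  if (is.null(transitions) && length(labels) >= 2L)
    transitions <- lapply(seq_len(length(labels) - 1L),
                          function(i) labels[i:(i + 1L)])
  for (tr in transitions)
    if (!all(tr %in% labels))
      stop("config error: transition references unknown state")
  structure(list(states = states, transitions = transitions,
                 cutoff = cutoff, occupancyThreshold = occupancyThreshold,
                 stabilityMinProbability = stabilityMinProbability,
                 stopDeltaQ = stopDeltaQ, geometry = geometry,
                 exclusion = as.integer(exclusion),
                 nModes = as.integer(nModes), mutations = mutations,
                 outputDir = outputDir),
            class = "dcnaRunConfig")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a run configuration from a YAML file
#'
#' The file mirrors [runConfig()]'s arguments; unknown keys are rejected.
#'
#' @param path YAML path.
#' @return a configuration list (see [runConfig()]).
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("states", "transitions", "cutoff", "occupancyThreshold",
             "stabilityMinProbability", "stopDeltaQ", "geometry",
             "exclusion", "nModes", "mutations", "outputDir")
  extra <- setdiff(names(y), known)
  if (length(extra))
    stop("config error: unknown key(s) ", paste(extra, collapse = ", "))
  do.call(runConfig, y)
}

.loadState <- function(config, s) {
  loadEnsemble(s$topology, s$trajectories, stride = s$stride,
               state = s$label, verbose = FALSE)
}

.writeMatrixTSV <- function(m, path) {
  utils::write.table(data.frame(node = rownames(m), m, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.configEcho <- function(config) {
  list(states = lapply(config$states, function(s)
         list(label = s$label, topology = s$topology,
              trajectories = s$trajectories, stride = s$stride)),
       transitions = config$transitions, cutoff = config$cutoff,
       occupancyThreshold = config$occupancyThreshold,
       stabilityMinProbability = config$stabilityMinProbability,
       stopDeltaQ = config$stopDeltaQ, geometry = config$geometry,
       exclusion = config$exclusion, nModes = config$nModes,
       mutations = config$mutations, outputDir = config$outputDir)
}

#' Run the four-step dCNA workflow
#'
#' Executes, in order: (1) per-state contact probability networks; (2) the
#' consensus network of contacts stable across every state; (3) community
#' detection on the consensus network; (4) per-transition difference
#' networks with community-aggregated contact changes and top-changed
#' residue lists. All products are written under `config$outputDir` (one
#' directory per state, one per transition) together with a JSON manifest
#' echoing every effective parameter.
#'
#' @param config a configuration from [runConfig()] or [readRunConfig()]
#'   with at least two states.
#' @param ensembles optional named list of pre-loaded [Ensemble-class]
#'   objects (bypasses file loading; names must match state labels).
#' @return invisibly, a list with the per-state probability matrices and
#'   networks, the consensus network, the partition, and per-transition
#'   difference results.
#' @export
runDCNA <- function(config, ensembles = NULL) {
  stopifnot(inherits(config, "dcnaRunConfig"))
  if (length(config$states) < 2L)
    stop("config error: dCNA needs at least two states")
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  labels <- vapply(config$states, function(s) s$label, character(1))

  ## step 1: per-state contact probability networks
  pmats <- list(); nets <- list()
  for (s in config$states) {
    ens <- if (!is.null(ensembles)) ensembles[[s$label]]
           else .loadState(config, s)
    P <- contactProbability(ens, cutoff = config$cutoff,
                            exclusion = config$exclusion,
                            geometry = config$geometry)
    net <- buildNetwork(P, mode = "dcna")
    sdir <- file.path(config$outputDir, paste0("state-", s$label))
    dir.create(sdir, showWarnings = FALSE)
    .writeMatrixTSV(probMatrix(P), file.path(sdir, "contact-probability.tsv"))
    writeEdgeList(net, file.path(sdir, "network-edges.tsv"))
    pmats[[s$label]] <- P
    nets[[s$label]] <- net
  }

  ## step 2: consensus network
  consensus <- consensusNetwork(nets, config$stabilityMinProbability)
  writeEdgeList(consensus, file.path(config$outputDir, "consensus-edges.tsv"))
  writeGraphML(consensus, file.path(config$outputDir, "consensus.graphml"))

  ## step 3: communities on the consensus network
  partition <- girvanNewman(consensus, stopDeltaQ = config$stopDeltaQ)
  writePartition(partition, file.path(config$outputDir, "communities.tsv"))

  ## step 4: difference networks per transition
  diffs <- list()
  for (tr in config$transitions) {
    label <- paste0(tr[1], "-to-", tr[2])
    tdir <- file.path(config$outputDir, paste0("transition-", label))
    dir.create(tdir, showWarnings = FALSE)
    dn <- differenceNetwork(consensus, tr[1], tr[2])
    cdm <- communityDelta(dn, partition)
    top <- topChangedResidues(dn)
    writeEdgeList(dn, file.path(tdir, "difference-edges.tsv"))
    writeDeltaMatrix(cdm, file.path(tdir, "community-delta.tsv"))
    utils::write.table(top, file.path(tdir, "top-changed-residues.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    diffs[[label]] <- list(difference = dn, communityDelta = cdm, top = top)
  }

  manifest <- list(
    tool = "dcna", version = as.character(utils::packageVersion("dcna")),
    config = .configEcho(config),
    states = labels,
    consensus = list(nodes = nrow(nodeTable(consensus)),
                     edges = nrow(edgeTable(consensus)),
                     dropped = length(consensus@dropped)),
    partition = list(n_communities = nCommunities(partition),
                     Q = partition@Q),
    transitions = lapply(names(diffs), function(nm) list(
      transition = nm,
      total_deltaP = sum(edgeTable(diffs[[nm]]$difference)$deltaP))))
  jsonlite::write_json(manifest, file.path(config$outputDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(probabilities = pmats, networks = nets,
                 consensus = consensus, partition = partition,
                 transitions = diffs))
}

#' B-factor and PCA profile of one state
#'
#' Superposes the state's ensemble (two-pass fit to the ensemble mean),
#' computes the per-node B-factor profile and the dominant principal modes,
#' and writes the profile tables plus a B-factor-annotated copy of the
#' topology.
#'
#' @param config a configuration from [runConfig()].
#' @param state label of the configured state to profile.
#' @param ensemble optional pre-loaded [Ensemble-class] for that state.
#' @return invisibly, a list with the superposed ensemble, the
#'   [BFactorProfile-class] and the [PCAResult-class].
#' @export
runStateProfile <- function(config, state, ensemble = NULL) {
  stopifnot(inherits(config, "dcnaRunConfig"))
  labels <- vapply(config$states, function(s) s$label, character(1))
  k <- match(state, labels)
  if (is.na(k)) stop("config error: unknown state '", state, "'")
  s <- config$states[[k]]
  ens <- ensemble %||% .loadState(config, s)
  ens <- superpose(ens)

  sdir <- file.path(config$outputDir, paste0("state-", state))
  dir.create(sdir, showWarnings = FALSE, recursive = TRUE)

  bf <- bFactors(ens)
  nodes <- nodeTable(ens)
  utils::write.table(
    data.frame(node = nodeKeys(nodes), msf = bf@msf, B = bf@B),
    file.path(sdir, "bfactors.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  writeAnnotatedPDB(nodes, bFactorValues(bf), s$topology,
                    file.path(sdir, "bfactors.pdb"))

  pca <- principalModes(ens, nModes = config$nModes)
  ev <- pca@eigenvalues
  utils::write.table(
    data.frame(mode = seq_len(config$nModes),
               eigenvalue = ev[seq_len(config$nModes)],
               varianceFraction = ev[seq_len(config$nModes)] / sum(ev)),
    file.path(sdir, "pca-eigenvalues.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    data.frame(frame = seq_len(nrow(pca@projections)), pca@projections),
    file.path(sdir, "pca-projections.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(list(ensemble = ens, bfactors = bf, pca = pca))
}

#' Map a mutation table onto dynamic communities
#'
#' Runs the dCNA partitioning (consensus partition when two or more states
#' are configured, the single state's own partition otherwise), classifies
#' every mutation as internal or interfacial in each state's contact
#' network, and reports cross-state reclassification plus a
#' phenotype-by-classification contingency summary.
#'
#' @param config a configuration from [runConfig()] with a `mutations` path.
#' @param ensembles optional named list of pre-loaded ensembles.
#' @return invisibly, a list with per-state `assignments`, `comparisons`
#'   (one per transition), and the `contingency` table of the first state.
#' @export
runMutationMap <- function(config, ensembles = NULL) {
  stopifnot(inherits(config, "dcnaRunConfig"))
  if (is.null(config$mutations))
    stop("config error: no mutation table configured")
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)

  nets <- list(); partition <- NULL
  if (length(config$states) >= 2L) {
    run <- runDCNA(config, ensembles = ensembles)
    nets <- run$networks
    partition <- run$partition
    classifyNet <- function(label) run$consensus
  } else {
    s <- config$states[[1]]
    ens <- if (!is.null(ensembles)) ensembles[[s$label]]
           else .loadState(config, s)
    P <- contactProbability(ens, cutoff = config$cutoff,
                            exclusion = config$exclusion,
                            geometry = config$geometry)
    nets[[s$label]] <- buildNetwork(P, mode = "dcna")
    partition <- girvanNewman(nets[[s$label]],
                              stopDeltaQ = config$stopDeltaQ)
    classifyNet <- function(label) nets[[label]]
  }

  firstNodes <- nodeTable(nets[[1]])
  muts <- loadMutations(config$mutations, nodes = firstNodes)
  nUnresolved <- sum(!muts$resolved)
  if (nUnresolved == nrow(muts))
    stop("no mutation could be resolved against the topology")
  if (nUnresolved > 0L)
    warning(nUnresolved, " mutation(s) unresolved; reported as such")

  assignments <- list()
  for (label in names(nets)) {
    asg <- classifyInterfacial(muts, partition, classifyNet(label),
                               state = label)
    utils::write.table(
      asg, file.path(config$outputDir,
                     paste0("mutations-", label, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    assignments[[label]] <- asg
  }

  comparisons <- list()
  for (tr in config$transitions %||% list()) {
    cmp <- compareStates(assignments[[tr[1]]], assignments[[tr[2]]])
    nm <- paste0(tr[1], "-to-", tr[2])
    utils::write.table(
      cmp$table, file.path(config$outputDir,
                           paste0("mutations-reclassified-", nm, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    comparisons[[nm]] <- cmp
  }

  contingency <- phenotypeContingency(assignments[[1]])
  summ <- list(
    n_mutations = nrow(muts), n_unresolved = nUnresolved,
    states = names(assignments),
    reclassification = lapply(comparisons, function(x) as.list(x$summary)))
  jsonlite::write_json(summ,
                       file.path(config$outputDir, "mutations-summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(assignments = assignments, comparisons = comparisons,
                 contingency = contingency, partition = partition))
}
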