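## Mapping of disease mutations onto dynamic community partitions:
## internal vs interfacial classification and cross-state comparison.

PHENOTYPES <- c("XP", "TTD", "XP/CS", "XP/TTD")
AA1 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Load a mutation annotation table
#'
#' Reads a TSV with columns `subunit`, `chain_id`, `wild_type` (1-letter),
#' `position` (author numbering), `mutant` (1-letter), `phenotype` (one of
#' XP, TTD, XP/CS, XP/TTD) and optional `note`. When a node table is
#' supplied, each mutation is resolved to its network node by
#' (chain, position) and the annotated wild-type letter is cross-checked
#' against the topology's residue name; mismatches keep the record but emit
#' a warning.
#'
#' @param path TSV path.
#' @param nodes optional node table for resolution and wild-type checks.
#' @return `data.frame` of mutation records with a `node` column (`NA` when
#'   unresolved) and logical `resolved`.
#' @export
loadMutations <- function(path, nodes = NULL) {
  mut <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  required <- c("subunit", "chain_id", "wild_type", "position", "mutant",
                "phenotype")
  missing <- setdiff(required, names(mut))
  if (length(missing))
    stop("mutation table lacks columns: ", paste(missing, collapse = ", "))
  if (nrow(mut) == 0L) {
    warning("empty mutation table")
    mut$node <- integer(0); mut$resolved <- logical(0)
    return(mut)
  }
  bad <- which(!mut$wild_type %in% AA1 | !mut$mutant %in% AA1)
  if (length(bad))
    stop("parse error at line ", bad[1] + 1L,
         ": invalid 1-letter residue code")
  badp <- which(!mut$phenotype %in% PHENOTYPES)
  if (length(badp))
    stop("parse error at line ", badp[1] + 1L, ": phenotype must be one of ",
         paste(PHENOTYPES, collapse = ", "))
  mut$position <- as.integer(mut$position)
  if (anyNA(mut$position)) stop("parse error: non-integer position")
  if (!"note" %in% names(mut)) mut$note <- ""

  mut$node <- NA_integer_
  mut$resolved <- FALSE
  if (!is.null(nodes)) {
    validateNodeTable(nodes)
    mut$node <- match(paste(mut$chain_id, mut$position),
                      paste(nodes$chain, nodes$resno))
    mut$resolved <- !is.na(mut$node)
    chk <- which(mut$resolved)
    if (length(chk)) {
      topo1 <- suppressWarnings(bio3d::aa321(nodes$resid[mut$node[chk]]))
      mismatch <- chk[!is.na(topo1) & topo1 != mut$wild_type[chk]]
      if (length(mismatch))
        warning("wild-type letter disagrees with topology for ",
                length(mismatch), " mutation(s), e.g. ",
                mut$subunit[mismatch[1]], " ", mut$wild_type[mismatch[1]],
                mut$position[mismatch[1]], mut$mutant[mismatch[1]],
                "; records kept")
    }
  }
  mut
}

#' Classify mutations as internal or interfacial
#'
#' A mutation is interfacial when its residue node has at least one network
#' edge to a node of a different dynamic community; its interface partners
#' are the community pairs so connected. The classification is invariant
#' under community relabelling. Unresolved mutations are carried through
#' with classification `"unresolved"` so every loaded mutation appears
#' exactly once in each per-state report.
#'
#' @param mutations mutation records from [loadMutations()] (resolved
#'   against the state's node table).
#' @param partition a [CommunityPartition-class] for the state.
#' @param network the [ContactNetwork-class] or [ConsensusNetwork-class]
#'   whose edges define residue contacts.
#' @param state optional state label recorded in the output.
#' @return `data.frame`: one row per mutation with `community`,
#'   `classification` (`internal`/`interfacial`/`unresolved`), `partners`
#'   (comma-separated community pairs, e.g. `"2-5"`) and
#'   `nForeignContacts`.
#' @export
classifyInterfacial <- function(mutations, partition, network, state = "") {
  stopifnot(is(partition, "CommunityPartition"))
  nodes <- nodeTable(network)
  keys <- nodeKeys(nodes)
  idx <- match(keys, names(partition@membership))
  if (anyNA(idx)) stop("partition does not cover the network's nodes")
  lab <- as.integer(partition@membership[idx])
  e <- edgeTable(network)

  ## adjacency list once
  adj <- vector("list", nrow(nodes))
  for (r in seq_len(nrow(e))) {
    adj[[e$i[r]]] <- c(adj[[e$i[r]]], e$j[r])
    adj[[e$j[r]]] <- c(adj[[e$j[r]]], e$i[r])
  }

  ## re-resolve against this network's node table (it may be a consensus
  ## subset of the state the mutations were loaded on)
  node <- match(paste(mutations$chain_id, mutations$position),
                paste(nodes$chain, nodes$resno))

  out <- mutations[, c("subunit", "chain_id", "wild_type", "position",
                       "mutant", "phenotype")]
  out$state <- state
  out$community <- ifelse(is.na(node), NA_integer_, lab[node])
  out$classification <- "unresolved"
  out$partners <- ""
  out$nForeignContacts <- 0L
  for (r in which(!is.na(node))) {
    v <- node[r]
    nb <- adj[[v]]
    foreign <- nb[lab[nb] != lab[v]]
    if (length(foreign)) {
      pairs <- unique(paste0(pmin(lab[v], lab[foreign]), "-",
                             pmax(lab[v], lab[foreign])))
      out$classification[r] <- "interfacial"
      out$partners[r] <- paste(sort(pairs), collapse = ",")
      out$nForeignContacts[r] <- length(foreign)
    } else {
      out$classification[r] <- "internal"
    }
  }
  rownames(out) <- NULL
  out
}

#' Cross-state mutation reclassification
#'
#' Joins two per-state interface assignments on the mutation identity and
#' tabulates how classifications change between states (e.g. mutations
#' internal in one functional state becoming interfacial in another).
#'
#' @param assignmentsA,assignmentsB outputs of [classifyInterfacial()] for
#'   the same mutation list in two states.
#' @return list with `table` (per-mutation classes and partner sets in both
#'   states, plus a `change` column) and `summary` (named counts:
#'   `internal_to_interfacial`, `interfacial_to_internal`, `unchanged`,
#'   `unresolved`).
#' @export
compareStates <- function(assignmentsA, assignmentsB) {
  keyOf <- function(a) paste(a$chain_id, a$position, a$wild_type, a$mutant)
  if (nrow(assignmentsA) != nrow(assignmentsB) ||
      !setequal(keyOf(assignmentsA), keyOf(assignmentsB)))
    stop("alignment error: the two assignments cover different mutations")
  b <- assignmentsB[match(keyOf(assignmentsA), keyOf(assignmentsB)), ]

  tab <- data.frame(
    subunit = assignmentsA$subunit, chain_id = assignmentsA$chain_id,
    wild_type = assignmentsA$wild_type, position = assignmentsA$position,
    mutant = assignmentsA$mutant, phenotype = assignmentsA$phenotype,
    classA = assignmentsA$classification, partnersA = assignmentsA$partners,
    classB = b$classification, partnersB = b$partners,
    stringsAsFactors = FALSE)
  tab$change <- ifelse(
    tab$classA == "unresolved" | tab$classB == "unresolved", "unresolved",
    ifelse(tab$classA == tab$classB, "unchanged",
           paste0(tab$classA, "_to_", tab$classB)))
  summary <- c(
    internal_to_interfacial = sum(tab$change == "internal_to_interfacial"),
    interfacial_to_internal = sum(tab$change == "interfacial_to_internal"),
    unchanged = sum(tab$change == "unchanged"),
    unresolved = sum(tab$change == "unresolved"))
  list(table = tab, summary = summary)
}

#' Phenotype-by-classification contingency table
#'
#' @param assignments output of [classifyInterfacial()].
#' @return a contingency `table` of phenotype vs classification.
#' @export
phenotypeContingency <- function(assignments) {
  table(phenotype = assignments$phenotype,
        classification = assignments$classification)
}
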