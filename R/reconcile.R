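## Parsimony inference of per-lineage duplication/loss events from leaf
## copy numbers.  Two phases per family:
##   1. Dollo presence/absence: the family originates at the root; a node
##      may have zero copies only when every descendant leaf has zero
##      (no regain after extinction).
##   2. Sankoff dynamic program on copy number over the remaining nodes,
##      states 0..(max count + 1), edge cost |parent - child| where each
##      +1 step is one duplication event and each -1 step one loss event.
## Gene-tree knowledge enters as constraints: species-specific-paralog
## assertions force duplications onto terminal branches; forbidden-clade
## entries veto duplications on a clade's stem.

#' Build a constraint set for event inference
#'
#' @param speciesSpecific \code{data.frame} with columns \code{family},
#'   \code{taxon}, \code{min_dup}: the terminal branch of \code{taxon}
#'   must carry at least \code{min_dup} duplications of \code{family}
#'   (the paralogs are species-specific, so an ancestral duplication is
#'   disallowed as their single origin).
#' @param forbiddenClades \code{data.frame} with columns \code{family},
#'   \code{clade_id}: no duplication may be placed on the stem branch of
#'   the named clade.
#' @return a \code{ConstraintSet} (list with the two components).
#' @export
constraintSet <- function(speciesSpecific = NULL, forbiddenClades = NULL) {
  if (is.null(speciesSpecific))
    speciesSpecific <- data.frame(family = character(), taxon = character(),
                                  min_dup = integer())
  if (is.null(forbiddenClades))
    forbiddenClades <- data.frame(family = character(), clade_id = character())
  structure(list(speciesSpecific = speciesSpecific,
                 forbiddenClades = forbiddenClades),
            class = "ConstraintSet")
}

#' Read a constraint set from YAML
#'
#' Expected layout: top-level keys \code{species_specific} (list of
#' \{family, taxon, min_dup\}) and \code{forbidden_clades} (list of
#' \{family, clade_id\}).
#'
#' @param path YAML file path.
#' @return a \code{ConstraintSet}.
#' @export
readConstraints <- function(path) {
  y <- yaml::read_yaml(path)
  ss <- if (length(y$species_specific))
    do.call(rbind, lapply(y$species_specific, function(e)
      data.frame(family = e$family, taxon = e$taxon,
                 min_dup = as.integer(e$min_dup))))
  fc <- if (length(y$forbidden_clades))
    do.call(rbind, lapply(y$forbidden_clades, function(e)
      data.frame(family = e$family, clade_id = e$clade_id)))
  constraintSet(ss, fc)
}

## core single-family DP; returns list(events = data.frame, cost = total)
.inferFamilyDP <- function(tree, leafCounts, rootCount, family,
                           constraints = NULL) {
  ph <- tree@phylo
  ntip <- length(ph$tip.label)
  nn <- ntip + ph$Nnode
  ids <- tree@nodeData$id
  miss <- setdiff(ph$tip.label, names(leafCounts))
  if (length(miss))
    stop("missing leaf count(s) for: ", paste(miss, collapse = ", "))
  cnt <- as.integer(leafCounts[ph$tip.label])
  if (any(cnt < 0)) stop("leaf counts must be non-negative")
  root <- .rootNode(ph)
  ch <- .nodeChildren(ph)
  tu <- .tipsUnder(ph)
  absent <- vapply(seq_len(nn), function(v) all(cnt[tu[[v]]] == 0L),
                   logical(1))

  if (rootCount == 0L) {
    if (any(cnt > 0L))
      stop("infeasible: root count 0 but family ", family,
           " present in extant taxa (single-origin constraint)")
    return(list(events = .emptyEvents(), cost = 0L))
  }

  maxState <- max(cnt, rootCount) + 1L
  states <- 0:maxState

  ## per-edge constraint lookups (by child node index)
  minDup <- integer(nn)
  noDup <- logical(nn)
  if (!is.null(constraints)) {
    ss <- constraints$speciesSpecific
    ss <- ss[ss$family == family, , drop = FALSE]
    if (nrow(ss)) {
      k <- match(ss$taxon, ph$tip.label)
      if (anyNA(k))
        stop("constraint references unknown taxon: ",
             paste(ss$taxon[is.na(k)], collapse = ", "))
      minDup[k] <- as.integer(ss$min_dup)
      bad <- which(cnt[k] - minDup[k] < 0L)
      if (length(bad))
        stop("infeasible constraint: taxon ", ph$tip.label[k[bad[1]]],
             " has ", cnt[k[bad[1]]], " copies of ", family,
             " but must carry >= ", minDup[k[bad[1]]],
             " terminal duplications")
      ## a terminal duplication requires the parent to hold fewer copies
      ## than the leaf; with 0 copies at the leaf the edge cannot dup
    }
    fc <- constraints$forbiddenClades
    fc <- fc[fc$family == family, , drop = FALSE]
    if (nrow(fc)) {
      k <- match(fc$clade_id, ids)
      if (anyNA(k))
        stop("constraint references unknown clade: ",
             paste(fc$clade_id[is.na(k)], collapse = ", "))
      noDup[k] <- TRUE
    }
  }

  ## allowed state mask per node
  allowed <- matrix(FALSE, nn, maxState + 1L)
  for (v in seq_len(nn)) {
    if (v <= ntip) allowed[v, cnt[v] + 1L] <- TRUE
    else if (v == root) allowed[v, min(rootCount, maxState) + 1L] <- TRUE
    else if (absent[v]) allowed[v, 1L] <- TRUE
    else allowed[v, states >= 1L] <- TRUE
  }

  cost <- matrix(Inf, nn, maxState + 1L)
  for (v in .postorderNodes(ph)) {
    if (v <= ntip) { cost[v, allowed[v, ]] <- 0; next }
    for (s in states[allowed[v, ]]) {
      tot <- 0
      for (c2 in ch[[v]]) {
        ec <- abs(states - s)                   # edge cost to child state t
        if (minDup[c2] > 0L)                    # forced terminal duplication
          ec[states - s < minDup[c2]] <- Inf
        if (noDup[c2]) ec[states > s] <- Inf    # no duplication on this stem
        tot <- tot + min(ec + cost[c2, ])
      }
      cost[v, s + 1L] <- tot
    }
  }

  best <- cost[root, rootCount + 1L]
  if (!is.finite(best))
    stop("infeasible constraints: no event assignment explains the counts",
         " of family ", family)

  ## backtrace, tie-break: smallest child state (keeps ancestral copy
  ## numbers low, i.e. pushes duplications toward the tips and places
  ## losses at the roots of extinct clades)
  assign <- integer(nn)
  assign[root] <- rootCount
  ord <- rev(.postorderNodes(ph))               # preorder
  ev <- list()
  for (v in ord) {
    s <- assign[v]
    for (c2 in ch[[v]]) {
      ec <- abs(states - s)
      if (minDup[c2] > 0L) ec[states - s < minDup[c2]] <- Inf
      if (noDup[c2]) ec[states > s] <- Inf
      tot <- ec + cost[c2, ]
      t <- states[which.min(tot)]               # which.min takes first = smallest
      assign[c2] <- t
      if (t != s)
        ev[[length(ev) + 1L]] <- data.frame(
          lineage_id = ids[c2], family = family,
          n_dup = max(0L, t - s), n_loss = max(0L, s - t))
    }
  }
  events <- if (length(ev)) do.call(rbind, ev) else .emptyEvents()
  list(events = events, cost = best)
}

.emptyEvents <- function() {
  data.frame(lineage_id = character(), family = character(),
             n_dup = integer(), n_loss = integer())
}

#' Infer minimal duplication/loss events for one family
#'
#' Finds an ancestral copy-number assignment of minimal total event
#' count (each event is a +-1 change on a branch) explaining the leaf
#' counts, under the single-origin (Dollo) rule that a family lost in a
#' clade is never regained, and under optional gene-tree constraints.
#' Ties are broken deterministically toward the smallest ancestral
#' state, which places duplications as late (tipward) as possible.
#'
#' @param tree a \linkS4class{SpeciesTree}.
#' @param leafCounts named non-negative integers, one per tip.
#' @param rootCount copy number at the root (default: the family's
#'   entry in \code{\link{ancestralProfile}}, else 1).
#' @param family family label.
#' @param constraints a \code{\link{constraintSet}} or \code{NULL}.
#' @return an \linkS4class{EventMap} for the family.
#' @examples
#' tr <- parseNewick("(((Ehis,Enut),Einv),Out);")
#' ev <- inferEvents(tr, c(Ehis = 0, Enut = 0, Einv = 0, Out = 1),
#'                   rootCount = 1, family = "ORC2")
#' eventTable(ev)  # a single loss on the Entamoeba stem lineage
#' @export
inferEvents <- function(tree, leafCounts, rootCount = NULL,
                        family = "family", constraints = NULL) {
  if (is.null(rootCount)) {
    ap <- ancestralProfile()
    rootCount <- if (family %in% names(ap)) unname(ap[family]) else 1L
  }
  res <- .inferFamilyDP(tree, leafCounts, as.integer(rootCount), family,
                        constraints)
  new("EventMap", events = res$events,
      rootCounts = setNames(as.integer(rootCount), family))
}

#' Infer events for every family of a copy-number matrix
#'
#' @param tree a \linkS4class{SpeciesTree} whose tips match the matrix
#'   taxa.
#' @param x a \linkS4class{CopyNumberMatrix}.
#' @param rootProfile named per-family root counts (default
#'   \code{\link{ancestralProfile}} entries where present, else 1).
#' @param constraints a \code{\link{constraintSet}} or \code{NULL}.
#' @return a combined \linkS4class{EventMap}.
#' @export
inferAllEvents <- function(tree, x, rootProfile = NULL, constraints = NULL) {
  fams <- families(x)
  ap <- ancestralProfile()
  rc <- vapply(fams, function(f) {
    if (!is.null(rootProfile) && f %in% names(rootProfile))
      as.integer(rootProfile[f])
    else if (f %in% names(ap)) unname(ap[f]) else 1L
  }, integer(1))
  m <- copyCounts(x)
  evs <- lapply(fams, function(f)
    .inferFamilyDP(tree, setNames(m[, f], rownames(m)), rc[f], f,
                   constraints)$events)
  new("EventMap", events = do.call(rbind, evs), rootCounts = rc)
}

#' Replay an event map down the tree
#'
#' Applies +duplications and -losses along every root-to-leaf path and
#' returns the implied leaf copy numbers; errors if any intermediate
#' count would drop below zero.
#'
#' @param tree a \linkS4class{SpeciesTree}.
#' @param events an \linkS4class{EventMap}.
#' @param family which family to replay (defaults to the only one).
#' @param rootCount override for the root copy number.
#' @return named integer vector of leaf counts.
#' @export
replayEvents <- function(tree, events, family = NULL, rootCount = NULL) {
  rc <- rootCounts(events)
  if (is.null(family)) {
    if (length(rc) != 1L)
      stop("event map covers several families; pick one")
    family <- names(rc)
  }
  if (is.null(rootCount)) {
    if (!family %in% names(rc)) stop("unknown family: ", family)
    rootCount <- rc[[family]]
  }
  ev <- events@events
  ev <- ev[ev$family == family, , drop = FALSE]
  ids <- tree@nodeData$id
  bad <- setdiff(ev$lineage_id, ids)
  if (length(bad))
    stop("events reference unknown lineage(s): ", paste(bad, collapse = ", "))
  delta <- setNames(integer(length(ids)), ids)
  if (nrow(ev)) delta[ev$lineage_id] <- ev$n_dup - ev$n_loss
  ph <- tree@phylo
  ntip <- length(ph$tip.label)
  ch <- .nodeChildren(ph)
  state <- integer(length(ids))
  root <- .rootNode(ph)
  state[root] <- rootCount
  for (v in rev(.postorderNodes(ph))) {   # preorder: parent before child
    for (c2 in ch[[v]]) {
      state[c2] <- state[v] + delta[ids[c2]]
      if (state[c2] < 0L)
        stop("loss event exceeds available copies on lineage ", ids[c2])
    }
  }
  setNames(state[seq_len(ntip)], ph$tip.label)
}

#' Tally events globally, per family, and per lineage class
#'
#' @param events an \linkS4class{EventMap} (possibly multi-family).
#' @param lineages optional \linkS4class{LineageSet}; when given, the
#'   tallies within the parasitic and WGD classes are reported too.
#' @return list with \code{global} (\code{losses}, \code{duplications}),
#'   \code{perFamily} \code{data.frame}, and (optionally)
#'   \code{perClass}.
#' @export
tallyEvents <- function(events, lineages = NULL) {
  ev <- events@events
  fams <- names(rootCounts(events))
  perFam <- data.frame(
    family = fams,
    losses = vapply(fams, function(f) sum(ev$n_loss[ev$family == f]),
                    numeric(1)),
    duplications = vapply(fams, function(f) sum(ev$n_dup[ev$family == f]),
                          numeric(1)),
    row.names = NULL)
  out <- list(
    global = c(losses = sum(perFam$losses),
               duplications = sum(perFam$duplications)),
    perFamily = perFam)
  if (!is.null(lineages)) {
    inPar <- ev$lineage_id %in% lineages@ids[lineages@parasitic]
    inWgd <- ev$lineage_id %in% lineages@ids[lineages@wgd]
    out$perClass <- data.frame(
      class = c("parasitic", "wgd"),
      losses = c(sum(ev$n_loss[inPar]), sum(ev$n_loss[inWgd])),
      duplications = c(sum(ev$n_dup[inPar]), sum(ev$n_dup[inWgd])))
  }
  out
}
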