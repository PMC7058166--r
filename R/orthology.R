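## Phylogenetic-placement classification of candidate sequences into
## subunit families, and removal of false species-specific paralogs.
## Inputs are reference-labeled gene trees (Newick, leaf names
## "seqid|species|family" for references, "seqid|species" for queries);
## the homology-search stages producing them are upstream of this
## package.  The confidence tiers (bona_fide >= 2 supporting reference
## leaves, likely = 1, uncertain = none below the root) are an explicit,
## testable reconstruction of the bona-fide/likely vocabulary.

.poolFamily <- function(f) ifelse(f %in% c("CDC6", "ORC1"), "CDC6/ORC1", f)

#' Read a reference-labeled gene tree
#'
#' @param newick path to (or text of) a Newick gene tree whose leaf
#'   labels are pipe-delimited \code{seqid|species|family} (references)
#'   or \code{seqid|species} (queries).  CDC6 and ORC1 reference labels
#'   are pooled into the single \code{CDC6/ORC1} family.
#' @return list with \code{phylo} and a \code{leafData} data.frame
#'   (\code{seqid}, \code{species}, \code{family}; \code{NA} family
#'   marks a query).
#' @export
readGeneTree <- function(newick) {
  txt <- if (file.exists(newick))
    paste(readLines(newick, warn = FALSE), collapse = "") else newick
  ph <- ape::read.tree(text = txt)
  if (is.null(ph)) stop("malformed gene-tree Newick")
  parts <- strsplit(ph$tip.label, "|", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad))
    stop("gene-tree leaf without seqid|species annotation: ",
         paste(ph$tip.label[bad], collapse = ", "))
  leafData <- data.frame(
    seqid = vapply(parts, `[`, character(1), 1L),
    species = vapply(parts, `[`, character(1), 2L),
    family = .poolFamily(vapply(parts, function(p)
      if (length(p) >= 3L) p[3L] else NA_character_, character(1))),
    stringsAsFactors = FALSE)
  list(phylo = ph, leafData = leafData)
}

#' Classify query sequences by phylogenetic placement
#'
#' Each query receives the family of the smallest enclosing clade whose
#' reference leaves all belong to one (pooled) family: confidence
#' \code{bona_fide} when that clade holds at least two reference
#' leaves, \code{likely} when exactly one.  A query with no family-pure
#' enclosing clade below the root is \code{(unassigned, uncertain)}.
#' The result is invariant to child-order rotations of the tree.
#'
#' @param geneTree list from \code{\link{readGeneTree}}.
#' @return \code{data.frame}: \code{seqid}, \code{species},
#'   \code{family}, \code{confidence}.
#' @export
classifyByPlacement <- function(geneTree) {
  ph <- geneTree$phylo
  ld <- geneTree$leafData
  if (all(is.na(ld$family))) stop("gene tree has no reference leaves")
  ntip <- length(ph$tip.label)
  nn <- ntip + ph$Nnode
  parent <- integer(nn)
  for (i in seq_len(nrow(ph$edge))) parent[ph$edge[i, 2L]] <- ph$edge[i, 1L]
  root <- .rootNode(ph)
  tu <- .tipsUnder(ph)
  queries <- which(is.na(ld$family))
  rows <- lapply(queries, function(q) {
    v <- parent[q]
    fam <- "unassigned"; conf <- "uncertain"
    while (v != 0L) {
      refFams <- ld$family[tu[[v]]]
      refFams <- refFams[!is.na(refFams)]
      if (length(refFams) && length(unique(refFams)) == 1L) {
        fam <- refFams[1L]
        conf <- if (length(refFams) >= 2L) "bona_fide" else "likely"
        break
      }
      if (length(unique(refFams)) > 1L) break  # mixed clade: stop climbing
      v <- if (v == root) 0L else parent[v]
    }
    data.frame(seqid = ld$seqid[q], species = ld$species[q],
               family = fam, confidence = conf, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

## pairwise global identity over columns where both rows are ungapped
.pairIdentity <- function(a, b, ...) {
  aln <- globalAlign(a, b, ...)
  cols <- list(ref = strsplit(aln@ref, "")[[1]],
               query = strsplit(aln@query, "")[[1]])
  unname(conservationMeasures(cols)["identity"])
}

#' Remove false species-specific paralogs
#'
#' Within each (species, family) group, sequences connected by pairwise
#' global identity >= \code{identityThreshold} (single linkage) are
#' collapsed to the single longest representative (ties to the
#' alphabetically first id).  The last member of a group is never
#' removed.
#'
#' @param assignments \code{data.frame} from
#'   \code{\link{classifyByPlacement}} (or any table with \code{seqid},
#'   \code{species}, \code{family}).
#' @param sequences named character vector covering every assigned id.
#' @param identityThreshold collapse threshold in [0, 1], default 0.95.
#' @param ... alignment parameters passed to \code{\link{globalAlign}}.
#' @return list with \code{assignments} (input plus logical
#'   \code{retained}) and \code{log} (\code{data.frame} of removals:
#'   \code{removed}, \code{kept}, \code{identity}, \code{species},
#'   \code{family}).
#' @export
filterFalseParalogs <- function(assignments, sequences,
                                identityThreshold = 0.95, ...) {
  miss <- setdiff(assignments$seqid, names(sequences))
  if (length(miss))
    stop("missing sequence(s) for: ", paste(miss, collapse = ", "))
  assignments$retained <- TRUE
  logRows <- list()
  groups <- split(seq_len(nrow(assignments)),
                  paste(assignments$species, assignments$family, sep = "\r"))
  for (g in groups) {
    if (length(g) < 2L) next
    ids <- assignments$seqid[g]
    k <- length(ids)
    sim <- matrix(0, k, k, dimnames = list(ids, ids))
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k)
      sim[i, j] <- sim[j, i] <-
        .pairIdentity(sequences[[ids[i]]], sequences[[ids[j]]], ...)
    ## single-linkage components at the threshold
    comp <- seq_len(k)
    repeat {
      changed <- FALSE
      for (i in seq_len(k - 1L)) for (j in (i + 1L):k)
        if (sim[i, j] >= identityThreshold && comp[i] != comp[j]) {
          comp[comp == comp[j]] <- comp[i]; changed <- TRUE
        }
      if (!changed) break
    }
    for (cc in unique(comp)) {
      members <- which(comp == cc)
      if (length(members) < 2L) next
      lens <- nchar(sequences[ids[members]])
      keep <- members[order(-lens, ids[members])][1L]
      for (m in setdiff(members, keep)) {
        assignments$retained[g[m]] <- FALSE
        logRows[[length(logRows) + 1L]] <- data.frame(
          removed = ids[m], kept = ids[keep],
          identity = max(sim[m, setdiff(members, m)]),
          species = assignments$species[g[m]],
          family = assignments$family[g[m]], stringsAsFactors = FALSE)
      }
    }
  }
  list(assignments = assignments,
       log = if (length(logRows)) do.call(rbind, logRows) else
         data.frame(removed = character(), kept = character(),
                    identity = numeric(), species = character(),
                    family = character()))
}
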