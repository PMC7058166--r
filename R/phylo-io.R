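## Tree parsing, serialization, lineage bookkeeping and the ancestral
## lifestyle rule.  Newick I/O is delegated to ape; everything here adds
## the annotation layer and the validation ape does not do.

.nodeChildren <- function(ph) {
  nn <- length(ph$tip.label) + ph$Nnode
  ch <- vector("list", nn)
  if (!is.null(ph$edge))
    for (i in seq_len(nrow(ph$edge)))
      ch[[ph$edge[i, 1L]]] <- c(ch[[ph$edge[i, 1L]]], ph$edge[i, 2L])
  ch
}

.rootNode <- function(ph) {
  ntip <- length(ph$tip.label)
  if (ntip == 1L && ph$Nnode == 1L) return(2L)
  setdiff(seq_len(ntip + ph$Nnode), ph$edge[, 2L])
}

## tips (indices) under each node, postorder accumulation
.tipsUnder <- function(ph) {
  ntip <- length(ph$tip.label)
  nn <- ntip + ph$Nnode
  ch <- .nodeChildren(ph)
  out <- vector("list", nn)
  for (i in seq_len(ntip)) out[[i]] <- i
  ord <- .postorderNodes(ph)
  for (v in ord)
    if (v > ntip) out[[v]] <- unlist(out[ch[[v]]], use.names = FALSE)
  out
}

## node indices in postorder (children before parents)
.postorderNodes <- function(ph) {
  ntip <- length(ph$tip.label)
  nn <- ntip + ph$Nnode
  ch <- .nodeChildren(ph)
  out <- integer(0)
  stack <- .rootNode(ph)
  seen <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    seen <- c(seen, v)
    stack <- c(stack, ch[[v]])
  }
  rev(seen)
}

.lineageIdsPhylo <- function(ph) {
  ntip <- length(ph$tip.label)
  tu <- .tipsUnder(ph)
  base <- vapply(seq_along(tu), function(v) {
    if (v <= ntip) return(ph$tip.label[v])
    labs <- sort(ph$tip.label[tu[[v]]])
    paste0(labs[1L], "..", labs[length(labs)])
  }, character(1))
  ## nested clades can share both extreme labels; the largest clade keeps
  ## the bare id, strictly smaller ones get a deterministic #k suffix
  ids <- base
  for (b in unique(base[duplicated(base)])) {
    hits <- which(base == b)
    hits <- hits[order(-lengths(tu[hits]), hits)]
    for (k in seq_along(hits)[-1L])
      ids[hits[k]] <- paste0(b, "#", k)
  }
  ids
}

.freshNodeData <- function(ph) {
  ntip <- length(ph$tip.label)
  nn <- ntip + ph$Nnode
  data.frame(
    node = seq_len(nn),
    id = .lineageIdsPhylo(ph),
    isLeaf = seq_len(nn) <= ntip,
    parasitic = NA,
    wgd = "none",
    centrioles = NA,
    stringsAsFactors = FALSE)
}

#' Construct a SpeciesTree from an ape phylo object
#'
#' @param phylo a rooted \code{ape::phylo}.
#' @param annotations optional \code{data.frame} as returned by
#'   \code{\link{readNodeAnnotations}}.
#' @return a \linkS4class{SpeciesTree}.
#' @export
speciesTree <- function(phylo, annotations = NULL) {
  st <- new("SpeciesTree", phylo = phylo, nodeData = .freshNodeData(phylo))
  if (!is.null(annotations)) st <- annotateTree(st, annotations)
  st
}

#' Parse a Newick string into a SpeciesTree
#'
#' Accepts strict Newick with plain or single-quoted labels;
#' multifurcations are preserved and single-leaf trees (\code{"(A);"})
#' are accepted.  Unbalanced parentheses and duplicate leaf labels are
#' rejected with an error naming the offending token.
#'
#' @param text a Newick string.
#' @return a \linkS4class{SpeciesTree} with all annotations unset.
#' @examples
#' parseNewick("((A,B),C);")
#' @export
parseNewick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  ## strip quoted labels before the balance check
  bare <- gsub("'[^']*'", "x", text)
  opens <- lengths(regmatches(bare, gregexpr("\\(", bare)))
  closes <- lengths(regmatches(bare, gregexpr("\\)", bare)))
  if (opens != closes)
    stop("unbalanced parentheses in Newick input ('(' x ", opens,
         " vs ')' x ", closes, ")")
  ph <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(ph)) stop("malformed Newick string: ", text)
  tl <- ph$tip.label
  if (anyDuplicated(tl))
    stop("duplicate leaf label(s): ",
         paste(unique(tl[duplicated(tl)]), collapse = ", "))
  speciesTree(ph)
}

#' Serialize a SpeciesTree back to Newick
#'
#' @param tree a \linkS4class{SpeciesTree}.
#' @return a Newick string; \code{parseNewick(writeNewick(tree))} is
#'   isomorphic to \code{tree}.
#' @export
writeNewick <- function(tree) {
  ape::write.tree(tree@phylo)
}

#' Read a species tree, optionally with its annotation sidecar
#'
#' @param newick path to a Newick file.
#' @param annotations optional path to the node-annotation TSV (columns
#'   \code{node_id}, \code{parasitic} \{0,1\}, \code{wgd}
#'   \{none,reported,uncertain\}, \code{centrioles} \{0,1,NA\}).
#' @return a \linkS4class{SpeciesTree}.
#' @export
readSpeciesTree <- function(newick, annotations = NULL) {
  txt <- paste(readLines(newick, warn = FALSE), collapse = "")
  tr <- parseNewick(txt)
  if (!is.null(annotations)) tr <- annotateTree(tr, readNodeAnnotations(annotations))
  tr
}

#' @rdname readSpeciesTree
#' @param path path to the annotation TSV.
#' @export
readNodeAnnotations <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("node_id", "parasitic", "wgd", "centrioles")
  if (!all(need %in% names(ann)))
    stop("annotation table must have columns: ", paste(need, collapse = ", "))
  ann
}

#' Attach node annotations to a tree
#'
#' Nodes are addressed by lineage id: the tip label for tips, or the
#' alphabetically first and last descendant tip labels joined by
#' \code{".."} for internal nodes.
#'
#' @param tree a \linkS4class{SpeciesTree}.
#' @param annotations \code{data.frame} with columns \code{node_id},
#'   \code{parasitic}, \code{wgd}, \code{centrioles}.
#' @return the annotated \linkS4class{SpeciesTree}.
#' @export
annotateTree <- function(tree, annotations) {
  nd <- tree@nodeData
  hit <- match(annotations$node_id, nd$id)
  if (anyNA(hit))
    stop("unknown node id(s): ",
         paste(annotations$node_id[is.na(hit)], collapse = ", "))
  if ("parasitic" %in% names(annotations)) {
    p <- as.logical(as.integer(annotations$parasitic))
    nd$parasitic[hit[!is.na(p)]] <- p[!is.na(p)]
  }
  if ("wgd" %in% names(annotations)) {
    w <- as.character(annotations$wgd)
    bad <- setdiff(unique(w[!is.na(w)]), c("none", "reported", "uncertain"))
    if (length(bad)) stop("invalid wgd category: ", paste(bad, collapse = ", "))
    nd$wgd[hit] <- ifelse(is.na(w), nd$wgd[hit], w)
  }
  if ("centrioles" %in% names(annotations)) {
    ce <- as.logical(as.integer(annotations$centrioles))
    nd$centrioles[hit[!is.na(ce)]] <- ce[!is.na(ce)]
  }
  tree@nodeData <- nd
  validObject(tree)
  tree
}

#' Propagate parasitic lifestyle to ancestral lineages
#'
#' A tip is parasitic iff it appears in \code{parasiticLeaves}; an
#' internal lineage is parasitic iff \emph{all} its descendant tips are
#' parasitic.  The operation is idempotent.
#'
#' @param tree a \linkS4class{SpeciesTree}.
#' @param parasiticLeaves character vector of tip labels.
#' @return the \linkS4class{SpeciesTree} with \code{parasitic} set on
#'   every node.
#' @export
propagateLifestyle <- function(tree, parasiticLeaves) {
  ph <- tree@phylo
  unknown <- setdiff(parasiticLeaves, ph$tip.label)
  if (length(unknown))
    stop("unknown leaf label(s): ", paste(unknown, collapse = ", "))
  ntip <- length(ph$tip.label)
  tu <- .tipsUnder(ph)
  leafPar <- ph$tip.label %in% parasiticLeaves
  tree@nodeData$parasitic <- vapply(seq_len(nLineages(tree)),
    function(v) all(leafPar[tu[[v]]]), logical(1))
  tree
}

#' Enumerate the lineages of a tree with their class masks
#'
#' Every node (root included) is one lineage, so a fully binary tree
#' with \eqn{n} tips yields \eqn{2n - 1} lineages.  The WGD mask
#' includes lineages flagged \code{"reported"}; branches where a WGD is
#' reported only by some sources (\code{"uncertain"}) are excluded
#' unless \code{includeUncertainWGD = TRUE}.
#'
#' @param tree a \linkS4class{SpeciesTree}.
#' @param includeUncertainWGD include \code{"uncertain"} branches in the
#'   WGD mask.
#' @return a \linkS4class{LineageSet}.
#' @export
countLineages <- function(tree, includeUncertainWGD = FALSE) {
  nd <- tree@nodeData
  wgdCats <- if (includeUncertainWGD) c("reported", "uncertain") else "reported"
  new("LineageSet",
      ids = nd$id,
      parasitic = !is.na(nd$parasitic) & nd$parasitic,
      wgd = nd$wgd %in% wgdCats)
}

#' Reroot a species tree on the branch above a named node
#'
#' Thin utility over \code{ape::root}; annotations for surviving node
#' ids are carried over, new internal nodes start unset.
#'
#' @param tree a \linkS4class{SpeciesTree}.
#' @param nodeId lineage id naming the outgroup node.
#' @return the rerooted \linkS4class{SpeciesTree}.
#' @export
rerootTree <- function(tree, nodeId) {
  nd <- tree@nodeData
  k <- match(nodeId, nd$id)
  if (is.na(k)) stop("unknown node id: ", nodeId)
  ph <- tree@phylo
  ph2 <- ape::root(ph, node = if (nd$isLeaf[k]) NULL else nd$node[k],
                   outgroup = if (nd$isLeaf[k]) nd$id[k] else NULL,
                   resolve.root = TRUE)
  out <- speciesTree(ph2)
  keep <- intersect(out@nodeData$id, nd$id)
  ann <- nd[nd$id %in% keep, c("id", "parasitic", "wgd", "centrioles")]
  names(ann)[1] <- "node_id"
  ann$parasitic <- as.integer(ann$parasitic)
  ann$centrioles <- as.integer(ann$centrioles)
  annotateTree(out, ann)
}
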