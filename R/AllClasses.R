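#' @import methods
#' @importFrom stats setNames
NULL

setOldClass("phylo")

#' Annotated rooted species tree
#'
#' Wraps an \code{ape} \code{phylo} tree together with per-node annotations.
#' Every node of the tree (tips and internal nodes, root included) is a
#' \emph{lineage}: the node plus the branch subtending it.  For a fully
#' binary tree with \eqn{n} tips there are \eqn{2n - 1} lineages.
#'
#' Annotations carried per node:
#' \describe{
#'   \item{parasitic}{logical; for internal nodes set by
#'     \code{\link{propagateLifestyle}} (parasitic iff all descendant tips
#'     are parasitic). \code{NA} when unset.}
#'   \item{wgd}{one of \code{"none"}, \code{"reported"}, \code{"uncertain"};
#'     whether at least one whole-genome duplication is reported on the
#'     branch subtending the node.}
#'   \item{centrioles}{logical, meaningful for tips only; \code{NA} when
#'     unknown.}
#' }
#'
#' @slot phylo an \code{ape::phylo} rooted tree.
#' @slot nodeData \code{data.frame} with one row per node (tips first,
#'   then internal nodes in \code{phylo} numbering): columns \code{node},
#'   \code{id}, \code{isLeaf}, \code{parasitic}, \code{wgd},
#'   \code{centrioles}.
#' @seealso \code{\link{speciesTree}}, \code{\link{parseNewick}},
#'   \code{\link{countLineages}}
#' @export
setClass("SpeciesTree",
  slots = c(phylo = "phylo", nodeData = "data.frame"))

setValidity("SpeciesTree", function(object) {
  ph <- object@phylo
  msgs <- character()
  tips <- ph$tip.label
  if (anyDuplicated(tips))
    msgs <- c(msgs, paste0("duplicate leaf labels: ",
      paste(unique(tips[duplicated(tips)]), collapse = ", ")))
  nn <- length(tips) + ph$Nnode
  if (nrow(object@nodeData) != nn)
    msgs <- c(msgs, "nodeData must have one row per tree node")
  if (!all(c("node", "id", "isLeaf", "parasitic", "wgd", "centrioles") %in%
        names(object@nodeData)))
    msgs <- c(msgs, "nodeData missing required columns")
  if (!all(object@nodeData$wgd %in% c("none", "reported", "uncertain")))
    msgs <- c(msgs, "wgd annotation must be none/reported/uncertain")
  # exactly one root: one node never appearing as a child
  if (length(tips) > 1) {
    kids <- ph$edge[, 2L]
    roots <- setdiff(seq_len(nn), kids)
    if (length(roots) != 1L)
      msgs <- c(msgs, "tree must have exactly one root")
  }
  if (length(msgs)) msgs else TRUE
})

#' Lineage set with class masks
#'
#' The ordered set of lineages (tree nodes, root included) of a
#' \linkS4class{SpeciesTree}, with logical masks marking the parasitic and
#' the whole-genome-duplication (WGD) lineage classes used by
#' \code{\link{enrichmentTest}}.
#'
#' @slot ids character lineage identifiers (tip label for tips; for
#'   internal nodes the alphabetically first and last descendant tip
#'   labels joined by \code{".."}).
#' @slot parasitic,wgd logical masks, parallel to \code{ids}.
#' @export
setClass("LineageSet",
  slots = c(ids = "character", parasitic = "logical", wgd = "logical"))

setValidity("LineageSet", function(object) {
  if (length(object@parasitic) != length(object@ids) ||
      length(object@wgd) != length(object@ids))
    return("class masks must be parallel to ids")
  if (anyDuplicated(object@ids)) return("lineage ids must be unique")
  TRUE
})

#' Per-taxon gene-family copy-number matrix
#'
#' Non-negative integer counts of gene-family members per taxon.  The
#' default family set pools CDC6 with ORC1 (one AAA+ ATPase initiator
#' family, \code{"CDC6/ORC1"}) followed by \code{ORC2}..\code{ORC5}.
#'
#' @slot counts integer matrix, taxa in rows (unique rownames), families
#'   in columns.
#' @seealso \code{\link{copyNumberMatrix}}, \code{\link{readCopyNumbers}},
#'   \code{\link{classifyConfiguration}}, \code{\link{summarizeCopyNumbers}}
#' @export
setClass("CopyNumberMatrix", slots = c(counts = "matrix"))

setValidity("CopyNumberMatrix", function(object) {
  m <- object@counts
  msgs <- character()
  if (nrow(m) > 0 && (is.null(rownames(m)) || anyDuplicated(rownames(m))))
    msgs <- c(msgs, "taxa labels must be present and unique")
  if (ncol(m) > 0 && nrow(m) > 0 && is.null(colnames(m)))
    msgs <- c(msgs, "family labels must be present")
  if (!is.numeric(m) || any(m < 0) || any(m != round(m)))
    msgs <- c(msgs, "counts must be non-negative integers")
  if (length(msgs)) msgs else TRUE
})

#' Per-lineage duplication/loss event map
#'
#' One row per (lineage, family) pair that carries at least one event;
#' each event changes the copy number by exactly one (a branch gaining two
#' copies carries two duplication events).  Replaying the events from the
#' family's root count down every root-to-leaf path reproduces the input
#' leaf copy numbers exactly.
#'
#' @slot events \code{data.frame} with columns \code{lineage_id},
#'   \code{family}, \code{n_dup}, \code{n_loss}.
#' @slot rootCounts named integer vector, copy number at the root per
#'   family.
#' @seealso \code{\link{inferEvents}}, \code{\link{replayEvents}},
#'   \code{\link{tallyEvents}}
#' @export
setClass("EventMap",
  slots = c(events = "data.frame", rootCounts = "numeric"))

setValidity("EventMap", function(object) {
  ev <- object@events
  need <- c("lineage_id", "family", "n_dup", "n_loss")
  if (!all(need %in% names(ev))) return("events missing required columns")
  if (nrow(ev) && (any(ev$n_dup < 0) || any(ev$n_loss < 0)))
    return("event counts must be non-negative")
  if (is.null(names(object@rootCounts))) return("rootCounts must be named")
  TRUE
})

#' Result of a statistical test
#'
#' @slot test test name.
#' @slot statistic named numeric statistic (U, rho, or the observed cell).
#' @slot p.value the P-value, one- or two-tailed as recorded in
#'   \code{tails}.
#' @slot tails \code{"one"} or \code{"two"}.
#' @slot method \code{"exact"} or \code{"normal-approximation"}.
#' @slot extra list of test-specific detail (e.g. the 2x2 table).
#' @export
setClass("StatResult",
  slots = c(test = "character", statistic = "numeric", p.value = "numeric",
            tails = "character", method = "character", extra = "list"))

setValidity("StatResult", function(object) {
  p <- object@p.value
  if (length(p) != 1L || is.na(p) || p < 0 || p > 1 + 1e-12)
    return("p.value must be a single value in [0, 1]")
  if (!object@tails %in% c("one", "two")) return("tails must be one/two")
  TRUE
})

#' Pairwise global alignment of a query against a reference
#'
#' Two equal-length gapped rows over the amino-acid alphabet, plus the
#' 1-based reference residue index of every column (\code{NA} on columns
#' where the reference row is a gap).  Degapping each row recovers the
#' input sequences.
#'
#' @slot ref,query gapped character rows (single strings).
#' @slot refIndex integer vector, one entry per column.
#' @slot score alignment score (\code{NA} for pre-aligned input).
#' @seealso \code{\link{globalAlign}}, \code{\link{alignmentPair}}
#' @export
setClass("AlignmentPair",
  slots = c(ref = "character", query = "character", refIndex = "integer",
            score = "numeric"))

setValidity("AlignmentPair", function(object) {
  r <- strsplit(object@ref, "")[[1]]
  q <- strsplit(object@query, "")[[1]]
  if (length(r) != length(q)) return("rows must have equal length")
  if (length(object@refIndex) != length(r))
    return("refIndex must have one entry per column")
  idx <- object@refIndex[r != "-"]
  if (any(is.na(idx)) || is.unsorted(idx, strictly = TRUE))
    return("reference indices must be strictly increasing over non-gap columns")
  TRUE
})
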