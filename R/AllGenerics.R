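#' @rdname SpeciesTree-class
#' @param x a \linkS4class{SpeciesTree}.
#' @export
setGeneric("treePhylo", function(x) standardGeneric("treePhylo"))

#' @rdname SpeciesTree-class
#' @export
setGeneric("nodeData", function(x) standardGeneric("nodeData"))

#' @rdname SpeciesTree-class
#' @export
setGeneric("lineageIds", function(x) standardGeneric("lineageIds"))

#' @rdname SpeciesTree-class
#' @export
setGeneric("leafLabels", function(x) standardGeneric("leafLabels"))

#' @rdname SpeciesTree-class
#' @export
setGeneric("nLineages", function(x) standardGeneric("nLineages"))

#' @rdname CopyNumberMatrix-class
#' @param x a \linkS4class{CopyNumberMatrix}.
#' @export
setGeneric("taxa", function(x) standardGeneric("taxa"))

#' @rdname CopyNumberMatrix-class
#' @export
setGeneric("families", function(x) standardGeneric("families"))

#' @rdname CopyNumberMatrix-class
#' @export
setGeneric("copyCounts", function(x) standardGeneric("copyCounts"))

#' @rdname EventMap-class
#' @param x an \linkS4class{EventMap}.
#' @export
setGeneric("eventTable", function(x) standardGeneric("eventTable"))

#' @rdname EventMap-class
#' @export
setGeneric("rootCounts", function(x) standardGeneric("rootCounts"))

#' @rdname EventMap-class
#' @export
setGeneric("totalLosses", function(x) standardGeneric("totalLosses"))

#' @rdname EventMap-class
#' @export
setGeneric("totalDuplications", function(x) standardGeneric("totalDuplications"))

setMethod("treePhylo", "SpeciesTree", function(x) x@phylo)
setMethod("nodeData", "SpeciesTree", function(x) x@nodeData)
setMethod("lineageIds", "SpeciesTree", function(x) x@nodeData$id)
setMethod("leafLabels", "SpeciesTree", function(x) x@phylo$tip.label)
setMethod("nLineages", "SpeciesTree",
  function(x) length(x@phylo$tip.label) + x@phylo$Nnode)

setMethod("taxa", "CopyNumberMatrix", function(x) rownames(x@counts))
setMethod("families", "CopyNumberMatrix", function(x) colnames(x@counts))
setMethod("copyCounts", "CopyNumberMatrix", function(x) x@counts)

setMethod("eventTable", "EventMap", function(x) x@events)
setMethod("rootCounts", "EventMap", function(x) x@rootCounts)
setMethod("totalLosses", "EventMap", function(x) sum(x@events$n_loss))
setMethod("totalDuplications", "EventMap", function(x) sum(x@events$n_dup))

setMethod("show", "SpeciesTree", function(object) {
  nd <- object@nodeData
  cat("SpeciesTree with", sum(nd$isLeaf), "taxa and", nrow(nd),
      "lineages\n")
  np <- sum(nd$parasitic, na.rm = TRUE)
  nw <- sum(nd$wgd == "reported")
  cat("  parasitic lineages:", np,
      " WGD lineages (reported):", nw, "\n")
})

setMethod("show", "LineageSet", function(object) {
  cat("LineageSet:", length(object@ids), "lineages (",
      sum(object@parasitic), "parasitic,", sum(object@wgd), "WGD )\n")
})

setMethod("show", "CopyNumberMatrix", function(object) {
  m <- object@counts
  cat("CopyNumberMatrix:", nrow(m), "taxa x", ncol(m), "families (",
      paste(colnames(m), collapse = ", "), ")\n")
  cat("  mean total copies per taxon:",
      format(mean(rowSums(m)), digits = 4), "\n")
})

setMethod("show", "EventMap", function(object) {
  cat("EventMap:", totalLosses(object), "losses,",
      totalDuplications(object), "duplications over",
      length(unique(object@events$family)), "families\n")
})

setMethod("show", "StatResult", function(object) {
  cat(object@test, " (", object@tails, "-tailed, ", object@method, ")\n",
      sep = "")
  st <- object@statistic
  cat(" ", paste(names(st), "=", format(st, digits = 6), collapse = ", "),
      ";  P =", format(object@p.value, digits = 6), "\n")
})

setMethod("show", "AlignmentPair", function(object) {
  w <- nchar(object@ref)
  cat("AlignmentPair of width", w, "\n")
  cat("  ref:  ", substr(object@ref, 1, 60),
      if (w > 60) "..." else "", "\n", sep = "")
  cat("  query:", substr(object@query, 1, 60),
      if (w > 60) "..." else "", "\n", sep = "")
})
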